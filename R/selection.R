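#' Select atoms by expression
#'
#' A small selection language for isolating parts of a structure (pore-lining
#' helices, water oxygens, single residues, ...). Keywords take one or more
#' values; `resid` values may be ranges written `a:b`. Terms combine with
#' `and`, `or`, `not` and parentheses (`not` binds tightest, then `and`).
#'
#' Grammar keywords: `name`, `resname`, `resid`, `chain`, `element`.
#'
#' Examples of expressions:
#' `"resname HOH and name O"`, `"resid 260:270 and chain A"`,
#' `"not element H"`.
#'
#' @param atoms An [atom_set].
#' @param expression Selection string.
#' @return An [atom_set] with the matching subset, in the original order.
#'   The subset may be empty; an empty selection returns a zero-row atom
#'   table wrapped without validation.
#' @export
select_atoms <- function(atoms, expression) {
  stopifnot(inherits(atoms, "atom_set"))
  keep <- selection_mask(atoms, expression)
  subset_atom_set(atoms, which(keep))
}

# Subset preserving class and metadata; tolerates an empty result.
subset_atom_set <- function(atoms, idx) {
  out <- atoms
  out$atoms <- atoms$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' @rdname select_atoms
#' @return `selection_mask` returns the logical vector over atoms instead.
#' @export
selection_mask <- function(atoms, expression) {
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, atoms$atoms)
  if (st$pos <= length(st$toks))
    sel_error(st, "unexpected token")
  mask
}

tokenize_selection <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (!length(toks) || identical(toks, ""))
    stop("selection syntax error at position 1: empty expression")
  toks
}

sel_error <- function(st, msg) {
  tok <- if (st$pos <= length(st$toks)) sprintf("'%s'", st$toks[st$pos])
         else "end of expression"
  stop(sprintf("selection syntax error at token %d (%s): %s",
               st$pos, tok, msg))
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

.sel_keywords <- c("name", "resname", "resid", "chain", "element")
.sel_reserved <- c(.sel_keywords, "and", "or", "not", "(", ")")

parse_or <- function(st, at) {
  m <- parse_and(st, at)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    m <- m | parse_and(st, at)
  }
  m
}

parse_and <- function(st, at) {
  m <- parse_not(st, at)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    m <- m & parse_not(st, at)
  }
  m
}

parse_not <- function(st, at) {
  if (!is.na(peek(st)) && peek(st) == "not") {
    advance(st)
    return(!parse_not(st, at))
  }
  parse_primary(st, at)
}

parse_primary <- function(st, at) {
  tok <- peek(st)
  if (is.na(tok)) sel_error(st, "expected a term")
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, at)
    if (is.na(peek(st)) || peek(st) != ")") sel_error(st, "expected ')'")
    advance(st)
    return(m)
  }
  if (!tok %in% .sel_keywords)
    sel_error(st, sprintf("expected a keyword (%s)",
                          paste(.sel_keywords, collapse = ", ")))
  advance(st)
  vals <- character()
  while (!is.na(peek(st)) && !peek(st) %in% .sel_reserved)
    vals <- c(vals, advance(st))
  if (!length(vals)) sel_error(st, sprintf("keyword '%s' needs a value", tok))
  keyword_mask(tok, vals, at, st)
}

keyword_mask <- function(kw, vals, at, st) {
  if (kw == "resid") {
    ids <- integer()
    for (v in vals) {
      if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
        ab <- as.integer(strsplit(v, ":")[[1]])
        ids <- c(ids, seq(ab[1], ab[2]))
      } else if (grepl("^-?[0-9]+$", v)) {
        ids <- c(ids, as.integer(v))
      } else {
        sel_error(st, sprintf("bad resid value '%s'", v))
      }
    }
    return(at$resid %in% ids)
  }
  col <- switch(kw, name = at$name, resname = at$resname,
                chain = at$chain, element = at$element)
  toupper(col) %in% toupper(vals)
}
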