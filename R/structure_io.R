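#' Construct an atom set
#'
#' The basic container for a structure or a single trajectory frame: an
#' ordered table of atom records (serial, name, residue, chain, coordinates
#' in Angstrom, element, and an optional van der Waals radius), plus an
#' optional orthorhombic box and provenance information.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z`, `element` and optionally `vdw_radius`.
#' @param box Optional numeric vector of 3 box lengths (Angstrom).
#' @param provenance Optional list (e.g. source path, model index).
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(atoms, box = NULL, provenance = list()) {
  req <- c("serial", "name", "resname", "resid", "chain", "x", "y", "z", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("atom set must be non-empty")
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a model")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  if (any(!is.na(atoms$vdw_radius) & atoms$vdw_radius <= 0))
    stop("assigned vdw_radius values must be positive")
  if (!is.null(box)) {
    stopifnot(is.numeric(box), length(box) == 3L, all(box > 0))
  }
  structure(list(atoms = atoms, box = box, provenance = provenance),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, %d residues%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (is.null(x$box)) "" else sprintf(", box %.1f x %.1f x %.1f A",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

n_atoms <- function(atoms) nrow(atoms$atoms)

coords <- function(atoms) as.matrix(atoms$atoms[, c("x", "y", "z")])

# Infer the chemical element from a PDB atom name ("OW" -> "O", "1HB" -> "H").
infer_element <- function(name) {
  stripped <- gsub("^[0-9'\"]+", "", trimws(name))
  toupper(substr(stripped, 1L, 1L))
}

validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    bad <- nchar(ln) < 54
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bad <- anyNA(xyz)
    }
    if (bad)
      stop(sprintf("malformed ATOM/HETATM record at line %d of '%s'", i, path))
  }
  invisible(idx)
}

parse_cryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (!length(i)) return(NULL)
  ln <- lines[i[1]]
  abc <- suppressWarnings(as.numeric(c(substr(ln, 7, 15),
                                       substr(ln, 16, 24),
                                       substr(ln, 25, 33))))
  if (anyNA(abc) || any(abc <= 0)) return(NULL)
  abc
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    serial = pdb$atom$eleno,
    name = trimws(pdb$atom$elety),
    resname = trimws(pdb$atom$resid),
    resid = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
    x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
    element = trimws(ifelse(is.na(pdb$atom$elesy), "", pdb$atom$elesy)),
    stringsAsFactors = FALSE
  )
  blank <- atoms$element == ""
  atoms$element[blank] <- infer_element(atoms$name[blank])
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  list(atoms = atoms, xyz = xyz, box = parse_cryst1(lines),
       n_models = nrow(xyz))
}

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || nat <= 0L) stop("bad atom count at line 2 of ", path)
  if (length(lines) < 2L + nat + 1L) stop("GRO file truncated: ", path)
  body <- lines[3:(2 + nat)]
  num <- function(s) suppressWarnings(as.numeric(s))
  resid <- as.integer(num(substr(body, 1, 5)))
  resname <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  serial <- as.integer(num(substr(body, 16, 20)))
  x <- num(substr(body, 21, 28)) * 10  # nm -> Angstrom
  y <- num(substr(body, 29, 36)) * 10
  z <- num(substr(body, 37, 44)) * 10
  bad <- which(is.na(resid) | is.na(serial) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("malformed GRO atom record at line %d of '%s'", 2L + bad[1], path))
  boxf <- num(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]])
  box <- if (length(boxf) >= 3 && all(is.finite(boxf[1:3])) && all(boxf[1:3] > 0))
    boxf[1:3] * 10 else NULL
  atoms <- data.frame(serial = serial, name = name, resname = resname,
                      resid = resid, chain = "", x = x, y = y, z = z,
                      element = infer_element(name), stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = matrix(t(as.matrix(atoms[, c("x", "y", "z")])),
                                   nrow = 1L),
       box = box, n_models = 1L)
}

#' Read a structure from PDB or GRO
#'
#' Parses fixed-column PDB (ATOM/HETATM/MODEL/ENDMDL/CRYST1) or GROMACS GRO
#' files into an [atom_set]. GRO coordinates (nm) are converted to Angstrom.
#' For multi-model PDB files, `model` selects which model to return.
#'
#' @param path Path to a `.pdb` or `.gro` file.
#' @param model Model number (1-based) for multi-model files.
#' @return An [atom_set].
#' @seealso [read_trajectory()] for reading all models as frames.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- if (ext == "gro") read_gro(path) else read_pdb_models(path)
  model <- as.integer(model)
  if (model < 1L || model > parsed$n_models)
    stop(sprintf("requested model %d but '%s' holds %d model(s) (empty model)",
                 model, path, parsed$n_models))
  atoms <- parsed$atoms
  xyz <- parsed$xyz[model, ]
  atoms$x <- xyz[seq(1, length(xyz), 3)]
  atoms$y <- xyz[seq(2, length(xyz), 3)]
  atoms$z <- xyz[seq(3, length(xyz), 3)]
  atom_set(atoms, box = parsed$box,
           provenance = list(source = path, model = model))
}

#' Construct a trajectory
#'
#' @param topology An [atom_set] describing every frame's atoms.
#' @param frames Numeric array `n_atoms x 3 x n_frames` of coordinates (A),
#'   or a list of `n_atoms x 3` matrices.
#' @param times Per-frame times in ns (strictly increasing). Defaults to
#'   `0, timestep, 2 timestep, ...`.
#' @param timestep Frame spacing in ns (used when `times` is NULL).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL, timestep = 1) {
  stopifnot(inherits(topology, "atom_set"))
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2] == 3L)
  if (dim(frames)[1] != n_atoms(topology))
    stop("frame atom count does not match topology")
  nf <- dim(frames)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * timestep
  if (length(times) != nf || any(diff(times) <= 0))
    stop("frame times must be strictly increasing, one per frame")
  structure(list(topology = topology, frames = frames, times = times,
                 timestep = timestep),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames, %.4g ns\n",
              dim(x$frames)[1], dim(x$frames)[3], diff(range(x$times))))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[3]

frame_coords <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Read a trajectory from a multi-model PDB
#'
#' Each MODEL block becomes one frame; frames are timestamped
#' `0, timestep, 2 timestep, ...` ns. Every model must contain exactly the
#' topology's atom count (an error names the offending frame otherwise).
#'
#' @param path Multi-model PDB file.
#' @param topology Optional [atom_set]; defaults to model 1 of `path`.
#' @param timestep Frame spacing in ns.
#' @return A [trajectory].
#' @export
read_trajectory <- function(path, topology = NULL, timestep = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  # per-MODEL atom counts from the raw text so a short frame is caught here
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), model_starts, model_ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf("frame %d of '%s' has %d atoms, expected %d",
                   bad, path, counts[bad], counts[1]))
    }
  }
  parsed <- read_pdb_models(path)
  if (is.null(topology)) {
    topology <- read_structure(path, model = 1L)
  } else if (n_atoms(topology) != ncol(parsed$xyz) / 3) {
    stop(sprintf("trajectory '%s' has %d atoms per frame, topology has %d",
                 path, ncol(parsed$xyz) / 3, n_atoms(topology)))
  }
  nf <- parsed$n_models
  frames <- array(0, dim = c(n_atoms(topology), 3, nf))
  for (i in seq_len(nf)) {
    xyz <- parsed$xyz[i, ]
    frames[, , i] <- matrix(xyz, ncol = 3, byrow = TRUE)
  }
  trajectory(topology, frames, timestep = timestep)
}

#' Write a structure or trajectory as PDB
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL blocks), the
#' package's mandatory trajectory dialect.
#'
#' @param x An [atom_set] or [trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "trajectory")) {
    at <- x$topology$atoms
    box <- x$topology$box
    nf <- n_frames(x)
    xyz <- matrix(0, nrow = nf, ncol = 3L * nrow(at))
    for (i in seq_len(nf)) xyz[i, ] <- as.vector(t(x$frames[, , i]))
  } else {
    stopifnot(inherits(x, "atom_set"))
    at <- x$atoms
    box <- x$box
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1L)
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   eleno = at$serial, elety = at$name, resid = at$resname,
                   resno = at$resid,
                   chain = ifelse(at$chain == "", " ", at$chain),
                   elesy = at$element)
  if (!is.null(box)) {
    lines <- readLines(path, warn = FALSE)
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

#' HOLE-style van der Waals radius table
#'
#' Per-element hard-sphere radii used by the pore profiler, in the spirit of
#' the HOLE defaults: C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 A, with
#' 2.00 A for anything unmatched. The table is a plain list and can be
#' extended or overridden; `prefix` entries match atom-name prefixes before
#' the per-element fallback is consulted.
#'
#' @return list with elements `prefix` (named numeric, may be empty),
#'   `element` (named numeric) and `default` (scalar).
#' @export
hole_radii <- function() {
  list(prefix = c(),
       element = c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, H = 1.00, P = 2.10),
       default = 2.00)
}

#' Assign van der Waals radii
#'
#' Every atom receives a radius: longest matching atom-name prefix first,
#' then the per-element entry, then the table default (with a warning
#' listing what fell through).
#'
#' @param atoms An [atom_set].
#' @param radius_set A table as returned by [hole_radii()].
#' @return The atom set with `vdw_radius` filled in.
#' @export
assign_vdw_radii <- function(atoms, radius_set = hole_radii()) {
  stopifnot(inherits(atoms, "atom_set"))
  at <- atoms$atoms
  r <- rep(NA_real_, nrow(at))
  pref <- radius_set$prefix
  if (length(pref)) {
    for (p in names(pref)[order(-nchar(names(pref)))]) {
      hit <- is.na(r) & startsWith(toupper(at$name), toupper(p))
      r[hit] <- pref[[p]]
    }
  }
  elem <- radius_set$element
  if (length(elem)) {
    m <- match(toupper(at$element), toupper(names(elem)))
    take <- is.na(r) & !is.na(m)
    r[take] <- unname(elem[m[take]])
  }
  if (anyNA(r)) {
    unk <- unique(at$element[is.na(r)])
    warning(sprintf("no vdW radius for element(s) %s; using default %.2f A",
                    paste(unk, collapse = ", "), radius_set$default))
    r[is.na(r)] <- radius_set$default
  }
  atoms$atoms$vdw_radius <- r
  atoms
}

#' Elastic-network (GNM) restraint pairs
#'
#' Enumerates all unordered pairs of C-alpha atoms whose separation lies
#' within a distance band, each pair carrying its reference distance and a
#' common force constant. This is the restraint specification used to hold a
#' helix bundle near its starting conformation during restrained MD
#' (default band 7-9 A, k = 1000 kJ mol^-1 nm^-2).
#'
#' @param atoms An [atom_set]; only atoms named "CA" are used. Pair indices
#'   refer to rows of `atoms$atoms`.
#' @param low,high Distance band in Angstrom (`low < high`).
#' @param force_constant Spring constant in kJ mol^-1 nm^-2.
#' @return An object of class `restraint_spec`: list with `pairs`
#'   (data.frame `i`, `j`, `ref_dist`) and `force_constant`.
#' @export
gnm_restraint_pairs <- function(atoms, low = 7, high = 9,
                                force_constant = 1000) {
  stopifnot(inherits(atoms, "atom_set"), low < high, force_constant > 0)
  ca <- which(atoms$atoms$name == "CA")
  if (length(ca) < 2L)
    stop("need at least 2 C-alpha atoms to build restraints (found ",
         length(ca), ")")
  xyz <- coords(atoms)[ca, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d >= low & d <= high, arr.ind = TRUE)
  ord <- order(sel[, 1], sel[, 2])
  sel <- sel[ord, , drop = FALSE]
  pairs <- data.frame(i = ca[sel[, 1]], j = ca[sel[, 2]],
                      ref_dist = d[sel])
  structure(list(pairs = pairs, force_constant = force_constant,
                 band = c(low, high)),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf("<restraint_spec> %d Ca pairs in [%.1f, %.1f] A, k = %g kJ/mol/nm^2\n",
              nrow(x$pairs), x$band[1], x$band[2], x$force_constant))
  invisible(x)
}
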