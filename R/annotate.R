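#' Annotation thresholds
#'
#' Calibration of the conductive/non-conductive verdict. A gate is called
#' CLOSED when its water free-energy barrier reaches `closed_barrier`
#' (default 10 kJ/mol, ~4 kT at 310 K — closed pLGIC structures show
#' 9-25 kJ/mol) or its gate slab is dewetted at least `dewetted` of the
#' time; OPEN requires every barrier at or below `open_barrier` (default
#' 5 kJ/mol, ~2 kT; open-state barriers sit near thermal energy) and a
#' continuously wetted pore. A pore narrower than `steric_radius`
#' (the ~1.4 A radius of a water molecule) is sterically occluded and
#' called CLOSED on geometry alone.
#'
#' @param closed_barrier,open_barrier Barrier thresholds (kJ/mol).
#' @param dewetted Dewetted-fraction threshold (0-1).
#' @param wetted_tol Largest dewetted fraction still counted as
#'   "continuously wetted".
#' @param radius_threshold Gate-candidate radius (A), see [identify_gate()].
#' @param steric_radius Radius (A) below which the pore excludes even water.
#' @return list of class `annotation_thresholds`.
#' @export
annotation_thresholds <- function(closed_barrier = 10, open_barrier = 5,
                                  dewetted = 0.5, wetted_tol = 0.05,
                                  radius_threshold = 4.5,
                                  steric_radius = 1.4) {
  stopifnot(open_barrier < closed_barrier, dewetted > 0, dewetted <= 1)
  structure(list(closed_barrier = closed_barrier, open_barrier = open_barrier,
                 dewetted = dewetted, wetted_tol = wetted_tol,
                 radius_threshold = radius_threshold,
                 steric_radius = steric_radius),
            class = "annotation_thresholds")
}

gate_verdict <- function(barrier, dewetted_fraction, min_radius, th) {
  if (!is.na(min_radius) && min_radius < th$steric_radius) return("CLOSED")
  b_known <- !is.na(barrier)
  d_known <- !is.na(dewetted_fraction)
  if ((b_known && barrier >= th$closed_barrier) ||
      (d_known && dewetted_fraction >= th$dewetted)) return("CLOSED")
  if (b_known && barrier <= th$open_barrier &&
      (!d_known || dewetted_fraction <= th$wetted_tol)) return("OPEN")
  "INDETERMINATE"
}

#' Classify the functional state of a channel structure
#'
#' Combines pore geometry with hydration evidence into a per-gate and
#' overall verdict: OPEN (conductive), CLOSED (non-conductive) or
#' INDETERMINATE. With geometry only, a sub-threshold constriction yields
#' INDETERMINATE (it may still wet) unless it is too narrow for water; the
#' hydration evidence — water free-energy barriers and dewetted fractions
#' at each gate — is what turns a candidate hydrophobic gate into a CLOSED
#' call. The overall verdict is the worst gate (CLOSED beats
#' INDETERMINATE beats OPEN). Note a CLOSED call means non-conductive
#' only; closed and desensitized states are deliberately not
#' distinguished.
#'
#' @param profile A `pore_profile` (required).
#' @param gates Optional list of `gate_region`s; derived from `profile`
#'   (and `atoms` if given) when NULL.
#' @param water_barriers Optional numeric vector, one barrier (kJ/mol) per
#'   gate; NA where unknown.
#' @param barrier_lower_bounds Optional logical vector flagging barriers
#'   that are lower bounds (empty-bin estimates from dewetted pores).
#' @param dewetted_fraction Optional numeric, one per gate (or scalar,
#'   recycled); NA where unknown.
#' @param flux Optional total water flux (ns^-1); reported as evidence,
#'   never a veto.
#' @param atoms Optional [atom_set] for gate lining annotation.
#' @param structure_id Identifier recorded in the report.
#' @param thresholds An [annotation_thresholds()].
#' @param seed Optional seed recorded in provenance.
#' @return Object of class `annotation_report`.
#' @export
classify_state <- function(profile, gates = NULL, water_barriers = NULL,
                           barrier_lower_bounds = NULL,
                           dewetted_fraction = NULL, flux = NULL,
                           atoms = NULL, structure_id = "structure",
                           thresholds = annotation_thresholds(),
                           seed = NULL) {
  if (missing(profile) || !inherits(profile, "pore_profile"))
    stop("a pore_profile is required")
  if (is.null(gates))
    gates <- identify_gate(profile, atoms,
                           radius_threshold = thresholds$radius_threshold)
  ng <- length(gates)
  pad <- function(x, default = NA_real_) {
    if (is.null(x)) rep(default, ng)
    else if (length(x) == 1L && ng > 1L) rep(x, ng)
    else { stopifnot(length(x) == ng); x }
  }
  barriers <- pad(water_barriers)
  lb <- pad(barrier_lower_bounds, NA)
  dew <- pad(dewetted_fraction)
  verdicts <- character(ng)
  for (g in seq_len(ng))
    verdicts[g] <- gate_verdict(barriers[g], dew[g], gates[[g]]$min_radius,
                                thresholds)
  overall <- if (ng == 0L) "OPEN"
             else if (any(verdicts == "CLOSED")) "CLOSED"
             else if (any(verdicts == "INDETERMINATE")) "INDETERMINATE"
             else "OPEN"
  mr <- min_radius(profile)
  structure(list(
    structure_id = structure_id,
    gates = gates,
    gate_verdicts = verdicts,
    water_barriers = barriers,
    barrier_lower_bounds = lb,
    dewetted_fraction = dew,
    min_radius = mr$radius,
    min_radius_z = mr$z,
    flux = flux,
    verdict = overall,
    thresholds = thresholds,
    provenance = list(package = "poreannotate",
                      version = as.character(utils::packageVersion("poreannotate")),
                      seed = seed)),
    class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}

report_as_list <- function(report) {
  gl <- lapply(seq_along(report$gates), function(g) {
    gate <- report$gates[[g]]
    list(z_min = gate$z_min, z_max = gate$z_max,
         min_radius_A = gate$min_radius, z_at_min_A = gate$z_at_min,
         hydrophobic_fraction = gate$hydrophobic_fraction,
         lining_residues = if (is.null(gate$lining_residues)) NULL
                           else gate$lining_residues,
         water_barrier_kJ_mol = report$water_barriers[g],
         barrier_is_lower_bound = report$barrier_lower_bounds[g],
         dewetted_fraction = report$dewetted_fraction[g],
         verdict = report$gate_verdicts[g])
  })
  list(structure_id = report$structure_id,
       verdict = report$verdict,
       min_radius_A = report$min_radius,
       min_radius_z_A = report$min_radius_z,
       flux_ns = report$flux,
       gates = gl,
       thresholds = unclass(report$thresholds),
       provenance = report$provenance)
}

#' Render an annotation report
#'
#' Deterministic serialisation of a report as JSON (machine-readable,
#' round-trips losslessly) or as a human-readable text view mirroring the
#' same content.
#'
#' @param report An `annotation_report`.
#' @param format `"json"` or `"text"`.
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "annotation_report"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_as_list(report),
                                         auto_unbox = TRUE, digits = 10,
                                         pretty = TRUE, null = "null")))
  }
  l <- report_as_list(report)
  out <- c(sprintf("Functional annotation: %s", l$structure_id),
           sprintf("  overall verdict: %s", l$verdict),
           sprintf("  minimum pore radius: %.2f A at z = %.2f A",
                   l$min_radius_A, l$min_radius_z_A))
  if (!is.null(l$flux_ns))
    out <- c(out, sprintf("  water flux: %.3g ns^-1", l$flux_ns))
  if (!length(l$gates)) {
    out <- c(out, "  no sub-threshold constriction detected (geometry favours OPEN)")
  } else {
    for (g in seq_along(l$gates)) {
      gate <- l$gates[[g]]
      out <- c(out, sprintf(
        "  gate %d: z [%.2f, %.2f] A, min radius %.2f A, barrier %s kJ/mol, dewetted %s -> %s",
        g, gate$z_min, gate$z_max, gate$min_radius_A,
        if (is.na(gate$water_barrier_kJ_mol)) "?" else
          sprintf("%.1f%s", gate$water_barrier_kJ_mol,
                  if (isTRUE(gate$barrier_is_lower_bound)) " (lower bound)" else ""),
        if (is.na(gate$dewetted_fraction)) "?" else
          sprintf("%.2f", gate$dewetted_fraction),
        gate$verdict))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
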