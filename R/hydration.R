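#' Pore cylinder
#'
#' The analysis region for hydration statistics: a cylinder of given radius
#' about the pore axis, bounded axially by the two pore mouths. Axial
#' coordinates (`z_lo`, `z_hi`, and all z values reported by the track
#' functions) are measured along `axis` relative to `center`.
#'
#' @param axis Unit axis vector.
#' @param center A 3-vector on the axis (z = 0 reference).
#' @param radius Cylinder radius (A).
#' @param z_lo,z_hi Axial bounds (A), `z_lo < z_hi`.
#' @return Object of class `pore_cylinder`.
#' @export
pore_cylinder <- function(axis = c(0, 0, 1), center = c(0, 0, 0),
                          radius = 5, z_lo = -15, z_hi = 15) {
  stopifnot(z_lo < z_hi, radius > 0, length(axis) == 3L, length(center) == 3L)
  structure(list(axis = axis / sqrt(sum(axis^2)), center = center,
                 radius = radius, z_lo = z_lo, z_hi = z_hi),
            class = "pore_cylinder")
}

#' Axial water tracks through a pore
#'
#' For every selected water (one reference atom per molecule, normally the
#' oxygen) the axial coordinate z(t) is extracted each frame, together with
#' an in-pore mask (radial distance from the axis within the cylinder
#' radius and z within the mouth bounds). Identities are preserved across
#' frames; when the trajectory carries a box, radial offsets are
#' minimum-imaged and z is unwrapped per particle between consecutive
#' frames so traversals across the periodic boundary are not miscounted.
#'
#' @param traj A [trajectory].
#' @param waters Selection string (see [select_atoms()]) or integer atom
#'   indices picking one atom per water.
#' @param cyl A [pore_cylinder()].
#' @return Object of class `water_tracks`: list with `z` (particles x
#'   frames matrix, unwrapped), `inpore` (logical matrix), `ids` (atom
#'   serials), `times`, `cyl`.
#' @export
water_axial_tracks <- function(traj, waters, cyl) {
  stopifnot(inherits(traj, "trajectory"), inherits(cyl, "pore_cylinder"))
  idx <- resolve_selection(traj$topology, waters)
  if (!length(idx)) stop("water selection matched no atoms")
  nf <- n_frames(traj)
  np <- length(idx)
  basis <- plane_basis(cyl$axis)
  zmat <- matrix(0, np, nf)
  inpore <- matrix(FALSE, np, nf)
  box <- traj$topology$box
  for (f in seq_len(nf)) {
    d <- sweep(traj$frames[idx, , f, drop = FALSE], 2, cyl$center)
    d <- d[, , 1, drop = TRUE]
    if (np == 1L) d <- matrix(d, 1L)
    if (!is.null(box)) {
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    zk <- d %*% cyl$axis
    r1 <- d %*% basis$e1
    r2 <- d %*% basis$e2
    zmat[, f] <- zk
    inpore[, f] <- sqrt(r1^2 + r2^2) <= cyl$radius &
      zk >= cyl$z_lo & zk <= cyl$z_hi
  }
  if (!is.null(box)) {
    bz <- sum(box * abs(cyl$axis))  # box extent along the axis
    if (nf > 1L && bz > 0) {
      for (f in 2:nf) {
        jump <- zmat[, f] - zmat[, f - 1]
        zmat[, f] <- zmat[, f] - bz * round(jump / bz)
      }
    }
  }
  structure(list(z = zmat, inpore = inpore,
                 ids = traj$topology$atoms$serial[idx],
                 times = traj$times, cyl = cyl),
            class = "water_tracks")
}

resolve_selection <- function(topology, sel) {
  if (is.character(sel)) which(selection_mask(topology, sel))
  else as.integer(sel)
}

#' Gate occupancy and dewetted fraction
#'
#' Counts waters inside the gate slab each frame; the dewetted fraction is
#' the fraction of frames in which the slab holds no water at all (the
#' vapour state of a hydrophobically gated pore).
#'
#' @param tracks A `water_tracks` object.
#' @param gate `c(z_min, z_max)` slab in track coordinates (A).
#' @return list with `occupancy` (integer per frame) and
#'   `dewetted_fraction`.
#' @export
occupancy_and_dewetting <- function(tracks, gate) {
  stopifnot(inherits(tracks, "water_tracks"), length(gate) == 2L,
            gate[1] < gate[2])
  inslab <- tracks$inpore & tracks$z >= gate[1] & tracks$z <= gate[2]
  occ <- colSums(inslab)
  list(occupancy = occ, dewetted_fraction = mean(occ == 0L))
}

#' Count completed permeation events
#'
#' Two-gate hysteresis: a particle completes an event when it passes from
#' beyond one boundary plane to beyond the other; oscillation across a
#' single boundary never counts. Direction is recorded ("up" = low to
#' high z) and the per-event log allows an exact replay.
#'
#' @param tracks A `water_tracks` object.
#' @param z_lo,z_hi Boundary planes (A); default the cylinder mouths.
#' @return Object of class `flux_result`: counts `events_up`/`events_down`,
#'   `duration` (ns), total `rate` (ns^-1) and the event `log`.
#' @export
count_permeation_events <- function(tracks, z_lo = NULL, z_hi = NULL) {
  stopifnot(inherits(tracks, "water_tracks"))
  if (is.null(z_lo)) z_lo <- tracks$cyl$z_lo
  if (is.null(z_hi)) z_hi <- tracks$cyl$z_hi
  if (z_lo >= z_hi) stop("z_lo must be < z_hi")
  region <- matrix(0L, nrow(tracks$z), ncol(tracks$z))
  region[tracks$z < z_lo] <- -1L
  region[tracks$z > z_hi] <- 1L
  logs <- vector("list", nrow(region))
  up <- down <- 0L
  for (p in seq_len(nrow(region))) {
    nz <- which(region[p, ] != 0L)
    if (length(nz) < 2L) next
    v <- region[p, nz]
    sw <- which(diff(v) != 0L)
    if (!length(sw)) next
    dir <- ifelse(v[sw] < 0L, "up", "down")
    up <- up + sum(dir == "up")
    down <- down + sum(dir == "down")
    logs[[p]] <- data.frame(particle = tracks$ids[p],
                            start_frame = nz[sw], end_frame = nz[sw + 1L],
                            direction = dir, stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(log))
    log <- data.frame(particle = integer(), start_frame = integer(),
                      end_frame = integer(), direction = character())
  duration <- diff(range(tracks$times))
  structure(list(events_up = up, events_down = down, duration = duration,
                 rate = if (duration > 0) (up + down) / duration else NA_real_,
                 log = log),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %d up + %d down over %.4g ns (total %.3g ns^-1)\n",
              x$events_up, x$events_down, x$duration, x$rate))
  invisible(x)
}

#' Axial density profile of in-pore particles
#'
#' Histograms in-pore observations along z; `counts` is the expected number
#' of tracked particles per bin per frame (total observations divided by
#' the frame count), the n(z) whose Boltzmann inversion gives the water
#' free-energy profile.
#'
#' @param tracks A `water_tracks` object.
#' @param bin_width Bin width in Angstrom.
#' @param z_range Optional `c(lo, hi)`; defaults to the cylinder mouths.
#' @return Object of class `density_profile`.
#' @export
density_profile <- function(tracks, bin_width = 1.0, z_range = NULL) {
  stopifnot(inherits(tracks, "water_tracks"), bin_width > 0)
  if (is.null(z_range)) z_range <- c(tracks$cyl$z_lo, tracks$cyl$z_hi)
  edges <- seq(z_range[1], z_range[2] + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < z_range[2]) edges <- c(edges, z_range[2])
  obs <- tracks$z[tracks$inpore]
  obs <- obs[obs >= edges[1] & obs <= edges[length(edges)]]
  bin <- findInterval(obs, edges, rightmost.closed = TRUE)
  counts_total <- tabulate(bin, nbins = length(edges) - 1L)
  nf <- ncol(tracks$z)
  new_density_profile(edges, counts_total, nf, bin_width)
}

#' Construct a density profile from raw bin counts
#'
#' @param bin_edges Increasing bin edges (A).
#' @param counts_total Integer observation count per bin (summed over
#'   frames).
#' @param n_frames Number of frames the counts were accumulated over.
#' @param bin_width Bin width (A); inferred from edges if NULL.
#' @return Object of class `density_profile` with `counts` = per-frame
#'   expected counts.
#' @export
new_density_profile <- function(bin_edges, counts_total, n_frames,
                                bin_width = NULL) {
  stopifnot(length(counts_total) == length(bin_edges) - 1L,
            all(counts_total >= 0), n_frames >= 1)
  if (is.null(bin_width)) bin_width <- stats::median(diff(bin_edges))
  structure(list(bin_edges = bin_edges, counts = counts_total / n_frames,
                 counts_total = counts_total, n_frames = n_frames,
                 bin_width = bin_width),
            class = "density_profile")
}

bin_centers <- function(x) (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2

#' Boltzmann inversion of a density profile
#'
#' Converts an axial number density n(z) into a free-energy profile through
#' the Boltzmann relation `E(z) = -kT ln n(z) + kT ln C`, with the
#' constant C fixed by requiring zero free energy (on average) over the
#' bulk-like reference bins at the two ends of the pore. Bins that were
#' never occupied yield a finite lower-bound estimate (one observation in
#' the whole run) and are flagged in `lower_bound_mask` so fully dewetted
#' pores serialise cleanly.
#'
#' @param density A `density_profile`.
#' @param temperature Temperature in K (default the 310 K simulation
#'   temperature).
#' @param reference Number of outermost occupied bins at each end averaged
#'   to define the bulk zero (default 3).
#' @return Object of class `free_energy_profile`: `z`, `energy` (kJ/mol),
#'   `temperature`, `reference`, `lower_bound_mask`.
#' @export
boltzmann_invert <- function(density, temperature = 310, reference = 3) {
  stopifnot(inherits(density, "density_profile"), reference >= 1)
  n <- density$counts
  if (all(n == 0)) stop("density profile is empty everywhere")
  occ <- which(n > 0)
  ref_idx <- unique(c(utils::head(occ, reference), utils::tail(occ, reference)))
  if (any(n[ref_idx] <= 0)) stop("reference end bins must have counts > 0")
  kT <- thermal_energy(temperature)
  C <- mean(n[ref_idx])
  n_eff <- n
  lb <- n == 0
  n_eff[lb] <- 1 / density$n_frames  # fewer than one observation in the run
  energy <- -kT * log(n_eff) + kT * log(C)
  structure(list(z = bin_centers(density), energy = energy,
                 temperature = temperature,
                 reference = sprintf(
                   "zero = -kT ln(mean density over %d outermost occupied bins per end)",
                   reference),
                 reference_bins = ref_idx,
                 lower_bound_mask = lb),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> %d bins, max %.2f kJ/mol at z = %.2f A (T = %g K)\n",
              length(x$z), max(x$energy), x$z[which.max(x$energy)],
              x$temperature))
  invisible(x)
}

#' Barrier height of a free-energy profile
#'
#' Maximum energy within an axial window (default: the whole profile),
#' relative to the profile's bulk zero.
#'
#' @param fe A `free_energy_profile` (or `pmf`).
#' @param z_window Optional `c(lo, hi)` (A).
#' @return Barrier height in kJ/mol.
#' @export
barrier_height <- function(fe, z_window = NULL) {
  keep <- if (is.null(z_window)) rep(TRUE, length(fe$z))
          else fe$z >= z_window[1] & fe$z <= z_window[2]
  e <- fe$energy[keep]
  e <- e[is.finite(e)]
  if (!length(e)) stop("window contains no finite energies")
  max(e)
}

#' Ion hydration-shell occupancies
#'
#' Per frame, counts the selected water oxygens in the first shell
#' (distance to the ion at most `first_cutoff`) and second shell (between
#' the two cutoffs). Diminution of the second shell while the first stays
#' intact is the signature of an ion squeezing past a hydrophobic
#' constriction.
#'
#' @param traj A [trajectory].
#' @param ion Selection resolving to exactly one atom.
#' @param first_cutoff,second_cutoff Shell cutoffs in A
#'   (`0 < first < second`). Defaults are the Na+ shells (3.2/5.5 A);
#'   use ~3.9/6.2 A for Cl-.
#' @param waters Selection for water reference atoms (default oxygens named
#'   O or OW).
#' @return data.frame with `frame`, `time`, `first_shell`, `second_shell`.
#' @export
hydration_numbers <- function(traj, ion, first_cutoff = 3.2,
                              second_cutoff = 5.5,
                              waters = "name O OW and resname HOH SOL WAT TIP4") {
  stopifnot(inherits(traj, "trajectory"),
            first_cutoff > 0, second_cutoff > first_cutoff)
  ion_idx <- resolve_selection(traj$topology, ion)
  if (length(ion_idx) != 1L)
    stop("ion selection must resolve to exactly one atom (got ",
         length(ion_idx), ")")
  w_idx <- resolve_selection(traj$topology, waters)
  nf <- n_frames(traj)
  box <- traj$topology$box
  first <- second <- integer(nf)
  for (f in seq_len(nf)) {
    d <- sweep(traj$frames[w_idx, , f, drop = FALSE], 2,
               traj$frames[ion_idx, , f])
    d <- d[, , 1, drop = TRUE]
    if (length(w_idx) == 1L) d <- matrix(d, 1L)
    if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    r <- sqrt(rowSums(d^2))
    first[f] <- sum(r <= first_cutoff)
    second[f] <- sum(r > first_cutoff & r <= second_cutoff)
  }
  data.frame(frame = seq_len(nf), time = traj$times,
             first_shell = first, second_shell = second)
}
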