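#' Slab charge-density profile
#'
#' Bins per-atom partial charges into slabs along laboratory z and averages
#' over frames; densities are reported in e/A^3 using the box cross-section
#' for volume normalisation.
#'
#' @param traj A [trajectory].
#' @param charges Per-atom charges in e: a numeric vector (one per topology
#'   atom, in order) or a data.frame with columns `serial`, `charge_e`.
#'   Every atom must have a charge.
#' @param bin_width Slab thickness (A).
#' @param z_range Optional `c(lo, hi)`; defaults to `[0, box_z]` when a box
#'   is present, otherwise the coordinate range.
#' @param cross_section Cross-sectional area (A^2); defaults to
#'   `box_x * box_y`.
#' @return Object of class `charge_density_profile`: `bin_edges`, `rho`
#'   (e/A^3), `cross_section`, `bin_width`, `total_charge`.
#' @export
charge_density_profile <- function(traj, charges, bin_width = 1.0,
                                   z_range = NULL, cross_section = NULL) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  at <- traj$topology$atoms
  if (is.data.frame(charges)) {
    m <- match(at$serial, charges$serial)
    if (anyNA(m)) {
      bad <- at$serial[which(is.na(m))[1]]
      stop("missing charge for atom serial ", bad)
    }
    q <- charges$charge_e[m]
  } else {
    q <- as.numeric(charges)
    if (length(q) != nrow(at))
      stop("charge vector length ", length(q), " != atom count ", nrow(at))
  }
  if (anyNA(q)) stop("missing charge for atom serial ",
                     at$serial[which(is.na(q))[1]])
  box <- traj$topology$box
  if (is.null(cross_section)) {
    if (is.null(box)) stop("cross_section required when the trajectory has no box")
    cross_section <- box[1] * box[2]
  }
  if (is.null(z_range)) {
    z_range <- if (!is.null(box)) c(0, box[3]) else range(traj$frames[, 3, ])
  }
  edges <- seq(z_range[1], z_range[2] + bin_width * 1e-9, by = bin_width)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    z <- traj$frames[, 3, f]
    if (!is.null(box)) z <- z - box[3] * floor((z - z_range[1]) / box[3])
    bin <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= nb
    acc <- acc + as.vector(tapply(q[ok], factor(bin[ok], levels = seq_len(nb)),
                                  sum, default = 0))
  }
  rho <- acc / nf / (cross_section * bin_width)
  structure(list(bin_edges = edges, rho = rho, cross_section = cross_section,
                 bin_width = bin_width,
                 total_charge = sum(rho) * cross_section * bin_width),
            class = "charge_density_profile")
}

#' Transmembrane potential by Poisson double integration
#'
#' Integrates the 1-D Poisson equation
#' `phi(z) = -(1/(eps0 epsr)) int_0^z int_0^z' rho(z'') dz'' dz'`
#' by cumulative trapezoids, with `phi = dphi/dz = 0` at the lower box edge
#' (the g_potential convention). The voltage difference `dV` is read as the
#' difference of mean potentials over the two bulk regions.
#'
#' @param rho A `charge_density_profile`.
#' @param eps_r Relative permittivity (default 1: explicit charges only).
#' @param bulk_frac Fraction of the z range at each end treated as bulk for
#'   the dV readout (ignored when `compartments` is given).
#' @param compartments Optional list of two `c(lo, hi)` z ranges;
#'   `dV = mean phi(second) - mean phi(first)`.
#' @return Object of class `voltage_profile`: `z`, `phi` (volts), `dV`.
#' @export
poisson_potential <- function(rho, eps_r = 1, bulk_frac = 0.1,
                              compartments = NULL) {
  stopifnot(inherits(rho, "charge_density_profile"), eps_r > 0)
  if (!length(rho$rho)) stop("empty charge-density profile")
  z <- (rho$bin_edges[-1] + rho$bin_edges[-length(rho$bin_edges)]) / 2
  I1 <- pracma::cumtrapz(z, rho$rho)
  phi <- -(.phi_conv / eps_r) * as.vector(pracma::cumtrapz(z, as.vector(I1)))
  if (is.null(compartments)) {
    n <- max(1L, floor(length(z) * bulk_frac))
    dV <- mean(utils::tail(phi, n)) - mean(utils::head(phi, n))
  } else {
    stopifnot(length(compartments) == 2L)
    inreg <- function(r) z >= r[1] & z <= r[2]
    dV <- mean(phi[inreg(compartments[[2]])]) -
          mean(phi[inreg(compartments[[1]])])
  }
  structure(list(z = z, phi = phi, dV = dV, eps_r = eps_r),
            class = "voltage_profile")
}

#' @export
print.voltage_profile <- function(x, ...) {
  cat(sprintf("<voltage_profile> %d points, dV = %.4g V\n", length(x$z), x$dV))
  invisible(x)
}

#' Compartment bookkeeping for double-bilayer systems
#'
#' Two membrane slabs partition the periodic box along z into a central
#' compartment (labelled alpha, between the slabs) and the outer,
#' periodically connected compartment (beta). Every selected ion is
#' assigned to exactly one compartment each frame; the per-species count
#' imbalance (alpha - beta) is the driving gradient of a computational
#' electrophysiology setup.
#'
#' @param traj A [trajectory] (box required for wrapping; optional
#'   otherwise).
#' @param membrane_slabs list of two `c(z_lo, z_hi)` membrane slabs (must
#'   not overlap).
#' @param ions Selection string for the ions to track.
#' @return Object of class `compartment_assignment`: `counts` (array
#'   frame x species x compartment) and `imbalance` (data.frame per frame
#'   and species).
#' @export
assign_compartments <- function(traj, membrane_slabs,
                                ions = "resname NA CL NA+ CL- SOD CLA") {
  stopifnot(inherits(traj, "trajectory"), length(membrane_slabs) == 2L)
  s1 <- sort(membrane_slabs[[1]]); s2 <- sort(membrane_slabs[[2]])
  if (s1[1] > s2[1]) { tmp <- s1; s1 <- s2; s2 <- tmp }
  if (s1[2] > s2[1]) stop("membrane slabs overlap")
  idx <- resolve_selection(traj$topology, ions)
  if (!length(idx)) stop("ion selection matched no atoms")
  species <- traj$topology$atoms$resname[idx]
  sp_levels <- sort(unique(species))
  nf <- n_frames(traj)
  box <- traj$topology$box
  counts <- array(0L, dim = c(nf, length(sp_levels), 2L),
                  dimnames = list(NULL, sp_levels, c("alpha", "beta")))
  for (f in seq_len(nf)) {
    z <- traj$frames[idx, 3, f]
    if (!is.null(box)) z <- z - box[3] * floor(z / box[3])
    in_alpha <- z > s1[2] & z < s2[1]
    for (s in seq_along(sp_levels)) {
      sp <- species == sp_levels[s]
      counts[f, s, 1L] <- sum(sp & in_alpha)
      counts[f, s, 2L] <- sum(sp & !in_alpha)
    }
  }
  imb <- do.call(rbind, lapply(seq_along(sp_levels), function(s)
    data.frame(frame = seq_len(nf), species = sp_levels[s],
               alpha = counts[, s, 1L], beta = counts[, s, 2L],
               imbalance = counts[, s, 1L] - counts[, s, 2L])))
  structure(list(counts = counts, imbalance = imb,
                 slabs = list(s1, s2)),
            class = "compartment_assignment")
}

#' Ion-crossing counts per species and membrane
#'
#' Applies the hysteresis permeation-event detector to each ion species
#' through each membrane's pore cylinder. Zero counts are a meaningful
#' outcome (a functionally closed pore passes no ions).
#'
#' @param traj A [trajectory].
#' @param species Named list of selection strings, e.g.
#'   `list(Na = "resname NA", Cl = "resname CL")`.
#' @param membranes list of [pore_cylinder()] objects, one per membrane.
#' @return Nested list `result[[species]][[membrane]]` of
#'   [count_permeation_events()] results.
#' @export
count_ion_crossings <- function(traj, species, membranes) {
  stopifnot(inherits(traj, "trajectory"), length(species) >= 1,
            length(membranes) >= 1)
  if (is.null(names(species))) names(species) <- paste0("species", seq_along(species))
  if (is.null(names(membranes))) names(membranes) <- paste0("membrane", seq_along(membranes))
  out <- lapply(species, function(sel) {
    lapply(membranes, function(cyl) {
      idx <- resolve_selection(traj$topology, sel)
      if (!length(idx)) {
        return(structure(list(events_up = 0L, events_down = 0L,
                              duration = diff(range(traj$times)),
                              rate = 0,
                              log = data.frame(particle = integer(),
                                               start_frame = integer(),
                                               end_frame = integer(),
                                               direction = character())),
                         class = "flux_result"))
      }
      tracks <- water_axial_tracks(traj, sel, cyl)
      count_permeation_events(tracks)
    })
  })
  out
}
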