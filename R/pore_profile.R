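#' Simulated-annealing schedule for the probe-sphere search
#'
#' Geometric cooling; at each of `n_stages` temperatures, `moves` in-plane
#' Gaussian displacements are proposed with a step size interpolated from
#' `step_hi` down to `step_lo` (Angstrom) as the system cools.
#'
#' @param n_stages Number of temperature stages.
#' @param moves Proposals per stage.
#' @param t0 Initial temperature (objective units, A).
#' @param t_end Final temperature.
#' @param step_hi,step_lo Proposal step at the hottest / coldest stage (A).
#' @return list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_stages = 30, moves = 50, t0 = 1.0,
                            t_end = 0.01, step_hi = 1.0, step_lo = 0.1) {
  stopifnot(n_stages >= 1, moves >= 1, t0 > t_end, t_end > 0)
  structure(list(n_stages = n_stages, moves = moves, t0 = t0, t_end = t_end,
                 step_hi = step_hi, step_lo = step_lo),
            class = "anneal_schedule")
}

# Probe objective in the axis-aligned frame: largest sphere centred at
# (cx, cy, z0) not overlapping any atom. xyz/vdw are the captured atoms.
probe_objective <- function(cx, cy, z0, xyz, vdw) {
  d <- sqrt((xyz[, 1] - cx)^2 + (xyz[, 2] - cy)^2 + (xyz[, 3] - z0)^2) - vdw
  min(d)
}

# Atoms whose sphere can intersect a probe of reach `reach` centred in the
# plane at z0 (axial capture band).
capture_atoms <- function(xyz, vdw, z0, reach) {
  which(abs(xyz[, 3] - z0) <= vdw + reach)
}

#' Largest probe sphere in one pore cross-section
#'
#' The HOLE-style objective: for an in-plane centre c at axial position z,
#' the probe radius is `min_i(|c - atom_i| - vdw_i)` over nearby atoms; the
#' centre is optimised by Monte Carlo simulated annealing in the plane
#' normal to the pore axis. With `anneal = NULL` the objective is simply
#' evaluated at `start_center`.
#'
#' @param atoms An [atom_set] with assigned vdW radii.
#' @param z Axial position of the plane (A, measured along `axis` from the
#'   coordinate origin unless `origin` is given).
#' @param axis Unit pore-axis vector (default z).
#' @param start_center Starting in-plane centre `c(x, y)` in the rotated
#'   frame; defaults to the in-plane centroid of captured atoms.
#' @param anneal An [anneal_schedule()], or NULL to disable optimisation.
#' @param seed Integer seed for reproducible annealing.
#' @param capture_reach Maximum probe reach considered when capturing atoms
#'   near the plane (A).
#' @param origin Optional 3-vector; axial positions are measured relative to
#'   its projection on the axis.
#' @return list with `radius` (A; `Inf` if no atom is within capture reach:
#'   the "unbounded" sentinel) and `center` (in-plane, rotated frame).
#' @export
max_sphere_radius_at <- function(atoms, z, axis = c(0, 0, 1),
                                 start_center = NULL,
                                 anneal = anneal_schedule(), seed = NULL,
                                 capture_reach = 10, origin = c(0, 0, 0)) {
  stopifnot(inherits(atoms, "atom_set"))
  if (anyNA(atoms$atoms$vdw_radius))
    stop("atoms must have vdW radii assigned (see assign_vdw_radii)")
  rot <- axis_rotation(axis)
  xyz <- coords(atoms) %*% t(rot)
  z0 <- z + sum((rot %*% origin) * c(0, 0, 1))
  probe_plane(xyz, atoms$atoms$vdw_radius, z0, start_center, anneal, seed,
              capture_reach)
}

probe_plane <- function(xyz, vdw, z0, start_center, anneal, seed,
                        capture_reach) {
  idx <- capture_atoms(xyz, vdw, z0, capture_reach)
  if (!length(idx)) return(list(radius = Inf, center = c(NA_real_, NA_real_)))
  xyzc <- xyz[idx, , drop = FALSE]
  vdwc <- vdw[idx]
  if (is.null(start_center))
    start_center <- c(mean(xyzc[, 1]), mean(xyzc[, 2]))
  f0 <- probe_objective(start_center[1], start_center[2], z0, xyzc, vdwc)
  if (is.null(anneal))
    return(list(radius = max(f0, 0), center = start_center))
  with_seed(seed, {
    best <- cur <- start_center
    fbest <- fcur <- f0
    alpha <- (anneal$t_end / anneal$t0)^(1 / max(anneal$n_stages - 1, 1))
    for (s in seq_len(anneal$n_stages)) {
      temp <- anneal$t0 * alpha^(s - 1)
      frac <- (s - 1) / max(anneal$n_stages - 1, 1)
      step <- anneal$step_hi + frac * (anneal$step_lo - anneal$step_hi)
      for (m in seq_len(anneal$moves)) {
        prop <- cur + stats::rnorm(2, sd = step)
        fp <- probe_objective(prop[1], prop[2], z0, xyzc, vdwc)
        # the probe sphere may never overlap an atom: a centre with negative
        # clearance sits inside the wall, and accepting it would let the
        # walker tunnel out of the pore (unless we start overlapped)
        if (fp < 0 && fcur >= 0) next
        if (fp > fcur || stats::runif(1) < exp((fp - fcur) / temp)) {
          cur <- prop; fcur <- fp
          if (fp > fbest) { best <- prop; fbest <- fp }
        }
      }
    }
    # deterministic polish: converge tightly onto the local optimum so the
    # result is invariant under rigid transforms of the input
    pol <- stats::optim(best, function(c_)
      -probe_objective(c_[1], c_[2], z0, xyzc, vdwc),
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 1000))
    if (-pol$value > fbest) { best <- pol$par; fbest <- -pol$value }
    list(radius = max(fbest, 0), center = best)
  })
}

resolve_axis <- function(atoms, axis) {
  if (is.character(axis) && identical(axis, "auto")) {
    xyz <- coords(atoms)
    ev <- eigen(stats::cov(xyz), symmetric = TRUE)
    a <- ev$vectors[, 1]
    if (a[3] < 0) a <- -a
    return(a / sqrt(sum(a^2)))
  }
  stopifnot(is.numeric(axis), length(axis) == 3L)
  axis / sqrt(sum(axis^2))
}

resolve_origin <- function(atoms, origin) {
  if (is.character(origin) && identical(origin, "centroid"))
    return(colMeans(coords(atoms)))
  if (inherits(origin, "atom_set")) return(colMeans(coords(origin)))
  stopifnot(is.numeric(origin), length(origin) == 3L)
  origin
}

#' Pore-radius profile along the channel axis
#'
#' Marches a probe sphere along the pore axis, optimising each plane's
#' centre by simulated annealing and using it as the next plane's start
#' (centre-line continuity). Axial positions are reported relative to
#' `origin` (default: the atom-set centroid; pass e.g. the C-alpha set of a
#' reference residue ring to adopt the "gate ring at z = 0" convention).
#'
#' @inheritParams max_sphere_radius_at
#' @param z_range Closed axial range `c(lo, hi)` relative to `origin` (A).
#' @param step Plane spacing in Angstrom.
#' @param origin `"centroid"`, a 3-vector, or an [atom_set] whose centroid
#'   defines z = 0.
#' @param axis Unit vector, or `"auto"` for the principal axis of the
#'   atom-set inertia.
#' @return A `pore_profile`: data.frame with columns `z`, `radius`, `cx`,
#'   `cy`, with the axis, origin and step recorded as attributes.
#' @export
compute_profile <- function(atoms, axis = "auto", z_range = NULL,
                            step = 0.25, seed = NULL,
                            anneal = anneal_schedule(), capture_reach = 10,
                            origin = "centroid") {
  stopifnot(inherits(atoms, "atom_set"), step > 0)
  if (anyNA(atoms$atoms$vdw_radius))
    stop("atoms must have vdW radii assigned (see assign_vdw_radii)")
  a <- resolve_axis(atoms, axis)
  o <- resolve_origin(atoms, origin)
  rot <- axis_rotation(a)
  xyz <- coords(atoms) %*% t(rot)
  z_origin <- sum((rot %*% o) * c(0, 0, 1))
  if (is.null(z_range)) {
    zr <- range(xyz[, 3]) - z_origin
    z_range <- c(zr[1], zr[2])
  }
  if (!(is.numeric(z_range) && length(z_range) == 2L && z_range[1] < z_range[2]))
    stop("z_range must be c(lo, hi) with lo < hi")
  zs <- seq(z_range[1], z_range[2], by = step)
  vdw <- atoms$atoms$vdw_radius
  radius <- numeric(length(zs))
  cx <- cy <- numeric(length(zs))
  center <- NULL
  for (i in seq_along(zs)) {
    plane_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    res <- probe_plane(xyz, vdw, zs[i] + z_origin, center, anneal,
                       plane_seed, capture_reach)
    radius[i] <- res$radius
    cx[i] <- res$center[1]; cy[i] <- res$center[2]
    if (all(is.finite(res$center))) center <- res$center
  }
  out <- data.frame(z = zs, radius = radius, cx = cx, cy = cy)
  structure(out, class = c("pore_profile", "data.frame"),
            axis = a, origin = o, step = step, rotation = rot,
            z_origin = z_origin)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d planes, z in [%.2f, %.2f] A, min radius %.2f A\n",
              nrow(x), min(x$z), max(x$z), min(x$radius)))
  invisible(x)
}

#' Minimum pore radius
#'
#' Global minimum of the radius profile within an axial window; ties are
#' broken toward smaller z.
#'
#' @param profile A `pore_profile`.
#' @param z_window `c(lo, hi)` in profile coordinates, or NULL for the whole
#'   profile.
#' @return list with `z` and `radius`.
#' @export
min_radius <- function(profile, z_window = NULL) {
  stopifnot(inherits(profile, "pore_profile"))
  keep <- if (is.null(z_window)) rep(TRUE, nrow(profile))
          else profile$z >= z_window[1] & profile$z <= z_window[2]
  if (!any(keep)) stop("z_window does not overlap the profile")
  sub <- profile[keep, ]
  i <- which.min(sub$radius)  # first minimum = smallest z (z ascending)
  list(z = sub$z[i], radius = sub$radius[i])
}

#' Kyte-Doolittle hydropathy scale
#'
#' Named per-residue hydropathy values; residues with positive values are
#' classed hydrophobic when computing a gate's hydrophobic fraction.
#'
#' @return Named numeric vector.
#' @export
kyte_doolittle <- function() {
  c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
    ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
    PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
    LYS = -3.9, ARG = -4.5)
}

#' Identify candidate hydrophobic gates
#'
#' Contiguous axial runs where the pore radius drops below
#' `radius_threshold` (default 4.5 A, the radius below which a hydrophobic
#' constriction can promote dewetting) become candidate gate regions. Each
#' region is annotated with its minimum radius, the residues lining the
#' local pore surface, and the fraction of those residues that are
#' hydrophobic on the chosen hydropathy scale.
#'
#' @param profile A `pore_profile`.
#' @param atoms Optional [atom_set] (with vdW radii) used to call lining
#'   residues; omit for a geometry-only gate list.
#' @param radius_threshold Gate radius threshold (A).
#' @param lining_cutoff Maximum heavy-atom offset from the local pore
#'   surface for a residue to count as lining (A).
#' @param hydropathy Named residue scale; positive = hydrophobic.
#' @return list of `gate_region` objects sorted by ascending minimum
#'   radius; empty list if no region qualifies.
#' @export
identify_gate <- function(profile, atoms = NULL, radius_threshold = 4.5,
                          lining_cutoff = 2.8, hydropathy = kyte_doolittle()) {
  stopifnot(inherits(profile, "pore_profile"))
  below <- is.finite(profile$radius) & profile$radius < radius_threshold
  if (!any(below)) return(list())
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gates <- list()
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    sub <- profile[idx, ]
    i <- which.min(sub$radius)
    gate <- list(z_min = min(sub$z), z_max = max(sub$z),
                 min_radius = sub$radius[i], z_at_min = sub$z[i],
                 lining_residues = NULL, hydrophobic_fraction = NA_real_)
    if (!is.null(atoms)) {
      lin <- lining_residues(profile, atoms, idx, lining_cutoff)
      gate$lining_residues <- lin
      if (nrow(lin)) {
        hv <- hydropathy[lin$resname]
        gate$hydrophobic_fraction <- mean(!is.na(hv) & hv > 0)
      }
    }
    gates[[length(gates) + 1L]] <- structure(gate, class = "gate_region")
  }
  gates[order(vapply(gates, function(g) g$min_radius, 0))]
}

lining_residues <- function(profile, atoms, idx, lining_cutoff) {
  rot <- attr(profile, "rotation")
  z_origin <- attr(profile, "z_origin")
  xyz <- coords(atoms) %*% t(rot)
  vdw <- atoms$atoms$vdw_radius
  heavy <- atoms$atoms$element != "H"
  hit <- rep(FALSE, nrow(xyz))
  for (i in idx) {
    if (!is.finite(profile$radius[i]) || !is.finite(profile$cx[i])) next
    d <- sqrt((xyz[, 1] - profile$cx[i])^2 + (xyz[, 2] - profile$cy[i])^2 +
              (xyz[, 3] - (profile$z[i] + z_origin))^2) -
         vdw - profile$radius[i]
    hit <- hit | (heavy & d <= lining_cutoff)
  }
  res <- unique(atoms$atoms[hit, c("resname", "resid", "chain")])
  rownames(res) <- NULL
  res
}

#' @export
print.gate_region <- function(x, ...) {
  cat(sprintf("<gate_region> z [%.2f, %.2f] A, min radius %.2f A at z = %.2f%s\n",
              x$z_min, x$z_max, x$min_radius, x$z_at_min,
              if (is.na(x$hydrophobic_fraction)) ""
              else sprintf(", hydrophobic fraction %.2f", x$hydrophobic_fraction)))
  invisible(x)
}

#' Write a pore profile as TSV
#'
#' Columns `z_A`, `radius_A`, `cx_A`, `cy_A`.
#'
#' @param profile A `pore_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(z_A = profile$z, radius_A = profile$radius,
                   cx_A = profile$cx, cy_A = profile$cy)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pore profile TSV written by [write_profile()]
#' @param path TSV path.
#' @param axis,origin Optional metadata to re-attach.
#' @return A `pore_profile`.
#' @export
read_profile <- function(path, axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- data.frame(z = df$z_A, radius = df$radius_A, cx = df$cx_A, cy = df$cy_A)
  step <- if (nrow(out) > 1) stats::median(diff(out$z)) else 1
  structure(out, class = c("pore_profile", "data.frame"),
            axis = axis, origin = origin, step = step,
            rotation = axis_rotation(axis), z_origin = 0)
}
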