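#' 1-D potential specification
#'
#' Prescribed free-energy landscapes U(z) (kJ/mol over Angstrom) used by
#' the synthetic samplers: `flat`, `harmonic` (`k/2 (z-center)^2`, `k` in
#' kJ/mol/A^2), `gaussian_barrier` (`height exp(-(z-center)^2/(2 width^2))`)
#' and `double_well` (`height (((z-center)/width)^2 - 1)^2`: minima at
#' `center +/- width`, barrier `height` between them).
#'
#' @param kind One of `"flat"`, `"harmonic"`, `"gaussian_barrier"`,
#'   `"double_well"`.
#' @param height Barrier height (kJ/mol); `k` for harmonic.
#' @param width Width scale (A).
#' @param center Centre (A).
#' @return Object of class `potential_spec`.
#' @export
potential_spec <- function(kind = c("flat", "harmonic", "gaussian_barrier",
                                    "double_well"),
                           height = 10, width = 3, center = 0) {
  kind <- match.arg(kind)
  stopifnot(is.finite(height), width > 0, is.finite(center))
  structure(list(kind = kind, height = height, width = width,
                 center = center),
            class = "potential_spec")
}

#' Evaluate a potential specification as a function U(z)
#' @param spec A [potential_spec()].
#' @return Function mapping z (A) to energy (kJ/mol).
#' @export
potential_fn <- function(spec) {
  stopifnot(inherits(spec, "potential_spec"))
  switch(spec$kind,
    flat = function(z) rep(0, length(z)),
    harmonic = function(z) 0.5 * spec$height * (z - spec$center)^2,
    gaussian_barrier = function(z)
      spec$height * exp(-(z - spec$center)^2 / (2 * spec$width^2)),
    double_well = function(z)
      spec$height * (((z - spec$center) / spec$width)^2 - 1)^2)
}

pore_atoms_from_rings <- function(ring_z, ring_r, atom_spacing, vdw,
                                  resnames) {
  rows <- list()
  serial <- 0L
  for (i in seq_along(ring_z)) {
    n_ang <- max(6L, ceiling(2 * pi * ring_r[i] / atom_spacing))
    th <- 2 * pi * (seq_len(n_ang) - 1) / n_ang
    rows[[i]] <- data.frame(
      serial = serial + seq_len(n_ang),
      name = "C", resname = resnames[i], resid = i, chain = "A",
      x = ring_r[i] * cos(th), y = ring_r[i] * sin(th), z = ring_z[i],
      element = "C", vdw_radius = vdw, stringsAsFactors = FALSE)
    serial <- serial + n_ang
  }
  atom_set(do.call(rbind, rows), provenance = list(source = "synthetic"))
}

# Largest perturbation of the inscribed radius caused by discretising the
# wall into atoms with spacing s on a ring of radius R: the probe sees the
# gap midpoint at distance ~ sqrt(R^2 + 2 (s/2)^2), i.e. ~ s^2/(4R) farther.
spacing_perturbation <- function(wall_radius, atom_spacing) {
  atom_spacing^2 / (4 * wall_radius)
}

#' Synthetic cylindrical pore
#'
#' A cylindrical lattice of pseudo-atoms whose inscribed probe radius is
#' `wall_radius - vdw` by construction — the geometry oracle for the pore
#' profiler. The atom spacing must be fine enough that discretisation
#' perturbs the inscribed radius by less than 0.05 A.
#'
#' @param wall_radius Radius of the atom-centre wall (A).
#' @param length Pore length (A), centred on z = 0.
#' @param atom_spacing Lattice spacing (A).
#' @param vdw Pseudo-atom van der Waals radius (A).
#' @return An [atom_set] with radii assigned.
#' @export
make_cylinder_pore <- function(wall_radius = 10, length = 30,
                               atom_spacing = 1, vdw = 1.85) {
  stopifnot(wall_radius > vdw, length > 0, atom_spacing > 0, vdw > 0)
  if (spacing_perturbation(wall_radius, atom_spacing) > 0.05)
    stop(sprintf(
      "atom_spacing %.2f A perturbs the inscribed radius by > 0.05 A at wall radius %.2f A",
      atom_spacing, wall_radius))
  zs <- seq(-length / 2, length / 2, by = atom_spacing)
  pore_atoms_from_rings(zs, rep(wall_radius, length(zs)), atom_spacing, vdw,
                        rep("POR", length(zs)))
}

#' Synthetic hourglass pore
#'
#' A pore whose wall radius narrows smoothly (Gaussian waist) from
#' `mouth_radius` to `waist_radius` at `waist_z` — a model of the central
#' hydrophobic constriction of a channel. Rings near the waist are
#' labelled LEU (hydrophobic), the rest SER, so gate lining and
#' hydrophobic fractions can be exercised.
#'
#' @param mouth_radius,waist_radius Wall radii at mouth / waist (A).
#' @param waist_z Axial position of the waist (A).
#' @param waist_width Gaussian width of the constriction (A).
#' @param length Pore length (A), centred on z = 0.
#' @param atom_spacing Lattice spacing (A).
#' @param vdw Pseudo-atom vdW radius (A).
#' @param hydrophobic_band Half-width (A) of the LEU-labelled band about
#'   the waist; rings outside it are SER.
#' @return An [atom_set] with radii assigned.
#' @export
make_hourglass_pore <- function(mouth_radius = 10, waist_radius = 4,
                                waist_z = 0, waist_width = 4, length = 30,
                                atom_spacing = 0.8, vdw = 1.85,
                                hydrophobic_band = 2.5 * waist_width) {
  stopifnot(mouth_radius >= waist_radius, waist_radius > vdw, length > 0)
  if (spacing_perturbation(waist_radius, atom_spacing) > 0.05)
    stop("atom_spacing too coarse for the waist radius (> 0.05 A perturbation)")
  zs <- seq(-length / 2, length / 2, by = atom_spacing)
  rr <- mouth_radius - (mouth_radius - waist_radius) *
    exp(-(zs - waist_z)^2 / (2 * waist_width^2))
  resnames <- ifelse(abs(zs - waist_z) <= hydrophobic_band, "LEU", "SER")
  pore_atoms_from_rings(zs, rr, atom_spacing, vdw, resnames)
}

# Vectorised Metropolis sweep on z for independent walkers; returns updated
# positions and the number of accepted moves.
metropolis_step <- function(z, U, kT, step, lo, hi) {
  prop <- z + stats::runif(length(z), -step, step)
  # reflect at the sampling range so the stationary density stays exp(-U/kT)
  below <- prop < lo; prop[below] <- 2 * lo - prop[below]
  above <- prop > hi; prop[above] <- 2 * hi - prop[above]
  dU <- U(prop) - U(z)
  acc <- log(stats::runif(length(z))) < -dU / kT
  z[acc] <- prop[acc]
  list(z = z, accepted = sum(acc))
}

#' Metropolis-sampled water trajectory in a pore cylinder
#'
#' Draws per-frame axial positions for `n_waters` independent walkers with
#' stationary density proportional to `exp(-U(z)/kT)` on
#' `[cyl$z_lo, cyl$z_hi]` (bounded-step Metropolis proposals preserve
#' particle identity between frames); in-plane positions perform a
#' reflected random walk inside the cylinder radius. A burn-in period is
#' discarded before recording. The result mimics the equilibrium water
#' behaviour inside a pore without running MD.
#'
#' @param potential A [potential_spec()] (or function of z, kJ/mol).
#' @param cyl A [pore_cylinder()].
#' @param n_waters,n_frames Walker and frame counts.
#' @param temperature Temperature (K).
#' @param seed Integer seed; the trajectory is fully reproducible.
#' @param step Metropolis half-step (A).
#' @param substeps Metropolis sweeps between recorded frames.
#' @param burn_in Discarded initial sweeps.
#' @param timestep Nominal frame spacing (ns).
#' @return A [trajectory] of water oxygens (resname HOH, name O).
#' @export
sample_water_trajectory <- function(potential, cyl, n_waters = 100,
                                    n_frames = 1000, temperature = 310,
                                    seed = NULL, step = 1.0, substeps = 10,
                                    burn_in = 500, timestep = 0.01) {
  stopifnot(inherits(cyl, "pore_cylinder"), n_waters >= 1, n_frames >= 1)
  U <- if (inherits(potential, "potential_spec")) potential_fn(potential)
       else potential
  kT <- thermal_energy(temperature)
  basis <- plane_basis(cyl$axis)
  with_seed(seed, {
    z <- stats::runif(n_waters, cyl$z_lo, cyl$z_hi)
    ang <- stats::runif(n_waters, 0, 2 * pi)
    rad <- cyl$radius * sqrt(stats::runif(n_waters))
    px <- rad * cos(ang); py <- rad * sin(ang)
    accepted <- 0; proposed <- 0
    sweep_xy <- function(px, py) {
      qx <- px + stats::rnorm(n_waters, sd = 0.5)
      qy <- py + stats::rnorm(n_waters, sd = 0.5)
      out <- sqrt(qx^2 + qy^2) > cyl$radius
      qx[out] <- px[out]; qy[out] <- py[out]
      list(px = qx, py = qy)
    }
    for (b in seq_len(burn_in)) {
      st <- metropolis_step(z, U, kT, step, cyl$z_lo, cyl$z_hi)
      z <- st$z
    }
    frames <- array(0, dim = c(n_waters, 3, n_frames))
    for (f in seq_len(n_frames)) {
      for (s in seq_len(substeps)) {
        st <- metropolis_step(z, U, kT, step, cyl$z_lo, cyl$z_hi)
        z <- st$z
        accepted <- accepted + st$accepted
        proposed <- proposed + n_waters
      }
      xy <- sweep_xy(px, py); px <- xy$px; py <- xy$py
      frames[, , f] <- matrix(cyl$center, n_waters, 3, byrow = TRUE) +
        outer(z, basis$axis) + outer(px, basis$e1) + outer(py, basis$e2)
    }
    if (accepted / proposed < 0.02)
      stop(sprintf(
        "Metropolis acceptance collapsed (%.1f%%): barrier too high for step %.2f A; reduce the step",
        100 * accepted / proposed, step))
    topo <- atom_set(data.frame(
      serial = seq_len(n_waters), name = "O", resname = "HOH",
      resid = seq_len(n_waters), chain = "W",
      x = frames[, 1, 1], y = frames[, 2, 1], z = frames[, 3, 1],
      element = "O", vdw_radius = 1.65, stringsAsFactors = FALSE),
      provenance = list(source = "synthetic water sampler", seed = seed))
    trajectory(topo, frames, timestep = timestep)
  })
}

#' Synthetic umbrella-sampling dataset
#'
#' Metropolis-samples each window from `exp(-(U(z) + w_i(z))/kT)` with the
#' harmonic bias `w_i(z) = k/2 ((z - c_i)/10)^2` (force constant in
#' kJ mol^-1 nm^-2). Defaults follow the standard pLGIC protocol: 1 A
#' window spacing and k = 1000 kJ mol^-1 nm^-2 at 310 K.
#'
#' @param potential A [potential_spec()] (or function of z).
#' @param centers Window centres (A).
#' @param force_constant Bias force constant (kJ mol^-1 nm^-2).
#' @param n_samples Recorded samples per window.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @param step Metropolis half-step (A).
#' @param substeps Sweeps between recorded samples.
#' @param burn_in Discarded initial sweeps.
#' @param timestep Nominal sample spacing (ns).
#' @return An [umbrella_dataset()].
#' @export
make_umbrella_dataset <- function(potential, centers = seq(-10, 10, by = 1),
                                  force_constant = 1000, n_samples = 2000,
                                  temperature = 310, seed = NULL,
                                  step = 0.5, substeps = 5, burn_in = 200,
                                  timestep = 0.001) {
  U <- if (inherits(potential, "potential_spec")) potential_fn(potential)
       else potential
  kT <- thermal_energy(temperature)
  nw <- length(centers)
  Utot <- function(z) U(z) + bias_energy(z, centers, force_constant)
  lo <- min(centers) - 10; hi <- max(centers) + 10
  with_seed(seed, {
    z <- centers
    for (b in seq_len(burn_in)) z <- metropolis_step(z, Utot, kT, step, lo, hi)$z
    samples <- matrix(0, nw, n_samples)
    for (s in seq_len(n_samples)) {
      for (k in seq_len(substeps))
        z <- metropolis_step(z, Utot, kT, step, lo, hi)$z
      samples[, s] <- z
    }
    times <- seq_len(n_samples) * timestep
    windows <- lapply(seq_len(nw), function(i)
      umbrella_window(centers[i], force_constant, samples[i, ], times))
    umbrella_dataset(windows, temperature = temperature)
  })
}

#' Charged parallel-slab frame
#'
#' Two planar sheets of pseudo-atoms carrying opposite surface charge —
#' the parallel-plate capacitor whose analytic voltage
#' `dV = sigma * separation / eps0` serves as the closed-form oracle for
#' the Poisson integrator. The frame is net-neutral by construction;
#' requesting unbalanced sheet charges is an error.
#'
#' @param sigma Surface charge density (e/A^2): a scalar (sheets get
#'   +sigma and -sigma) or a length-2 vector summing to zero.
#' @param separation Sheet separation along z (A).
#' @param box Box lengths (A); sheets are centred in z.
#' @param nx Atoms per sheet edge (nx^2 atoms per sheet).
#' @return list with `atoms` (an [atom_set] frame), `charges` (e, per
#'   atom), and `dV_analytic` (volts).
#' @export
make_charged_slabs <- function(sigma = 1e-3, separation = 40,
                               box = c(40, 40, 100), nx = 10) {
  stopifnot(separation > 0, length(box) == 3L, all(box > 0), nx >= 2)
  if (length(sigma) == 1L) sigma <- c(sigma, -sigma)
  stopifnot(length(sigma) == 2L)
  if (abs(sum(sigma)) > 1e-15 * max(abs(sigma), 1e-30))
    stop("sheet charges must balance (net-neutral frame required)")
  z_sheets <- box[3] / 2 + c(-1, 1) * separation / 2
  area <- box[1] * box[2]
  gx <- (seq_len(nx) - 0.5) / nx * box[1]
  gy <- (seq_len(nx) - 0.5) / nx * box[2]
  grid <- expand.grid(x = gx, y = gy)
  n_sheet <- nrow(grid)
  atoms <- data.frame(
    serial = seq_len(2L * n_sheet),
    name = "Q", resname = "SLB",
    resid = rep(1:2, each = n_sheet), chain = "A",
    x = rep(grid$x, 2), y = rep(grid$y, 2),
    z = rep(z_sheets, each = n_sheet),
    element = "X", vdw_radius = 1.0, stringsAsFactors = FALSE)
  charges <- rep(sigma * area / n_sheet, each = n_sheet)
  dV <- abs(sigma[1]) * .e_charge / 1e-20 * (separation * 1e-10) / .eps0
  list(atoms = atom_set(atoms, box = box,
                        provenance = list(source = "synthetic charged slabs")),
       charges = charges, dV_analytic = dV)
}
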