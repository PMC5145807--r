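make_water_traj <- function(zmat, radius_offsets = NULL) {
  # build a trajectory whose water p sits at (offset, 0, z) each frame
  np <- nrow(zmat); nf <- ncol(zmat)
  if (is.null(radius_offsets)) radius_offsets <- rep(0, np)
  frames <- array(0, dim = c(np, 3, nf))
  for (f in seq_len(nf)) {
    frames[, 1, f] <- radius_offsets
    frames[, 3, f] <- zmat[, f]
  }
  topo <- atom_set(data.frame(
    serial = seq_len(np), name = "O", resname = "HOH",
    resid = seq_len(np), chain = "W",
    x = frames[, 1, 1], y = 0, z = frames[, 3, 1],
    element = "O", stringsAsFactors = FALSE))
  trajectory(topo, frames, timestep = 1)
}

test_that("axial tracks keep identities and apply the cylinder test", {
  cyl <- pore_cylinder(radius = 3, z_lo = -10, z_hi = 10)
  zmat <- rbind(rep(2, 5), rep(0, 5))
  traj <- make_water_traj(zmat, radius_offsets = c(0, 5))  # second outside r
  tr <- water_axial_tracks(traj, "resname HOH", cyl)
  expect_equal(tr$z[1, ], rep(2, 5))
  expect_true(all(tr$inpore[1, ]))
  expect_false(any(tr$inpore[2, ]))
  expect_error(water_axial_tracks(traj, "resname XXX", cyl), "no atoms")
})

test_that("in-pore membership equals the brute-force cylinder oracle", {
  cyl <- pore_cylinder(axis = c(0, 0, 1), center = c(1, -2, 3),
                       radius = 4, z_lo = -8, z_hi = 8)
  set.seed(7)
  np <- 100; nf <- 6
  frames <- array(rnorm(np * 3 * nf, sd = 6), dim = c(np, 3, nf))
  topo <- atom_set(data.frame(
    serial = seq_len(np), name = "O", resname = "HOH", resid = seq_len(np),
    chain = "W", x = frames[, 1, 1], y = frames[, 2, 1], z = frames[, 3, 1],
    element = "O", stringsAsFactors = FALSE))
  traj <- trajectory(topo, frames, timestep = 1)
  tr <- water_axial_tracks(traj, "resname HOH", cyl)
  for (f in seq_len(nf))
    expect_equal(tr$inpore[, f],
                 as.vector(in_cylinder_oracle(frames[, , f], cyl)))
})

test_that("dewetted fraction counts empty-slab frames and ignores frame order", {
  always <- tracks_from_z(matrix(0, 1, 10))
  expect_equal(occupancy_and_dewetting(always, c(-1, 1))$dewetted_fraction, 0)

  never <- tracks_from_z(matrix(4.9, 1, 10))
  expect_equal(occupancy_and_dewetting(never, c(-1, 1))$dewetted_fraction, 1)

  alternating <- tracks_from_z(matrix(rep(c(0, 4), 5), 1))
  expect_equal(occupancy_and_dewetting(alternating, c(-1, 1))$dewetted_fraction,
               0.5)

  set.seed(1)
  z <- matrix(runif(200, -6, 6), 4)
  perm <- sample(ncol(z))
  t1 <- occupancy_and_dewetting(tracks_from_z(z), c(-2, 2))
  t2 <- occupancy_and_dewetting(tracks_from_z(z[, perm]), c(-2, 2))
  expect_equal(t1$dewetted_fraction, t2$dewetted_fraction)
})

test_that("permeation counting uses two-gate hysteresis", {
  # monotone traverse: one up event
  up <- tracks_from_z(matrix(seq(-8, 8, length.out = 20), 1))
  r <- count_permeation_events(up, -5, 5)
  expect_equal(r$events_up, 1L)
  expect_equal(r$events_down, 0L)
  expect_equal(nrow(r$log), 1L)
  expect_equal(r$log$direction, "up")

  # oscillation across the lower gate only: no events
  osc <- tracks_from_z(matrix(rep(c(-6, -4), 10), 1))
  r2 <- count_permeation_events(osc, -5, 5)
  expect_equal(r2$events_up + r2$events_down, 0L)

  # rate identity
  expect_equal(r$rate, (r$events_up + r$events_down) / r$duration)
  expect_error(count_permeation_events(up, 5, -5), "z_lo")
})

test_that("event counts match the state-machine oracle on random walks", {
  set.seed(23)
  z <- matrix(0, 500, 120)
  z[, 1] <- runif(500, -12, 12)
  for (f in 2:120) z[, f] <- z[, f - 1] + rnorm(500, sd = 2.5)
  tr <- tracks_from_z(z, z_lo = -6, z_hi = 6)
  got <- count_permeation_events(tr, -6, 6)
  want <- flux_oracle(z, -6, 6)
  expect_identical(got$events_up, want$up)
  expect_identical(got$events_down, want$down)

  # time reversal swaps the directions and preserves the total
  rev_tr <- tracks_from_z(z[, ncol(z):1], z_lo = -6, z_hi = 6)
  back <- count_permeation_events(rev_tr, -6, 6)
  expect_identical(back$events_up, got$events_down)
  expect_identical(back$events_down, got$events_up)
  expect_equal(back$rate, got$rate)
})

test_that("density histogram conserves every in-pore observation", {
  set.seed(3)
  z <- matrix(runif(50 * 40, -10, 10), 50)
  tr <- tracks_from_z(z, z_lo = -10, z_hi = 10, radius = 5)
  d <- density_profile(tr, bin_width = 1)
  expect_equal(sum(d$counts) * d$n_frames, sum(tr$inpore & z >= -10 & z <= 10))
  expect_true(all(d$counts_total == round(d$counts_total)))

  # an empty slab yields zero counts in those bins
  z2 <- matrix(runif(400, 3, 10), 10)
  d2 <- density_profile(tracks_from_z(z2, z_lo = -10, z_hi = 10), 1)
  ctr <- (d2$bin_edges[-1] + d2$bin_edges[-length(d2$bin_edges)]) / 2
  expect_true(all(d2$counts[ctr < 2.5] == 0))
})

test_that("Boltzmann inversion matches the closed form and is invertible", {
  # flat density -> zero free energy everywhere
  flat <- new_density_profile(seq(-5, 5), rep(100L, 10), n_frames = 10)
  fe <- boltzmann_invert(flat, temperature = 310)
  expect_equal(fe$energy, rep(0, 10), tolerance = 1e-12)

  # a dip to 1% of bulk at 310 K is a barrier of -kT ln(0.01) ~ 11.9 kJ/mol
  counts <- rep(1000L, 21); counts[11] <- 10L
  dip <- new_density_profile(seq(-10.5, 10.5), counts, n_frames = 1)
  fe2 <- boltzmann_invert(dip, temperature = 310)
  expect_equal(max(fe2$energy), thermal_energy(310) * log(100),
               tolerance = 1e-9)
  expect_equal(thermal_energy(310) * log(100), 11.87, tolerance = 0.01)

  # round trip: re-exponentiating recovers the density up to the constant C
  n_back <- exp(-fe2$energy / thermal_energy(310))
  expect_equal(n_back / n_back[1], counts / counts[1], tolerance = 1e-9)
})

test_that("empty interior bins become finite lower bounds, not infinities", {
  counts <- c(50L, 50L, 50L, 0L, 0L, 50L, 50L, 50L)
  d <- new_density_profile(seq(-4, 4), counts, n_frames = 25)
  fe <- boltzmann_invert(d, 310)
  expect_true(all(is.finite(fe$energy)))
  expect_identical(fe$lower_bound_mask, counts == 0L)
  # the lower bound corresponds to < 1 observation in the whole run
  kT <- thermal_energy(310)
  expect_equal(max(fe$energy), -kT * log(1 / 25) + kT * log(2),
               tolerance = 1e-9)
  expect_error(boltzmann_invert(new_density_profile(seq(-2, 2),
                                                    rep(0L, 4), 5)),
               "empty")
})

test_that("hydration numbers count shell members like the brute force", {
  # 6 waters at 2.3 A around an ion: all first shell at cutoff 3.0
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  wat <- 2.3 * dirs
  at <- data.frame(
    serial = 1:7,
    name = c("NA", rep("O", 6)),
    resname = c("NA", rep("HOH", 6)),
    resid = 1:7, chain = "A",
    x = c(0, wat[, 1]), y = c(0, wat[, 2]), z = c(0, wat[, 3]),
    element = c("NA", rep("O", 6)), stringsAsFactors = FALSE)
  topo <- atom_set(at)
  traj <- trajectory(topo, array(as.matrix(at[, c("x", "y", "z")]),
                                 dim = c(7, 3, 1)))
  hn <- hydration_numbers(traj, "element NA", 3.0, 5.5,
                          waters = "resname HOH")
  expect_equal(hn$first_shell, 6L)
  expect_equal(hn$second_shell, 0L)

  # no waters in range
  far <- at; far[2:7, c("x", "y", "z")] <- far[2:7, c("x", "y", "z")] + 50
  traj2 <- trajectory(atom_set(far), array(as.matrix(far[, c("x", "y", "z")]),
                                           dim = c(7, 3, 1)))
  hn2 <- hydration_numbers(traj2, "element NA", 3.2, 5.5,
                           waters = "resname HOH")
  expect_equal(c(hn2$first_shell, hn2$second_shell), c(0L, 0L))

  # random cloud vs direct pairwise distances
  set.seed(9)
  n <- 80
  cloud <- data.frame(
    serial = 1:(n + 1), name = c("CL", rep("O", n)),
    resname = c("CL", rep("HOH", n)), resid = 1:(n + 1), chain = "A",
    x = c(0, rnorm(n, sd = 4)), y = c(0, rnorm(n, sd = 4)),
    z = c(0, rnorm(n, sd = 4)), element = c("CL", rep("O", n)),
    stringsAsFactors = FALSE)
  traj3 <- trajectory(atom_set(cloud),
                      array(as.matrix(cloud[, c("x", "y", "z")]),
                            dim = c(n + 1, 3, 1)))
  hn3 <- hydration_numbers(traj3, "element CL", 3.9, 6.2,
                           waters = "resname HOH")
  r <- sqrt(rowSums(as.matrix(cloud[-1, c("x", "y", "z")])^2))
  expect_equal(hn3$first_shell, sum(r <= 3.9))
  expect_equal(hn3$second_shell, sum(r > 3.9 & r <= 6.2))

  expect_error(hydration_numbers(traj3, "resname HOH", 3, 5), "exactly one")
})
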