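write_window_files <- function(dir, centers, k = 1000, n = 50, sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  meta <- data.frame(path = character(), center_A = numeric(),
                     k_kJ_mol_nm2 = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(centers)) {
    p <- file.path(dir, sprintf("win%02d.dat", i))
    z <- rnorm(n, centers[i], sd)
    write.table(data.frame(t = seq_len(n) * 0.001, z = z), p,
                sep = " ", row.names = FALSE, col.names = FALSE)
    meta[i, ] <- list(p, centers[i], k)
  }
  meta
}

test_that("umbrella windows load, sort and validate overlap", {
  dir <- withr::local_tempdir()
  meta <- write_window_files(dir, centers = c(2, 0, 1))
  ds <- load_umbrella_windows(meta)
  expect_equal(vapply(ds$windows, function(w) w$center, 0), c(0, 1, 2))
  expect_equal(length(ds$windows), 3L)

  # disjoint histograms warn
  meta2 <- write_window_files(dir, centers = c(0, 30), sd = 0.2, seed = 2)
  expect_warning(load_umbrella_windows(meta2), "no occupied bin")

  # non-numeric rows error with file and line
  bad <- file.path(dir, "bad.dat")
  writeLines(c("0.001 1.0", "0.002 oops"), bad)
  expect_error(
    load_umbrella_windows(data.frame(path = bad, center_A = 0,
                                     k_kJ_mol_nm2 = 1000)),
    "line 2")
})

test_that("window samples under a pure bias have the analytic Gaussian moments", {
  # the harmonic bias k = 1000 kJ/mol/nm^2 on a flat landscape gives, after
  # the nm^2 -> A^2 conversion, sd = sqrt(kT / (k/100)) ~ 0.51 A at 310 K;
  # getting this wrong by the unit factor (10x) would be unmissable here
  ds <- make_umbrella_dataset(potential_spec("flat"),
                              centers = c(-1, 0, 1), force_constant = 1000,
                              n_samples = 4000, seed = 31)
  kT <- thermal_energy(310)
  for (w in ds$windows) {
    expect_equal(mean(w$samples), w$center, tolerance = 0.05)
    expect_equal(stats::var(w$samples), kT / 10, tolerance = 0.03)
  }
})

test_that("WHAM on a single unbiased window equals Boltzmann inversion", {
  set.seed(5)
  samples <- runif(4000, -10, 10)
  w <- umbrella_window(center = 0, force_constant = 1e-12,
                       samples = samples)
  ds <- umbrella_dataset(list(w), temperature = 310)
  bins <- seq(-10, 10, by = 1)
  p <- wham(ds, bins = bins)
  expect_lte(p$n_iter, 3L)

  counts <- tabulate(findInterval(samples, bins, rightmost.closed = TRUE),
                     nbins = length(bins) - 1L)
  fe <- boltzmann_invert(new_density_profile(bins, counts, n_frames = 1),
                         temperature = 310)
  expect_equal(p$energy, fe$energy, tolerance = 1e-9)
})

test_that("iid Gaussian windows on a flat landscape give a flat PMF", {
  set.seed(8)
  kT <- thermal_energy(310)
  centers <- seq(-5, 5, by = 1)
  sdw <- sqrt(kT / 10)  # k = 1000 kJ/mol/nm^2
  windows <- lapply(centers, function(c0)
    umbrella_window(c0, 1000, rnorm(8000, c0, sdw)))
  p <- wham(umbrella_dataset(windows), bins = seq(-5.5, 5.5, 0.5))
  expect_lt(max(abs(p$energy), na.rm = TRUE), 0.3)
})

test_that("WHAM recovers known landscapes from Metropolis windows", {
  cases <- list(
    list(spec = potential_spec("gaussian_barrier", height = 15, width = 3),
         centers = seq(-10, 10, 1), well_sampled = 10),
    list(spec = potential_spec("harmonic", height = 0.3),
         centers = seq(-8, 8, 1), well_sampled = 7),
    list(spec = potential_spec("double_well", height = 8, width = 6),
         centers = seq(-9, 9, 1), well_sampled = 8))
  for (case in cases) {
    ds <- make_umbrella_dataset(case$spec, centers = case$centers,
                                n_samples = 3000, seed = 17)
    p <- wham(ds)
    u <- potential_fn(case$spec)
    ok <- is.finite(p$energy) & abs(p$z) <= case$well_sampled
    # a PMF is defined up to an additive constant; compare shapes over the
    # well-sampled bins (the bulk-zero convention only pins the constant
    # when the landscape is flat at the ends, which the double well is not)
    dev <- p$energy[ok] - u(p$z)[ok]
    expect_lt(sqrt(mean((dev - mean(dev))^2)), 1.0)
  }
})

test_that("the WHAM self-consistency iteration reports convergence", {
  ds <- make_umbrella_dataset(potential_spec("harmonic", height = 0.5),
                              centers = seq(-4, 4, 1), n_samples = 500,
                              seed = 3)
  p <- wham(ds, tol = 1e-6)
  expect_gt(p$n_iter, 1L)
  expect_error(wham(ds, max_iter = 2), "did not converge")
})

test_that("bootstrap errors are seeded, shrink with data, and vanish for degenerate windows", {
  # every window holds a single sample: resampling is the identity, so the
  # replicate PMFs coincide and the error bars are exactly zero
  suppressWarnings({
    one <- umbrella_dataset(lapply(seq(-2, 2), function(c0)
      umbrella_window(c0, 1000, c0)))
    z0 <- bootstrap_errors(one, bins = seq(-2.5, 2.5, 1), n_boot = 3,
                           seed = 1)
  })
  expect_equal(max(z0$error, na.rm = TRUE), 0)

  expect_error(bootstrap_errors(one, n_boot = 1), "at least 2")

  ds_small <- make_umbrella_dataset(potential_spec("flat"),
                                    centers = seq(-3, 3, 1),
                                    n_samples = 100, seed = 7)
  ds_big <- make_umbrella_dataset(potential_spec("flat"),
                                  centers = seq(-3, 3, 1),
                                  n_samples = 2000, seed = 7)
  bins <- seq(-3.5, 3.5, 0.5)
  e_small <- bootstrap_errors(ds_small, bins, n_boot = 12, seed = 5)
  e_big <- bootstrap_errors(ds_big, bins, n_boot = 12, seed = 5)
  expect_lt(mean(e_big$error, na.rm = TRUE),
            mean(e_small$error, na.rm = TRUE))

  again <- bootstrap_errors(ds_small, bins, n_boot = 12, seed = 5)
  expect_identical(e_small$error, again$error)
})

test_that("convergence series ends at the full-data barrier and flags drift", {
  ds <- make_umbrella_dataset(potential_spec("gaussian_barrier", height = 10,
                                             width = 2),
                              centers = seq(-6, 6, 1), n_samples = 1000,
                              seed = 9, timestep = 0.001)
  cs <- convergence_series(ds, segment = 0.25, barrier_region = c(-2, 2))
  expect_equal(nrow(cs), 4L)
  full <- wham(ds)
  expect_equal(cs$barrier[4], barrier_height(full, c(-2, 2)),
               tolerance = 1e-9)
  # stationary sampling: later cumulative estimates stay near the final one
  expect_lt(max(abs(cs$barrier[-1] - cs$barrier[4])), 1.5)

  expect_error(convergence_series(ds, segment = 10, c(-2, 2)),
               "exceeds")

  # non-equilibrated windows: an early transient shifts the barrier estimate
  drift <- ds
  drift$windows <- lapply(drift$windows, function(w) {
    n <- length(w$samples)
    shift <- c(rep(2, n %/% 4), rep(0, n - n %/% 4))
    umbrella_window(w$center, w$force_constant, w$samples + shift, w$times)
  })
  cs2 <- convergence_series(drift, segment = 0.25, barrier_region = c(-2, 2),
                            bins = seq(-7.5, 9.5, by = 0.5))
  expect_gt(abs(cs2$barrier[1] - cs2$barrier[4]), 1.0)
})

test_that("the PMF is invariant to a constant shift of the initial guesses", {
  ds <- make_umbrella_dataset(potential_spec("gaussian_barrier", height = 6),
                              centers = seq(-4, 4, 1), n_samples = 400,
                              seed = 13)
  p0 <- wham(ds)
  p1 <- wham(ds, f_init = rep(12.34, length(ds$windows)))
  expect_equal(p0$energy, p1$energy, tolerance = 1e-6)
})
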