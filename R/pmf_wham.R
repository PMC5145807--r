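#' Umbrella-sampling window
#'
#' One biased simulation window: a harmonic restraint
#' `w(z) = k/2 (z - center)^2` on the axial coordinate (force constant in
#' kJ mol^-1 nm^-2, coordinates in Angstrom; the unit conversion
#' 1 nm^2 = 100 A^2 is applied wherever the bias is evaluated) together
#' with the reaction-coordinate time series sampled under that bias.
#'
#' @param center Bias anchor on z (A).
#' @param force_constant Harmonic force constant (kJ mol^-1 nm^-2).
#' @param samples Reaction-coordinate samples (A).
#' @param times Optional per-sample times (ns).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant = 1000, samples,
                            times = NULL) {
  stopifnot(force_constant > 0, length(samples) >= 1, all(is.finite(samples)))
  if (!is.null(times)) stopifnot(length(times) == length(samples))
  structure(list(center = center, force_constant = force_constant,
                 samples = as.numeric(samples), times = times),
            class = "umbrella_window")
}

# Harmonic bias energy in kJ/mol for coordinates in Angstrom.
bias_energy <- function(z, center, force_constant) {
  0.5 * force_constant * ((z - center) / 10)^2
}

#' Umbrella dataset
#'
#' Ordered collection of windows at one temperature. Windows are sorted by
#' bias centre; a warning is raised if any adjacent pair of windows shares
#' no occupied histogram bin (no overlap means WHAM cannot stitch them).
#'
#' @param windows list of [umbrella_window()] objects.
#' @param temperature Temperature (K).
#' @param bin_width Bin width used for the overlap diagnostic (A).
#' @return Object of class `umbrella_dataset`.
#' @export
umbrella_dataset <- function(windows, temperature = 310, bin_width = 0.5) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "umbrella_window")))
  centers <- vapply(windows, function(w) w$center, 0)
  windows <- windows[order(centers)]
  centers <- sort(centers)
  if (length(windows) > 1L) {
    rng <- range(unlist(lapply(windows, function(w) w$samples)))
    edges <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
    occ <- lapply(windows, function(w)
      unique(findInterval(w$samples, edges)))
    for (i in seq_len(length(windows) - 1L)) {
      if (!length(intersect(occ[[i]], occ[[i + 1L]])))
        warning(sprintf(
          "windows at z = %g and z = %g A share no occupied bin (histogram gap)",
          centers[i], centers[i + 1L]))
    }
  }
  structure(list(windows = windows, temperature = temperature),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  centers <- vapply(x$windows, function(w) w$center, 0)
  cat(sprintf("<umbrella_dataset> %d windows, centers %g..%g A, T = %g K\n",
              length(x$windows), min(centers), max(centers), x$temperature))
  invisible(x)
}

#' Load umbrella windows from two-column files
#'
#' Each window file is plain text with two whitespace-separated columns
#' (time in ns, reaction coordinate in A); lines starting with `#` or `@`
#' are skipped. Metadata (file path, bias centre, force constant) comes
#' from a data.frame or a TSV file with columns `path`, `center_A`,
#' `k_kJ_mol_nm2`.
#'
#' @param meta data.frame or path to a metadata TSV.
#' @param temperature Temperature (K).
#' @return An [umbrella_dataset()].
#' @export
load_umbrella_windows <- function(meta, temperature = 310) {
  if (is.character(meta))
    meta <- utils::read.table(meta, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  req <- c("path", "center_A", "k_kJ_mol_nm2")
  if (!all(req %in% names(meta)))
    stop("window metadata needs columns: ", paste(req, collapse = ", "))
  windows <- lapply(seq_len(nrow(meta)), function(i) {
    ts <- read_window_file(meta$path[i])
    umbrella_window(center = meta$center_A[i],
                    force_constant = meta$k_kJ_mol_nm2[i],
                    samples = ts$z, times = ts$time)
  })
  umbrella_dataset(windows, temperature = temperature)
}

read_window_file <- function(path) {
  if (!file.exists(path)) stop("window file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|@|$)", lines))
  if (!length(keep)) stop("no data rows in window file: ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  for (j in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[j]][1:2]))
    if (length(fields[[j]]) < 2L || anyNA(v))
      stop(sprintf("non-numeric row at line %d of '%s'", keep[j], path))
  }
  m <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
  list(time = m[, 1], z = m[, 2])
}

default_wham_bins <- function(dataset, bin_width = 0.5, pad = 1.0) {
  centers <- vapply(dataset$windows, function(w) w$center, 0)
  seq(min(centers) - pad, max(centers) + pad + bin_width * 1e-9,
      by = bin_width)
}

wham_histograms <- function(dataset, bins) {
  nb <- length(bins) - 1L
  nw <- length(dataset$windows)
  n_ib <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    s <- dataset$windows[[i]]$samples
    s <- s[s >= bins[1] & s <= bins[length(bins)]]
    n_ib[i, ] <- tabulate(findInterval(s, bins, rightmost.closed = TRUE),
                          nbins = nb)
  }
  n_ib
}

#' Weighted histogram analysis (WHAM)
#'
#' Self-consistent reconstruction of a 1-D potential of mean force from
#' biased window histograms:
#' `P(z_b) = sum_i n_i(z_b) / sum_i N_i exp[(F_i - w_i(z_b)) / kT]` and
#' `F_i = -kT ln sum_b P(z_b) exp[-w_i(z_b) / kT]`, iterated from
#' `F_i = 0` until the largest change in any window free energy falls
#' below `tol` (in units of kT). The PMF is `-kT ln P`, zero-shifted so
#' that the mean probability over the outermost occupied bins at each end
#' (the bulk regions) maps to zero energy — the same bulk convention used
#' by [boltzmann_invert()].
#'
#' @param dataset An [umbrella_dataset()].
#' @param bins Bin edges (A); default 0.5 A bins spanning the window-centre
#'   range plus 1 A of padding.
#' @param tol Convergence tolerance on max |dF_i|, in kT.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @param reference Outermost occupied bins per end defining the zero.
#' @param f_init Optional initial window free energies (the converged PMF
#'   is invariant, up to the zero shift, to a constant added here).
#' @return Object of class `pmf`: `z` (bin centres), `energy` (kJ/mol, NA
#'   for empty bins), `error` (NULL until [bootstrap_errors()] is run),
#'   `window_free_energies`, `n_iter`, `bins`, `temperature`.
#' @export
wham <- function(dataset, bins = NULL, tol = 1e-6, max_iter = 1e5,
                 reference = 3, f_init = NULL) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (is.null(bins)) bins <- default_wham_bins(dataset)
  kT <- thermal_energy(dataset$temperature)
  zc <- (bins[-1] + bins[-length(bins)]) / 2
  n_ib <- wham_histograms(dataset, bins)
  N_i <- rowSums(n_ib)
  if (any(N_i == 0)) stop("window with no samples inside the binned range")
  n_b <- colSums(n_ib)
  w_ib <- t(vapply(dataset$windows,
                   function(w) bias_energy(zc, w$center, w$force_constant),
                   numeric(length(zc))))
  F_i <- if (is.null(f_init)) rep(0, length(dataset$windows))
         else { stopifnot(length(f_init) == length(dataset$windows)); f_init }
  expw <- exp(-w_ib / kT)  # window x bin
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(N_i * exp(F_i / kT) * expw)
    P <- ifelse(denom > 0, n_b / denom, 0)
    F_new <- -kT * log(as.vector(expw %*% P))
    F_new <- F_new - F_new[1]
    delta <- max(abs(F_new - F_i))
    F_i <- F_new
    if (delta < tol * kT) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (last max|dF| = %.3g kJ/mol)",
                   as.integer(max_iter), delta))
  }
  occupied <- n_b > 0
  P[!occupied] <- NA_real_
  occ <- which(occupied)
  ref_idx <- unique(c(utils::head(occ, reference), utils::tail(occ, reference)))
  shift <- -kT * log(mean(P[ref_idx]))
  energy <- -kT * log(P) - shift
  structure(list(z = zc, energy = energy, error = NULL,
                 window_free_energies = F_i, n_iter = iter, bins = bins,
                 probability = P, reference_bins = ref_idx,
                 temperature = dataset$temperature),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("<pmf> %d bins, peak %.2f kJ/mol, %d WHAM iterations%s\n",
              length(x$z), max(x$energy, na.rm = TRUE), x$n_iter,
              if (is.null(x$error)) "" else ", bootstrap errors attached"))
  invisible(x)
}

#' Bootstrap errors for a PMF
#'
#' Resamples each window's sample vector with replacement (window identity
#' preserved), re-runs WHAM on every replicate, and reports the per-bin
#' standard deviation of the replicate PMFs.
#'
#' @inheritParams wham
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; replicates are reproducible.
#' @return A `pmf` as from [wham()] with per-bin `error` (kJ/mol) attached.
#' @export
bootstrap_errors <- function(dataset, bins = NULL, n_boot = 50, seed = NULL,
                             tol = 1e-6, max_iter = 1e5, reference = 3) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (is.null(bins)) bins <- default_wham_bins(dataset)
  base <- wham(dataset, bins, tol, max_iter, reference)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ds <- dataset
      ds$windows <- lapply(dataset$windows, function(w) {
        w$samples <- w$samples[sample.int(length(w$samples),
                                          replace = TRUE)]
        w
      })
      wham(ds, bins, tol, max_iter, reference)$energy
    }, numeric(length(base$z)))
  })
  base$error <- apply(reps, 1, stats::sd)
  base
}

#' PMF convergence series
#'
#' Recomputes the central barrier from cumulatively longer slices of every
#' window (first segment, first two segments, ...): a flat series indicates
#' the windows have equilibrated; drift flags unconverged sampling.
#'
#' @inheritParams wham
#' @param segment Segment length in ns (must not exceed the shortest
#'   window).
#' @param barrier_region `c(lo, hi)` (A) within which the barrier height is
#'   measured.
#' @return data.frame with `t_max` (ns) and `barrier` (kJ/mol).
#' @export
convergence_series <- function(dataset, segment, barrier_region,
                               bins = NULL, tol = 1e-6, max_iter = 1e5,
                               reference = 3) {
  stopifnot(inherits(dataset, "umbrella_dataset"), segment > 0)
  if (any(vapply(dataset$windows, function(w) is.null(w$times), TRUE)))
    stop("all windows need per-sample times for convergence analysis")
  duration <- min(vapply(dataset$windows, function(w) max(w$times), 0))
  if (segment > duration)
    stop(sprintf("segment (%g ns) exceeds the common window duration (%g ns)",
                 segment, duration))
  n_seg <- floor(duration / segment + 1e-9)
  out <- data.frame(t_max = numeric(n_seg), barrier = numeric(n_seg))
  for (m in seq_len(n_seg)) {
    t_max <- m * segment
    ds <- dataset
    ds$windows <- lapply(dataset$windows, function(w) {
      keep <- w$times <= t_max + 1e-12
      umbrella_window(w$center, w$force_constant, w$samples[keep],
                      w$times[keep])
    })
    p <- wham(ds, bins, tol, max_iter, reference)
    out$t_max[m] <- t_max
    out$barrier[m] <- barrier_height(p, barrier_region)
  }
  out
}

#' Write a PMF as TSV (columns z_A, E_kJ_mol, err_kJ_mol)
#' @param pmf A `pmf`.
#' @param path Output path.
#' @export
write_pmf <- function(pmf, path) {
  df <- data.frame(z_A = pmf$z, E_kJ_mol = pmf$energy,
                   err_kJ_mol = if (is.null(pmf$error)) NA_real_ else pmf$error)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
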