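# Independent oracles used to validate the package's implementations.
# These deliberately re-derive each quantity by brute force or by an
# explicit state machine, sharing no code with the functions under test.

# Exhaustive in-plane grid search for the largest probe sphere at axial
# position z (axis assumed +z). `lim` bounds |cx|,|cy|; `res` is the grid
# resolution in Angstrom.
grid_probe_oracle <- function(atoms, z, lim = 5, res = 0.02, reach = 12) {
  xyz <- as.matrix(atoms$atoms[, c("x", "y", "z")])
  vdw <- atoms$atoms$vdw_radius
  keep <- abs(xyz[, 3] - z) <= vdw + reach
  xyz <- xyz[keep, , drop = FALSE]
  vdw <- vdw[keep]
  gx <- seq(-lim, lim, by = res)
  best <- -Inf
  for (cx in gx) {
    dmin <- rep(Inf, length(gx))
    for (i in seq_len(nrow(xyz))) {
      d <- sqrt((cx - xyz[i, 1])^2 + (gx - xyz[i, 2])^2 +
                (z - xyz[i, 3])^2) - vdw[i]
      dmin <- pmin(dmin, d)
    }
    best <- max(best, max(dmin))
  }
  best
}

# Explicit per-particle state machine for two-gate permeation counting:
# a particle arms on one side (beyond a boundary) and fires an event when
# it next appears beyond the opposite boundary.
flux_oracle <- function(zmat, z_lo, z_hi) {
  up <- down <- 0L
  for (p in seq_len(nrow(zmat))) {
    state <- 0L   # -1 armed below, +1 armed above, 0 unarmed
    for (f in seq_len(ncol(zmat))) {
      z <- zmat[p, f]
      if (z < z_lo) {
        if (state == 1L) down <- down + 1L
        state <- -1L
      } else if (z > z_hi) {
        if (state == -1L) up <- up + 1L
        state <- 1L
      }
    }
  }
  list(up = up, down = down)
}

# All unordered index pairs of atoms named CA whose distance lies in
# [low, high], by direct double loop.
pair_band_oracle <- function(atoms, low, high) {
  ca <- which(atoms$atoms$name == "CA")
  xyz <- as.matrix(atoms$atoms[ca, c("x", "y", "z")])
  out <- list()
  for (a in seq_along(ca)) {
    for (b in seq_along(ca)) {
      if (b <= a) next
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d >= low && d <= high)
        out[[length(out) + 1L]] <- c(ca[a], ca[b], d)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      ref_dist = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], ref_dist = m[, 3])
}

# Direct cylinder-membership test for one frame.
in_cylinder_oracle <- function(xyz, cyl) {
  d <- sweep(xyz, 2, cyl$center)
  z <- d %*% cyl$axis
  radial <- sqrt(rowSums((d - outer(as.vector(z), cyl$axis))^2))
  radial <= cyl$radius & z >= cyl$z_lo & z <= cyl$z_hi
}

# Build a water_tracks object directly from a z matrix (particles x frames),
# for event-detector tests that need exact scripted paths.
tracks_from_z <- function(zmat, times = NULL, z_lo = -5, z_hi = 5,
                          radius = 5, inpore = NULL) {
  cyl <- pore_cylinder(radius = radius, z_lo = z_lo, z_hi = z_hi)
  if (is.null(times)) times <- seq_len(ncol(zmat)) - 1
  if (is.null(inpore))
    inpore <- zmat >= z_lo & zmat <= z_hi
  structure(list(z = zmat, inpore = inpore, ids = seq_len(nrow(zmat)),
                 times = times, cyl = cyl),
            class = "water_tracks")
}

# Minimal hand-written fixed-column PDB text for parser tests.
write_tiny_pdb <- function(path, coords, names = NULL, resnames = NULL,
                           elements = NULL, models = 1L) {
  n <- nrow(coords)
  if (is.null(names)) names <- rep("CA", n)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  if (is.null(elements)) elements <- substr(names, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(models)) {
    if (models > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    off <- (m - 1) * 0.1
    for (i in seq_len(n)) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, names[i], resnames[i], "A", i,
        coords[i, 1] + off, coords[i, 2] + off, coords[i, 3] + off,
        elements[i]), con)
    }
    if (models > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# A ring of carbon pseudo-atoms in the z = z0 plane.
ring_atoms <- function(ring_radius = 10, n = 120, z0 = 0, vdw = 1.85) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  atom_set(data.frame(
    serial = seq_len(n), name = "C", resname = "RNG", resid = 1L,
    chain = "A", x = ring_radius * cos(th), y = ring_radius * sin(th),
    z = z0, element = "C", vdw_radius = vdw, stringsAsFactors = FALSE))
}
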