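# Physical constants and small internal utilities shared across modules.
# Units throughout the package: lengths in Angstrom, energies in kJ/mol,
# times in ns, charges in elementary charges (e), potentials in volts.

# Boltzmann constant times Avogadro's number, kJ mol^-1 K^-1
.kB <- 8.314462618e-3

# Elementary charge (C) and vacuum permittivity (F/m)
.e_charge <- 1.602176634e-19
.eps0 <- 8.8541878128e-12

# Conversion factor for the 1-D Poisson integral: a charge density in e/A^3
# double-integrated over Angstrom^2 becomes volts when multiplied by this.
#   e [C] / eps0 [F/m] * (1e-10 m/A)^2 / (1e-10 m/A)^3 = e * 1e10 / eps0
.phi_conv <- .e_charge * 1e10 / .eps0

#' Thermal energy kT
#'
#' Boltzmann constant (as molar gas constant) times temperature, in kJ/mol.
#' At the simulation temperature of 310 K this is ~2.58 kJ/mol, i.e. the
#' "RT ~ 2.6 kJ/mol" yardstick used when judging barrier heights.
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy in kJ/mol.
#' @examples
#' thermal_energy(310)
#' @export
thermal_energy <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Rotation matrix R such that R %*% axis == c(0, 0, 1) (axis normalised).
axis_rotation <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2],
         a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  c_ <- sum(a * z)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about x
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Orthonormal basis (e1, e2) spanning the plane normal to a unit axis.
plane_basis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  list(e1 = e1, e2 = e2, axis = a)
}
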