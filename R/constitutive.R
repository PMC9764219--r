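#' Dynamic blood viscosity from hematocrit
#'
#' Empirical hematocrit--viscosity relation `mu = mu0 / (1 - phi)`, where
#' `mu0` is the dynamic viscosity of plasma and `phi` the hematocrit
#' fraction. With the default plasma viscosity of 1.2 cP a hematocrit of
#' 39.2% gives 1.97 cP.
#'
#' @param mu0_cP plasma viscosity in centipoise (default 1.2).
#' @param hematocrit hematocrit as a fraction in `[0, 1)`. Values > 1 and
#'   <= 100 are interpreted as percent and divided by 100.
#' @return dynamic viscosity of whole blood in cP.
#' @examples
#' blood_viscosity(1.2, 0.392)
#' @export
blood_viscosity <- function(mu0_cP = 1.2, hematocrit) {
  if (mu0_cP <= 0) stop("plasma viscosity must be positive")
  phi <- hematocrit
  if (length(phi) == 1 && is.finite(phi) && phi > 1 && phi <= 100) phi <- phi / 100
  if (any(phi < 0 | phi >= 1)) stop("hematocrit fraction must lie in [0, 1)")
  mu0_cP / (1 - phi)
}

#' Blood fluid properties
#'
#' Bundles the constants the 1D momentum equation needs: density `rho`,
#' dynamic viscosity `mu` (derived from hematocrit), the momentum-flux
#' correction `alpha` for the assumed velocity profile, and the kinematic
#' friction coefficient `Cf = 22*pi*mu/rho` (m^2/s) appearing in the wall
#' friction term `-Cf*Q/A`. The default `alpha = 1.1` is the correction
#' consistent with the polynomial velocity profile implied by `22*pi*nu`
#' friction.
#'
#' @param hematocrit hematocrit fraction (default 0.392).
#' @param plasma_viscosity_cP plasma viscosity in cP (default 1.2).
#' @param density blood density in kg/m^3 (default 1060).
#' @param alpha momentum-flux correction coefficient (>= 1).
#' @return an object of class `blood_properties` with elements `rho`, `mu`
#'   (Pa s), `mu_cP`, `alpha`, `Cf` (m^2/s), `hematocrit`, `mu0_cP`.
#' @examples
#' blood_properties(hematocrit = 0.392)
#' @export
blood_properties <- function(hematocrit = 0.392, plasma_viscosity_cP = 1.2,
                             density = 1060, alpha = 1.1) {
  if (density <= 0) stop("density must be positive")
  if (alpha < 1) stop("alpha must be >= 1")
  mu_cP <- blood_viscosity(plasma_viscosity_cP, hematocrit)
  mu <- mu_cP * CP_PAS
  structure(list(rho = density, mu = mu, mu_cP = mu_cP,
                 mu0_cP = plasma_viscosity_cP, hematocrit = hematocrit,
                 alpha = alpha, Cf = 22 * pi * mu / density),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("Blood: rho = %g kg/m^3, mu = %.4g cP (hct %.1f%%), alpha = %g, Cf = %.3e m^2/s\n",
              x$rho, x$mu_cP, 100 * x$hematocrit, x$alpha, x$Cf))
  invisible(x)
}

#' Vessel wall constitutive parameters
#'
#' Parameters of the algebraic tube law closing the 1D equations:
#' `P = Pext + beta(A0) * (sqrt(A) - sqrt(A0))` with stiffness
#' `beta = sqrt(pi) * h * E / ((1 - nu^2) * A0)`. The physical defaults
#' (h = 0.945 mm, E = 1.41 MPa, nu = 0.5) put the wall in a quasi-rigid
#' regime at coronary pressures; `stiffness_multiplier` scales `beta` for
#' rigid-limit studies.
#'
#' @param h_mm wall thickness in mm.
#' @param E_MPa elastic modulus in MPa.
#' @param nu Poisson ratio in `(0, 0.5]`.
#' @param Pext_Pa external pressure in Pa (gauge reference).
#' @param stiffness_multiplier dimensionless factor on `beta` (default 1).
#' @return an object of class `wall_law`.
#' @examples
#' wall_law()
#' @export
wall_law <- function(h_mm = 0.945, E_MPa = 1.41, nu = 0.5, Pext_Pa = 0,
                     stiffness_multiplier = 1) {
  if (h_mm <= 0 || E_MPa <= 0) stop("h and E must be positive")
  if (nu <= 0 || nu > 0.5) stop("Poisson ratio must lie in (0, 0.5]")
  if (stiffness_multiplier <= 0) stop("stiffness_multiplier must be positive")
  structure(list(h = h_mm * MM_M, E = E_MPa * 1e6, nu = nu, Pext = Pext_Pa,
                 stiffness_multiplier = stiffness_multiplier),
            class = "wall_law")
}

#' @export
print.wall_law <- function(x, ...) {
  cat(sprintf("Wall law: h = %g mm, E = %g MPa, nu = %g, Pext = %g Pa, stiffness x%g\n",
              x$h / MM_M, x$E / 1e6, x$nu, x$Pext, x$stiffness_multiplier))
  invisible(x)
}

#' Tube-law stiffness beta(A0)
#'
#' @param A0 reference (undeformed) cross-sectional area in m^2.
#' @param wall a [wall_law()] object.
#' @return stiffness `beta` in Pa/m, vectorized over `A0`.
#' @export
beta_stiffness <- function(A0, wall = wall_law()) {
  if (any(A0 <= 0)) stop("A0 must be positive")
  wall$stiffness_multiplier * sqrt(pi) * wall$h * wall$E /
    ((1 - wall$nu^2) * A0)
}

#' Tube law: pressure from area, and its inverse
#'
#' `tube_law()` evaluates `P = Pext + beta*(sqrt(A) - sqrt(A0))`;
#' `tube_law_area()` inverts it for `A`.
#'
#' @param A cross-sectional area, m^2.
#' @param A0 reference area, m^2.
#' @param wall a [wall_law()] object.
#' @param P pressure in Pa.
#' @return pressure in Pa (`tube_law`) or area in m^2 (`tube_law_area`).
#' @examples
#' A0 <- pi * (1.95e-3)^2
#' tube_law(1.01 * A0, A0)
#' tube_law_area(tube_law(1.01 * A0, A0), A0)
#' @export
tube_law <- function(A, A0, wall = wall_law()) {
  if (any(A <= 0) || any(A0 <= 0)) stop("areas must be positive")
  wall$Pext + beta_stiffness(A0, wall) * (sqrt(A) - sqrt(A0))
}

#' @rdname tube_law
#' @export
tube_law_area <- function(P, A0, wall = wall_law()) {
  if (any(A0 <= 0)) stop("A0 must be positive")
  s <- sqrt(A0) + (P - wall$Pext) / beta_stiffness(A0, wall)
  if (any(s <= 0)) stop("pressure implies non-physical (non-positive) area")
  s^2
}

#' Characteristic pulse-wave speed
#'
#' Wave speed implied by the tube law, `c = sqrt(beta * sqrt(A) / (2*rho))`,
#' i.e. `c^2 = (A/rho) * dP/dA`. Used for the CFL stability check and the
#' characteristic boundary couplings.
#'
#' @param A area, m^2.
#' @param A0 reference area, m^2.
#' @param rho blood density, kg/m^3.
#' @param wall a [wall_law()] object.
#' @return wave speed in m/s.
#' @export
wave_speed <- function(A, A0, rho = 1060, wall = wall_law()) {
  if (any(A <= 0)) stop("area must be positive")
  sqrt(beta_stiffness(A0, wall) * sqrt(A) / (2 * rho))
}
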