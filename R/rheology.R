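#' Local logarithmic slope of an MSD curve
#'
#' `alpha(omega) = d ln MSD / d ln t` evaluated at `t = 1/omega`. For a
#' fitted power law the slope is the (constant) exponent; for a tabulated
#' curve it is a central finite difference on log-log linearly interpolated
#' data.
#'
#' @param msd a `PowerLawFit` or an `MSDSeries` (tabulated, positive MSD).
#' @param omega frequency vector, 1/ns.
#' @return alpha(omega), same length as `omega`.
#' @export
localLogSlope <- function(msd, omega) {
  stopifnot(all(omega > 0))
  if (inherits(msd, "PowerLawFit")) return(rep(msd$alpha, length(omega)))
  t <- msd$t; y <- msd$msd
  keep <- t > 0 & y > 0
  lt <- log(t[keep]); ly <- log(y[keep])
  teval <- log(1 / omega)
  h <- min(diff(sort(lt))) / 2
  if (any(teval - h < min(lt) | teval + h > max(lt)))
    stop("1/omega outside the tabulated time range")
  f <- stats::approxfun(lt, ly)
  (f(teval + h) - f(teval - h)) / (2 * h)
}

## MSD evaluated at t = 1/omega (Angstrom^2)
.msdAt <- function(msd, omega) {
  if (inherits(msd, "PowerLawFit"))
    return(msd$prefactor * msd$D * (1 / omega)^msd$alpha)
  t <- msd$t; y <- msd$msd
  keep <- t > 0 & y > 0
  f <- stats::approxfun(log(t[keep]), log(y[keep]))
  lv <- f(log(1 / omega))
  if (anyNA(lv)) stop("1/omega outside the tabulated time range")
  exp(lv)
}

#' Viscoelastic moduli from an MSD via the generalized Stokes-Einstein
#' relation
#'
#' The probe (a lipid molecule) is approximated as a sphere of radius `Rg`;
#' the magnitude of the complex shear modulus is estimated as
#' `|G*|(omega) = kB T / (pi Rg MSD(1/omega) Gamma[1 + alpha(omega)])`
#' with `G' = |G*| cos(pi alpha/2)` (storage) and
#' `G'' = |G*| sin(pi alpha/2)` (loss). Input units are Angstrom, ns and
#' K; moduli are reported in kPa.
#'
#' @param msd a `PowerLawFit` (default pipeline) or tabulated `MSDSeries`.
#' @param Rg probe radius of gyration, Angstrom.
#' @param temperature temperature, K.
#' @param omega frequency grid, 1/ns; default 40 log-spaced points spanning
#'   the inverse fitted/tabulated time range.
#' @return A `Moduli` data.frame: `omega` (1/ns), `alpha`, `Gstar_kPa`,
#'   `Gprime_kPa`, `Gdoubleprime_kPa`.
#' @export
gserModuli <- function(msd, Rg, temperature = 310, omega = NULL) {
  stopifnot(Rg > 0, temperature > 0)
  if (is.null(omega)) {
    rng <- if (inherits(msd, "PowerLawFit")) msd$fit_range
           else range(msd$t[msd$t > 0])
    omega <- exp(seq(log(1 / rng[2]), log(1 / rng[1]), length.out = 40))
  }
  stopifnot(all(omega > 0))
  alpha <- localLogSlope(msd, omega)
  if (any(alpha <= 0 | alpha >= 2))
    stop("alpha(omega) must lie in (0, 2) for the GSER estimate")
  m <- .msdAt(msd, omega)
  if (any(m <= 0)) stop("MSD(1/omega) must be positive")
  ## kB T [J] / (pi * Rg [m] * MSD [m^2] * Gamma) -> Pa; /1000 -> kPa
  G <- .kB * temperature / (pi * (Rg * .A2m) * (m * .A2m^2) * gamma(1 + alpha)) / 1000
  out <- data.frame(omega = omega, alpha = alpha,
                    Gstar_kPa = G,
                    Gprime_kPa = G * cospi(alpha / 2),
                    Gdoubleprime_kPa = G * sinpi(alpha / 2))
  class(out) <- c("Moduli", class(out))
  out
}
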