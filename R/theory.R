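## Closed-form theory for the reaction-limited regime: characteristic time
## scales, mean-field bridge saturation, and the fluctuation-dissipation
## drift estimate.

#' Bond-rearrangement time scale
#'
#' \eqn{\tau_r = 1 / (2 k_{off} n_{cb})}: the time over which the
#' translational configuration space accessible to the disk changes through
#' unbinding of one of its constraining bridges.
#'
#' @param kOff unbinding rate, s^-1.
#' @param nCb mean number of constraining bridges (default 5).
#' @return seconds.
#' @export
tauR <- function(kOff, nCb = 5) {
  if (any(kOff <= 0) || any(nCb <= 0)) stop("inputs must be positive")
  1 / (2 * kOff * nCb)
}

#' Diffusive exploration time scale of the feasible region
#'
#' \eqn{\tau_d = \pi R^2 n_{cb} / (D_{free} n_b^2)}: the time a disk with
#' free-diffusion coefficient D_free needs to explore the feasible region
#' left open by its n_b bridges.
#'
#' @param R disk radius, nm.
#' @param nCb mean constraining-bridge count.
#' @param DFree free (non-adhering) diffusion coefficient, nm^2/s.
#' @param nB bridge count.
#' @return seconds.
#' @export
tauD <- function(R, nCb = 5, DFree, nB) {
  if (any(c(R, nCb, DFree, nB) <= 0)) stop("inputs must be positive")
  pi * R^2 * nCb / (DFree * nB^2)
}

#' Stokes-Einstein diffusion coefficient
#'
#' @param RHydro hydrodynamic radius, nm.
#' @param eta medium viscosity, Pa s (default 0.001, water).
#' @param temperature kelvin (default 293.15).
#' @return nm^2/s.
#' @export
stokesEinsteinD <- function(RHydro, eta = 1e-3, temperature = 293.15) {
  if (any(c(RHydro, eta, temperature) <= 0)) stop("inputs must be positive")
  .kB * temperature / (6 * pi * eta * RHydro * 1e-9) * 1e18
}

#' Mean-field equilibrium bridge density
#'
#' Solves the mass-action balance
#' \eqn{\rho_b = K' (\rho_L - \rho_b)(\rho_R - \rho_b)} for the physical
#' root \eqn{0 \le \rho_b \le \min(\rho_L, \rho_R)}, and reports which
#' species limits binding in the saturated regime.
#'
#' @param rhoL local ligand density, nm^-2.
#' @param rhoR effective receptor density over the contact patch, nm^-2
#'   (note: a receptor budget spread over the hemisphere area 3 pi R^2
#'   concentrates to three times its nominal density over the patch).
#' @param Kprime pair equilibrium constant in area units,
#'   \code{kOnPair * pi R^2 / kOff}, nm^2.
#' @return list with \code{rho_b} (nm^-2), \code{saturation} (rho_b over the
#'   limiting density), and \code{limiting} ("ligand" or "receptor").
#' @export
equilibriumBridgeDensity <- function(rhoL, rhoR, Kprime) {
  if (any(c(rhoL, rhoR, Kprime) <= 0)) stop("densities and K' must be positive")
  b <- Kprime * (rhoL + rhoR) + 1
  disc <- b^2 - 4 * Kprime^2 * rhoL * rhoR
  stopifnot(disc >= 0)  # impossible for valid inputs
  ## smaller quadratic root, evaluated in the numerically stable form
  rho_b <- (2 * Kprime * rhoL * rhoR) / (b + sqrt(disc))
  lim <- min(rhoL, rhoR)
  stopifnot(rho_b >= 0, rho_b <= lim * (1 + 1e-12))
  list(rho_b = min(rho_b, lim),
       saturation = rho_b / lim,
       limiting = if (rhoL <= rhoR) "ligand" else "receptor")
}

#' Equilibrium bridge number of a disk on the engine's bookkeeping
#'
#' Convenience wrapper mapping the engine parameters onto
#' \code{\link{equilibriumBridgeDensity}}: the receptor budget
#' \code{rhoR * 3 pi R^2} concentrates over the patch area \code{pi R^2}
#' (effective density \code{3 rhoR}) and the pair constant is
#' \code{kOnPair * pi R^2 / kOff}.
#'
#' @param rates \linkS4class{RateConstants}.
#' @param R disk radius, nm.
#' @param rhoL local ligand density, nm^-2.
#' @param rhoR nominal receptor density over the hemisphere, nm^-2.
#' @return list with \code{rho_b}, \code{n_b}, \code{saturation},
#'   \code{limiting}.
#' @export
bridgeEquilibrium <- function(rates, R, rhoL = 0.021, rhoR = 0.008) {
  stopifnot(is(rates, "RateConstants"))
  eq <- equilibriumBridgeDensity(rhoL, 3 * rhoR,
                                 rates@kOnPair * pi * R^2 / rates@kOff)
  eq$n_b <- eq$rho_b * pi * R^2
  eq
}

#' Mean-field multivalent free energy of the contact patch
#'
#' Standard mobile-linker mean-field form: with bridge density rho_b from
#' the mass-action solution, the attractive free energy per unit area is
#' \deqn{\beta f = \rho_L \log(1 - \rho_b/\rho_L)
#'               + \rho_R \log(1 - \rho_b/\rho_R) + \rho_b,}
#' and \eqn{V_{multi} = \pi R^2 f}. Negative for binding interactions.
#'
#' @inheritParams equilibriumBridgeDensity
#' @param area contact-patch area, nm^2 (use \code{pi * R^2}).
#' @return free energy in kBT.
#' @export
multivalentFreeEnergy <- function(rhoL, rhoR, Kprime, area) {
  eq <- equilibriumBridgeDensity(rhoL, rhoR, Kprime)
  rb <- eq$rho_b
  f <- rhoL * log(max(1 - rb / rhoL, .Machine$double.xmin)) +
       rhoR * log(max(1 - rb / rhoR, .Machine$double.xmin)) + rb
  area * f
}

#' Fluctuation-dissipation estimate of the drift velocity
#'
#' Linear-response estimate: drift = mobility x thermodynamic force, with
#' the adhering-disk diffusion coefficient
#' \eqn{D_{multi} = \pi R^2 n_{cb}^2 k_{off} / (2 n_b^2)} (the feasible-region
#' area \eqn{\pi R^2 n_{cb}/n_b^2} explored once per bond-rearrangement time
#' \eqn{\tau_r}) as the mobility and the spatial gradient of the multivalent
#' free energy \eqn{V_{multi}} as the force:
#' \deqn{v^{FD} = -D_{multi} \, \beta \, dV_{multi}/dx.}
#' The derivative is taken numerically through the local ligand density,
#' \eqn{dV/dx = (dV/d\rho_L)\,\lambda}. Because n_b grows as R^2 at fixed
#' densities while the force grows as R^2 too, the estimate is independent
#' of disk size. It is a linear-response overestimate: at the bridge numbers
#' of saturated carpets the system leaves the regime where the underlying
#' fluctuation-dissipation argument applies, so treat the number as an upper
#' bound (the returned value carries an \code{overestimate} attribute).
#'
#' @param rates \linkS4class{RateConstants} at radius R.
#' @param R disk radius, nm.
#' @param rhoL local ligand density at the disk centre, nm^-2.
#' @param rhoR nominal receptor density (hemisphere convention), nm^-2.
#' @param lambda ligand-density slope, nm^-2 per nm.
#' @param nCb mean constraining-bridge count (default 5).
#' @return drift velocity in nm/s (positive = up-gradient), with attribute
#'   \code{overestimate = TRUE}.
#' @export
fdDriftVelocity <- function(rates, R, rhoL = 0.021, rhoR = 0.008, lambda,
                            nCb = 5) {
  stopifnot(is(rates, "RateConstants"))
  if (lambda == 0) {
    out <- 0
    attr(out, "overestimate") <- TRUE
    return(out)
  }
  Kprime <- rates@kOnPair * pi * R^2 / rates@kOff
  area <- pi * R^2
  nB <- bridgeEquilibrium(rates, R, rhoL, rhoR)$n_b
  Dmulti <- pi * R^2 * nCb^2 * rates@kOff / (2 * nB^2)
  h <- rhoL * 1e-4
  dVdrho <- (multivalentFreeEnergy(rhoL + h, 3 * rhoR, Kprime, area) -
             multivalentFreeEnergy(rhoL - h, 3 * rhoR, Kprime, area)) / (2 * h)
  out <- -Dmulti * dVdrho * lambda
  attr(out, "overestimate") <- TRUE
  out
}

#' Regime report: reaction-limited or diffusion-limited
#'
#' @param kOff unbinding rate, s^-1.
#' @param R disk radius, nm.
#' @param nB bridge count (e.g. the saturated value).
#' @param DFree free diffusion coefficient, nm^2/s (default Stokes-Einstein
#'   at RHydro = R).
#' @param nCb constraining-bridge count (default 5).
#' @param ratioThreshold tau_r/tau_d ratio above which the dynamics count as
#'   reaction-limited (default 10).
#' @return list with tau_r, tau_d, their ratio, log10 ratio and the regime
#'   label.
#' @export
regimeReport <- function(kOff, R, nB, DFree = stokesEinsteinD(R), nCb = 5,
                         ratioThreshold = 10) {
  tr <- tauR(kOff, nCb)
  td <- tauD(R, nCb, DFree, nB)
  ratio <- tr / td
  list(tau_r_s = tr, tau_d_s = td, ratio = ratio, log10_ratio = log10(ratio),
       regime = if (ratio >= ratioThreshold) "reaction-limited"
                else "diffusion-limited")
}

#' Drift-velocity ratio versus the unbinding-rate ratio
#'
#' In the reaction-limited saturated regime the drift velocity is
#' proportional to k_off, so the ratio of drift velocities between two
#' kinetic conditions should match the ratio of their unbinding rates. The
#' standard error of the ratio is propagated from the two fit errors.
#'
#' @param v1,v2 drift velocities, nm/s.
#' @param se1,se2 their standard errors.
#' @param kOffRatio reference unbinding-rate ratio.
#' @param nSigma agreement window in propagated standard errors (default 2).
#' @return list with \code{ratio}, \code{se}, \code{kOffRatio} and a
#'   \code{consistent} flag.
#' @export
scalingCheck <- function(v1, se1, v2, se2, kOffRatio, nSigma = 2) {
  ratio <- v1 / v2
  se <- abs(ratio) * sqrt((se1 / v1)^2 + (se2 / v2)^2)
  list(ratio = ratio, se = se, kOffRatio = kOffRatio,
       consistent = abs(ratio - kOffRatio) <= nSigma * se)
}
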