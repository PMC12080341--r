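#' @import methods
#' @importFrom stats lm coef quantile sd median approx rpois runif setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib haptosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Physical constants (SI unless stated)
.kB      <- 1.380649e-23          # J / K
.Rgas    <- 1.98720425864083e-3   # kcal / (mol K)
.avogadro <- 6.02214076e23        # 1 / mol

#' KineticParameters: the symbols of the bridge rate model
#'
#' Holds everything needed to evaluate the per-pair binding rate and the
#' per-bridge unbinding rate of a DNA sticky-end bridge:
#' \eqn{k_{off} = \alpha k_{on}^{sol} \rho_0 e^{\beta \Delta G_0}} and
#' \eqn{k_{on} = \alpha k_{on}^{sol} c_{eff}(R, L)}.
#'
#' @slot deltaG0 standard hybridization free energy of the sticky-end duplex,
#'   in units of \eqn{k_B T} (negative = binding).
#' @slot alpha dimensionless slowdown factor in (0, 1] accounting for the
#'   reduced hybridization kinetics of surface-tethered strands.
#' @slot kOnSol solution hybridization rate of free oligonucleotides,
#'   M^-1 s^-1.
#' @slot L spacer length (thickness of the sticky-end layer), nm.
#' @slot rho0 standard concentration, M (fixed at 1).
#' @slot temperature temperature, K.
#' @exportClass KineticParameters
setClass("KineticParameters",
  representation(deltaG0 = "numeric", alpha = "numeric", kOnSol = "numeric",
                 L = "numeric", rho0 = "numeric", temperature = "numeric"),
  prototype(alpha = 0.1, kOnSol = 1e6, L = 10, rho0 = 1, temperature = 293.15))

setValidity("KineticParameters", function(object) {
  msg <- character(0)
  if (length(object@deltaG0) != 1 || !is.finite(object@deltaG0))
    msg <- c(msg, "deltaG0 must be a single finite number (kBT)")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  if (length(object@kOnSol) != 1 || object@kOnSol <= 0)
    msg <- c(msg, "kOnSol must be positive")
  if (length(object@L) != 1 || object@L <= 0)
    msg <- c(msg, "L must be positive (nm)")
  if (!isTRUE(all.equal(object@rho0, 1)))
    msg <- c(msg, "rho0 is fixed at 1 M")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msg <- c(msg, "temperature must be positive (K)")
  if (length(msg)) msg else TRUE
})

#' RateConstants: realized per-pair binding and per-bridge unbinding rates
#'
#' @slot kOnPair binding rate of one free receptor with one free ligand under
#'   the disk, s^-1 (scales as 1/R^2).
#' @slot kOff unbinding rate of one bridge, s^-1 (independent of R).
#' @slot cEff effective molar concentration of one free sticky end in the
#'   hemispherical shell of area 3*pi*R^2 and thickness L, M.
#' @slot R disk radius the on-rate was evaluated at, nm.
#' @exportClass RateConstants
setClass("RateConstants",
  representation(kOnPair = "numeric", kOff = "numeric",
                 cEff = "numeric", R = "numeric"))

setValidity("RateConstants", function(object) {
  if (object@kOnPair <= 0 || object@kOff <= 0)
    return("kOnPair and kOff must be strictly positive")
  TRUE
})

#' GradientProfile: linear ligand-density profile
#'
#' Density at planar point p is \code{rhoL + lambda * (p . direction)}, with
#' the origin taken as the reference (starting) location of the disks.
#'
#' @slot rhoL reference ligand density at the origin, nm^-2.
#' @slot lambda density slope along \code{direction}, nm^-2 per nm.
#' @slot direction unit 2-vector of increasing density.
#' @exportClass GradientProfile
setClass("GradientProfile",
  representation(rhoL = "numeric", lambda = "numeric", direction = "numeric"))

setValidity("GradientProfile", function(object) {
  msg <- character(0)
  if (length(object@rhoL) != 1 || object@rhoL <= 0)
    msg <- c(msg, "rhoL must be a single positive density (nm^-2)")
  if (length(object@lambda) != 1 || !is.finite(object@lambda))
    msg <- c(msg, "lambda must be a single finite slope (nm^-2 per nm)")
  if (length(object@direction) != 2 ||
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    msg <- c(msg, "direction must be a unit 2-vector")
  if (length(msg)) msg else TRUE
})

#' LigandField: a realized carpet of surface ligands
#'
#' Immutable point set drawn from an inhomogeneous Poisson process with the
#' linear intensity of a \linkS4class{GradientProfile}. Bound/free bookkeeping
#' is carried by the simulation state, not by the field.
#'
#' @slot positions n x 2 matrix of ligand coordinates, nm.
#' @slot extent axis-aligned rectangle c(xmin, xmax, ymin, ymax), nm.
#' @slot profile the generating \linkS4class{GradientProfile}.
#' @slot seed integer seed the field was drawn with.
#' @slot index spatial bin index (list) for sub-linear disk queries.
#' @exportClass LigandField
setClass("LigandField",
  representation(positions = "matrix", extent = "numeric",
                 profile = "GradientProfile", seed = "integer",
                 index = "list"))

setValidity("LigandField", function(object) {
  e <- object@extent
  if (length(e) != 4 || e[2] <= e[1] || e[4] <= e[3])
    return("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  p <- object@positions
  if (ncol(p) != 2) return("positions must be an n x 2 matrix")
  if (nrow(p) > 0) {
    if (min(p[, 1]) < e[1] - 1e-9 || max(p[, 1]) > e[2] + 1e-9 ||
        min(p[, 2]) < e[3] - 1e-9 || max(p[, 2]) > e[4] + 1e-9)
      return("all ligands must lie inside the extent")
  }
  TRUE
})

#' VesicleState: instantaneous state of the adhering disk
#'
#' @slot R disk radius, nm.
#' @slot center disk centre, nm.
#' @slot bridges integer ids of bound ligands (rows of the field positions).
#' @slot nReceptors total receptor budget round(rhoR * 3 pi R^2); free
#'   receptor positions are not tracked.
#' @slot time simulation time, s.
#' @slot detached logical detachment flag.
#' @exportClass VesicleState
setClass("VesicleState",
  representation(R = "numeric", center = "numeric", bridges = "integer",
                 nReceptors = "integer", time = "numeric",
                 detached = "logical"),
  prototype(time = 0, detached = FALSE))

setValidity("VesicleState", function(object) {
  msg <- character(0)
  if (object@R <= 0) msg <- c(msg, "R must be positive")
  if (length(object@center) != 2) msg <- c(msg, "center must be a 2-vector")
  if (anyDuplicated(object@bridges))
    msg <- c(msg, "a ligand can carry at most one bridge")
  if (length(object@bridges) > object@nReceptors)
    msg <- c(msg, "more bridges than receptors")
  if (length(msg)) msg else TRUE
})

#' SimConfig: full run-control for the engine
#'
#' @slot rates \linkS4class{RateConstants} (per-pair on, per-bridge off).
#' @slot profile \linkS4class{GradientProfile} of the surface.
#' @slot R disk radius, nm.
#' @slot rhoR receptor density over the hemisphere area 3 pi R^2, nm^-2.
#' @slot dt reaction-window duration, s.
#' @slot tTotal total simulated time, s.
#' @slot nReplicates number of independent replicates.
#' @slot seed base seed; replicate streams are derived from (seed, replicate).
#' @slot detachmentPolicy "terminate" (default) or "continue".
#' @slot recordEvery record one trajectory row every this many windows.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(rates = "RateConstants", profile = "GradientProfile",
                 R = "numeric", rhoR = "numeric", dt = "numeric",
                 tTotal = "numeric", nReplicates = "integer",
                 seed = "integer", detachmentPolicy = "character",
                 recordEvery = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@tTotal < object@dt) msg <- c(msg, "tTotal must be >= dt")
  if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
  if (!object@detachmentPolicy %in% c("terminate", "continue"))
    msg <- c(msg, 'detachmentPolicy must be "terminate" or "continue"')
  if (object@recordEvery < 1) msg <- c(msg, "recordEvery must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trajectory: one simulated (or imported) disk trajectory
#'
#' @slot data data.frame with columns t_s, x_nm, y_nm, n_b, n_cb, n_bind,
#'   n_unbind (event counts since the previous recorded row).
#' @slot status "ok", "detached" or "margin" (disk reached the field edge).
#' @slot R disk radius, nm.
#' @slot seed replicate seed index used.
#' @slot metadata list echoing the generating configuration and RNG name.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(data = "data.frame", status = "character", R = "numeric",
                 seed = "integer", metadata = "list"))

setValidity("Trajectory", function(object) {
  d <- object@data
  need <- c("t_s", "x_nm", "y_nm", "n_b", "n_cb")
  if (!all(need %in% names(d)))
    return(paste("trajectory data must contain", paste(need, collapse = ", ")))
  if (nrow(d) > 1 && any(diff(d$t_s) <= 0))
    return("times must be strictly increasing")
  if (any(d$n_cb > d$n_b))
    return("n_cb cannot exceed n_b")
  TRUE
})

## ---- show methods ------------------------------------------------------

setMethod("show", "KineticParameters", function(object) {
  cat(sprintf(
    "KineticParameters: dG0 = %.3f kBT, alpha = %g, kOnSol = %g /M/s, L = %g nm, T = %.2f K\n",
    object@deltaG0, object@alpha, object@kOnSol, object@L, object@temperature))
})

setMethod("show", "RateConstants", function(object) {
  cat(sprintf(
    "RateConstants: kOnPair = %.4g /s (R = %g nm, cEff = %.4g M), kOff = %.4g /s\n",
    object@kOnPair, object@R, object@cEff, object@kOff))
})

setMethod("show", "GradientProfile", function(object) {
  cat(sprintf(
    "GradientProfile: rhoL = %g nm^-2, lambda = %g nm^-2/nm along (%g, %g)\n",
    object@rhoL, object@lambda, object@direction[1], object@direction[2]))
})

setMethod("show", "LigandField", function(object) {
  e <- object@extent
  cat(sprintf(
    "LigandField: %d ligands on [%g, %g] x [%g, %g] nm (seed %d)\n",
    nrow(object@positions), e[1], e[2], e[3], e[4], object@seed))
})

setMethod("show", "VesicleState", function(object) {
  cat(sprintf(
    "VesicleState: R = %g nm, center = (%.2f, %.2f), %d/%d receptors bridged%s\n",
    object@R, object@center[1], object@center[2], length(object@bridges),
    object@nReceptors, if (object@detached) " [detached]" else ""))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: R = %g nm, rhoR = %g nm^-2, dt = %.4g s, tTotal = %g s, %d replicate(s), seed %d\n",
    object@R, object@rhoR, object@dt, object@tTotal, object@nReplicates,
    object@seed))
})

setMethod("show", "Trajectory", function(object) {
  d <- object@data
  cat(sprintf(
    "Trajectory: %d samples over %.4g s, status '%s', final n_b = %d\n",
    nrow(d), if (nrow(d)) max(d$t_s) else 0, object@status,
    if (nrow(d)) tail(d$n_b, 1) else 0L))
})

## ---- accessors ---------------------------------------------------------

#' Trajectory accessors
#'
#' @param x a \linkS4class{Trajectory}.
#' @return \code{trajectoryData} returns the sample table,
#'   \code{trajectoryStatus} the run status flag, \code{diskRadius} the disk
#'   radius in nm.
#' @export
trajectoryData <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@data
}

#' @rdname trajectoryData
#' @export
trajectoryStatus <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@status
}

#' @rdname trajectoryData
#' @export
diskRadius <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@R
}

#' Ligand field accessors
#'
#' @param x a \linkS4class{LigandField}.
#' @return \code{ligandPositions} returns the n x 2 coordinate matrix (nm),
#'   \code{fieldExtent} the rectangle c(xmin, xmax, ymin, ymax).
#' @export
ligandPositions <- function(x) {
  stopifnot(is(x, "LigandField"))
  x@positions
}

#' @rdname ligandPositions
#' @export
fieldExtent <- function(x) {
  stopifnot(is(x, "LigandField"))
  x@extent
}

#' @rdname ligandPositions
#' @export
fieldProfile <- function(x) {
  stopifnot(is(x, "LigandField"))
  x@profile
}
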