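## R surface of the stochastic engine. The heavy lifting (Gillespie windows,
## circle-intersection geometry, constrained-move sampling) lives in src/;
## the step functions here call the same compiled routines as the full run
## loop, so what the unit tests exercise is the production path.

#' Construct a vesicle (disk) state
#'
#' @param R disk radius, nm.
#' @param center disk centre, nm.
#' @param rhoR receptor density over the hemisphere area 3 pi R^2, nm^-2;
#'   the receptor budget is round(rhoR * 3 pi R^2). Free receptor positions
#'   are not tracked; bridges carry only the ligand anchor.
#' @param bridges integer ids of initially bound ligands (default none).
#' @param time simulation time, s.
#' @return a \linkS4class{VesicleState}.
#' @export
vesicleState <- function(R, center = c(0, 0), rhoR = 0.008,
                         bridges = integer(0), time = 0) {
  new("VesicleState", R = R, center = as.numeric(center),
      bridges = as.integer(bridges),
      nReceptors = as.integer(round(rhoR * 3 * pi * R^2)),
      time = time, detached = FALSE)
}

#' Assemble a simulation configuration
#'
#' When \code{dt} is omitted it is fixed at setup as
#' \code{min(10, 0.2 * Lfree) / (kOff * max(nb, 1))}, where \code{nb} and
#' \code{Lfree} are the mean-field equilibrium bridge number and free-ligand
#' number under the disk at the origin density. The first term targets on
#' the order of ten events per reaction window; the second keeps the
#' expected number of binding events per window well below the free-ligand
#' pool. The cap matters in the saturated regime: the eligible-ligand set is
#' frozen at window start, so windows whose event count approaches the small
#' free pool starve binding, depress the bridge number by a few units, and
#' thereby inflate the free-ligand density and the mobility of
#' strongly-bound disks.
#'
#' @param rates \linkS4class{RateConstants} for this disk radius.
#' @param profile \linkS4class{GradientProfile} of the surface.
#' @param R disk radius, nm (must match \code{rates@R}).
#' @param rhoR receptor density, nm^-2.
#' @param tTotal total simulated time, s.
#' @param dt reaction-window duration, s (default: auto as above).
#' @param nReplicates number of replicates for \code{\link{runEnsemble}}.
#' @param seed base seed; each replicate gets an independent RNG stream
#'   derived from (seed, replicate index).
#' @param detachmentPolicy "terminate" (record detachment and stop; default)
#'   or "continue" (keep the centre in place and allow rebinding).
#' @param recordEvery record one trajectory row every this many windows
#'   (default: thin to at most ~2000 rows).
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(rates, profile, R, rhoR = 0.008, tTotal,
                      dt = NULL, nReplicates = 1L, seed = 1L,
                      detachmentPolicy = c("terminate", "continue"),
                      recordEvery = NULL) {
  stopifnot(is(rates, "RateConstants"), is(profile, "GradientProfile"))
  detachmentPolicy <- match.arg(detachmentPolicy)
  if (!isTRUE(all.equal(R, rates@R)))
    stop("rates were computed for R = ", rates@R, " nm, not ", R, " nm")
  if (is.null(dt)) {
    eq <- bridgeEquilibrium(rates, R, rhoL = profile@rhoL, rhoR = rhoR)
    nFree <- (profile@rhoL - eq$rho_b) * pi * R^2
    dt <- min(10, 0.2 * max(nFree, 1)) / (rates@kOff * max(eq$n_b, 1))
  }
  nWindows <- ceiling(tTotal / dt - 1e-12)
  if (is.null(recordEvery)) recordEvery <- max(1, ceiling(nWindows / 2000))
  new("SimConfig", rates = rates, profile = profile, R = R, rhoR = rhoR,
      dt = dt, tTotal = tTotal, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed), detachmentPolicy = detachmentPolicy,
      recordEvery = as.integer(recordEvery))
}

#' One Gillespie reaction window with the disk frozen
#'
#' Eligible ligands are those free and under the disk at window start; total
#' formation propensity is \code{kOnPair * freeReceptors * freeEligible},
#' total breakage propensity \code{kOff * nBridges}. Exponential waiting
#' times are accumulated and the first event exceeding \code{dt} is
#' discarded (time truncates at \code{dt}). A zero total propensity leaves
#' the state unchanged.
#'
#' @param state a \linkS4class{VesicleState}.
#' @param field a \linkS4class{LigandField}.
#' @param rates \linkS4class{RateConstants}.
#' @param dt window duration, s.
#' @param seed integer seed for this window.
#' @return list with the updated \code{state} and the event counts
#'   \code{nBind}, \code{nUnbind}.
#' @export
reactionStep <- function(state, field, rates, dt, seed = 1L) {
  stopifnot(is(state, "VesicleState"), is(field, "LigandField"),
            is(rates, "RateConstants"), dt >= 0)
  validObject(state)
  p <- field@positions
  res <- .reactionWindowCpp(p[, 1], p[, 2], state@bridges,
                            state@nReceptors, state@center, state@R,
                            rates@kOnPair, rates@kOff, dt, as.numeric(seed))
  state@bridges <- as.integer(res$bridges)
  state@time <- state@time + dt
  state@detached <- length(state@bridges) == 0
  list(state = state, nBind = res$nBind, nUnbind = res$nUnbind)
}

#' Feasible region of the disk centre under the current bridges
#'
#' The set of centre positions compatible with the bridges is the
#' intersection of circles of radius R centred on each bridged ligand. The
#' boundary vertices and the subset of bridges whose circles contribute an
#' arc to the boundary (the constraining bridges) are computed exactly.
#'
#' @param anchors n x 2 matrix of bridged ligand positions, nm (or a
#'   \linkS4class{VesicleState} plus \code{field}).
#' @param R disk radius, nm (ignored when a state is given).
#' @param center a point known to lie inside the region (the current disk
#'   centre); with a state, taken from the state.
#' @param field \linkS4class{LigandField} resolving bridge ids when a state
#'   is given.
#' @return list with \code{vertices} (m x 2 matrix), \code{constraining}
#'   (indices into the anchor rows), and \code{rReg}, the maximal distance
#'   between the region and \code{center}.
#' @export
feasibleRegion <- function(anchors, R = NULL, center = NULL, field = NULL) {
  if (is(anchors, "VesicleState")) {
    state <- anchors
    stopifnot(is(field, "LigandField"))
    if (length(state@bridges) < 1) stop("feasible region requires >= 1 bridge")
    anchors <- field@positions[state@bridges, , drop = FALSE]
    R <- state@R
    center <- state@center
  }
  stopifnot(is.matrix(anchors), ncol(anchors) == 2, nrow(anchors) >= 1,
            length(center) == 2, R > 0)
  .feasibleRegionCpp(anchors, R, as.numeric(center))
}

#' Resample the disk centre uniformly inside the feasible region
#'
#' Uses the closed form for a single bridge (uniform in the disk) and exact
#' rejection sampling inside the square circumscribing the region for two or
#' more; a sampler failure after 1e6 proposals is a hard error, as it
#' signals a geometry bug rather than a physical state.
#'
#' @param state a \linkS4class{VesicleState} with at least one bridge.
#' @param field the \linkS4class{LigandField} the bridge ids refer to.
#' @param seed integer seed.
#' @return list with the updated \code{state} and \code{nCb}, the number of
#'   constraining bridges.
#' @export
moveStep <- function(state, field, seed = 1L) {
  stopifnot(is(state, "VesicleState"), is(field, "LigandField"))
  if (length(state@bridges) < 1) stop("move step requires >= 1 bridge")
  anchors <- field@positions[state@bridges, , drop = FALSE]
  res <- .moveStepCpp(anchors, state@R, state@center, as.numeric(seed))
  d <- sqrt((anchors[, 1] - res$center[1])^2 +
            (anchors[, 2] - res$center[2])^2)
  stopifnot(all(d <= state@R * (1 + 1e-9)))
  state@center <- res$center
  list(state = state, nCb = res$nCb)
}

#' Run one trajectory of the reaction-diffusion engine
#'
#' Alternates Gillespie reaction windows (\code{\link{reactionStep}}
#' semantics) with uniform resampling of the centre inside the
#' bridge-constrained feasible region, until \code{tTotal}. The initial
#' bridge set is empty unless supplied (no pre-equilibration by default;
#' analyses discard an initial transient instead). When all bridges are
#' lost the detachment policy applies; a disk reaching the field margin
#' truncates the trajectory with a flagged status.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param field a \linkS4class{LigandField}.
#' @param initialCenter starting centre, nm (default origin, the reference
#'   density location).
#' @param replicate replicate index (>= 1), selecting the RNG stream.
#' @param initialBridges optional integer ligand ids bound at t = 0.
#' @return a \linkS4class{Trajectory}.
#' @export
runTrajectory <- function(config, field, initialCenter = c(0, 0),
                          replicate = 1L, initialBridges = integer(0)) {
  stopifnot(is(config, "SimConfig"), is(field, "LigandField"))
  e <- field@extent
  R <- config@R
  if (initialCenter[1] - R < e[1] || initialCenter[1] + R > e[2] ||
      initialCenter[2] - R < e[3] || initialCenter[2] + R > e[4])
    stop("initial disk is not entirely inside the field extent")
  p <- field@positions
  nRec <- as.integer(round(config@rhoR * 3 * pi * R^2))
  res <- .runTrajectoryCpp(p[, 1], p[, 2], e, R,
                           config@rates@kOnPair, config@rates@kOff,
                           config@dt, config@tTotal, nRec,
                           as.numeric(config@seed), as.integer(replicate),
                           config@detachmentPolicy == "terminate",
                           as.numeric(initialCenter), config@recordEvery,
                           as.integer(initialBridges))
  d <- as.data.frame(res$traj)
  new("Trajectory", data = d, status = res$status, R = R,
      seed = as.integer(replicate),
      metadata = list(
        rng = res$rng, baseSeed = config@seed, replicate = replicate,
        dt_s = config@dt, tTotal_s = config@tTotal, R_nm = R,
        rhoR_nm2 = config@rhoR, nReceptors = nRec,
        kOnPair_per_s = config@rates@kOnPair,
        kOff_per_s = config@rates@kOff,
        rhoL_nm2 = field@profile@rhoL,
        lambda_nm2_per_nm = field@profile@lambda,
        direction = field@profile@direction,
        recordEvery = config@recordEvery,
        detachmentPolicy = config@detachmentPolicy,
        units = c(time = "s", length = "nm", energy = "kBT")))
}

#' Run an ensemble of independent replicates
#'
#' Each replicate uses an independent RNG stream derived from the base seed
#' and the replicate index, so ensembles are reproducible and replicate
#' trajectories differ. Optionally each replicate also gets an independent
#' ligand-field realization.
#'
#' @param config a \linkS4class{SimConfig}; \code{config@nReplicates}
#'   replicates are run unless \code{nReplicates} is given.
#' @param field a \linkS4class{LigandField} shared by all replicates, or
#'   NULL with \code{extent} given to draw an independent field per
#'   replicate (field seeds derived from the base seed).
#' @param nReplicates optional override of the replicate count.
#' @param extent field extent when fields are drawn per replicate.
#' @param initialCenter starting centre passed to each replicate.
#' @return list of \linkS4class{Trajectory} objects.
#' @export
runEnsemble <- function(config, field = NULL, nReplicates = NULL,
                        extent = NULL, initialCenter = c(0, 0)) {
  stopifnot(is(config, "SimConfig"))
  n <- if (is.null(nReplicates)) config@nReplicates else as.integer(nReplicates)
  if (is.null(field) && is.null(extent))
    stop("supply a shared field or an extent for per-replicate fields")
  lapply(seq_len(n), function(i) {
    f <- if (is.null(field))
      generateField(config@profile, extent,
                    seed = (config@seed %% 1000000L) * 1000L + i)
    else field
    runTrajectory(config, f, initialCenter = initialCenter, replicate = i)
  })
}

#' Write / read engine trajectories as CSV
#'
#' CSV columns t_s, x_nm, y_nm, n_b, n_cb, n_bind, n_unbind with a JSON
#' sidecar carrying the run metadata (units, seeds, rates, RNG name).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param csvPath output path; sidecar written with extension .json.
#' @export
writeTrajectory <- function(traj, csvPath) {
  stopifnot(is(traj, "Trajectory"))
  write.csv(traj@data, csvPath, row.names = FALSE)
  jsonlite::write_json(
    c(traj@metadata, list(status = traj@status, R_nm = traj@R)),
    sub("\\.csv$", ".json", csvPath), auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' @rdname writeTrajectory
#' @param csvPath path previously written by \code{writeTrajectory} (or an
#'   external tracker CSV with the same schema; missing bookkeeping columns
#'   are filled with zeros).
#' @export
readTrajectory <- function(csvPath) {
  d <- read.csv(csvPath)
  for (col in c("n_b", "n_cb", "n_bind", "n_unbind"))
    if (is.null(d[[col]])) d[[col]] <- 0
  jsonPath <- sub("\\.csv$", ".json", csvPath)
  meta <- if (file.exists(jsonPath))
    jsonlite::read_json(jsonPath, simplifyVector = TRUE) else list()
  R <- if (!is.null(meta$R_nm)) meta$R_nm else NA_real_
  status <- if (!is.null(meta$status)) meta$status else "ok"
  new("Trajectory", data = d, status = status,
      R = as.numeric(R), seed = NA_integer_, metadata = as.list(meta))
}
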