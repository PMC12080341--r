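# Shared fixtures: everything is generated in code at test time.

# reference surface conditions (ligand density nm^-2, receptor density nm^-2,
# simulated gradient slope nm^-2 per nm)
REF_RHO_L <- 0.021
REF_RHO_R <- 0.008
REF_LAMBDA <- REF_RHO_L / 1e4

# a small homogeneous field shared across engine tests
flatField <- local({
  f <- NULL
  function() {
    if (is.null(f))
      f <<- generateField(gradientProfile(lambda = 0),
                          c(-500, 500, -500, 500), seed = 101)
    f
  }
})

# build a LigandField directly from a coordinate matrix (no Poisson draw)
fieldFromPoints <- function(pos, extent,
                            profile = gradientProfile(lambda = 0)) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  colnames(pos) <- c("x_nm", "y_nm")
  new("LigandField", positions = pos, extent = as.numeric(extent),
      profile = profile, seed = 0L,
      index = haptosim:::.buildIndex(pos, as.numeric(extent)))
}

quickConfig <- function(preset = "l5", R = 100, tTotal = 20, seed = 1L,
                        lambda = 0, rhoL = REF_RHO_L, ...) {
  prof <- gradientProfile(rhoL = rhoL, lambda = lambda)
  simConfig(rateConstants(kineticPreset(preset), R), prof, R = R,
            tTotal = tTotal, seed = seed, ...)
}

# per-vesicle drift slope on the trajectory's own grid (OLS through the
# projected parallel displacement); the mean-displacement fit equals the mean
# of these when all trajectories share the sampling grid
vesicleSlope <- function(proj) {
  unname(coef(lm(proj$s_par_nm ~ proj$t_s))[2])
}

# reference drift-ensemble conditions: 2R = 0.2 um disks on a gradient ten
# times the simulated reference slope, one independent carpet per replicate.
# Memoized so several test files can share the same ensembles.
DRIFT_EXTENT <- c(-400, 400, -300, 300)

l5DriftEnsemble <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      cfg <- quickConfig("l5", tTotal = 800, seed = 42, lambda = 2.1e-5)
      trs <- runEnsemble(cfg, field = NULL, extent = DRIFT_EXTENT,
                         nReplicates = 200)
      v <<- list(trajs = trs,
                 proj = lapply(trs, projectTrajectory),
                 slopes = vapply(lapply(trs, projectTrajectory),
                                 vesicleSlope, numeric(1)))
    }
    v
  }
})

l6DriftEnsemble <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      cfg <- quickConfig("l6", tTotal = 1600, seed = 42, lambda = 2.1e-5)
      trs <- runEnsemble(cfg, field = NULL, extent = DRIFT_EXTENT,
                         nReplicates = 200)
      v <<- list(trajs = trs,
                 proj = lapply(trs, projectTrajectory),
                 slopes = vapply(lapply(trs, projectTrajectory),
                                 vesicleSlope, numeric(1)))
    }
    v
  }
})

# bootstrap CI for the ratio of ensemble drift velocities (resampling
# vesicles within each group); slopes precomputed per vesicle
bootstrapRatioCI <- function(slopesA, slopesB, nBoot = 2000, level = 0.95,
                             seed = 1) {
  haptosim:::.withSeed(seed, {
    nA <- length(slopesA); nB <- length(slopesB)
    r <- vapply(seq_len(nBoot), function(i)
      mean(slopesA[sample.int(nA, replace = TRUE)]) /
        mean(slopesB[sample.int(nB, replace = TRUE)]), numeric(1))
    quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  })
}
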