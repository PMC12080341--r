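# Gillespie reaction windows, the alternation loop, and its invariants.

test_that("a pure-death window follows the exponential decay closed form", {
  # all ligands under the disk are bridged at window start, so no rebinding
  # is eligible: bridge count after dt is Binomial(n0, exp(-koff dt))
  n0 <- 20; koff <- 1; dt <- 0.5
  th <- runif(n0, 0, 2 * pi); r <- 40 * sqrt(runif(n0))
  f <- fieldFromPoints(cbind(r * cos(th), r * sin(th)),
                       c(-200, 200, -200, 200))
  st <- vesicleState(R = 50, bridges = 1:n0)
  rc <- new("RateConstants", kOnPair = 1e-9, kOff = koff, cEff = 1, R = 50)
  left <- vapply(1:4000, function(s)
    length(reactionStep(st, f, rc, dt, seed = s)$state@bridges), numeric(1))
  p <- exp(-koff * dt)
  expect_lt(abs(mean(left) - n0 * p), 3 * sqrt(n0 * p * (1 - p) / 4000))
})

test_that("a single free receptor binds at most once per window", {
  M <- 30
  th <- runif(M, 0, 2 * pi); r <- 40 * sqrt(runif(M))
  pos <- cbind(r * cos(th), r * sin(th))
  kOnPair <- 0.05; dt <- 0.4
  events <- vapply(1:4000, function(s) {
    res <- haptosim:::.reactionWindowCpp(pos[, 1], pos[, 2], integer(0),
                                         1L, c(0, 0), 50, kOnPair, 0, dt, s)
    length(res$bridges)
  }, numeric(1))
  expect_lte(max(events), 1)
  p <- 1 - exp(-kOnPair * M * dt)
  expect_lt(abs(mean(events) - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("a zero-duration window leaves the state unchanged", {
  f <- flatField()
  st <- vesicleState(R = 100, bridges = ligandsUnderDisk(f, c(0, 0), 100)[1:5])
  rc <- rateConstants(kineticPreset("l5"), 100)
  out <- reactionStep(st, f, rc, dt = 0, seed = 1)
  expect_identical(out$state@bridges, st@bridges)
  expect_identical(out$nBind + out$nUnbind, 0L)
})

test_that("event bookkeeping conserves bridges against bind/unbind counts", {
  cfg <- quickConfig(tTotal = 10, recordEvery = 3)
  d <- trajectoryData(runTrajectory(cfg, flatField()))
  expect_true(all(diff(d$n_b) == (d$n_bind - d$n_unbind)[-1]))
  nRec <- round(REF_RHO_R * 3 * pi * 100^2)
  expect_true(all(d$n_b >= 0 & d$n_b <= nRec))
  expect_true(all(d$n_cb <= pmax(d$n_b, 0)))
})

test_that("rescaling rates by c and time by 1/c is bitwise identical", {
  f <- flatField()
  rc <- rateConstants(kineticPreset("l5"), 100)
  prof <- gradientProfile(lambda = 0)
  cfg1 <- simConfig(rc, prof, R = 100, tTotal = 15, seed = 5)
  cc <- 4
  rc2 <- new("RateConstants", kOnPair = rc@kOnPair * cc, kOff = rc@kOff * cc,
             cEff = rc@cEff, R = 100)
  cfg2 <- simConfig(rc2, prof, R = 100, tTotal = 15 / cc, dt = cfg1@dt / cc,
                    seed = 5, recordEvery = cfg1@recordEvery)
  t1 <- trajectoryData(runTrajectory(cfg1, f))
  t2 <- trajectoryData(runTrajectory(cfg2, f))
  expect_identical(t1$x_nm, t2$x_nm)
  expect_identical(t1$y_nm, t2$y_nm)
  expect_identical(t1$n_b, t2$n_b)
  expect_identical(t1$t_s, t2$t_s * cc)
})

test_that("replicate streams are reproducible and mutually distinct", {
  cfg <- quickConfig(tTotal = 5, nReplicates = 2L)
  f <- flatField()
  e1 <- runEnsemble(cfg, f)
  e2 <- runEnsemble(cfg, f)
  expect_identical(trajectoryData(e1[[1]]), trajectoryData(e2[[1]]))
  expect_identical(trajectoryData(e1[[2]]), trajectoryData(e2[[2]]))
  expect_false(identical(trajectoryData(e1[[1]]), trajectoryData(e1[[2]])))
  expect_equal(e1[[1]]@metadata$rng, "xoshiro256++/splitmix64")
})

test_that("equilibrium bridge count matches the mean-field prediction", {
  # averaged over independent carpets: a single realization deviates by the
  # Poisson fluctuation of the ligand count under the disk (~4%)
  cfg <- quickConfig(tTotal = 40, recordEvery = 1L, seed = 63)
  trs <- runEnsemble(cfg, field = NULL, extent = c(-300, 300, -300, 300),
                     nReplicates = 8)
  nbSim <- mean(vapply(trs, function(tr) {
    d <- trajectoryData(tr)
    mean(d$n_b[d$t_s > 10])
  }, numeric(1)))
  nbTheory <- bridgeEquilibrium(cfg@rates, 100)$n_b
  expect_lt(abs(nbSim - nbTheory) / nbTheory, 0.05)
})

test_that("losing the last bridge detaches the vesicle", {
  prof <- gradientProfile(lambda = 0)
  rc <- new("RateConstants", kOnPair = 1e-300, kOff = 1.1, cEff = 1e-300,
            R = 100)
  cfg <- simConfig(rc, prof, R = 100, tTotal = 1, dt = 0.01, seed = 1)
  tr <- runTrajectory(cfg, flatField())
  expect_identical(trajectoryStatus(tr), "detached")
  expect_equal(nrow(trajectoryData(tr)), 2)  # t = 0 and the detachment row
  # continue policy keeps integrating with the centre in place
  cfg2 <- simConfig(rc, prof, R = 100, tTotal = 1, dt = 0.01, seed = 1,
                    detachmentPolicy = "continue", recordEvery = 10L)
  tr2 <- runTrajectory(cfg2, flatField())
  d2 <- trajectoryData(tr2)
  expect_identical(trajectoryStatus(tr2), "ok")
  expect_equal(max(d2$t_s), 1, tolerance = 0.02)
  expect_true(all(d2$x_nm == 0))
})

test_that("reaching the field margin truncates with a flagged status", {
  # start the disk 0.3 nm from the edge: the rattling motion crosses it
  # well before the nominal end of the run
  prof <- gradientProfile(lambda = 0)
  f <- generateField(prof, c(-300, 100.3, -300, 300), seed = 19)
  cfg <- quickConfig(tTotal = 120, recordEvery = 1)
  tr <- runTrajectory(cfg, f, initialCenter = c(0, 0))
  expect_identical(trajectoryStatus(tr), "margin")
  d <- trajectoryData(tr)
  expect_lt(nrow(d), 120 / cfg@dt)
  expect_gt(tail(d$x_nm, 1) + 100, 100.3)  # the disk did overrun the edge
})

test_that("an ensemble with zero gradient shows no directional bias", {
  # independent field realizations per replicate: a shared carpet would give
  # every vesicle the same quenched-disorder bias
  cfg <- quickConfig(tTotal = 400, seed = 71)
  trs <- runEnsemble(cfg, field = NULL, extent = c(-400, 400, -300, 300),
                     nReplicates = 60)
  md <- meanDisplacement(lapply(trs, projectTrajectory))
  last <- md[nrow(md), ]
  expect_lt(abs(last$mean_par_nm), 3 * last$sem_par_nm)
  expect_lt(abs(last$mean_perp_nm), 3 * last$sem_perp_nm)
})

test_that("drift grows with gradient steepness (paired replicates)", {
  cfg <- quickConfig(tTotal = 800, seed = 42, lambda = 2.1e-6)
  trs <- runEnsemble(cfg, field = NULL, extent = DRIFT_EXTENT,
                     nReplicates = 100)
  mild <- vapply(lapply(trs, projectTrajectory), vesicleSlope, numeric(1))
  steep <- l5DriftEnsemble()$slopes[1:100]
  # same replicate seeds and field seeds in both ensembles: paired contrast
  tt <- t.test(steep, mild, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # and the steep-gradient drift is itself clearly positive
  ttPos <- t.test(l5DriftEnsemble()$slopes, alternative = "greater")
  expect_lt(ttPos$p.value, 0.01)
})

test_that("drift velocity is non-decreasing with disk radius", {
  reps <- c(`50` = 240, `200` = 40)
  out <- lapply(names(reps), function(Rc) {
    R <- as.numeric(Rc)
    prof <- gradientProfile(lambda = 2.1e-5)
    cfg <- simConfig(rateConstants(kineticPreset("l5"), R), prof, R = R,
                     tTotal = 600, seed = 42)
    trs <- runEnsemble(cfg, field = NULL, extent = DRIFT_EXTENT,
                       nReplicates = reps[[Rc]])
    vapply(lapply(trs, projectTrajectory), vesicleSlope, numeric(1))
  })
  mid <- l5DriftEnsemble()$slopes  # R = 100 nm, shared ensemble
  m <- c(mean(out[[1]]), mean(mid), mean(out[[2]]))
  se <- c(sd(out[[1]]) / sqrt(length(out[[1]])),
          sd(mid) / sqrt(length(mid)),
          sd(out[[2]]) / sqrt(length(out[[2]])))
  # bin means non-decreasing within error, strict increase across the range
  expect_gt(m[3] - m[1], 2 * sqrt(se[1]^2 + se[3]^2))
  expect_gt(m[2], m[1] - 2 * sqrt(se[1]^2 + se[2]^2))
  expect_gt(m[3], m[2] - 2 * sqrt(se[2]^2 + se[3]^2))
  # and the pooled rank correlation of per-vesicle velocity with radius
  Rall <- c(rep(50, length(out[[1]])), rep(100, length(mid)),
            rep(200, length(out[[2]])))
  vall <- c(out[[1]], mid, out[[2]])
  trend <- sizeBinnedVelocities(Rall, vall)$trend
  expect_gt(trend$rho, 0)
  expect_lt(trend$p, 0.05)
})

test_that("trajectories round-trip through CSV with metadata", {
  cfg <- quickConfig(tTotal = 5)
  tr <- runTrajectory(cfg, flatField())
  csv <- tempfile(fileext = ".csv")
  writeTrajectory(tr, csv)
  tr2 <- readTrajectory(csv)
  expect_equal(trajectoryData(tr2)$x_nm, trajectoryData(tr)$x_nm,
               tolerance = 1e-12)
  expect_equal(diskRadius(tr2), 100)
  expect_identical(trajectoryStatus(tr2), "ok")
})
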