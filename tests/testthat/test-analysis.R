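# Ensemble statistics: projections, drift fits, MSD, mobility, size bins.

lineTraj <- function(v, n = 50, dt = 10, dir = c(1, 0), x0 = 0, y0 = 0) {
  t <- seq(0, by = dt, length.out = n)
  data.frame(t_s = t, x_nm = x0 + v * t * dir[1], y_nm = y0 + v * t * dir[2])
}

walkTraj <- function(D, n = 200, dt = 1, vdrift = 0) {
  sdStep <- sqrt(2 * D * dt)
  data.frame(t_s = seq(0, by = dt, length.out = n),
             x_nm = cumsum(c(0, rnorm(n - 1, vdrift * dt, sdStep))),
             y_nm = cumsum(c(0, rnorm(n - 1, 0, sdStep))))
}

test_that("projection rotates displacements into gradient coordinates", {
  tr <- lineTraj(2, dir = c(1, 0))
  p <- projectTrajectory(tr, c(1, 0))
  expect_true(all(p$s_perp_nm == 0))
  expect_equal(tail(p$s_par_nm, 1), 2 * tail(tr$t_s, 1))
  # 45 degrees: displacement (1, 0) splits evenly
  p45 <- projectTrajectory(data.frame(t_s = 0:1, x_nm = c(0, 1),
                                      y_nm = c(0, 0)),
                           c(1, 1))
  expect_equal(p45$s_par_nm[2], 1 / sqrt(2))
  expect_equal(p45$s_perp_nm[2], -1 / sqrt(2))
  expect_error(projectTrajectory(tr, c(0, 0)), "norm")
})

test_that("projection is an isometry and rotation-equivariant", {
  set.seed(5)
  for (i in 1:20) {
    tr <- walkTraj(3, n = 40)
    u <- c(cos(a <- runif(1, 0, 2 * pi)), sin(a))
    p <- projectTrajectory(tr, u)
    dx <- tr$x_nm - tr$x_nm[1]; dy <- tr$y_nm - tr$y_nm[1]
    expect_equal(p$s_par_nm^2 + p$s_perp_nm^2, dx^2 + dy^2,
                 tolerance = 1e-9)
    # rotating trajectory and gradient together changes nothing
    b <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(b), sin(b), -sin(b), cos(b)), 2)
    xy <- cbind(dx, dy) %*% t(Rm)
    tr2 <- data.frame(t_s = tr$t_s, x_nm = xy[, 1], y_nm = xy[, 2])
    p2 <- projectTrajectory(tr2, as.numeric(Rm %*% u))
    expect_equal(p2$s_par_nm, p$s_par_nm, tolerance = 1e-9)
    expect_equal(p2$s_perp_nm, p$s_perp_nm, tolerance = 1e-9)
  }
})

test_that("mean displacement averages, crops and propagates SEM", {
  # mirror-image pair cancels exactly
  a <- projectTrajectory(lineTraj(1))
  b <- projectTrajectory(lineTraj(-1))
  md <- meanDisplacement(list(a, b))
  expect_true(all(md$mean_par_nm == 0))
  # identical straight lines: slope recovered, SEM zero
  md2 <- meanDisplacement(list(a, a, a))
  expect_equal(fitDrift(md2, "par")$v_nm_s, 1, tolerance = 1e-12)
  expect_true(all(md2$sem_par_nm == 0))
  # cropping to the shortest trajectory
  c2 <- projectTrajectory(lineTraj(1, n = 20))
  md3 <- meanDisplacement(list(a, c2))
  expect_equal(max(md3$t_s), max(c2$t_s))
  expect_error(meanDisplacement(list(a)), "two")
})

test_that("a diffusive ensemble is a null for the drift at 3 SEM", {
  set.seed(9)
  hits <- vapply(1:100, function(i) {
    md <- meanDisplacement(lapply(1:20, function(j)
      projectTrajectory(walkTraj(2, n = 50))))
    last <- md[nrow(md), ]
    abs(last$mean_par_nm) < 3 * last$sem_par_nm
  }, logical(1))
  expect_gte(sum(hits), 97)
})

test_that("drift fit recovers known slopes and reports honest errors", {
  md <- data.frame(t_s = 0:10 * 10, mean_par_nm = 0:10 * 10 * 0.5)
  fit <- fitDrift(md, "par")
  expect_equal(fit$v_nm_s, 0.5, tolerance = 1e-12)
  expect_lt(fit$se_nm_s, 1e-12)
  expect_error(fitDrift(md[1:2, ], "par"), "3 time points")
  # parameter recovery: drift + noise sized for ~20% relative SE
  set.seed(12)
  v <- 1e-3
  res <- t(vapply(1:100, function(i) {
    t <- seq(0, 1000, by = 20)
    curve <- data.frame(t_s = t,
                        mean_par_nm = v * t + rnorm(length(t), 0, 0.12))
    f <- fitDrift(curve, "par")
    c(f$v_nm_s, f$se_nm_s)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) - v), mean(res[, 2]))      # bias < SE
  expect_gte(mean(abs(res[, 1] - v) < 3 * res[, 2]), 0.95)  # coverage
})

test_that("per-vesicle velocity is end-to-end displacement over duration", {
  tr <- data.frame(t_s = c(0, 36000), x_nm = c(0, 360), y_nm = c(0, 0))
  v <- perVesicleVelocity(tr)
  expect_equal(v$v_par_nm_s, 0.01)
  expect_equal(v$v_perp_nm_s, 0)
  loop <- data.frame(t_s = 0:4, x_nm = c(0, 5, 5, 0, 0),
                     y_nm = c(0, 0, 5, 5, 0))
  expect_equal(unlist(perVesicleVelocity(loop)), c(v_par_nm_s = 0,
                                                   v_perp_nm_s = 0))
  expect_error(perVesicleVelocity(tr[1, , drop = FALSE]), "two samples")
})

test_that("per-vesicle velocities come from uncropped trajectories", {
  # the mean-displacement curve crops to the shortest duration, but the
  # per-vesicle velocity path must keep using the full trajectory
  set.seed(17)
  long <- walkTraj(2, n = 100, dt = 10, vdrift = 1e-2)
  short <- walkTraj(2, n = 40, dt = 10)
  s <- summarizeEnsemble(list(long, short))
  expect_equal(max(s$meanDisplacement$t_s), max(short$t_s))
  expect_equal(s$perVesicle$v_par_nm_s[1],
               perVesicleVelocity(long)$v_par_nm_s)
  cropped <- long[long$t_s <= max(short$t_s), ]
  expect_false(isTRUE(all.equal(perVesicleVelocity(cropped)$v_par_nm_s,
                                perVesicleVelocity(long)$v_par_nm_s)))
})

test_that("MSD slope recovers a known diffusion coefficient", {
  set.seed(3)
  D <- 5
  est <- vapply(1:100, function(i)
    diffusionCoefficient(walkTraj(D, n = 300))$D_nm2_s, numeric(1))
  expect_lt(abs(median(est) - D) / D, 0.2)
  # immobile trajectory sits below the noise floor
  still <- data.frame(t_s = 0:99, x_nm = rnorm(100, 0, 1e-3),
                      y_nm = rnorm(100, 0, 1e-3))
  dc <- diffusionCoefficient(still, noiseFloor = 1e-4)
  expect_identical(dc$flag, "immobile")
  # pure drift: MSD ~ t^2, flagged non-diffusive
  drift <- lineTraj(2, n = 100, dt = 1)
  dc2 <- diffusionCoefficient(drift)
  expect_identical(dc2$flag, "superdiffusive")
  expect_equal(dc2$alpha, 2, tolerance = 1e-6)
  expect_error(diffusionCoefficient(drift[1:5, ]), "10 samples")
})

test_that("mobility filter separates a static subpopulation", {
  expect_length(mobilityFilter(rep(2, 40), "quantile", 0)$immobileIdx, 0)
  set.seed(21)
  D1 <- 10
  D <- c(rnorm(95, D1, 1), rnorm(5, D1 / 100, 0.02))
  part <- mobilityFilter(D, "fixed", threshold = 1)
  expect_equal(length(part$immobileIdx) / length(D), 0.05)
  expect_true(all(D[part$immobileIdx] < 1))
  # excluding a zero-drift immobile subpopulation raises the fitted drift
  set.seed(22)
  mobile <- lapply(1:40, function(i) walkTraj(2, n = 60, dt = 10,
                                              vdrift = 0.5))
  stuck <- lapply(1:10, function(i) walkTraj(1e-4, n = 60, dt = 10))
  all <- c(mobile, stuck)
  Dhat <- vapply(all, function(tr) diffusionCoefficient(tr)$D_nm2_s,
                 numeric(1))
  keep <- mobilityFilter(Dhat, "fixed", 0.5)$mobile
  vAll <- fitDrift(meanDisplacement(lapply(all, projectTrajectory)),
                   "par")$v_nm_s
  vMob <- fitDrift(meanDisplacement(lapply(all[keep], projectTrajectory)),
                   "par")$v_nm_s
  expect_gt(vMob, vAll)
  expect_true(all(which(!keep) > 40))  # exactly the constructed stuck set
})

test_that("size-binned velocities summarize and rank the trend", {
  # identical velocities: zero trend
  sb <- sizeBinnedVelocities(rep(c(100, 500, 900), each = 10), rep(2, 30))
  expect_equal(sb$trend$rho, 0)
  # noisy linear v(R): positive rank correlation detected reliably
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    R <- rep(c(100, 500, 900), each = 12)
    v <- 1e-5 * R + rnorm(length(R), 0, 2e-3)
    sizeBinnedVelocities(R, v)$trend$p < 0.05 &
      sizeBinnedVelocities(R, v)$trend$rho > 0
  }, logical(1))
  expect_gte(sum(hits), 95)
  # summary block: quartiles and outliers per bin
  set.seed(32)
  v <- c(rnorm(30), 50)
  sb2 <- sizeBinnedVelocities(c(rep(100, 31), rep(500, 10)),
                              c(v, rnorm(10)))
  expect_equal(sb2$summary$n[1], 31)
  expect_gte(sb2$summary$nOutliers[1], 1)
})

test_that("the ensemble summary pipeline wires the pieces together", {
  set.seed(41)
  trs <- lapply(1:12, function(i) walkTraj(2, n = 80, dt = 10,
                                           vdrift = 0.2))
  s <- summarizeEnsemble(trs)
  expect_named(s$drift, c("par", "perp"))
  expect_equal(nrow(s$perVesicle), 12)
  expect_lt(abs(s$drift$par$v_nm_s - 0.2), 0.15)
  expect_lt(s$biasTest$p, 0.01)
  expect_match(s$biasTest$name, "t test")
})
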