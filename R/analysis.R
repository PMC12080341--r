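## Trajectory ensemble statistics: gradient-projected displacements, drift
## fits, per-vesicle velocities, diffusion coefficients, mobility filtering
## and size binning.

.asTrajData <- function(traj) {
  if (is(traj, "Trajectory")) traj@data else as.data.frame(traj)
}

.unitDirection <- function(direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("gradient direction must have non-zero norm")
  direction / nrm
}

#' Project a trajectory onto the gradient direction
#'
#' Displacements relative to the first sample, rotated into components
#' parallel (positive = up-gradient) and perpendicular to the gradient.
#' The projection is an isometry: s_par^2 + s_perp^2 equals the squared
#' planar displacement at every sample.
#'
#' @param traj a \linkS4class{Trajectory} or data.frame with t_s, x_nm,
#'   y_nm.
#' @param direction gradient direction (normalized internally).
#' @return data.frame with t_s, s_par_nm, s_perp_nm.
#' @export
projectTrajectory <- function(traj, direction = c(1, 0)) {
  d <- .asTrajData(traj)
  if (nrow(d) == 0) stop("empty trajectory")
  u <- .unitDirection(direction)
  dx <- d$x_nm - d$x_nm[1]
  dy <- d$y_nm - d$y_nm[1]
  data.frame(t_s = d$t_s,
             s_par_nm = dx * u[1] + dy * u[2],
             s_perp_nm = -dx * u[2] + dy * u[1])
}

#' Ensemble mean displacement with SEM
#'
#' Trajectories are cropped to the shortest common duration; the common
#' time grid is the sampling grid of the shortest trajectory, onto which
#' every trajectory is linearly interpolated. SEM is the per-time sample
#' standard deviation over vesicles divided by sqrt(n).
#'
#' @param projected list of projected trajectories
#'   (\code{\link{projectTrajectory}} outputs).
#' @return data.frame with t_s, mean_par_nm, sem_par_nm, mean_perp_nm,
#'   sem_perp_nm and the ensemble size as attribute \code{n}.
#' @export
meanDisplacement <- function(projected) {
  if (length(projected) < 2) stop("need at least two trajectories")
  ends <- vapply(projected, function(p) max(p$t_s), numeric(1))
  grid <- projected[[which.min(ends)]]$t_s
  grid <- grid[grid <= min(ends) + 1e-12]
  par <- vapply(projected, function(p)
    approx(p$t_s, p$s_par_nm, xout = grid, rule = 2)$y, numeric(length(grid)))
  perp <- vapply(projected, function(p)
    approx(p$t_s, p$s_perp_nm, xout = grid, rule = 2)$y, numeric(length(grid)))
  n <- length(projected)
  out <- data.frame(
    t_s = grid,
    mean_par_nm = rowMeans(par),
    sem_par_nm = apply(par, 1, sd) / sqrt(n),
    mean_perp_nm = rowMeans(perp),
    sem_perp_nm = apply(perp, 1, sd) / sqrt(n))
  attr(out, "n") <- n
  out
}

#' Drift velocity from a mean-displacement curve
#'
#' Ordinary least-squares slope of mean displacement versus time, intercept
#' free.
#'
#' @param curve data.frame from \code{\link{meanDisplacement}} (or any
#'   data.frame with a time column and a displacement column).
#' @param component "par" or "perp", selecting mean_par_nm / mean_perp_nm;
#'   ignored if \code{value} is given.
#' @param value optional displacement column name.
#' @return list with \code{v_nm_s} (slope) and \code{se_nm_s}.
#' @export
fitDrift <- function(curve, component = c("par", "perp"), value = NULL) {
  component <- match.arg(component)
  col <- if (!is.null(value)) value else paste0("mean_", component, "_nm")
  if (nrow(curve) < 3) stop("need at least 3 time points for a drift fit")
  if (length(unique(curve$t_s)) < 2) stop("degenerate time grid")
  fit <- lm(curve[[col]] ~ curve$t_s)
  # exact lines are legitimate inputs; silence the perfect-fit warning
  s <- suppressWarnings(summary(fit))$coefficients
  list(v_nm_s = unname(s[2, 1]), se_nm_s = unname(s[2, 2]))
}

#' Per-vesicle average velocity
#'
#' End-to-end displacement divided by trajectory duration, projected onto
#' the gradient direction. This follows the end-point definition used for
#' per-vesicle scatter statistics, distinct from the slope of a fitted
#' line; both are computed on the uncropped trajectory.
#'
#' @param traj a \linkS4class{Trajectory} or data.frame.
#' @param direction gradient direction.
#' @return list with v_par_nm_s and v_perp_nm_s.
#' @export
perVesicleVelocity <- function(traj, direction = c(1, 0)) {
  d <- .asTrajData(traj)
  if (nrow(d) < 2) stop("per-vesicle velocity needs at least two samples")
  dur <- d$t_s[nrow(d)] - d$t_s[1]
  if (dur <= 0) stop("trajectory duration must be positive")
  u <- .unitDirection(direction)
  dx <- d$x_nm[nrow(d)] - d$x_nm[1]
  dy <- d$y_nm[nrow(d)] - d$y_nm[1]
  list(v_par_nm_s = (dx * u[1] + dy * u[2]) / dur,
       v_perp_nm_s = (-dx * u[2] + dy * u[1]) / dur)
}

#' Diffusion coefficient from the time-averaged MSD
#'
#' Time-averaged mean squared displacement over the first decade of lag
#' times (lags 1..10 sampling intervals, or fewer when the trajectory is
#' short); D is the OLS slope over lag time divided by 4 (2D convention).
#' A log-log slope of the same MSD curve is returned as the anomaly
#' exponent; values well above 1 flag ballistic (drift-dominated,
#' non-diffusive) motion.
#'
#' @param traj a \linkS4class{Trajectory} or data.frame (>= 10 samples).
#' @param maxLag largest lag in sampling intervals (default 10).
#' @param noiseFloor D values below this are reported as immobile-grade
#'   (nm^2/s; default 0).
#' @return list with D_nm2_s, alpha (log-log MSD exponent), lags_s,
#'   msd_nm2, and flag in {"diffusive", "superdiffusive", "immobile"}.
#' @export
diffusionCoefficient <- function(traj, maxLag = 10, noiseFloor = 0) {
  d <- .asTrajData(traj)
  n <- nrow(d)
  if (n < 10) stop("need at least 10 samples for an MSD estimate")
  lags <- seq_len(min(maxLag, n - 2))
  msd <- vapply(lags, function(k) {
    dx <- d$x_nm[(1 + k):n] - d$x_nm[1:(n - k)]
    dy <- d$y_nm[(1 + k):n] - d$y_nm[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  dtSamp <- mean(diff(d$t_s))
  tl <- lags * dtSamp
  D <- unname(coef(lm(msd ~ tl))[2]) / 4
  alpha <- if (all(msd > 0)) unname(coef(lm(log(msd) ~ log(tl)))[2]) else 0
  flag <- if (D <= noiseFloor) "immobile"
          else if (alpha > 1.5) "superdiffusive" else "diffusive"
  list(D_nm2_s = D, alpha = alpha, lags_s = tl, msd_nm2 = msd, flag = flag,
       method = "time-averaged MSD, OLS over first lag decade / 4")
}

#' Partition an ensemble into mobile and immobile vesicles
#'
#' A small static subpopulation (in experiments, of order 5 percent) shows
#' up as an outlying low mode in the per-vesicle diffusion coefficients;
#' downstream statistics are computed on the mobile subset by default,
#' with the immobile partition retained and labelled so analyses can be
#' replicated with it included.
#'
#' @param D numeric vector of per-vesicle diffusion coefficients, nm^2/s.
#' @param policy "fixed" (threshold is an absolute D cutoff; default) or
#'   "quantile" (threshold is the quantile level of D to exclude).
#' @param threshold cutoff for the chosen policy. For "fixed", vesicles
#'   with D < threshold are immobile. For "quantile", the lowest
#'   \code{threshold} fraction is immobile (0 excludes none).
#' @return list with logical \code{mobile}, and index vectors
#'   \code{mobileIdx}, \code{immobileIdx}, plus the realized cutoff.
#' @export
mobilityFilter <- function(D, policy = c("fixed", "quantile"),
                           threshold = 0) {
  policy <- match.arg(policy)
  cut <- if (policy == "fixed") threshold
         else if (threshold <= 0) -Inf
         else quantile(D, threshold, names = FALSE)
  mobile <- D >= cut
  list(mobile = mobile,
       mobileIdx = which(mobile), immobileIdx = which(!mobile),
       cutoff_nm2_s = cut, policy = policy)
}

#' Size-binned drift-velocity summary
#'
#' Box-plot-style summary of per-vesicle parallel velocities by disk
#' radius: per-bin quartiles, mean and 1.5 IQR outliers, plus a
#' monotonic-trend statistic (Spearman rank correlation of velocity
#' against radius).
#'
#' @param R_nm per-vesicle radii, nm.
#' @param v_par_nm_s per-vesicle parallel velocities, nm/s.
#' @param bins optional break points for radius bins; by default each
#'   distinct radius is its own bin.
#' @return list with \code{summary} (one row per bin: R_nm, n, q1, median,
#'   q3, mean, outliers) and \code{trend} (Spearman rho and p value).
#' @export
sizeBinnedVelocities <- function(R_nm, v_par_nm_s, bins = NULL) {
  stopifnot(length(R_nm) == length(v_par_nm_s))
  grp <- if (is.null(bins)) factor(R_nm)
         else cut(R_nm, breaks = bins, include.lowest = TRUE)
  if (nlevels(droplevels(grp)) < 2) stop("need at least two occupied bins")
  rows <- lapply(levels(droplevels(grp)), function(g) {
    v <- v_par_nm_s[grp == g]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    data.frame(bin = g, R_nm = mean(R_nm[grp == g]), n = length(v),
               q1 = q[1], median = q[2], q3 = q[3], mean = mean(v),
               nOutliers = length(out))
  })
  summ <- do.call(rbind, rows)
  trend <- if (sd(v_par_nm_s) == 0 || sd(R_nm) == 0) {
    list(rho = 0, p = 1)  # constant input: no trend by convention
  } else {
    ct <- suppressWarnings(
      stats::cor.test(R_nm, v_par_nm_s, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(summary = summ, trend = trend)
}

#' Summarize a simulated (or imported) ensemble for one condition
#'
#' Convenience pipeline: project, average, fit drift parallel and
#' perpendicular, compute per-vesicle velocities and diffusion
#' coefficients, apply the mobility filter, and report a directional-bias
#' test. The bias test is a two-sided one-sample t test of the per-vesicle
#' parallel velocities against zero (named in the output metadata).
#'
#' @param trajs list of \linkS4class{Trajectory} objects (or data.frames).
#' @param direction gradient direction.
#' @param mobility optional list(policy, threshold) for
#'   \code{\link{mobilityFilter}}; default excludes nothing.
#' @param includeImmobile compute the headline statistics on all vesicles
#'   instead of the mobile subset.
#' @return list with \code{drift} (parallel and perpendicular fits),
#'   \code{perVesicle} data.frame, \code{meanDisplacement} curve,
#'   \code{mobility} partition and \code{biasTest}.
#' @export
summarizeEnsemble <- function(trajs, direction = c(1, 0), mobility = NULL,
                              includeImmobile = FALSE) {
  pv <- do.call(rbind, lapply(trajs, function(tr) {
    v <- perVesicleVelocity(tr, direction)
    dc <- tryCatch(diffusionCoefficient(tr),
                   error = function(e) list(D_nm2_s = NA_real_))
    data.frame(R_nm = if (is(tr, "Trajectory")) tr@R else NA_real_,
               v_par_nm_s = v$v_par_nm_s, v_perp_nm_s = v$v_perp_nm_s,
               D_nm2_s = dc$D_nm2_s)
  }))
  filt <- if (is.null(mobility))
    mobilityFilter(pv$D_nm2_s, "fixed", -Inf)
  else mobilityFilter(pv$D_nm2_s, mobility$policy, mobility$threshold)
  keep <- if (includeImmobile) rep(TRUE, nrow(pv)) else filt$mobile
  proj <- lapply(trajs[keep], projectTrajectory, direction = direction)
  md <- meanDisplacement(proj)
  bias <- stats::t.test(pv$v_par_nm_s[keep])
  list(drift = list(par = fitDrift(md, "par"), perp = fitDrift(md, "perp")),
       perVesicle = pv, meanDisplacement = md, mobility = filt,
       biasTest = list(name = "two-sided one-sample t test of v_par vs 0",
                       p = bias$p.value,
                       ci_nm_s = unname(bias$conf.int)))
}
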