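## Ligand carpet: inhomogeneous Poisson sampling and spatial queries.

## run code with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Construct a linear ligand-density profile
#'
#' The default slope reproduces the simulated-gradient convention
#' lambda = rhoL / 10 per micrometre, i.e. the density doubles 10 um
#' up-gradient of the reference origin.
#'
#' @param rhoL reference ligand density at the origin, nm^-2
#'   (default 0.021).
#' @param lambda density slope, nm^-2 per nm (default rhoL / 1e4).
#' @param direction 2-vector pointing up-gradient (normalized internally).
#' @return a \linkS4class{GradientProfile}.
#' @export
gradientProfile <- function(rhoL = 0.021, lambda = rhoL / 1e4,
                            direction = c(1, 0)) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must have non-zero norm")
  new("GradientProfile", rhoL = rhoL, lambda = lambda,
      direction = direction / nrm)
}

#' Local ligand density of a profile or field
#'
#' @param x a \linkS4class{GradientProfile} or \linkS4class{LigandField}.
#' @param point 2-vector (or n x 2 matrix) of coordinates, nm. For a field,
#'   points outside the extent are an error.
#' @return density in nm^-2.
#' @export
localDensity <- function(x, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  if (is(x, "LigandField")) {
    e <- x@extent
    out <- pts[, 1] < e[1] | pts[, 1] > e[2] | pts[, 2] < e[3] | pts[, 2] > e[4]
    if (any(out))
      stop(sprintf("point (%g, %g) lies outside the field extent",
                   pts[which(out)[1], 1], pts[which(out)[1], 2]))
    x <- x@profile
  }
  stopifnot(is(x, "GradientProfile"))
  drop(x@rhoL + x@lambda * (pts %*% x@direction))
}

.buildIndex <- function(positions, extent, cell = 25) {
  if (nrow(positions) == 0)
    return(list(cell = cell, nx = 1L, ny = 1L, starts = c(1L, 1L),
                order = integer(0)))
  nx <- max(1L, as.integer(ceiling((extent[2] - extent[1]) / cell)))
  ny <- max(1L, as.integer(ceiling((extent[4] - extent[3]) / cell)))
  ix <- pmin(nx - 1L, pmax(0L, as.integer((positions[, 1] - extent[1]) / cell)))
  iy <- pmin(ny - 1L, pmax(0L, as.integer((positions[, 2] - extent[3]) / cell)))
  code <- ix + nx * iy
  ord <- order(code)
  counts <- tabulate(code[ord] + 1L, nbins = nx * ny)
  starts <- c(1L, 1L + cumsum(counts))
  list(cell = cell, nx = nx, ny = ny, starts = as.integer(starts), order = ord)
}

#' Generate a ligand field by Poisson thinning
#'
#' Draws ligand positions from an inhomogeneous Poisson point process with
#' intensity \code{rhoL + lambda * (p . direction)} by thinning a homogeneous
#' process at the maximum intensity over the extent. Deterministic given
#' \code{seed}; the caller's RNG state is untouched.
#'
#' @param profile a \linkS4class{GradientProfile}.
#' @param extent rectangle c(xmin, xmax, ymin, ymax), nm. Must be large
#'   enough that the intensity is non-negative throughout, and should leave
#'   a margin of at least the expected trajectory span + 4 R around the
#'   start: the engine errors rather than extending the field lazily.
#' @param seed integer seed.
#' @return a \linkS4class{LigandField}.
#' @export
generateField <- function(profile, extent, seed = 1L) {
  stopifnot(is(profile, "GradientProfile"))
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  corners <- cbind(extent[c(1, 1, 2, 2)], extent[c(3, 4, 3, 4)])
  dens <- localDensity(profile, corners)
  if (min(dens) < 0)
    stop(sprintf(
      "intensity is negative inside the extent (reaches %.3g nm^-2 at corner (%g, %g)); shrink the extent or reduce |lambda|",
      min(dens), corners[which.min(dens), 1], corners[which.min(dens), 2]))
  rhoMax <- max(dens)
  area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  pos <- .withSeed(seed, {
    n <- rpois(1, rhoMax * area)
    x <- runif(n, extent[1], extent[2])
    y <- runif(n, extent[3], extent[4])
    keep <- runif(n) * rhoMax < localDensity(profile, cbind(x, y))
    cbind(x[keep], y[keep])
  })
  colnames(pos) <- c("x_nm", "y_nm")
  new("LigandField", positions = pos, extent = as.numeric(extent),
      profile = profile, seed = as.integer(seed),
      index = .buildIndex(pos, extent))
}

#' Ligands under the adhesion disk
#'
#' Returns the indices of all ligands with |p - center| <= R (closed-disk
#' convention), using the field's spatial bin index so the query touches
#' only cells overlapping the disk.
#'
#' @param field a \linkS4class{LigandField}.
#' @param center disk centre, nm.
#' @param R disk radius, nm. The disk must lie entirely inside the extent.
#' @return integer vector of ligand indices (rows of
#'   \code{ligandPositions(field)}).
#' @export
ligandsUnderDisk <- function(field, center, R) {
  stopifnot(is(field, "LigandField"), length(center) == 2, R > 0)
  e <- field@extent
  over <- max(0, e[1] - (center[1] - R), (center[1] + R) - e[2],
              e[3] - (center[2] - R), (center[2] + R) - e[4])
  if (over > 0)
    stop(sprintf(
      "disk overhangs the field extent by %.3g nm; enlarge the extent to avoid edge bias",
      over))
  idx <- field@index
  if (length(idx$order) == 0) return(integer(0))
  cx0 <- max(0L, as.integer((center[1] - R - e[1]) / idx$cell))
  cx1 <- min(idx$nx - 1L, as.integer((center[1] + R - e[1]) / idx$cell))
  cy0 <- max(0L, as.integer((center[2] - R - e[3]) / idx$cell))
  cy1 <- min(idx$ny - 1L, as.integer((center[2] + R - e[3]) / idx$cell))
  cand <- integer(0)
  for (iy in cy0:cy1) {
    codes <- (cx0:cx1) + idx$nx * iy + 1L
    for (cc in codes) {
      lo <- idx$starts[cc]
      hi <- idx$starts[cc + 1L] - 1L
      if (hi >= lo) cand <- c(cand, idx$order[lo:hi])
    }
  }
  p <- field@positions
  d2 <- (p[cand, 1] - center[1])^2 + (p[cand, 2] - center[2])^2
  sort(cand[d2 <= R^2])
}

#' Dump / load a ligand field as CSV + JSON sidecar
#'
#' The CSV holds columns id, x_nm, y_nm; the sidecar records profile,
#' extent and seed so the exact point set can be regenerated or audited.
#'
#' @param field a \linkS4class{LigandField}.
#' @param csvPath output CSV path; the sidecar is written next to it with
#'   extension .json.
#' @export
writeLigandField <- function(field, csvPath) {
  stopifnot(is(field, "LigandField"))
  df <- data.frame(id = seq_len(nrow(field@positions)),
                   x_nm = field@positions[, 1],
                   y_nm = field@positions[, 2])
  write.csv(df, csvPath, row.names = FALSE)
  side <- list(rhoL_nm2 = field@profile@rhoL,
               lambda_nm2_per_nm = field@profile@lambda,
               direction = field@profile@direction,
               extent_nm = field@extent, seed = field@seed)
  jsonlite::write_json(side, sub("\\.csv$", ".json", csvPath),
                       auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' @rdname writeLigandField
#' @param csvPath path previously written by \code{writeLigandField}.
#' @return \code{readLigandField}: the reconstructed
#'   \linkS4class{LigandField}.
#' @export
readLigandField <- function(csvPath) {
  df <- read.csv(csvPath)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csvPath),
                              simplifyVector = TRUE)
  prof <- gradientProfile(rhoL = side$rhoL_nm2,
                          lambda = side$lambda_nm2_per_nm,
                          direction = side$direction)
  pos <- cbind(x_nm = df$x_nm, y_nm = df$y_nm)
  new("LigandField", positions = pos, extent = as.numeric(side$extent_nm),
      profile = prof, seed = as.integer(side$seed),
      index = .buildIndex(pos, as.numeric(side$extent_nm)))
}
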