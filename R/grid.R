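# Equal-area grid geometry: constructor, Albers transform, cell assignment.

# GRS80 ellipsoid
.A_GRS80 <- 6378137
.F_GRS80 <- 1 / 298.257222101

#' Construct an equal-area analysis grid
#'
#' Defaults reproduce the standard Australian Albers configuration (central
#' meridian 132 degrees E, standard parallels -18 and -36, latitude of origin 0,
#' zero false easting/northing) with 100 km cells; every parameter is
#' configurable. The default origin and extent give a 30 x 30 window over the
#' Australian mainland.
#'
#' @param lon0 central meridian, degrees east.
#' @param lat0 latitude of origin, degrees.
#' @param lat1,lat2 standard parallels, degrees.
#' @param falseEasting,falseNorthing metres.
#' @param cellSize cell edge, metres.
#' @param x0,y0 projected coordinates of the grid's lower-left corner, metres.
#' @param nx,ny extent in cells.
#' @return a [GridSpec-class] object.
#' @examples
#' g <- gridSpec(nx = 10, ny = 10)
#' albersForward(132, 0, g)   # the projection origin maps to (0, 0)
#' @export
gridSpec <- function(lon0 = 132, lat0 = 0, lat1 = -18, lat2 = -36,
                     falseEasting = 0, falseNorthing = 0,
                     cellSize = 100000, x0 = -1500000, y0 = -4400000,
                     nx = 30L, ny = 30L) {
  new("GridSpec", lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
      falseEasting = falseEasting, falseNorthing = falseNorthing,
      cellSize = cellSize, x0 = x0, y0 = y0,
      nx = as.integer(nx), ny = as.integer(ny))
}

#' @describeIn gridSpec number of cells (nx * ny).
#' @param x a GridSpec.
#' @export
setMethod("length", "GridSpec", function(x) as.integer(x@nx * x@ny))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %.0f m (Albers lon0=%g, parallels %g/%g)\n",
    object@nx, object@ny, object@cellSize, object@lon0, object@lat1,
    object@lat2))
  cat(sprintf("  origin (%.0f, %.0f) m\n", object@x0, object@y0))
})

# q auxiliary of the equal-area latitude (Snyder 3-12)
.albersQ <- function(phi, e) {
  s <- sin(phi)
  (1 - e^2) * (s / (1 - e^2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.albersM <- function(phi, e) cos(phi) / sqrt(1 - e^2 * sin(phi)^2)

.albersConst <- function(grid) {
  e <- sqrt(2 * .F_GRS80 - .F_GRS80^2)
  phi1 <- grid@lat1 * pi / 180
  phi2 <- grid@lat2 * pi / 180
  m1 <- .albersM(phi1, e); m2 <- .albersM(phi2, e)
  q1 <- .albersQ(phi1, e); q2 <- .albersQ(phi2, e)
  n <- if (abs(phi1 - phi2) < 1e-12) sin(phi1) else (m1^2 - m2^2) / (q2 - q1)
  if (!is.finite(n) || abs(n) < 1e-12)
    stop("degenerate cone: check the standard parallels")
  C <- m1^2 + n * q1
  rho0 <- .A_GRS80 * sqrt(C - n * .albersQ(grid@lat0 * pi / 180, e)) / n
  list(e = e, n = n, C = C, rho0 = rho0)
}

#' Albers equal-area conic transform
#'
#' Forward and inverse ellipsoidal (GRS80) Albers equal-area conic projection
#' with the parameters of a [GridSpec-class]. Closed-form equations; the
#' inverse recovers latitude from the equal-area auxiliary by fixed-point
#' iteration to below 1e-12 radians.
#'
#' @param lon,lat coordinates in degrees (vectors allowed).
#' @param x,y projected coordinates in metres.
#' @param grid a [GridSpec-class] carrying the projection parameters.
#' @return `albersForward`: data.frame with columns `x`, `y` (metres).
#'   `albersInverse`: data.frame with columns `lon`, `lat` (degrees).
#' @export
albersForward <- function(lon, lat, grid = gridSpec()) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop("coordinates outside [-180,180] x [-90,90]")
  k <- .albersConst(grid)
  phi <- lat * pi / 180
  q <- .albersQ(phi, k$e)
  under <- k$C - k$n * q
  if (any(under < 0)) stop("latitude beyond the projectable domain for this cone")
  rho <- .A_GRS80 * sqrt(under) / k$n
  theta <- k$n * (lon - grid@lon0) * pi / 180
  data.frame(x = grid@falseEasting + rho * sin(theta),
             y = grid@falseNorthing + k$rho0 - rho * cos(theta))
}

#' @rdname albersForward
#' @export
albersInverse <- function(x, y, grid = gridSpec()) {
  stopifnot(length(x) == length(y))
  k <- .albersConst(grid)
  e <- k$e
  xr <- x - grid@falseEasting
  yr <- k$rho0 - (y - grid@falseNorthing)
  rho <- sqrt(xr^2 + yr^2)
  theta <- atan2(sign(k$n) * xr, sign(k$n) * yr)
  q <- (k$C - (rho * k$n / .A_GRS80)^2) / k$n
  # iterate Snyder 3-16 for phi given q
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  for (it in 1:30) {
    s <- sin(phi)
    d <- (1 - e^2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - e^2) - s / (1 - e^2 * s^2) +
         (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
    phi2 <- phi + d
    if (max(abs(phi2 - phi)) < 1e-13) { phi <- phi2; break }
    phi <- phi2
  }
  data.frame(lon = grid@lon0 + theta / k$n * 180 / pi, lat = phi * 180 / pi)
}

#' Assign projected points to grid cells
#'
#' Half-open convention: a point exactly on a shared edge belongs to the
#' higher-index cell whose lower edge it sits on. Points outside the grid
#' extent get `NA` indices; their count is reported with a message.
#'
#' @param x,y projected coordinates, metres.
#' @param grid a [GridSpec-class].
#' @return data.frame with integer columns `ix`, `iy` (0-based), `NA` for
#'   off-grid points.
#' @export
assignCell <- function(x, y, grid) {
  ix <- floor((x - grid@x0) / grid@cellSize)
  iy <- floor((y - grid@y0) / grid@cellSize)
  off <- ix < 0 | ix >= grid@nx | iy < 0 | iy >= grid@ny
  off[is.na(off)] <- TRUE
  ix[off] <- NA_integer_; iy[off] <- NA_integer_
  if (any(off)) message(sum(off), " point(s) fall outside the grid extent")
  data.frame(ix = as.integer(ix), iy = as.integer(iy))
}

#' @describeIn gridSpec centroids of all cells (or of the cells given by
#'   0-based `ix`, `iy`), as a data.frame with columns `ix`, `iy`, `x`, `y`.
#' @param object a GridSpec.
#' @param ix,iy optional 0-based cell indices; defaults to every cell.
#' @export
setMethod("cellCentroids", "GridSpec", function(object, ix = NULL, iy = NULL) {
  if (is.null(ix)) {
    ij <- expand.grid(ix = seq_len(object@nx) - 1L, iy = seq_len(object@ny) - 1L)
    ix <- ij$ix; iy <- ij$iy
  }
  data.frame(ix = as.integer(ix), iy = as.integer(iy),
             x = object@x0 + (ix + 0.5) * object@cellSize,
             y = object@y0 + (iy + 0.5) * object@cellSize)
})
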