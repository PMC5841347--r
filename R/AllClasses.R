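#' @import methods
NULL

#' GridSpec: an equal-area analysis grid
#'
#' Describes a regular square grid in an Albers equal-area conic projection:
#' the projection parameters, the cell size in metres, the lower-left origin
#' of the grid in projected coordinates, and the grid extent in cells.
#' Cells are half-open squares \code{[x, x + cellSize) x [y, y + cellSize)}
#' indexed by integer \code{(ix, iy)} starting at \code{(0, 0)} in the
#' lower-left corner.
#'
#' @slot lon0 central meridian, degrees east.
#' @slot lat0 latitude of origin, degrees.
#' @slot lat1,lat2 the two standard parallels, degrees.
#' @slot falseEasting,falseNorthing false easting / northing, metres.
#' @slot cellSize cell edge length, metres.
#' @slot x0,y0 projected coordinates of the grid's lower-left corner, metres.
#' @slot nx,ny number of cells along x and y.
#'
#' @seealso [gridSpec()] for the user-facing constructor with Australian
#'   Albers defaults, [albersForward()], [assignCell()].
#' @export
setClass("GridSpec",
  representation(
    lon0 = "numeric", lat0 = "numeric", lat1 = "numeric", lat2 = "numeric",
    falseEasting = "numeric", falseNorthing = "numeric",
    cellSize = "numeric", x0 = "numeric", y0 = "numeric",
    nx = "integer", ny = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number (metres)")
  if (object@nx < 1L || object@ny < 1L)
    msg <- c(msg, "grid extent must be at least 1 x 1 cells")
  if (abs(object@lat1 + object@lat2) < 1e-9)
    msg <- c(msg, "degenerate cone: standard parallels symmetric about the equator give n = 0")
  if (length(msg)) msg else TRUE
})

#' EnvSurface: a gridded environmental variable
#'
#' A single environmental surface (maximum temperature, vapour pressure,
#' vapour pressure deficit, or leaf area index) on a [GridSpec-class] grid.
#' Values are stored as an \code{nx x ny} matrix indexed \code{[ix + 1, iy + 1]};
#' missing cells are \code{NA}.
#'
#' @slot variable one of \code{"tmax"}, \code{"vp"}, \code{"vpd"}, \code{"lai"},
#'   or another label for derived fields.
#' @slot units unit string; fixed per variable ("degC", "kPa", "dimensionless").
#' @slot grid the [GridSpec-class] geometry.
#' @slot values numeric matrix, \code{dim = c(nx, ny)}.
#' @slot period free-text label for the time span the surface summarises.
#'
#' @seealso [envSurface()], [surfaceValues()], [readAsciiGrid()].
#' @export
setClass("EnvSurface",
  representation(
    variable = "character", units = "character", grid = "GridSpec",
    values = "matrix", period = "character"
  )
)

setValidity("EnvSurface", function(object) {
  msg <- character()
  g <- object@grid
  if (!identical(dim(object@values), c(as.integer(g@nx), as.integer(g@ny))))
    msg <- c(msg, sprintf("values must be an nx x ny = %d x %d matrix", g@nx, g@ny))
  v <- object@values
  if (object@variable %in% c("vpd", "lai") && any(v < 0, na.rm = TRUE))
    msg <- c(msg, sprintf("%s must be non-negative everywhere defined",
                          object@variable))
  if (length(msg)) msg else TRUE
})

#' SpatialWeights: neighbour lists and weights for grid cells
#'
#' Sparse spatial weights built from cell centroids: cell pairs whose
#' Euclidean (projected-plane) distance is at or below a threshold are
#' neighbours. Weights are either binary (1 for every neighbour) or row
#' standardised (each non-empty row sums to 1). Self-neighbours are never
#' included; isolated cells have empty rows.
#'
#' @slot n number of cells.
#' @slot neighbors list of integer vectors; \code{neighbors[[i]]} are the
#'   indices of cell i's neighbours (sorted, 1-based).
#' @slot weights list of numeric vectors parallel to \code{neighbors}.
#' @slot style \code{"binary"} or \code{"row_standardised"}.
#' @slot threshold neighbourhood distance, metres (inclusive).
#'
#' @seealso [buildWeights()], [moransI()], [fitSarError()].
#' @export
setClass("SpatialWeights",
  representation(
    n = "integer", neighbors = "list", weights = "list",
    style = "character", threshold = "numeric"
  )
)

setValidity("SpatialWeights", function(object) {
  msg <- character()
  n <- object@n
  if (length(object@neighbors) != n || length(object@weights) != n)
    msg <- c(msg, "neighbors and weights must each have one entry per cell")
  for (i in seq_len(n)) {
    nb <- object@neighbors[[i]]
    if (any(nb == i)) { msg <- c(msg, "self-neighbours are not allowed"); break }
    if (length(nb) != length(object@weights[[i]])) {
      msg <- c(msg, "weights must be parallel to neighbors"); break
    }
    if (any(!vapply(nb, function(j) i %in% object@neighbors[[j]], logical(1)))) {
      msg <- c(msg, "neighbour relation must be symmetric"); break
    }
  }
  if (object@style == "row_standardised") {
    rs <- vapply(object@weights, sum, numeric(1))
    ne <- lengths(object@neighbors) > 0L
    if (any(abs(rs[ne] - 1) > 1e-12))
      msg <- c(msg, "row-standardised rows must sum to 1")
  }
  if (!object@style %in% c("binary", "row_standardised"))
    msg <- c(msg, "style must be 'binary' or 'row_standardised'")
  if (length(msg)) msg else TRUE
})

#' MoranResult: Moran's I with its normality-null moments
#'
#' @slot observed the Moran's I statistic.
#' @slot expected the null expectation, exactly \code{-1/(n-1)}.
#' @slot variance variance under the normality null.
#' @slot z standardised statistic.
#' @slot p two-sided p-value (normal reference, or permutation when requested).
#' @slot n number of observations.
#' @slot method \code{"normality"} or \code{"permutation"}.
#' @export
setClass("MoranResult",
  representation(observed = "numeric", expected = "numeric",
                 variance = "numeric", z = "numeric", p = "numeric",
                 n = "integer", method = "character"))

#' OLSFit: ordinary least squares with a VPD x LAI interaction
#'
#' @slot beta named coefficient vector (intercept, covariates, interaction).
#' @slot se coefficient standard errors.
#' @slot sigma2 maximum-likelihood residual variance (RSS / n).
#' @slot logLik Gaussian log-likelihood at the MLE.
#' @slot r2 coefficient of determination.
#' @slot residuals,fitted per-observation residuals and fitted values.
#' @slot data model frame (response plus covariates) used for the fit.
#' @slot response name of the response column.
#' @slot covariates names of the covariate columns.
#' @slot interaction logical; whether the product term was included.
#' @export
setClass("OLSFit",
  representation(beta = "numeric", se = "numeric", sigma2 = "numeric",
                 logLik = "numeric", r2 = "numeric",
                 residuals = "numeric", fitted = "numeric",
                 data = "data.frame", response = "character",
                 covariates = "character", interaction = "logical"))

#' SARFit: maximum-likelihood simultaneous autoregressive error model
#'
#' The spatial error model \eqn{y = X\beta + u}, \eqn{u = \lambda W u + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2 I)}, estimated by profile maximum
#' likelihood over \eqn{\lambda} with the log-Jacobian
#' \eqn{\log|I - \lambda W|} evaluated from the eigenvalues of W.
#'
#' @slot lambda the spatial-error coefficient at the likelihood maximum.
#' @slot lambdaBounds feasible interval \code{(1/min(eig), 1/max(eig))}.
#' @slot beta,se GLS coefficients at \code{lambda} and their conditional
#'   standard errors.
#' @slot sigma2 ML innovation variance.
#' @slot logLik maximised log-likelihood.
#' @slot logLikNull log-likelihood of the intercept-only non-spatial Gaussian
#'   model (the Nagelkerke reference).
#' @slot pseudoR2 Nagelkerke pseudo-R-squared against that null.
#' @slot residuals trend residuals \eqn{u = y - X\beta}.
#' @slot innovations spatially filtered innovations
#'   \eqn{\hat\varepsilon = (I - \lambda W)(y - X\beta)}.
#' @slot fixedLambda TRUE when lambda was supplied rather than estimated.
#' @slot data,response,covariates,interaction as in [OLSFit-class].
#' @export
setClass("SARFit",
  representation(lambda = "numeric", lambdaBounds = "numeric",
                 beta = "numeric", se = "numeric", sigma2 = "numeric",
                 logLik = "numeric", logLikNull = "numeric",
                 pseudoR2 = "numeric",
                 residuals = "numeric", innovations = "numeric",
                 fixedLambda = "logical",
                 data = "data.frame", response = "character",
                 covariates = "character", interaction = "logical"))

#' RandomInterceptFit: REML linear mixed model with one grouping factor
#'
#' @slot fixef named fixed-effect estimates.
#' @slot varGroup between-group (taxonomic family) variance; the zero
#'   boundary is allowed.
#' @slot varResid residual variance.
#' @slot logReml REML log-likelihood at the optimum.
#' @slot waldF list with the Wald F statistic for the fixed factor:
#'   \code{statistic}, \code{df1}, \code{df2}, \code{p}.
#' @export
setClass("RandomInterceptFit",
  representation(fixef = "numeric", varGroup = "numeric",
                 varResid = "numeric", logReml = "numeric",
                 waldF = "list"))
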