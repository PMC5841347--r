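# Spatial statistics: distance-band weights, Moran's I and correlograms,
# OLS with a VPD x LAI interaction, maximum-likelihood SAR spatial-error
# models with Nagelkerke pseudo-R2, percentile prediction curves.

#' Distance-band spatial weights
#'
#' Neighbours are all cell pairs whose Euclidean centroid distance (projected
#' plane) is at or below `threshold` (inclusive tie-break). Weights are 1
#' (binary) or 1/row-count (row standardised). Isolated cells keep empty
#' rows; their count is reported in a message. If every cell is isolated the
#' weights carry no spatial structure and construction fails.
#'
#' @param centroids data.frame or matrix with columns `x`, `y` in metres.
#' @param threshold neighbourhood distance, metres; default 200 km.
#' @param style `"row_standardised"` (default) or `"binary"`.
#' @return a [SpatialWeights-class].
#' @export
buildWeights <- function(centroids, threshold = 200000,
                         style = c("row_standardised", "binary")) {
  style <- match.arg(style)
  xy <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  n <- nrow(xy)
  stopifnot(n >= 2, all(is.finite(xy)))
  d <- as.matrix(stats::dist(xy))
  adj <- d <= threshold
  diag(adj) <- FALSE
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  if (all(lengths(nbrs) == 0L))
    stop("no spatial structure: all cells are isolated at this threshold")
  nIso <- sum(lengths(nbrs) == 0L)
  if (nIso > 0) message(nIso, " isolated cell(s) (empty weight rows)")
  wts <- lapply(nbrs, function(nb) {
    if (length(nb) == 0L) numeric(0)
    else if (style == "binary") rep(1, length(nb))
    else rep(1 / length(nb), length(nb))
  })
  new("SpatialWeights", n = as.integer(n), neighbors = nbrs, weights = wts,
      style = style, threshold = threshold)
}

#' @rdname accessors
#' @export
setMethod("neighborCounts", "SpatialWeights",
          function(object) lengths(object@neighbors))

#' @rdname accessors
#' @export
setMethod("weightsStyle", "SpatialWeights", function(object) object@style)

#' @rdname accessors
#' @export
setMethod("totalWeight", "SpatialWeights",
          function(object) sum(vapply(object@weights, sum, numeric(1))))

setMethod("show", "SpatialWeights", function(object) {
  k <- neighborCounts(object)
  cat(sprintf("SpatialWeights: %d cells, %s, threshold %.0f m\n",
              object@n, object@style, object@threshold))
  cat(sprintf("  neighbours per cell: min %d / mean %.2f / max %d; %d isolated\n",
              min(k), mean(k), max(k), sum(k == 0L)))
})

#' @describeIn buildWeights dense matrix form of the weights.
#' @param x a [SpatialWeights-class].
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SpatialWeights", function(x, ...) {
  W <- matrix(0, x@n, x@n)
  for (i in seq_len(x@n))
    W[i, x@neighbors[[i]]] <- x@weights[[i]]
  W
})

#' Export weights as a sparse triplet table
#'
#' @param weights a [SpatialWeights-class].
#' @return data.frame with columns `i`, `j`, `w` (1-based indices).
#' @export
weightsTriplets <- function(weights) {
  i <- rep(seq_len(weights@n), lengths(weights@neighbors))
  data.frame(i = i, j = unlist(weights@neighbors),
             w = unlist(weights@weights))
}

# W %*% v via the neighbour lists; v may be a vector or a column matrix.
.lagVector <- function(weights, v) {
  vapply(seq_len(weights@n), function(i) {
    nb <- weights@neighbors[[i]]
    if (length(nb) == 0L) 0 else sum(weights@weights[[i]] * v[nb])
  }, numeric(1))
}

.lagMatrix <- function(weights, M) {
  apply(M, 2, function(col) .lagVector(weights, col))
}

#' Moran's I with normality-null inference
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with z the centred values. Expectation is exactly `-1/(n-1)`; the variance
#' uses the closed-form normality null. A seeded permutation test (999
#' permutations by default) is available as an alternative reference.
#'
#' @param values numeric vector, one per cell, non-constant.
#' @param weights a [SpatialWeights-class] on the same cells.
#' @param permutations 0 for the analytic normality null (default), or a
#'   positive count of random permutations.
#' @param seed RNG seed for the permutation test.
#' @return a [MoranResult-class].
#' @export
moransI <- function(values, weights, permutations = 0, seed = 1) {
  n <- weights@n
  stopifnot(length(values) == n, all(is.finite(values)))
  z <- values - mean(values)
  ssz <- sum(z^2)
  if (ssz == 0) stop("zero variance: Moran's I undefined for constant values")
  s0 <- totalWeight(weights)
  if (s0 == 0) stop("weights sum to zero")
  num <- sum(z * .lagVector(weights, z))
  obs <- (n / s0) * num / ssz
  expected <- -1 / (n - 1)
  if (permutations > 0) {
    perm <- .withSeed(seed, vapply(seq_len(permutations), function(k) {
      zp <- sample(z)
      (n / s0) * sum(zp * .lagVector(weights, zp)) / ssz
    }, numeric(1)))
    p <- (1 + sum(abs(perm - expected) >= abs(obs - expected))) /
      (permutations + 1)
    return(new("MoranResult", observed = obs, expected = expected,
               variance = stats::var(perm), z = NA_real_, p = p,
               n = as.integer(n), method = "permutation"))
  }
  W <- as.matrix(weights)
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - expected^2
  zstat <- (obs - expected) / sqrt(varI)
  new("MoranResult", observed = obs, expected = expected, variance = varI,
      z = zstat, p = 2 * stats::pnorm(-abs(zstat)), n = as.integer(n),
      method = "normality")
}

setMethod("show", "MoranResult", function(object) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, %s), z = %.3f, p = %.4g\n",
              object@observed, object@expected, object@method, object@z,
              object@p))
})

#' Moran correlogram over distance bands
#'
#' Moran's I computed with binary weights restricted to pairs whose centroid
#' distance falls in half-open bands `((k-1)w, kw]` (upper-inclusive, so
#' lattice neighbours at exactly one cell size fall in band 1); the default
#' band width is the analysis cell size (100 km). Bands with no pairs are
#' reported missing.
#'
#' @param values numeric vector, one per cell.
#' @param centroids data.frame with columns `x`, `y` (metres).
#' @param nClasses number of distance bands; default 20.
#' @param classWidth band width, metres; default 100 km.
#' @return data.frame with one row per band: `band`, `d_lo`, `d_hi`,
#'   `n_pairs`, `observed`, `expected`, `variance`, `z`, `p`.
#' @export
moranCorrelogram <- function(values, centroids, nClasses = 20,
                             classWidth = 100000) {
  xy <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  n <- nrow(xy)
  stopifnot(length(values) == n)
  d <- as.matrix(stats::dist(xy))
  out <- lapply(seq_len(nClasses), function(k) {
    lo <- (k - 1) * classWidth; hi <- k * classWidth
    adj <- d > lo & d <= hi
    diag(adj) <- FALSE
    base <- data.frame(band = k, d_lo = lo, d_hi = hi,
                       n_pairs = sum(adj) / 2,
                       observed = NA_real_, expected = NA_real_,
                       variance = NA_real_, z = NA_real_, p = NA_real_)
    if (!any(adj)) return(base)
    nbrs <- apply(adj, 1, which, simplify = FALSE)
    wts <- lapply(nbrs, function(nb) rep(1, length(nb)))
    w <- new("SpatialWeights", n = as.integer(n), neighbors = nbrs,
             weights = wts, style = "binary", threshold = hi)
    m <- moransI(values, w)
    base$observed <- m@observed; base$expected <- m@expected
    base$variance <- m@variance; base$z <- m@z; base$p <- m@p
    base
  })
  do.call(rbind, out)
}

.designMatrix <- function(data, covariates, interaction) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  if (interaction && length(covariates) == 2) {
    X <- cbind(X, data[[covariates[1]]] * data[[covariates[2]]])
    colnames(X)[ncol(X)] <- paste(covariates, collapse = ":")
  }
  X
}

#' OLS regression with a VPD x LAI interaction
#'
#' Ordinary least squares of a cell-level response on two covariates plus
#' their product, through [stats::lm()]. Residuals are exposed for Moran
#' diagnostics; the Gaussian log-likelihood uses the ML variance (RSS/n).
#'
#' @param data data.frame holding the response and covariates (complete
#'   cases only are used; rows dropped are reported).
#' @param response response column name.
#' @param covariates two covariate names; default `c("vpd", "lai")`.
#' @param interaction include the product term; default TRUE.
#' @return an [OLSFit-class].
#' @export
fitOls <- function(data, response, covariates = c("vpd", "lai"),
                   interaction = TRUE) {
  d <- data[, c(response, covariates), drop = FALSE]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message(sum(!cc), " row(s) with missing values dropped")
  d <- d[cc, , drop = FALSE]
  stopifnot(nrow(d) > 4)
  fml <- stats::as.formula(paste(
    response, "~", paste(covariates, collapse = if (interaction) "*" else "+")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)
  new("OLSFit",
      beta = stats::coef(fit), se = sm$coefficients[, "Std. Error"],
      sigma2 = sum(stats::residuals(fit)^2) / nrow(d),
      logLik = as.numeric(stats::logLik(fit)),
      r2 = sm$r.squared,
      residuals = unname(stats::residuals(fit)),
      fitted = unname(stats::fitted(fit)),
      data = d, response = response, covariates = covariates,
      interaction = interaction)
}

setMethod("show", "OLSFit", function(object) {
  cat(sprintf("OLS fit: %s ~ %s%s  (n = %d)\n", object@response,
              paste(object@covariates, collapse = " + "),
              if (object@interaction) " + interaction" else "",
              nrow(object@data)))
  print(round(object@beta, 6))
  cat(sprintf("  R2 = %.4f, logLik = %.3f\n", object@r2, object@logLik))
})

#' @describeIn fitOls coef method.
#' @export
setMethod("coef", "OLSFit", function(object) object@beta)
#' @describeIn fitOls residuals method.
#' @export
setMethod("residuals", "OLSFit", function(object) object@residuals)
#' @describeIn fitOls logLik method.
#' @export
setMethod("logLik", "OLSFit", function(object) object@logLik)

# Real eigenvalues of W. The neighbour relation is symmetric by
# construction; row-standardised W = D^-1 A is similar to the symmetric
# D^-1/2 A D^-1/2, so its spectrum is real. Zero rows contribute zero
# eigenvalues (determinant expansion along the zero row).
.weightsEigen <- function(weights) {
  W <- as.matrix(weights)
  if (weights@style == "binary" || isTRUE(all.equal(W, t(W))))
    return(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  deg <- lengths(weights@neighbors)
  live <- which(deg > 0L)
  A <- (W[live, live, drop = FALSE] > 0) + 0
  if (!isTRUE(all.equal(A, t(A))))
    stop("eigen bounds require a symmetric neighbour relation")
  s <- 1 / sqrt(deg[live])
  S <- A * (s %o% s)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  c(ev, rep(0, weights@n - length(live)))
}

# profile log-likelihood pieces shared by fitSarError
.sarProfile <- function(lambda, y, X, Wy, WX, ev) {
  yt <- y - lambda * Wy
  Xt <- X - lambda * WX
  qrX <- qr(Xt)
  beta <- qr.coef(qrX, yt)
  rss <- sum(qr.resid(qrX, yt)^2)
  n <- length(y)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) + sum(log(1 - lambda * ev))
  list(ll = ll, beta = beta, sigma2 = sigma2, Xt = Xt)
}

#' Maximum-likelihood SAR spatial-error model
#'
#' Fits \eqn{y = X\beta + u}, \eqn{u = \lambda W u + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2 I)} by profile maximum likelihood:
#' for each \eqn{\lambda}, \eqn{\beta} and \eqn{\sigma^2} are closed-form
#' GLS/ML solutions of the spatially filtered regression, and the Jacobian
#' \eqn{\log|I-\lambda W| = \sum_i \log(1-\lambda\omega_i)} comes from the
#' eigenvalues \eqn{\omega_i} of W (computed once). \eqn{\lambda} is found by
#' bounded golden-section/parabolic search strictly inside
#' \eqn{(1/\omega_{min}, 1/\omega_{max})}. OLS is the \eqn{\lambda = 0}
#' submodel; the reported Nagelkerke pseudo-R2 is taken against the
#' intercept-only non-spatial Gaussian null.
#'
#' @param data data.frame with response and covariates (complete cases used).
#' @param response,covariates,interaction as in [fitOls()].
#' @param weights a [SpatialWeights-class] matching the rows of `data`.
#' @param lambda optional fixed value: skips the search and evaluates the
#'   profile at this \eqn{\lambda} (0 reproduces OLS exactly).
#' @param tol search tolerance on \eqn{\lambda}.
#' @return a [SARFit-class].
#' @export
fitSarError <- function(data, response, covariates = c("vpd", "lai"),
                        weights, interaction = TRUE, lambda = NULL,
                        tol = 1e-8) {
  d <- data[, c(response, covariates), drop = FALSE]
  cc <- stats::complete.cases(d)
  if (any(!cc))
    stop("missing values in the model frame; subset data and weights together")
  stopifnot(nrow(d) >= 10, nrow(d) == weights@n)
  y <- d[[response]]
  X <- .designMatrix(d, covariates, interaction)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design; collinear columns in: ",
         paste(colnames(X), collapse = ", "))
  ev <- .weightsEigen(weights)
  lb <- 1 / min(ev); ub <- 1 / max(ev)
  Wy <- .lagVector(weights, y)
  WX <- .lagMatrix(weights, X)
  prof <- function(l) .sarProfile(l, y, X, Wy, WX, ev)$ll
  if (is.null(lambda)) {
    eps <- 1e-6 * (ub - lb)
    opt <- stats::optimize(prof, interval = c(lb + eps, ub - eps),
                           maximum = TRUE, tol = tol)
    lamHat <- opt$maximum
    if (min(lamHat - lb, ub - lamHat) < 1e-4 * (ub - lb))
      warning("boundary solution: lambda at the edge of its feasible interval")
    fixed <- FALSE
  } else {
    stopifnot(lambda > lb, lambda < ub)
    lamHat <- lambda
    fixed <- TRUE
  }
  at <- .sarProfile(lamHat, y, X, Wy, WX, ev)
  n <- length(y)
  u <- as.vector(y - X %*% at$beta)
  innov <- u - lamHat * .lagVector(weights, u)
  # conditional-on-lambda GLS covariance for the coefficients
  vc <- at$sigma2 * solve(crossprod(at$Xt))
  s0 <- mean((y - mean(y))^2)
  ll0 <- -n / 2 * (log(2 * pi * s0) + 1)
  new("SARFit",
      lambda = lamHat, lambdaBounds = c(lb, ub),
      beta = at$beta, se = sqrt(diag(vc)), sigma2 = at$sigma2,
      logLik = at$ll, logLikNull = ll0,
      pseudoR2 = .pseudoR2Safe(at$ll, ll0, n),
      residuals = u, innovations = innov, fixedLambda = fixed,
      data = d, response = response, covariates = covariates,
      interaction = interaction)
}

setMethod("show", "SARFit", function(object) {
  cat(sprintf("SAR error fit: %s ~ %s%s  (n = %d)\n", object@response,
              paste(object@covariates, collapse = " + "),
              if (object@interaction) " + interaction" else "",
              nrow(object@data)))
  cat(sprintf("  lambda = %.4f in (%.3f, %.3f)%s\n", object@lambda,
              object@lambdaBounds[1], object@lambdaBounds[2],
              if (object@fixedLambda) " [fixed]" else ""))
  print(round(object@beta, 6))
  cat(sprintf("  logLik = %.3f, Nagelkerke pseudo-R2 = %.4f\n",
              object@logLik, object@pseudoR2))
})

#' @describeIn fitSarError coef method.
#' @export
setMethod("coef", "SARFit", function(object) object@beta)
#' @describeIn fitSarError residuals method.
#' @export
setMethod("residuals", "SARFit", function(object) object@residuals)
#' @describeIn fitSarError logLik method.
#' @export
setMethod("logLik", "SARFit", function(object) object@logLik)

#' @rdname accessors
#' @export
setMethod("lambdaHat", "SARFit", function(object) object@lambda)

#' @rdname accessors
#' @export
setMethod("pseudoR2", "SARFit", function(object) object@pseudoR2)

#' @rdname accessors
#' @export
setMethod("pseudoR2", "OLSFit", function(object) {
  n <- nrow(object@data)
  y <- object@data[[object@response]]
  s0 <- mean((y - mean(y))^2)
  ll0 <- -n / 2 * (log(2 * pi * s0) + 1)
  .pseudoR2Safe(object@logLik, ll0, n)
})

# Rescaled Nagelkerke when its divisor is defined; otherwise the unrescaled
# likelihood-ratio R2 (the rescaling is undefined for continuous-density
# nulls with positive log-likelihood, e.g. small-variance Gaussian
# responses; the unrescaled form equals classical R2 for Gaussian OLS).
.pseudoR2Safe <- function(logLikModel, logLikNull, n) {
  denom <- 1 - exp((2 / n) * logLikNull)
  r2cs <- 1 - exp(-(2 / n) * (logLikModel - logLikNull))
  if (denom > 0) nagelkerkeR2(logLikModel, logLikNull, n)
  else min(max(r2cs, 0), 1 - 1e-15)
}

#' @rdname accessors
#' @export
setMethod("innovations", "SARFit", function(object) object@innovations)

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell \eqn{R^2_{CS} = 1 - \exp(-\tfrac{2}{n}(\ell_M - \ell_0))}
#' rescaled by its maximum attainable value
#' \eqn{1 - \exp(\tfrac{2}{n}\ell_0)}; clipped to [0, 1). The null here is
#' the intercept-only non-spatial Gaussian model.
#'
#' @param logLikModel model log-likelihood (>= null's, up to 1e-8).
#' @param logLikNull null log-likelihood.
#' @param n number of observations.
#' @return the pseudo-R2 in [0, 1).
#' @export
nagelkerkeR2 <- function(logLikModel, logLikNull, n) {
  stopifnot(n >= 1, logLikModel >= logLikNull - 1e-8)
  r2cs <- 1 - exp(-(2 / n) * (logLikModel - logLikNull))
  denom <- 1 - exp((2 / n) * logLikNull)
  if (denom <= 0)
    stop("pathological null likelihood: maximum Cox-Snell R2 is not positive")
  min(max(r2cs / denom, 0), 1 - 1e-15)
}

#' Predicted response curves at LAI percentiles
#'
#' Trend-component predictions \eqn{X\beta} over a VPD grid at three LAI
#' levels (5th percentile, mean, 95th percentile of the training data by
#' default); the spatial error term is excluded. Used to draw the
#' interaction structure of a fitted assemblage model.
#'
#' @param fit an [OLSFit-class] or [SARFit-class] with the interaction term.
#' @param vpdRange length-2 numeric; defaults to the training VPD range.
#'   Values outside the training support trigger a warning but are computed.
#' @param laiProbs probabilities for the low/high LAI levels.
#' @param nPoints grid resolution along VPD.
#' @return data.frame with columns `curve` ("lai_p5", "lai_mean", "lai_p95"),
#'   `lai`, `vpd`, `predicted`.
#' @export
predictPercentileCurves <- function(fit, vpdRange = NULL,
                                    laiProbs = c(0.05, 0.95), nPoints = 50) {
  stopifnot(is(fit, "OLSFit") || is(fit, "SARFit"))
  if (!fit@interaction) warning("fit has no interaction term; curves will be parallel")
  cv <- fit@covariates
  vpdName <- cv[1]; laiName <- cv[2]
  tr <- fit@data
  if (is.null(vpdRange)) vpdRange <- range(tr[[vpdName]])
  else if (vpdRange[1] < min(tr[[vpdName]]) || vpdRange[2] > max(tr[[vpdName]]))
    warning("vpd range extends outside the training support")
  laiLevels <- c(lai_p5 = unname(stats::quantile(tr[[laiName]], laiProbs[1])),
                 lai_mean = mean(tr[[laiName]]),
                 lai_p95 = unname(stats::quantile(tr[[laiName]], laiProbs[2])))
  vgrid <- seq(vpdRange[1], vpdRange[2], length.out = nPoints)
  out <- lapply(names(laiLevels), function(nm) {
    nd <- data.frame(v = vgrid, l = laiLevels[[nm]])
    names(nd) <- c(vpdName, laiName)
    X <- .designMatrix(nd, cv, fit@interaction)
    data.frame(curve = nm, lai = laiLevels[[nm]], vpd = vgrid,
               predicted = as.vector(X %*% fit@beta[colnames(X)]))
  })
  do.call(rbind, out)
}

#' Coefficient table for a fitted model
#'
#' Tidy coefficients with Wald z statistics and two-sided normal p-values,
#' ready for CSV export.
#'
#' @param fit an [OLSFit-class] or [SARFit-class].
#' @return data.frame with columns `term`, `estimate`, `se`, `statistic`, `p`.
#' @export
coefTable <- function(fit) {
  est <- fit@beta; se <- fit@se
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}
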