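# Spatial weights, Moran's I, correlograms, OLS, pseudo-R2, curves.

test_that("distance-band weights honour the lattice neighbour geometry", {
  two <- buildWeights(data.frame(x = c(0, 1e5), y = c(0, 0)),
                      threshold = 2e5, style = "row_standardised")
  expect_identical(unname(unlist(two@weights)), c(1, 1))
  latt <- buildWeights(latticeCentroids(20L, 20L), threshold = 2e5)
  k <- neighborCounts(latt)
  # interior cells: 4 rook + 4 diagonal + 4 orthogonal-distance-2
  expect_identical(max(k), 12L)
  interior <- with(expand.grid(ix = 0:19, iy = 0:19),
                   ix >= 2 & ix <= 17 & iy >= 2 & iy <= 17)
  expect_true(all(k[interior] == 12L))
  expect_error(buildWeights(latticeCentroids(3L, 3L), threshold = 5e4),
               "no spatial structure")
})

test_that("row-standardised rows sum to one and the relation is symmetric", {
  w <- buildWeights(latticeCentroids(6L, 5L), threshold = 1.5e5)
  rs <- vapply(w@weights, sum, numeric(1))
  expect_true(all(abs(rs[lengths(w@neighbors) > 0] - 1) < 1e-12))
  W <- as.matrix(w)
  expect_true(all((W > 0) == t(W > 0)))
  expect_true(all(diag(W) == 0))
  trip <- weightsTriplets(w)
  expect_identical(nrow(trip), sum(lengths(w@neighbors)))
  expect_equal(sum(trip$w), totalWeight(w))
})

test_that("Moran's I matches the antithetic pair and the analytic null mean", {
  w2 <- buildWeights(data.frame(x = c(0, 1e5), y = c(0, 0)), threshold = 2e5)
  m <- moransI(c(1, -1), w2)
  expect_equal(m@observed, -1, tolerance = 1e-12)
  w <- buildWeights(latticeCentroids(7L, 7L), threshold = 1.5e5)
  set.seed(40)
  m2 <- moransI(rnorm(49), w)
  expect_identical(m2@expected, -1 / 48)
  expect_gt(m2@variance, 0)
  expect_error(moransI(rep(2, 49), w), "zero variance")
})

test_that("row-standardised Moran's I agrees with ape and the variance with
           a direct moment assembly", {
  skip_if_not_installed("ape")
  cen <- latticeCentroids(8L, 8L)
  set.seed(41)
  vals <- rnorm(64)
  # ape::Moran.I row-standardises internally, so only that coding is
  # directly comparable (its variance is the randomisation one; the
  # observed statistic and null mean are shared)
  w <- buildWeights(cen, threshold = 1.5e5, style = "row_standardised")
  mine <- moransI(vals, w)
  ref <- ape::Moran.I(vals, as.matrix(w), scaled = FALSE)
  expect_equal(mine@observed, ref$observed, tolerance = 1e-12)
  expect_equal(mine@expected, ref$expected, tolerance = 1e-12)
  # normality-null variance re-assembled from the dense matrix moments
  for (style in c("binary", "row_standardised")) {
    ws <- buildWeights(cen, threshold = 1.5e5, style = style)
    W <- as.matrix(ws)
    n <- 64; s0 <- sum(W)
    s1 <- sum((W + t(W))^2) / 2
    s2 <- sum((rowSums(W) + colSums(W))^2)
    vRef <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) -
      (1 / (n - 1))^2
    expect_equal(moransI(vals, ws)@variance, vRef, tolerance = 1e-12)
  }
})

test_that("permutation inference is seeded and reproducible", {
  w <- buildWeights(latticeCentroids(6L, 6L), threshold = 1.5e5)
  set.seed(42)
  vals <- rnorm(36)
  p1 <- moransI(vals, w, permutations = 199, seed = 5)
  p2 <- moransI(vals, w, permutations = 199, seed = 5)
  expect_identical(p1@p, p2@p)
  expect_identical(p1@method, "permutation")
})

test_that("a single all-pairs band collapses the correlogram to global Moran", {
  cen <- latticeCentroids(5L, 5L)
  set.seed(43)
  vals <- rnorm(25)
  cg <- moranCorrelogram(vals, cen, nClasses = 1, classWidth = 1e7)
  wAll <- buildWeights(cen, threshold = 1e7, style = "binary")
  expect_equal(cg$observed[1], moransI(vals, wAll)@observed,
               tolerance = 1e-12)
})

test_that("white noise stays inside correlogram bounds, smooth fields decay", {
  cen <- latticeCentroids()
  ok <- vapply(1:200, function(s) {
    set.seed(5000 + s)
    cg <- moranCorrelogram(rnorm(100), cen)
    # the normal reference needs a workable pair count per band
    cg <- cg[cg$n_pairs >= 30, ]
    all(abs(cg$z) < 3, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # strongly smoothed field: positive near-range I, declining with distance
  env <- generateEnvironment(syntheticConfig(seed = 44, grid = latticeGrid(),
                                             gpRange = 3e5))
  f <- as.vector(surfaceValues(env$vpd))
  cg <- moranCorrelogram(f, cen)
  expect_gt(cg$observed[1], 0.3)
  expect_gt(cg$observed[1], cg$observed[4])
  # empty band is reported missing
  cgE <- moranCorrelogram(f, cen, nClasses = 30)
  expect_true(is.na(cgE$observed[30]))
  expect_identical(cgE$n_pairs[30], 0)
})

test_that("OLS reproduces exact fits, zero slopes, and the normal equations", {
  set.seed(45)
  n <- 60
  d <- data.frame(vpd = rnorm(n), lai = rnorm(n))
  d$y <- 2 + 0.5 * d$vpd - 0.3 * d$lai + 0.1 * d$vpd * d$lai
  exact <- suppressWarnings(fitOls(d, "y"))  # lm warns on a perfect fit
  expect_lt(max(abs(residuals(exact))), 1e-10)
  expect_equal(exact@r2, 1, tolerance = 1e-10)
  d$y2 <- rnorm(n)
  d$y2 <- d$y2 - fitted(lm(y2 ~ vpd * lai, data = d)) + mean(d$y2)
  orth <- fitOls(transform(d, y = y2), "y")
  expect_lt(max(abs(coef(orth)[-1])), 1e-10)
  d$y3 <- d$y + rnorm(n)
  f <- fitOls(transform(d, y = y3), "y")
  X <- cbind(1, d$vpd, d$lai, d$vpd * d$lai)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% d$y3
  expect_equal(unname(coef(f)), as.vector(oracle), tolerance = 1e-9)
  expect_lt(max(abs(t(X) %*% residuals(f))), 1e-8)
  d$dup <- d$vpd
  expect_error(fitOls(transform(d, y = y3), "y", c("vpd", "dup")), "collinear")
})

test_that("Nagelkerke rescaling behaves and maps from classical R2 for OLS", {
  expect_equal(nagelkerkeR2(-50, -50, 25), 0)
  expect_gt(nagelkerkeR2(-40, -50, 25), nagelkerkeR2(-45, -50, 25))
  expect_error(nagelkerkeR2(5, 2, 10), "pathological")
  # Gaussian OLS: Cox-Snell equals classical R2, then rescale algebraically
  set.seed(46)
  n <- 80
  d <- data.frame(vpd = rnorm(n, 0, 3), lai = rnorm(n, 0, 3))
  d$y <- 5 + d$vpd - d$lai + rnorm(n, 0, 4)   # sd large so logLik0 < 0
  f <- fitOls(d, "y")
  s0 <- mean((d$y - mean(d$y))^2)
  ll0 <- -n / 2 * (log(2 * pi * s0) + 1)
  expect_lt(ll0, 0)
  r2cs <- 1 - exp(-(2 / n) * (f@logLik - ll0))
  expect_equal(r2cs, f@r2, tolerance = 1e-9)
  expect_equal(nagelkerkeR2(f@logLik, ll0, n),
               f@r2 / (1 - exp(2 * ll0 / n)), tolerance = 1e-9)
  expect_equal(pseudoR2(f), nagelkerkeR2(f@logLik, ll0, n), tolerance = 1e-12)
})

test_that("prediction curves are exact dot products and parallel without interaction", {
  set.seed(47)
  n <- 50
  d <- data.frame(vpd = runif(n, 0.2, 4), lai = runif(n, 0.1, 5))
  d$y <- 1 + 0.3 * d$vpd - 0.2 * d$lai + 0.05 * d$vpd * d$lai + rnorm(n, 0, .1)
  f <- fitOls(d, "y")
  cv <- predictPercentileCurves(f, nPoints = 3)
  expect_identical(nrow(cv), 9L)
  b <- coef(f)
  for (i in seq_len(nrow(cv))) {
    manual <- b[1] + b["vpd"] * cv$vpd[i] + b["lai"] * cv$lai[i] +
      b["vpd:lai"] * cv$vpd[i] * cv$lai[i]
    expect_equal(cv$predicted[i], unname(manual), tolerance = 1e-12)
  }
  fNo <- fitOls(d, "y", interaction = FALSE)
  expect_warning(cvNo <- predictPercentileCurves(fNo, nPoints = 4),
                 "no interaction")
  gaps <- with(cvNo, tapply(predicted, curve, function(p) diff(p)))
  expect_equal(gaps[[1]], gaps[[2]], tolerance = 1e-12)
  expect_equal(gaps[[2]], gaps[[3]], tolerance = 1e-12)
  expect_warning(predictPercentileCurves(f, vpdRange = c(-5, 10)),
                 "outside the training support")
})

test_that("coefficient tables carry estimates, errors and Wald p-values", {
  cells <- studyCells()
  kept <- cells[cells$retained, ]
  f <- fitOls(transform(kept, y = prop_dome), "y")
  tab <- coefTable(f)
  expect_identical(tab$term, names(coef(f)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_equal(tab$statistic, tab$estimate / tab$se, tolerance = 1e-12)
})
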