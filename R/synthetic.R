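# Synthetic-world generator: species traits, spatially autocorrelated
# environmental surfaces, niche-driven occurrences, and SAR responses with
# known parameters, so every pipeline stage is testable without downloads.

#' Synthetic-world configuration
#'
#' Defaults emulate the study system: ~300 Australian passerine-like species
#' with elongation ~ Normal(1.37, 0.07) truncated to [1.05, 1.70] and a
#' 62% cup / 33% dome / 5% cavity nest-type mix; a 30 x 30 grid of 100 km
#' equal-area cells; spatially autocorrelated VPD and LAI surfaces mapped to
#' [0.2, 4.5] kPa and [0.05, 5.5] with latent correlation -0.6; and a niche
#' model that associates dome nesting and low elongation with high-VPD cells.
#' A single root seed derives fixed per-stage sub-seeds (+1 species, +2
#' environment, +3 occurrences, +4 responses) so stages regenerate
#' independently.
#'
#' @param seed root seed (integer).
#' @param nSpecies number of species.
#' @param nestTypeProbs named probabilities for cup/dome/cavity; must sum to 1.
#' @param elongMean,elongSd,elongRange truncated-normal elongation parameters.
#' @param grid a [GridSpec-class]; default 30 x 30 cells of 100 km.
#' @param gpRange correlation length of the Gaussian random fields, metres.
#' @param vpdRange,laiRange affine target ranges for the two surfaces.
#' @param envCorr latent correlation between the VPD and LAI fields.
#' @param nicheStrength in [0, 1]: 0 decouples occupancy from traits; high
#'   values pull dome-nesting and round-egged species toward high-VPD cells.
#' @param nicheWidth Gaussian niche width on the VPD axis, kPa.
#' @param pMax occupancy probability at the niche optimum.
#' @param eventsPerCell sampling events available in each cell (for
#'   completeness estimation).
#' @param maxRecordsPerCell at most this many point records per occupied
#'   (species, cell) pair.
#' @param responseBeta,responseLambda,responseSigma known coefficients for
#'   [generateSarResponse()] parameter-recovery runs.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L, nSpecies = 300L,
                            nestTypeProbs = c(cup = 0.62, dome = 0.33,
                                              cavity = 0.05),
                            elongMean = 1.37, elongSd = 0.07,
                            elongRange = c(1.05, 1.70),
                            grid = gridSpec(),
                            gpRange = 500000,
                            vpdRange = c(0.2, 4.5), laiRange = c(0.05, 5.5),
                            envCorr = -0.6,
                            nicheStrength = 0.8, nicheWidth = 0.9,
                            pMax = 0.85, eventsPerCell = 20L,
                            maxRecordsPerCell = 3L,
                            responseBeta = c(1, 0.5, -0.3, 0.1),
                            responseLambda = 0.7, responseSigma = 1) {
  stopifnot(abs(sum(nestTypeProbs) - 1) < 1e-12, elongSd > 0,
            nicheStrength >= 0, nicheStrength <= 1,
            seed < 2^31 - 5)
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              nestTypeProbs = nestTypeProbs, elongMean = elongMean,
              elongSd = elongSd, elongRange = elongRange, grid = grid,
              gpRange = gpRange, vpdRange = vpdRange, laiRange = laiRange,
              envCorr = envCorr, nicheStrength = nicheStrength,
              nicheWidth = nicheWidth, pMax = pMax,
              eventsPerCell = as.integer(eventsPerCell),
              maxRecordsPerCell = as.integer(maxRecordsPerCell),
              responseBeta = responseBeta,
              responseLambda = responseLambda,
              responseSigma = responseSigma)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# truncated-normal sampling by rejection; the default truncation is mild
# (about 4.5 sd each side) so rejection is cheap.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic species trait table
#'
#' Nest types are multinomial draws; elongation is truncated normal; egg
#' breadth is uniform on 14-18 mm and length back-solved so that
#' length/breadth reproduces the drawn elongation exactly. Families are
#' assigned in blocks of ~10 species to support the random-intercept model.
#'
#' @param cfg a [syntheticConfig()] list.
#' @return trait data.frame (`species_id`, `common_name`, `family`,
#'   `nest_type`, `egg_length_mm`, `egg_breadth_mm`, `elongation`).
#' @export
generateSpecies <- function(cfg) {
  .withSeed(cfg$seed + 1L, {
    n <- cfg$nSpecies
    nest <- sample(names(cfg$nestTypeProbs), n, replace = TRUE,
                   prob = cfg$nestTypeProbs)
    elong <- .rtruncnorm(n, cfg$elongMean, cfg$elongSd,
                         cfg$elongRange[1], cfg$elongRange[2])
    breadth <- stats::runif(n, 14, 18)
    data.frame(
      species_id = sprintf("sp%04d", seq_len(n)),
      common_name = sprintf("Synthetic species %d", seq_len(n)),
      family = sprintf("fam%02d", ((seq_len(n) - 1L) %/% 10L) + 1L),
      nest_type = nest,
      egg_length_mm = breadth * elong,
      egg_breadth_mm = breadth,
      elongation = elong)
  })
}

# Gaussian random field on the grid: kernel-smoothed white noise with a
# Gaussian kernel of length-scale `rangeM`, standardised to mean 0 / sd 1.
.grfField <- function(grid, rangeM, noise) {
  cen <- cellCentroids(grid)
  if (rangeM <= 0) return(as.vector(scale(noise)))
  d2 <- as.matrix(stats::dist(cen[, c("x", "y")]))^2
  K <- exp(-d2 / (2 * rangeM^2))
  f <- K %*% noise
  as.vector(scale(f))
}

#' Generate correlated VPD and LAI surfaces
#'
#' Two seeded Gaussian random fields with correlation length `gpRange`; the
#' LAI latent field is built as a linear blend of the VPD latent and an
#' independent field so their correlation is `envCorr` (negative by default:
#' dry places have sparse canopies). Each field is affinely mapped to its
#' configured range, which preserves the correlation.
#'
#' @param cfg a [syntheticConfig()] list.
#' @return list with elements `vpd` and `lai`, both [EnvSurface-class].
#' @export
generateEnvironment <- function(cfg) {
  g <- cfg$grid
  n <- length(g)
  .withSeed(cfg$seed + 2L, {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    f1 <- .grfField(g, cfg$gpRange, z1)
    f2 <- .grfField(g, cfg$gpRange, z2)
    rho <- cfg$envCorr
    fLai <- rho * f1 + sqrt(1 - rho^2) * f2
    toRange <- function(f, r)
      r[1] + (f - min(f)) / (max(f) - min(f)) * (r[2] - r[1])
    vpdVals <- matrix(toRange(f1, cfg$vpdRange), g@nx, g@ny)
    laiVals <- matrix(toRange(fLai, cfg$laiRange), g@nx, g@ny)
    list(vpd = envSurface("vpd", vpdVals, g, period = "synthetic mean"),
         lai = envSurface("lai", laiVals, g, period = "synthetic mean"))
  })
}

#' Generate occurrence records from trait-linked niches
#'
#' Each species gets a niche optimum on the VPD axis. With `nicheStrength`
#' 0 the optimum is uniform over the observed VPD range, independent of
#' traits; as it grows, dome-nesting species and species with rounder eggs
#' (lower elongation) have optima pulled toward the high-VPD end. Cell
#' occupancy is Bernoulli with probability
#' `pMax * exp(-(vpd - optimum)^2 / (2 nicheWidth^2))`; each occupied cell
#' emits 1..`maxRecordsPerCell` point records at uniform positions inside
#' the cell (inverse-projected to lon/lat) tagged with sampling-event ids
#' drawn from the cell's event pool. Species occupying no cell are
#' re-sampled up to 10 times, then reported.
#'
#' @param species trait table from [generateSpecies()].
#' @param env surface list from [generateEnvironment()].
#' @param cfg a [syntheticConfig()] list.
#' @return data.frame with columns `species_id`, `lon`, `lat`, `event_id`.
#' @export
generateOccurrences <- function(species, env, cfg) {
  g <- cfg$grid
  cen <- cellCentroids(g)
  vpdCell <- surfaceAt(env$vpd, cen$ix, cen$iy)
  vr <- range(vpdCell)
  .withSeed(cfg$seed + 3L, {
    n <- nrow(species)
    zE <- as.vector(scale(species$elongation))
    pull <- cfg$nicheStrength *
      (0.5 * (species$nest_type == "dome") + 0.5 * stats::pnorm(-zE))
    base <- stats::runif(n, vr[1], vr[2])
    optimum <- (1 - pull) * base + pull * vr[2]
    recs <- vector("list", n)
    nFailed <- 0L
    for (i in seq_len(n)) {
      occ <- logical(length(vpdCell))
      for (try in 1:10) {
        p <- cfg$pMax * exp(-(vpdCell - optimum[i])^2 / (2 * cfg$nicheWidth^2))
        occ <- stats::runif(length(p)) < p
        if (any(occ)) break
      }
      if (!any(occ)) { nFailed <- nFailed + 1L; next }
      cells <- which(occ)
      nRec <- sample.int(cfg$maxRecordsPerCell, length(cells), replace = TRUE)
      idx <- rep(cells, nRec)
      px <- cen$x[idx] + stats::runif(length(idx), -0.5, 0.5) * g@cellSize
      py <- cen$y[idx] + stats::runif(length(idx), -0.5, 0.5) * g@cellSize
      ll <- albersInverse(px, py, g)
      ev <- unlist(lapply(seq_along(cells), function(k) {
        sample.int(cfg$eventsPerCell, nRec[k], replace = FALSE)
      }))
      recs[[i]] <- data.frame(
        species_id = species$species_id[i], lon = ll$lon, lat = ll$lat,
        event_id = sprintf("c%d_%d_e%02d", cen$ix[idx], cen$iy[idx], ev))
    }
    if (nFailed > 0)
      message(nFailed, " species occupied no cell after 10 attempts")
    do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  })
}

#' Simulate a SAR-error response with known parameters
#'
#' \eqn{y = X\beta + (I - \lambda W)^{-1}\varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2 I)}, computed with a linear solve
#' (never an explicit inverse). `lambda` must lie strictly inside the
#' stability bounds given by the eigenvalues of W.
#'
#' @param X design matrix (n x p), including the intercept column.
#' @param weights a [SpatialWeights-class] with n cells.
#' @param beta length-p coefficient vector.
#' @param lambda spatial-error coefficient.
#' @param sigma innovation standard deviation (>= 0).
#' @param seed RNG seed.
#' @return numeric response vector of length n.
#' @export
generateSarResponse <- function(X, weights, beta, lambda, sigma, seed = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == weights@n, length(beta) == ncol(X), sigma >= 0)
  ev <- .weightsEigen(weights)
  if (lambda <= 1 / min(ev) || lambda >= 1 / max(ev))
    stop("lambda outside the stability bounds of these weights")
  eps <- .withSeed(seed, stats::rnorm(weights@n, 0, sigma))
  A <- diag(weights@n) - lambda * as.matrix(weights)
  u <- solve(A, eps)
  as.vector(X %*% beta + u)
}

#' Simulate a complete synthetic world
#'
#' Runs the three generator stages and returns everything a pipeline run
#' needs. `nx`, `ny` and other config fields come from `cfg`.
#'
#' @param cfg a [syntheticConfig()] list.
#' @return list with `config`, `species`, `env` (vpd + lai surfaces),
#'   `occurrences`.
#' @export
simulateWorld <- function(cfg = syntheticConfig()) {
  species <- generateSpecies(cfg)
  env <- generateEnvironment(cfg)
  occurrences <- generateOccurrences(species, env, cfg)
  list(config = cfg, species = species, env = env, occurrences = occurrences)
}

#' Materialise a small fixture world on disk
#'
#' Writes the exact file dialects the ingestion functions read: a trait CSV,
#' an occurrence CSV (point dialect), and `.asc` rasters of the two
#' environmental surfaces. The default is a compact 10 x 10-cell world with
#' 60 species used by the unit tests.
#'
#' @param dir output directory (created if needed).
#' @param cfg configuration; defaults to the compact fixture world.
#' @return invisibly, the list of file paths written.
#' @export
makeFixtureWorld <- function(dir,
                             cfg = syntheticConfig(
                               seed = 42L, nSpecies = 60L,
                               grid = gridSpec(nx = 10L, ny = 10L,
                                               x0 = -500000, y0 = -3900000),
                               gpRange = 300000)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- simulateWorld(cfg)
  paths <- list(
    traits = file.path(dir, "traits.csv"),
    occurrences = file.path(dir, "occurrences.csv"),
    vpd = file.path(dir, "vpd.asc"),
    lai = file.path(dir, "lai.asc"))
  utils::write.csv(w$species, paths$traits, row.names = FALSE)
  utils::write.csv(w$occurrences, paths$occurrences, row.names = FALSE)
  writeAsciiGrid(w$env$vpd, paths$vpd)
  writeAsciiGrid(w$env$lai, paths$lai)
  invisible(paths)
}
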