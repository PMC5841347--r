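# Assemblage construction, Chao2 completeness, retention filters,
# quantile thresholds.

test_that("Chao2 completeness reproduces the worked incidence example", {
  # s_obs = 10, m = 20, q1 = 4, q2 = 2
  inc <- c(1, 1, 1, 1, 2, 2, 5, 7, 9, 12)
  r <- completenessIndex(inc, nEvents = 20)
  expect_identical(c(r$q1, r$q2, r$s_obs), c(4L, 2L, 10L))
  expect_equal(r$s_est, 10 + (19 / 20) * (4 * 3) / (2 * 3), tolerance = 1e-12)
  expect_equal(r$s_est, 11.9)
  expect_equal(r$index, 10 / 11.9, tolerance = 1e-12)
})

test_that("Chao2 edge behaviour: no uniques, few events, full detection", {
  allSeen <- completenessIndex(c(3, 4, 2), nEvents = 6)
  expect_equal(allSeen$index, 1)
  expect_equal(allSeen$s_est, allSeen$s_obs)
  few <- completenessIndex(c(1, 1), nEvents = 1)
  expect_true(is.na(few$index))
  # doubling everyone's incidence empties q1 and pushes the index to 1
  before <- completenessIndex(c(1, 1, 2, 4), nEvents = 10)
  after <- completenessIndex(c(2, 2, 4, 8), nEvents = 10)
  expect_gt(after$index, before$index)
  expect_equal(after$index, 1)
})

test_that("Chao2 equals an independent formula evaluation on random tables", {
  set.seed(30)
  for (k in 1:1000) {
    sObs <- sample(2:60, 1)
    inc <- 1L + rpois(sObs, sample(0:3, 1))
    m <- max(inc) + rpois(1, 5) + 1L
    r <- completenessIndex(inc, nEvents = m)
    q1 <- sum(inc == 1); q2 <- sum(inc == 2)
    sEst <- sObs + ((m - 1) / m) * q1 * (q1 - 1) / (2 * (q2 + 1))
    expect_identical(r$s_est, sEst)
    expect_identical(r$index, sObs / sEst)
  }
})

test_that("assemblages aggregate traits per cell with cavity excluded from means", {
  traits <- data.frame(
    species_id = c("a", "b", "c", "d", "e"),
    nest_type = c("cup", "cup", "dome", "cavity", "dome"),
    elongation = c(1.30, 1.40, 1.50, 1.20, 1.60))
  occ <- data.frame(species_id = c("a", "b", "c", "d"),
                    cell_ix = 0L, cell_iy = 0L)
  cells <- buildAssemblages(occ, traits, latticeGrid())
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$mean_elong_cup, 1.35)
  expect_equal(cells$mean_elong_dome, 1.50)
  expect_equal(cells$prop_dome, 1 / 4)
  alt <- buildAssemblages(occ, traits, latticeGrid(),
                          propDomeDenominator = "cup_dome")
  expect_equal(alt$prop_dome, 1 / 3)
})

test_that("assemblage construction is idempotent under duplication and order", {
  w <- fixtureWorld()
  occ <- w$occurrences
  base <- suppressMessages(buildAssemblages(occ, w$species, w$config$grid))
  dup <- suppressMessages(
    buildAssemblages(rbind(occ, occ), w$species, w$config$grid))
  shuf <- suppressMessages(
    buildAssemblages(occ[sample(nrow(occ)), ], w$species, w$config$grid))
  cols <- c("cell_ix", "cell_iy", "n_species", "n_cup", "n_dome",
            "n_cavity", "mean_elong_cup", "mean_elong_dome", "prop_dome")
  expect_equal(base[cols], dup[cols])
  expect_equal(base[cols], shuf[cols])
  # count identity and bounded proportions
  expect_identical(base$n_cup + base$n_dome + base$n_cavity, base$n_trait)
  expect_true(all(base$prop_dome >= 0 & base$prop_dome <= 1, na.rm = TRUE))
})

test_that("per-cell means stay inside member elongation ranges", {
  w <- fixtureWorld()
  cells <- fixtureCells()
  lo <- min(w$species$elongation); hi <- max(w$species$elongation)
  expect_true(all(cells$mean_elong_cup >= lo & cells$mean_elong_cup <= hi,
                  na.rm = TRUE))
  expect_true(all(cells$mean_elong_dome >= lo & cells$mean_elong_dome <= hi,
                  na.rm = TRUE))
})

test_that("point records project into the expected cells", {
  g <- latticeGrid()
  cen <- cellCentroids(g, ix = 3L, iy = 4L)
  ll <- albersInverse(cen$x, cen$y, g)
  traits <- data.frame(species_id = "a", nest_type = "dome", elongation = 1.5)
  occ <- data.frame(species_id = "a", lon = ll$lon, lat = ll$lat)
  cells <- buildAssemblages(occ, traits, g)
  expect_identical(c(cells$cell_ix, cells$cell_iy), c(3L, 4L))
  expect_identical(cells$n_species, 1L)
  expect_true(cells$prop_dome %in% c(0, 1))
})

test_that("species without trait records are counted but excluded from summaries", {
  traits <- data.frame(species_id = "known", nest_type = "cup",
                       elongation = 1.4)
  occ <- data.frame(species_id = c("known", "mystery"),
                    cell_ix = 0L, cell_iy = 0L)
  cells <- buildAssemblages(occ, traits, latticeGrid())
  expect_identical(cells$n_species, 2L)
  expect_identical(cells$n_trait, 1L)
  expect_identical(cells$n_untraited, 1L)
  expect_equal(cells$prop_dome, 0)
})

test_that("retention filter applies inclusive count thresholds and the CI rule", {
  cells <- data.frame(n_dome = c(9, 10, 50, 12), n_cup = c(50, 10, 9, 30),
                      completeness = c(0.9, 0.9, 0.9, NA))
  f <- filterCells(cells, minPerType = 10, ciThreshold = 0.7)
  expect_identical(f$retained, c(FALSE, TRUE, FALSE, TRUE))
  fd <- filterCells(cells, ciThreshold = 0.7, missingCompleteness = "drop")
  expect_identical(fd$retained[4], FALSE)
  lowCi <- filterCells(transform(cells, completeness = 0.5), ciThreshold = 0.7)
  expect_true(!any(lowCi$retained))
  off <- filterCells(transform(cells, completeness = 0.5), ciThreshold = 0)
  expect_identical(off$retained, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("raising the per-type minimum never rescues an excluded cell", {
  cells <- fixtureCells()
  prev <- rep(TRUE, nrow(cells))
  for (m in c(2, 5, 8, 12, 20)) {
    cur <- filterCells(cells, minPerType = m, ciThreshold = 0)$retained
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("quantile thresholds use linear interpolation between order statistics", {
  expect_equal(quantileThreshold(1:5, 0.8), 4.2, tolerance = 1e-12)
  expect_identical(quantileThreshold(c(3, 9, 1), 1), 9)
  expect_identical(quantileThreshold(rep(2.5, 7), 0.8), 2.5)
  expect_error(quantileThreshold(numeric(0)), "finite")
})

test_that("assemblage tables and rasters export the scalar columns", {
  cells <- fixtureCells()
  tf <- tempfile(fileext = ".csv")
  writeAssemblageTable(cells, tf)
  back <- read.csv(tf)
  expect_identical(nrow(back), nrow(cells))
  expect_false("species" %in% names(back))
  surf <- assemblageSurface(cells, "prop_dome", latticeGrid())
  expect_equal(surfaceAt(surf, cells$cell_ix, cells$cell_iy),
               cells$prop_dome)
})
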