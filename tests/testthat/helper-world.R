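# Shared fixtures, built in code. The compact world (10 x 10 cells, 60
# species) is generated once per test run and reused.

latticeGrid <- function(nx = 10L, ny = 10L)
  gridSpec(nx = nx, ny = ny, x0 = -500000, y0 = -3900000)

latticeCentroids <- function(nx = 10L, ny = 10L)
  cellCentroids(latticeGrid(nx, ny))[, c("x", "y")]

# dense direct double-summation Moran's I, independent of the
# neighbour-list implementation
moranOracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  (n / sum(W)) * sum(W * (z %o% z)) / sum(z^2)
}

.worldCache <- new.env(parent = emptyenv())

fixtureWorld <- function() {
  if (is.null(.worldCache$world)) {
    cfg <- syntheticConfig(seed = 42L, nSpecies = 60L,
                           grid = latticeGrid(), gpRange = 300000)
    .worldCache$world <- suppressMessages(simulateWorld(cfg))
  }
  .worldCache$world
}

fixtureCells <- function() {
  if (is.null(.worldCache$cells)) {
    w <- fixtureWorld()
    cells <- suppressMessages(
      buildAssemblages(w$occurrences, w$species, w$config$grid))
    cells$vpd <- surfaceAt(w$env$vpd, cells$cell_ix, cells$cell_iy)
    cells$lai <- surfaceAt(w$env$lai, cells$cell_ix, cells$cell_iy)
    .worldCache$cells <- cells
  }
  .worldCache$cells
}

# assemblage world at study scale (30 x 30), one seed, reused where a
# larger spatial sample is needed
studyCells <- function() {
  if (is.null(.worldCache$study)) {
    w <- suppressMessages(simulateWorld(syntheticConfig(seed = 7L)))
    cells <- suppressMessages(
      buildAssemblages(w$occurrences, w$species, w$config$grid))
    cells$vpd <- surfaceAt(w$env$vpd, cells$cell_ix, cells$cell_iy)
    cells$lai <- surfaceAt(w$env$lai, cells$cell_ix, cells$cell_iy)
    .worldCache$study <- filterCells(cells)
  }
  .worldCache$study
}
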