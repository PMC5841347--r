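# Assemblage construction: occurrences -> per-cell species sets and trait
# summaries, Chao2 sampling completeness, retention filters.

#' Chao2 sampling-completeness index for one cell
#'
#' Bias-corrected Chao2 incidence estimator of cell richness,
#' \deqn{S_{est} = S_{obs} + \frac{m-1}{m}\,\frac{Q_1(Q_1-1)}{2(Q_2+1)},}
#' where m is the number of sampling events in the cell and Q1, Q2 count
#' species detected in exactly one and two events. The completeness index is
#' `S_obs / S_est`. With fewer than two events completeness is undefined and
#' reported missing.
#'
#' @param incidence integer vector: per species, the number of distinct
#'   sampling events in which it was detected in the cell (all >= 1).
#' @param nEvents m, the number of sampling events in the cell.
#' @return list with `s_obs`, `s_est`, `q1`, `q2`, `m`, `index` (all `NA`
#'   except counts when `m < 2`).
#' @examples
#' completenessIndex(c(rep(1, 4), rep(2, 2), rep(5, 4)), nEvents = 20)
#' @export
completenessIndex <- function(incidence, nEvents) {
  stopifnot(all(incidence >= 1), nEvents >= max(incidence, 0))
  sObs <- length(incidence)
  q1 <- sum(incidence == 1L)
  q2 <- sum(incidence == 2L)
  if (nEvents < 2)
    return(list(s_obs = sObs, s_est = NA_real_, q1 = q1, q2 = q2,
                m = nEvents, index = NA_real_))
  sEst <- sObs + ((nEvents - 1) / nEvents) * q1 * (q1 - 1) / (2 * (q2 + 1))
  list(s_obs = sObs, s_est = sEst, q1 = q1, q2 = q2, m = nEvents,
       index = sObs / sEst)
}

#' Build grid-cell species assemblages
#'
#' Projects occurrence records onto the analysis grid and collects, per cell,
#' the distinct set of species (set semantics: duplicated records change
#' nothing), then joins traits to produce nest-type counts, mean elongation
#' per nest type (cavity nesters excluded from elongation summaries), the
#' proportion of domed-nest species, and — when records carry `event_id` —
#' the Chao2 completeness index.
#'
#' Input dialects: point records (`species_id`, `lon`, `lat`, optional
#' `event_id`) are projected and gridded; pre-gridded records (`species_id`,
#' `cell_ix`, `cell_iy`) bypass projection, for reproduction runs against
#' deposited species-by-cell tables.
#'
#' @param occurrences data.frame in one of the two dialects above.
#' @param traits trait data.frame (`species_id`, `nest_type`, `elongation`).
#' @param grid a [GridSpec-class].
#' @param propDomeDenominator `"all"` (cup + dome + cavity; default) or
#'   `"cup_dome"`.
#' @return data.frame, one row per non-empty cell: `cell_ix`, `cell_iy`,
#'   `x`, `y` (centroids, m), `n_species`, `n_trait`, `n_untraited`, `n_cup`,
#'   `n_dome`, `n_cavity`, `mean_elong_cup`, `mean_elong_dome`, `prop_dome`,
#'   `s_obs`, `s_est`, `completeness`; plus a `species` list-column of
#'   species ids.
#' @export
buildAssemblages <- function(occurrences, traits, grid,
                             propDomeDenominator = c("all", "cup_dome")) {
  propDomeDenominator <- match.arg(propDomeDenominator)
  occ <- occurrences
  if (all(c("cell_ix", "cell_iy") %in% names(occ))) {
    ix <- as.integer(occ$cell_ix); iy <- as.integer(occ$cell_iy)
  } else {
    stopifnot(all(c("species_id", "lon", "lat") %in% names(occ)))
    xy <- albersForward(occ$lon, occ$lat, grid)
    cells <- assignCell(xy$x, xy$y, grid)
    ix <- cells$ix; iy <- cells$iy
  }
  keep <- !is.na(ix) & !is.na(iy)
  occ <- occ[keep, , drop = FALSE]; ix <- ix[keep]; iy <- iy[keep]
  if (nrow(occ) == 0L) return(.emptyAssemblageFrame())
  cellKey <- paste(ix, iy, sep = "_")
  hasEvents <- "event_id" %in% names(occ) && !all(is.na(occ$event_id))

  traitIdx <- match(occ$species_id, traits$species_id)
  nestType <- traits$nest_type[traitIdx]
  elong <- traits$elongation[traitIdx]

  idxByCell <- split(seq_len(nrow(occ)), cellKey)
  ij <- do.call(rbind, lapply(strsplit(names(idxByCell), "_", fixed = TRUE),
                              as.integer))
  ord <- order(ij[, 1], ij[, 2])
  idxByCell <- idxByCell[ord]; ij <- ij[ord, , drop = FALSE]

  rows <- mapply(function(sel, cix, ciy) {
    spAll <- occ$species_id[sel]
    first <- sel[!duplicated(spAll)]
    sp <- occ$species_id[first]
    nt <- nestType[first]
    el <- elong[first]
    nCup <- sum(nt == "cup", na.rm = TRUE)
    nDome <- sum(nt == "dome", na.rm = TRUE)
    nCav <- sum(nt == "cavity", na.rm = TRUE)
    denom <- if (propDomeDenominator == "all") nCup + nDome + nCav
             else nCup + nDome
    comp <- list(s_obs = length(sp), s_est = NA_real_, index = NA_real_)
    if (hasEvents) {
      ev <- occ$event_id[sel]
      pair <- !duplicated(paste(spAll, ev))
      inc <- as.integer(table(factor(spAll[pair], levels = sp)))
      comp <- completenessIndex(inc, nEvents = length(unique(ev)))
    }
    data.frame(
      cell_ix = cix, cell_iy = ciy,
      x = grid@x0 + (cix + 0.5) * grid@cellSize,
      y = grid@y0 + (ciy + 0.5) * grid@cellSize,
      n_species = length(sp),
      n_trait = sum(!is.na(nt)),
      n_untraited = sum(is.na(nt)),
      n_cup = nCup, n_dome = nDome, n_cavity = nCav,
      mean_elong_cup = if (nCup > 0) mean(el[nt == "cup"], na.rm = TRUE) else NA_real_,
      mean_elong_dome = if (nDome > 0) mean(el[nt == "dome"], na.rm = TRUE) else NA_real_,
      prop_dome = if (denom > 0) nDome / denom else NA_real_,
      s_obs = comp$s_obs, s_est = comp$s_est,
      completeness = comp$index)
  }, idxByCell, ij[, 1], ij[, 2], SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out$species <- lapply(idxByCell, function(sel) sort(unique(occ$species_id[sel])))
  rownames(out) <- NULL
  out
}

.emptyAssemblageFrame <- function() {
  out <- data.frame(cell_ix = integer(), cell_iy = integer(),
                    x = numeric(), y = numeric(), n_species = integer(),
                    n_trait = integer(), n_untraited = integer(),
                    n_cup = integer(), n_dome = integer(), n_cavity = integer(),
                    mean_elong_cup = numeric(), mean_elong_dome = numeric(),
                    prop_dome = numeric(), s_obs = integer(),
                    s_est = numeric(), completeness = numeric())
  out$species <- list()
  out
}

#' Cell retention filter
#'
#' A cell is retained when it has at least `minPerType` species with domed
#' nests AND at least `minPerType` with cup-shaped nests, and its
#' completeness index passes `ciThreshold`. Cells with missing completeness
#' are kept or dropped according to `missingCompleteness`.
#'
#' @param cells assemblage data.frame from [buildAssemblages()].
#' @param minPerType minimum species per nest type; default 10 (inclusive).
#' @param ciThreshold completeness cut-off; 0 disables the completeness rule.
#' @param missingCompleteness `"keep"` or `"drop"` cells lacking an index.
#' @return `cells` with a logical `retained` column.
#' @export
filterCells <- function(cells, minPerType = 10, ciThreshold = 0.7,
                        missingCompleteness = c("keep", "drop")) {
  missingCompleteness <- match.arg(missingCompleteness)
  countOk <- cells$n_dome >= minPerType & cells$n_cup >= minPerType
  ci <- cells$completeness
  ciOk <- if (ciThreshold <= 0) rep(TRUE, nrow(cells)) else ci >= ciThreshold
  ciOk[is.na(ci)] <- missingCompleteness == "keep" | ciThreshold <= 0
  cells$retained <- countOk & ciOk
  cells
}

#' Empirical quantile threshold
#'
#' Linear interpolation between order statistics (type 7, the default
#' convention of the analysis environment), used for the mapped 80% quantile
#' thresholds.
#'
#' @param values numeric vector with at least one finite value.
#' @param q probability in [0, 1]; default 0.8.
#' @return the empirical quantile.
#' @examples
#' quantileThreshold(1:5, 0.8)  # 4.2
#' @export
quantileThreshold <- function(values, q = 0.8) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  unname(stats::quantile(values, probs = q, type = 7))
}

#' Write assemblage scalars to CSV / ASCII grids
#'
#' @param cells assemblage data.frame.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeAssemblageTable <- function(cells, path) {
  utils::write.csv(cells[setdiff(names(cells), "species")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Rasterise one assemblage column onto its grid
#'
#' @param cells assemblage data.frame.
#' @param column scalar column name, e.g. `"prop_dome"`.
#' @param grid the [GridSpec-class] the cells live on.
#' @return an [EnvSurface-class] (missing where no assemblage exists).
#' @export
assemblageSurface <- function(cells, column, grid) {
  v <- matrix(NA_real_, grid@nx, grid@ny)
  v[cbind(cells$cell_ix + 1L, cells$cell_iy + 1L)] <- cells[[column]]
  envSurface(column, v, grid, units = "dimensionless")
}
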