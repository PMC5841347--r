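# Environmental surfaces: saturation vapour pressure, VPD, temporal
# averaging, aggregation to the analysis grid, ESRI ASCII grid I/O.

.UNITS <- c(tmax = "degC", vp = "kPa", vpd = "kPa", lai = "dimensionless")

#' Construct an environmental surface
#'
#' @param variable "tmax", "vp", "vpd", "lai", or another label.
#' @param values numeric matrix with `dim = c(nx, ny)`; `NA` marks missing.
#' @param grid the [GridSpec-class] geometry.
#' @param units unit string; inferred for the four standard variables.
#' @param period free-text time-span label.
#' @return an [EnvSurface-class].
#' @export
envSurface <- function(variable, values, grid, units = NULL, period = "") {
  if (is.null(units))
    units <- if (variable %in% names(.UNITS)) .UNITS[[variable]] else "unknown"
  new("EnvSurface", variable = variable, units = units, grid = grid,
      values = values, period = period)
}

#' @rdname accessors
#' @export
setMethod("surfaceValues", "EnvSurface", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("variableName", "EnvSurface", function(object) object@variable)

#' @rdname accessors
#' @export
setMethod("gridOf", "EnvSurface", function(object) object@grid)

setMethod("show", "EnvSurface", function(object) {
  v <- object@values
  cat(sprintf("EnvSurface '%s' [%s] %d x %d cells, %d missing\n",
              object@variable, object@units, nrow(v), ncol(v), sum(is.na(v))))
  if (nzchar(object@period)) cat("  period:", object@period, "\n")
  cat(sprintf("  range %.4g .. %.4g\n", suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' Saturation vapour pressure
#'
#' `esat(T) = 0.61375 * exp(17.502 T / (240.97 + T))` kPa, the
#' Jones (1992) formulation. Strictly increasing in temperature; the formula
#' has a pole at -240.97 degC and inputs at or below it are rejected.
#'
#' @param tCelsius air temperature, degrees Celsius.
#' @return saturation vapour pressure, kPa.
#' @examples
#' esat(0)    # 0.61375 exactly
#' esat(25)   # about 3.18 kPa
#' @export
esat <- function(tCelsius) {
  if (any(!is.finite(tCelsius)) || any(tCelsius <= -240.97))
    stop("temperature at or below the -240.97 degC formula pole")
  0.61375 * exp(17.502 * tCelsius / (240.97 + tCelsius))
}

#' Vapour pressure deficit
#'
#' VPD is the saturation vapour pressure at daily maximum temperature minus
#' the actual (3 pm) vapour pressure: the drying capacity of the air.
#' Supersaturated inputs (vp > esat(tmax)) clamp to 0 kPa; their count is
#' reported in a warning.
#'
#' @param tmax daily maximum temperature, degC.
#' @param vp vapour pressure, kPa, non-negative.
#' @return VPD, kPa (non-negative).
#' @export
vpd <- function(tmax, vp) {
  if (any(vp < 0, na.rm = TRUE)) stop("negative vapour pressure")
  raw <- esat(tmax) - vp
  nClamp <- sum(raw < 0, na.rm = TRUE)
  if (nClamp > 0)
    warning(nClamp, " supersaturated value(s) clamped to 0 kPa")
  pmax(raw, 0)
}

.sameGeometry <- function(a, b) {
  ga <- a@grid; gb <- b@grid
  isTRUE(all.equal(c(ga@cellSize, ga@x0, ga@y0, ga@nx, ga@ny),
                   c(gb@cellSize, gb@x0, gb@y0, gb@nx, gb@ny)))
}

#' Temporal mean of a stack of surfaces
#'
#' Per-cell arithmetic mean over non-missing time steps. All surfaces must
#' share the same grid geometry and variable.
#'
#' @param surfaces list of [EnvSurface-class] objects (e.g. daily fields).
#' @param period label for the averaged product.
#' @return an [EnvSurface-class] of per-cell means; cells missing on every
#'   day stay missing.
#' @export
temporalAverage <- function(surfaces, period = "mean") {
  stopifnot(length(surfaces) >= 1)
  g1 <- surfaces[[1]]
  for (s in surfaces[-1])
    if (!.sameGeometry(g1, s)) stop("surfaces do not share grid geometry")
  arr <- vapply(surfaces, function(s) s@values,
                matrix(0, nrow(g1@values), ncol(g1@values)))
  tot <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  envSurface(g1@variable, tot, g1@grid, units = g1@units, period = period)
}

#' Daily VPD averaged over a period
#'
#' Computes VPD from paired daily Tmax and VP surfaces and averages the daily
#' VPD fields (the default). The alternative order — average Tmax and VP
#' first, then take VPD of the means — is exposed for sensitivity checks;
#' because esat is convex the two orders differ.
#'
#' @param tmaxDaily,vpDaily lists of paired daily [EnvSurface-class] objects.
#' @param order `"daily"` (VPD per day, then mean) or `"averaged"`
#'   (mean Tmax and VP, then one VPD).
#' @param period label for the product.
#' @return an [EnvSurface-class] of variable "vpd".
#' @export
vpdSurface <- function(tmaxDaily, vpDaily, order = c("daily", "averaged"),
                       period = "mean") {
  order <- match.arg(order)
  stopifnot(length(tmaxDaily) == length(vpDaily), length(tmaxDaily) >= 1)
  if (order == "daily") {
    daily <- mapply(function(tm, pv) {
      if (!.sameGeometry(tm, pv)) stop("surfaces do not share grid geometry")
      envSurface("vpd", .vpdMatrix(tm@values, pv@values), tm@grid)
    }, tmaxDaily, vpDaily, SIMPLIFY = FALSE)
    temporalAverage(daily, period = period)
  } else {
    tm <- temporalAverage(tmaxDaily, period = period)
    pv <- temporalAverage(vpDaily, period = period)
    envSurface("vpd", .vpdMatrix(tm@values, pv@values), tm@grid,
               period = period)
  }
}

.vpdMatrix <- function(tmaxVals, vpVals) {
  out <- tmaxVals * NA_real_
  ok <- !is.na(tmaxVals) & !is.na(vpVals)
  out[ok] <- suppressWarnings(vpd(tmaxVals[ok], vpVals[ok]))
  out
}

# per-axis rectangle overlap lengths between coarse and fine cell edges
.axisOverlap <- function(c0, cSize, cn, f0, fSize, fn) {
  cl <- c0 + (seq_len(cn) - 1) * cSize; cu <- cl + cSize
  fl <- f0 + (seq_len(fn) - 1) * fSize; fu <- fl + fSize
  ov <- outer(cu, fu, pmin) - outer(cl, fl, pmax)
  ov[ov < 0] <- 0
  ov
}

#' Aggregate a fine surface to a coarser analysis grid
#'
#' Coarse cell values are area-weighted means of the overlapping fine cells
#' (exact rectangle-intersection areas; equal weights when fine cells nest).
#' Missing fine cells are excluded from the weight sum; a coarse cell with no
#' coverage is missing.
#'
#' @param fine an [EnvSurface-class] on a (finer) grid sharing the projection.
#' @param grid the target [GridSpec-class].
#' @return an [EnvSurface-class] on `grid`.
#' @export
aggregateToGrid <- function(fine, grid) {
  fg <- fine@grid
  Wx <- .axisOverlap(grid@x0, grid@cellSize, grid@nx, fg@x0, fg@cellSize, fg@nx)
  Wy <- .axisOverlap(grid@y0, grid@cellSize, grid@ny, fg@y0, fg@cellSize, fg@ny)
  V <- fine@values
  M <- !is.na(V)
  V0 <- ifelse(M, V, 0)
  num <- Wx %*% V0 %*% t(Wy)
  den <- Wx %*% (M + 0) %*% t(Wy)
  out <- ifelse(den > 0, num / den, NA_real_)
  envSurface(fine@variable, out, grid, units = fine@units,
             period = fine@period)
}

#' ESRI ASCII grid I/O
#'
#' Plain-text `.asc` raster exchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from the northern edge southwards. Reading attaches a default
#' Albers [GridSpec-class] (the format itself carries no projection).
#'
#' @param path file path.
#' @param variable,units,period metadata for the returned surface.
#' @param proj a [GridSpec-class] whose projection parameters to adopt.
#' @return `readAsciiGrid`: an [EnvSurface-class]. `writeAsciiGrid`: the
#'   path, invisibly.
#' @export
readAsciiGrid <- function(path, variable = "unknown", units = NULL,
                          period = "", proj = gridSpec()) {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  vals <- scan(path, skip = 6, quiet = TRUE)
  nx <- as.integer(hdr["ncols"]); ny <- as.integer(hdr["nrows"])
  if (length(vals) != nx * ny) stop("ASCII grid body does not match header")
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)  # rows: N -> S
  m[m == hdr["nodata_value"]] <- NA_real_
  values <- t(m[ny:1, , drop = FALSE])                   # -> [ix, iy], iy S -> N
  g <- gridSpec(lon0 = proj@lon0, lat0 = proj@lat0, lat1 = proj@lat1,
                lat2 = proj@lat2, falseEasting = proj@falseEasting,
                falseNorthing = proj@falseNorthing,
                cellSize = hdr[["cellsize"]], x0 = hdr[["xllcorner"]],
                y0 = hdr[["yllcorner"]], nx = nx, ny = ny)
  envSurface(variable, values, g, units = units, period = period)
}

#' @rdname readAsciiGrid
#' @param surface an [EnvSurface-class] to write.
#' @param nodata sentinel written for missing cells.
#' @export
writeAsciiGrid <- function(surface, path, nodata = -9999) {
  g <- surface@grid
  v <- surface@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g@nx), sprintf("nrows %d", g@ny),
           sprintf("xllcorner %.6f", g@x0), sprintf("yllcorner %.6f", g@y0),
           sprintf("cellsize %.6f", g@cellSize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(t(v)[g@ny:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Extract per-cell surface values for a set of cells
#'
#' @param surface an [EnvSurface-class].
#' @param ix,iy 0-based cell indices.
#' @return numeric vector of cell values (`NA` off-grid or missing).
#' @export
surfaceAt <- function(surface, ix, iy) {
  v <- surface@values
  ok <- !is.na(ix) & !is.na(iy) & ix >= 0 & ix < nrow(v) & iy >= 0 & iy < ncol(v)
  out <- rep(NA_real_, length(ix))
  out[ok] <- v[cbind(ix[ok] + 1L, iy[ok] + 1L)]
  out
}
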