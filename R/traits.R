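# Species trait table: egg elongation, nest types, species-level statistics.

.NEST_TYPES <- c("cup", "dome", "cavity")

#' Egg elongation
#'
#' Elongation is the ratio of egg length to egg breadth (1 = circular
#' cross-section profile, larger = more elongate). No rounding is applied.
#'
#' @param length egg length, mm, positive.
#' @param breadth egg breadth, mm, positive.
#' @param id optional row labels used in error messages.
#' @return numeric vector `length / breadth`.
#' @examples
#' computeElongation(22.6, 16.3)
#' @export
computeElongation <- function(length, breadth, id = NULL) {
  stopifnot(base::length(length) == base::length(breadth))
  bad <- !is.finite(length) | !is.finite(breadth) | length <= 0 | breadth <= 0
  if (any(bad)) {
    lab <- if (is.null(id)) which(bad) else id[bad]
    stop("non-positive or missing egg measurement for: ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  length / breadth
}

#' Read and validate a species trait table
#'
#' Expects a UTF-8 CSV with header columns `species_id`, `common_name`,
#' `family`, `nest_type`, `egg_length_mm`, `egg_breadth_mm` (an optional
#' `elongation` column is cross-validated, never trusted). Rows missing either
#' egg measurement are dropped with a message reporting raw and retained
#' counts per nest type; elongation is always recomputed from length and
#' breadth.
#'
#' @param path CSV file path.
#' @return data.frame with the input columns plus `elongation`; attributes
#'   `n_raw`, `n_dropped` and `counts_raw` record the pre-exclusion state.
#' @export
readTraitTable <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species_id", "family", "nest_type", "egg_length_mm", "egg_breadth_mm")
  miss <- setdiff(need, names(tr))
  if (base::length(miss))
    stop("trait table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(tr$nest_type %in% .NEST_TYPES))
    stop("nest_type values must be one of: ", paste(.NEST_TYPES, collapse = ", "))
  nRaw <- nrow(tr)
  countsRaw <- table(factor(tr$nest_type, levels = .NEST_TYPES))
  ok <- is.finite(tr$egg_length_mm) & is.finite(tr$egg_breadth_mm)
  if (any(!ok))
    message(sum(!ok), " species dropped for missing egg measurements (",
            nRaw, " raw rows)")
  kept <- tr[ok, , drop = FALSE]
  elong <- computeElongation(kept$egg_length_mm, kept$egg_breadth_mm,
                             id = kept$species_id)
  if ("elongation" %in% names(kept)) {
    disagree <- abs(kept$elongation - elong) > 1e-6 * pmax(1, abs(elong))
    if (any(disagree, na.rm = TRUE))
      warning(sum(disagree, na.rm = TRUE),
              " published elongation value(s) disagree with length/breadth; ",
              "recomputed values are used")
  }
  kept$elongation <- elong
  attr(kept, "n_raw") <- nRaw
  attr(kept, "n_dropped") <- sum(!ok)
  attr(kept, "counts_raw") <- countsRaw
  kept
}

#' Screen elongation outliers
#'
#' Flags species whose elongation lies more than `kSd` sample standard
#' deviations from the overall mean (mean and sd over all species). Both the
#' retained and flagged sets are returned so analyses can be run across all
#' species and across the screened subset.
#'
#' @param traits trait data.frame with an `elongation` column.
#' @param kSd threshold in standard deviations; default 3.
#' @return list with data.frames `retained` and `flagged`.
#' @export
screenOutliers <- function(traits, kSd = 3) {
  stopifnot(nrow(traits) >= 3)
  e <- traits$elongation
  mu <- mean(e); sde <- stats::sd(e)
  out <- abs(e - mu) > kSd * sde
  list(retained = traits[!out, , drop = FALSE],
       flagged = traits[out, , drop = FALSE])
}

#' Per-nest-type summary: n, mean elongation, standard error
#'
#' SE is `sd/sqrt(n)` with the n-1 sample standard deviation (the package's
#' mean +/- SE reporting convention throughout). A group of one species gets
#' SE 0 with a warning; empty groups are omitted with a warning.
#'
#' @param traits trait data.frame with `elongation` and `nest_type`.
#' @return data.frame with columns `nest_type`, `n`, `mean_elongation`,
#'   `se_elongation`.
#' @export
summarizeNestTypes <- function(traits) {
  out <- lapply(.NEST_TYPES, function(nt) {
    e <- traits$elongation[traits$nest_type == nt]
    n <- base::length(e)
    if (n == 0L) {
      warning("nest type '", nt, "' has no species; omitted from summary")
      return(NULL)
    }
    se <- if (n == 1L) {
      warning("nest type '", nt, "' has a single species; SE reported as 0")
      0
    } else stats::sd(e) / sqrt(n)
    data.frame(nest_type = nt, n = n, mean_elongation = mean(e),
               se_elongation = se)
  })
  do.call(rbind, out)
}

.groupsToFrame <- function(valuesByGroup) {
  stopifnot(is.list(valuesByGroup), base::length(valuesByGroup) >= 2)
  if (is.null(names(valuesByGroup)))
    names(valuesByGroup) <- paste0("g", seq_along(valuesByGroup))
  data.frame(
    value = unlist(valuesByGroup, use.names = FALSE),
    group = factor(rep(names(valuesByGroup), lengths(valuesByGroup)),
                   levels = names(valuesByGroup)))
}

#' Classical one-way ANOVA
#'
#' F = MS_between / MS_within with df (k-1, N-k); for a single factor this is
#' also the Type II Wald F. Computed through [stats::aov()].
#'
#' @param valuesByGroup named list of numeric vectors, one per group.
#' @return list with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `group_means`.
#' @export
anovaOneway <- function(valuesByGroup) {
  d <- .groupsToFrame(valuesByGroup)
  stopifnot(nrow(d) > nlevels(d$group))
  tot <- stats::var(d$value)
  if (!is.finite(tot) || tot == 0)
    stop("degenerate ANOVA: zero between-group and within-group variance")
  a <- stats::aov(value ~ group, data = d)
  tab <- summary(a)[[1]]
  list(f_stat = tab[["F value"]][1],
       df_between = as.integer(tab[["Df"]][1]),
       df_within = as.integer(tab[["Df"]][2]),
       p_value = tab[["Pr(>F)"]][1],
       group_means = tapply(d$value, d$group, mean))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range comparisons with the Tukey-Kramer harmonic-mean
#' adjustment for unequal group sizes, via [stats::TukeyHSD()].
#'
#' @param valuesByGroup named list of numeric vectors.
#' @param confLevel confidence level for the interval columns; default 0.95.
#' @return data.frame with columns `group_a`, `group_b`, `mean_difference`,
#'   `lwr`, `upr`, `adjusted_p`.
#' @export
tukeyPairwise <- function(valuesByGroup, confLevel = 0.95) {
  d <- .groupsToFrame(valuesByGroup)
  tot <- stats::var(d$value)
  if (!is.finite(tot) || tot == 0)
    stop("degenerate ANOVA: zero between-group and within-group variance")
  a <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(a, conf.level = confLevel)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(pairs, `[`, "", 1),
             group_b = vapply(pairs, `[`, "", 2),
             mean_difference = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             adjusted_p = tk[, "p adj"],
             row.names = NULL)
}

# REML machinery for y = X beta + Z b + e with a single grouping factor.
# With gamma = varGroup/varResid the per-group covariance is
# sigma_e^2 (I + gamma J); its inverse and determinant are closed form,
# so the criterion is profiled down to a 1-D search over gamma.
.remlProfile <- function(gamma, y, X, groupIdx, sizes) {
  n <- base::length(y); p <- ncol(X)
  # Sigma^{-1} x = x - gamma/(1+gamma n_g) * groupsum replication
  shrink <- gamma / (1 + gamma * sizes)
  siX <- X - (shrink[groupIdx] *
                apply(X, 2, function(col) ave(col, groupIdx, FUN = sum)))
  siY <- y - shrink[groupIdx] * ave(y, groupIdx, FUN = sum)
  XtSiX <- crossprod(X, siX)
  XtSiY <- crossprod(X, siY)
  beta <- solve(XtSiX, XtSiY)
  r <- y - X %*% beta
  siR <- r - shrink[groupIdx] * ave(as.vector(r), groupIdx, FUN = sum)
  quad <- sum(r * siR)
  sigma2e <- quad / (n - p)
  logDetSigma <- sum(log1p(gamma * sizes))
  logDetXtSiX <- determinant(XtSiX, logarithm = TRUE)$modulus
  logReml <- -0.5 * ((n - p) * log(2 * pi * sigma2e) + (n - p) +
                       logDetSigma + as.numeric(logDetXtSiX))
  list(logReml = logReml, beta = as.vector(beta), sigma2e = sigma2e,
       XtSiX = XtSiX)
}

#' REML random-intercept model for shared-ancestry robustness
#'
#' Linear mixed model with nest type as fixed effect and taxonomic family as
#' a random intercept, estimated by REML with the single variance ratio
#' profiled out (closed-form per-family inverse), then a bounded 1-D search.
#' The zero-variance boundary is checked explicitly and may be forced to
#' demonstrate collapse to OLS.
#'
#' @param traits trait data.frame with `elongation`, `nest_type`, `family`
#'   columns (or supply `response`, `fixed`, `group` to rename).
#' @param response,fixed,group column names.
#' @param forceVarGroupZero if TRUE the group variance is pinned at 0.
#' @return a [RandomInterceptFit-class].
#' @export
fitRandomIntercept <- function(traits, response = "elongation",
                               fixed = "nest_type", group = "family",
                               forceVarGroupZero = FALSE) {
  y <- traits[[response]]
  f <- factor(traits[[fixed]])
  g <- factor(traits[[group]])
  if (nlevels(g) < 2) stop("need at least two groups (families)")
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0(fixed, levels(f)[-1]))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  groupIdx <- as.integer(g)
  sizes <- as.vector(table(groupIdx))
  obj <- function(logGamma)
    .remlProfile(exp(logGamma), y, X, groupIdx, sizes)$logReml
  if (forceVarGroupZero) {
    gammaHat <- 0
  } else {
    opt <- stats::optimize(obj, interval = c(-12, 8), maximum = TRUE,
                           tol = 1e-9)
    if (!is.finite(opt$objective))
      stop("REML optimisation failed; criterion at optimum: ", opt$objective)
    atZero <- .remlProfile(0, y, X, groupIdx, sizes)$logReml
    gammaHat <- if (atZero >= opt$objective) 0 else exp(opt$maximum)
  }
  fit <- .remlProfile(gammaHat, y, X, groupIdx, sizes)
  vcovBeta <- fit$sigma2e * solve(fit$XtSiX)
  # Wald F for the fixed factor (all non-intercept contrasts)
  sel <- seq_len(ncol(X))[-1]
  b <- fit$beta[sel]
  Fstat <- if (base::length(sel))
    drop(t(b) %*% solve(vcovBeta[sel, sel, drop = FALSE], b)) / base::length(sel)
  else NA_real_
  df2 <- base::length(y) - ncol(X)
  names(fit$beta) <- colnames(X)
  new("RandomInterceptFit",
      fixef = fit$beta,
      varGroup = gammaHat * fit$sigma2e,
      varResid = fit$sigma2e,
      logReml = fit$logReml,
      waldF = list(statistic = Fstat, df1 = base::length(sel), df2 = df2,
                   p = stats::pf(Fstat, base::length(sel), df2,
                                 lower.tail = FALSE)))
}

#' @describeIn fitRandomIntercept evaluate the REML criterion at an arbitrary
#'   variance ratio `gamma = varGroup/varResid` (used for probe checks).
#' @param gamma non-negative variance ratio.
#' @export
remlCriterion <- function(traits, gamma, response = "elongation",
                          fixed = "nest_type", group = "family") {
  y <- traits[[response]]
  X <- stats::model.matrix(~factor(traits[[fixed]]))
  g <- factor(traits[[group]])
  groupIdx <- as.integer(g)
  sizes <- as.vector(table(groupIdx))
  .remlProfile(gamma, y, X, groupIdx, sizes)$logReml
}

setMethod("show", "RandomInterceptFit", function(object) {
  cat("Random-intercept REML fit\n")
  cat("  var(group) =", format(object@varGroup, digits = 4),
      " var(resid) =", format(object@varResid, digits = 4), "\n")
  cat("  REML logLik =", format(object@logReml, digits = 6), "\n")
  cat("  Wald F =", format(object@waldF$statistic, digits = 4),
      "on", object@waldF$df1, "and", object@waldF$df2, "df, p =",
      format.pval(object@waldF$p), "\n")
})
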