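# Species-level trait operations: elongation, screening, summaries,
# ANOVA / Tukey, family random intercept.

test_that("elongation is the exact length/breadth ratio", {
  expect_identical(computeElongation(20, 20), 1)
  expect_identical(computeElongation(30, 15), 2)
  expect_equal(computeElongation(22.6, 16.3), 22.6 / 16.3, tolerance = 1e-15)
  expect_error(computeElongation(-1, 10, id = "spX"), "spX")
  expect_error(computeElongation(10, 0), "non-positive")
})

test_that("trait loader validates, drops unmeasured species, cross-checks elongation", {
  tf <- tempfile(fileext = ".csv")
  tr <- data.frame(species_id = paste0("s", 1:5),
                   common_name = letters[1:5],
                   family = c("f1", "f1", "f2", "f2", "f3"),
                   nest_type = c("cup", "dome", "cavity", "cup", "dome"),
                   egg_length_mm = c(20, 21, NA, 19, 24),
                   egg_breadth_mm = c(15, 14, 16, 14, 16),
                   elongation = c(20 / 15, 21 / 14, NA, 1.9, 24 / 16))
  write.csv(tr, tf, row.names = FALSE)
  expect_warning(
    expect_message(out <- readTraitTable(tf), "dropped"),
    "disagree")
  expect_identical(nrow(out), 4L)
  expect_identical(attr(out, "n_raw"), 5L)
  expect_identical(attr(out, "n_dropped"), 1L)
  expect_equal(unname(attr(out, "counts_raw")["cavity"]), 1)
  expect_equal(out$elongation[out$species_id == "s4"], 19 / 14)
  tr$nest_type[1] <- "burrow"
  write.csv(tr, tf, row.names = FALSE)
  expect_error(readTraitTable(tf), "nest_type")
})

test_that("outlier screening flags only far-out elongations", {
  base <- data.frame(species_id = sprintf("s%03d", 1:101),
                     elongation = c(rep(1.37, 100), 9.99))
  scr <- screenOutliers(base)
  expect_identical(scr$flagged$species_id, "s101")
  expect_identical(nrow(scr$retained), 100L)
  none <- screenOutliers(data.frame(species_id = 1:3,
                                    elongation = c(1.3, 1.35, 1.4)))
  expect_identical(nrow(none$flagged), 0L)
  all <- screenOutliers(base, kSd = 0)
  expect_true(all(base$elongation[base$elongation != mean(base$elongation)]
                  %in% all$flagged$elongation))
})

test_that("nest-type summaries use sd/sqrt(n) and survive degenerate groups", {
  tr <- data.frame(nest_type = c("cup", "cup", "dome"),
                   elongation = c(1.2, 1.4, 1.5))
  wAll <- capture_warnings(s <- summarizeNestTypes(tr))
  expect_match(wAll, "single species|no species", all = TRUE)
  cup <- s[s$nest_type == "cup", ]
  expect_equal(cup$mean_elongation, 1.3)
  expect_equal(cup$se_elongation, sd(c(1.2, 1.4)) / sqrt(2))
  expect_equal(cup$se_elongation, 0.1, tolerance = 1e-12)
  w1 <- capture_warnings(s2 <- summarizeNestTypes(tr[3, , drop = FALSE]))
  expect_true(any(grepl("single species", w1)))
  expect_identical(s2$se_elongation, 0)
})

test_that("summaries are invariant to row order and duplication doubles n only", {
  w <- fixtureWorld()
  tr <- w$species
  s1 <- summarizeNestTypes(tr)
  s2 <- summarizeNestTypes(tr[rev(seq_len(nrow(tr))), ])
  expect_equal(s1, s2)
  sdup <- summarizeNestTypes(rbind(tr, tr))
  expect_equal(sdup$mean_elongation, s1$mean_elongation)
  expect_identical(sdup$n, 2L * s1$n)
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  a <- anovaOneway(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a$f_stat, 13.5, tolerance = 1e-12)
  expect_identical(c(a$df_between, a$df_within), c(1L, 4L))
  eq <- anovaOneway(list(a = c(1, 2), b = c(1.5, 1.5), c = c(2, 1)))
  expect_equal(eq$f_stat, 0, tolerance = 1e-12)
  expect_error(anovaOneway(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  # F = t^2 for two groups (pooled-variance t)
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  a2 <- anovaOneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a2$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey-Kramer pairs match a direct studentized-range evaluation", {
  set.seed(4)
  g <- list(a = rnorm(16, 1.30, 0.05), b = rnorm(191, 1.37, 0.05),
            c = rnorm(101, 1.37, 0.05))
  tk <- tukeyPairwise(g)
  expect_identical(nrow(tk), 3L)
  # independent assembly of the Tukey-Kramer adjusted p for one pair
  d <- data.frame(v = unlist(g), grp = rep(names(g), lengths(g)))
  mse <- sum(unlist(lapply(g, function(v) sum((v - mean(v))^2)))) /
    (length(d$v) - 3)
  for (i in 1:3) {
    ga <- tk$group_a[i]; gb <- tk$group_b[i]
    diff <- mean(g[[ga]]) - mean(g[[gb]])
    seKramer <- sqrt(mse / 2 * (1 / length(g[[ga]]) + 1 / length(g[[gb]])))
    pRef <- ptukey(abs(diff) / seKramer, nmeans = 3,
                   df = length(d$v) - 3, lower.tail = FALSE)
    expect_equal(tk$adjusted_p[i], pRef, tolerance = 1e-10)
  }
})

test_that("Tukey adjusted p exceeds the unadjusted pairwise p and is ~1 for clones", {
  set.seed(5)
  x <- rnorm(20)
  cl <- tukeyPairwise(list(a = x, b = x + 1e-12, c = rnorm(20, 3)))
  same <- cl[cl$group_a == "b" & cl$group_b == "a", ]
  expect_gt(same$adjusted_p, 0.999)
  expect_lt(cl$adjusted_p[cl$group_a == "c" & cl$group_b == "a"], 1e-3)
  g <- list(a = rnorm(15), b = rnorm(15, 0.8), c = rnorm(15, 1.6))
  tk <- tukeyPairwise(g)
  mse <- sum(unlist(lapply(g, function(v) (v - mean(v))^2))) / (45 - 3)
  for (i in 1:3) {
    diffAb <- mean(g[[tk$group_a[i]]]) - mean(g[[tk$group_b[i]]])
    se <- sqrt(mse * (1 / 15 + 1 / 15))
    raw <- 2 * pt(-abs(diffAb) / se, df = 42)  # same pooled MSE, no adjustment
    expect_gte(tk$adjusted_p[i] + 1e-12, raw)
  }
})

test_that("random-intercept REML matches lme4 and collapses to OLS at the boundary", {
  skip_if_not_installed("lme4")
  tr <- generateSpecies(syntheticConfig(seed = 9))
  # inject real family structure
  set.seed(9)
  fam <- rnorm(30, 0, sqrt(0.002))
  tr$elongation <- tr$elongation +
    fam[as.integer(factor(tr$family))]
  fit <- fitRandomIntercept(tr)
  ref <- lme4::lmer(elongation ~ nest_type + (1 | family), data = tr,
                    REML = TRUE)
  expect_equal(unname(fit@fixef),
               unname(lme4::fixef(ref)), tolerance = 1e-5)
  expect_equal(fit@varResid, sigma(ref)^2, tolerance = 1e-4)
  expect_equal(fit@varGroup,
               as.numeric(lme4::VarCorr(ref)$family), tolerance = 1e-3)
  expect_equal(fit@logReml, as.numeric(logLik(ref)), tolerance = 1e-6)
  # forced zero group variance reproduces OLS exactly
  f0 <- fitRandomIntercept(tr, forceVarGroupZero = TRUE)
  ols <- lm(elongation ~ nest_type, data = tr)
  expect_equal(unname(f0@fixef), unname(coef(ols)), tolerance = 1e-10)
})

test_that("REML detects an absent family effect as a boundary solution", {
  tr <- generateSpecies(syntheticConfig(seed = 10))  # no family signal
  fit <- fitRandomIntercept(tr)
  expect_lt(fit@varGroup, 1e-4 * fit@varResid + 1e-8)
})

test_that("REML recovers both variances within 50% relative error (median)", {
  errs <- t(vapply(1:100, function(s) {
    tr <- generateSpecies(syntheticConfig(seed = 1000 + s))
    set.seed(2000 + s)
    fam <- rnorm(30, 0, sqrt(0.002))
    tr$elongation <- 1.37 + fam[as.integer(factor(tr$family))] +
      rnorm(nrow(tr), 0, sqrt(0.004))
    fit <- fitRandomIntercept(tr)
    c(abs(fit@varGroup - 0.002) / 0.002, abs(fit@varResid - 0.004) / 0.004)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.5)
  expect_lt(median(errs[, 2]), 0.5)
})

test_that("returned REML optimum dominates random variance-ratio probes", {
  tr <- generateSpecies(syntheticConfig(seed = 12))
  set.seed(12)
  fam <- rnorm(30, 0, 0.03)
  tr$elongation <- tr$elongation + fam[as.integer(factor(tr$family))]
  fit <- fitRandomIntercept(tr)
  probes <- exp(runif(50, -10, 4))
  crit <- vapply(probes, function(g) remlCriterion(tr, g), numeric(1))
  expect_gte(fit@logReml + 1e-6, max(crit))
})
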