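test_that("paired TOST declares equivalence for tiny differences", {
  d <- c(0.001, -0.002, 0.000, 0.001, -0.001)
  ts <- tost_paired(d, rep(0, 5), bound_mm = 0.05)
  expect_true(ts$equivalent)
  expect_lt(ts$p_tost, 0.001)
  # closed-form t CDF check
  se <- sd(d) / sqrt(5)
  expect_equal(ts$p_lower, pt((mean(d) + 0.05) / se, 4, lower.tail = FALSE))
  expect_equal(ts$p_upper, pt((mean(d) - 0.05) / se, 4))
})

test_that("TOST at the bound and far outside the bound behaves as stated", {
  x <- c(0.04, 0.05, 0.06)
  ts <- tost_paired(x, rep(0, 3), bound_mm = 0.05)
  expect_equal(ts$p_upper, 0.5)          # t statistic exactly 0 under H02
  expect_false(ts$equivalent)
  far <- tost_paired(rep(0.5, 4) + c(0, 0.001, -0.001, 0.002), rep(0, 4),
                     bound_mm = 0.05)
  expect_gt(far$p_tost, 0.999)
  expect_error(tost_paired(1:2, 1:2, 0.05), "n >= 3")
})

test_that("TOST is symmetric in its arguments and monotone in the bound", {
  set.seed(10)
  x <- rnorm(8, 0.01, 0.02); y <- rnorm(8, 0, 0.02)
  a <- tost_paired(x, y, 0.05)$p_tost
  b <- tost_paired(y, x, 0.05)$p_tost
  expect_equal(a, b)
  wide <- tost_paired(x, y, 0.10)$p_tost
  expect_lte(wide, a)
})

test_that("degenerate zero-variance TOST reports the stated verdicts", {
  inside <- tost_paired(rep(0.01, 5), rep(0, 5), 0.05)
  expect_true(inside$degenerate)
  expect_true(inside$equivalent)
  expect_equal(inside$p_tost, 0)
  outside <- tost_paired(rep(0.2, 5), rep(0, 5), 0.05)
  expect_false(outside$equivalent)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.4, m = 3), 1.0)
  expect_equal(bonferroni_adjust(0.2), 0.2)  # m = 1 identity
})

test_that("model passes when equivalent to at least two raters", {
  bones <- paste0("b", 1:6)
  base <- seq(0.55, 0.68, length.out = 6)
  tab <- rbind(
    data.frame(bone_id = bones, source = "model", value_mm = base),
    data.frame(bone_id = bones, source = "r1", value_mm = base + 0.2),
    data.frame(bone_id = bones, source = "r2", value_mm = base + 0.001),
    data.frame(bone_id = bones, source = "r3", value_mm = base - 0.002))
  res <- model_vs_raters_equivalence(tab)
  expect_equal(res$family_size, 6)  # all pairs among 4 sources
  expect_true(res$pass)
  expect_equal(res$n_equivalent_raters, 2)
  ident <- rbind(
    data.frame(bone_id = bones, source = "model", value_mm = base),
    data.frame(bone_id = bones, source = "r1", value_mm = base + 1e-4),
    data.frame(bone_id = bones, source = "r2", value_mm = base - 1e-4),
    data.frame(bone_id = bones, source = "r3", value_mm = base + 2e-4))
  res2 <- model_vs_raters_equivalence(ident)
  expect_equal(res2$n_equivalent_raters, 3)
  expect_error(model_vs_raters_equivalence(
    tab[tab$source %in% c("model", "r1"), ]), "2 raters")
})

test_that("unbiased model passes the rater equivalence gate almost always", {
  set.seed(2024)
  passes <- vapply(1:200, function(i) {
    truth <- runif(5, 0.5, 0.7)
    tab <- do.call(rbind, lapply(c("model", "r1", "r2", "r3"), function(s)
      data.frame(bone_id = paste0("b", 1:5), source = s,
                 value_mm = truth + rnorm(5, 0, 0.01))))
    model_vs_raters_equivalence(tab)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("ICC(2,1) equals 1 for identical raters and matches lme4", {
  m <- matrix(rep(c(1, 2, 3, 4, 5, 6), 3), ncol = 3)
  expect_equal(icc(m), 1)
  set.seed(9)
  n <- 12; k <- 3
  mat <- outer(rnorm(n, 0, 2), rnorm(k, 0, 0.5), `+`) +
    matrix(rnorm(n * k, 0, 0.7), n, k)
  df <- data.frame(y = as.vector(mat), s = factor(rep(1:n, k)),
                   r = factor(rep(1:k, each = n)))
  fit <- lme4::lmer(y ~ 1 + (1 | s) + (1 | r), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_lmm <- vc$vcov[vc$grp == "s"] / sum(vc$vcov)
  expect_equal(icc(mat), icc_lmm, tolerance = 1e-4)
})

test_that("ICC of independent raters is near zero; errors are raised", {
  set.seed(3)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc(noise)), 0.1)
  expect_error(icc(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc(matrix(1:3, 1, 3)), "2 subjects")
})

test_that("one-way ANOVA F matches the hand sum-of-squares computation", {
  gr <- list(g1 = c(6, 8, 4, 5, 3, 4), g2 = c(8, 12, 9, 11, 6, 8),
             g3 = c(13, 9, 11, 8, 7, 12))
  at <- anova_tukey(gr)
  v <- unlist(gr); gm <- mean(v)
  ssb <- sum(vapply(gr, function(x) length(x) * (mean(x) - gm)^2, 1))
  ssw <- sum(vapply(gr, function(x) sum((x - mean(x))^2), 1))
  expect_equal(at$F, (ssb / 2) / (ssw / 15))
  expect_equal(at$df, c(2, 15))
  expect_true(!is.null(at$pairwise))  # omnibus significant here
  expect_true(all(c("shapiro_p", "levene_p") %in% names(at)))
})

test_that("identical constant groups produce F = 0 and no post hoc", {
  at <- anova_tukey(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(at$F, 0)
  expect_null(at$pairwise)
})

test_that("post hoc tests are gated on the omnibus result", {
  set.seed(11)
  g <- list(a = rnorm(6), b = rnorm(6, 0.1), c = rnorm(6, -0.1))
  at <- anova_tukey(g)
  if (at$p_omnibus > 0.05) expect_null(at$pairwise)
  g2 <- list(a = rnorm(6), b = rnorm(6, 10))
  expect_false(is.null(anova_tukey(g2)$pairwise))
})

test_that("Games-Howell equals Tukey for two equal-variance equal-n groups", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(4.5, 5.5, 6.5, 7.5, 8.5))
  at <- anova_tukey(g)
  gh <- games_howell(g)
  expect_lt(abs(at$pairwise$p - gh$p), 1e-6)
  ident <- games_howell(list(a = c(1, 2, 3), b = c(1.01, 2.01, 2.99)))
  expect_gt(ident$p, 0.99)
  expect_error(games_howell(list(a = c(1, 1), b = c(2, 2))), "zero variance")
})

test_that("the significance color code follows the caption intervals", {
  expect_equal(significance_color(0.2), "blue")
  expect_equal(significance_color(0.0500001), "blue")
  expect_equal(significance_color(0.05), "light_blue")
  expect_equal(significance_color(0.0100001), "light_blue")
  expect_equal(significance_color(0.01), "orange")
  expect_equal(significance_color(0.00999), "orange")
  expect_equal(significance_color(0.001), "red")
  expect_equal(significance_color(0.0001), "red")
})

test_that("depth comparison colors a constructed change point correctly", {
  set.seed(42)
  bins <- 0:49
  mk <- function(group, shift_from) {
    do.call(rbind, lapply(1:5, function(b) {
      val <- rnorm(50, 10, 0.4)
      if (!is.na(shift_from)) val[bins >= shift_from] <-
          val[bins >= shift_from] + 8
      data.frame(bone_id = paste0(group, b), group = group, bin = bins,
                 value = val)
    }))
  }
  prof <- rbind(mk("ctrl", NA), mk("treat", 25))
  res <- depth_profile_comparison(prof)
  cols <- res$colors
  early <- cols$color[cols$bin < 23]
  late <- cols$color[cols$bin >= 27]
  expect_true(mean(early == "blue") > 0.9)
  expect_true(all(late == "red"))
  # identical groups: everything blue
  prof2 <- rbind(mk("a", NA), mk("b", NA))
  res2 <- depth_profile_comparison(prof2)
  expect_true(mean(res2$colors$color == "blue") > 0.9)
  # mismatched grids are rejected
  bad <- prof[!(prof$bone_id == "ctrl1" & prof$bin == 0), ]
  expect_error(depth_profile_comparison(bad), "grid")
})
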