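#' Paired TOST equivalence test
#'
#' Two one-sided t-tests on paired differences `d = x - y` against the
#' hypotheses H01: mean(d) <= -bound and H02: mean(d) >= +bound. Equivalence
#' (the mean difference lies significantly inside the +/- bound interval) is
#' declared when `p_tost = max(p_lower, p_upper) <= alpha`. Any multiplicity
#' correction is the caller's responsibility.
#'
#' @param x,y paired samples (same bones measured by two sources), n >= 3.
#' @param bound_mm equivalence bound (same units as the data; default
#'   0.05 mm, the standard margin for landmark positions).
#' @param alpha significance level.
#' @return List with `p_lower`, `p_upper`, `p_tost`, `equivalent`,
#'   `mean_diff`, `sd_diff`, `n`, and `degenerate` (TRUE when the
#'   differences have zero variance, in which case p is reported as 0 or 1
#'   according to whether the constant difference lies inside the bounds).
#' @export
tost_paired <- function(x, y, bound_mm = 0.05, alpha = 0.05) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  d <- x - y
  n <- length(d)
  if (n < 3) stopf("TOST requires n >= 3 pairs")
  if (bound_mm <= 0) stopf("equivalence bound must be > 0")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    inside <- abs(m) < bound_mm
    p <- if (inside) 0 else 1
    return(list(p_lower = p, p_upper = p, p_tost = p,
                equivalent = inside && p <= alpha,
                mean_diff = m, sd_diff = 0, n = n, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t_lower <- (m + bound_mm) / se   # H01: mean <= -bound, reject for large t
  t_upper <- (m - bound_mm) / se   # H02: mean >= +bound, reject for small t
  p_lower <- pt(t_lower, df = n - 1, lower.tail = FALSE)
  p_upper <- pt(t_upper, df = n - 1, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  list(p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
       equivalent = p_tost <= alpha, mean_diff = m, sd_diff = s, n = n,
       degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the family size (defaults to the number
#' of p-values supplied).
#'
#' @param pvals numeric vector of p-values.
#' @param m family size.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (m < 1) stopf("family size must be >= 1")
  pmin(1, m * pvals)
}

#' Equivalence configuration
#'
#' @param bound_mm equivalence bound (default 0.05 mm).
#' @param alpha significance level.
#' @param min_agreeing_raters the model passes when equivalent to at least
#'   this many raters (default 2).
#' @return An `equivalence_config`.
#' @export
equivalence_config <- function(bound_mm = 0.05, alpha = 0.05,
                               min_agreeing_raters = 2L) {
  if (bound_mm <= 0) stopf("bound must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  structure(list(bound_mm = bound_mm, alpha = alpha,
                 correction = "bonferroni",
                 min_agreeing_raters = as.integer(min_agreeing_raters)),
            class = "equivalence_config")
}

#' Model-versus-raters equivalence verdict
#'
#' Runs all pairwise paired TOSTs among the sources (raters and model) of a
#' landmark, Bonferroni-corrects over that comparison family, and declares
#' the model equivalent when it is equivalent to at least
#' `min_agreeing_raters` raters.
#'
#' @param table data frame with columns `bone_id`, `source`, `value_mm`;
#'   one source must be named `"model"`, the others are raters.
#' @param config an [equivalence_config()].
#' @return List with `pairwise` (data frame of all source pairs with raw and
#'   adjusted p), `n_equivalent_raters`, `pass`.
#' @export
model_vs_raters_equivalence <- function(table, config = equivalence_config()) {
  need <- c("bone_id", "source", "value_mm")
  if (!all(need %in% names(table)))
    stopf("table must have columns %s", paste(need, collapse = ", "))
  sources <- unique(table$source)
  raters <- setdiff(sources, "model")
  if (length(raters) < 2) stopf("need at least 2 raters besides the model")
  wide <- split(table, table$source)
  get_vals <- function(src, bones) {
    df <- wide[[src]]
    df$value_mm[match(bones, df$bone_id)]
  }
  bones <- sort(unique(table$bone_id))
  pairs <- utils::combn(sources, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    ts <- tost_paired(get_vals(pr[1], bones), get_vals(pr[2], bones),
                      bound_mm = config$bound_mm, alpha = config$alpha)
    data.frame(source_a = pr[1], source_b = pr[2], p_tost = ts$p_tost,
               mean_diff = ts$mean_diff, stringsAsFactors = FALSE)
  }))
  res$p_adj <- bonferroni_adjust(res$p_tost, m = nrow(res))
  res$equivalent <- res$p_adj <= config$alpha
  model_rows <- res$source_a == "model" | res$source_b == "model"
  n_eq <- sum(res$equivalent[model_rows])
  list(pairwise = res, n_equivalent_raters = n_eq,
       pass = n_eq >= config$min_agreeing_raters,
       family_size = nrow(res))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard mean-squares decomposition: with MSR the between-subject, MSC
#' the between-rater and MSE the residual mean squares over an n x k
#' subjects-by-raters matrix,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Intra-operator ICC is obtained by passing a subjects-by-repeats matrix
#' for one rater.
#'
#' @param ratings numeric matrix, subjects in rows, raters (or repeats) in
#'   columns; no missing cells.
#' @return The ICC estimate (a scalar in (-Inf, 1]).
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("ICC needs >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stopf("ICC requires complete ratings (no missing cells)")
  grand <- mean(ratings)
  if (all(ratings == grand)) stopf("zero total variance: ICC undefined")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' One-way ANOVA for a main group effect; when the omnibus test is
#' significant at `alpha`, Tukey's HSD pairwise comparisons are computed
#' (controlling the family-wise error rate); otherwise no post hoc tests are
#' emitted. Shapiro-Wilk normality (per group) and Levene homogeneity of
#' variance are reported as diagnostics only and never gate execution.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param alpha omnibus significance gate for post hoc testing.
#' @return List with `F`, `p_omnibus`, `df`, `pairwise` (data frame or
#'   `NULL`), `shapiro_p` (per group; NA for n < 3), `levene_p`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2)) stopf("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  if (var(values) == 0) {
    # no variation at all: no effect, nothing to test post hoc
    return(list(F = 0, p_omnibus = 1,
                df = c(length(groups) - 1L, length(values) - length(groups)),
                pairwise = NULL,
                shapiro_p = rep(NA_real_, length(groups)),
                levene_p = NA_real_))
  }
  fit <- aov(values ~ g)
  an <- anova(fit)
  shapiro_p <- vapply(groups, function(v) {
    if (length(v) >= 3 && sd(v) > 0) shapiro.test(v)$p.value else NA_real_
  }, numeric(1))
  levene_p <- tryCatch(
    car::leveneTest(values ~ g, center = mean)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  p_omni <- an[["Pr(>F)"]][1]
  pairwise <- NULL
  if (is.finite(p_omni) && p_omni <= alpha) {
    tk <- TukeyHSD(fit)$g
    pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                           p = tk[, "p adj"], row.names = NULL)
  }
  list(F = an[["F value"]][1], p_omnibus = p_omni,
       df = c(an[["Df"]][1], an[["Df"]][2]),
       pairwise = pairwise, shapiro_p = shapiro_p, levene_p = levene_p)
}

#' Games-Howell post hoc comparisons
#'
#' Welch-type pairwise statistics for unequal variances:
#' `t = (m_i - m_j) / sqrt(v_i/n_i + v_j/n_j)` with Welch-Satterthwaite
#' degrees of freedom, referred to the studentized-range distribution with a
#' sqrt(2) scaling. With two groups of equal size and equal sample variance
#' this coincides with Tukey's HSD.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return Data frame with `comparison`, `diff`, `t`, `df`, `p`.
#' @export
games_howell <- function(groups) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2)) stopf("each group needs n >= 2")
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    if (se2 == 0)
      stopf("zero variance in both groups of pair %s-%s", nm[i], nm[j])
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    p <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                lower.tail = FALSE)
    data.frame(comparison = paste(nm[j], nm[i], sep = "-"),
               diff = m[j] - m[i], t = tstat, df = df, p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Significance color code
#'
#' Maps p-values to the four-band color scheme used in depth-resolved
#' significance heatmaps: blue for p > 0.05 (not significant), light blue
#' for 0.01 < p <= 0.05, orange for 0.001 < p <= 0.01, red for p <= 0.001.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return Character vector of color names.
#' @export
significance_color <- function(p) {
  ifelse(p > 0.05, "blue",
         ifelse(p > 0.01, "light_blue",
                ifelse(p > 0.001, "orange", "red")))
}

#' Depth-resolved group comparison
#'
#' Per z-bin: one-way ANOVA over the groups; when significant, Games-Howell
#' pairwise comparisons, each mapped through the significance color code.
#' Bins where the omnibus test is not significant emit no pairwise tests and
#' are colored blue for every pair.
#'
#' @param profiles tidy data frame with columns `bone_id`, `group`, `bin`,
#'   `value` — one row per bone and bin, all on the identical bin grid.
#' @param alpha omnibus gate.
#' @return List with `per_bin` (data frame: bin, F, p_omnibus) and `colors`
#'   (data frame: bin, comparison, p, color).
#' @export
depth_profile_comparison <- function(profiles, alpha = 0.05) {
  need <- c("bone_id", "group", "bin", "value")
  if (!all(need %in% names(profiles)))
    stopf("profiles must have columns %s", paste(need, collapse = ", "))
  bins <- sort(unique(profiles$bin))
  grids <- split(profiles$bin, profiles$bone_id)
  ref <- sort(unique(grids[[1]]))
  for (g in grids)
    if (!identical(sort(unique(g)), ref))
      stopf("profiles are not on an identical bin grid")
  groups_all <- sort(unique(profiles$group))
  pair_names <- apply(utils::combn(groups_all, 2), 2,
                      function(pr) paste(pr[2], pr[1], sep = "-"))
  per_bin <- list(); colors <- list()
  for (b in bins) {
    sub <- profiles[profiles$bin == b & !is.na(profiles$value), ]
    gl <- split(sub$value, factor(sub$group, levels = groups_all))
    gl <- gl[lengths(gl) >= 2]
    if (length(gl) < 2)
      stopf("bin %s has fewer than 2 groups with n >= 2", b)
    at <- anova_tukey(gl, alpha = alpha)
    per_bin[[length(per_bin) + 1L]] <-
      data.frame(bin = b, F = at$F, p_omnibus = at$p_omnibus)
    if (is.finite(at$p_omnibus) && at$p_omnibus <= alpha) {
      gh <- games_howell(gl)
      colors[[length(colors) + 1L]] <-
        data.frame(bin = b, comparison = gh$comparison, p = gh$p,
                   color = significance_color(gh$p),
                   stringsAsFactors = FALSE)
    } else {
      colors[[length(colors) + 1L]] <-
        data.frame(bin = b, comparison = pair_names, p = NA_real_,
                   color = "blue", stringsAsFactors = FALSE)
    }
  }
  list(per_bin = do.call(rbind, per_bin), colors = do.call(rbind, colors))
}

#' Plot a depth-resolved significance heatmap
#'
#' Renders the group-pair by bin color matrix produced by
#' [depth_profile_comparison()] as horizontal significance bars.
#'
#' @param colors the `colors` element of [depth_profile_comparison()].
#' @param bin_width_mm bin width for the x axis (default 0.020).
#' @param main plot title.
#' @return Invisibly, the color matrix used.
#' @export
plot_significance_bars <- function(colors, bin_width_mm = 0.020,
                                   main = "") {
  pal <- c(blue = "#2166ac", light_blue = "#92c5de", orange = "#f4a582",
           red = "#b2182b")
  comps <- unique(colors$comparison)
  bins <- sort(unique(colors$bin))
  z <- matrix("blue", length(bins), length(comps),
              dimnames = list(bins, comps))
  for (r in seq_len(nrow(colors)))
    z[as.character(colors$bin[r]), colors$comparison[r]] <- colors$color[r]
  graphics::plot(NULL, xlim = range(bins + 1) * bin_width_mm,
                 ylim = c(0, length(comps)), xlab = "depth (mm)",
                 ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = seq_along(comps) - 0.5, labels = comps, las = 1,
                 cex.axis = 0.7)
  for (ci in seq_along(comps))
    graphics::rect(bins * bin_width_mm, ci - 0.9,
                   (bins + 1) * bin_width_mm, ci - 0.1,
                   col = pal[z[, ci]], border = NA)
  invisible(z)
}
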