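# Rank-based statistical layer: two-sample Wilcoxon rank-sum tests with
# bootstrap median-difference effect sizes, Kruskal-Wallis multi-group
# tests, and Dunn's post-hoc z tests with Benjamini-Hochberg adjustment.

stat_result <- function(comparison, method, statistic, p_value,
                        effect_size = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, adjusted_p = NA_real_,
                        n1 = NA_integer_, n2 = NA_integer_,
                        seed = NA_integer_) {
  out <- data.frame(comparison = comparison, method = method,
                    statistic = statistic, p_value = p_value,
                    effect_size = effect_size, ci_low = ci_low,
                    ci_high = ci_high, adjusted_p = adjusted_p,
                    n1 = n1, n2 = n2, seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-values are computed by the exact rank-sum distribution when the
#' combined sample size is at most 12 and there are no ties (`mode =
#' "auto"`); otherwise the tie-corrected normal approximation with
#' continuity correction is used. Ties always force the approximation, even
#' under `mode = "exact"` (with a warning). When every value in both groups
#' is identical the test is degenerate: p = 1 is returned with a warning.
#'
#' @param x,y Numeric samples (each non-empty; `NA`s dropped).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param comparison Label stored in the result row.
#' @return A one-row `stat_result` data frame with the rank-sum statistic
#'   `W`, the two-sided p-value and the group sizes.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx"),
                              comparison = "x vs y") {
  mode <- match.arg(mode)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("degenerate data: all values identical in both groups; p = 1")
    return(stat_result(comparison, "wilcoxon rank-sum (degenerate)",
                       statistic = n1 * n2 / 2, p_value = 1,
                       n1 = n1, n2 = n2))
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
    auto = (n1 + n2 <= 12) && !ties,
    exact = {
      if (ties) warning("ties present: falling back to the corrected normal approximation")
      !ties
    },
    approx = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = use_exact,
                                            correct = TRUE))
  stat_result(comparison,
              if (use_exact) "wilcoxon rank-sum (exact)"
              else "wilcoxon rank-sum (normal approx.)",
              statistic = unname(wt$statistic),
              p_value = min(1, wt$p.value), n1 = n1, n2 = n2)
}

#' Bootstrap median difference with percentile CI
#'
#' Effect size `median(x) - median(y)` with a percentile 95% interval of the
#' bootstrap distribution of median differences: each group is resampled
#' with replacement `n_boot` times under one fixed seed, so published
#' intervals are replayable.
#'
#' @param x,y Numeric samples (each of size >= 2; `NA`s dropped).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `effect`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#'   `ci_low <= ci_high` always holds; under heavy skew a percentile
#'   interval need not be centred on the point estimate.
#' @export
bootstrap_median_diff <- function(x, y, n_boot = 10000, seed = 1,
                                  conf = 0.95) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("insufficient data: both groups need at least 2 values")
  }
  d <- with_seed(seed, {
    bx <- matrix(sample(x, n1 * n_boot, replace = TRUE), nrow = n1)
    by <- matrix(sample(y, n2 * n_boot, replace = TRUE), nrow = n2)
    apply(bx, 2, stats::median) - apply(by, 2, stats::median)
  })
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(d, c(alpha, 1 - alpha)))
  list(effect = stats::median(x) - stats::median(y),
       ci_low = qs[1], ci_high = qs[2], n_boot = n_boot, seed = seed)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-squared p-value on k - 1 degrees of
#' freedom.
#'
#' @param groups Named or unnamed list of at least two non-empty numeric
#'   samples.
#' @param comparison Label stored in the result row.
#' @return A one-row `stat_result` with the H statistic and p-value.
#' @export
kruskal_wallis <- function(groups, comparison = "all groups") {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (sum(lengths(groups) > 0) < 2) {
    stop("need at least 2 non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    warning("degenerate data: all values identical across groups; H = 0, p = 1")
    return(stat_result(comparison, "kruskal-wallis (degenerate)",
                       statistic = 0, p_value = 1,
                       n1 = length(values), n2 = length(groups)))
  }
  kt <- stats::kruskal.test(values, g)
  stat_result(comparison, "kruskal-wallis",
              statistic = unname(kt$statistic),
              p_value = unname(kt$p.value),
              n1 = length(values), n2 = length(groups))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled mid-rank means of a Kruskal-Wallis
#' analysis, with the usual tie correction, two-sided p-values, and
#' Benjamini-Hochberg step-up adjustment across all pairs of the analysis
#' (the adjustment family is the post-hoc family, not anything wider). When
#' the pooled sample is constant every pair is reported with p = 1.
#'
#' @param groups Named list of at least two non-empty numeric samples; names
#'   default to `g1, g2, ...`.
#' @param adjust Adjustment method; only `"bh"` is offered.
#' @return A `stat_result` data frame with one row per pair, carrying the z
#'   statistic, raw and BH-adjusted p-values (`adjusted_p >= p_value`
#'   always).
#' @export
dunn_posthoc <- function(groups, adjust = "bh") {
  adjust <- match.arg(adjust, "bh")
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  N <- length(values)
  rk <- rank(values)                       # mid-ranks
  rbar <- tapply(rk, gl, mean)
  n <- tapply(rk, gl, length)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    num <- rbar[[a]] - rbar[[b]]
    den2 <- s2 * (1 / n[[a]] + 1 / n[[b]])
    z <- if (den2 <= 0 || num == 0) 0 else num / sqrt(den2)
    p <- if (den2 <= 0) 1 else 2 * stats::pnorm(-abs(z))
    stat_result(paste(a, "vs", b), "dunn post-hoc (z)",
                statistic = z, p_value = min(1, p),
                effect_size = stats::median(groups[[a]]) -
                  stats::median(groups[[b]]),
                n1 = n[[a]], n2 = n[[b]])
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Compare a behavioural measure across groups
#'
#' Dispatcher for the standard design of plate and tracking studies: with
#' two groups it runs the Wilcoxon rank-sum test plus the bootstrap
#' median-difference effect size; with more it runs Kruskal-Wallis followed
#' by Dunn's post-hoc pairs with BH adjustment. Rows are flagged
#' significant at `alpha` on the adjusted p-value where one exists, the raw
#' p-value otherwise. A single group yields an empty table with a notice.
#'
#' @param data Data frame holding one numeric measure and a group label.
#' @param value Name of the measure column (e.g. `"ci"`, `"median_speed"`,
#'   `"head_swinging_index"`, `"pirouette_rate"`).
#' @param group Name of the grouping column.
#' @param alpha Significance level for the flag (default 0.05).
#' @param n_boot,seed Bootstrap settings for the two-group effect size.
#' @return A `stat_result` data frame with a logical `significant` column.
#' @export
compare_conditions <- function(data, value, group, alpha = 0.05,
                               n_boot = 10000, seed = 1) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  v <- as.numeric(data[[value]])
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  groups <- split(v, g)
  if (length(groups) < 2) {
    message("fewer than 2 groups: nothing to compare")
    out <- stat_result("none", "none", NA_real_, NA_real_)[0, , drop = FALSE]
    out$significant <- logical(0)
    class(out) <- c("stat_result", "data.frame")
    return(out)
  }
  out <- if (length(groups) == 2) {
    nm <- names(groups)
    res <- wilcoxon_rank_sum(groups[[1]], groups[[2]],
                             comparison = paste(nm[1], "vs", nm[2]))
    bs <- bootstrap_median_diff(groups[[1]], groups[[2]], n_boot = n_boot,
                                seed = seed)
    res$effect_size <- bs$effect
    res$ci_low <- bs$ci_low
    res$ci_high <- bs$ci_high
    res$seed <- seed
    res
  } else {
    rbind(kruskal_wallis(groups), dunn_posthoc(groups))
  }
  p_flag <- ifelse(is.na(out$adjusted_p), out$p_value, out$adjusted_p)
  out$significant <- p_flag < alpha
  class(out) <- c("stat_result", "data.frame")
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %d comparison(s)\n", nrow(x)))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
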