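test_that("exact Wilcoxon matches enumeration on the textbook example", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)                       # 2/20 assignments
  expect_equal(res$p_value, enum_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  expect_match(res$method, "exact")
})

test_that("exact Wilcoxon equals the enumeration oracle on random no-tie samples", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, enum_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon symmetry, ties, and degenerate data are handled", {
  x <- c(1, 2, 3, 7); y <- c(2.5, 4, 6)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(y, x)$p_value)

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)                        # identical samples

  expect_warning(deg <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)),
                 "degenerate")
  expect_equal(deg$p_value, 1)

  expect_warning(tied <- wilcoxon_rank_sum(c(1, 2, 2), c(2, 3, 4),
                                           mode = "exact"),
                 "ties")
  expect_match(tied$method, "approx")
})

test_that("bootstrap median difference honours shifts, nulls, and seeds", {
  set.seed(5)
  x <- rnorm(30, sd = 0.1)
  b <- bootstrap_median_diff(x, x + 5, n_boot = 2000, seed = 4)
  expect_equal(b$effect, -5)
  expect_lt(b$ci_low, -5 + 0.2)
  expect_gt(b$ci_high, -5 - 0.2)
  expect_lte(b$ci_low, b$ci_high)

  b0 <- bootstrap_median_diff(x, x, n_boot = 2000, seed = 4)
  expect_equal(b0$effect, 0)
  expect_lte(b0$ci_low, 0)
  expect_gte(b0$ci_high, 0)

  again <- bootstrap_median_diff(x, x + 5, n_boot = 2000, seed = 4)
  expect_identical(b[c("ci_low", "ci_high")], again[c("ci_low", "ci_high")])
  expect_error(bootstrap_median_diff(x, 1), "at least 2")
})

test_that("Kruskal-Wallis matches the explicit rank-sum formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, kw_h_formula(groups))
  expect_equal(res$statistic, 32 / 7)                 # hand evaluation
  expect_equal(res$p_value,
               stats::pchisq(32 / 7, df = 2, lower.tail = FALSE))

  ident <- suppressWarnings(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(ident$statistic, 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("two-group Kruskal-Wallis agrees with the Wilcoxon approximation", {
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50, 0.3)
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_w <- wilcoxon_rank_sum(x, y, mode = "approx")$p_value
  expect_equal(p_kw, p_w, tolerance = 0.01)
})

test_that("Dunn post-hoc z matches a hand computation and BH is applied", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- dunn_posthoc(groups)
  expect_equal(nrow(res), 3)
  # hand formula, no ties: sigma^2 = N(N+1)/12 = 7.5; mean ranks 2, 5, 8
  z_ab <- (2 - 5) / sqrt(7.5 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic[res$comparison == "a vs b"], z_ab)
  expect_equal(res$p_value[res$comparison == "a vs b"],
               2 * stats::pnorm(-abs(z_ab)))
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_equal(res$adjusted_p, bh_stepup(res$p_value))

  flat <- dunn_posthoc(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_true(all(flat$adjusted_p == 1))
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("BH step-up reproduces the worked vector and is monotone", {
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03), method = "BH"),
               c(0.03, 0.04, 0.04))
  expect_equal(bh_stepup(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(2)
  p <- runif(20)
  adj <- bh_stepup(p)
  expect_equal(stats::p.adjust(p, method = "BH"), adj)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))  # order-preserving
})

test_that("compare_conditions dispatches by the number of groups", {
  set.seed(4)
  df2 <- data.frame(g = rep(c("a", "b"), each = 10),
                    v = c(rnorm(10), rnorm(10, 3)))
  r2 <- compare_conditions(df2, "v", "g", n_boot = 500, seed = 1)
  expect_equal(nrow(r2), 1)
  expect_match(r2$method, "wilcoxon")
  expect_false(is.na(r2$effect_size))
  expect_false(is.na(r2$ci_low))

  set.seed(9)
  df6 <- data.frame(g = rep(letters[1:6], each = 5), v = rnorm(30))
  r6 <- compare_conditions(df6, "v", "g")
  expect_equal(nrow(r6), 1 + choose(6, 2))            # KW + 15 Dunn pairs
  expect_true(all(!is.na(r6$adjusted_p[r6$method != "kruskal-wallis"])))

  df1 <- data.frame(g = "a", v = rnorm(5))
  expect_message(r1 <- compare_conditions(df1, "v", "g"), "fewer than 2")
  expect_equal(nrow(r1), 0)
})
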