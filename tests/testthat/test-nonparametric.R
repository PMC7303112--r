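test_that("exact Wilcoxon p-values equal exhaustive enumeration", {
  set.seed(10)
  for (n in 2:5) {
    for (m in 2:5) {
      x <- rnorm(n); y <- rnorm(m)  # continuous draws: no ties
      for (alt in c("two_sided", "less", "greater")) {
        got <- wilcoxon_rank_sum(x, y, alternative = alt)
        expect_identical(got$method, "exact")
        expect_equal(got$p_value, enum_wilcoxon_p(x, y, alt),
                     tolerance = 1e-12,
                     label = sprintf("n=%d m=%d alt=%s", n, m, alt))
      }
    }
  }
})

test_that("the separated three-vs-three case gives one-sided p = 1/20", {
  got <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(got$p_value, 0.05)
  expect_identical(got$method, "exact")
})

test_that("identical samples give two-sided p = 1", {
  got <- wilcoxon_rank_sum(c(3, 1, 2), c(1, 2, 3))
  expect_equal(got$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "invalid input")
})

test_that("exact and approximate Wilcoxon p agree for larger samples", {
  # exact two-sided p from the Mann-Whitney distribution function
  exact_two_sided <- function(w, n, m) {
    min(1, 2 * min(pwilcox(w, n, m), 1 - pwilcox(w - 1, n, m)))
  }
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9, 0.3)
    approx <- wilcoxon_rank_sum(x, y)  # n+m = 18 > 16 -> normal approx
    expect_identical(approx$method, "normal_approx")
    expect_lt(abs(approx$p_value -
                    exact_two_sided(approx$statistic, 9, 9)), 0.01)
  }
})

test_that("Kruskal-Wallis H matches the textbook rank formula", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  got <- kruskal_wallis(g)
  expect_equal(got$statistic, hand_kruskal_h(g))  # = 7.2 for this layout
  expect_equal(got$statistic, 7.2)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  set.seed(12)
  g2 <- list(a = rnorm(4), b = rnorm(5), c = rnorm(3))
  expect_equal(kruskal_wallis(g2)$statistic, hand_kruskal_h(g2),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis handles degenerate and invalid input", {
  expect_equal(kruskal_wallis(list(a = c(2, 2), b = c(2, 2)))$statistic, 0)
  expect_error(kruskal_wallis(list(a = 1:3)), "invalid input")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))),
               "invalid input")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(13)
  g <- list(a = runif(4, 1, 2), b = runif(4, 1.2, 2.2), c = runif(4, 1, 3))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))$statistic
  expect_equal(h1, h2)
  w1 <- wilcoxon_rank_sum(g$a, g$b)$p_value
  w2 <- wilcoxon_rank_sum(log(g$a), log(g$b))$p_value
  expect_equal(w1, w2)
})

test_that("Dunn z matches the hand-computed pooled-rank statistic", {
  # groups {1,4}, {2,5}, {3,6}: mean ranks 2.5, 3.5, 4.5; no ties;
  # variance core N(N+1)/12 = 3.5, se = sqrt(3.5 * (1/2 + 1/2))
  g <- list(a = c(1, 4), b = c(2, 5), c = c(3, 6))
  dn <- dunn_posthoc(g, adjust = "none")
  se <- sqrt(3.5)
  expect_equal(dn$z, c(-1, -2, -1) / se, tolerance = 1e-12)
  expect_equal(dn$p_raw, 2 * pnorm(-abs(c(-1, -2, -1) / se)),
               tolerance = 1e-12)
  expect_equal(dn$p_adjusted, dn$p_raw)
})

test_that("Dunn comparisons of identical groups give z = 0, p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  dn <- dunn_posthoc(g)
  ab <- dn[dn$group1 == "a" & dn$group2 == "b", ]
  expect_equal(ab$z, 0)
  expect_equal(ab$p_raw, 1)
})

test_that("adjusted Dunn p-values are never below the raw ones", {
  set.seed(14)
  for (i in 1:5) {
    g <- list(a = rnorm(3), b = rnorm(4, 1), c = rnorm(3, 2),
              d = rnorm(4, 0.5))
    for (meth in c("holm", "bonferroni", "BH")) {
      dn <- dunn_posthoc(g, adjust = meth)
      expect_true(all(dn$p_adjusted >= dn$p_raw - 1e-15))
    }
  }
})

test_that("Dunn with two groups falls back to a rank-sum test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_warning(dn <- dunn_posthoc(g), "post-hoc unnecessary")
  expect_equal(dn$p_raw, wilcoxon_rank_sum(g$a, g$b)$p_value)
})

test_that("the grouped comparison table covers the design's contrasts", {
  cfg <- sim_config(seed = 15, n_animals_per_group = 4)
  sim <- simulate_experiment(cfg)
  out <- run_pipeline(sim)
  st <- out$stats
  expect_true(all(c("kruskal_wallis", "dunn", "wilcoxon") %in% st$test))
  # one KW per substrate per quantity, one Wilcoxon per taxon per quantity
  expect_equal(sum(st$test == "kruskal_wallis"), 3 * 2)
  expect_equal(sum(st$test == "wilcoxon"), 3 * 3)
  expect_true(all(st$p_value > 0 & st$p_value <= 1))
})
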