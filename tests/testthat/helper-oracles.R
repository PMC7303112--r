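# Independent oracles used to freeze / cross-check expected values.

# Exhaustive-enumeration Wilcoxon rank-sum p-value (no ties assumed):
# enumerates all C(n+m, n) assignments of the pooled ranks to the first
# sample and computes tail probabilities of the Mann-Whitney W.
enum_wilcoxon_p <- function(x, y, alternative = "two_sided") {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  w_all <- colSums(matrix(combos, nrow = n)) - n * (n + 1) / 2
  p_less <- mean(w_all <= w_obs)
  p_greater <- mean(w_all >= w_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

# Textbook Kruskal-Wallis H (no tie correction; use on tie-free data only)
hand_kruskal_h <- function(samples) {
  n <- vapply(samples, length, 1L)
  big_n <- sum(n)
  rk <- rank(unlist(samples, use.names = FALSE))
  grp <- rep(seq_along(samples), n)
  rbar <- tapply(rk, grp, mean)
  12 / (big_n * (big_n + 1)) * sum(n * (rbar - (big_n + 1) / 2)^2)
}

# Noise-free simulation settings shared by the recovery tests
zero_noise <- function() {
  list(dic_sd = 0, doc_sd = 0, poc_sd = 0, delta_sd = 0, o2_sd = 0,
       foodchain_rel_sd = 0)
}
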