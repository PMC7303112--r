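#' Wilcoxon rank-sum test with explicit small-sample behaviour
#'
#' Two-sample rank-sum comparison as used for low-replicate flux data.
#' When the combined sample size is at most 16 and the data contain no ties,
#' the p-value is exact (enumeration over all \eqn{C(n+m, n)} rank
#' assignments); otherwise mid-ranks with the tie-corrected,
#' continuity-corrected normal approximation are used. The reported
#' statistic is the Mann-Whitney W of the first sample.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative One of `"two_sided"`, `"less"`, `"greater"`.
#' @return List with `statistic`, `p_value` and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y)) {
    stop("invalid input: both samples must be non-empty and free of NA",
         call. = FALSE)
  }
  alt_r <- switch(alternative, two_sided = "two.sided", less = "less",
                  greater = "greater")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 16L) && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt_r, exact = use_exact,
                       correct = TRUE)
  )
  list(statistic = unname(res$statistic),
       p_value = res$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom. H is zero when all pooled observations are
#' identical, and invariant under strictly monotone transforms of the data.
#'
#' @param samples Named list of numeric vectors, one per group; at least two
#'   groups, each non-empty, total n >= 3.
#' @return List with `statistic` (H), `p_value` and `df`.
#' @examples
#' kruskal_wallis(list(a = c(1, 5, 8), b = c(2, 6, 9), c = c(3, 7, 10)))
#' @export
kruskal_wallis <- function(samples) {
  check_grouped(samples, min_groups = 2L)
  n <- vapply(samples, length, 1L)
  if (sum(n) < 3L) stop("invalid input: total n must be >= 3", call. = FALSE)
  values <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), n))
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(samples) - 1L))
  }
  res <- stats::kruskal.test(values, g)
  list(statistic = unname(res$statistic),
       p_value = res$p.value,
       df = unname(res$parameter))
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from pooled mid-rank mean differences with the
#' tie-corrected variance
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' and two-sided normal p-values, adjusted for multiple comparisons
#' (Holm by default).
#'
#' @param samples Named list of numeric vectors; at least three groups (with
#'   two groups a rank-sum test is the appropriate comparison, and the
#'   function falls back to it with a warning).
#' @param adjust Adjustment method passed to [stats::p.adjust()];
#'   default `"holm"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @examples
#' dunn_posthoc(list(a = c(1, 5, 8), b = c(2, 6, 9), c = c(30, 70, 100)))
#' @export
dunn_posthoc <- function(samples, adjust = "holm") {
  check_grouped(samples, min_groups = 2L)
  if (length(samples) < 3L) {
    warning("fewer than 3 groups: post-hoc unnecessary, falling back to a ",
            "Wilcoxon rank-sum test", call. = FALSE)
    w <- wilcoxon_rank_sum(samples[[1L]], samples[[2L]])
    return(data.frame(group1 = names(samples)[1L],
                      group2 = names(samples)[2L],
                      z = NA_real_, p_raw = w$p_value,
                      p_adjusted = w$p_value,
                      stringsAsFactors = FALSE))
  }
  n <- vapply(samples, length, 1L)
  big_n <- sum(n)
  values <- unlist(samples, use.names = FALSE)
  rk <- rank(values)  # mid-ranks
  grp <- rep(seq_along(samples), n)
  rbar <- tapply(rk, grp, mean)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (big_n - 1))
  var_core <- big_n * (big_n + 1) / 12 - tie_term
  pairs <- utils::combn(length(samples), 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(var_core * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = names(samples)[pairs[1L, ]],
             group2 = names(samples)[pairs[2L, ]],
             z = as.numeric(z),
             p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = adjust),
             stringsAsFactors = FALSE)
}

check_grouped <- function(samples, min_groups) {
  if (!is.list(samples) || length(samples) < min_groups) {
    stop("invalid input: need a list of >= ", min_groups, " groups",
         call. = FALSE)
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("invalid input: groups must be named", call. = FALSE)
  }
  if (any(vapply(samples, length, 1L) == 0L)) {
    stop("invalid input: every group must be non-empty", call. = FALSE)
  }
  invisible(samples)
}

#' Compare tracer fluxes across taxa and substrates
#'
#' Runs the statistical battery on a budget table: per substrate, a
#' Kruskal-Wallis test with Dunn post-hoc comparisons of a flux quantity
#' across taxa; per taxon, a Wilcoxon rank-sum comparison of the quantity
#' between substrates. Emits one tidy row per comparison.
#'
#' @param budget A budget data.frame containing at least the columns named
#'   by `quantity`, plus `taxon` and `substrate`.
#' @param quantity Column name of the flux to compare.
#' @param adjust Dunn adjustment method, default `"holm"`.
#' @return data.frame with columns `test`, `quantity`, `stratum`, `groups`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_flux_groups <- function(budget, quantity, adjust = "holm") {
  stopifnot(is.data.frame(budget),
            all(c(quantity, "taxon", "substrate") %in% names(budget)))
  out <- list()
  for (sub in unique(budget$substrate)) {
    d <- budget[budget$substrate == sub, ]
    groups <- split(d[[quantity]], d$taxon)
    groups <- groups[vapply(groups, length, 1L) > 0L]
    if (length(groups) >= 2L) {
      kw <- kruskal_wallis(groups)
      out[[length(out) + 1L]] <- data.frame(
        test = "kruskal_wallis", quantity = quantity, stratum = sub,
        groups = paste(names(groups), collapse = "|"),
        statistic = kw$statistic, p_value = kw$p_value,
        p_adjusted = NA_real_, stringsAsFactors = FALSE)
      if (length(groups) >= 3L) {
        dn <- dunn_posthoc(groups, adjust = adjust)
        out[[length(out) + 1L]] <- data.frame(
          test = "dunn", quantity = quantity, stratum = sub,
          groups = paste(dn$group1, dn$group2, sep = "-"),
          statistic = dn$z, p_value = dn$p_raw,
          p_adjusted = dn$p_adjusted, stringsAsFactors = FALSE)
      }
    }
  }
  for (tx in unique(budget$taxon)) {
    d <- budget[budget$taxon == tx, ]
    subs <- split(d[[quantity]], d$substrate)
    subs <- subs[vapply(subs, length, 1L) > 0L]
    if (length(subs) == 2L) {
      w <- wilcoxon_rank_sum(subs[[1L]], subs[[2L]])
      out[[length(out) + 1L]] <- data.frame(
        test = "wilcoxon", quantity = quantity, stratum = tx,
        groups = paste(names(subs), collapse = "|"),
        statistic = w$statistic, p_value = w$p_value,
        p_adjusted = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(test = character(), quantity = character(),
                      stratum = character(), groups = character(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
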