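# Summary statistics over per-pair selection results: the age trend
# (Spearman correlation of a rate or the neutral fraction with age rank) and
# the between-lineage comparison (Wilcoxon rank-sum).

#' Spearman trend of a selection statistic with age rank
#'
#' Correlates Ka, Ks, omega, or the per-rank neutral fraction with the
#' numeric age rank. For per-pair values every pair contributes one
#' observation (midranks for ties, t-approximation p-value); for the neutral
#' fraction one value per rank is used and the p-value is exact for up to 9
#' ranks.
#'
#' @param results Data frame from [selection_scan()] (needs `age_rank` plus
#'   the requested value column, and `neutral` for the fraction).
#' @param value One of "Ka", "Ks", "omega", "neutral_fraction".
#' @param exclude_ranks Age-rank labels dropped before the trend is computed
#'   (default "A": the ancient class is not part of the within-family ladder).
#' @return List with `rho`, `p_value`, `n`, `value`.
#' @export
age_trend <- function(results, value = c("Ka", "Ks", "omega", "neutral_fraction"),
                      exclude_ranks = "A") {
  value <- match.arg(value)
  res <- results[!is.na(results$age_rank) &
    !(results$age_rank %in% c(exclude_ranks, "non_ranked", "not_applicable")), ]
  if ("converged" %in% names(res)) {
    res <- res[res$converged, ]
  }
  rank_num <- suppressWarnings(as.numeric(res$age_rank))
  if (anyNA(rank_num)) {
    stopf("non-numeric age ranks remain after exclusion: %s",
      paste(unique(res$age_rank[is.na(rank_num)]), collapse = ", "))
  }
  if (value == "neutral_fraction") {
    frac <- tapply(res$neutral, rank_num, mean)
    x <- as.numeric(names(frac))
    y <- as.numeric(frac)
  } else {
    x <- rank_num
    y <- res[[value]]
    keep <- is.finite(y)
    x <- x[keep]
    y <- y[keep]
  }
  if (length(unique(x)) < 3L) {
    stopf("age trend needs >= 3 distinct age ranks, got %d", length(unique(x)))
  }
  if (length(unique(y)) < 2L) {
    stopf("age trend undefined: all values identical")
  }
  exact <- length(x) <= 9L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  list(
    rho = unname(ct$estimate), p_value = ct$p.value,
    n = length(x), value = value
  )
}

#' Compare a selection statistic between two lineages
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test of a per-pair statistic
#' between two sets of results (e.g. Aly-Ath vs Osa-Obr orthologous pairs);
#' exact when samples are small and untied, otherwise the normal
#' approximation with tie correction.
#'
#' @param results_a,results_b Data frames from [selection_scan()], or numeric
#'   vectors of the statistic itself.
#' @param value Column compared when data frames are supplied.
#' @return List with `statistic` (Mann-Whitney U of sample a), `p_value`,
#'   `direction` ("a_greater", "b_greater" or "equal"), `n_a`, `n_b`.
#' @export
lineage_compare <- function(results_a, results_b, value = "omega") {
  pull <- function(r) {
    if (is.data.frame(r)) {
      v <- r[[value]]
      if ("converged" %in% names(r)) v <- v[r$converged]
      v[is.finite(v)]
    } else {
      as.numeric(r)
    }
  }
  a <- pull(results_a)
  b <- pull(results_b)
  if (length(a) == 0L || length(b) == 0L) {
    stopf("both samples must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  med_a <- stats::median(a)
  med_b <- stats::median(b)
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    direction = if (med_a > med_b) "a_greater" else if (med_a < med_b) "b_greater" else "equal",
    n_a = length(a), n_b = length(b)
  )
}
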