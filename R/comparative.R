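# Between-plant-family comparative statistics: per-family size comparison by
# Wilcoxon rank-sum, accessory-domain enrichment by two-sample Student's
# t-test, and hierarchical clustering of species x family count profiles
# (Manhattan distance, Ward linkage).

#' Compare gene-family sizes between two species groups
#'
#' For each family (column of the count matrix), a two-sided Wilcoxon
#' rank-sum test between the two groups of species; significant families are
#' labeled with the group of larger mean count.
#'
#' @param counts Matrix species x family of locus counts.
#' @param groups Named character vector species -> group label (exactly two
#'   labels, each with at least two species).
#' @param alpha Significance threshold (default 0.05).
#' @param p_adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()]; default "none" (nominal thresholds).
#' @return Data frame with one row per family: means per group, `statistic`
#'   (rank-sum W), `p_value`, `significant`, `enriched_in`.
#' @export
family_size_compare <- function(counts, groups, alpha = 0.05,
                                p_adjust = "none") {
  groups <- groups[rownames(counts)]
  if (anyNA(groups)) stopf("every species needs a group label")
  lv <- unique(unname(groups))
  if (length(lv) != 2L) stopf("exactly two groups required, got %d", length(lv))
  if (any(table(groups) < 2L)) stopf("each group needs at least 2 species")
  rows <- lapply(colnames(counts), function(fam) {
    x <- counts[groups == lv[1L], fam]
    y <- counts[groups == lv[2L], fam]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1 # fully tied samples carry no signal
    data.frame(
      category = fam,
      mean_group1 = mean(x), mean_group2 = mean(y),
      statistic = unname(wt$statistic), p_value = p,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_value_adj <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_value_adj < alpha
  res$enriched_in <- ifelse(
    !res$significant, NA_character_,
    ifelse(res$mean_group1 > res$mean_group2, lv[1L], lv[2L])
  )
  attr(res, "group_labels") <- lv
  res
}

#' Accessory-domain enrichment between species groups
#'
#' For each (family, accessory domain) category with counts per genome, a
#' two-sample Student's t-test (pooled variance) between the two species
#' groups. Categories absent from every genome are skipped; zero-variance
#' categories with equal means are reported as non-significant.
#'
#' @param counts Matrix species x category of per-genome accessory-domain
#'   locus counts (e.g. category = "FBX:Kelch").
#' @param groups Named character vector species -> group label (two labels).
#' @param alpha Significance threshold (default 0.01).
#' @param p_adjust Correction method (default "none").
#' @return Data frame as in [family_size_compare()] with t statistics.
#' @export
domain_enrichment <- function(counts, groups, alpha = 0.01, p_adjust = "none") {
  groups <- groups[rownames(counts)]
  if (anyNA(groups)) stopf("every species needs a group label")
  lv <- unique(unname(groups))
  if (length(lv) != 2L) stopf("exactly two groups required")
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  rows <- lapply(colnames(counts), function(cat) {
    x <- counts[groups == lv[1L], cat]
    y <- counts[groups == lv[2L], cat]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stat <- NA_real_
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(
      category = cat, mean_group1 = mean(x), mean_group2 = mean(y),
      statistic = stat, p_value = p, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_value_adj <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_value_adj < alpha
  res$enriched_in <- ifelse(
    !res$significant, NA_character_,
    ifelse(res$mean_group1 > res$mean_group2, lv[1L], lv[2L])
  )
  attr(res, "group_labels") <- lv
  res
}

#' Hierarchically cluster species and category count profiles
#'
#' Agglomerative clustering of both matrix axes with Manhattan distance and
#' Ward linkage ("ward.D", classical Ward on the unsquared distances),
#' mirroring heatmap-style two-way clustering of family-size profiles.
#'
#' @param counts Matrix species x category with at least 2 rows; a constant
#'   matrix is an error.
#' @return List with `species_tree`, `category_tree` (hclust objects; the
#'   category tree is `NULL` for a single column), and the corresponding
#'   leaf orders.
#' @export
cluster_profiles <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stopf("need at least 2 species rows")
  if (stats::sd(as.numeric(counts)) == 0) {
    stopf("constant count matrix cannot be clustered")
  }
  species_tree <- stats::hclust(
    stats::dist(counts, method = "manhattan"), method = "ward.D"
  )
  category_tree <- if (ncol(counts) >= 2L) {
    stats::hclust(
      stats::dist(t(counts), method = "manhattan"), method = "ward.D"
    )
  } else {
    NULL
  }
  list(
    species_tree = species_tree,
    category_tree = category_tree,
    species_order = rownames(counts)[species_tree$order],
    category_order = if (is.null(category_tree)) {
      colnames(counts)
    } else {
      colnames(counts)[category_tree$order]
    }
  )
}

#' Accessory-domain count matrix from family assignments
#'
#' Counts loci per genome carrying each accessory domain within each family
#' (categories named "family:domain"), the input to [domain_enrichment()].
#'
#' @param assignments Output of [assign_families()].
#' @param species_of Named character vector locus_id -> species.
#' @return Matrix species x "family:domain" counts.
#' @export
accessory_domain_counts <- function(assignments, species_of) {
  sp <- species_of[assignments$locus_id]
  if (anyNA(sp)) stopf("unknown species for some assigned loci")
  doms <- strsplit(assignments$subfamily_signature, ";", fixed = TRUE)
  n <- lengths(doms)
  long <- data.frame(
    species = rep(unname(sp), n),
    category = paste(rep(assignments$family, n), unlist(doms), sep = ":"),
    stringsAsFactors = FALSE
  )
  long <- long[nzchar(unlist(doms)), , drop = FALSE]
  species_levels <- sort(unique(unname(species_of)))
  tab <- table(
    factor(long$species, levels = species_levels),
    long$category
  )
  matrix(as.numeric(tab), nrow = length(species_levels),
         dimnames = list(species_levels, colnames(tab)))
}
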