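mk_counts <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("sp%d", seq_len(nrow(m)))
  m
}

two_groups <- function(n1, n2) {
  stats::setNames(
    rep(c("brassicaceae", "poaceae"), c(n1, n2)),
    sprintf("sp%d", seq_len(n1 + n2))
  )
}

test_that("family size comparison reproduces the exact rank-sum p-value", {
  counts <- cbind(FBX = c(10, 11, 12, 13, 14, 15, 1, 2, 3, 4, 5, 6))
  rownames(counts) <- sprintf("sp%d", 1:12)
  res <- family_size_compare(counts, two_groups(6, 6))
  expect_equal(res$p_value, 2 / choose(12, 6), tolerance = 1e-9)
  expect_true(res$significant)
  expect_equal(res$enriched_in, "brassicaceae")
})

test_that("identical count vectors are not significant", {
  counts <- cbind(FBX = rep(5, 8), RING = rep(c(3, 4), 4))
  rownames(counts) <- sprintf("sp%d", 1:8)
  res <- family_size_compare(counts, two_groups(4, 4))
  expect_false(any(res$significant))
})

test_that("group labels must cover two groups of at least two species", {
  counts <- cbind(FBX = 1:4)
  rownames(counts) <- sprintf("sp%d", 1:4)
  expect_error(family_size_compare(counts, two_groups(1, 3)), "at least 2")
  g <- stats::setNames(rep("one", 4), rownames(counts))
  expect_error(family_size_compare(counts, g), "two groups")
})

test_that("swapping group labels flips direction but preserves p-values", {
  set.seed(3)
  counts <- cbind(FBX = c(rpois(4, 20), rpois(4, 5)), BTB = rpois(8, 10))
  rownames(counts) <- sprintf("sp%d", 1:8)
  g1 <- two_groups(4, 4)
  g2 <- stats::setNames(rev(g1), names(g1))
  r1 <- family_size_compare(counts, g1)
  r2 <- family_size_compare(counts, g2)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  sig <- which(r1$significant)
  expect_true(length(sig) > 0)
  expect_false(any(r1$enriched_in[sig] == r2$enriched_in[sig]))
})

test_that("domain enrichment flags a planted accessory-domain excess", {
  set.seed(11)
  counts <- cbind(
    "FBX:Kelch_1" = c(rpois(6, 30), rpois(6, 8)),
    "FBX:LRR_1" = rpois(12, 10),
    "RING:zf-MYND" = rep(0, 12)
  )
  rownames(counts) <- sprintf("sp%d", 1:12)
  res <- domain_enrichment(counts, two_groups(6, 6))
  # the all-zero category is skipped entirely
  expect_false("RING:zf-MYND" %in% res$category)
  kelch <- res[res$category == "FBX:Kelch_1", ]
  expect_true(kelch$significant)
  expect_equal(kelch$enriched_in, "brassicaceae")
  expect_false(res$significant[res$category == "FBX:LRR_1"])
})

test_that("zero-variance equal categories yield p = 1, not an error", {
  counts <- cbind("FBX:PP2" = rep(4, 8))
  rownames(counts) <- sprintf("sp%d", 1:8)
  res <- domain_enrichment(counts, two_groups(4, 4))
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("accessory domain counts pivot the assignment signatures", {
  asg <- data.frame(
    locus_id = c("a1", "a2", "b1"),
    family = c("FBX", "FBX", "RING"),
    subfamily_signature = c("Kelch_1;LRR_1", "Kelch_1", ""),
    subfamily = "", is_pseudogene = FALSE, stringsAsFactors = FALSE
  )
  sp <- c(a1 = "A", a2 = "A", b1 = "B")
  m <- accessory_domain_counts(asg, sp)
  expect_equal(m["A", "FBX:Kelch_1"], 2)
  expect_equal(m["A", "FBX:LRR_1"], 1)
  # signature-less loci contribute no category
  expect_false(any(grepl("RING", colnames(m))))
})

test_that("profile clustering merges identical species first and recovers blocks", {
  m <- rbind(
    sp1 = c(10, 10, 1), sp2 = c(10, 10, 1),
    sp3 = c(1, 1, 10), sp4 = c(2, 1, 9)
  )
  colnames(m) <- c("FBX", "RP", "BTB")
  cl <- cluster_profiles(m)
  merge1 <- cl$species_tree$merge[1, ]
  expect_setequal(-merge1, c(1, 2)) # identical rows join at the first merge
  expect_equal(cl$species_tree$height[1], 0)
  expect_true(all(diff(cl$species_tree$height) >= -1e-9))
  groups <- stats::cutree(cl$species_tree, k = 2)
  expect_equal(groups[["sp1"]], groups[["sp2"]])
  expect_equal(groups[["sp3"]], groups[["sp4"]])
  expect_false(groups[["sp1"]] == groups[["sp3"]])
})

test_that("degenerate profile matrices are rejected", {
  m <- matrix(5, 3, 3, dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
  expect_error(cluster_profiles(m), "constant")
  expect_error(cluster_profiles(m[1, , drop = FALSE]), "2 species")
  one_col <- cbind(FBX = c(1, 5, 9))
  rownames(one_col) <- paste0("s", 1:3)
  cl <- cluster_profiles(one_col)
  expect_null(cl$category_tree)
  expect_s3_class(cl$species_tree, "hclust")
})
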