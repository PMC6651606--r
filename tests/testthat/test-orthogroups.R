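test_that("graph weights transform, cap, and symmetrize as documented", {
  sp <- c(a = "s1", b = "s2", c = "s1")
  rows <- data.frame(
    qseqid = c("a", "b", "a", "a"),
    sseqid = c("b", "a", "c", "a"),
    evalue = c(1e-40, 1e-60, 0, 1e-10)
  )
  g <- build_graph(rows, sp, cap = 200)
  e <- g$edges
  # reciprocal rows average: (40 + 60) / 2
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 50)
  # E-value 0 capped
  expect_equal(e$weight[e$from == "a" & e$to == "c"], 200)
  # self-hit not stored as an edge
  expect_equal(nrow(e), 2)
  expect_warning(
    build_graph(
      data.frame(qseqid = "a", sseqid = "b", evalue = 2), sp
    ),
    "non-positive"
  )
})

test_that("MCL separates disjoint cliques and keeps singletons", {
  sp <- stats::setNames(rep("s", 7), c(paste0("x", 1:3), paste0("y", 1:3), "z"))
  clique <- function(ids) {
    p <- t(utils::combn(ids, 2))
    data.frame(qseqid = p[, 1], sseqid = p[, 2], score = 50)
  }
  rows <- rbind(clique(paste0("x", 1:3)), clique(paste0("y", 1:3)),
                data.frame(qseqid = "z", sseqid = "z", score = 50))
  g <- build_graph(rows, sp, transform = "raw_score")
  memb <- mcl_cluster(g)
  grp <- stats::setNames(memb$group_id, memb$locus_id)
  expect_equal(length(unique(grp)), 3)
  expect_equal(length(unique(grp[paste0("x", 1:3)])), 1)
  expect_equal(length(unique(grp[paste0("y", 1:3)])), 1)
  expect_false(grp[["x1"]] == grp[["y1"]])
  # singleton node keeps its own group
  expect_false(grp[["z"]] %in% grp[c("x1", "y1")])
  # partition covers all nodes exactly once
  expect_setequal(memb$locus_id, names(sp))
})

test_that("column normalization keeps the matrix stochastic", {
  set.seed(1)
  M <- matrix(stats::runif(64), 8, 8)
  M[M < 0.3] <- 0
  N <- upsdiverge:::mcl_normalize(M)
  expect_equal(colSums(N), rep(1, 8), tolerance = 1e-9)
  # a fully pruned column falls back to a self-loop
  M[, 3] <- 0
  N <- upsdiverge:::mcl_normalize(M)
  expect_equal(colSums(N), rep(1, 8), tolerance = 1e-9)
  expect_equal(N[3, 3], 1)
})

test_that("MCL recovers a planted partition and is deterministic", {
  pg <- make_planted_graph(n_groups = 12, per = 5, seed = 4)
  memb1 <- mcl_cluster(pg$graph)
  memb2 <- mcl_cluster(pg$graph)
  expect_identical(memb1, memb2)
  ari <- mclust::adjustedRandIndex(
    memb1$group_id, pg$truth[memb1$locus_id]
  )
  expect_gte(ari, 0.95)
})

test_that("age ranks follow the ladder worked examples", {
  lad <- brassicaceae_ladder()
  expect_equal(assign_age_rank(c("Aly", "Aha", "Ath", "Cru"), lad), "8")
  expect_equal(assign_age_rank("Aly", lad), "0")
  expect_equal(assign_age_rank(c("Aly", "Aha"), lad), "6")
  expect_equal(
    assign_age_rank(c("Aly", "Aha", "Ath", "Cru", "Bst", "Bra"), lad), "10"
  )
  # full family set plus the outgroup (or the other family) is ancient
  expect_equal(
    assign_age_rank(c("Aly", "Aha", "Ath", "Cru", "Bst", "Bra", "Atr"), lad),
    "A"
  )
  expect_equal(
    assign_age_rank(c("Aly", "Aha", "Ath", "Cru", "Bst", "Bra", "Osa"), lad),
    "A"
  )
  # skipping a rung of the ladder breaks the strict ranking
  expect_equal(assign_age_rank(c("Aly", "Ath", "Cru"), lad), "non_ranked")
  # outgroup without the full family set is likewise non-ranked
  expect_equal(assign_age_rank(c("Aly", "Aha", "Atr"), lad), "non_ranked")
  # no focal species: not applicable rather than an error
  expect_equal(assign_age_rank(c("Aha", "Ath"), lad), "not_applicable")
})

test_that("lenient mode ranks at the deepest split represented", {
  lad <- brassicaceae_ladder()
  expect_equal(assign_age_rank(c("Aly", "Ath", "Cru"), lad, strict = FALSE), "8")
  expect_equal(assign_age_rank(c("Aly", "Bra"), lad, strict = FALSE), "10")
})

test_that("adding the next ladder species raises the rank by exactly one", {
  lad <- brassicaceae_ladder()
  ranks <- vapply(seq_along(lad$nested_sets), function(k) {
    assign_age_rank(c(lad$focal, lad$nested_sets[[k]]), lad)
  }, character(1))
  expect_equal(ranks, lad$rank_labels)
  idx <- match(ranks, lad$rank_labels)
  expect_equal(diff(idx), rep(1L, length(idx) - 1L))
})

test_that("age count matrix reproduces planted counts at the no-loss limit", {
  tr <- shared_truth()
  lad <- small_ladder()
  mem <- age_rank_groups(truth_membership(tr), lad)
  m <- age_count_matrix(mem, lad)
  planted <- table(
    tr$loci$family[tr$loci$species == "Aly"],
    tr$loci$age_class[tr$loci$species == "Aly"]
  )
  for (fam in rownames(planted)) {
    for (cls in colnames(planted)) {
      expect_equal(m[fam, cls], planted[fam, cls],
                   label = paste(fam, cls))
    }
  }
  expect_equal(sum(m), sum(tr$loci$species == "Aly"))
})
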