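test_that("identical sequences fit to zero divergence and a neutral call", {
  s <- evolve_codon_pair(60, 0, 2, 1, seed = 1)[["a"]]
  aln <- codon_alignment(s, s)
  fit <- fit_codon_pair(aln)
  expect_lte(fit$t, 1e-4)
  res <- neutrality_test(aln)
  expect_lt(res$LR, 0.01)
  expect_true(res$neutral)
  expect_equal(res$Ka, 0, tolerance = 1e-4)
  expect_equal(res$Ks, 0, tolerance = 1e-4)
})

test_that("Ka/Ks from the fitted model equals the fitted omega", {
  p <- evolve_codon_pair(300, 0.5, 2, 0.4, seed = 21)
  fit <- fit_codon_pair(codon_alignment(p[["a"]], p[["b"]]))
  kk <- ml_ka_ks(fit)
  expect_equal(kk$Ka / kk$Ks, fit$omega, tolerance = 1e-6)
  # with omega fixed at 1 the two rates coincide
  fit1 <- fit_codon_pair(codon_alignment(p[["a"]], p[["b"]]), fix_omega = 1)
  kk1 <- ml_ka_ks(fit1)
  expect_equal(kk1$Ka, kk1$Ks, tolerance = 1e-9)
})

test_that("the likelihood ratio is nonnegative and order-invariant", {
  for (seed in 1:3) {
    p <- evolve_codon_pair(150, 0.4, 2, 0.6, seed = seed)
    fwd <- neutrality_test(p[["a"]], p[["b"]])
    rev <- neutrality_test(p[["b"]], p[["a"]])
    expect_gte(fwd$LR, 0)
    expect_equal(fwd$LR, rev$LR, tolerance = 0.02)
    expect_equal(2 * (fwd$lnL_free - fwd$lnL_fixed), fwd$LR, tolerance = 0.051)
  }
})

test_that("the free fit recovers a purifying omega", {
  med <- stats::median(vapply(1:30, function(i) {
    p <- evolve_codon_pair(500, 0.5, 2, 0.2, seed = 1000 + i)
    fit_codon_pair(codon_alignment(p[["a"]], p[["b"]]))$omega
  }, numeric(1)))
  expect_gte(med, 0.15)
  expect_lte(med, 0.25)
})

test_that("selection_scan returns one classified row per pair", {
  pairs <- data.frame(
    pair_id = c("p1", "p2"), locus_a = c("x1", "x2"), locus_b = c("y1", "y2"),
    age_rank = c("7", "8"), stringsAsFactors = FALSE
  )
  cds <- c(
    evolve_codon_pair(80, 0.3, 2, 0.2, seed = 5),
    evolve_codon_pair(80, 0.3, 2, 1.0, seed = 6)
  )
  names(cds) <- c("x1", "y1", "x2", "y2")
  res <- selection_scan(pairs, cds)
  expect_equal(nrow(res), 2)
  expect_true(all(res$LR >= 0))
  expect_true(all(is.finite(res$Ka) & is.finite(res$Ks)))
  expect_equal(res$age_rank, c("7", "8"))
  expect_error(selection_scan(pairs, cds[-1]), "no CDS")
})

test_that("codon back-threading drops gapped columns", {
  # proteins: M-KF vs MG-F aligned; only columns 1 and 4 are shared
  aln <- thread_codon_alignment(
    "M-KF", "MG-F",
    cds_a = "ATGAAATTT", cds_b = "ATGGGATTC"
  )
  expect_equal(aln$length, 2)
  expect_equal(aln$seq_a, "ATGTTT")
  expect_equal(aln$seq_b, "ATGTTC")
  expect_error(
    thread_codon_alignment("MK", "MKF", "ATGAAA", "ATGAAATTT"),
    "differ in length"
  )
})

test_that("age trend detects a monotone decline and rejects degenerate input", {
  res <- data.frame(
    age_rank = rep(c("7", "8", "9", "10"), each = 5),
    neutral = rep(c(TRUE, FALSE), c(10, 10)),
    Ka = 1, converged = TRUE, stringsAsFactors = FALSE
  )
  # neutral fractions 1, 1, 0, 0 are monotone but tied; use a strict series
  res$neutral <- c(
    rep(TRUE, 5), # rank 7: 1.0
    c(TRUE, TRUE, TRUE, FALSE, FALSE), # rank 8: 0.6
    c(TRUE, FALSE, FALSE, FALSE, FALSE), # rank 9: 0.2
    rep(FALSE, 5) # rank 10: 0.0
  )
  tr <- age_trend(res, "neutral_fraction")
  expect_equal(tr$rho, -1)
  expect_lt(tr$p_value, 0.1)
  expect_error(age_trend(res, "Ka"), "identical")
  expect_error(
    age_trend(res[res$age_rank %in% c("7", "8"), ], "neutral_fraction"),
    "3 distinct"
  )
})

test_that("lineage comparison reproduces the exact rank-sum null", {
  r <- lineage_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-9)
  expect_equal(r$direction, "b_greater")
  same <- lineage_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_error(lineage_compare(numeric(0), 1), "non-empty")
})

test_that("the planted omega decline with age is recovered by the scan", {
  lad <- small_ladder()
  tr <- simulate_genomes(lad, small_params(
    seed = 31, codon_length = 150, birth_rate = 3,
    omega_by_class = c("0" = 0.8, "6" = 0.8, "7" = 0.3, "8" = 0.1, "A" = 0.1)
  ))
  mem <- age_rank_groups(truth_membership(tr), lad)
  pairs <- orthologous_pairs(mem, "Aly", "Aha")
  pairs <- pairs[pairs$age_rank %in% lad$rank_labels, ]
  res <- selection_scan(pairs, tr$cds)
  trend <- age_trend(res, "omega")
  expect_lt(trend$rho, 0)
  expect_lt(trend$p_value, 0.05)
})

test_that("a planted omega shift between lineages is detected", {
  mk <- function(omega, seeds) {
    vapply(seeds, function(s) {
      p <- evolve_codon_pair(200, 0.4, 2, omega, seed = s)
      fit_codon_pair(codon_alignment(p[["a"]], p[["b"]]))$omega
    }, numeric(1))
  }
  a <- mk(0.8, 1:8)
  b <- mk(0.15, 11:18)
  r <- lineage_compare(a, b)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$direction, "a_greater")
})
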