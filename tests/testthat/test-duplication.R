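mk_loci <- function(order_index, start, subfam, species = "sp",
                    chromosome = "chr1", width = 2000L) {
  data.frame(
    locus_id = sprintf("L%02d", seq_along(order_index)),
    species = species, chromosome = chromosome,
    start = as.integer(start), end = as.integer(start) + width - 1L,
    order_index = as.integer(order_index),
    stringsAsFactors = FALSE
  )
}

subfam_of <- function(loci, subfam) stats::setNames(subfam, loci$locus_id)

test_that("the two-condition tandem rule is applied on both boundaries", {
  # 5 intervening genes and 120 kb apart: tandem
  loci <- mk_loci(c(1, 7), c(1, 120001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, c("F|x", "F|x")))
  expect_true(all(calls$tandem))
  expect_equal(calls$tandem_partner, c("L02", "L01"))
  # 11 intervening genes fails the gene-count condition
  loci <- mk_loci(c(1, 13), c(1, 120001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, c("F|x", "F|x")))
  expect_false(any(calls$tandem))
  # exactly 10 intervening genes passes (boundary)
  loci <- mk_loci(c(1, 12), c(1, 120001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, c("F|x", "F|x")))
  expect_true(all(calls$tandem))
  # adjacent but more than 300 kb apart fails the distance condition
  loci <- mk_loci(c(1, 2), c(1, 310001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, c("F|x", "F|x")))
  expect_false(any(calls$tandem))
  # different subfamilies never pair
  loci <- mk_loci(c(1, 2), c(1, 30001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, c("F|x", "F|y")))
  expect_false(any(calls$tandem))
})

test_that("a three-member array is tandem throughout", {
  loci <- mk_loci(c(1, 2, 3), c(1, 30001, 60001), NULL)
  calls <- classify_tandem(loci, subfam_of(loci, rep("F|x", 3)))
  expect_true(all(calls$tandem))
})

test_that("the tandem relation is symmetric and threshold-monotone", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    ord <- sample(n)
    loci <- mk_loci(ord, (ord - 1) * 25000 + 1,
                    NULL)
    subf <- subfam_of(loci, sample(c("F|a", "F|b", "R|c"), n, replace = TRUE))
    calls <- classify_tandem(loci, subf)
    # symmetry: a tandem locus's partner is itself tandem
    partners <- calls$tandem_partner[calls$tandem]
    expect_true(all(calls$tandem[match(partners, calls$locus_id)]))
    # monotonicity in both thresholds
    n_base <- sum(calls$tandem)
    wider_genes <- classify_tandem(
      loci, subf, dup_config(max_intervening_genes = 20)
    )
    wider_bp <- classify_tandem(
      loci, subf, dup_config(max_distance_bp = 6e5)
    )
    expect_gte(sum(wider_genes$tandem), n_base)
    expect_gte(sum(wider_bp$tandem), n_base)
  }
})

test_that("missing order_index or subfamily is an error", {
  loci <- mk_loci(c(1, 2), c(1, 30001), NULL)
  subf <- subfam_of(loci, c("F|x", "F|x"))
  loci_bad <- loci
  loci_bad$order_index[1] <- NA
  expect_error(classify_tandem(loci_bad, subf), "order_index")
  expect_error(classify_tandem(loci, subf[1]), "subfamily")
})

test_that("intronless status comes from the longest-CDS representative", {
  mk <- function(locus, tx, n_exons, cds_per_exon) {
    data.frame(
      locus_id = locus, transcript_id = tx,
      type = rep(c("exon", "CDS"), each = n_exons),
      start = rep(seq(1, by = 1000, length.out = n_exons), 2),
      end = rep(seq(1, by = 1000, length.out = n_exons), 2) + cds_per_exon - 1L,
      stringsAsFactors = FALSE
    )
  }
  models <- rbind(
    mk("g1", "g1.t1", 1, 900), # single exon
    mk("g2", "g2.t1", 2, 450), # two exons
    # two isoforms: 1-exon 300 bp CDS vs 3-exon 900 bp CDS; the longer,
    # multi-exon isoform is the representative, so g3 is NOT intronless
    mk("g3", "g3.t1", 1, 300),
    mk("g3", "g3.t2", 3, 300)
  )
  calls <- classify_intronless(models)
  il <- stats::setNames(calls$intronless, calls$locus_id)
  expect_true(il[["g1"]])
  expect_false(il[["g2"]])
  expect_false(il[["g3"]])
  expect_equal(
    calls$representative[calls$locus_id == "g3"], "g3.t2"
  )
  no_exon <- data.frame(
    locus_id = "g4", transcript_id = "g4.t1", type = "CDS",
    start = 1, end = 100, stringsAsFactors = FALSE
  )
  expect_error(classify_intronless(rbind(models, no_exon)), "g4")
})

test_that("Fisher enrichment matches exact hypergeometric values", {
  # all-vs-none 10/10 table: p = 2 / choose(20, 10)
  r <- duplication_enrichment(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  # identical proportions carry no signal
  r <- duplication_enrichment(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(r$p_value, 1)
  expect_error(duplication_enrichment(logical(0), TRUE), "at least one")
})

test_that("planted tandem-fraction differences are detected", {
  set.seed(7)
  a <- stats::runif(100) < 0.8
  b <- stats::runif(100) < 0.2
  r <- duplication_enrichment(a, b)
  expect_lt(r$p_value, 1e-5)
})

test_that("tandem and intronless calls recover the planted truth exactly", {
  tr <- shared_truth() # death_rate = 0
  calls <- classify_tandem(tr$loci, true_subfamilies(tr))
  truth <- true_tandem_flags(tr)
  expect_equal(calls$tandem, unname(truth[calls$locus_id]))
  dirn <- shared_emitted()
  models <- do.call(rbind, lapply(tr$species$species, function(sp) {
    read_gene_models(file.path(dirn, paste0(sp, ".gff3")))
  }))
  il <- classify_intronless(models)
  truth_il <- stats::setNames(tr$loci$intron_count == 0, tr$loci$locus_id)
  expect_equal(il$intronless, unname(truth_il[il$locus_id]))
})
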