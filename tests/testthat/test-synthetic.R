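test_that("no-event limit yields one locus per species, all ancestral rank", {
  tr <- simulate_genomes(
    small_ladder(),
    small_params(seed = 3, birth_rate = 0, death_rate = 0)
  )
  n_sp <- nrow(tr$species)
  per_group <- table(tr$loci$group_id)
  expect_true(all(per_group == n_sp))
  expect_true(all(tr$groups$age_class == "A"))
  # every group present in all species -> recomputed rank is the oldest (A)
  mem <- age_rank_groups(truth_membership(tr), small_ladder())
  expect_true(all(mem$age_rank == "A"))
})

test_that("forced tandem mode places every duplicate adjacent to a sibling", {
  tr <- simulate_genomes(
    small_ladder(),
    small_params(seed = 7, tandem_fraction = 1, retro_fraction = 0,
                 birth_rate = 3)
  )
  dup <- tr$loci[tr$loci$duplication_mode == "tandem", ]
  expect_gt(nrow(dup), 0)
  expect_true(all(!is.na(dup$tandem_partner)))
  # every tandem copy must satisfy the distance rule against SOME
  # same-subfamily sibling (tandem arrays stay contiguous)
  subf <- true_subfamilies(tr)
  for (k in seq_len(nrow(dup))) {
    sibs <- tr$loci[
      tr$loci$species == dup$species[k] &
        subf[tr$loci$locus_id] == subf[[dup$locus_id[k]]] &
        tr$loci$locus_id != dup$locus_id[k],
    ]
    sep <- abs(sibs$order_index - dup$order_index[k]) - 1L
    gap <- pmax(pmax(sibs$start, dup$start[k]) -
                  pmin(sibs$end, dup$end[k]), 0L)
    expect_true(any(sep <= 10 & gap <= 300000), label = dup$locus_id[k])
  }
})

test_that("the simulation is byte-identical for a fixed seed", {
  a <- simulate_genomes(small_ladder(), small_params(seed = 5))
  b <- simulate_genomes(small_ladder(), small_params(seed = 5))
  expect_identical(a, b)
  c <- simulate_genomes(small_ladder(), small_params(seed = 6))
  expect_false(identical(a$loci, c$loci))
})

test_that("simulated CDS never contain internal stop codons", {
  tr <- shared_truth()
  has_stop <- vapply(tr$cds, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(has_stop))
  expect_true(all(nchar(tr$cds) %% 3 == 0))
})

test_that("planted age ranks are recomputable from species presence", {
  tr <- shared_truth() # death_rate = 0
  lad <- small_ladder()
  mem <- age_rank_groups(truth_membership(tr), lad)
  g <- unique(mem[, c("group_id", "age_rank")])
  planted <- stats::setNames(tr$groups$age_class, tr$groups$group_id)[g$group_id]
  clade1 <- planted %in% c("0", lad$rank_labels, "A")
  expect_true(all(g$age_rank[clade1] == planted[clade1]))
  # second-family groups contain no focal species -> not applicable
  expect_true(all(g$age_rank[!clade1] == "not_applicable"))
})

test_that("retro-mode groups are intronless and others have introns", {
  tr <- shared_truth()
  retro <- tr$loci$duplication_mode == "retro"
  expect_true(all(tr$loci$intron_count[retro] == 0))
  expect_true(all(tr$loci$intron_count[!retro] >= 1))
})

test_that("lethal death rates abort naming the vanished family", {
  expect_error(
    simulate_genomes(
      small_ladder(),
      small_params(seed = 2, birth_rate = 0, death_rate = 0.95)
    ),
    "family"
  )
})

test_that("evolve_codon_pair honors t=0 and the seed", {
  p0 <- evolve_codon_pair(50, 0, 2, 0.5, seed = 9)
  expect_identical(p0[["a"]], p0[["b"]])
  p1 <- evolve_codon_pair(50, 0.4, 2, 0.5, seed = 9)
  p2 <- evolve_codon_pair(50, 0.4, 2, 0.5, seed = 9)
  expect_identical(p1, p2)
  expect_error(evolve_codon_pair(0, 0.1, 2, 0.5))
  expect_error(evolve_codon_pair(10, -1, 2, 0.5))
})

test_that("emitted files round-trip the locus complement", {
  tr <- shared_truth()
  dirn <- shared_emitted()
  for (sp in tr$species$species[c(1, 4)]) {
    cds <- read_cds(file.path(dirn, paste0(sp, ".cds.fasta")))
    truth_ids <- tr$loci$locus_id[tr$loci$species == sp]
    expect_setequal(names(cds), truth_ids)
    models <- read_gene_models(file.path(dirn, paste0(sp, ".gff3")))
    expect_setequal(unique(models$locus_id), truth_ids)
    genes <- attr(models, "genes")
    expect_equal(nrow(genes), length(truth_ids))
  }
})

test_that("retro loci are emitted as single-exon gene models", {
  tr <- shared_truth()
  dirn <- shared_emitted()
  sp <- tr$species$species[1]
  models <- read_gene_models(file.path(dirn, paste0(sp, ".gff3")))
  exons <- table(models$locus_id[models$type == "exon"])
  loci_sp <- tr$loci[tr$loci$species == sp, ]
  expect_equal(
    unname(as.integer(exons[loci_sp$locus_id])),
    loci_sp$intron_count + 1L
  )
})

test_that("identical paralogs score as high as self-hits in the similarity table", {
  tr <- shared_truth()
  sim <- read_similarity(file.path(shared_emitted(), "similarity.tsv"))
  self <- sim[sim$qseqid == sim$sseqid, ]
  expect_true(all(self$pident == 100))
  expect_equal(self$score, 100 * self$length)
})
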