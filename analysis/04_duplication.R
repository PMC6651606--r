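#!/usr/bin/env Rscript

# Step 4: recent duplications.
#
# Classifies tandem duplicates (same subfamily, at most 10 intervening genes
# and 300 kb apart) and intronless loci (single-exon representative
# transcript, the retrotransposition proxy), then compares the tandem and
# intronless proportions of the large E3 families between the focal species
# of the two plant families with Fisher's exact test.

suppressMessages(library(upsdiverge))

in_dir <- "results/synthetic"
truth_loci <- utils::read.delim(file.path(in_dir, "truth_loci.tsv"))
assignments <- utils::read.delim("results/assignments.tsv")
subfamily_of <- stats::setNames(assignments$subfamily, assignments$locus_id)

calls_tandem <- classify_tandem(truth_loci, subfamily_of)

species <- sort(unique(truth_loci$species))
models <- do.call(rbind, lapply(species, function(sp) {
  read_gene_models(file.path(in_dir, paste0(sp, ".gff3")))
}))
calls_intronless <- classify_intronless(models)

calls <- merge(calls_tandem, calls_intronless[, c("locus_id", "intronless")],
               by = "locus_id")
calls$species <- stats::setNames(
  truth_loci$species, truth_loci$locus_id
)[calls$locus_id]
calls$family <- stats::setNames(
  assignments$family, assignments$locus_id
)[calls$locus_id]
utils::write.table(
  calls, "results/duplication_calls.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

focal_a <- "Aly"
focal_b <- "Osa"
rows <- list()
for (fam in c("FBX", "RING", "BTB")) {
  a <- calls[calls$species == focal_a & calls$family == fam, ]
  b <- calls[calls$species == focal_b & calls$family == fam, ]
  for (what in c("tandem", "intronless")) {
    enr <- duplication_enrichment(a[[what]], b[[what]],
                                  labels = c(focal_a, focal_b))
    rows[[paste(fam, what)]] <- data.frame(
      family = fam, call = what,
      pct_a = round(100 * mean(a[[what]]), 1),
      pct_b = round(100 * mean(b[[what]]), 1),
      p_value = enr$p_value
    )
    message(sprintf(
      "%s %s: %s %.1f%% vs %s %.1f%% (Fisher p = %.3g)",
      fam, what, focal_a, 100 * mean(a[[what]]),
      focal_b, 100 * mean(b[[what]]), enr$p_value
    ))
  }
}
utils::write.table(
  do.call(rbind, rows), "results/duplication_enrichment.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
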