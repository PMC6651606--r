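#!/usr/bin/env Rscript

# Step 5: mutation rates and neutral evolution.
#
# Forms focal-reference orthologous pairs (Aly-Ath style) from the age-ranked
# orthogroups, estimates Ka, Ks and omega for each pair under the pairwise
# codon model, runs the likelihood-ratio neutrality test (free omega vs
# omega = 1, cutoff 2.71), and summarizes the age trend of the neutral
# fraction and omega.

suppressMessages(library(upsdiverge))

in_dir <- "results/synthetic"
ladder <- brassicaceae_ladder()
reference <- "Ath"

membership <- utils::read.delim("results/orthogroups.tsv",
                                colClasses = "character")
cds <- do.call(c, lapply(
  sort(unique(membership$species)),
  function(sp) read_cds(file.path(in_dir, paste0(sp, ".cds.fasta")))
))

pairs <- orthologous_pairs(membership, ladder$focal, reference)
pairs$family <- stats::setNames(
  membership$family, membership$locus_id
)[pairs$locus_a]
message("scanning ", nrow(pairs), " ", ladder$focal, "-", reference,
        " orthologous pairs ...")

res <- selection_scan(pairs, cds)
res$family <- pairs$family
utils::write.table(
  res, "results/selection_results.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

n_neutral <- sum(res$neutral & res$converged)
message(sprintf(
  "%d of %d pairs (%.1f%%) classified as neutrally evolving (LR < %.2f)",
  n_neutral, nrow(res), 100 * n_neutral / nrow(res), neutrality_lr_cutoff()
))

ranked <- res[res$age_rank %in% c(ladder$rank_labels), ]
for (value in c("omega", "Ka", "neutral_fraction")) {
  tr <- tryCatch(age_trend(ranked, value), error = function(e) NULL)
  if (!is.null(tr)) {
    message(sprintf(
      "age trend of %s: Spearman rho = %.3f (p = %.3g, n = %d)",
      value, tr$rho, tr$p_value, tr$n
    ))
  }
}

frac_by_rank <- tapply(ranked$neutral, ranked$age_rank, mean)
utils::write.table(
  data.frame(age_rank = names(frac_by_rank),
             neutral_fraction = round(as.numeric(frac_by_rank), 4)),
  "results/neutral_fraction_by_age.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
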