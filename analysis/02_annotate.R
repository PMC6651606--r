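#!/usr/bin/env Rscript

# Step 2: UPS family annotation from domain-hit tables.
#
# Loads the per-species protein-domain hits emitted in step 1, filters at the
# E-value cutoff of 1, assigns each protein to one of the 11 UPS families by
# the domain-combination rules, and writes the per-locus assignments and the
# species x family size table.

suppressMessages(library(upsdiverge))

in_dir <- "results/synthetic"
truth_loci <- utils::read.delim(file.path(in_dir, "truth_loci.tsv"))
species <- sort(unique(truth_loci$species))

hits <- do.call(rbind, lapply(species, function(sp) {
  load_domain_hits(file.path(in_dir, paste0(sp, ".domains.tsv")))
}))
message("retained ", nrow(hits), " domain hits")

pseudo <- stats::setNames(truth_loci$is_pseudogene, truth_loci$locus_id)
assignments <- assign_families(hits, pseudogene_of = pseudo)
message("assigned ", nrow(assignments), " loci to families")

species_of <- stats::setNames(truth_loci$species, truth_loci$locus_id)
sizes <- family_size_table(assignments, species_of)

utils::write.table(
  assignments, "results/assignments.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
utils::write.table(
  data.frame(species = rownames(sizes$total), sizes$total,
             check.names = FALSE),
  "results/family_sizes_total.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
utils::write.table(
  data.frame(species = rownames(sizes$active), sizes$active,
             check.names = FALSE),
  "results/family_sizes_active.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

acc <- mean(assignments$family ==
  stats::setNames(truth_loci$family, truth_loci$locus_id)[assignments$locus_id])
message("agreement with planted families: ", round(100 * acc, 2), "%")
message("family size table (total loci):")
print(sizes$total)
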