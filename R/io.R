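# File emission for the synthetic genomes (FASTA / GFF3 / TSV) and readers
# for the pipeline's tabular and annotation inputs.

translate_cds <- function(cds) {
  aa <- Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE
  )
  stats::setNames(as.character(aa), names(cds))
}

write_fasta <- function(seqs, path, protein = FALSE) {
  x <- if (protein) {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(x, filepath = path)
}

# Exon layout for one locus: the CDS split into (introns + 1) exons separated
# by fixed-length introns, fully coding.
exon_layout <- function(start, cds_len, n_introns, intron_length) {
  n_ex <- n_introns + 1L
  base <- cds_len %/% n_ex
  lens <- rep(base, n_ex)
  lens[n_ex] <- lens[n_ex] + cds_len - sum(lens)
  starts <- integer(n_ex)
  cur <- start
  for (i in seq_len(n_ex)) {
    starts[i] <- cur
    cur <- cur + lens[i] + intron_length
  }
  data.frame(start = starts, end = starts + lens - 1L)
}

write_species_gff3 <- function(loci_sp, cds, path, intron_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  loci_sp <- loci_sp[order(loci_sp$start), ]
  for (k in seq_len(nrow(loci_sp))) {
    l <- loci_sp[k, ]
    cds_len <- nchar(cds[[l$locus_id]])
    tid <- paste0(l$locus_id, ".t1")
    ex <- exon_layout(l$start, cds_len, l$intron_count, intron_length)
    lines <- c(
      sprintf(
        "%s\tupsdiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        l$chromosome, l$start, l$end, l$strand, l$locus_id
      ),
      sprintf(
        "%s\tupsdiverge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        l$chromosome, l$start, l$end, l$strand, tid, l$locus_id
      ),
      sprintf(
        "%s\tupsdiverge\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        l$chromosome, ex$start, ex$end, l$strand, tid, seq_len(nrow(ex)), tid
      ),
      sprintf(
        "%s\tupsdiverge\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
        l$chromosome, ex$start, ex$end, l$strand, tid, tid
      )
    )
    writeLines(lines, con)
  }
  invisible(path)
}

# Percent identity matrix for equal-length sequences via per-symbol one-hot
# cross products.
identity_matrix <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stopf("identity_matrix needs equal-length sequences")
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  ids <- matrix(0, n, n)
  for (s in unique(as.vector(chars))) {
    m <- (chars == s) * 1
    ids <- ids + tcrossprod(m)
  }
  dimnames(ids) <- list(names(seqs), names(seqs))
  100 * ids / L
}

#' Write the synthetic genome set to disk
#'
#' Emits, per species, the CDS FASTA, protein FASTA (standard-code
#' translation), and a GFF3 with gene/mRNA/exon/CDS features whose exon count
#' encodes the intron number; plus a per-species protein-domain hit table, a
#' joint all-vs-all protein similarity table (percent identity x length on
#' ungapped comparison of equal-length family members, within-family pairs
#' only, below-threshold pairs omitted), and the ground-truth tables as TSV.
#'
#' @param truth A `genome_truth` from [simulate_genomes()].
#' @param out_dir Output directory (created if needed).
#' @param min_pident Reporting threshold for the similarity table (percent).
#' @return Invisibly, the named list of written paths.
#' @export
emit_files <- function(truth, out_dir, min_pident = 30) {
  stopifnot(inherits(truth, "genome_truth"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stopf("output directory '%s' is not writable", out_dir)
  }
  bad_len <- nchar(truth$cds) %% 3L != 0L
  if (any(bad_len)) {
    stopf(
      "CDS length not a multiple of 3 for locus %s",
      names(truth$cds)[bad_len][1L]
    )
  }
  paths <- list()
  prot <- translate_cds(truth$cds)
  arch <- domain_architecture_table(truth)
  plen <- stats::setNames(nchar(prot), names(prot))

  with_seed(truth$params$seed + 1L, {
    for (sp in truth$species$species) {
      loci_sp <- truth$loci[truth$loci$species == sp, ]
      ids <- loci_sp$locus_id
      paths[[paste0(sp, "_cds")]] <- fp <- file.path(out_dir, paste0(sp, ".cds.fasta"))
      write_fasta(truth$cds[ids], fp)
      paths[[paste0(sp, "_pep")]] <- fp <- file.path(out_dir, paste0(sp, ".pep.fasta"))
      write_fasta(prot[ids], fp, protein = TRUE)
      paths[[paste0(sp, "_gff")]] <- fp <- file.path(out_dir, paste0(sp, ".gff3"))
      write_species_gff3(loci_sp, truth$cds, fp, truth$params$intron_length)

      hits_sp <- arch[arch$locus_id %in% ids, ]
      n <- nrow(hits_sp)
      dom_start <- pmax(1L, as.integer(stats::runif(n, 1, plen[hits_sp$locus_id] - 40)))
      hits <- data.frame(
        locus_id = hits_sp$locus_id,
        domain = hits_sp$domain,
        e_value = signif(10^stats::runif(n, -50, -2), 3),
        start = dom_start,
        end = pmin(dom_start + 39L, plen[hits_sp$locus_id]),
        stringsAsFactors = FALSE
      )
      # decoy hits above the reporting E-value cutoff exercise the filter
      decoys <- data.frame(
        locus_id = ids, domain = "Unrelated_dom",
        e_value = signif(stats::runif(length(ids), 1.5, 8), 3),
        start = 1L, end = 30L, stringsAsFactors = FALSE
      )
      hits <- rbind(hits, decoys)
      hits <- hits[order(hits$locus_id, hits$domain), ]
      paths[[paste0(sp, "_hits")]] <- fp <- file.path(out_dir, paste0(sp, ".domains.tsv"))
      utils::write.table(hits, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  sim_rows <- list()
  for (fam in unique(truth$loci$family)) {
    ids <- truth$loci$locus_id[truth$loci$family == fam]
    pid <- identity_matrix(prot[ids])
    idx <- which(pid >= min_pident | row(pid) == col(pid), arr.ind = TRUE)
    sim_rows[[fam]] <- data.frame(
      qseqid = ids[idx[, 1L]], sseqid = ids[idx[, 2L]],
      pident = round(pid[idx], 2),
      length = unname(plen[ids[idx[, 1L]]]),
      score = round(pid[idx] * unname(plen[ids[idx[, 1L]]]), 1),
      evalue = pmax(10^(-pid[idx]), 1e-180),
      stringsAsFactors = FALSE
    )
  }
  sim <- do.call(rbind, sim_rows)
  rownames(sim) <- NULL
  paths$similarity <- fp <- file.path(out_dir, "similarity.tsv")
  utils::write.table(sim, fp, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$loci <- fp <- file.path(out_dir, "truth_loci.tsv")
  utils::write.table(truth$loci, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$groups <- fp <- file.path(out_dir, "truth_groups.tsv")
  utils::write.table(truth$groups, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read an all-vs-all similarity table
#' @param path TSV with columns qseqid, sseqid, pident, length, score, evalue.
#' @return Data frame.
#' @export
read_similarity <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features and resolves each feature to its gene
#' locus through the Parent attributes.
#'
#' @param path GFF3 file.
#' @return Data frame with `locus_id`, `transcript_id`, `type`, `seqid`,
#'   `start`, `end`, `strand` for exon and CDS features, plus attributes
#'   `genes` (data frame of gene spans) accessible via
#'   `attr(x, "genes")`.
#' @export
read_gene_models <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$Parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  genes <- g[g$type == "gene", c("ID", "seqid", "start", "end", "strand")]
  names(genes)[1L] <- "locus_id"
  tx <- g[g$type == "mRNA", ]
  gene_of_tx <- stats::setNames(tx$Parent, tx$ID)
  feat <- g[g$type %in% c("exon", "CDS"), ]
  out <- data.frame(
    locus_id = unname(gene_of_tx[feat$Parent]),
    transcript_id = feat$Parent,
    type = as.character(feat$type),
    seqid = as.character(feat$seqid),
    start = feat$start, end = feat$end,
    strand = as.character(feat$strand),
    stringsAsFactors = FALSE
  )
  attr(out, "genes") <- genes
  out
}

#' Read coding sequences from a FASTA file
#' @param path FASTA of CDS.
#' @return Named character vector.
#' @export
read_cds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
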