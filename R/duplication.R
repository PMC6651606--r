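# Recent-duplication classification: tandem duplicates (same-subfamily
# neighbors separated by at most a fixed number of genes and a fixed
# distance) and intronless loci (retrotransposition proxy), with Fisher's
# exact test for enrichment between genomes.

#' Duplication-detection configuration
#'
#' @param max_intervening_genes Maximum number of gene loci of any family
#'   lying between a tandem pair (default 10, i.e. order-index difference at
#'   most 11).
#' @param max_distance_bp Maximum gap between the gene spans of a tandem pair
#'   (default 300 kb; end of the upstream gene to start of the downstream).
#' @param subfamily_mode "family+signature" (default: tandem partners must
#'   share the accessory-domain signature) or "family".
#' @return List of class `dup_config`.
#' @export
dup_config <- function(max_intervening_genes = 10L, max_distance_bp = 300000L,
                       subfamily_mode = c("family+signature", "family")) {
  assert_scalar_number(max_intervening_genes, "max_intervening_genes", lower = 1)
  assert_scalar_number(max_distance_bp, "max_distance_bp", lower = 1)
  structure(
    list(
      max_intervening_genes = as.integer(max_intervening_genes),
      max_distance_bp = as.integer(max_distance_bp),
      subfamily_mode = match.arg(subfamily_mode)
    ),
    class = "dup_config"
  )
}

#' Classify tandem duplicates
#'
#' A locus is tandem iff some other locus of the same subfamily on the same
#' chromosome is separated from it by at most `max_intervening_genes` gene
#' loci (counted against the full gene complement via the order index) AND
#' the gap between the two gene spans is at most `max_distance_bp`. The
#' relation is symmetric; the reported partner is the qualifying locus with
#' the smallest gene separation.
#'
#' @param loci Data frame with columns `locus_id`, `species`, `chromosome`,
#'   `start`, `end`, `order_index` (rank among ALL annotated genes of the
#'   chromosome, not only the family members).
#' @param subfamily_of Named character vector locus_id -> subfamily key
#'   (family plus accessory-domain signature, or plain family, matching
#'   `subfamily_mode` of the config).
#' @param config A [dup_config()].
#' @return Data frame with `locus_id`, `tandem`, `tandem_partner`.
#' @export
classify_tandem <- function(loci, subfamily_of, config = dup_config()) {
  required <- c("locus_id", "species", "chromosome", "start", "end", "order_index")
  if (!all(required %in% names(loci))) {
    stopf(
      "loci must have columns: %s", paste(required, collapse = ", ")
    )
  }
  if (anyNA(loci$order_index)) {
    stopf("missing order_index for %d loci", sum(is.na(loci$order_index)))
  }
  subf <- subfamily_of[loci$locus_id]
  if (anyNA(subf)) {
    stopf(
      "no subfamily for loci: %s",
      paste(utils::head(loci$locus_id[is.na(subf)], 5), collapse = ", ")
    )
  }
  tandem <- rep(FALSE, nrow(loci))
  partner <- rep(NA_character_, nrow(loci))
  key <- paste(loci$species, loci$chromosome, subf, sep = "\r")
  for (rows in split(seq_len(nrow(loci)), key)) {
    if (length(rows) < 2L) next
    ord <- loci$order_index[rows]
    for (a in seq_along(rows)) {
      sep <- abs(ord - ord[a]) - 1L # intervening gene loci
      # end-of-upstream to start-of-downstream distance; 0 when spans touch
      gap <- pmax(
        pmax(loci$start[rows], loci$start[rows[a]]) -
          pmin(loci$end[rows], loci$end[rows[a]]),
        0L
      )
      ok <- sep >= 0L & sep <= config$max_intervening_genes &
        gap <= config$max_distance_bp
      ok[a] <- FALSE
      if (any(ok)) {
        tandem[rows[a]] <- TRUE
        best <- which(ok)[which.min(sep[ok])]
        partner[rows[a]] <- loci$locus_id[rows[best]]
      }
    }
  }
  data.frame(
    locus_id = loci$locus_id, tandem = tandem, tandem_partner = partner,
    stringsAsFactors = FALSE
  )
}

#' Classify intronless loci from gene models
#'
#' A locus is intronless iff its representative transcript (the one with the
#' longest total CDS) consists of a single exon.
#'
#' @param models Data frame of gene-model features with columns `locus_id`,
#'   `transcript_id`, `type` ("exon" or "CDS"), `start`, `end` (one row per
#'   feature), e.g. from [read_gene_models()].
#' @return Data frame with `locus_id`, `intronless`, `n_exons`,
#'   `representative`.
#' @export
classify_intronless <- function(models) {
  required <- c("locus_id", "transcript_id", "type", "start", "end")
  if (!all(required %in% names(models))) {
    stopf("models must have columns: %s", paste(required, collapse = ", "))
  }
  ex <- models[models$type == "exon", ]
  cds <- models[models$type == "CDS", ]
  no_exon <- setdiff(unique(models$locus_id), unique(ex$locus_id))
  if (length(no_exon) > 0L) {
    stopf(
      "loci without exon features: %s",
      paste(utils::head(no_exon, 5), collapse = ", ")
    )
  }
  cds_len <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
  exon_count <- tapply(ex$transcript_id, ex$transcript_id, length)
  tx <- unique(ex[, c("locus_id", "transcript_id")])
  tx$cds_len <- as.numeric(cds_len[tx$transcript_id])
  tx$cds_len[is.na(tx$cds_len)] <- 0
  tx$n_exons <- as.integer(exon_count[tx$transcript_id])
  out <- lapply(split(tx, tx$locus_id), function(d) {
    rep_row <- d[order(-d$cds_len, d$transcript_id), ][1L, ]
    data.frame(
      locus_id = rep_row$locus_id,
      intronless = rep_row$n_exons == 1L,
      n_exons = rep_row$n_exons,
      representative = rep_row$transcript_id,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher's exact test for duplication enrichment between two genomes
#'
#' Builds the 2x2 table (genome x tandem/non-tandem, or intronless/intronic)
#' for one family and tests association with the exact hypergeometric test,
#' two-sided.
#'
#' @param calls_a,calls_b Logical vectors of per-locus calls (e.g. `tandem`
#'   column of [classify_tandem()] subset to one family) for the two genomes.
#' @param labels Genome labels for the output table.
#' @return List with `table` (2x2 counts), `p_value`, `odds_ratio`.
#' @export
duplication_enrichment <- function(calls_a, calls_b, labels = c("a", "b")) {
  calls_a <- as.logical(calls_a)
  calls_b <- as.logical(calls_b)
  if (length(calls_a) == 0L || length(calls_b) == 0L) {
    stopf("both genomes need at least one locus in the family")
  }
  tab <- rbind(
    c(sum(calls_a), sum(!calls_a)),
    c(sum(calls_b), sum(!calls_b))
  )
  dimnames(tab) <- list(labels, c("yes", "no"))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
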