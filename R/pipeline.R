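# Glue between pipeline stages: membership tables and orthologous pair
# construction for the selection scan.

#' Orthogroup membership table of a synthetic genome set
#'
#' @param truth A `genome_truth`.
#' @return Data frame with `group_id`, `locus_id`, `species`, `family`.
#' @export
truth_membership <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  truth$loci[, c("group_id", "locus_id", "species", "family")]
}

#' Focal-reference orthologous pairs for the selection scan
#'
#' For every orthogroup containing both the focal and the reference species,
#' pairs each focal-species locus with the (alphabetically first) reference
#' locus of the group, carrying the group's age rank.
#'
#' @param membership Age-ranked membership table (see [age_rank_groups()]).
#' @param focal,reference Species names (e.g. "Aly" and "Ath").
#' @return Data frame with `pair_id`, `locus_a`, `locus_b`, `group_id`,
#'   `age_rank`.
#' @export
orthologous_pairs <- function(membership, focal, reference) {
  stopifnot(all(c("group_id", "locus_id", "species") %in% names(membership)))
  out <- lapply(split(membership, membership$group_id), function(d) {
    a <- sort(d$locus_id[d$species == focal])
    b <- sort(d$locus_id[d$species == reference])
    if (length(a) == 0L || length(b) == 0L) {
      return(NULL)
    }
    data.frame(
      locus_a = a, locus_b = b[1L], group_id = d$group_id[1L],
      age_rank = if ("age_rank" %in% names(d)) d$age_rank[1L] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(
      pair_id = character(), locus_a = character(), locus_b = character(),
      group_id = character(), age_rank = character(), stringsAsFactors = FALSE
    ))
  }
  rownames(res) <- NULL
  res$pair_id <- sprintf("pair%04d", seq_len(nrow(res)))
  res[, c("pair_id", "locus_a", "locus_b", "group_id", "age_rank")]
}
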