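# Rule-based UPS family annotation from protein-domain hit tables: each of
# the 11 families is defined by one or more domain combinations (a protein
# matches if all domains of any combination are present), with per-family
# excluded domains and a fixed priority order for multi-family conflicts.

#' Load protein-domain hits from a TSV table
#'
#' Reads a tab-separated table with columns `locus_id`, `domain`, `e_value`,
#' `start`, `end` (header required) and drops hits whose E-value exceeds the
#' cutoff, reporting how many rows were dropped.
#'
#' @param path Path to the TSV file.
#' @param e_value_cutoff Hits with `e_value` strictly greater than this are
#'   dropped (default 1, the HMM-search reporting threshold used for
#'   domain-architecture annotation).
#' @return Data frame of retained hits.
#' @export
load_domain_hits <- function(path, e_value_cutoff = 1.0) {
  assert_scalar_number(e_value_cutoff, "e_value_cutoff", lower = 0)
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("locus_id", "domain", "e_value", "start", "end")
  if (nrow(hits) == 0L) {
    return(data.frame(
      locus_id = character(), domain = character(), e_value = numeric(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    ))
  }
  if (!all(required %in% names(hits))) {
    stopf(
      "domain-hit table %s lacks columns: %s", path,
      paste(setdiff(required, names(hits)), collapse = ", ")
    )
  }
  bad <- which(
    !is.finite(hits$e_value) | hits$e_value < 0 |
      !is.finite(hits$start) | !is.finite(hits$end) | hits$start > hits$end |
      !nzchar(hits$locus_id) | !nzchar(hits$domain)
  )
  if (length(bad) > 0L) {
    # +1 for the header row so the number matches the file line
    stopf("malformed domain-hit row at line %d of %s", bad[1L] + 1L, path)
  }
  keep <- hits$e_value <= e_value_cutoff
  if (any(!keep)) {
    message(sprintf(
      "load_domain_hits: dropped %d of %d hits above E-value %g",
      sum(!keep), nrow(hits), e_value_cutoff
    ))
  }
  hits[keep, required]
}

#' Default family-definition rules shipped with the package
#'
#' Reads the editable YAML rule file defining the 11 UPS families by domain
#' combinations, per-family excluded domains, and the conflict-resolution
#' priority order.
#'
#' @param path Optional path to an alternative rule file.
#' @return A list with `priority` (character) and `families` (named list with
#'   `combinations` and optional `excluded` per family), class `family_rules`.
#' @export
default_family_rules <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "family_rules.yaml", package = "upsdiverge")
  rules <- yaml::read_yaml(path)
  if (is.null(rules$priority) || is.null(rules$families)) {
    stopf("rule file %s must define 'priority' and 'families'", path)
  }
  rules$families <- lapply(rules$families, function(f) {
    if (length(f$combinations) == 0L) {
      stopf("every family needs at least one domain combination")
    }
    f$combinations <- lapply(f$combinations, as.character)
    if (any(lengths(f$combinations) == 0L)) {
      stopf("empty domain combination in rule file")
    }
    f$excluded <- as.character(f$excluded %||% character())
    f
  })
  missing <- setdiff(rules$priority, names(rules$families))
  if (length(missing) > 0L) {
    stopf("priority lists unknown families: %s", paste(missing, collapse = ", "))
  }
  class(rules) <- "family_rules"
  rules
}

#' Assign each protein to a UPS family from its domain hits
#'
#' A locus matches a family if all domains of any one of the family's
#' combinations are present among its hits (domains on the family's excluded
#' list are ignored for that family). Loci matching several families are
#' resolved by the rule priority order; loci matching none are omitted from
#' the output with a message. The subfamily signature is the sorted set of
#' accessory domains: every hit domain that is not part of the assigned
#' family's defining combinations.
#'
#' @param hits Data frame of domain hits (see [load_domain_hits()]).
#' @param rules A `family_rules` object (default: the shipped rule set).
#' @param pseudogene_of Optional named logical vector locus_id -> pseudogene
#'   flag (caller-supplied; pseudogene status is an input, not computed here).
#' @return Data frame with one row per assigned locus: `locus_id`, `family`,
#'   `subfamily_signature` (";"-joined sorted accessory domains, "" if none),
#'   `subfamily` (family plus signature key), `is_pseudogene`.
#' @export
assign_families <- function(hits, rules = default_family_rules(),
                            pseudogene_of = NULL) {
  stopifnot(inherits(rules, "family_rules"))
  if (nrow(hits) == 0L) {
    return(data.frame(
      locus_id = character(), family = character(),
      subfamily_signature = character(), subfamily = character(),
      is_pseudogene = logical(), stringsAsFactors = FALSE
    ))
  }
  domains_by_locus <- split(hits$domain, hits$locus_id)
  defining <- lapply(rules$families, function(f) unique(unlist(f$combinations)))
  out <- lapply(names(domains_by_locus), function(lid) {
    doms <- unique(domains_by_locus[[lid]])
    for (fam in rules$priority) {
      f <- rules$families[[fam]]
      usable <- setdiff(doms, f$excluded)
      hit <- any(vapply(
        f$combinations, function(cmb) all(cmb %in% usable), logical(1)
      ))
      if (hit) {
        acc <- sort(setdiff(doms, defining[[fam]]))
        return(data.frame(
          locus_id = lid, family = fam,
          subfamily_signature = paste(acc, collapse = ";"),
          stringsAsFactors = FALSE
        ))
      }
    }
    NULL
  })
  res <- do.call(rbind, out)
  n_unassigned <- length(domains_by_locus) - NROW(res)
  if (n_unassigned > 0L) {
    message(sprintf(
      "assign_families: %d loci matched no family rule and were excluded",
      n_unassigned
    ))
  }
  if (is.null(res)) {
    return(assign_families(hits[0, ], rules))
  }
  if (anyDuplicated(res$locus_id)) {
    stopf("internal error: locus assigned to multiple families")
  }
  res$subfamily <- paste(res$family, res$subfamily_signature, sep = "|")
  res$is_pseudogene <- if (is.null(pseudogene_of)) {
    FALSE
  } else {
    unname(pseudogene_of[res$locus_id]) %in% TRUE
  }
  rownames(res) <- NULL
  res
}

#' Family-size table across species
#'
#' Counts assigned loci per species and family, both in total and excluding
#' pseudogenes.
#'
#' @param assignments Output of [assign_families()] (one row per locus).
#' @param species_of Named character vector locus_id -> species; every
#'   assigned locus must be covered. Species present in the vector but absent
#'   from the assignments get zero-filled rows.
#' @return List with matrices `total` and `active` (species x family).
#' @export
family_size_table <- function(assignments, species_of) {
  if (anyDuplicated(assignments$locus_id)) {
    stopf("duplicate locus ids in assignments")
  }
  sp <- species_of[assignments$locus_id]
  if (anyNA(sp)) {
    stopf(
      "unknown species for loci: %s",
      paste(utils::head(assignments$locus_id[is.na(sp)], 5), collapse = ", ")
    )
  }
  species_levels <- sort(unique(unname(species_of)))
  fam_levels <- sort(unique(assignments$family))
  count <- function(rows) {
    tab <- table(
      factor(sp[rows], levels = species_levels),
      factor(assignments$family[rows], levels = fam_levels)
    )
    m <- matrix(as.numeric(tab), nrow = length(species_levels),
                dimnames = list(species_levels, fam_levels))
    m
  }
  all_rows <- rep(TRUE, nrow(assignments))
  list(
    total = count(all_rows),
    active = count(all_rows & !assignments$is_pseudogene)
  )
}
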