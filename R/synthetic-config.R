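# Configuration objects for the synthetic multi-genome generator: the species
# ladder (focal species plus nested sets of increasingly distant relatives,
# an outgroup, and the species of a second plant family) and the evolutionary
# parameters of the gene-family birth/death process.

#' Species ladder configuration
#'
#' Describes the chronological ladder of speciation events used for age
#' ranking: a focal species, an ordered list of strictly nested species sets
#' (each the previous set plus the next relative to split), an outgroup, and
#' the species of a second, distant plant family.
#'
#' @param focal Focal species name (e.g. "Aly").
#' @param nested_sets List of character vectors; each must strictly contain
#'   the previous one and none may contain the focal species.
#' @param outgroup Outgroup species name (ancestral-angiosperm stand-in).
#' @param second_family Character vector of species names from the other
#'   plant family.
#' @param rank_labels Labels for the nested sets, oldest label last; defaults
#'   to "6", "7", ... matching a six-species family whose deepest within-family
#'   rank is 10.
#' @return An object of class `ladder_config`.
#' @export
ladder_config <- function(focal, nested_sets, outgroup,
                          second_family = character(),
                          rank_labels = NULL) {
  stopifnot(is.character(focal), length(focal) == 1L, nzchar(focal))
  if (!is.list(nested_sets) || length(nested_sets) == 0L) {
    stopf("nested_sets must be a non-empty list of species-name vectors")
  }
  nested_sets <- lapply(nested_sets, as.character)
  for (k in seq_along(nested_sets)) {
    s <- nested_sets[[k]]
    if (anyDuplicated(s)) stopf("duplicate species in nested set %d", k)
    if (focal %in% s) stopf("focal species must not appear in nested sets")
    if (k > 1L) {
      prev <- nested_sets[[k - 1L]]
      if (!all(prev %in% s) || length(s) <= length(prev)) {
        stopf("nested set %d must strictly contain set %d", k, k - 1L)
      }
    }
  }
  within <- nested_sets[[length(nested_sets)]]
  all_names <- c(focal, within, outgroup, second_family)
  if (anyDuplicated(all_names)) {
    stopf("species names must be unique across focal/nested/outgroup/second family")
  }
  rank_labels <- rank_labels %||%
    as.character(seq(6L, length.out = length(nested_sets)))
  if (length(rank_labels) != length(nested_sets)) {
    stopf("need one rank label per nested set")
  }
  structure(
    list(
      focal = focal, nested_sets = nested_sets, outgroup = outgroup,
      second_family = as.character(second_family), rank_labels = rank_labels
    ),
    class = "ladder_config"
  )
}

#' @export
print.ladder_config <- function(x, ...) {
  cat(sprintf(
    "ladder_config: focal %s; ranks %s; outgroup %s; other family: %s\n",
    x$focal,
    paste(sprintf("%s={%s}", x$rank_labels,
      vapply(x$nested_sets, paste, character(1), collapse = ",")),
      collapse = " "),
    x$outgroup, paste(x$second_family, collapse = ",")
  ))
  invisible(x)
}

#' The Brassicaceae six-species ladder
#'
#' Aly focal, with Aha (rank 6), +Ath (7), +Cru (8), +Bst (9), +Bra (10),
#' Atr as outgroup and the six Poaceae species as the second family.
#' @export
brassicaceae_ladder <- function() {
  ladder_config(
    focal = "Aly",
    nested_sets = list(
      "Aha",
      c("Aha", "Ath"),
      c("Aha", "Ath", "Cru"),
      c("Aha", "Ath", "Cru", "Bst"),
      c("Aha", "Ath", "Cru", "Bst", "Bra")
    ),
    outgroup = "Atr",
    second_family = c("Osa", "Obr", "Opu", "Lpe", "Bdi", "Sbi")
  )
}

#' The Poaceae six-species ladder
#'
#' Osa focal, with Obr (rank 6), +Opu (7), +Lpe (8), +Bdi (9), +Sbi (10),
#' Atr as outgroup and the six Brassicaceae species as the second family.
#' @export
poaceae_ladder <- function() {
  ladder_config(
    focal = "Osa",
    nested_sets = list(
      "Obr",
      c("Obr", "Opu"),
      c("Obr", "Opu", "Lpe"),
      c("Obr", "Opu", "Lpe", "Bdi"),
      c("Obr", "Opu", "Lpe", "Bdi", "Sbi")
    ),
    outgroup = "Atr",
    second_family = c("Aly", "Aha", "Ath", "Cru", "Bst", "Bra")
  )
}

#' The 11 UPS gene families
#' @export
ups_families <- function() {
  c("E1", "E2", "FBX", "RING", "BTB", "HECT", "APC", "Cullin", "Skp1",
    "RP", "CP")
}

#' Parameters of the synthetic gene-family evolution process
#'
#' @param birth_rate Expected number of new orthologous groups born per
#'   family per ladder step (Poisson).
#' @param death_rate Per-lineage, per-age-step probability that a gene copy
#'   is lost.
#' @param tandem_fraction,retro_fraction Probability that a duplication event
#'   is a tandem duplication / a retrotransposition (intronless copy); the
#'   remainder are dispersed duplications. Must sum to at most 1.
#' @param kappa Transition/transversion ratio of the codon model used to
#'   evolve sequences.
#' @param omega_by_class Named numeric vector mapping age-class labels
#'   ("0", the ladder rank labels, "A") to the true Ka/Ks ratio of groups born
#'   in that class; `NULL` for a default declining series (young relaxed, old
#'   constrained).
#' @param codon_length Codons per gene (>= 30).
#' @param n_ancestral Ancestral (age "A") orthogroups per family.
#' @param t_step Divergence (expected substitutions per codon) accumulated
#'   per lineage per ladder step.
#' @param t_min Minimum per-lineage divergence from the group ancestor.
#' @param gene_spacing Start-to-start distance between neighboring genes (bp).
#' @param intron_length Length of each intron in emitted gene models (bp).
#' @param pseudo_fraction Fraction of loci in the two youngest age classes
#'   flagged as pseudogenes.
#' @param root_weight Multiplier of the birth rate at each clade's oldest
#'   shared step (default 3): most family expansion predates the
#'   within-family radiation, so the bulk of groups is shared by all clade
#'   members rather than scattered along the ladder.
#' @param family_bias Optional list with named numeric vectors `clade1` and
#'   `clade2`: per-family multipliers of the birth rate in each plant family.
#' @param families Family names simulated; defaults to [ups_families()].
#' @param accessory_pool Optional character vector of accessory
#'   protein-protein interaction domain names shared between groups; by
#'   default each duplication lineage gets a unique accessory domain.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return An object of class `evolve_params`.
#' @export
evolve_params <- function(birth_rate = 2, death_rate = 0,
                          tandem_fraction = 0.3, retro_fraction = 0.15,
                          kappa = 2, omega_by_class = NULL,
                          codon_length = 300, n_ancestral = 3,
                          t_step = 0.05, t_min = 0.02,
                          gene_spacing = 30000, intron_length = 200,
                          pseudo_fraction = 0.05, root_weight = 3,
                          family_bias = NULL,
                          families = ups_families(),
                          accessory_pool = NULL, seed = 1L) {
  assert_scalar_number(birth_rate, "birth_rate", lower = 0)
  assert_scalar_number(death_rate, "death_rate", lower = 0, upper = 1)
  assert_scalar_number(tandem_fraction, "tandem_fraction", lower = 0, upper = 1)
  assert_scalar_number(retro_fraction, "retro_fraction", lower = 0, upper = 1)
  if (tandem_fraction + retro_fraction > 1) {
    stopf("tandem_fraction + retro_fraction must be <= 1")
  }
  assert_scalar_number(kappa, "kappa", lower = 1e-6)
  assert_scalar_number(codon_length, "codon_length", lower = 30)
  assert_scalar_number(n_ancestral, "n_ancestral", lower = 1)
  assert_scalar_number(t_step, "t_step", lower = 0)
  assert_scalar_number(t_min, "t_min", lower = 0)
  assert_scalar_number(gene_spacing, "gene_spacing", lower = 1000)
  assert_scalar_number(pseudo_fraction, "pseudo_fraction", lower = 0, upper = 1)
  assert_scalar_number(root_weight, "root_weight", lower = 0)
  if (!is.null(omega_by_class)) {
    if (is.null(names(omega_by_class)) || any(omega_by_class <= 0)) {
      stopf("omega_by_class must be a named vector of positive values")
    }
  }
  structure(
    list(
      birth_rate = birth_rate, death_rate = death_rate,
      tandem_fraction = tandem_fraction, retro_fraction = retro_fraction,
      kappa = kappa, omega_by_class = omega_by_class,
      codon_length = as.integer(codon_length),
      n_ancestral = as.integer(n_ancestral),
      t_step = t_step, t_min = t_min,
      gene_spacing = as.integer(gene_spacing),
      intron_length = as.integer(intron_length),
      pseudo_fraction = pseudo_fraction, root_weight = root_weight,
      family_bias = family_bias, families = as.character(families),
      accessory_pool = accessory_pool, seed = as.integer(seed)
    ),
    class = "evolve_params"
  )
}
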