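# Synthetic multi-genome generator with planted ground truth. Orthologous
# groups are born along the speciation ladder (so their species presence
# encodes their age), duplicate by tandem, retrotransposition or dispersed
# events, and optionally die per lineage; every group carries a domain
# architecture and codon sequences evolved under a class-specific omega.

default_omega_by_class <- function(classes) {
  # declining from young (relaxed) to old (constrained)
  stats::setNames(seq(0.7, 0.1, length.out = length(classes)), classes)
}

#' Simulate a set of genomes with planted evolutionary ground truth
#'
#' Generates gene loci for every species of the ladder (focal family,
#' outgroup, second family). Ancestral orthogroups (age class "A") are present
#' in all species; at each ladder step, new groups are born by duplication of
#' an existing family member and inherited by exactly the species that
#' diverged later, so the species-presence set of each group is consistent
#' with its planted age. Duplications are tandem (the new locus is placed
#' adjacent to its template in every descendant genome), retrotranspositions
#' (intronless copies), or dispersed. Each group carries a family-defining
#' domain combination, an accessory protein-protein interaction domain
#' (inherited through tandem chains, so tandem siblings share a subfamily
#' signature), and coding sequences evolved from a group ancestor under the
#' codon model with the age-class omega.
#'
#' @param ladder A [ladder_config()].
#' @param params An [evolve_params()].
#' @return An object of class `genome_truth`: list with `species` (data frame
#'   of species and clade), `loci` (one row per gene with coordinates, order
#'   index, intron count, pseudogene flag, duplication mode, tandem partner,
#'   group id, family and age class), `groups` (one row per orthogroup with
#'   age class, true omega, branch length and domain architecture), `cds`
#'   (named vector of coding sequences), plus the input `ladder` and `params`.
#' @export
simulate_genomes <- function(ladder, params = evolve_params()) {
  stopifnot(inherits(ladder, "ladder_config"), inherits(params, "evolve_params"))
  within_fam <- ladder$nested_sets[[length(ladder$nested_sets)]]
  clade1 <- c(ladder$focal, within_fam)
  clade2 <- ladder$second_family
  species <- c(clade1, ladder$outgroup, clade2)
  if (length(species) == 0L) stopf("ladder names zero species")
  gene_span <- 3L * params$codon_length +
    2L * params$intron_length * 4L # generous bound; checked per locus below
  if (gene_span >= params$gene_spacing) {
    stopf(
      "gene_spacing (%d bp) too small for gene span; increase spacing or shorten genes",
      params$gene_spacing
    )
  }

  n1 <- length(ladder$rank_labels)
  classes <- c("0", ladder$rank_labels, "A") # young -> old within the family
  depth_of_class <- stats::setNames(seq_along(classes), classes)
  omega_map <- params$omega_by_class %||%
    default_omega_by_class(classes) # young (relaxed, 0.7) -> old (0.1)
  omega_of <- function(class, depth) {
    if (class %in% names(omega_map)) {
      return(unname(omega_map[[class]]))
    }
    # clade2 classes fall back to the clade1 class of equal depth
    cl1 <- classes[min(depth, length(classes))]
    if (!cl1 %in% names(omega_map)) {
      stopf("omega_by_class has no entry for class '%s'", class)
    }
    unname(omega_map[[cl1]])
  }

  rules <- default_family_rules()
  combos_of <- function(fam) rules$families[[fam]]$combinations
  for (fam in params$families) {
    if (is.null(combos_of(fam))) {
      stopf("no domain-combination rule for family '%s'", fam)
    }
  }

  with_seed(params$seed, {
    groups <- list()
    new_group <- function(family, age_class, depth, sp, mode, template,
                          accessory, combo_idx) {
      gid <- sprintf("OG%05d", length(groups) + 1L)
      groups[[gid]] <<- list(
        group_id = gid, family = family, age_class = age_class,
        depth = depth, species = sp, mode = mode, template = template,
        accessory = accessory, combo_idx = combo_idx,
        omega = omega_of(age_class, depth),
        t_branch = params$t_min + params$t_step * (depth - 1L),
        intron_count = if (mode == "retro") 0L else 1L + stats::rpois(1L, 2)
      )
      gid
    }

    # ancestral groups: one per family per slot, present everywhere
    for (fam in params$families) {
      for (k in seq_len(params$n_ancestral)) {
        new_group(
          fam, "A", depth_of_class[["A"]] + 1L, species, "ancestral",
          NA_character_, sprintf("ACC_%s_anc%02d", fam, k),
          combo_idx = (k - 1L) %% length(combos_of(fam)) + 1L
        )
      }
    }

    bias <- function(clade, fam) {
      b <- params$family_bias[[clade]]
      if (is.null(b) || is.na(b[fam] %||% NA)) 1 else unname(b[[fam]])
    }
    # births per branch: lambda = birth_rate x branch weight (in ladder
    # steps) x per-clade family bias; the clade-root branch carries
    # root_weight (expansion concentrated before the within-clade radiation)
    do_births <- function(steps, clade_name) {
      for (s in seq_along(steps)) {
        sp_set <- steps[[s]]$species
        cls <- steps[[s]]$class
        depth <- steps[[s]]$depth
        step_w <- steps[[s]]$weight
        for (fam in params$families) {
          fam_groups <- Filter(function(g) g$family == fam, groups)
          n_births <- stats::rpois(
            1L, params$birth_rate * step_w * bias(clade_name, fam)
          )
          for (b in seq_len(n_births)) {
            candidates <- Filter(
              function(g) all(sp_set %in% g$species), fam_groups
            )
            if (length(candidates) == 0L) next
            tmpl <- candidates[[sample.int(length(candidates), 1L)]]
            u <- stats::runif(1)
            mode <- if (u < params$tandem_fraction) {
              "tandem"
            } else if (u < params$tandem_fraction + params$retro_fraction) {
              "retro"
            } else {
              "dispersed"
            }
            accessory <- if (mode == "tandem") {
              tmpl$accessory # tandem copies keep the subfamily signature
            } else if (!is.null(params$accessory_pool)) {
              sample(params$accessory_pool, 1L)
            } else {
              sprintf("ACC_n%05d", length(groups) + 1L)
            }
            new_group(fam, cls, depth, sp_set, mode, tmpl$group_id,
                      accessory, tmpl$combo_idx)
          }
        }
      }
    }

    # clade 1: oldest split first (largest nested set, the clade root), down
    # to the focal-only step, plus a lineage-specific step for every other
    # clade member (post-split duplications continue in each lineage)
    # terminal-branch weights equal the number of ladder steps a lineage has
    # evolved on its own, so expected root-to-tip birth counts are
    # clock-consistent across species
    steps1 <- c(
      lapply(rev(seq_len(n1)), function(k) {
        list(
          species = c(ladder$focal, ladder$nested_sets[[k]]),
          class = ladder$rank_labels[k], depth = k + 1L,
          weight = if (k == n1) params$root_weight else 1
        )
      }),
      list(list(species = ladder$focal, class = "0", depth = 1L, weight = 1)),
      lapply(seq_along(within_fam), function(k) {
        sp <- within_fam[k] # first appears in nested set k: k-step branch
        list(species = sp, class = paste0("sp_", sp), depth = 1L, weight = k)
      })
    )
    do_births(steps1, "clade1")
    if (length(clade2) > 0L) {
      m <- length(clade2)
      steps2 <- c(
        lapply(rev(seq_len(m)), function(j) {
          list(
            species = clade2[seq_len(j)], class = paste0("c2_", j),
            depth = j, weight = if (j == m) params$root_weight else 1
          )
        }),
        lapply(seq_len(m)[-1L], function(k) { # clade2[1]'s terminal is c2_1
          list(
            species = clade2[k], class = paste0("sp2_", clade2[k]),
            depth = 1L, weight = k - 1L
          )
        })
      )
      do_births(steps2, "clade2")
    }

    # per-lineage losses: copies present for more steps have had more chances
    if (params$death_rate > 0) {
      for (gid in names(groups)) {
        g <- groups[[gid]]
        p_lose <- 1 - (1 - params$death_rate)^(g$depth - 1L)
        keep <- stats::runif(length(g$species)) >= p_lose
        groups[[gid]]$species <- g$species[keep]
      }
      groups <- Filter(function(g) length(g$species) > 0L, groups)
      for (fam in params$families) {
        if (!any(vapply(groups, function(g) g$family == fam, logical(1)))) {
          stopf("death_rate wiped out family '%s' entirely", fam)
        }
      }
    }

    # instantiate loci
    loci <- list()
    locus_of <- new.env(parent = emptyenv()) # key "<gid>|<sp>" -> locus_id
    counter <- stats::setNames(integer(length(species)), species)
    for (gid in names(groups)) {
      g <- groups[[gid]]
      for (sp in g$species) {
        counter[sp] <- counter[sp] + 1L
        lid <- sprintf("%s_g%04d", sp, counter[sp])
        assign(paste0(gid, "|", sp), lid, envir = locus_of)
        loci[[lid]] <- list(
          locus_id = lid, species = sp, group_id = gid, family = g$family,
          age_class = g$age_class, duplication_mode = g$mode,
          intron_count = g$intron_count, depth = g$depth
        )
      }
    }

    # tandem partner resolution
    for (lid in names(loci)) {
      l <- loci[[lid]]
      g <- groups[[l$group_id]]
      partner <- NA_character_
      if (g$mode == "tandem" && !is.na(g$template)) {
        key <- paste0(g$template, "|", l$species)
        if (exists(key, envir = locus_of)) {
          partner <- get(key, envir = locus_of)
        }
      }
      loci[[lid]]$tandem_partner <- partner
    }

    # chromosome layout per species: shuffled order, tandem copies inserted
    # immediately after their partner so the distance rule holds by design
    for (sp in species) {
      sp_ids <- names(Filter(function(l) l$species == sp, loci))
      has_partner <- vapply(
        sp_ids, function(id) !is.na(loci[[id]]$tandem_partner), logical(1)
      )
      base <- sp_ids[!has_partner]
      ord <- if (length(base) > 1L) sample(base) else base
      # each new copy goes to the end of its partner's tandem array, so array
      # members stay contiguous and every copy is adjacent to a sibling
      chain_end <- new.env(parent = emptyenv())
      root_of <- new.env(parent = emptyenv())
      get0e <- function(k, env, default) {
        if (exists(k, envir = env)) get(k, envir = env) else default
      }
      for (id in sp_ids[has_partner]) { # creation order = birth order
        p <- loci[[id]]$tandem_partner
        root <- get0e(p, root_of, p)
        assign(id, root, envir = root_of)
        anchor <- get0e(root, chain_end, root)
        at <- match(anchor, ord)
        if (is.na(at)) at <- length(ord)
        ord <- append(ord, id, after = at)
        assign(root, id, envir = chain_end)
      }
      for (pos in seq_along(ord)) {
        id <- ord[pos]
        span <- 3L * params$codon_length +
          loci[[id]]$intron_count * params$intron_length
        if (span >= params$gene_spacing) {
          stopf("gene %s (span %d bp) exceeds gene_spacing", id, span)
        }
        loci[[id]]$chromosome <- "chr1"
        loci[[id]]$order_index <- pos
        loci[[id]]$start <- (pos - 1L) * params$gene_spacing + 1L
        loci[[id]]$end <- loci[[id]]$start + span - 1L
        loci[[id]]$strand <- "+"
      }
    }

    # pseudogene flags on the youngest classes
    for (lid in names(loci)) {
      young <- loci[[lid]]$depth <= 2L
      loci[[lid]]$is_pseudogene <-
        young && stats::runif(1) < params$pseudo_fraction
    }

    # sequences: group ancestor -> per-member branch of length t_branch
    eig_cache <- new.env(parent = emptyenv())
    eig_for <- function(omega) {
      key <- sprintf("%.10g", omega)
      if (!exists(key, envir = eig_cache)) {
        assign(key, gy94_eigen(params$kappa, omega), envir = eig_cache)
      }
      get(key, envir = eig_cache)
    }
    cds <- stats::setNames(character(length(loci)), names(loci))
    for (gid in names(groups)) {
      g <- groups[[gid]]
      anc <- random_sense_codons(params$codon_length)
      P <- gy94_pmat(eig_for(g$omega), g$t_branch)
      for (sp in g$species) {
        lid <- get(paste0(gid, "|", sp), envir = locus_of)
        cds[[lid]] <- indices_to_seq(evolve_codon_indices(anc, P))
      }
    }

    fld_chr <- function(f) vapply(loci, function(l) l[[f]], character(1))
    fld_int <- function(f) vapply(loci, function(l) as.integer(l[[f]]), integer(1))
    loci_df <- data.frame(
      locus_id = fld_chr("locus_id"), species = fld_chr("species"),
      chromosome = fld_chr("chromosome"),
      start = fld_int("start"), end = fld_int("end"),
      strand = fld_chr("strand"), order_index = fld_int("order_index"),
      intron_count = fld_int("intron_count"),
      is_pseudogene = vapply(loci, function(l) l$is_pseudogene, logical(1)),
      group_id = fld_chr("group_id"), family = fld_chr("family"),
      age_class = fld_chr("age_class"),
      duplication_mode = fld_chr("duplication_mode"),
      tandem_partner = fld_chr("tandem_partner"),
      stringsAsFactors = FALSE
    )
    rownames(loci_df) <- NULL
    groups_df <- do.call(rbind, lapply(groups, function(g) {
      data.frame(
        group_id = g$group_id, family = g$family, age_class = g$age_class,
        depth = g$depth, mode = g$mode, template = g$template,
        accessory = g$accessory, combo_idx = g$combo_idx,
        omega = g$omega, t_branch = g$t_branch,
        n_species = length(g$species),
        stringsAsFactors = FALSE
      )
    }))
    rownames(groups_df) <- NULL
    structure(
      list(
        species = data.frame(
          species = species,
          clade = c(
            rep("focal_family", length(clade1)),
            "outgroup",
            rep("second_family", length(clade2))
          ),
          stringsAsFactors = FALSE
        ),
        loci = loci_df, groups = groups_df, cds = cds,
        ladder = ladder, params = params
      ),
      class = "genome_truth"
    )
  })
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf(
    "genome_truth: %d loci in %d orthogroups across %d species (%d families)\n",
    nrow(x$loci), nrow(x$groups), nrow(x$species),
    length(unique(x$loci$family))
  ))
  invisible(x)
}

#' Per-locus domain architecture of a synthetic genome set
#'
#' Expands the group-level architecture into one row per (locus, domain):
#' the family-defining combination plus the accessory protein-protein
#' interaction domain.
#'
#' @param truth A `genome_truth` from [simulate_genomes()].
#' @return Data frame with columns `locus_id`, `domain`.
#' @export
domain_architecture_table <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  rules <- default_family_rules()
  g <- truth$groups
  arch_of_group <- stats::setNames(lapply(seq_len(nrow(g)), function(k) {
    combos <- rules$families[[g$family[k]]]$combinations
    c(combos[[g$combo_idx[k]]], g$accessory[k])
  }), g$group_id)
  doms <- arch_of_group[truth$loci$group_id]
  data.frame(
    locus_id = rep(truth$loci$locus_id, lengths(doms)),
    domain = unlist(doms, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' True tandem flags of a synthetic genome set
#'
#' A locus is truly tandem when it was placed adjacent to a same-subfamily
#' sibling: either it is a tandem-duplication copy with a placed partner, or
#' it is the partner of one.
#'
#' @param truth A `genome_truth`.
#' @return Named logical vector locus_id -> tandem.
#' @export
true_tandem_flags <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  flags <- !is.na(truth$loci$tandem_partner) |
    truth$loci$locus_id %in% truth$loci$tandem_partner
  stats::setNames(flags, truth$loci$locus_id)
}

#' True subfamily (family + accessory-domain signature) per locus
#'
#' @param truth A `genome_truth`.
#' @return Named character vector locus_id -> subfamily key.
#' @export
true_subfamilies <- function(truth) {
  acc <- stats::setNames(truth$groups$accessory, truth$groups$group_id)
  stats::setNames(
    paste(truth$loci$family, acc[truth$loci$group_id], sep = "|"),
    truth$loci$locus_id
  )
}
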