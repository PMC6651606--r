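# Shared fixtures and independent oracles for the test suite. Simulations are
# kept small (three families, short genes, a three-step ladder) so the whole
# suite stays fast; the acceptance tests run the full study conditions.

small_ladder <- function() {
  ladder_config(
    focal = "Aly",
    nested_sets = list("Aha", c("Aha", "Ath"), c("Aha", "Ath", "Cru")),
    outgroup = "Atr",
    second_family = c("Osa", "Obr")
  )
}

small_params <- function(seed = 1L, ...) {
  defaults <- list(
    families = c("FBX", "RING", "Skp1"),
    codon_length = 60, n_ancestral = 2, birth_rate = 2, seed = seed
  )
  override <- list(...)
  do.call(evolve_params, utils::modifyList(defaults, override))
}

# One small default-parameter truth shared across tests (computed once).
.fixture_env <- new.env()
shared_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$truth <- simulate_genomes(small_ladder(), small_params(seed = 99))
  }
  .fixture_env$truth
}

shared_emitted <- function() {
  if (is.null(.fixture_env$dir)) {
    dirn <- file.path(tempdir(), "upsdiverge-fixture")
    emit_files(shared_truth(), dirn)
    .fixture_env$dir <- dirn
  }
  .fixture_env$dir
}

# Independent enumeration oracle for NG86 synonymous site fractions: mutate
# each codon position to every alternative nucleotide and classify via the
# genetic code, skipping changes to stops.
oracle_syn_fraction <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  cur <- strsplit(codon, "")[[1]]
  aa0 <- code[[codon]]
  vapply(1:3, function(p) {
    aas <- vapply(setdiff(nts, cur[p]), function(n) {
      x <- cur
      x[p] <- n
      code[[paste(x, collapse = "")]]
    }, character(1))
    aas <- aas[aas != "*"]
    if (length(aas) == 0L) 0 else mean(aas == aa0)
  }, numeric(1))
}

# Planted-partition similarity graph: `n_groups` clusters of `per` members
# with strong within-cluster edges and sparse weak between-cluster edges.
make_planted_graph <- function(n_groups = 20, per = 6, seed = 1,
                               p_between = 0.05) {
  set.seed(seed)
  ids <- sprintf("g%02d_m%d", rep(seq_len(n_groups), each = per),
                 rep(seq_len(per), n_groups))
  grp <- rep(seq_len(n_groups), each = per)
  species <- stats::setNames(
    rep(sprintf("sp%d", seq_len(per)), n_groups), ids
  )
  edges <- list()
  for (g in seq_len(n_groups)) {
    members <- which(grp == g)
    pairs <- t(utils::combn(members, 2))
    edges[[g]] <- data.frame(
      qseqid = ids[pairs[, 1]], sseqid = ids[pairs[, 2]],
      score = stats::runif(nrow(pairs), 40, 60)
    )
  }
  cross <- t(utils::combn(length(ids), 2))
  cross <- cross[grp[cross[, 1]] != grp[cross[, 2]], ]
  pick <- stats::runif(nrow(cross)) < p_between
  if (any(pick)) {
    edges$between <- data.frame(
      qseqid = ids[cross[pick, 1]], sseqid = ids[cross[pick, 2]],
      score = stats::runif(sum(pick), 1, 5)
    )
  }
  rows <- do.call(rbind, edges)
  list(
    graph = build_graph(rows, species, transform = "raw_score"),
    truth = stats::setNames(grp, ids)
  )
}
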