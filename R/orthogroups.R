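# Orthologous groups by native Markov clustering of an all-vs-all protein
# similarity graph, and age ranking of groups from their species-presence
# pattern along the speciation ladder.

#' Build a similarity graph from all-vs-all hit rows
#'
#' Transforms pairwise similarity rows into a weighted undirected graph:
#' by default edge weight is -log10(E-value) capped at a maximum (raw-score
#' mode available), reciprocal asymmetric rows are averaged into one edge,
#' self-hits are discarded (self-loops are handled inside the clustering),
#' and rows with non-positive transformed weight are dropped with a warning.
#'
#' @param rows Data frame with columns `qseqid`, `sseqid`, and `evalue`
#'   and/or `score`.
#' @param species_of Named character vector locus_id -> species label.
#' @param transform "neglog10_evalue" (default) or "raw_score".
#' @param cap Maximum weight under the E-value transform (guards E-value 0).
#' @return An object of class `similarity_graph`: list with `nodes` (data
#'   frame of locus and species) and `edges` (from, to, weight).
#' @export
build_graph <- function(rows, species_of,
                        transform = c("neglog10_evalue", "raw_score"),
                        cap = 200) {
  transform <- match.arg(transform)
  stopifnot(all(c("qseqid", "sseqid") %in% names(rows)))
  unknown <- setdiff(
    unique(c(rows$qseqid, rows$sseqid)), names(species_of)
  )
  if (length(unknown) > 0L) {
    stopf(
      "similarity rows reference unknown loci: %s",
      paste(utils::head(unknown, 5), collapse = ", ")
    )
  }
  w <- if (transform == "neglog10_evalue") {
    if (is.null(rows$evalue)) stopf("transform needs an 'evalue' column")
    pmin(-log10(pmax(rows$evalue, 10^(-cap))), cap)
  } else {
    if (is.null(rows$score)) stopf("raw_score transform needs a 'score' column")
    as.numeric(rows$score)
  }
  keep <- rows$qseqid != rows$sseqid
  drop_w <- keep & w <= 0
  if (any(drop_w)) {
    warning(sprintf(
      "build_graph: dropped %d rows with non-positive weight", sum(drop_w)
    ), call. = FALSE)
  }
  keep <- keep & w > 0
  a <- pmin(rows$qseqid[keep], rows$sseqid[keep])
  b <- pmax(rows$qseqid[keep], rows$sseqid[keep])
  agg <- if (any(keep)) {
    tapply(w[keep], paste(a, b, sep = "\r"), mean)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  pair <- strsplit(names(agg), "\r", fixed = TRUE)
  nodes <- sort(unique(c(rows$qseqid, rows$sseqid)))
  structure(
    list(
      nodes = data.frame(
        locus_id = nodes, species = unname(species_of[nodes]),
        stringsAsFactors = FALSE
      ),
      edges = data.frame(
        from = vapply(pair, `[`, character(1), 1L),
        to = vapply(pair, `[`, character(1), 2L),
        weight = as.numeric(agg),
        stringsAsFactors = FALSE
      )
    ),
    class = "similarity_graph"
  )
}

#' Markov clustering configuration
#'
#' @param inflation Entrywise-power parameter controlling granularity
#'   (default 1.5, the value used for orthologous-group construction).
#' @param expansion_power Matrix power of the expansion step (default 2).
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @param max_iterations Iteration cap; non-convergence is an error.
#' @param convergence_tol Maximum entrywise change defining convergence.
#' @return List of class `mcl_config`.
#' @export
mcl_config <- function(inflation = 1.5, expansion_power = 2L,
                       prune_threshold = 1e-5, max_iterations = 200L,
                       convergence_tol = 1e-6) {
  assert_scalar_number(inflation, "inflation", lower = 1 + 1e-9)
  assert_scalar_number(expansion_power, "expansion_power", lower = 2)
  assert_scalar_number(prune_threshold, "prune_threshold", lower = 0)
  structure(
    list(
      inflation = inflation, expansion_power = as.integer(expansion_power),
      prune_threshold = prune_threshold,
      max_iterations = as.integer(max_iterations),
      convergence_tol = convergence_tol
    ),
    class = "mcl_config"
  )
}

# Column-normalize to a stochastic matrix; columns that pruned to zero fall
# back to an absorbing self-loop so the matrix stays stochastic.
mcl_normalize <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2L, cs, "/")
}

#' Cluster a similarity graph into orthologous groups by Markov clustering
#'
#' Native implementation of the Markov Cluster algorithm: self-loops are
#' added (weight = the node's maximum incident edge weight), columns are
#' normalized to a stochastic matrix, and expansion (matrix power),
#' inflation (entrywise power + renormalization) and pruning iterate until
#' the matrix change falls below tolerance. Clusters are the connected
#' components of the converged matrix's non-zero structure and partition all
#' nodes.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param config An [mcl_config()].
#' @return Data frame with one row per locus: `group_id`, `locus_id`,
#'   `species`. Group ids are ordered by first member appearance.
#' @export
mcl_cluster <- function(graph, config = mcl_config()) {
  stopifnot(inherits(graph, "similarity_graph"), inherits(config, "mcl_config"))
  ids <- graph$nodes$locus_id
  n <- length(ids)
  if (n == 0L) stopf("empty similarity graph")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges$from, ids)
    j <- match(graph$edges$to, ids)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(A, 1L, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- mcl_normalize(A)
  converged <- FALSE
  residual <- NA_real_
  for (it in seq_len(config$max_iterations)) {
    Mexp <- M
    for (k in seq_len(config$expansion_power - 1L)) {
      Mexp <- Mexp %*% M
    }
    Minf <- Mexp^config$inflation
    Minf[Minf < config$prune_threshold] <- 0
    Mnew <- mcl_normalize(Minf)
    residual <- max(abs(Mnew - M))
    M <- Mnew
    if (residual < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stopf(
      "MCL did not converge in %d iterations (residual %.3g)",
      config$max_iterations, residual
    )
  }
  support <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable group ids by first appearance in input order
  relabel <- match(comp, unique(comp[order(ave(seq_len(n), comp, FUN = min))]))
  data.frame(
    group_id = sprintf("OG%05d", relabel),
    locus_id = ids,
    species = graph$nodes$species,
    stringsAsFactors = FALSE
  )
}

#' Assign the ladder age rank of one orthologous group
#'
#' Implements the age-ranking rule: for a group containing the focal species,
#' the rank is "0" when the focal species is alone, the k-th ladder label when
#' the non-focal within-family presence exactly equals the k-th nested set
#' (with no outgroup or other-family species present), and "A" when the full
#' within-family set plus the outgroup or any other-family species is present.
#' Anything else is "non_ranked". Groups without the focal species yield
#' "not_applicable".
#'
#' @param presence Character vector of species present in the group (or a
#'   one-group subset of the membership data frame with a `species` column).
#' @param ladder A [ladder_config()].
#' @param strict If `FALSE`, a lenient mode ranks a non-conforming group at
#'   the deepest ladder split represented instead of "non_ranked".
#' @return A single rank label.
#' @export
assign_age_rank <- function(presence, ladder, strict = TRUE) {
  stopifnot(inherits(ladder, "ladder_config"))
  if (is.data.frame(presence)) presence <- presence$species
  presence <- unique(as.character(presence))
  if (!(ladder$focal %in% presence)) {
    return("not_applicable")
  }
  within_all <- ladder$nested_sets[[length(ladder$nested_sets)]]
  inside <- setdiff(intersect(presence, within_all), ladder$focal)
  outside <- setdiff(presence, c(ladder$focal, within_all))
  if (length(outside) > 0L) {
    if (setequal(inside, within_all)) {
      return("A")
    }
    if (strict) {
      return("non_ranked")
    }
  }
  if (length(inside) == 0L && length(outside) == 0L) {
    return("0")
  }
  for (k in seq_along(ladder$nested_sets)) {
    if (setequal(inside, ladder$nested_sets[[k]])) {
      return(ladder$rank_labels[k])
    }
  }
  if (strict) {
    return("non_ranked")
  }
  deepest <- max(which(vapply(
    ladder$nested_sets,
    function(s) length(intersect(inside, s)) > 0L, logical(1)
  )))
  # deepest split represented: the largest nested set whose newest member is hit
  newest_hit <- vapply(seq_along(ladder$nested_sets), function(k) {
    new_sp <- setdiff(
      ladder$nested_sets[[k]],
      if (k > 1L) ladder$nested_sets[[k - 1L]] else character()
    )
    length(intersect(inside, new_sp)) > 0L
  }, logical(1))
  ladder$rank_labels[max(which(newest_hit))]
}

#' Age-rank all orthologous groups of a membership table
#'
#' @param membership Data frame from [mcl_cluster()] (`group_id`, `locus_id`,
#'   `species`).
#' @inheritParams assign_age_rank
#' @return The membership data frame with an `age_rank` column added.
#' @export
age_rank_groups <- function(membership, ladder, strict = TRUE) {
  ranks <- vapply(
    split(membership$species, membership$group_id),
    assign_age_rank, character(1), ladder = ladder, strict = strict
  )
  membership$age_rank <- unname(ranks[membership$group_id])
  membership
}

#' Counts of focal-species orthologous loci per family and age rank
#'
#' @param membership Age-ranked membership table (see [age_rank_groups()])
#'   with a `family` column (e.g. merged from the family assignments).
#' @param ladder A [ladder_config()].
#' @return Matrix family x age rank ("0", ladder labels, "A", and a separate
#'   "non_ranked" column) of focal-species locus counts.
#' @export
age_count_matrix <- function(membership, ladder) {
  stopifnot("family" %in% names(membership), "age_rank" %in% names(membership))
  rank_levels <- c("0", ladder$rank_labels, "A", "non_ranked")
  focal <- membership[membership$species == ladder$focal &
    membership$age_rank %in% rank_levels, ]
  tab <- table(
    factor(focal$family, levels = sort(unique(membership$family))),
    factor(focal$age_rank, levels = rank_levels)
  )
  m <- matrix(as.numeric(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}
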