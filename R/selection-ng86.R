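# Nei-Gojobori (1986) pairwise Ka/Ks with Jukes-Cantor correction. Serves as
# the approximate counting method alongside the ML codon-model estimates, and
# as an independent cross-check of the sequence simulator.

.ng86_cache <- new.env(parent = emptyenv())

# Per-codon synonymous site fractions: at each position the fraction of
# single-nucleotide changes, among those not creating a stop codon, that are
# synonymous. Changes to stops are excluded from numerator and denominator, so
# each position still contributes one full site (S + N = 3 per codon).
ng86_site_fractions <- function() {
  if (!is.null(.ng86_cache$sites)) {
    return(.ng86_cache$sites)
  }
  code <- Biostrings::GENETIC_CODE
  tab <- codon_tables()
  nts <- c("T", "C", "A", "G")
  s <- matrix(0, length(tab$codons), 3)
  for (ci in seq_along(tab$codons)) {
    cod <- strsplit(tab$codons[ci], "")[[1]]
    for (p in 1:3) {
      syn <- 0L
      nonstop <- 0L
      for (nt in setdiff(nts, cod[p])) {
        mut <- cod
        mut[p] <- nt
        aa <- code[[paste(mut, collapse = "")]]
        if (aa == "*") next
        nonstop <- nonstop + 1L
        if (aa == tab$aa[ci]) syn <- syn + 1L
      }
      s[ci, p] <- if (nonstop > 0L) syn / nonstop else 0
    }
  }
  .ng86_cache$sites <- s
  s
}

# Average synonymous/nonsynonymous difference counts between two sense codons
# over all minimal mutational pathways. Pathways passing through a stop codon
# are discarded; if every pathway is blocked, all are used with steps into or
# out of a stop counted as nonsynonymous.
ng86_path_diffs <- function(i, j) {
  code <- Biostrings::GENETIC_CODE
  tab <- codon_tables()
  a <- strsplit(tab$codons[i], "")[[1]]
  b <- strsplit(tab$codons[j], "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) {
    return(c(0, 0))
  }
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      o <- list(
        c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
      )
      lapply(o, function(k) pos[k])
    }
  )
  walk <- function(order) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    blocked <- FALSE
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_from <- code[[paste(cur, collapse = "")]]
      aa_to <- code[[paste(nxt, collapse = "")]]
      if (aa_from == "*" || aa_to == "*") {
        blocked <- TRUE
        nonsyn <- nonsyn + 1
      } else if (aa_from == aa_to) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    c(syn, nonsyn, blocked)
  }
  res <- t(vapply(perms, walk, numeric(3)))
  open <- res[res[, 3] == 0, , drop = FALSE]
  use <- if (nrow(open) > 0L) open else res
  c(mean(use[, 1]), mean(use[, 2]))
}

ng86_diff_matrices <- function() {
  if (!is.null(.ng86_cache$diffs)) {
    return(.ng86_cache$diffs)
  }
  tab <- codon_tables()
  n <- length(tab$codons)
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- ng86_path_diffs(i, j)
        Sd[i, j] <- Sd[j, i] <- d[1]
        Nd[i, j] <- Nd[j, i] <- d[2]
      }
    }
  }
  .ng86_cache$diffs <- list(Sd = Sd, Nd = Nd)
  .ng86_cache$diffs
}

jc_correct <- function(p) {
  if (is.na(p)) {
    return(NA_real_)
  }
  if (p >= 0.75) {
    return(NA_real_)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) pairwise substitution rates
#'
#' Counts synonymous and nonsynonymous sites (one-step neighbor enumeration
#' under the standard code, stop-codon changes excluded) and differences
#' (averaged over all minimal mutational pathways), then applies the
#' Jukes-Cantor multiple-hit correction.
#'
#' @param aln A [codon_alignment()], or a coding sequence (then `seq_b` must
#'   be supplied).
#' @param seq_b Optional second sequence when `aln` is a raw sequence.
#' @return A list with `S_sites`, `N_sites`, `S_diffs`, `N_diffs`, `pS`, `pN`,
#'   `Ka`, `Ks`, and `saturated` (TRUE when the Jukes-Cantor argument for
#'   either rate is out of range, in which case that rate is `NA`).
#' @export
ng86 <- function(aln, seq_b = NULL) {
  if (!inherits(aln, "codon_alignment")) {
    aln <- codon_alignment(aln, seq_b)
  }
  sites <- ng86_site_fractions()
  dm <- ng86_diff_matrices()
  S_a <- sum(sites[aln$a, ])
  S_b <- sum(sites[aln$b, ])
  S_sites <- (S_a + S_b) / 2
  N_sites <- 3 * aln$length - S_sites
  idx <- cbind(aln$a, aln$b)
  S_diffs <- sum(dm$Sd[idx])
  N_diffs <- sum(dm$Nd[idx])
  pS <- if (S_sites > 0) S_diffs / S_sites else NA_real_
  pN <- if (N_sites > 0) N_diffs / N_sites else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  list(
    S_sites = S_sites, N_sites = N_sites,
    S_diffs = S_diffs, N_diffs = N_diffs,
    pS = pS, pN = pN, Ka = Ka, Ks = Ks,
    saturated = is.na(Ka) || is.na(Ks)
  )
}
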