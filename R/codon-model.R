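# Codon substitution machinery shared by the selection module and the sequence
# simulator: the 61 sense codons of the standard genetic code, a GY94-style
# rate matrix (single-nucleotide exchanges, transition/transversion ratio
# kappa, nonsynonymous ratio omega, target-codon frequencies), and transition
# probabilities via spectral decomposition of the reversible generator.

.codon_cache <- new.env(parent = emptyenv())

#' Sense-codon tables for the standard genetic code
#'
#' Returns the internal lookup tables used by the codon model: the 61 sense
#' codons, their amino acids, and pairwise single-step structure (which codon
#' pairs differ at one position, whether that change is a transition, and
#' whether it is synonymous).
#'
#' @return A list with elements `codons` (character, length 61), `aa`
#'   (amino-acid letter per codon), and 61 x 61 logical matrices `one_step`,
#'   `transition`, `synonymous`.
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) {
    return(.codon_cache$tab)
  }
  code <- Biostrings::GENETIC_CODE
  codons_all <- names(code)
  sense <- codons_all[code != "*"]
  aa <- unname(code[sense])
  n <- length(sense)
  stopifnot(n == 61L)
  mat <- do.call(rbind, strsplit(sense, ""))
  ndiff <- matrix(0L, n, n)
  pos_change <- matrix(NA_integer_, n, n)
  for (p in 1:3) {
    d <- outer(mat[, p], mat[, p], "!=")
    ndiff <- ndiff + d
    pos_change[d & ndiff == 1L] <- p
  }
  one_step <- ndiff == 1L
  transition <- matrix(FALSE, n, n)
  purine <- c("A", "G")
  for (p in 1:3) {
    sel <- one_step & pos_change == p
    is_ts <- outer(mat[, p] %in% purine, mat[, p] %in% purine, "==")
    transition[sel] <- is_ts[sel]
  }
  synonymous <- outer(aa, aa, "==")
  tab <- list(
    codons = sense, aa = aa, one_step = one_step,
    transition = transition, synonymous = synonymous,
    ndiff = ndiff,
    # numeric masks so the rate matrix is a few elementwise products
    ts_m = (one_step & transition) * 1,
    tv_m = (one_step & !transition) * 1,
    syn_m = (one_step & synonymous) * 1,
    nonsyn_m = (one_step & !synonymous) * 1
  )
  .codon_cache$tab <- tab
  tab
}

#' Split a coding sequence into sense-codon indices
#'
#' @param seq A single DNA string (character or `DNAString`), gapless, length
#'   a multiple of 3, containing no internal stop codons.
#' @return Integer vector of indices into `codon_tables()$codons`.
#' @keywords internal
codon_indices <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stopf("coding sequence length (%d) is not a positive multiple of 3", n)
  }
  tab <- codon_tables()
  cods <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  idx <- match(cods, tab$codons)
  if (anyNA(idx)) {
    bad <- cods[is.na(idx)][1L]
    if (bad %in% c("TAA", "TAG", "TGA")) {
      stopf("internal stop codon '%s' in coding sequence", bad)
    }
    stopf("unrecognized codon '%s' in coding sequence", bad)
  }
  idx
}

indices_to_seq <- function(idx) {
  paste(codon_tables()$codons[idx], collapse = "")
}

#' Construct a pairwise codon alignment
#'
#' Validates and packages two gapless, equal-length coding sequences (standard
#' genetic code, no internal stops) for Ka/Ks estimation.
#'
#' @param seq_a,seq_b Coding sequences (character or `DNAString`).
#' @return An object of class `codon_alignment` with fields `a`, `b` (codon
#'   index vectors), `length` (codons) and the input sequences.
#' @export
codon_alignment <- function(seq_a, seq_b) {
  a <- codon_indices(seq_a)
  b <- codon_indices(seq_b)
  if (length(a) != length(b)) {
    stopf("sequences differ in length (%d vs %d codons)", length(a), length(b))
  }
  structure(
    list(
      a = a, b = b, length = length(a),
      seq_a = as.character(seq_a), seq_b = as.character(seq_b)
    ),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  tab <- codon_tables()
  nd <- sum(tab$ndiff[cbind(x$a, x$b)] > 0L)
  cat(sprintf(
    "codon_alignment: %d codons, %d differing (%.1f%%)\n",
    x$length, nd, 100 * nd / x$length
  ))
  invisible(x)
}

#' GY94-style codon rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix with entries proportional to
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]` for single-nucleotide
#' changes and zero otherwise, scaled so the expected number of substitutions
#' per codon per unit time equals 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param codon_freqs Equilibrium codon frequencies over the 61 sense codons;
#'   `NULL` for uniform.
#' @return A list with `Q` (scaled generator), `pi`, and `scale` (the raw
#'   expected flux used for scaling).
#' @export
gy94_rate_matrix <- function(kappa, omega, codon_freqs = NULL) {
  assert_scalar_number(kappa, "kappa", lower = 1e-12)
  assert_scalar_number(omega, "omega", lower = 1e-12)
  tab <- codon_tables()
  n <- length(tab$codons)
  pi <- codon_freqs %||% rep(1 / n, n)
  if (length(pi) != n || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stopf("codon_freqs must be %d nonnegative values summing to 1", n)
  }
  R <- (kappa * tab$ts_m + tab$tv_m) * (tab$syn_m + omega * tab$nonsyn_m)
  Q <- R * rep(pi, each = n) # Q[i, j] = R[i, j] * pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stopf("degenerate rate matrix (zero flux)")
  list(Q = Q / mu, pi = pi, scale = mu)
}

# Spectral decomposition of the reversible generator: with D = diag(pi),
# B = D^(1/2) Q D^(-1/2) is symmetric, so P(t) = D^(-1/2) U exp(L t) U' D^(1/2)
# with a single symmetric eigendecomposition reused for every t.
gy94_eigen <- function(kappa, omega, codon_freqs = NULL) {
  rm_ <- gy94_rate_matrix(kappa, omega, codon_freqs)
  sq <- sqrt(rm_$pi)
  B <- rm_$Q * (sq / rep(sq, each = length(sq)))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(
    U = e$vectors, lambda = e$values, sqrt_pi = sq, pi = rm_$pi, Q = rm_$Q
  )
}

gy94_pmat <- function(eig, t) {
  if (t < 0) stopf("branch length t must be >= 0")
  E <- eig$U %*% (exp(eig$lambda * t) * t(eig$U))
  P <- E * (rep(eig$sqrt_pi, each = length(eig$sqrt_pi)) / eig$sqrt_pi)
  P[P < 0] <- 0
  P
}

#' Log-likelihood of a codon alignment under the pairwise GY94 model
#'
#' Computes `sum over codon columns of log(pi_i P(t)_{ij})`, the likelihood of
#' one sequence evolving into the other along total divergence `t` (expected
#' substitutions per codon); by time-reversibility the value is independent of
#' which sequence is treated as ancestral.
#'
#' @param aln A [codon_alignment()].
#' @param t Divergence in expected substitutions per codon (>= 0).
#' @inheritParams gy94_rate_matrix
#' @return The log-likelihood (finite scalar).
#' @export
gy94_loglik <- function(aln, t, kappa, omega, codon_freqs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  assert_scalar_number(t, "t", lower = 0)
  eig <- gy94_eigen(kappa, omega, codon_freqs)
  ll <- gy94_loglik_patterns(codon_patterns(aln), eig, t)
  if (!is.finite(ll)) {
    stopf(
      "non-finite log-likelihood at t=%g, kappa=%g, omega=%g", t, kappa, omega
    )
  }
  ll
}

# Collapse an alignment into unique (i, j) codon-pair patterns with counts.
codon_patterns <- function(aln) {
  key <- (aln$a - 1L) * 61L + aln$b
  cnt <- table(key)
  k <- as.integer(names(cnt))
  list(
    i = (k - 1L) %/% 61L + 1L,
    j = (k - 1L) %% 61L + 1L,
    n = as.numeric(cnt)
  )
}

gy94_loglik_patterns <- function(pat, eig, t) {
  P <- gy94_pmat(eig, t)
  p <- eig$pi[pat$i] * P[cbind(pat$i, pat$j)]
  sum(pat$n * log(pmax(p, 1e-300)))
}

# Empirical F3x4 codon frequencies from the two aligned sequences: positional
# nucleotide frequencies multiplied per codon, stops removed, renormalized.
f3x4_freqs <- function(aln) {
  tab <- codon_tables()
  mat <- do.call(rbind, strsplit(tab$codons, ""))
  nts <- c("T", "C", "A", "G")
  counts <- matrix(0, 3, 4, dimnames = list(NULL, nts))
  for (idx in c(aln$a, aln$b)) {
    for (p in 1:3) {
      counts[p, mat[idx, p]] <- counts[p, mat[idx, p]] + 1
    }
  }
  # Laplace smoothing keeps every sense codon reachable on short alignments
  counts <- counts + 1
  freq <- counts / rowSums(counts)
  pi <- freq[1, mat[, 1]] * freq[2, mat[, 2]] * freq[3, mat[, 3]]
  pi / sum(pi)
}
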