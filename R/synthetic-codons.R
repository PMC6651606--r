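# Codon-sequence simulation under the GY94 model: exact transition-probability
# sampling per codon (matrix exponential of the generator), never producing
# internal stop codons because the state space is the 61 sense codons.

# Sample descendants of each codon index from the rows of P.
evolve_codon_indices <- function(idx, P) {
  out <- integer(length(idx))
  for (v in unique(idx)) {
    sel <- idx == v
    out[sel] <- sample.int(61L, sum(sel), replace = TRUE, prob = P[v, ])
  }
  out
}

random_sense_codons <- function(n) {
  sample.int(61L, n, replace = TRUE)
}

#' Simulate a pair of coding sequences diverged under the codon model
#'
#' Draws an ancestral sequence uniformly from the 61 sense codons and evolves
#' two descendant lineages, each for divergence `t/2`, under the GY94-style
#' rate matrix with the given transition/transversion ratio and Ka/Ks ratio.
#' Substitution is sampled exactly from the matrix-exponential transition
#' probabilities, so the pair's total expected divergence is `t` substitutions
#' per codon and no internal stop codon can arise.
#'
#' @param length_codons Number of codons (>= 1).
#' @param t Total pairwise divergence in expected substitutions per codon.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Ka/Ks rate ratio.
#' @param seed Integer seed; the same seed reproduces the pair exactly.
#' @return Character vector of two sequences, named `a` and `b`.
#' @export
evolve_codon_pair <- function(length_codons, t, kappa, omega, seed = 1L) {
  assert_scalar_number(length_codons, "length_codons", lower = 1)
  assert_scalar_number(t, "t", lower = 0)
  assert_scalar_number(kappa, "kappa", lower = 1e-12)
  assert_scalar_number(omega, "omega", lower = 1e-12)
  length_codons <- as.integer(length_codons)
  with_seed(seed, {
    anc <- random_sense_codons(length_codons)
    if (t == 0) {
      s <- indices_to_seq(anc)
      return(c(a = s, b = s))
    }
    eig <- gy94_eigen(kappa, omega)
    P <- gy94_pmat(eig, t / 2)
    c(
      a = indices_to_seq(evolve_codon_indices(anc, P)),
      b = indices_to_seq(evolve_codon_indices(anc, P))
    )
  })
}
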