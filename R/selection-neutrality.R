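# Likelihood-ratio test for neutral evolution of an orthologous pair: the
# free-omega codon model against omega fixed at 1, compared to the chi-square
# critical value 2.71 (5% significance with one degree of freedom; the null
# lies on the boundary, so this is the 90th percentile of chi-square(1)).

#' Default likelihood-ratio cutoff for the neutrality call
#'
#' The 5% critical value of the chi-square distribution with one degree of
#' freedom used one-sided at the omega = 1 boundary, i.e. its 90th percentile
#' (approximately 2.71).
#' @export
neutrality_lr_cutoff <- function() 2.71

#' Likelihood-ratio neutrality test for one orthologous pair
#'
#' Fits the pairwise codon model twice (omega free, and omega fixed at 1),
#' forms LR = 2(lnL_free - lnL_fixed), and calls the pair neutrally evolving
#' when LR falls below the cutoff: purifying (or positive) selection cannot be
#' distinguished from drift. Ka and Ks are reported from the free fit, along
#' with the Nei-Gojobori counting estimates.
#'
#' @param aln A [codon_alignment()] (or a coding sequence, with `seq_b`).
#' @param seq_b Optional second sequence when `aln` is a raw sequence.
#' @param lr_cutoff Critical value for the likelihood ratio (default 2.71).
#' @param codon_freq_mode Passed to [fit_codon_pair()].
#' @return An object of class `selection_result`: list with `Ka`, `Ks`,
#'   `omega`, `lnL_free`, `lnL_fixed`, `LR`, `neutral`, `converged`, plus the
#'   NG86 estimates `Ka_ng`, `Ks_ng` and `ng_saturated`.
#' @export
neutrality_test <- function(aln, seq_b = NULL, lr_cutoff = neutrality_lr_cutoff(),
                            codon_freq_mode = "uniform") {
  if (!inherits(aln, "codon_alignment")) {
    aln <- codon_alignment(aln, seq_b)
  }
  assert_scalar_number(lr_cutoff, "lr_cutoff", lower = 0)
  fixed <- fit_codon_pair(aln, fix_omega = 1, codon_freq_mode = codon_freq_mode)
  # Seed the free fit with the fixed-fit solution so the nested models can
  # never invert (lnL_free >= lnL_fixed up to optimizer tolerance).
  free <- fit_codon_pair(
    aln,
    codon_freq_mode = codon_freq_mode,
    extra_starts = list(c(max(fixed$t, 1e-6), fixed$kappa, 1))
  )
  # ... and symmetrically reseed the fixed fit from the free solution, so
  # neither likelihood is under-optimized relative to the other.
  fixed2 <- fit_codon_pair(
    aln,
    fix_omega = 1, codon_freq_mode = codon_freq_mode,
    extra_starts = list(c(max(free$t, 1e-6), free$kappa, 1))
  )
  if (fixed2$lnL > fixed$lnL) fixed <- fixed2
  lr <- 2 * (free$lnL - fixed$lnL)
  if (lr < 0) {
    lr <- if (lr > -0.05) 0 else stopf(
      "free fit worse than nested fixed fit (LR = %.4f); optimizer failure", lr
    )
  }
  kaks <- ml_ka_ks(free)
  ngr <- ng86(aln)
  structure(
    list(
      Ka = kaks$Ka, Ks = kaks$Ks, omega = free$omega,
      lnL_free = free$lnL, lnL_fixed = fixed$lnL,
      LR = lr, neutral = lr < lr_cutoff,
      converged = free$converged && fixed$converged,
      t = free$t, kappa = free$kappa,
      Ka_ng = ngr$Ka, Ks_ng = ngr$Ks, ng_saturated = ngr$saturated
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: Ka=%.4f Ks=%.4f omega=%.4f LR=%.3f -> %s\n",
    x$Ka, x$Ks, x$omega, x$LR,
    if (x$neutral) "neutral" else "non-neutral"
  ))
  invisible(x)
}

#' Run the selection analysis over a table of orthologous pairs
#'
#' @param pairs Data frame with columns `pair_id`, `locus_a`, `locus_b` and
#'   optionally `age_rank`.
#' @param cds Named character vector (or `DNAStringSet`) of coding sequences
#'   indexed by locus id. Each pair must be gapless and equal-length (e.g.
#'   back-threaded from a protein alignment; see [thread_codon_alignment()]).
#' @param lr_cutoff Critical value for the neutrality call.
#' @param codon_freq_mode Passed to [fit_codon_pair()].
#' @return Data frame with one row per pair: Ka, Ks, omega, lnL_fixed,
#'   lnL_free, LR, neutral, converged, ng_saturated and age_rank.
#' @export
selection_scan <- function(pairs, cds, lr_cutoff = neutrality_lr_cutoff(),
                           codon_freq_mode = "uniform") {
  stopifnot(all(c("pair_id", "locus_a", "locus_b") %in% names(pairs)))
  cds <- stats::setNames(as.character(cds), names(cds))
  missing <- setdiff(
    unique(c(pairs$locus_a, pairs$locus_b)), names(cds)
  )
  if (length(missing) > 0L) {
    stopf("no CDS for loci: %s", paste(utils::head(missing, 5), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    res <- neutrality_test(
      cds[[pairs$locus_a[k]]], cds[[pairs$locus_b[k]]],
      lr_cutoff = lr_cutoff, codon_freq_mode = codon_freq_mode
    )
    data.frame(
      pair_id = pairs$pair_id[k],
      locus_a = pairs$locus_a[k], locus_b = pairs$locus_b[k],
      age_rank = if ("age_rank" %in% names(pairs)) pairs$age_rank[k] else NA,
      Ka = res$Ka, Ks = res$Ks, omega = res$omega,
      lnL_fixed = res$lnL_fixed, lnL_free = res$lnL_free,
      LR = res$LR, neutral = res$neutral, converged = res$converged,
      Ka_ng = res$Ka_ng, Ks_ng = res$Ks_ng, ng_saturated = res$ng_saturated,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Back-thread a codon alignment from an aligned protein pair
#'
#' Builds the gapless codon alignment of two coding sequences from their
#' aligned protein sequences: aligned columns where either protein has a gap
#' are dropped, and the remaining columns are mapped back to codons.
#'
#' @param prot_a,prot_b Aligned protein sequences (same length, `-` for gaps).
#' @param cds_a,cds_b The corresponding unaligned coding sequences (length
#'   3 x number of residues, stop codon optional and trimmed).
#' @return A [codon_alignment()].
#' @export
thread_codon_alignment <- function(prot_a, prot_b, cds_a, cds_b) {
  pa <- strsplit(as.character(prot_a), "")[[1]]
  pb <- strsplit(as.character(prot_b), "")[[1]]
  if (length(pa) != length(pb)) {
    stopf("aligned proteins differ in length")
  }
  take_codons <- function(cds, prot_gapped) {
    cds <- toupper(as.character(cds))
    n_res <- sum(prot_gapped != "-")
    if (nchar(cds) %in% (3 * n_res + c(3L, 0L))) {
      cds <- substr(cds, 1L, 3L * n_res)
    } else {
      stopf("CDS length %d does not match %d aligned residues", nchar(cds), n_res)
    }
    substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  }
  ca <- take_codons(cds_a, pa)
  cb <- take_codons(cds_b, pb)
  keep <- pa != "-" & pb != "-"
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  codon_alignment(
    paste(ca[ia[keep]], collapse = ""),
    paste(cb[ib[keep]], collapse = "")
  )
}
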