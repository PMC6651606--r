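# Maximum-likelihood fitting of the pairwise codon model: deterministic
# grid multi-start with bounded quasi-Newton refinement, plus conversion of
# the fitted divergence into Ka and Ks on the per-site scale.

.fit_bounds <- list(t = c(1e-6, 50), kappa = c(1e-3, 100), omega = c(1e-4, 20))

#' Fit the pairwise codon model by maximum likelihood
#'
#' Maximizes the GY94 pairwise likelihood over divergence `t`, the
#' transition/transversion ratio `kappa`, and (unless fixed) the Ka/Ks ratio
#' `omega`. Optimization is deterministic: a fixed grid over (kappa, omega)
#' with the divergence profiled out by one-dimensional search, followed by
#' bounded L-BFGS-B refinement of the best starts on the log scale.
#'
#' @param aln A [codon_alignment()].
#' @param fix_omega Optional fixed value for omega (e.g. 1 for the neutral
#'   model of the likelihood-ratio test); `NULL` fits it freely.
#' @param codon_freq_mode "uniform" (equal frequencies over the 61 sense
#'   codons) or "F3x4" (empirical positional nucleotide frequencies).
#' @param extra_starts Optional list of c(t, kappa, omega) vectors appended to
#'   the start grid (used internally to seed the free fit from the fixed fit).
#' @return An object of class `codon_fit`: list with `t`, `kappa`, `omega`,
#'   `lnL`, `converged`, `fixed_omega`, `pi`.
#' @export
fit_codon_pair <- function(aln, fix_omega = NULL,
                           codon_freq_mode = c("uniform", "F3x4"),
                           extra_starts = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  codon_freq_mode <- match.arg(codon_freq_mode)
  if (!is.null(fix_omega)) {
    assert_scalar_number(fix_omega, "fix_omega", lower = .fit_bounds$omega[1])
  }
  pi <- if (codon_freq_mode == "F3x4") f3x4_freqs(aln) else NULL
  pat <- codon_patterns(aln)

  # Profiled objective: best lnL over t for fixed (kappa, omega), reusing one
  # eigendecomposition for every t evaluation.
  profile_t <- function(kappa, omega) {
    eig <- gy94_eigen(kappa, omega, pi)
    f <- function(logt) -gy94_loglik_patterns(pat, eig, exp(logt))
    o <- stats::optimize(f, log(.fit_bounds$t), tol = 1e-8)
    # the zero-divergence boundary is a valid optimum (identical sequences)
    at0 <- -gy94_loglik_patterns(pat, eig, .fit_bounds$t[1])
    if (at0 <= o$objective) {
      list(t = .fit_bounds$t[1], nll = at0)
    } else {
      list(t = exp(o$minimum), nll = o$objective)
    }
  }

  kappa_grid <- c(1, 2, 8)
  omega_grid <- if (is.null(fix_omega)) c(0.1, 1, 4) else fix_omega
  starts <- expand.grid(kappa = kappa_grid, omega = omega_grid)
  cand <- lapply(seq_len(nrow(starts)), function(k) {
    pr <- profile_t(starts$kappa[k], starts$omega[k])
    list(t = pr$t, kappa = starts$kappa[k], omega = starts$omega[k],
         nll = pr$nll)
  })
  for (st in extra_starts %||% list()) {
    eig <- gy94_eigen(st[2], st[3], pi)
    cand <- c(cand, list(list(
      t = st[1], kappa = st[2], omega = st[3],
      nll = -gy94_loglik_patterns(pat, eig, st[1])
    )))
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "nll"))
  refine_from <- cand[ord[seq_len(min(2L, length(cand)))]]

  free_omega <- is.null(fix_omega)
  nll_joint <- function(par) {
    t <- exp(par[1])
    kappa <- exp(par[2])
    omega <- if (free_omega) exp(par[3]) else fix_omega
    eig <- gy94_eigen(kappa, omega, pi)
    -gy94_loglik_patterns(pat, eig, t)
  }
  lower <- log(c(.fit_bounds$t[1], .fit_bounds$kappa[1],
                 if (free_omega) .fit_bounds$omega[1]))
  upper <- log(c(.fit_bounds$t[2], .fit_bounds$kappa[2],
                 if (free_omega) .fit_bounds$omega[2]))

  best <- NULL
  any_ok <- FALSE
  for (st in refine_from) {
    par0 <- log(c(
      max(st$t, .fit_bounds$t[1]), st$kappa, if (free_omega) st$omega
    ))
    o <- tryCatch(
      stats::optim(par0, nll_joint,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e4, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(o)) next
    any_ok <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!any_ok) {
    stopf("codon model fit failed from every start")
  }
  par <- best$par
  # final polish: exact one-dimensional t-profile at the refined (kappa, omega)
  pol <- profile_t(exp(par[2]), if (free_omega) exp(par[3]) else fix_omega)
  if (pol$nll < best$value) {
    best$value <- pol$nll
    par[1] <- log(pol$t)
  }
  structure(
    list(
      t = exp(par[1]),
      kappa = exp(par[2]),
      omega = if (free_omega) exp(par[3]) else fix_omega,
      lnL = -best$value,
      converged = best$convergence == 0,
      fixed_omega = !free_omega,
      codon_freq_mode = codon_freq_mode,
      pi = pi
    ),
    class = "codon_fit"
  )
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf(
    "codon_fit: t=%.4f kappa=%.3f omega=%.4f%s lnL=%.3f%s\n",
    x$t, x$kappa, x$omega, if (x$fixed_omega) " (fixed)" else "",
    x$lnL, if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' Convert a fitted codon model into Ka and Ks
#'
#' Partitions the fitted divergence `t` (expected substitutions per codon)
#' into nonsynonymous and synonymous per-site rates: the expected synonymous
#' flux fraction under the fitted (kappa, omega) gives the substitutions of
#' each class, and site proportions are taken from the same matrix with omega
#' set to 1, so that Ka/Ks equals the fitted omega.
#'
#' @param fit A `codon_fit` from [fit_codon_pair()].
#' @return A list with `Ka` and `Ks`.
#' @export
ml_ka_ks <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"))
  flux <- function(omega) {
    rm_ <- gy94_rate_matrix(fit$kappa, omega, fit$pi)
    tab <- codon_tables()
    off <- rm_$Q * rm_$pi # pi_i * q_ij
    diag(off) <- 0
    syn <- sum(off[tab$synonymous])
    tot <- sum(off)
    c(s = syn / tot, n = 1 - syn / tot)
  }
  at_fit <- flux(fit$omega)
  at_one <- flux(1)
  if (at_one["s"] <= 0) stopf("no synonymous sites under the fitted model")
  list(
    Ka = fit$t * at_fit[["n"]] / (3 * at_one[["n"]]),
    Ks = fit$t * at_fit[["s"]] / (3 * at_one[["s"]])
  )
}
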