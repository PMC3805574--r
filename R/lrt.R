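# Likelihood-ratio tests of haplotype-based Hardy-Weinberg equilibrium.
# Null: HWE (EM fit). Alternative: the Niu model (ECM) or the inbreeding
# model (IEM). Both statistics are 2 * (loglik_alt - loglik_null), referred
# to chi-square with 1 df, following the original proposal; for the
# inbreeding alternative the f >= 0 boundary makes the plain chi-square
# reference conservative, and an optional 0.5*chi2_0 + 0.5*chi2_1 mixture is
# available.

#' Likelihood-ratio test of haplotype-based Hardy-Weinberg equilibrium
#'
#' Fits the HWE null by EM and the chosen alternative (excess-homozygosity
#' Niu model by ECM, or inbreeding model by IEM) on the same genotype data;
#' the statistic is twice the log-likelihood gain, with a chi-square(1)
#' p-value.
#'
#' @inheritParams fit_hwe
#' @param alternative `"niu"` or `"inbreeding"`.
#' @param mixture If `TRUE`, use the boundary-corrected
#'   `0.5*chi2(0) + 0.5*chi2(1)` reference instead of plain chi-square(1)
#'   (only meaningful for the inbreeding alternative; default `FALSE`,
#'   matching the original tests).
#' @return An object of class `hap_hwe_test` with fields `statistic`, `df`,
#'   `p_value`, `null_fit`, `alt_fit`, `test`. `tidy()` and `glance()`
#'   return tibble summaries.
#' @examples
#' g <- sim_genotypes(300, model = "niu", theta = 1.5, seed = 7)
#' hwe_lrt(g, alternative = "niu")
#' @export
hwe_lrt <- function(data, alternative = c("niu", "inbreeding"), snps = NULL,
                    control = hap_control(), mixture = FALSE) {
  alternative <- match.arg(alternative)
  gd <- prepare_gdata(data, snps)
  if (gd$K < 2) {
    inform("degenerate data: a single genotype class; the test is trivial")
  }
  null_core <- run_core(gd, "hwe", control)
  alt_core <- run_core(gd, alternative, control)
  stat <- 2 * (alt_core$loglik - null_core$loglik)
  # the models are nested, so the true statistic is nonnegative; small
  # deficits are stopping-rule slack (boundary fits converge linearly) and
  # are clamped to 0, large ones signal genuine non-convergence
  if (stat < -max(1e-4, 100 * control$tol)) {
    warn(sprintf("alternative fit log-likelihood below null by %.2e; check convergence", -stat / 2))
  }
  stat <- max(stat, 0)
  p <- if (mixture) {
    0.5 * pchisq(stat, df = 1, lower.tail = FALSE) + 0.5 * (stat <= 0)
  } else {
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(
    test = if (alternative == "niu") "LRT_NM" else "LRT_IM",
    statistic = stat, df = 1L, p_value = p, mixture = mixture,
    null_fit = new_hap_fit("hwe", gd, null_core),
    alt_fit = new_hap_fit(alternative, gd, alt_core)
  ), class = "hap_hwe_test")
}

#' @export
print.hap_hwe_test <- function(x, ...) {
  cat("Haplotype-based HWE likelihood-ratio test:", x$test, "\n")
  cat(sprintf("  statistic = %.4f, df = %d, p-value = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$mixture) " (boundary mixture reference)" else ""))
  if (!is.null(x$alt_fit$theta)) cat(sprintf("  theta-hat = %.4f\n", x$alt_fit$theta))
  if (!is.null(x$alt_fit$f)) cat(sprintf("  f-hat = %.4f\n", x$alt_fit$f))
  cat(sprintf("  n = %d individuals, %d SNPs\n", x$null_fit$n, x$null_fit$n_snp))
  invisible(x)
}

#' Tidy a haplotype HWE test
#'
#' @param x A `hap_hwe_test`.
#' @param ... Unused.
#' @return A one-row tibble with `test`, `statistic`, `df`, `p.value`, and
#'   the alternative's parameter estimate (`theta` or `f`).
#' @exportS3Method generics::tidy
tidy.hap_hwe_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    theta = x$alt_fit$theta %||% NA_real_,
    f = x$alt_fit$f %||% NA_real_
  )
}

#' Glance at a haplotype HWE test
#'
#' @param x A `hap_hwe_test`.
#' @param ... Unused.
#' @return A one-row tibble adding the two fits' log-likelihoods and
#'   convergence flags to [tidy.hap_hwe_test()].
#' @exportS3Method generics::glance
glance.hap_hwe_test <- function(x, ...) {
  dplyr::mutate(tidy(x),
    loglik_null = x$null_fit$loglik,
    loglik_alt = x$alt_fit$loglik,
    converged_null = x$null_fit$converged,
    converged_alt = x$alt_fit$converged,
    n = x$null_fit$n
  )
}
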