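# User-facing model fitting.  Genotype data come in as a data frame with one
# row per individual and one character column per SNP ("1/1", "1/2", "2/2";
# NA or "0/0" = missing).  Rows with any missing SNP are dropped (with a
# message) before fitting: compatible-pair enumeration never guesses.

#' Fitting control parameters
#'
#' @param tol Convergence tolerance on the absolute change of the observed
#'   log-likelihood between iterations.
#' @param max_iter Maximum number of iterations.
#' @param theta_init,f_init Initial values for the Niu parameter and the
#'   inbreeding coefficient.
#' @param theta_max Cap on `theta` when the expected homozygote count makes it
#'   unbounded; capped fits are flagged.
#' @param p_init Optional initial frequency vector over the sample support
#'   (mainly for robustness checks); default is uniform over the support.
#' @return A list of class `hap_control`.
#' @export
hap_control <- function(tol = 1e-6, max_iter = 1000L, theta_init = 1,
                        f_init = 0.01, theta_max = 1e3, p_init = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 theta_init = theta_init, f_init = f_init,
                 theta_max = theta_max, p_init = p_init),
            class = "hap_control")
}

# data frame -> per-SNP genotype-code matrix + bookkeeping
geno_codes_matrix <- function(data, snps = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(snps)) {
    snps <- setdiff(names(data),
                    c("id", "fam_id", "father_id", "mother_id", "sex",
                      "phenotype", "founder"))
  }
  if (length(snps) < 1) abort("no SNP columns found")
  gmat <- vapply(snps, function(s) geno_str_to_code(as.character(data[[s]])),
                 integer(nrow(data)))
  if (nrow(data) == 1L) gmat <- matrix(gmat, nrow = 1L, dimnames = list(NULL, snps))
  gmat
}

# shared front door: data frame -> gdata (+ dropped count)
prepare_gdata <- function(data, snps = NULL, quiet = FALSE) {
  gmat <- geno_codes_matrix(data, snps)
  miss <- apply(gmat, 1L, anyNA)
  if (any(miss) && !quiet) {
    inform(paste0("dropping ", sum(miss),
                  " individual(s) with missing genotypes in the block"))
  }
  gmat <- gmat[!miss, , drop = FALSE]
  if (nrow(gmat) < 1) abort("no individuals with complete genotypes")
  gd <- gdata_from_codes(gmat)
  gd$n_dropped <- sum(miss)
  gd
}

new_hap_fit <- function(model, gd, core) {
  structure(list(
    model = model,
    freqs = tibble::tibble(
      haplotype = hap_label(gd$hap_codes, gd$L),
      freq = core$p
    ),
    theta = core$theta, f = core$f,
    loglik = core$loglik, n_iter = core$n_iter,
    converged = core$converged, loglik_trace = core$trace,
    flags = core$flags, n = gd$n, n_dropped = gd$n_dropped %||% 0L,
    n_snp = gd$L, n_hap = length(gd$hap_codes)
  ), class = "hap_fit")
}

fit_engine <- function(data, snps, control, model, quiet = FALSE) {
  gd <- prepare_gdata(data, snps, quiet = quiet)
  core <- run_core(gd, model, control)
  if (!core$converged) {
    warn(paste0(toupper(model), " fit did not converge in ",
                control$max_iter, " iterations"))
  }
  new_hap_fit(model, gd, core)
}

run_core <- function(gd, model, control) {
  switch(model,
    hwe = em_core(gd, control$tol, control$max_iter, control$p_init),
    niu = ecm_core(gd, control$tol, control$max_iter, control$p_init,
                   control$theta_init, control$theta_max),
    inbreeding = iem_core(gd, control$tol, control$max_iter, control$p_init,
                          control$f_init)
  )
}

#' Haplotype frequencies by EM under Hardy-Weinberg equilibrium
#'
#' Excoffier-Slatkin gene-counting EM for haplotype frequencies from unphased
#' multilocus genotypes of unrelated individuals.
#'
#' @param data Data frame, one row per individual, one character column per
#'   SNP with genotypes `"1/1"`, `"1/2"`, `"2/2"` (NA or `"0/0"` = missing).
#'   Rows with any missing SNP are dropped. Columns named `id`, `fam_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`, `founder` are ignored
#'   unless listed in `snps`.
#' @param snps Optional character vector naming the SNP columns (default: all
#'   non-bookkeeping columns).
#' @param control A [hap_control()] list.
#' @return An object of class `hap_fit` with the estimated frequency table
#'   (`$freqs`, over the sample-support haplotypes), the observed-data
#'   log-likelihood, iteration count and trace. Use [tidy()][generics::tidy]
#'   and [glance()][generics::glance] for tibble summaries.
#' @examples
#' g <- sim_genotypes(100, model = "hwe", seed = 1)
#' fit_hwe(g)
#' @export
fit_hwe <- function(data, snps = NULL, control = hap_control()) {
  fit_engine(data, snps, control, "hwe")
}

#' Fit the excess-homozygosity (Niu) model by ECM
#'
#' Expectation-conditional-maximization: each iteration runs one E-step, one
#' closed-form conditional update of `theta`, and one cubic-root conditional
#' update per free haplotype frequency (the highest-weight haplotype absorbs
#' the simplex constraint). `theta = 1` is Hardy-Weinberg equilibrium;
#' `theta > 1` means excess haplotype homozygosity.
#'
#' @inheritParams fit_hwe
#' @return A `hap_fit` with `$theta`.
#' @examples
#' g <- sim_genotypes(200, model = "niu", theta = 1.4, seed = 1)
#' fit_niu(g)$theta
#' @export
fit_niu <- function(data, snps = NULL, control = hap_control()) {
  fit_engine(data, snps, control, "niu")
}

#' Fit the inbreeding model by augmented-data EM (IEM)
#'
#' With probability `f` an individual's two haplotypes are identical by
#' descent (a single founder draw); otherwise they are two independent draws.
#' `f = 0` is Hardy-Weinberg equilibrium. The latent data are the haplotype
#' pair and the IBD indicator; the M-step re-derives `f` as the mean posterior
#' IBD probability and the frequencies as normalized expected draw counts.
#'
#' @inheritParams fit_hwe
#' @return A `hap_fit` with `$f` (clipped to `[0, 1)`).
#' @examples
#' g <- sim_genotypes(200, model = "inbreeding", f = 0.1, seed = 1)
#' fit_inbreeding(g)$f
#' @export
fit_inbreeding <- function(data, snps = NULL, control = hap_control()) {
  fit_engine(data, snps, control, "inbreeding")
}

#' Observed-data log-likelihood of a genotype sample under fixed parameters
#'
#' Sums, over individuals, the log of the total probability of the haplotype
#' pairs compatible with each genotype. A genotype all of whose compatible
#' pairs have probability 0 under `freqs` is an error (support collapse).
#'
#' @inheritParams fit_hwe
#' @param freqs Haplotype frequency table ([hap_freqs()]); haplotypes absent
#'   from it have frequency 0.
#' @param model `"hwe"`, `"niu"` or `"inbreeding"`.
#' @param theta,f Model parameters.
#' @return A single number.
#' @examples
#' g <- tibble::tibble(s1 = "1/1", s2 = "2/2", s3 = "1/1")
#' hap_loglik(g, hap_freqs("121", 1))
#' @export
hap_loglik <- function(data, freqs, model = c("hwe", "niu", "inbreeding"),
                       theta = 1, f = 0, snps = NULL) {
  model <- match.arg(model)
  freqs <- validate_freqs(freqs)
  gd <- prepare_gdata(data, snps, quiet = TRUE)
  p <- numeric(length(gd$hap_codes))
  idx <- match(gd$hap_codes, hap_code(freqs$haplotype))
  p[!is.na(idx)] <- freqs$freq[idx[!is.na(idx)]]
  # the Niu normalizer uses the full supplied support, not just sample haps
  if (model == "niu") {
    C <- 1 + (theta - 1) * sum(freqs$freq^2)
    pp <- pair_prob_kernel(p[gd$h1], p[gd$h2], gd$hom, "niu", theta, C = C)
    den <- as.vector(rowsum(pp, gd$pair_class))
    check_support(gd, den)
    return(sum(gd$cnt * log(den)))
  }
  gd_loglik(gd, p, model, theta = theta, f = f)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.hap_fit <- function(x, ...) {
  lab <- c(hwe = "HWE (EM)", niu = "Niu / excess homozygosity (ECM)",
           inbreeding = "inbreeding (IEM)")[[x$model]]
  cat("Haplotype frequency fit:", lab, "\n")
  cat(sprintf("  n = %d individuals (%d dropped), %d SNPs, %d support haplotypes\n",
              x$n, x$n_dropped, x$n_snp, x$n_hap))
  if (!is.null(x$theta)) cat(sprintf("  theta-hat = %.4f\n", x$theta))
  if (!is.null(x$f)) cat(sprintf("  f-hat = %.4f\n", x$f))
  cat(sprintf("  log-likelihood = %.4f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  top <- dplyr::arrange(x$freqs, dplyr::desc(.data$freq))
  print(head(top, 8), n = 8)
  invisible(x)
}

#' Tidy a haplotype fit
#'
#' @param x A `hap_fit`.
#' @param threshold Haplotypes with estimated frequency below this are
#'   dropped from the report (they are kept during fitting).
#' @param ... Unused.
#' @return A tibble with columns `haplotype`, `freq`, sorted by decreasing
#'   frequency.
#' @exportS3Method generics::tidy
tidy.hap_fit <- function(x, threshold = 0, ...) {
  dplyr::arrange(dplyr::filter(x$freqs, .data$freq >= threshold),
                 dplyr::desc(.data$freq))
}

#' Glance at a haplotype fit
#'
#' @param x A `hap_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model, parameter estimates, log-likelihood
#'   and convergence information.
#' @exportS3Method generics::glance
glance.hap_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    theta = x$theta %||% NA_real_,
    f = x$f %||% NA_real_,
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    n = x$n,
    n_hap = x$n_hap
  )
}

#' Plot the log-likelihood trace of a fit
#'
#' @param object A `hap_fit`.
#' @param ... Unused.
#' @return A ggplot of observed log-likelihood by iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.hap_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "observed log-likelihood",
                  title = paste("Convergence of", object$model, "fit"))
}
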