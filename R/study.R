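# The size/power/accuracy study: for each (model, parameter, n) setting,
# replicate data sets are sampled, all three fitters are run on the shared
# collapsed genotype classes, and the two LRTs are evaluated at level alpha.

# deterministic per-replicate child seed (< 2^31 - 1)
child_seed <- function(master, setting, rep) {
  as.integer((as.numeric(master) * 1009 + setting * 100003 + rep) %% 2147483647)
}

run_one_setting <- function(model, param, n, n_reps, alpha, freqs, freqs2,
                            control, master_seed, setting_idx, true_by_code) {
  theta <- if (model == "niu") param else 1
  f <- if (model == "inbreeding") param else 0
  lambda <- if (model == "stratified") param else 0.6

  theta_hat <- numeric(n_reps); f_hat <- numeric(n_reps)
  sad_em <- numeric(n_reps); sad_ecm <- numeric(n_reps); sad_iem <- numeric(n_reps)
  rej_nm <- logical(n_reps); rej_im <- logical(n_reps)
  fails <- 0L

  for (r in seq_len(n_reps)) {
    set.seed(child_seed(master_seed, setting_idx, r))
    sc <- sample_class_ids(n, model, freqs, theta, f, lambda, freqs2)
    tab <- tabulate(sc$ids, nbins = 3L^sc$L)
    keep <- which(tab > 0L)
    gd <- build_gdata(keep, tab[keep], sc$L)

    em <- em_core(gd, control$tol, control$max_iter)
    ecm <- ecm_core(gd, control$tol, control$max_iter,
                    theta_init = control$theta_init, theta_max = control$theta_max)
    iem <- iem_core(gd, control$tol, control$max_iter, f_init = control$f_init)
    if (!(em$converged && ecm$converged && iem$converged)) fails <- fails + 1L

    theta_hat[r] <- ecm$theta
    f_hat[r] <- iem$f
    sad_em[r] <- sad_codes(true_by_code, gd$hap_codes, em$p)
    sad_ecm[r] <- sad_codes(true_by_code, gd$hap_codes, ecm$p)
    sad_iem[r] <- sad_codes(true_by_code, gd$hap_codes, iem$p)

    stat_nm <- max(2 * (ecm$loglik - em$loglik), 0)
    stat_im <- max(2 * (iem$loglik - em$loglik), 0)
    rej_nm[r] <- pchisq(stat_nm, 1, lower.tail = FALSE) < alpha
    rej_im[r] <- pchisq(stat_im, 1, lower.tail = FALSE) < alpha
  }

  tibble::tibble(
    model = model, param = param, n = n, n_reps = n_reps, alpha = alpha,
    theta_mean = mean(theta_hat), theta_sd = stats::sd(theta_hat),
    f_mean = mean(f_hat), f_sd = stats::sd(f_hat),
    sad_em = mean(sad_em), sad_ecm = mean(sad_ecm), sad_iem = mean(sad_iem),
    reject_nm = mean(rej_nm), reject_im = mean(rej_im),
    n_fail = fails, seed = master_seed
  )
}

#' Run the size/power/accuracy simulation study
#'
#' For each combination of `param` and `n`: draws `n_reps` replicate samples
#' under the generating model, fits all three estimators (EM under HWE, ECM
#' under the Niu model, IEM under the inbreeding model), records the mean and
#' SD of the parameter estimates, the mean sum of absolute differences (SAD)
#' of each frequency estimate from the generating frequencies, and the
#' rejection rates of both LRTs at level `alpha`.
#'
#' @param model Generating model: `"hwe"`, `"niu"`, `"inbreeding"` or
#'   `"stratified"`.
#' @param param Vector of generating parameter values: `theta` for `"niu"`,
#'   `f` for `"inbreeding"`, `lambda` for `"stratified"`; ignored (fixed at
#'   HWE) for `"hwe"`.
#' @param n Vector of sample sizes.
#' @param n_reps Replicates per setting (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; per-replicate child seeds are derived from it
#'   deterministically, so results are fully reproducible.
#' @param freqs Generating haplotype frequencies; default
#'   [default_sim_freqs()] (subpopulation I of [stratified_sim_freqs()] for
#'   `"stratified"`).
#' @param freqs2 Subpopulation-II frequencies for `"stratified"`.
#' @param control A [hap_control()] list for the fitters.
#' @return A tibble of class `hap_study`, one row per (param, n) setting,
#'   with columns `theta_mean`, `theta_sd`, `f_mean`, `f_sd`, `sad_em`,
#'   `sad_ecm`, `sad_iem`, `reject_nm`, `reject_im`, `n_fail`, `seed`.
#' @examples
#' run_study("niu", param = 1.5, n = 200, n_reps = 20, seed = 1)
#' @export
run_study <- function(model = c("hwe", "niu", "inbreeding", "stratified"),
                      param = NULL, n = 1000, n_reps = 1000, alpha = 0.05,
                      seed = 1, freqs = NULL, freqs2 = NULL,
                      control = hap_control()) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1, all(n >= 1))
  if (model == "stratified") {
    st <- stratified_sim_freqs()
    freqs <- freqs %||% hap_freqs(st$haplotype, st$freq_I)
    freqs2 <- freqs2 %||% hap_freqs(st$haplotype, st$freq_II)
    freqs2 <- validate_freqs(freqs2)
  }
  freqs <- freqs %||% default_sim_freqs()
  freqs <- validate_freqs(freqs)
  param <- param %||% switch(model, hwe = 1, niu = 1, inbreeding = 0,
                             stratified = 0.6)
  if (model == "stratified") stopifnot(all(param > 0), all(param < 1))

  # SAD truth: the generating marginal haplotype distribution (for the
  # stratified model, the lambda-mixture of the two subpopulations)
  grid <- tidyr::expand_grid(param = param, n = n)
  out <- purrr::pmap(list(grid$param, grid$n, seq_len(nrow(grid))),
    function(pm, nn, si) {
      tbc <- if (model == "stratified") {
        v <- pm * freqs$freq + (1 - pm) *
          freqs2$freq[match(freqs$haplotype, freqs2$haplotype)]
        extra <- setdiff(freqs2$haplotype, freqs$haplotype)
        v2 <- (1 - pm) * freqs2$freq[match(extra, freqs2$haplotype)]
        setNames(c(v, v2), as.character(hap_code(c(freqs$haplotype, extra))))
      } else {
        setNames(freqs$freq, as.character(hap_code(freqs$haplotype)))
      }
      run_one_setting(model, pm, nn, n_reps, alpha, freqs, freqs2,
                      control, seed, si, tbc)
    })
  res <- dplyr::bind_rows(out)
  class(res) <- c("hap_study", class(res))
  res
}

#' Plot rejection rates of a simulation study
#'
#' @param object A `hap_study` tibble from [run_study()].
#' @param ... Unused.
#' @return A ggplot of rejection rate against the generating parameter, one
#'   line per test, faceted by sample size.
#' @exportS3Method ggplot2::autoplot
autoplot.hap_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("reject_nm", "reject_im"),
                              names_to = "test", values_to = "rate")
  long$test <- c(reject_nm = "LRT_NM", reject_im = "LRT_IM")[long$test]
  ggplot2::ggplot(long, ggplot2::aes(.data$param, .data$rate,
                                     colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = unique(object$alpha), linetype = 2) +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "generating parameter", y = "rejection rate",
                  colour = NULL,
                  title = paste("Size/power under the", object$model[1], "model"))
}
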