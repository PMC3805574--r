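# Genotype sampling under the four generating models of the simulation
# study: HWE, the excess-homozygosity (Niu) model, the inbreeding model, and
# a two-subpopulation stratification model (HWE within each subpopulation).
# Pairs are drawn exactly from the model's unordered-pair distribution and
# combined into unphased genotypes.

#' Three-SNP haplotype distribution used in the simulation study
#'
#' The five-haplotype distribution over three tightly linked SNPs that drives
#' the single-population size/power/accuracy study (homozygosity
#' `S = sum(p^2) = 0.37369`).
#'
#' @return A haplotype frequency tibble (see [hap_freqs()]).
#' @examples
#' default_sim_freqs()
#' @export
default_sim_freqs <- function() {
  hap_freqs(c("122", "221", "121", "211", "111"),
            c(0.082, 0.525, 0.283, 0.004, 0.106))
}

#' Two-subpopulation haplotype distributions for the stratification model
#'
#' @return A tibble with columns `haplotype`, `freq_I`, `freq_II`; each
#'   frequency column sums to 1.
#' @examples
#' stratified_sim_freqs()
#' @export
stratified_sim_freqs <- function() {
  tibble::tibble(
    haplotype = c("122", "212", "112", "221", "121", "211", "111"),
    freq_I  = c(0.082, 0.000, 0.000, 0.525, 0.283, 0.004, 0.106),
    freq_II = c(0.030, 0.170, 0.050, 0.470, 0.100, 0.150, 0.030)
  )
}

# internal: pair distribution (codes + probs) for a single-population model
pair_distribution <- function(freqs, model, theta = 1, f = 0) {
  pp <- pair_probs(freqs, model = model, theta = theta, f = f)
  L <- nchar(freqs$haplotype[1])
  list(
    h1 = hap_code(pp$hap1), h2 = hap_code(pp$hap2),
    prob = pp$prob, L = L
  )
}

# internal: sample n genotype-class ids (1..3^L) under a generating model
sample_class_ids <- function(n, model, freqs, theta, f, lambda, freqs2) {
  if (model %in% c("hwe", "niu", "inbreeding")) {
    pd <- pair_distribution(freqs, model, theta, f)
    j <- sample.int(length(pd$prob), n, replace = TRUE, prob = pd$prob)
    h1 <- pd$h1[j]; h2 <- pd$h2[j]; L <- pd$L
  } else { # stratified: HWE within each subpopulation
    L <- nchar(freqs$haplotype[1])
    in_I <- stats::runif(n) < lambda
    n1 <- sum(in_I)
    cod1 <- hap_code(freqs$haplotype)
    cod2 <- hap_code(freqs2$haplotype)
    h1 <- integer(n); h2 <- integer(n)
    if (n1 > 0) {
      h1[in_I] <- sample(cod1, n1, replace = TRUE, prob = freqs$freq)
      h2[in_I] <- sample(cod1, n1, replace = TRUE, prob = freqs$freq)
    }
    if (n1 < n) {
      h1[!in_I] <- sample(cod2, n - n1, replace = TRUE, prob = freqs2$freq)
      h2[!in_I] <- sample(cod2, n - n1, replace = TRUE, prob = freqs2$freq)
    }
  }
  wt <- 2L^((L - 1L):0L)
  # per-SNP genotype code = allele-2 count; class id in base 3
  ids <- rep(1L, n)
  for (s in seq_len(L)) {
    g <- bitwAnd(h1 %/% wt[s], 1L) + bitwAnd(h2 %/% wt[s], 1L)
    ids <- ids + g * 3L^(s - 1L)
  }
  list(ids = ids, L = L)
}

#' Simulate unphased genotypes of unrelated individuals
#'
#' Draws one unordered haplotype pair per individual exactly from the
#' generating model's pair distribution, then combines the two haplotypes
#' into an unphased multilocus genotype.
#'
#' @param n Number of individuals.
#' @param model `"hwe"`, `"niu"`, `"inbreeding"` or `"stratified"`.
#' @param freqs Haplotype frequency table; default [default_sim_freqs()]
#'   (for `"stratified"`, subpopulation I of [stratified_sim_freqs()]).
#' @param theta Niu parameter (> 0; `model = "niu"`).
#' @param f Inbreeding coefficient (`model = "inbreeding"`).
#' @param lambda Proportion of subpopulation I (`model = "stratified"`).
#' @param freqs2 Subpopulation-II frequency table (`model = "stratified"`).
#' @param seed Optional integer seed.
#' @param snp_names Column names for the SNPs; default `snp1..snpL`.
#' @return A tibble with an `id` column and one genotype column per SNP.
#' @examples
#' sim_genotypes(5, model = "niu", theta = 1.3, seed = 1)
#' @export
sim_genotypes <- function(n, model = c("hwe", "niu", "inbreeding", "stratified"),
                          freqs = NULL, theta = 1, f = 0, lambda = 0.6,
                          freqs2 = NULL, seed = NULL, snp_names = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (model == "stratified") {
    st <- stratified_sim_freqs()
    freqs <- freqs %||% hap_freqs(st$haplotype, st$freq_I)
    freqs2 <- freqs2 %||% hap_freqs(st$haplotype, st$freq_II)
    freqs2 <- validate_freqs(freqs2)
    stopifnot(lambda > 0, lambda < 1)
  } else {
    freqs <- freqs %||% default_sim_freqs()
  }
  freqs <- validate_freqs(freqs)
  sc <- sample_class_ids(n, model, freqs, theta, f, lambda, freqs2)
  L <- sc$L
  cols <- lapply(seq_len(L), function(s) {
    geno_code_to_str((sc$ids - 1L) %/% 3L^(s - 1L) %% 3L)
  })
  names(cols) <- snp_names %||% paste0("snp", seq_len(L))
  dplyr::bind_cols(tibble::tibble(id = seq_len(n)), tibble::as_tibble(cols))
}

#' Sum of absolute differences between two haplotype frequency tables
#'
#' `sum_h |p_h - phat_h|` over the union of the two supports (a haplotype
#' absent from one table counts with frequency 0 there). 0 means perfect
#' estimation; the maximum is 2.
#'
#' @param true,est Haplotype frequency tables (see [hap_freqs()]).
#' @return A single nonnegative number.
#' @examples
#' sad(hap_freqs(c("11", "22"), c(1, 0)), hap_freqs(c("11", "22"), c(0, 1)))
#' @export
sad <- function(true, est) {
  true <- validate_freqs(true)
  est <- validate_freqs(est)
  j <- dplyr::full_join(true, est, by = "haplotype", suffix = c("_true", "_est"))
  sum(abs(dplyr::coalesce(j$freq_true, 0) - dplyr::coalesce(j$freq_est, 0)))
}

# internal: SAD from a named true-frequency vector (names = hap codes as
# character) and a support-estimate vector; used by run_study's hot loop
sad_codes <- function(true_by_code, est_codes, est_p) {
  key <- as.character(est_codes)
  idx <- match(key, names(true_by_code))
  tr <- ifelse(is.na(idx), 0, true_by_code[idx])
  sum(abs(tr - est_p)) + sum(true_by_code[!(names(true_by_code) %in% key)])
}
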