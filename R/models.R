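# Probability of an unordered haplotype pair under three population models:
#   hwe          : P(k,k) = p_k^2,                 P(k,l) = 2 p_k p_l
#   niu          : P(k,k) = theta p_k^2 / C,       P(k,l) = 2 p_k p_l / C
#                  with C = 1 + (theta - 1) * S,   S = sum_h p_h^2
#   inbreeding   : P(k,k) = f p_k + (1-f) p_k^2,   P(k,l) = (1-f) 2 p_k p_l
# theta = 1 and f = 0 both reduce to hwe.

#' Construct a haplotype frequency table
#'
#' @param haplotype Character vector of haplotype strings over alleles `{1,2}`,
#'   all of equal length.
#' @param freq Numeric frequencies, nonnegative, summing to 1 (within 1e-8).
#' @return A tibble with columns `haplotype` and `freq`.
#' @examples
#' hap_freqs(c("11", "22"), c(0.5, 0.5))
#' @export
hap_freqs <- function(haplotype, freq) {
  stopifnot(length(haplotype) == length(freq))
  if (anyDuplicated(haplotype)) abort("duplicated haplotypes in frequency table")
  if (length(unique(nchar(haplotype))) != 1L) abort("haplotypes differ in length")
  hap_code(haplotype)  # validates alleles
  if (any(freq < -1e-12)) abort("negative haplotype frequency")
  if (abs(sum(freq) - 1) > 1e-8) {
    abort(paste0("haplotype frequencies sum to ", format(sum(freq)), ", not 1"))
  }
  tibble::tibble(haplotype = haplotype, freq = pmax(freq, 0))
}

validate_freqs <- function(freqs) {
  if (!is.data.frame(freqs) || !all(c("haplotype", "freq") %in% names(freqs))) {
    abort("`freqs` must be a data frame with columns `haplotype` and `freq`")
  }
  hap_freqs(freqs$haplotype, freqs$freq)
}

#' Normalizing constant of the excess-homozygosity (Niu) model
#'
#' Up-weighting homozygous pairs by `theta` leaves the pair probabilities
#' summing to `C = 1 + (theta - 1) * S` with `S = sum(p^2)` the haplotype
#' homozygosity; all pair probabilities are divided by `C`.
#'
#' @param freqs Haplotype frequency table (see [hap_freqs()]).
#' @param theta Homozygosity parameter, `theta > 0`; `theta = 1` is HWE.
#' @return The normalizer `C` as a single number.
#' @examples
#' niu_normalizer(hap_freqs(c("11", "22"), c(0.5, 0.5)), theta = 1.5)
#' @export
niu_normalizer <- function(freqs, theta) {
  freqs <- validate_freqs(freqs)
  if (theta <= 0) abort("`theta` must be > 0")
  1 + (theta - 1) * sum(freqs$freq^2)
}

#' Unordered haplotype-pair probabilities under a population model
#'
#' Enumerates every unordered pair over the support of `freqs` and returns the
#' probability each model assigns to it. Under every model the probabilities
#' sum to 1.
#'
#' @param freqs Haplotype frequency table (see [hap_freqs()]).
#' @param model `"hwe"`, `"niu"` (excess homozygosity, parameter `theta`) or
#'   `"inbreeding"` (inbreeding coefficient `f`).
#' @param theta Niu-model parameter (> 0); ignored otherwise.
#' @param f Inbreeding coefficient in `[0, 1)`; ignored otherwise.
#' @return A tibble with columns `hap1`, `hap2`, `homozygous`, `prob`.
#' @examples
#' pair_probs(hap_freqs(c("11", "22"), c(0.5, 0.5)), model = "niu", theta = 1.5)
#' @export
pair_probs <- function(freqs, model = c("hwe", "niu", "inbreeding"),
                       theta = 1, f = 0) {
  model <- match.arg(model)
  freqs <- validate_freqs(freqs)
  H <- nrow(freqs)
  idx <- which(upper.tri(matrix(0, H, H), diag = TRUE), arr.ind = TRUE)
  k <- idx[, "row"]; l <- idx[, "col"]
  # canonical within-pair order by integer code
  cd <- hap_code(freqs$haplotype)
  flip <- cd[k] > cd[l]
  tmp <- k[flip]; k[flip] <- l[flip]; l[flip] <- tmp
  p <- freqs$freq
  hom <- k == l
  C <- if (model == "niu") niu_normalizer(freqs, theta) else 1
  prob <- pair_prob_kernel(p[k], p[l], hom, model, theta, f, C)
  ord <- order(cd[k], cd[l])
  tibble::tibble(
    hap1 = freqs$haplotype[k],
    hap2 = freqs$haplotype[l],
    homozygous = hom,
    prob = prob
  )[ord, ]
}

# vectorised pair-probability kernel shared by pair_probs and the fitters;
# C is the Niu normalizer 1 + (theta - 1) * sum(p^2) over the FULL support
pair_prob_kernel <- function(pk, pl, hom, model, theta = 1, f = 0, C = 1) {
  switch(model,
    hwe = ifelse(hom, pk^2, 2 * pk * pl),
    niu = {
      if (theta <= 0) abort("`theta` must be > 0")
      ifelse(hom, theta * pk^2, 2 * pk * pl) / C
    },
    inbreeding = {
      if (f < 0 || f >= 1) abort("`f` must be in [0, 1)")
      ifelse(hom, f * pk + (1 - f) * pk^2, (1 - f) * 2 * pk * pl)
    }
  )
}
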