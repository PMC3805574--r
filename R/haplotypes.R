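# Haplotypes over L biallelic SNPs, alleles coded 1/2.  A haplotype is held
# user-side as a string of allele codes ("121") and internally as the integer
# obtained by reading the alleles as binary digits (1 -> 0, 2 -> 1, SNP 1 most
# significant), so "121" -> 010b -> 2.  Unphased genotypes are per-SNP
# unordered allele pairs, user-side strings "1/1", "1/2", "2/2" (heterozygotes
# normalised to "1/2") and internally per-SNP counts of allele 2 (0, 1, 2).

#' Integer code of a haplotype
#'
#' Haplotypes over L biallelic SNPs are stored as integers in `[0, 2^L)`:
#' allele 1 maps to binary digit 0, allele 2 to 1, with SNP 1 the most
#' significant digit. So `"121"` has code 2 and `"222"` code 7.
#'
#' @param haplotype Character vector of haplotypes, e.g. `"121"`; each
#'   character must be `"1"` or `"2"`.
#' @return Integer vector of codes.
#' @examples
#' hap_code(c("111", "121", "222"))
#' @seealso [hap_label()] for the inverse.
#' @export
hap_code <- function(haplotype) {
  stopifnot(is.character(haplotype))
  vapply(haplotype, function(h) {
    a <- strsplit(h, "", fixed = TRUE)[[1]]
    if (!all(a %in% c("1", "2"))) {
      abort(paste0("invalid haplotype '", h, "': alleles must be 1 or 2"))
    }
    bits <- as.integer(a == "2")
    as.integer(sum(bits * 2L^((length(bits) - 1L):0L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Haplotype string from an integer code
#'
#' @param code Integer vector of haplotype codes in `[0, 2^n_snp)`.
#' @param n_snp Number of SNPs L.
#' @return Character vector of allele strings over `{1,2}`.
#' @examples
#' hap_label(0:7, n_snp = 3)
#' @export
hap_label <- function(code, n_snp) {
  stopifnot(all(code >= 0), all(code < 2^n_snp))
  vapply(code, function(cd) {
    bits <- bitwAnd(cd %/% 2L^((n_snp - 1L):0L), 1L)
    paste(ifelse(bits == 1L, "2", "1"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- internal genotype-code plumbing ---------------------------------------

# per-SNP genotype codes: 0 = 1/1, 1 = 1/2, 2 = 2/2 (count of allele 2)

# parse user genotype strings "a/b" -> codes; NA or "0/0" -> NA
geno_str_to_code <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & x != "0/0" & x != "0"
  if (!any(ok)) return(out)
  parts <- strsplit(x[ok], "/", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2 || !all(p %in% c("1", "2")), logical(1))
  if (any(bad)) {
    abort(paste0("invalid genotype string(s): ",
                 paste(unique(x[ok][bad]), collapse = ", "),
                 " (expected '1/1', '1/2', '2/2', or NA/'0/0' for missing)"))
  }
  out[ok] <- vapply(parts, function(p) sum(p == "2"), integer(1))
  out
}

geno_code_to_str <- function(code) {
  c("1/1", "1/2", "2/2")[code + 1L]
}

# class id (1-based) from per-SNP genotype codes; base-3, SNP 1 least significant
geno_class_id <- function(codes) {
  sum(codes * 3L^(seq_along(codes) - 1L)) + 1L
}

class_codes <- function(id, L) {
  x <- id - 1L
  codes <- integer(L)
  for (j in seq_len(L)) {
    codes[j] <- x %% 3L
    x <- x %/% 3L
  }
  codes
}

# enumerate compatible haplotype pairs (integer codes, canonical order) for
# one genotype given as per-SNP codes; s het SNPs -> max(1, 2^(s-1)) pairs
pairs_for_codes <- function(codes) {
  L <- length(codes)
  if (anyNA(codes)) abort("genotype has missing SNPs; filter or impute first")
  wt <- 2L^((L - 1L):0L)
  base <- sum(wt[codes == 2L])
  het <- which(codes == 1L)
  s <- length(het)
  if (s == 0L) return(cbind(first = base, second = base))
  m <- 2L^(s - 1L)
  tot_het <- sum(wt[het])
  first <- integer(m); second <- integer(m)
  rest <- het[-1L]
  for (i in seq_len(m) - 1L) {
    bitsA <- 0L
    if (s > 1L) {
      sel <- bitwAnd(i, 2L^(seq_len(s - 1L) - 1L)) > 0L
      bitsA <- sum(wt[rest[sel]])
    }
    # hap A takes allele 1 at the first het SNP, so A < B: canonical order
    first[i + 1L] <- base + bitsA
    second[i + 1L] <- base + tot_het - bitsA
  }
  ord <- order(first, second)
  cbind(first = first[ord], second = second[ord])
}

# per-SNP genotype codes induced by a pair of haplotype codes
codes_for_pair <- function(h1, h2, L) {
  wt <- 2L^((L - 1L):0L)
  b1 <- bitwAnd(h1 %/% wt, 1L)
  b2 <- bitwAnd(h2 %/% wt, 1L)
  b1 + b2
}

# ---- exported tidy wrappers -------------------------------------------------

#' Enumerate haplotype pairs compatible with an unphased genotype
#'
#' For a genotype with `s` heterozygous SNPs there are `max(1, 2^(s-1))`
#' unordered haplotype pairs that induce it; they are returned in a
#' deterministic order (sorted by integer codes).
#'
#' @param genotype Character vector, one entry per SNP, each `"1/1"`, `"1/2"`
#'   or `"2/2"`. Missing genotypes are an error: this function never guesses.
#' @return A tibble with columns `hap1`, `hap2` (haplotype strings, canonical
#'   order `hap_code(hap1) <= hap_code(hap2)`) and `homozygous`.
#' @examples
#' compatible_pairs(c("1/2", "1/1", "1/2"))
#' @export
compatible_pairs <- function(genotype) {
  codes <- geno_str_to_code(genotype)
  if (anyNA(codes)) abort("genotype has missing SNPs; filter or impute first")
  pm <- pairs_for_codes(codes)
  L <- length(codes)
  tibble::tibble(
    hap1 = hap_label(pm[, 1L], L),
    hap2 = hap_label(pm[, 2L], L),
    homozygous = pm[, 1L] == pm[, 2L]
  )
}

#' Unphased genotype induced by a haplotype pair
#'
#' @param hap1,hap2 Haplotype strings of equal length.
#' @return Character vector of per-SNP genotypes (`"1/1"`, `"1/2"`, `"2/2"`).
#' @examples
#' pair_genotype("111", "212")
#' @export
pair_genotype <- function(hap1, hap2) {
  if (nchar(hap1) != nchar(hap2)) abort("haplotypes differ in length")
  L <- nchar(hap1)
  geno_code_to_str(codes_for_pair(hap_code(hap1), hap_code(hap2), L))
}
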