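# Linkage pedigree (PED) input, haplotype-block definitions, founder
# selection, and the block-by-block HWE analysis with text + delimited
# output.

#' Read a linkage pedigree (PED) file
#'
#' Whitespace-delimited text, one row per individual: six bookkeeping columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele tokens per SNP. Allele labels may be anything (`1/2`, `A/C/G/T`,
#' ...); per SNP they are mapped to codes 1 and 2 in order of first
#' appearance, `"0"` meaning missing. The mapping is returned in the
#' `allele_map` attribute so results are label-stable. Malformed rows
#' (wrong column count, more than two alleles at a SNP) are dropped with a
#' warning naming the line numbers.
#'
#' @param path Path to the PED file.
#' @param snp_names Optional SNP names; default `snp1..snpM`.
#' @return A tibble with columns `fam_id`, `id`, `father_id`, `mother_id`,
#'   `sex`, `phenotype`, `founder` (both parent ids `"0"`), and one genotype
#'   column per SNP (`"1/1"`, `"1/2"`, `"2/2"`, NA). Attributes:
#'   `allele_map` (tibble snp/allele/code), `rejected_lines` (integer).
#' @export
read_ped <- function(path, snp_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty PED file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(toks)
  n_col <- as.integer(stats::median(nc))
  if (n_col < 8 || (n_col - 6) %% 2 != 0) {
    abort(paste0("PED rows must have 6 + 2*M columns; found ", n_col))
  }
  bad <- which(nc != n_col)
  M <- (n_col - 6L) %/% 2L
  snp_names <- snp_names %||% paste0("snp", seq_len(M))
  stopifnot(length(snp_names) == M)

  ok <- setdiff(seq_along(toks), bad)
  tm <- do.call(rbind, toks[ok])
  ped <- tibble::tibble(
    fam_id = tm[, 1], id = tm[, 2], father_id = tm[, 3], mother_id = tm[, 4],
    sex = tm[, 5], phenotype = tm[, 6],
    founder = tm[, 3] == "0" & tm[, 4] == "0"
  )

  amap <- vector("list", M)
  for (s in seq_len(M)) {
    a1 <- tm[, 5 + 2 * s]
    a2 <- tm[, 6 + 2 * s]
    labs <- unique(c(a1, a2))
    labs <- labs[labs != "0"]
    # labels already coded 1/2 are kept as-is so numeric PED files
    # round-trip exactly; other labels map in order of first appearance
    if (all(labs %in% c("1", "2"))) labs <- c("1", "2")
    if (length(labs) > 2) {
      abort(paste0("SNP ", snp_names[s], " has more than 2 alleles: ",
                   paste(labs, collapse = ", ")))
    }
    amap[[s]] <- tibble::tibble(snp = snp_names[s],
                                allele = labs,
                                code = seq_along(labs))
    c1 <- match(a1, labs); c2 <- match(a2, labs)
    g <- ifelse(is.na(c1) | is.na(c2), NA_character_,
                paste(pmin(c1, c2), pmax(c1, c2), sep = "/"))
    ped[[snp_names[s]]] <- g
  }
  if (length(bad) > 0) {
    warn(paste0("rejected ", length(bad), " malformed PED row(s) at line(s): ",
                paste(bad, collapse = ", ")))
  }
  attr(ped, "allele_map") <- dplyr::bind_rows(amap)
  attr(ped, "rejected_lines") <- as.integer(bad)
  ped
}

#' Read a haplotype-block definition file
#'
#' One block per line: the SNP names or 1-based SNP indices belonging to the
#' block, whitespace-separated. Lines starting with `#` are comments.
#'
#' @param path Path to the block file.
#' @return A list of character vectors (one per block).
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort("no blocks in block file")
  blocks <- strsplit(lines, "[ \t,]+")
  short <- which(lengths(blocks) < 2)
  if (length(short) > 0) {
    abort(paste0("block(s) ", paste(short, collapse = ", "),
                 " have fewer than 2 SNPs"))
  }
  blocks
}

#' Keep only pedigree founders
#'
#' Founders (both parent ids `"0"`) are treated as unrelated individuals; all
#' nonfounders are excluded from HWE analysis.
#'
#' @param ped A tibble from [read_ped()] (needs a `founder` column).
#' @return The founder rows; the number excluded is reported via a message.
#' @export
select_founders <- function(ped) {
  stopifnot("founder" %in% names(ped))
  out <- dplyr::filter(ped, .data$founder)
  if (nrow(out) == 0) abort("no founders in the pedigree data")
  n_ex <- nrow(ped) - nrow(out)
  if (n_ex > 0) inform(paste0("excluded ", n_ex, " nonfounder(s)"))
  out
}

# resolve a block (names or indices) to genotype column names of ped
resolve_block <- function(block, ped) {
  snp_cols <- setdiff(names(ped), c("fam_id", "id", "father_id", "mother_id",
                                    "sex", "phenotype", "founder"))
  if (all(grepl("^[0-9]+$", block))) {
    idx <- as.integer(block)
    if (any(idx < 1 | idx > length(snp_cols))) {
      abort(paste0("block SNP index out of range (1..", length(snp_cols), ")"))
    }
    return(snp_cols[idx])
  }
  missing <- setdiff(block, snp_cols)
  if (length(missing) > 0) {
    abort(paste0("block SNP(s) not in PED data: ", paste(missing, collapse = ", ")))
  }
  block
}

#' Block-wise haplotype-based HWE analysis
#'
#' For each haplotype block: founders with a complete in-block genotype are
#' analysed (individuals missing any in-block SNP are dropped and counted);
#' haplotype frequencies are fitted by EM (HWE), ECM (Niu model) and IEM
#' (inbreeding model); both LRTs of HWE are computed. Blocks with fewer than
#' `min_individuals` usable founders are skipped with a reason.
#'
#' @param ped A tibble from [read_ped()]; nonfounders are excluded
#'   automatically.
#' @param blocks A list of blocks from [read_blocks()] (SNP names or 1-based
#'   indices), or a single character vector for one block.
#' @param control A [hap_control()] list.
#' @param alpha Significance level for the (optionally Bonferroni-adjusted)
#'   significance flags.
#' @param bonferroni Adjust the significance threshold to `alpha / n_blocks`
#'   across analysed blocks (default `TRUE`).
#' @param min_individuals Minimum usable founders per block (default 20).
#' @param report_threshold Haplotypes with all three frequency estimates
#'   below this are omitted from the per-block frequency table (default
#'   1e-3).
#' @return A tibble of class `hap_block_report`, one row per block, with the
#'   per-block sample sizes, `theta`/`f` estimates, both LRT statistics and
#'   p-values, significance flags, a `skipped` reason (NA when analysed) and
#'   a list-column `freq_table` of per-haplotype estimates under the three
#'   fits.
#' @export
analyze_blocks <- function(ped, blocks, control = hap_control(), alpha = 0.05,
                           bonferroni = TRUE, min_individuals = 20,
                           report_threshold = 1e-3) {
  if (is.character(blocks)) blocks <- list(blocks)
  founders <- select_founders(ped)
  rows <- purrr::imap(blocks, function(block, bi) {
    snps <- resolve_block(block, founders)
    gmat_ok <- !apply(geno_codes_matrix(founders, snps), 1L, anyNA)
    n_used <- sum(gmat_ok)
    base <- tibble::tibble(
      block = bi, snps = paste(snps, collapse = ","),
      n_founders = nrow(founders), n_used = n_used,
      n_missing_dropped = nrow(founders) - n_used
    )
    if (n_used < min_individuals) {
      return(dplyr::mutate(base,
        skipped = paste0("only ", n_used, " usable founders (< ",
                         min_individuals, ")"),
        theta = NA_real_, lrt_nm = NA_real_, p_nm = NA_real_,
        f = NA_real_, lrt_im = NA_real_, p_im = NA_real_,
        converged = NA, freq_table = list(NULL)))
    }
    dat <- founders[gmat_ok, ]
    nm <- hwe_lrt(dat, "niu", snps = snps, control = control)
    im <- hwe_lrt(dat, "inbreeding", snps = snps, control = control)
    ft <- dplyr::full_join(
      dplyr::full_join(
        dplyr::rename(nm$null_fit$freqs, em = "freq"),
        dplyr::rename(nm$alt_fit$freqs, ecm = "freq"), by = "haplotype"),
      dplyr::rename(im$alt_fit$freqs, iem = "freq"), by = "haplotype")
    ft <- dplyr::filter(ft, pmax(.data$em, .data$ecm, .data$iem, na.rm = TRUE)
                        >= report_threshold)
    dplyr::mutate(base,
      skipped = NA_character_,
      theta = nm$alt_fit$theta, lrt_nm = nm$statistic, p_nm = nm$p_value,
      f = im$alt_fit$f, lrt_im = im$statistic, p_im = im$p_value,
      converged = nm$null_fit$converged && nm$alt_fit$converged &&
        im$alt_fit$converged,
      freq_table = list(ft))
  })
  out <- dplyr::bind_rows(rows)
  n_tested <- sum(is.na(out$skipped))
  thr <- if (bonferroni && n_tested > 0) alpha / n_tested else alpha
  out <- dplyr::mutate(out,
    alpha = alpha, sig_threshold = thr,
    sig_nm = .data$p_nm < thr, sig_im = .data$p_im < thr)
  class(out) <- c("hap_block_report", class(out))
  out
}

#' Write a block analysis report to text files
#'
#' Writes a human-readable `results.txt`-style report (per block: sample
#' sizes, haplotype frequency table under the three algorithms, `theta` with
#' the Niu-model LRT and p-value, `f` with the inbreeding-model LRT and
#' p-value) plus a machine-readable tab-separated sidecar (same path with
#' extension `.tsv`) that round-trips the numbers at full precision.
#'
#' @param report A `hap_block_report` from [analyze_blocks()].
#' @param path Output text file path.
#' @return Invisibly, the sidecar path.
#' @export
write_results <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Haplotype-based HWE test results")
  w("================================")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    w("")
    w("Block ", r$block, " [", r$snps, "]")
    w("  founders: ", r$n_founders, "; used: ", r$n_used,
      " (", r$n_missing_dropped, " dropped for in-block missingness)")
    if (!is.na(r$skipped)) { w("  SKIPPED: ", r$skipped); next }
    ft <- r$freq_table[[1]]
    w("  haplotype frequencies (EM / ECM / IEM):")
    for (j in seq_len(nrow(ft))) {
      w(sprintf("    %s  %.6f  %.6f  %.6f", ft$haplotype[j],
                ft$em[j], ft$ecm[j], ft$iem[j]))
    }
    w(sprintf("  theta-hat = %.6f; LRT_NM = %.6f; p = %.6g%s", r$theta,
              r$lrt_nm, r$p_nm, if (isTRUE(r$sig_nm)) "  *" else ""))
    w(sprintf("  f-hat     = %.6f; LRT_IM = %.6f; p = %.6g%s", r$f,
              r$lrt_im, r$p_im, if (isTRUE(r$sig_im)) "  *" else ""))
  }
  w("")
  w(sprintf("significance threshold: %.6g", report$sig_threshold[1]))
  sidecar <- paste0(sub("\\.[^./]*$", "", path), ".tsv")
  flat <- dplyr::select(report, -"freq_table")
  utils::write.table(flat, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sidecar)
}

#' Simulate a pedigree sample and optionally write it as a PED file
#'
#' Generates `n_fam` families each with two founders (drawn from the
#' generating model) and `n_child` offspring whose haplotypes are inherited
#' from the parents (no recombination within the tightly linked block), then
#' flattens to PED layout. Useful for fixtures and for exercising founder
#' selection.
#'
#' @inheritParams sim_genotypes
#' @param n_fam Number of families.
#' @param n_child Offspring per family.
#' @param path Optional path; when given, a whitespace-delimited PED file is
#'   written there.
#' @return A PED-shaped tibble (as from [read_ped()]).
#' @export
sim_ped <- function(n_fam, n_child = 1, model = "hwe", freqs = NULL,
                    theta = 1, f = 0, lambda = 0.6, freqs2 = NULL,
                    seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- freqs %||% default_sim_freqs()
  freqs <- validate_freqs(freqs)
  L <- nchar(freqs$haplotype[1])
  pd <- pair_distribution(freqs, if (model == "stratified") "hwe" else model,
                          theta, f)
  draw_pair <- function() {
    j <- sample.int(length(pd$prob), 1, prob = pd$prob)
    c(pd$h1[j], pd$h2[j])
  }
  rows <- list()
  for (fam in seq_len(n_fam)) {
    pa <- draw_pair(); ma <- draw_pair()
    mk <- function(id, father, mother, sex, h) {
      g <- geno_code_to_str(codes_for_pair(h[1], h[2], L))
      c(fam_id = paste0("F", fam), id = id, father_id = father,
        mother_id = mother, sex = sex, phenotype = "0",
        setNames(g, paste0("snp", seq_len(L))))
    }
    rows[[length(rows) + 1]] <- mk(paste0("I", fam, "_1"), "0", "0", "1", pa)
    rows[[length(rows) + 1]] <- mk(paste0("I", fam, "_2"), "0", "0", "2", ma)
    for (k in seq_len(n_child)) {
      h <- c(pa[sample.int(2, 1)], ma[sample.int(2, 1)])
      rows[[length(rows) + 1]] <- mk(paste0("I", fam, "_c", k),
                                     paste0("I", fam, "_1"),
                                     paste0("I", fam, "_2"),
                                     as.character(sample.int(2, 1)), h)
    }
  }
  ped <- tibble::as_tibble(do.call(rbind, rows))
  ped$founder <- ped$father_id == "0" & ped$mother_id == "0"
  ped <- dplyr::relocate(ped, "founder", .after = "phenotype")
  if (!is.null(path)) write_ped(ped, path)
  ped
}

#' Write a PED-shaped tibble to a linkage pedigree file
#'
#' @param ped A tibble as returned by [read_ped()] or [sim_ped()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  snp_cols <- setdiff(names(ped), c("fam_id", "id", "father_id", "mother_id",
                                    "sex", "phenotype", "founder"))
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    g <- vapply(snp_cols, function(s) {
      x <- ped[[s]][i]
      if (is.na(x)) "0 0" else gsub("/", " ", x, fixed = TRUE)
    }, character(1))
    paste(ped$fam_id[i], ped$id[i], ped$father_id[i], ped$mother_id[i],
          ped$sex[i], ped$phenotype[i], paste(g, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
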