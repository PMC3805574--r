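# Internal estimation engine.  All three fitters work on a collapsed
# representation of the sample: distinct genotype classes with multiplicities
# and, for each class, the compatible haplotype pairs over the sample support
# (the haplotypes occurring in at least one compatible pair).  Expectation
# sums over classes are exact and orders of magnitude cheaper than
# per-individual sums, which is what makes the simulation study tractable.

# Build the collapsed data structure from distinct genotype-class ids and
# their counts.  Fields:
#   L, n, K            number of SNPs, individuals, classes
#   cnt                class multiplicities (length K)
#   pair_class         class index (1..K) of each compatible pair
#   h1, h2             support indices of each pair's haplotypes
#   hom                logical, haplotype-homozygous pair
#   M                  pairs x support matrix of haplotype counts (0/1/2)
#   hap_codes          integer codes of the support haplotypes
build_gdata <- function(class_ids, counts, L) {
  stopifnot(length(class_ids) == length(counts), all(counts > 0))
  pl <- lapply(class_ids, function(ci) pairs_for_codes(class_codes(ci, L)))
  np <- vapply(pl, nrow, integer(1))
  pm <- do.call(rbind, pl)
  codes_all <- sort(unique(c(pm)))
  h1 <- match(pm[, 1L], codes_all)
  h2 <- match(pm[, 2L], codes_all)
  P <- nrow(pm)
  H <- length(codes_all)
  M <- matrix(0, P, H)
  M[cbind(seq_len(P), h1)] <- M[cbind(seq_len(P), h1)] + 1
  M[cbind(seq_len(P), h2)] <- M[cbind(seq_len(P), h2)] + 1
  list(
    L = L, n = sum(counts), K = length(class_ids),
    class_ids = as.integer(class_ids), cnt = as.numeric(counts),
    pair_class = rep(seq_along(class_ids), np),
    h1 = h1, h2 = h2, hom = h1 == h2, M = M,
    hap_codes = codes_all
  )
}

# genotype matrix (rows = individuals, per-SNP codes 0/1/2) -> gdata
gdata_from_codes <- function(gmat) {
  L <- ncol(gmat)
  ids <- apply(gmat, 1L, geno_class_id)
  tab <- table(ids)
  build_gdata(as.integer(names(tab)), as.numeric(tab), L)
}

# pair probabilities for all compatible pairs under current parameters
gd_pair_probs <- function(gd, p, model, theta = 1, f = 0) {
  C <- if (model == "niu") 1 + (theta - 1) * sum(p^2) else 1
  pair_prob_kernel(p[gd$h1], p[gd$h2], gd$hom, model, theta, f, C)
}

# observed-data log-likelihood; errors on support collapse naming the class
gd_loglik <- function(gd, p, model, theta = 1, f = 0) {
  pp <- gd_pair_probs(gd, p, model, theta, f)
  den <- as.vector(rowsum(pp, gd$pair_class))
  check_support(gd, den)
  sum(gd$cnt * log(den))
}

check_support <- function(gd, den) {
  if (any(den <= 0)) {
    k <- which(den <= 0)[1L]
    g <- paste(geno_code_to_str(class_codes(gd$class_ids[k], gd$L)), collapse = " ")
    abort(paste0("support collapse: every haplotype pair compatible with genotype (",
                 g, ") has probability 0 under the supplied frequencies"))
  }
  invisible(NULL)
}

# E-step weights: w_ij = cnt_i * pp_ij / sum_j pp_ij.  Returns list(w, den, ll).
gd_estep <- function(gd, p, model, theta = 1, f = 0) {
  pp <- gd_pair_probs(gd, p, model, theta, f)
  den <- as.vector(rowsum(pp, gd$pair_class))
  check_support(gd, den)
  w <- gd$cnt[gd$pair_class] * pp / den[gd$pair_class]
  list(w = w, ll = sum(gd$cnt * log(den)), pp = pp, den = den)
}

# ---- EM under HWE (Excoffier-Slatkin gene counting) ------------------------

em_core <- function(gd, tol = 1e-6, max_iter = 1000L, p_init = NULL) {
  H <- length(gd$hap_codes)
  p <- p_init %||% rep(1 / H, H)
  trace <- numeric(max_iter)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- gd_estep(gd, p, "hwe")
    trace[it] <- es$ll
    p <- as.vector(crossprod(gd$M, es$w)) / (2 * gd$n)
    if (abs(es$ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- es$ll
  }
  ll <- gd_loglik(gd, p, "hwe")
  list(p = p, theta = NULL, f = NULL, loglik = ll, n_iter = it,
       converged = converged, trace = c(trace[seq_len(it)], ll), flags = character(0))
}

# ---- ECM under the Niu model -----------------------------------------------

# Conditional-maximization update of one free frequency p_h, absorbing
# haplotype aH carrying the simplex constraint.  The stationarity condition of
# the Q-function in x = p_h (with p_aH = T - x) is the cubic
#   A x^3 + B x^2 + Cc x + D = 0,
#   A  = 2 d (2n - e_h - e_H)
#   B  = 2 d T (2 e_h + e_H - 3n)
#   Cc = 2 d T^2 (n - e_h) - g (e_h + e_H)
#   D  = e_h g T
# with d = theta - 1, T = p_h + p_aH, S0 = sum of squared other frequencies,
# g = 1 + d (T^2 + S0).  d = 0 reduces to the linear EM share e_h T/(e_h+e_H).
# Among admissible roots the one closest to the previous value is taken, with
# a Q-increase safeguard (fall back to the best-Q root, then to no move).
cm_update_p <- function(p, h, aH, e, theta, n) {
  Tt <- p[h] + p[aH]
  if (Tt <= 1e-14) return(p)
  a1 <- e[h]; a2 <- e[aH]
  d <- theta - 1
  S0 <- sum(p^2) - p[h]^2 - p[aH]^2
  g <- 1 + d * (Tt^2 + S0)

  Qh <- function(x) {
    t1 <- if (a1 > 0) a1 * log(x) else 0
    t2 <- if (a2 > 0) a2 * log(Tt - x) else 0
    Cx <- 1 + d * (2 * x^2 - 2 * Tt * x + Tt^2 + S0)
    t1 + t2 - n * log(Cx)
  }

  coefs <- c(e[h] * g * Tt,                       # D
             2 * d * Tt^2 * (n - a1) - g * (a1 + a2),  # Cc
             2 * d * Tt * (2 * a1 + a2 - 3 * n),  # B
             2 * d * (2 * n - a1 - a2))           # A
  # trim trailing ~zero coefficients so polyroot sees the true degree
  nz <- which(abs(coefs) > 1e-12 * max(1, abs(coefs)))
  cand <- numeric(0)
  if (length(nz) >= 2) {
    deg <- max(nz) - 1L
    r <- tryCatch(polyroot(coefs[seq_len(deg + 1L)]), error = function(e) NULL)
    if (is.null(r)) {
      # rare polyroot failure: bounded numeric maximization of Q instead
      cand <- optimize(Qh, c(1e-9, Tt - 1e-9), maximum = TRUE,
                       tol = 1e-12)$maximum
    } else {
      re <- Re(r)[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]
      cand <- re[re > 0 & re < Tt]
    }
  }
  # boundary optima when an expected count vanishes
  if (a1 <= 1e-12) cand <- c(cand, 0)
  if (a2 <= 1e-12) cand <- c(cand, Tt)
  if (length(cand) == 0) return(p)

  prev <- p[h]
  pick <- cand[which.min(abs(cand - prev))]
  if (Qh(pick) < Qh(prev) - 1e-10) pick <- cand[which.max(vapply(cand, Qh, numeric(1)))]
  if (Qh(pick) < Qh(prev) - 1e-10) pick <- prev
  p[h] <- pick
  p[aH] <- Tt - pick
  p
}

ecm_core <- function(gd, tol = 1e-6, max_iter = 1000L, p_init = NULL,
                     theta_init = 1, theta_max = 1e3) {
  H <- length(gd$hap_codes)
  n <- gd$n
  p <- p_init %||% rep(1 / H, H)
  theta <- theta_init
  flags <- character(0)

  # absorbing haplotype: largest expected count at initialization
  e0 <- as.vector(crossprod(gd$M, gd_estep(gd, p, "niu", theta = theta)$w))
  absorb <- which.max(e0)
  free <- setdiff(seq_len(H), absorb)

  trace <- numeric(max_iter)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- gd_estep(gd, p, "niu", theta = theta)
    trace[it] <- es$ll
    # CM-step 1: theta at fixed p (stationary point of Q)
    m <- sum(es$w[gd$hom])
    S <- sum(p^2)
    theta <- if (m <= 1e-12) {
      flags <- union(flags, "theta_floor"); 1e-6
    } else if (m >= n - 1e-9) {
      flags <- union(flags, "theta_cap"); theta_max
    } else {
      min(max(m * (1 - S) / (S * (n - m)), 1e-6), theta_max)
    }
    if (theta == theta_max) flags <- union(flags, "theta_cap")
    # CM-steps 2..H: one free frequency at a time, constraint absorbed by aH
    e <- as.vector(crossprod(gd$M, es$w))
    for (h in free) p <- cm_update_p(p, h, absorb, e, theta, n)
    if (abs(es$ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- es$ll
  }
  ll <- gd_loglik(gd, p, "niu", theta = theta)
  list(p = p, theta = theta, f = NULL, loglik = ll, n_iter = it,
       converged = converged, trace = c(trace[seq_len(it)], ll), flags = flags)
}

# ---- IEM under the inbreeding model ----------------------------------------

# Augmented-data EM: latent pair Z_i and IBD indicator B_i.  For a homozygous
# pair (k,k) the posterior IBD probability is b = f p_k / (f p_k + (1-f) p_k^2)
# = f / (f + (1-f) p_k); 0 for heterozygous pairs.  M-step:
#   f'   = (1/n) sum_ij w_ij b_ij
#   p'_h = expected draws of h / (2n - sum_ij w_ij b_ij)
# where an IBD individual contributes one draw of its shared haplotype and a
# non-IBD individual two draws.
iem_core <- function(gd, tol = 1e-6, max_iter = 1000L, p_init = NULL,
                     f_init = 0.01) {
  H <- length(gd$hap_codes)
  n <- gd$n
  p <- p_init %||% rep(1 / H, H)
  f <- f_init
  flags <- character(0)

  trace <- numeric(max_iter)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- gd_estep(gd, p, "inbreeding", f = f)
    trace[it] <- es$ll
    b <- numeric(length(es$w))
    hk <- gd$h1[gd$hom]
    denom <- f + (1 - f) * p[hk]
    b[gd$hom] <- ifelse(denom > 0, f / denom, 0)
    wb <- es$w * b
    sum_wb <- sum(wb)
    e <- as.vector(crossprod(gd$M, es$w))
    if (any(gd$hom)) {
      # IBD mass contributes one draw, not two
      ehom <- as.vector(crossprod(gd$M[gd$hom, , drop = FALSE] / 2, wb[gd$hom]))
      e <- e - ehom
    }
    p <- e / (2 * n - sum_wb)
    f <- min(max(sum_wb / n, 0), 1 - 1e-9)
    if (f == 1 - 1e-9) flags <- union(flags, "f_cap")
    if (abs(es$ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- es$ll
  }
  ll <- gd_loglik(gd, p, "inbreeding", f = f)
  list(p = p, theta = NULL, f = f, loglik = ll, n_iter = it,
       converged = converged, trace = c(trace[seq_len(it)], ll), flags = flags)
}
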