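# Independent oracles used across the suite.  They enumerate pairs and
# probabilities from first principles (via pair_genotype string matching and
# explicit model formulas), never through the fitting engine.

# observed log-likelihood by exhaustive pair enumeration over a given
# haplotype set; independent of the package's collapsed-class engine
oracle_loglik <- function(data, haps, p, model = "hwe", theta = 1, f = 0) {
  H <- length(haps)
  S <- sum(p^2)
  C <- 1 + (theta - 1) * S
  pair_pr <- function(i, j) {
    if (i == j) {
      switch(model, hwe = p[i]^2, niu = theta * p[i]^2 / C,
             inbreeding = f * p[i] + (1 - f) * p[i]^2)
    } else {
      switch(model, hwe = 2 * p[i] * p[j], niu = 2 * p[i] * p[j] / C,
             inbreeding = (1 - f) * 2 * p[i] * p[j])
    }
  }
  snps <- setdiff(names(data), c("id"))
  ll <- 0
  for (r in seq_len(nrow(data))) {
    g <- unname(vapply(snps, function(s) data[[s]][r], character(1)))
    tot <- 0
    for (i in seq_len(H)) {
      for (j in i:H) {
        if (identical(pair_genotype(haps[i], haps[j]), g)) {
          tot <- tot + pair_pr(i, j)
        }
      }
    }
    if (tot <= 0) stop("oracle support collapse")
    ll <- ll + log(tot)
  }
  ll
}

# numeric maximization of the observed likelihood over the simplex (softmax
# parametrization, multi-start Nelder-Mead); theta optionally free (log scale)
oracle_max_loglik <- function(data, haps, model = "hwe", free_theta = FALSE,
                              n_starts = 8, seed = 99) {
  H <- length(haps)
  obj <- function(v) {
    p <- exp(c(v[seq_len(H - 1)], 0))
    p <- p / sum(p)
    theta <- if (free_theta) exp(v[H]) else 1
    -oracle_loglik(data, haps, p, model = model, theta = theta)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    v0 <- c(stats::rnorm(H - 1), if (free_theta) stats::rnorm(1) * 0.3)
    o <- stats::optim(v0, obj, control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- exp(c(best$par[seq_len(H - 1)], 0))
  list(p = p / sum(p),
       theta = if (free_theta) exp(best$par[H]) else 1,
       ll = -best$value)
}

# the ECM conditional objective in one free frequency x = p_h (absorbing
# haplotype carries T - x); written from the Q-function definition, used to
# cross-check the cubic-root update
oracle_cm_q <- function(x, e1, e2, Tt, S0, d, n) {
  t1 <- if (e1 > 0) e1 * log(x) else 0
  t2 <- if (e2 > 0) e2 * log(Tt - x) else 0
  t1 + t2 - n * log(1 + d * (x^2 + (Tt - x)^2 + S0))
}

# random frequency vector over all 2^L haplotypes
rand_freqs <- function(L, seed) {
  set.seed(seed)
  g <- stats::rexp(2^L)
  hap_freqs(hap_label(0:(2^L - 1), L), g / sum(g))
}

# small random genotype data set under HWE with random frequencies
rand_geno <- function(n, L, seed) {
  sim_genotypes(n, model = "hwe", freqs = rand_freqs(L, seed), seed = seed + 1)
}
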