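freqs1 <- default_sim_freqs()

test_that("observed log-likelihood matches exhaustive-enumeration oracle", {
  g <- tibble::tibble(s1 = "1/1", s2 = "2/2", s3 = "1/1")
  expect_equal(hap_loglik(g, freqs1), log(0.283^2))

  set.seed(31)
  dat <- rand_geno(30, 3, 31)
  fr <- rand_freqs(3, 32)
  for (m in c("hwe", "niu", "inbreeding")) {
    expect_equal(
      hap_loglik(dat, fr, model = m, theta = 1.4, f = 0.07),
      oracle_loglik(dat, fr$haplotype, fr$freq, m, theta = 1.4, f = 0.07),
      tolerance = 1e-10
    )
  }
  # theta = 1 Niu log-likelihood equals the HWE one on any data
  expect_equal(hap_loglik(dat, fr, "niu", theta = 1), hap_loglik(dat, fr))
})

test_that("support collapse is an error, not a silent zero", {
  # (1/2, 1/1, 1/2) needs haplotypes 212 or 112, both absent from the
  # five-haplotype study distribution
  g <- tibble::tibble(s1 = "1/2", s2 = "1/1", s3 = "1/2")
  expect_error(hap_loglik(g, freqs1), "support collapse")
})

test_that("E-step weights are normalized posteriors", {
  uni <- hap_freqs(hap_label(0:7, 3), rep(1 / 8, 8))
  dat <- tibble::tibble(s1 = c("1/2", "1/1"), s2 = c("1/1", "2/2"),
                        s3 = c("1/2", "1/1"))
  gd <- haplohwe:::prepare_gdata(dat, quiet = TRUE)
  p <- numeric(length(gd$hap_codes))
  p[match(hap_code(uni$haplotype), gd$hap_codes, nomatch = 0)] <- 1 / 8
  es <- haplohwe:::gd_estep(gd, p, "hwe")
  w_by_class <- rowsum(es$w, gd$pair_class)
  expect_equal(as.vector(w_by_class), gd$cnt)  # rows sum to class counts
  # the double-het genotype's two phasings are equally likely under uniform p
  amb <- which(gd$pair_class == which(gd$cnt == 1 &
                 tabulate(gd$pair_class) == 2)[1])
  expect_equal(es$w[amb], c(0.5, 0.5))
})

test_that("EM reduces to direct counting on fully homozygous data", {
  dat <- tibble::tibble(s1 = rep(c("1/1", "2/2"), c(6, 4)),
                        s2 = rep(c("1/1", "2/2"), c(6, 4)))
  fit <- fit_hwe(dat)
  expect_equal(sort(fit$freqs$freq, decreasing = TRUE), c(0.6, 0.4))
  expect_lte(fit$n_iter, 3)
})

test_that("EM resolves the classic two-SNP double heterozygote", {
  dat <- tibble::tibble(s1 = c("1/1", "2/2", "1/2"),
                        s2 = c("1/1", "2/2", "1/2"))
  fit <- fit_hwe(dat)
  td <- tidy(fit)
  expect_equal(td$freq[td$haplotype == "11"], 0.5, tolerance = 1e-4)
  expect_equal(td$freq[td$haplotype == "22"], 0.5, tolerance = 1e-4)
  expect_lt(sum(td$freq[td$haplotype %in% c("12", "21")]), 1e-4)
})

test_that("closed-form theta update maximizes Q (numeric cross-check)", {
  # identity: expected homozygosity exactly at its HWE value gives theta = 1
  S <- 0.37369; n <- 100; m <- n * S
  expect_equal(m * (1 - S) / (S * (n - m)), 1)
  expect_equal(50 * (1 - S) / (S * 50), (1 - S) / S)  # m = n/2 case
  set.seed(77)
  for (i in 1:25) {
    n <- sample(20:500, 1)
    S <- stats::runif(1, 0.05, 0.95)
    m <- stats::runif(1, 0.5, n - 0.5)
    closed <- m * (1 - S) / (S * (n - m))
    qfun <- function(th) m * log(th) - n * log(1 + (th - 1) * S)
    num <- stats::optimize(qfun, c(1e-4, 1e3), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(closed - num$maximum), 1e-4 * (1 + closed))
    # and the closed form beats a log-grid
    grid <- exp(seq(log(0.01), log(100), length.out = 400))
    expect_gte(qfun(closed) + 1e-9, max(qfun(grid)))
  }
})

test_that("cubic CM-step equals the bounded numeric maximizer of Q", {
  set.seed(42)
  for (i in 1:25) {
    H <- sample(2:6, 1)
    p <- stats::rexp(H); p <- p / sum(p)
    e <- stats::rexp(H) * 20
    n <- sum(e) / 2
    theta <- exp(stats::runif(1, log(0.3), log(3)))
    h <- 1L; aH <- H
    upd <- haplohwe:::cm_update_p(p, h, aH, e, theta, n)
    Tt <- p[h] + p[aH]
    S0 <- sum(p^2) - p[h]^2 - p[aH]^2
    num <- stats::optimize(oracle_cm_q, c(1e-9, Tt - 1e-9), maximum = TRUE,
                           e1 = e[h], e2 = e[aH], Tt = Tt, S0 = S0,
                           d = theta - 1, n = n, tol = 1e-10)
    expect_lt(abs(upd[h] - num$maximum), 1e-6)
    expect_lt(abs(upd[h] + upd[aH] - Tt), 1e-12)
    # Q never decreases at the update (CM property)
    expect_gte(oracle_cm_q(upd[h], e[h], e[aH], Tt, S0, theta - 1, n) + 1e-10,
               oracle_cm_q(p[h], e[h], e[aH], Tt, S0, theta - 1, n))
  }
})

test_that("at theta = 1 the CM frequency update is the plain EM share", {
  set.seed(43)
  for (i in 1:10) {
    H <- sample(2:5, 1)
    p <- stats::rexp(H); p <- p / sum(p)
    e <- stats::rexp(H) * 30
    n <- sum(e) / 2
    upd <- haplohwe:::cm_update_p(p, 1L, H, e, theta = 1, n = n)
    Tt <- p[1] + p[H]
    expect_equal(upd[1], e[1] * Tt / (e[1] + e[H]), tolerance = 1e-9)
  }
})

test_that("all three fitters have nondecreasing log-likelihood traces", {
  for (s in 1:100) {
    dat <- rand_geno(sample(10:50, 1), sample(2:4, 1), 1000 + s)
    for (fitter in list(fit_hwe, fit_niu, fit_inbreeding)) {
      fit <- suppressMessages(suppressWarnings(fitter(dat)))
      expect_true(all(diff(fit$loglik_trace) > -1e-9))
    }
  }
})

test_that("fitted optima match free numeric maximization of the likelihood", {
  # support of three haplotypes (single-het genotypes only): EM vs simplex
  dat3 <- tibble::tibble(
    s1 = c("1/1", "1/2", "1/2", "1/1", "2/2", "1/1", "1/1"),
    s2 = c("1/1", "1/1", "1/1", "1/2", "1/1", "1/2", "2/2")
  )
  fit <- fit_hwe(dat3, control = hap_control(tol = 1e-10))
  expect_equal(fit$n_hap, 3L)
  ora <- oracle_max_loglik(dat3, fit$freqs$haplotype)
  expect_lt(abs(fit$loglik - ora$ll), 1e-6)
  expect_lt(max(abs(fit$freqs$freq - ora$p)), 1e-4)

  # ambiguous 4-haplotype data: EM and ECM against multi-start optimizer
  dat4 <- rand_geno(40, 2, 7)
  em <- fit_hwe(dat4, control = hap_control(tol = 1e-10))
  ora4 <- oracle_max_loglik(dat4, em$freqs$haplotype)
  expect_lt(abs(em$loglik - ora4$ll), 1e-4)

  ecm <- fit_niu(dat4, control = hap_control(tol = 1e-10))
  oran <- oracle_max_loglik(dat4, ecm$freqs$haplotype, model = "niu",
                            free_theta = TRUE)
  expect_lt(abs(ecm$loglik - oran$ll), 1e-3)
  expect_lt(abs(ecm$theta - oran$theta), 0.02 * (1 + ecm$theta))

  # ECM optimum is not beaten by a coarse grid over (p, theta)
  dat5 <- tibble::tibble(s1 = c("1/2", "1/2", "1/1", "2/2", "1/2"),
                         s2 = c("1/2", "1/1", "1/2", "2/2", "2/2"))
  ecm5 <- fit_niu(dat5)
  haps <- ecm5$freqs$haplotype
  best_grid <- -Inf
  qs <- seq(0.05, 0.9, by = 0.05)
  for (a in qs) for (b in qs) for (cc in qs) {
    d <- 1 - a - b - cc
    if (d <= 0) next
    for (th in c(0.5, 0.8, 1, 1.3, 1.8, 2.5, 4)) {
      best_grid <- max(best_grid,
                       oracle_loglik(dat5, haps, c(a, b, cc, d), "niu", theta = th))
    }
  }
  expect_gte(ecm5$loglik + 1e-6, best_grid)
})

test_that("IEM matches a dense 2-D grid on single-SNP data", {
  dat <- tibble::tibble(s1 = rep(c("1/1", "1/2", "2/2"), c(30, 30, 40)))
  fit <- fit_inbreeding(dat, control = hap_control(tol = 1e-12))
  ll_ib <- function(p1, f) {
    30 * log(f * p1 + (1 - f) * p1^2) +
      30 * log((1 - f) * 2 * p1 * (1 - p1)) +
      40 * log(f * (1 - p1) + (1 - f) * (1 - p1)^2)
  }
  grid <- expand.grid(p1 = seq(0.01, 0.99, by = 0.001),
                      f = seq(0, 0.6, by = 0.001))
  vals <- mapply(ll_ib, grid$p1, grid$f)
  top <- grid[which.max(vals), ]
  expect_lt(abs(fit$freqs$freq[fit$freqs$haplotype == "1"] - top$p1), 2e-3)
  expect_lt(abs(fit$f - top$f), 2e-3)
  expect_gte(fit$loglik + 1e-8, max(vals))
})

test_that("f initialized at 0 is a fixed point reproducing the EM fit", {
  dat <- rand_geno(60, 3, 55)
  em <- fit_hwe(dat)
  iem0 <- fit_inbreeding(dat, control = hap_control(f_init = 0))
  expect_equal(iem0$f, 0)
  expect_equal(iem0$freqs$freq, em$freqs$freq, tolerance = 1e-6)
  expect_equal(iem0$loglik, em$loglik, tolerance = 1e-8)
})

test_that("nested models never lose likelihood and fits are init-robust", {
  for (s in 1:5) {
    dat <- rand_geno(50, 3, 300 + s)
    em <- fit_hwe(dat)
    ecm <- fit_niu(dat)
    iem <- fit_inbreeding(dat)
    # nesting holds up to the stopping-rule scale (tol = 1e-6 on the loglik)
    expect_gte(ecm$loglik + 1e-5, em$loglik)
    expect_gte(iem$loglik + 1e-5, em$loglik)
    # five random restarts reach the same optimum
    H <- em$n_hap
    set.seed(s)
    for (r in 1:5) {
      p0 <- stats::rexp(H); p0 <- p0 / sum(p0)
      refit <- fit_hwe(dat, control = hap_control(p_init = p0))
      expect_equal(refit$loglik, em$loglik, tolerance = 1e-4)
    }
  }
})

test_that("degenerate all-homozygous data caps theta with a flag", {
  dat <- tibble::tibble(s1 = rep("1/1", 10), s2 = rep(c("1/1", "2/2"), 5))
  fit <- fit_niu(dat)
  expect_equal(fit$theta, 1e3)
  expect_true("theta_cap" %in% fit$flags)
})

test_that("simulated-data estimates recover the generating parameters", {
  st_nm <- run_study("niu", param = 1.2, n = 400, n_reps = 60, seed = 21)
  expect_lt(abs(st_nm$theta_mean - 1.2), 3 * 0.14 / sqrt(60))
  st_im <- run_study("inbreeding", param = 0.05, n = 400, n_reps = 60, seed = 22)
  expect_lt(abs(st_im$f_mean - 0.05), 3 * 0.032 / sqrt(60))
})
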