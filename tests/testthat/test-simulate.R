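test_that("study frequency tables are the documented distributions", {
  f1 <- default_sim_freqs()
  expect_equal(sum(f1$freq), 1)
  expect_equal(sum(f1$freq^2), 0.37369, tolerance = 1e-12)
  st <- stratified_sim_freqs()
  expect_equal(sum(st$freq_I), 1)
  expect_equal(sum(st$freq_II), 1)
})

test_that("sampler matches the exact pair distribution", {
  n <- 1e5
  S <- 0.37369

  # under HWE (theta = 1) the homozygous-pair fraction is S; a homozygous
  # pair is exactly a genotype with no heterozygous SNP
  g <- sim_genotypes(n, model = "niu", theta = 1, seed = 101)
  hom <- rowSums(cbind(g$snp1 == "1/2", g$snp2 == "1/2", g$snp3 == "1/2")) == 0
  expect_equal(mean(hom), S, tolerance = 4 * sqrt(S * (1 - S) / n))

  # inbreeding f = 0.1: hom fraction f + (1 - f) S
  gi <- sim_genotypes(n, model = "inbreeding", f = 0.1, seed = 102)
  homi <- rowSums(cbind(gi$snp1 == "1/2", gi$snp2 == "1/2", gi$snp3 == "1/2")) == 0
  pe <- 0.1 + 0.9 * S
  expect_equal(mean(homi), pe, tolerance = 4 * sqrt(pe * (1 - pe) / n))

  # stratified lambda = 0.6: marginal frequency of haplotype 221 is
  # 0.6 * 0.525 + 0.4 * 0.470 = 0.503; count it among unambiguous draws via
  # the 221-homozygote frequency p^2 is unusable, so use the genotype-class
  # chi-square below instead and here just check the all-hom fraction
  gs <- sim_genotypes(n, model = "stratified", lambda = 0.6, seed = 103)
  st <- stratified_sim_freqs()
  S_mix <- 0.6 * sum(st$freq_I^2) + 0.4 * sum(st$freq_II^2)
  homs <- rowSums(cbind(gs$snp1 == "1/2", gs$snp2 == "1/2", gs$snp3 == "1/2")) == 0
  expect_equal(mean(homs), S_mix, tolerance = 4 * sqrt(S_mix * (1 - S_mix) / n))
})

test_that("genotype-class counts pass a goodness-of-fit test per model", {
  n <- 2e4
  for (spec in list(list(model = "niu", theta = 1.3, f = 0),
                    list(model = "inbreeding", theta = 1, f = 0.08))) {
    g <- sim_genotypes(n, model = spec$model, theta = spec$theta, f = spec$f,
                       seed = 104)
    pp <- pair_probs(default_sim_freqs(), spec$model,
                     theta = spec$theta, f = spec$f)
    cls <- apply(cbind(g$snp1, g$snp2, g$snp3), 1, paste, collapse = "|")
    expcls <- vapply(seq_len(nrow(pp)), function(i) {
      paste(pair_genotype(pp$hap1[i], pp$hap2[i]), collapse = "|")
    }, character(1))
    probs <- tapply(pp$prob, expcls, sum)
    obs <- table(factor(cls, levels = names(probs)))
    expect_equal(sum(obs), n)   # no sampled genotype outside the class set
    keep <- probs > 5 / n
    rem <- 1 - sum(probs[keep])
    chi <- if (rem > 5 / n) {
      stats::chisq.test(c(obs[keep], n - sum(obs[keep])),
                        p = c(probs[keep], rem))
    } else {
      stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))
    }
    expect_gt(chi$p.value, 1e-4)
  }
})

test_that("SAD is the plain sum of absolute frequency differences", {
  f1 <- default_sim_freqs()
  expect_equal(sad(f1, f1), 0)
  expect_equal(sad(hap_freqs(c("1", "2"), c(1, 0)),
                   hap_freqs(c("1", "2"), c(0, 1))), 2)
  uni <- hap_freqs(f1$haplotype, rep(0.2, 5))
  expect_equal(sad(f1, uni),
               abs(0.082 - 0.2) + abs(0.525 - 0.2) + abs(0.283 - 0.2) +
                 abs(0.004 - 0.2) + abs(0.106 - 0.2))
  # haplotypes absent from one table count fully
  expect_equal(sad(hap_freqs("11", 1), hap_freqs(c("11", "22"), c(0.8, 0.2))),
               0.4)
})

test_that("run_study is deterministic in its seed and well-formed", {
  a <- run_study("niu", param = c(1, 1.5), n = c(100, 200), n_reps = 10,
                 seed = 5)
  b <- run_study("niu", param = c(1, 1.5), n = c(100, 200), n_reps = 10,
                 seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 4L)
  expect_true(all(a$reject_nm >= 0 & a$reject_nm <= 1))
  expect_true(all(a$sad_em >= 0))
  expect_s3_class(a, "hap_study")
})

test_that("power rises with effect size and sample size; SAD falls with n", {
  nm <- run_study("niu", param = c(1, 1.25, 1.5), n = c(250, 1000),
                  n_reps = 150, seed = 6)
  for (nn in unique(nm$n)) {
    sub <- nm[nm$n == nn, ]
    expect_true(all(diff(sub$reject_nm) >= 0))
    expect_true(all(diff(sub$reject_im) >= 0))
  }
  for (th in unique(nm$param)) {
    sub <- nm[nm$param == th, ]
    expect_true(all(diff(sub$sad_em) < 0))
    expect_true(all(diff(sub$sad_ecm) < 0))
    expect_true(all(diff(sub$sad_iem) < 0))
  }
  hi <- nm[nm$param == 1.5 & nm$n == 1000, ]
  lo <- nm[nm$param == 1.5 & nm$n == 250, ]
  expect_gt(hi$reject_nm, lo$reject_nm)

  im <- run_study("inbreeding", param = c(0, 0.05, 0.1), n = 500,
                  n_reps = 150, seed = 7)
  expect_true(all(diff(im$reject_im) >= 0))
})

test_that("the study plot maps one line per test", {
  st <- run_study("niu", param = c(1, 1.5), n = 100, n_reps = 5, seed = 8)
  pl <- autoplot(st)
  expect_s3_class(pl, "ggplot")
})
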