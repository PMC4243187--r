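test_that("haplotype counts use pairwise-complete haplotypes", {
  H <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  p <- make_panel(H, c(100, 200))
  expect_equal(haplotype_counts(p, 1, 2),
               c(n11 = 2L, n10 = 0L, n01 = 0L, n00 = 2L))
  H[2, 2] <- NA
  p <- make_panel(H, c(100, 200))
  expect_equal(sum(haplotype_counts(p, 1, 2)), 3)
})

test_that("pair_ld reproduces hand-evaluated two-locus statistics", {
  perfect <- pair_ld(c(50, 0, 0, 50))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$dprime, 1)
  expect_equal(perfect$signed_r, 1)

  indep <- pair_ld(c(25, 25, 25, 25))
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)
  expect_equal(indep$signed_r, 0)
  expect_equal(indep$dprime, 0)

  x <- pair_ld(c(4, 1, 1, 4))
  expect_equal(x$p_i, 0.5)
  expect_equal(x$p_j, 0.5)
  expect_equal(x$p_ij, 0.4)
  expect_equal(x$D, 0.15)
  expect_equal(x$r2, 0.36)
  expect_equal(x$dprime, 0.6)
  expect_equal(x$signed_r, 0.6)

  mono <- pair_ld(c(5, 0, 3, 0))  # marker j monomorphic
  expect_true(is.na(mono$r2))
})

test_that("pair_ld matches the indicator-vector oracle on random counts", {
  set.seed(501)
  for (k in 1:2000) {
    cnts <- random_counts()
    got <- pair_ld(cnts)
    want <- oracle_pair_ld(cnts)
    expect_equal(got$D, want$D, tolerance = 1e-12)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
    expect_equal(got$signed_r, want$signed_r, tolerance = 1e-12)
    expect_equal(got$dprime, want$dprime, tolerance = 1e-12)
  }
})

test_that("LD invariants hold over random counts", {
  set.seed(502)
  cnts <- t(replicate(500, random_counts()))
  got <- pair_ld(cnts[, 1], cnts[, 2], cnts[, 3], cnts[, 4])
  expect_true(all(got$r2 >= 0 & got$r2 <= 1 + 1e-12))
  expect_true(all(got$dprime >= 0 & got$dprime <= 1 + 1e-12))
  expect_true(all(got$r2 <= got$dprime + 1e-12))
  expect_equal(got$signed_r^2, got$r2, tolerance = 1e-12)
  expect_true(all(sign(got$signed_r) == sign(got$D)))
})

test_that("ld_pair_table equals per-pair counting on panels with missing data", {
  set.seed(503)
  H <- matrix(rbinom(40 * 30, 1, 0.5), nrow = 40)
  H[sample(length(H), 60)] <- NA
  p <- make_panel(H, sort(sample.int(5e5, 30)))
  tab <- ld_pair_table(p, max_distance = 5e5)
  for (k in sample.int(nrow(tab), 25)) {
    cnts <- haplotype_counts(p, tab$i[k], tab$j[k])
    want <- pair_ld(cnts)
    expect_equal(tab$r2[k], want$r2, tolerance = 1e-12)
    expect_equal(tab$signed_r[k], want$signed_r, tolerance = 1e-12)
    expect_equal(tab$n[k], sum(cnts))
  }
})

test_that("EM reproduces the closed-form answer when phase is unambiguous", {
  g <- matrix(c(5, 2, 0,
                1, 0, 3,
                0, 2, 4), 3, 3, byrow = TRUE)  # no double heterozygotes
  fit <- em_haplotype_freqs(g)
  n2 <- 2 * sum(g)
  expect_equal(unname(fit$freqs["p11"]),
               (2 * g[3, 3] + g[3, 2] + g[2, 3]) / n2, tolerance = 1e-9)
  expect_equal(unname(fit$freqs["p00"]),
               (2 * g[1, 1] + g[1, 2] + g[2, 1]) / n2, tolerance = 1e-9)
  expect_equal(sum(fit$freqs), 1, tolerance = 1e-12)
})

test_that("EM attains the profiled maximum on an all-double-heterozygote table", {
  g <- matrix(0, 3, 3); g[2, 2] <- 20
  fit <- em_haplotype_freqs(g)
  # the symmetric point (0.25, ...) is stationary but not the maximum;
  # multi-start EM must reach the oracle's profiled optimum
  expect_equal(fit$loglik, oracle_em_loglik(g), tolerance = 1e-6)
  sym_ll <- 20 * log(2 * (0.25 * 0.25 + 0.25 * 0.25))
  expect_gte(fit$loglik, sym_ll)
})

test_that("EM log-likelihood matches the grid-search oracle on random tables", {
  set.seed(504)
  for (k in 1:120) {
    g <- random_geno_table(30)
    fit <- em_haplotype_freqs(g)
    expect_equal(fit$loglik, oracle_em_loglik(g), tolerance = 1e-6)
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-10)
  }
})

test_that("EM rejects an empty table", {
  expect_error(em_haplotype_freqs(matrix(0, 3, 3)), "empty")
})

test_that("D' confidence bounds behave as the grid likelihood dictates", {
  strong <- dprime_ci(c(100, 0, 0, 100))
  expect_gte(strong$ci_low, 0.70)
  expect_gte(strong$ci_high, 0.98)

  indep <- dprime_ci(c(25, 25, 25, 25))
  expect_lt(indep$ci_high, 0.90)

  weak <- dprime_ci(c(4, 1, 1, 4))
  expect_lt(weak$ci_low, 0.70)
})

test_that("vectorised D' bounds equal the scalar grid transcription", {
  set.seed(505)
  cnts <- t(replicate(200, random_counts()))
  got <- dprime_ci(cnts[, 1], cnts[, 2], cnts[, 3], cnts[, 4])
  for (k in sample.int(200, 60)) {
    want <- oracle_dprime_ci(cnts[k, ])
    expect_equal(got$ci_low[k], unname(want["ci_low"]), tolerance = 1e-12)
    expect_equal(got$ci_high[k], unname(want["ci_high"]), tolerance = 1e-12)
  }
})

test_that("D' bounds widen as the sample shrinks at fixed frequencies", {
  width <- function(n) {
    ci <- dprime_ci(round(c(0.4, 0.1, 0.1, 0.4) * n))
    ci$ci_high - ci$ci_low
  }
  expect_gt(width(10), width(50))
  expect_gt(width(50), width(200))
})
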