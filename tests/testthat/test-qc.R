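test_that("sample call rate counts complete genotypes", {
  H <- matrix(1L, nrow = 4, ncol = 10)
  H[3, 1] <- NA  # sample 2 misses one of 10 markers
  p <- make_panel(H, seq(100, 1000, by = 100))
  expect_equal(sample_call_rate(p), c(1.0, 0.9))
  H[] <- NA
  p <- make_panel(H, seq(100, 1000, by = 100))
  expect_equal(sample_call_rate(p), c(0, 0))
})

test_that("MAF folds the alternate-allele frequency", {
  H <- matrix(0L, nrow = 10, ncol = 3)
  H[1:3, 1] <- 1L    # 3 alt of 10
  H[1:7, 3] <- 1L    # 7 alt of 10 folds to 0.3
  p <- make_panel(H, c(100, 200, 300))
  expect_equal(marker_maf(p), c(0.3, 0.0, 0.3))
})

test_that("exact HWE test matches hand-checked limits", {
  expect_equal(hwe_exact_pvalue(100, 0, 0), 1.0)
  expect_equal(hwe_exact_pvalue(0, 100, 0), oracle_hwe(0, 100, 0))
  p <- hwe_exact_pvalue(25, 50, 25)
  expect_equal(p, oracle_hwe(25, 50, 25))
  expect_gt(p, 0.8)
  expect_error(hwe_exact_pvalue(-1, 2, 3), ">= 0")
})

test_that("exact HWE test agrees with the enumeration oracle on random tables", {
  set.seed(401)
  for (k in 1:200) {
    n <- sample(1:60, 1)
    g <- as.vector(stats::rmultinom(1, n, stats::runif(3)))
    expect_equal(hwe_exact_pvalue(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("HWE rejection rate is calibrated on random-mating genotypes", {
  set.seed(402)
  m <- 2000
  n <- 400
  p <- stats::runif(m, 0.1, 0.9)
  H <- matrix(stats::rbinom(2L * n * m, 1L, rep(p, each = 2L * n)), nrow = 2L * n)
  panel <- make_panel(H, sort(sample.int(1e7, m)))
  pv <- hwe_exact_pvalue(colSums(panel_genotypes(panel) == 0L),
                         colSums(panel_genotypes(panel) == 1L),
                         colSums(panel_genotypes(panel) == 2L))
  for (alpha in c(0.05, 0.01)) {
    rate <- mean(pv < alpha)
    se <- sqrt(alpha * (1 - alpha) / m)
    # the exact test is conservative: never above alpha + noise, and the
    # discreteness deficit is bounded away from zero
    expect_lte(rate, alpha + 4 * se)
    expect_gte(rate, alpha / 2)
  }
})

toy_qc_panel <- function() {
  # 20 markers so one missing marker leaves sample call rates at 0.95
  set.seed(11)
  n <- 40
  m <- 20
  H <- matrix(rbinom(2 * n * m, 1, 0.5), nrow = 2 * n, ncol = m)
  # marker 2: rare (MAF 0.025); marker 4: missing in half the samples
  H[, 2] <- 0L
  H[1:2, 2] <- 1L
  H[seq_len(n), 4] <- NA
  make_panel(H, seq(100, by = 100, length.out = m))
}

test_that("apply_qc filters in fixed order and attributes removals", {
  res <- apply_qc(toy_qc_panel())
  r <- res$report
  expect_equal(r$removed_samples_call_rate, 0)
  expect_equal(n_markers(res$panel), 18)
  expect_equal(r$removed_snps_call_rate, 1)
  expect_equal(r$removed_snps_hwe, 0)
  expect_equal(r$removed_snps_maf, 1)
  expect_equal(r$n_snps_in - r$n_snps_out,
               r$removed_snps_call_rate + r$removed_snps_hwe + r$removed_snps_maf)
  # disabling the MAF filter leaves the rare marker in
  res0 <- apply_qc(toy_qc_panel(), qc_thresholds(min_maf = 0))
  expect_equal(n_markers(res0$panel), 19)
})

test_that("apply_qc is idempotent", {
  res1 <- apply_qc(toy_qc_panel())
  res2 <- apply_qc(res1$panel)
  expect_identical(res2$panel$haplotypes, res1$panel$haplotypes)
  expect_equal(res2$report$n_snps_in, res2$report$n_snps_out)
  expect_equal(res2$report$removed_samples_call_rate, 0)
})

test_that("low call-rate samples are removed before SNP filters", {
  H <- matrix(rbinom(6 * 4, 1, 0.5), nrow = 6, ncol = 4)
  H[1:2, 1:3] <- NA   # sample 1 call rate 0.25
  p <- make_panel(H, c(10, 20, 30, 40))
  res <- apply_qc(p, qc_thresholds(min_maf = 0))
  expect_equal(res$report$removed_samples_call_rate, 1)
  expect_equal(n_samples(res$panel), 2)
})
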