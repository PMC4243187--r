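ld_table_of <- function(panel) ld_pair_table(panel, max_distance = 5e5)

random_phased_panel <- function(seed, n_hap = 60, m = 40) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  H <- matrix(rbinom(n_hap * m, 1, rep(p, each = n_hap)), nrow = n_hap)
  make_panel(H, sort(sample.int(4e5, m)))
}

test_that("matching is an inner join with logged drop counts", {
  p <- random_phased_panel(701)
  ld <- ld_table_of(p)
  expect_message(m <- shared_pairs(ld, ld), "0 only in A")
  expect_equal(nrow(m), nrow(ld))

  sub <- ld[1:3, ]
  attr(sub, "orientation") <- attr(ld, "orientation")
  expect_message(m2 <- shared_pairs(ld, sub), sprintf("%d only in A", nrow(ld) - 3))
  expect_equal(nrow(m2), 3)

  none <- ld[0, ]
  attr(none, "orientation") <- attr(ld, "orientation")
  expect_equal(nrow(suppressMessages(shared_pairs(ld, none))), 0)
})

test_that("identical groups give PL exactly 1 in every defined bin", {
  p <- random_phased_panel(702)
  m <- suppressMessages(shared_pairs(ld_table_of(p), ld_table_of(p)))
  pp <- persistence_profile(m)
  expect_true(any(!is.na(pp$pl)))
  expect_equal(pp$pl[!is.na(pp$pl)], rep(1, sum(!is.na(pp$pl))))
})

test_that("flipping one margin's orientation flips the sign of PL", {
  # matched stream built directly: B identical to A except the sign of r
  # flips at marker j of every pair
  set.seed(703)
  m <- data.frame(chrom = "1", pos_i = 1:50, pos_j = 2:51,
                  distance = sample(500:2000, 50, replace = TRUE),
                  signed_r_a = runif(50, -1, 1))
  m$signed_r_b <- m$signed_r_a
  pp1 <- persistence_profile(m)
  m$signed_r_b <- -m$signed_r_a
  pp2 <- persistence_profile(m)
  expect_equal(pp1$pl[!is.na(pp1$pl)], rep(1, sum(!is.na(pp1$pl))))
  expect_equal(pp2$pl[!is.na(pp2$pl)], rep(-1, sum(!is.na(pp2$pl))))
})

test_that("orientation digests must agree for shared markers", {
  p <- random_phased_panel(704)
  ld_a <- ld_table_of(p)
  flipped <- p
  flipped$haplotypes[, 5] <- 1L - flipped$haplotypes[, 5]
  flipped$markers$ref[5] <- "C"
  flipped$markers$alt[5] <- "A"
  ld_b <- ld_table_of(flipped)
  expect_error(shared_pairs(ld_a, ld_b), "orientation")
})

test_that("bin PL equals the direct Pearson correlation at known rho", {
  set.seed(705)
  n <- 200
  rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  # squash into [-1, 1] monotonically to look like signed r
  m <- data.frame(chrom = "1", pos_i = seq_len(n), pos_j = seq_len(n) + 1,
                  distance = 1000, signed_r_a = tanh(x), signed_r_b = tanh(y))
  pp <- persistence_profile(m)
  a <- tanh(x); b <- tanh(y)
  expect_equal(pp$pl[1], sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 1e-12)
  # centered variant matches stats::cor; both sit in the rho SE band
  ppc <- persistence_profile(m, center = TRUE)
  expect_equal(ppc$pl[1], cor(a, b), tolerance = 1e-12)
  expect_lt(abs(pp$pl[1] - rho), 3 / sqrt(n))
})

test_that("PL is symmetric and invariant to joint marker flips", {
  pa <- random_phased_panel(706)
  pb <- random_phased_panel(707, m = 40)
  pb$markers <- pa$markers   # same map, different haplotypes
  ld_a <- ld_table_of(pa)
  ld_b <- ld_table_of(pb)
  pp_ab <- persistence_profile(suppressMessages(shared_pairs(ld_a, ld_b)))
  pp_ba <- persistence_profile(suppressMessages(shared_pairs(ld_b, ld_a)))
  expect_equal(pp_ab$pl, pp_ba$pl)

  flip <- sample(n_markers(pa), 7)
  pa2 <- pa; pb2 <- pb
  pa2$haplotypes[, flip] <- 1L - pa2$haplotypes[, flip]
  pb2$haplotypes[, flip] <- 1L - pb2$haplotypes[, flip]
  pa2$markers$ref[flip] <- "C"; pa2$markers$alt[flip] <- "A"
  pb2$markers <- pa2$markers
  pp_flipped <- persistence_profile(
    suppressMessages(shared_pairs(ld_table_of(pa2), ld_table_of(pb2))))
  expect_equal(pp_flipped$pl, pp_ab$pl, tolerance = 1e-12)
})

test_that("undefined bins need at least three pairs and nonzero variance", {
  m <- data.frame(chrom = "1", pos_i = 1:2, pos_j = 2:3, distance = c(1000, 1200),
                  signed_r_a = c(0.5, 0.4), signed_r_b = c(0.5, 0.4))
  expect_true(all(is.na(persistence_profile(m)$pl)))   # 2 pairs < 3
  m <- rbind(m, m[1, ])
  m$signed_r_a <- 0.5   # zero variance margin
  expect_true(all(is.na(persistence_profile(m)$pl)))
})
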