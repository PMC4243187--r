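test_that("the same configuration reproduces panels exactly", {
  cfg <- small_sim(seed = 902, n_markers = 120, chromosome_length = 3e5)
  a <- simulate_panels(cfg)
  b <- simulate_panels(cfg)
  expect_identical(a[[1]]$haplotypes, b[[1]]$haplotypes)
  expect_identical(a[[2]]$haplotypes, b[[2]]$haplotypes)
  expect_identical(a[[1]]$markers, b[[1]]$markers)
})

hudson_fst <- function(pa, pb, na, nb) {
  # per-marker Hudson estimator, averaged as ratio of sums
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  sum(num) / sum(den)
}

test_that("founder divergence drives differentiation; zero divergence does not", {
  fst_at <- function(div, seed) {
    cfg <- small_sim(seed = seed, n_markers = 150, chromosome_length = 3e5,
                     founder_divergence_gens = div)
    f <- simulate_founders(cfg)
    pa <- marker_maf_freq(f$A)
    pb <- marker_maf_freq(f$B)
    hudson_fst(pa, pb, nrow(f$A$haplotypes), nrow(f$B$haplotypes))
  }
  marker_maf_freq <- function(p) colMeans(p$haplotypes)
  f0 <- fst_at(0, 903)
  f80 <- fst_at(80, 903)
  expect_lt(abs(f0), 0.03)
  expect_gt(f80, f0 + 0.05)
})

test_that("fixture files round-trip the in-memory panels", {
  panels <- simulate_panels(small_sim(seed = 904, n_markers = 60,
                                      chromosome_length = 2e5))
  dir <- withr::local_tempdir()
  files <- write_fixture(panels, dir)
  back <- read_vcf_panels(files["vcf"], read_group_map(files["groups"]))[[1]]
  groups <- split_panel_by_group(back)
  for (g in names(panels)) {
    H <- groups[[g]]$haplotypes
    dimnames(H) <- NULL
    expect_identical(H, panels[[g]]$haplotypes)
  }
  expect_true(back$phased)
})

test_that("ten-fold higher recombination lowers mid-range LD", {
  mid_r2 <- function(rate, seed) {
    cfg <- small_sim(seed = seed, n_markers = 200, chromosome_length = 1e6,
                     recomb_rate = rate)
    p <- simulate_population(cfg)
    ld <- ld_pair_table(p)
    mean(ld$r2[ld$distance > 5e4 & ld$distance <= 3e5])
  }
  expect_gt(mid_r2(1e-6, 905), mid_r2(1e-5, 905))
})

test_that("group divergence erodes phase persistence and heterozygosity", {
  overall_pl <- function(split, seed) {
    cfg <- small_sim(seed = seed, n_markers = 200, chromosome_length = 8e5,
                     group_split_gens = split)
    ps <- simulate_panels(cfg)
    lda <- ld_pair_table(apply_qc(ps[[1]])$panel)
    ldb <- ld_pair_table(apply_qc(ps[[2]])$panel)
    pp <- persistence_profile(suppressMessages(shared_pairs(lda, ldb)))
    c(pl = attr(pp, "overall_mean_pl"),
      het = mean(2 * colMeans(ps[[1]]$haplotypes) *
                   (1 - colMeans(ps[[1]]$haplotypes))))
  }
  none <- overall_pl(0, 906)
  deep <- overall_pl(60, 906)
  expect_gt(none["pl"], deep["pl"])
  expect_gt(none["pl"], 0.95)   # same composite: phase agrees everywhere
  expect_gt(none["het"], deep["het"])
})

test_that("infeasible marker demands fail with guidance", {
  cfg <- small_sim(seed = 907, n_markers = 5000, oversample = 1)
  expect_error(simulate_panels(cfg), "polymorphic")
})
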