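test_that("pair classification applies the Gabriel thresholds", {
  ld <- data.frame(ci_low = c(0.75, 0.10, 0.50),
                   ci_high = c(0.99, 0.80, 0.95))
  cls <- classify_pairs(ld)
  expect_equal(as.character(cls),
               c("strong_ld", "strong_recombination", "uninformative"))
})

all_pairs <- function(m, class) {
  pr <- expand.grid(i = seq_len(m), j = seq_len(m))
  pr <- pr[pr$i < pr$j, ]
  pr$class <- factor(class, levels = c("strong_ld", "strong_recombination",
                                       "uninformative"))
  pr
}

test_that("fully strong chromosomes yield the full interval and sub-intervals", {
  pr <- all_pairs(5, "strong_ld")
  cand <- candidate_blocks(pr, 5)
  expect_true(any(cand$first == 1 & cand$last == 5))
  expect_equal(nrow(cand), nrow(pr))  # every strong pair is its own candidate
})

test_that("strong recombination between clusters splits candidates", {
  pr <- all_pairs(6, "strong_ld")
  cross <- pr$i <= 3 & pr$j >= 4
  pr$class[cross] <- "strong_recombination"
  cand <- candidate_blocks(pr, 6)
  expect_true(all(cand$last <= 3 | cand$first >= 4))
  expect_true(any(cand$first == 1 & cand$last == 3))
  expect_true(any(cand$first == 4 & cand$last == 6))
})

test_that("candidate enumeration matches the exhaustive oracle", {
  set.seed(801)
  for (k in 1:100) {
    inst <- random_block_instance()
    got <- candidate_blocks(inst$pairs, inst$n_markers)
    want <- oracle_candidates(inst$pairs, inst$n_markers)
    expect_equal(got$first, want$first)
    expect_equal(got$last, want$last)
  }
})

test_that("greedy selection keeps the longest disjoint candidates", {
  pos <- c(1000, 2000, 5000, 11000, 15000)
  cand <- data.frame(first = c(1L, 3L), last = c(4L, 5L),
                     n_snps = c(4L, 3L))
  out <- select_blocks(cand, pos)
  expect_equal(nrow(out), 1)
  expect_equal(out$first, 1)
  expect_equal(out$last, 4)
  expect_equal(out$length, 10000)
})

test_that("two-SNP blocks are discarded; disjoint blocks come out sorted", {
  pos <- c(1000, 2000, 5000, 11000, 15000, 15500)
  only2 <- data.frame(first = 1L, last = 2L, n_snps = 2L)
  expect_equal(nrow(select_blocks(only2, pos)), 0)
  cand <- data.frame(first = c(4L, 1L), last = c(6L, 3L), n_snps = c(3L, 3L))
  out <- select_blocks(cand, pos)
  expect_equal(out$first, c(1L, 4L))
  expect_true(all(diff(out$start_pos) > 0))
})

test_that("accepted blocks are disjoint and satisfy the Gabriel predicate", {
  set.seed(802)
  panels <- simulate_panels(small_sim(seed = 21, n_markers = 120,
                                      chromosome_length = 4e5))
  joint <- haplotype_panel(rbind(panels[[1]]$haplotypes, panels[[2]]$haplotypes),
                           panels[[1]]$markers,
                           c(panels[[1]]$sample_ids, panels[[2]]$sample_ids),
                           c(panels[[1]]$groups, panels[[2]]$groups), TRUE)
  qp <- apply_qc(joint)$panel
  params <- gabriel_params()
  ld <- ld_pair_table(qp, params$max_pair_distance, with_ci = TRUE)
  ld$class <- classify_pairs(ld, params)
  blocks <- find_blocks(qp, params)
  if (nrow(blocks) >= 2) {
    covered <- unlist(Map(seq, blocks$first, blocks$last))
    expect_equal(anyDuplicated(covered), 0)
  }
  for (k in seq_len(nrow(blocks))) {
    a <- blocks$first[k]; b <- blocks$last[k]
    ep <- ld$class[ld$i == a & ld$j == b]
    expect_equal(as.character(ep), "strong_ld")
    inside <- ld$i >= a & ld$j <= b
    ns <- sum(ld$class[inside] == "strong_ld")
    ni <- ns + sum(ld$class[inside] == "strong_recombination")
    expect_gte(ns / ni, params$min_strong_fraction)
    expect_gte(blocks$n_snps[k], params$min_block_snps)
  }
})

test_that("block summaries reduce to hand arithmetic", {
  H <- matrix(rep(c(0L, 1L), each = 4), nrow = 8, ncol = 5)
  p <- make_panel(H, c(1000, 2000, 3000, 9000, 11000))
  blocks <- data.frame(chrom = "1", first = 1L, last = 3L,
                       start_pos = 1000L, end_pos = 3000L,
                       n_snps = 3L, length = 2000L)
  s <- summarize_blocks(blocks, p)
  expect_equal(s$pct_chrom_covered, 20)
  expect_equal(s$snps_in_blocks, 3)
  expect_equal(s$pct_snps_in_blocks, 60)
  expect_equal(s$max_block_bp, 2000)
  expect_equal(s$mean_block_bp, 2000)

  s0 <- summarize_blocks(blocks[0, ], p)
  expect_equal(s0$n_blocks, 0)
  expect_equal(s0$pct_chrom_covered, 0)
})
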