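# Independent oracles and small fixture builders shared across the suite.
# Every oracle recomputes its quantity from the definition, never through
# the code path it checks.

# build a panel from a haplotype matrix and positions
make_panel <- function(H, pos, chrom = "1", groups = NULL, phased = TRUE,
                       ref = "A", alt = "C") {
  H <- as.matrix(H)
  mk <- data.frame(id = paste0("m", seq_along(pos)), chrom = chrom,
                   pos = as.integer(pos), ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  haplotype_panel(H, mk, sample_ids = paste0("s", seq_len(nrow(H) / 2)),
                  groups = groups, phased = phased)
}

# random gametic count vector with polymorphic margins
random_counts <- function(n_max = 200) {
  repeat {
    n <- sample(4:n_max, 1)
    f <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
    pa <- (f[1] + f[2]) / n
    pb <- (f[1] + f[3]) / n
    if (pa > 0 && pa < 1 && pb > 0 && pb < 1) return(f)
  }
}

# LD statistics straight from allele indicator vectors (definitional route):
# r from Pearson correlation, D from the mean cross-product
oracle_pair_ld <- function(cnts) {
  a <- rep(c(1, 1, 0, 0), cnts)
  b <- rep(c(1, 0, 1, 0), cnts)
  r <- suppressWarnings(stats::cor(a, b))
  pa <- mean(a); pb <- mean(b)
  D <- mean(a * b) - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(D = D, r2 = r^2, signed_r = r,
       dprime = if (D == 0) 0 else abs(D) / dmax)
}

# full-enumeration exact HWE p-value: all feasible heterozygote counts given
# the allele counts, probabilities from log-factorials
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  if (min(na, 2 * n - na) == 0) return(1.0)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- vapply(hs, function(h) {
    nA <- (na - h) / 2
    nB <- n - nA - h
    lfactorial(n) - lfactorial(nA) - lfactorial(h) - lfactorial(nB) +
      h * log(2) +
      lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[match(nab, hs)] * (1 + 1e-9)])
}

# genotype-table log-likelihood under random union of gametes, profiled over
# the one free haplotype frequency by dense grid search plus local refinement
oracle_em_loglik <- function(g) {
  g <- as.matrix(g)
  n <- sum(g)
  pa <- (2 * sum(g[3, ]) + sum(g[2, ])) / (2 * n)
  pb <- (2 * sum(g[, 3]) + sum(g[, 2])) / (2 * n)
  ll <- function(p11) {
    p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - pa - pb + p11
    P <- matrix(c(p00^2,       2 * p00 * p01,               p01^2,
                  2 * p00 * p10, 2 * (p11 * p00 + p10 * p01), 2 * p01 * p11,
                  p10^2,       2 * p10 * p11,               p11^2),
                3, 3, byrow = TRUE)
    sum(ifelse(g > 0, g * log(pmax(P, 0)), 0))
  }
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  if (hi - lo < 1e-14) return(ll(lo))
  grid <- seq(lo, hi, length.out = 2001)
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  opt <- stats::optimize(ll, lower = grid[max(1, k - 2)],
                         upper = grid[min(length(grid), k + 2)],
                         maximum = TRUE, tol = 1e-12)
  max(opt$objective, vals[k])
}

# random 3x3 genotype table drawn from random haplotype frequencies under
# random mating
random_geno_table <- function(n_max = 30) {
  f <- as.vector(stats::rmultinom(1, 60, stats::runif(4, 0.05, 1))) / 60
  p11 <- f[1]; p10 <- f[2]; p01 <- f[3]; p00 <- f[4]
  P <- matrix(c(p00^2,       2 * p00 * p01,               p01^2,
                2 * p00 * p10, 2 * (p11 * p00 + p10 * p01), 2 * p01 * p11,
                p10^2,       2 * p10 * p11,               p11^2),
              3, 3, byrow = TRUE)
  n <- sample(2:n_max, 1)
  matrix(stats::rmultinom(1, n, as.vector(P)), 3, 3)
}

# scalar grid-likelihood D' interval, written as a direct loop over the grid
oracle_dprime_ci <- function(cnts, grid_points = 101L, mass = 0.90) {
  n11 <- cnts[1]; n10 <- cnts[2]; n01 <- cnts[3]; n00 <- cnts[4]
  n <- sum(cnts)
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  D <- n11 / n - pa * pb
  s <- if (D >= 0) 1 else -1
  dmax <- if (s > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  grid <- seq(0, 1, length.out = grid_points)
  ll <- numeric(grid_points)
  for (k in seq_len(grid_points)) {
    Dg <- s * grid[k] * dmax
    p <- c(pa * pb + Dg, pa - pa * pb - Dg, pb - pa * pb - Dg,
           1 - pa - pb + pa * pb + Dg)
    cnt <- c(n11, n10, n01, n00)
    terms <- ifelse(cnt > 0, cnt * log(pmax(p, 0)), 0)
    ll[k] <- sum(terms)
  }
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  a <- (1 - mass) / 2
  c(ci_low = grid[which(cdf >= a)[1]], ci_high = grid[which(cdf >= 1 - a)[1]])
}

# exhaustive Gabriel candidate enumeration: test every interval against the
# definition directly
oracle_candidates <- function(pairs, n_markers, params = gabriel_params()) {
  out <- list()
  key <- paste(pairs$i, pairs$j)
  for (a in seq_len(n_markers - 1)) {
    for (b in seq(a + 1, n_markers)) {
      ep <- match(paste(a, b), key)
      if (is.na(ep) || pairs$class[ep] != "strong_ld") next
      inside <- pairs$i >= a & pairs$j <= b
      ns <- sum(pairs$class[inside] == "strong_ld")
      ni <- ns + sum(pairs$class[inside] == "strong_recombination")
      if (ni > 0 && ns / ni >= params$min_strong_fraction)
        out[[length(out) + 1]] <- c(a, b)
    }
  }
  if (!length(out)) return(data.frame(first = integer(), last = integer()))
  m <- do.call(rbind, out)
  data.frame(first = m[, 1], last = m[, 2])[order(m[, 1], m[, 2]), ]
}

# random classified-pair instance over <= max_markers markers; a random
# subset of pairs is left unclassified (as if beyond the distance cap)
random_block_instance <- function(max_markers = 10) {
  m <- sample(3:max_markers, 1)
  pr <- expand.grid(i = seq_len(m), j = seq_len(m))
  pr <- pr[pr$i < pr$j, ]
  pr <- pr[stats::runif(nrow(pr)) < 0.9, , drop = FALSE]  # some pairs missing
  pr$class <- factor(sample(c("strong_ld", "strong_recombination", "uninformative"),
                            nrow(pr), replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                     levels = c("strong_ld", "strong_recombination", "uninformative"))
  list(pairs = pr, n_markers = m)
}

# small fast simulator configuration for unit tests
small_sim <- function(seed = 1, ...) {
  args <- list(seed = seed, n_markers = 250, chromosome_length = 1e6,
               Ne_founder = 50, n_samples_per_group = c(50, 50),
               burn_in_gens = 150L, founder_divergence_gens = 40L,
               post_admixture_gens = 8L, group_split_gens = 6L)
  extra <- list(...)
  args[names(extra)] <- extra
  # keep roughly one crossover per meiosis so tiny test chromosomes still
  # recombine enough to hold polymorphism through the drift phases
  if (is.null(extra$recomb_rate))
    args$recomb_rate <- 1 / args$chromosome_length
  do.call(sim_config, args)
}
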