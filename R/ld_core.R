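#' Two-locus haplotype counts
#'
#' Counts the four gametic types over haplotype rows at which both markers
#' are non-missing (pairwise-complete deletion).
#'
#' @param panel a phased [haplotype_panel()].
#' @param i,j marker column indices with `i < j`.
#' @return named integer vector `c(n11, n10, n01, n00)`; `n11` counts
#'   haplotypes carrying the alternate allele at both markers.
#' @export
haplotype_counts <- function(panel, i, j) {
  if (!panel$phased)
    stop("panel is unphased: use em_haplotype_freqs() on the genotype table")
  stopifnot(i < j, j <= n_markers(panel))
  a <- panel$haplotypes[, i]
  b <- panel$haplotypes[, j]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  c(n11 = sum(a == 1L & b == 1L),
    n10 = sum(a == 1L & b == 0L),
    n01 = sum(a == 0L & b == 1L),
    n00 = sum(a == 0L & b == 0L))
}

#' Two-locus LD statistics from haplotype counts
#'
#' Given gametic counts `(n11, n10, n01, n00)` the function computes the
#' two-marker haplotype frequency `p_ij = n11 / n`, the marginal
#' alternate-allele frequencies `p_i`, `p_j`, and from them
#' `D = p_ij - p_i p_j`,
#' `r2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))`,
#' `D' = |D| / D_max` with
#' `D_max = min(p_i (1 - p_j), (1 - p_i) p_j)` when `D > 0` and
#' `D_max = min(p_i p_j, (1 - p_i) (1 - p_j))` when `D < 0`,
#' and `signed_r = sign(D) * sqrt(r2)` — the square root of r2 carrying the
#' sign of D, the quantity whose cross-group correlation measures
#' persistence of LD phase.
#'
#' All arguments are vectorised; scalars describe one pair.
#'
#' @param n11,n10,n01,n00 gametic counts (alt-alt, alt-ref, ref-alt,
#'   ref-ref). Alternatively pass a single vector of four counts as `n11`.
#' @return data.frame with columns `n`, `p_i`, `p_j`, `p_ij`, `D`, `r2`,
#'   `dprime`, `signed_r`. Statistics are `NA` where either marker is
#'   monomorphic within the counted haplotypes (LD undefined; such pairs
#'   are skipped upstream, never zero-filled).
#' @export
pair_ld <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL) {
  if (is.null(n10)) {
    stopifnot(length(n11) == 4L)
    n00 <- n11[4L]; n01 <- n11[3L]; n10 <- n11[2L]; n11 <- n11[1L]
  }
  n <- n11 + n10 + n01 + n00
  p_i <- (n11 + n10) / n
  p_j <- (n11 + n01) / n
  p_ij <- n11 / n
  D <- p_ij - p_i * p_j
  denom <- p_i * (1 - p_i) * p_j * (1 - p_j)
  poly <- denom > 0
  r2 <- ifelse(poly, D^2 / denom, NA_real_)
  dmax <- ifelse(D >= 0,
                 pmin(p_i * (1 - p_j), (1 - p_i) * p_j),
                 pmin(p_i * p_j, (1 - p_i) * (1 - p_j)))
  dprime <- ifelse(poly, ifelse(D == 0, 0, abs(D) / dmax), NA_real_)
  signed_r <- ifelse(poly, sign(D) * sqrt(r2), NA_real_)
  data.frame(n = n, p_i = p_i, p_j = p_j, p_ij = p_ij, D = D,
             r2 = r2, dprime = dprime, signed_r = signed_r)
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' For a 3x3 genotype table (alt-allele dosages 0/1/2 at each marker) the
#' only phase ambiguity is the double heterozygote, which can carry the
#' coupling (11/00) or repulsion (10/01) gamete pair. The EM algorithm
#' splits that cell between the two configurations at their current expected
#' proportions and re-estimates the four haplotype frequencies until the
#' largest frequency change falls below `tol`. The likelihood surface can be
#' bimodal, so the algorithm is restarted from linkage equilibrium,
#' near-coupling and near-repulsion states and the best solution kept.
#'
#' @param geno_table 3x3 matrix of genotype counts; `geno_table[a, b]` is
#'   the number of samples with dosage `a - 1` at marker i and `b - 1` at
#'   marker j.
#' @param tol convergence tolerance on the haplotype frequencies
#'   (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `freqs` (named vector `p11, p10, p01, p00`, summing to
#'   one), `loglik` (multinomial log-likelihood of the genotype table),
#'   `iterations`, `converged`.
#' @export
em_haplotype_freqs <- function(geno_table, tol = 1e-10, max_iter = 1000L) {
  g <- as.matrix(geno_table)
  stopifnot(all(dim(g) == c(3L, 3L)), all(g >= 0))
  n <- sum(g)
  if (n == 0) stop("empty genotype table")
  # gamete counts fixed by unambiguous cells (marker i allele, marker j allele)
  base11 <- 2 * g[3, 3] + g[3, 2] + g[2, 3]
  base10 <- 2 * g[3, 1] + g[3, 2] + g[2, 1]
  base01 <- 2 * g[1, 3] + g[1, 2] + g[2, 3]
  base00 <- 2 * g[1, 1] + g[1, 2] + g[2, 1]
  ndh <- g[2, 2]                       # double heterozygotes
  nh <- 2 * n                          # total gametes

  run_em <- function(start) {
    f <- start
    it <- 0L
    repeat {
      it <- it + 1L
      # E step: expected share of coupling (11/00) double heterozygotes
      cpl <- f[1] * f[4]
      rpl <- f[2] * f[3]
      w <- if (cpl + rpl > 0) cpl / (cpl + rpl) else 0.5
      f_new <- c(base11 + ndh * w, base10 + ndh * (1 - w),
                 base01 + ndh * (1 - w), base00 + ndh * w) / nh
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol || it >= max_iter) break
    }
    list(f = f, iterations = it, converged = max(abs(delta)) < tol)
  }

  starts <- list(
    {p <- (base11 + base10 + ndh) / nh; q <- (base11 + base01 + ndh) / nh
     c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))},
    c(base11 + ndh, base10, base01, base00 + ndh) / nh,   # all coupling
    c(base11, base10 + ndh, base01 + ndh, base00) / nh)   # all repulsion
  fits <- lapply(starts, run_em)
  lls <- vapply(fits, function(x) em_genotype_loglik(g, x$f), numeric(1))
  best <- which.max(lls)
  f <- fits[[best]]$f
  names(f) <- c("p11", "p10", "p01", "p00")
  list(freqs = f, loglik = lls[best],
       iterations = fits[[best]]$iterations,
       converged = fits[[best]]$converged)
}

# multinomial log-likelihood of a 3x3 genotype table under random union of
# gametes with haplotype frequencies f = (p11, p10, p01, p00)
em_genotype_loglik <- function(g, f) {
  p11 <- f[1]; p10 <- f[2]; p01 <- f[3]; p00 <- f[4]
  probs <- matrix(0, 3, 3)
  probs[1, 1] <- p00^2
  probs[1, 2] <- 2 * p00 * p01
  probs[1, 3] <- p01^2
  probs[2, 1] <- 2 * p00 * p10
  probs[2, 2] <- 2 * (p11 * p00 + p10 * p01)
  probs[2, 3] <- 2 * p01 * p11
  probs[3, 1] <- p10^2
  probs[3, 2] <- 2 * p10 * p11
  probs[3, 3] <- p11^2
  lp <- ifelse(g > 0, g * log(pmax(probs, 0)), 0)
  sum(lp)
}

#' Likelihood-based confidence interval on D'
#'
#' Evaluates the multinomial likelihood of the observed gametic counts on a
#' uniform grid of D' values in \[0, 1\], holding the marginal allele
#' frequencies at their observed values and the sign of D at its observed
#' sign, normalises the grid likelihood to a discrete posterior under a flat
#' prior, and returns the central interval holding `mass` of that posterior.
#' These are the bounds the Gabriel block classification consumes.
#'
#' @param n11,n10,n01,n00 gametic counts, vectorised as in [pair_ld()]; a
#'   single 4-vector may be passed as `n11`.
#' @param grid_points number of grid points over \[0, 1\] (default 101).
#' @param mass central posterior mass of the interval (default 0.90).
#' @return data.frame with columns `ci_low`, `ci_high` (both in \[0, 1\],
#'   `ci_low <= ci_high`); `NA` rows where a marker is monomorphic.
#' @export
dprime_ci <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL,
                      grid_points = 101L, mass = 0.90) {
  if (is.null(n10)) {
    stopifnot(length(n11) == 4L)
    n00 <- n11[4L]; n01 <- n11[3L]; n10 <- n11[2L]; n11 <- n11[1L]
  }
  stopifnot(grid_points >= 3L, mass > 0, mass < 1)
  npairs <- length(n11)
  n <- n11 + n10 + n01 + n00
  p_i <- (n11 + n10) / n
  p_j <- (n11 + n01) / n
  D <- n11 / n - p_i * p_j
  poly <- p_i > 0 & p_i < 1 & p_j > 0 & p_j < 1
  # sign of D fixed at its observed sign; D = 0 scanned on the positive branch
  s <- ifelse(D >= 0, 1, -1)
  dmax <- ifelse(s > 0,
                 pmin(p_i * (1 - p_j), (1 - p_i) * p_j),
                 pmin(p_i * p_j, (1 - p_i) * (1 - p_j)))
  grid <- seq(0, 1, length.out = grid_points)
  lo <- hi <- rep(NA_real_, npairs)
  idx <- which(poly)
  chunk <- 20000L
  for (start in seq(1L, length(idx), by = chunk)) {
    ii <- idx[start:min(start + chunk - 1L, length(idx))]
    Dg <- (s[ii] * dmax[ii]) %o% grid            # pairs x grid
    P11 <- p_i[ii] * p_j[ii] + Dg
    P10 <- p_i[ii] - P11
    P01 <- p_j[ii] - P11
    P00 <- 1 - p_i[ii] - p_j[ii] + P11
    ll <- cnt_log(n11[ii], P11) + cnt_log(n10[ii], P10) +
      cnt_log(n01[ii], P01) + cnt_log(n00[ii], P00)
    w <- exp(ll - apply(ll, 1L, max))
    cdf <- t(apply(w, 1L, cumsum))
    cdf <- cdf / cdf[, grid_points]
    a <- (1 - mass) / 2
    lo[ii] <- grid[max.col(cdf >= a, ties.method = "first")]
    hi[ii] <- grid[max.col(cdf >= 1 - a, ties.method = "first")]
  }
  data.frame(ci_low = lo, ci_high = hi)
}

# n * log(p) with the conventions 0 * log(0) = 0 and n>0, p<=0 -> -Inf
cnt_log <- function(cnt, p) {
  out <- cnt * log(pmax(p, 0))
  out[cnt == 0] <- 0
  out
}

#' Pairwise LD table for a panel
#'
#' Computes [pair_ld()] statistics (and optionally [dprime_ci()] bounds)
#' for every marker pair within `max_distance`, using a sliding-window
#' enumeration and lag-vectorised counting. Pairs where either marker is
#' monomorphic over the pairwise-complete haplotypes are dropped.
#'
#' @param panel a phased [haplotype_panel()].
#' @param max_distance maximum pair distance in bp (default 500000).
#' @param with_ci also compute D' confidence bounds (needed for block
#'   finding; default `FALSE`).
#' @param grid_points,mass passed to [dprime_ci()].
#' @return data.frame with columns `chrom`, `i`, `j`, `pos_i`, `pos_j`,
#'   `distance`, `n`, `p_i`, `p_j`, `p_ij`, `D`, `r2`, `dprime`,
#'   `signed_r` (and `ci_low`, `ci_high` when `with_ci`). Carries the
#'   panel's allele-orientation digest as attribute `"orientation"`.
#' @export
ld_pair_table <- function(panel, max_distance = 500000, with_ci = FALSE,
                          grid_points = 101L, mass = 0.90) {
  if (!panel$phased)
    stop("panel is unphased: phase it or use the EM route per pair")
  pr <- enumerate_pairs(panel, max_distance)
  H <- panel$haplotypes
  m <- nrow(pr)
  n11 <- n10 <- n01 <- n00 <- integer(m)
  has_na <- anyNA(H)
  lag <- pr$j - pr$i
  for (k in unique(lag)) {
    sel <- which(lag == k)
    A <- H[, pr$i[sel], drop = FALSE]
    B <- H[, pr$j[sel], drop = FALSE]
    if (has_na) {
      ok <- !is.na(A) & !is.na(B)
      A[!ok] <- 0L; B[!ok] <- 0L
      nok <- colSums(ok)
    } else {
      nok <- rep(nrow(H), length(sel))
    }
    s11 <- colSums(A * B)
    sA <- colSums(A)
    sB <- colSums(B)
    n11[sel] <- s11
    n10[sel] <- sA - s11
    n01[sel] <- sB - s11
    n00[sel] <- nok - sA - sB + s11
  }
  stats <- pair_ld(n11, n10, n01, n00)
  out <- data.frame(chrom = if (nrow(panel$markers)) panel$markers$chrom[1] else character(m),
                    i = pr$i, j = pr$j,
                    pos_i = panel$markers$pos[pr$i],
                    pos_j = panel$markers$pos[pr$j],
                    distance = pr$distance,
                    stringsAsFactors = FALSE)
  out <- cbind(out, stats)
  keep <- !is.na(out$r2)
  n11 <- n11[keep]; n10 <- n10[keep]; n01 <- n01[keep]; n00 <- n00[keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (with_ci)
    out <- cbind(out, dprime_ci(n11, n10, n01, n00,
                                grid_points = grid_points, mass = mass))
  attr(out, "orientation") <- orientation_key(panel)
  out
}

#' Write a pairwise LD table as TSV
#'
#' @param ld data.frame from [ld_pair_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(format(ld, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
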