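#' Parameters of the Gabriel confidence-interval block definition
#'
#' The published definition (the Haploview default): a pair is in "strong
#' LD" when its D' confidence bounds satisfy lower >= 0.70 and upper >=
#' 0.98, and shows "strong evidence of historical recombination" when the
#' upper bound is < 0.90; an interval is a block when its endpoint pair is
#' in strong LD and at least 95% of its informative internal pairs are in
#' strong LD. Pairs farther apart than `max_pair_distance` never enter the
#' computation, and blocks of fewer than `min_block_snps` markers are
#' discarded from the output (two-SNP blocks are prone to spurious
#' formation).
#'
#' @param strong_ld_low,strong_ld_high D' CI thresholds for strong LD.
#' @param recomb_high D' CI upper-bound threshold for strong recombination.
#' @param min_strong_fraction minimum fraction of informative pairs in
#'   strong LD inside a block.
#' @param max_pair_distance pair-distance cap in bp.
#' @param min_block_snps minimum markers per reported block.
#' @return list of class `gabriel_params`.
#' @export
gabriel_params <- function(strong_ld_low = 0.70, strong_ld_high = 0.98,
                           recomb_high = 0.90, min_strong_fraction = 0.95,
                           max_pair_distance = 500000, min_block_snps = 3L) {
  stopifnot(recomb_high > 0, recomb_high < strong_ld_high,
            strong_ld_high <= 1, min_strong_fraction > 0,
            min_strong_fraction <= 1, min_block_snps >= 2L)
  structure(list(strong_ld_low = strong_ld_low,
                 strong_ld_high = strong_ld_high,
                 recomb_high = recomb_high,
                 min_strong_fraction = min_strong_fraction,
                 max_pair_distance = max_pair_distance,
                 min_block_snps = as.integer(min_block_snps)),
            class = "gabriel_params")
}

#' Classify marker pairs for block finding
#'
#' @param ld data.frame with `ci_low`, `ci_high` columns (from
#'   [ld_pair_table()] with `with_ci = TRUE`).
#' @param params a [gabriel_params()].
#' @return factor with levels `strong_ld`, `strong_recombination`,
#'   `uninformative`, one per row of `ld`.
#' @export
classify_pairs <- function(ld, params = gabriel_params()) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(ld)))
  out <- rep("uninformative", nrow(ld))
  out[ld$ci_high < params$recomb_high] <- "strong_recombination"
  out[ld$ci_low >= params$strong_ld_low &
        ld$ci_high >= params$strong_ld_high] <- "strong_ld"
  factor(out, levels = c("strong_ld", "strong_recombination", "uninformative"))
}

#' Candidate block intervals on one chromosome
#'
#' Every marker interval `[a, b]` whose endpoint pair `(a, b)` is in strong
#' LD and in which the fraction strong / (strong + recombination), over all
#' classified pairs inside the interval, is at least
#' `min_strong_fraction`. Uninformative pairs are excluded from the
#' denominator; pairs beyond the distance cap are never classified and so
#' never counted. Counting uses 2D prefix sums, so each candidate is
#' evaluated in O(1).
#'
#' @param pairs data.frame with columns `i`, `j` (marker indices, `i < j`)
#'   and `class` (a factor as from [classify_pairs()]).
#' @param n_markers number of markers on the chromosome.
#' @param params a [gabriel_params()].
#' @return data.frame with columns `first`, `last`, `n_snps`,
#'   `n_strong`, `n_informative`, `strong_fraction`, one row per candidate,
#'   ordered by (`first`, `last`).
#' @export
candidate_blocks <- function(pairs, n_markers, params = gabriel_params()) {
  stopifnot(all(c("i", "j", "class") %in% names(pairs)))
  empty <- data.frame(first = integer(), last = integer(), n_snps = integer(),
                      n_strong = integer(), n_informative = integer(),
                      strong_fraction = numeric())
  if (!nrow(pairs)) return(empty)
  stopifnot(all(pairs$i < pairs$j), max(pairs$j) <= n_markers)
  is_strong <- pairs$class == "strong_ld"
  is_inform <- is_strong | pairs$class == "strong_recombination"

  # prefix matrices P[x, y] = number of pairs with i <= x, j <= y;
  # count inside [a, b] (a <= i < j <= b) = P[b, b] - P[a - 1, b]
  prefix <- function(sel) {
    M <- matrix(0, n_markers, n_markers)
    if (any(sel))
      M[cbind(pairs$i[sel], pairs$j[sel])] <- 1
    M <- apply(M, 2L, cumsum)
    t(apply(M, 1L, cumsum))
  }
  Ps <- prefix(is_strong)
  Pi <- prefix(is_inform)

  a <- pairs$i[is_strong]
  b <- pairs$j[is_strong]
  if (!length(a)) return(empty)
  cnt <- function(P, a, b) {
    P[cbind(b, b)] - ifelse(a > 1L, P[cbind(pmax(a - 1L, 1L), b)], 0)
  }
  n_strong <- cnt(Ps, a, b)
  n_inform <- cnt(Pi, a, b)
  frac <- n_strong / n_inform
  keep <- n_inform > 0 & frac >= params$min_strong_fraction
  out <- data.frame(first = a[keep], last = b[keep],
                    n_snps = b[keep] - a[keep] + 1L,
                    n_strong = as.integer(n_strong[keep]),
                    n_informative = as.integer(n_inform[keep]),
                    strong_fraction = frac[keep])
  out <- out[order(out$first, out$last), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy selection of non-overlapping blocks
#'
#' Candidates are ranked by physical length (bp) descending, ties broken by
#' more SNPs, then leftmost position, and accepted greedily when
#' marker-disjoint from everything already accepted. Blocks with fewer
#' than `min_block_snps` markers are discarded from the accepted set.
#'
#' @param candidates data.frame from [candidate_blocks()].
#' @param positions marker positions (bp) of the chromosome the candidates
#'   index into.
#' @param chrom chromosome label for the output.
#' @param params a [gabriel_params()].
#' @return data.frame of blocks sorted by position: `chrom`, `first`,
#'   `last`, `start_pos`, `end_pos`, `n_snps`, `length` (bp, end - start).
#' @export
select_blocks <- function(candidates, positions, chrom = "1",
                          params = gabriel_params()) {
  empty <- data.frame(chrom = character(), first = integer(), last = integer(),
                      start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || !nrow(candidates)) return(empty)
  len <- positions[candidates$last] - positions[candidates$first]
  ord <- order(-len, -candidates$n_snps, candidates$first)
  covered <- logical(length(positions))
  acc <- logical(nrow(candidates))
  for (k in ord) {
    rng <- candidates$first[k]:candidates$last[k]
    if (!any(covered[rng])) {
      covered[rng] <- TRUE
      acc[k] <- TRUE
    }
  }
  sel <- acc & candidates$n_snps >= params$min_block_snps
  if (!any(sel)) return(empty)
  out <- data.frame(chrom = chrom,
                    first = candidates$first[sel],
                    last = candidates$last[sel],
                    start_pos = positions[candidates$first[sel]],
                    end_pos = positions[candidates$last[sel]],
                    n_snps = candidates$n_snps[sel],
                    length = positions[candidates$last[sel]] -
                      positions[candidates$first[sel]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find haplotype blocks on a panel
#'
#' Convenience wrapper: pairwise LD with D' confidence bounds,
#' Gabriel classification, candidate enumeration and greedy selection.
#'
#' @param panel a phased [haplotype_panel()].
#' @param params a [gabriel_params()].
#' @param grid_points,mass passed to [dprime_ci()].
#' @return data.frame of blocks as from [select_blocks()].
#' @export
find_blocks <- function(panel, params = gabriel_params(),
                        grid_points = 101L, mass = 0.90) {
  ld <- ld_pair_table(panel, max_distance = params$max_pair_distance,
                      with_ci = TRUE, grid_points = grid_points, mass = mass)
  ld$class <- classify_pairs(ld, params)
  cand <- candidate_blocks(ld, n_markers(panel), params)
  select_blocks(cand, panel$markers$pos,
                chrom = if (nrow(panel$markers)) panel$markers$chrom[1] else "1",
                params = params)
}

#' Per-chromosome haplotype-block summary
#'
#' Rolls blocks up into the usual per-chromosome table: marker count,
#' chromosome length (span of the markers), mean inter-marker distance,
#' block count, total block length, percent of the chromosome covered by
#' blocks, markers inside blocks (count and percent), and the maximum and
#' mean block length.
#'
#' @param blocks data.frame from [select_blocks()] / [find_blocks()]
#'   (one chromosome).
#' @param panel the [haplotype_panel()] the blocks were computed on.
#' @return one-row data.frame with columns `chrom`, `n_snps`,
#'   `chrom_length_bp`, `mean_snp_spacing_bp`, `n_blocks`,
#'   `block_coverage_bp`, `pct_chrom_covered`, `snps_in_blocks`,
#'   `pct_snps_in_blocks`, `max_block_bp`, `mean_block_bp`.
#' @export
summarize_blocks <- function(blocks, panel) {
  pos <- panel$markers$pos
  span <- if (length(pos) >= 2L) max(pos) - min(pos) else 0L
  nb <- if (is.null(blocks)) 0L else nrow(blocks)
  total_bp <- if (nb) sum(blocks$length) else 0
  snps_in <- if (nb) sum(blocks$n_snps) else 0L
  data.frame(
    chrom = if (nrow(panel$markers)) panel$markers$chrom[1] else NA_character_,
    n_snps = length(pos),
    chrom_length_bp = span,
    mean_snp_spacing_bp = if (length(pos) >= 2L) span / (length(pos) - 1L) else NA_real_,
    n_blocks = nb,
    block_coverage_bp = total_bp,
    pct_chrom_covered = if (span > 0) 100 * total_bp / span else 0,
    snps_in_blocks = snps_in,
    pct_snps_in_blocks = if (length(pos)) 100 * snps_in / length(pos) else 0,
    max_block_bp = if (nb) max(blocks$length) else 0,
    mean_block_bp = if (nb) mean(blocks$length) else 0,
    stringsAsFactors = FALSE)
}
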