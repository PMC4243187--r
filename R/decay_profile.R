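#' Distance-bin scheme for LD-decay profiles
#'
#' Breakpoints are given in kb. Bins are half-open `[low, high)` except the
#' final bin, which is closed at the cap, so every distance in
#' `(0, cap]` maps to exactly one bin. The default edges follow the usual
#' presentation of high-density bovine LD maps: 2.5-kb bins up to 10 kb,
#' 10-kb bins up to 100 kb, then 100-kb bins up to the 500-kb cap.
#'
#' @param edges_kb strictly increasing numeric vector of breakpoints in kb;
#'   first edge 0, last edge the maximum-distance cap.
#' @return list of class `distance_bins` with elements `edges_kb`,
#'   `edges_bp`, `labels`, `n_bins`, `cap_bp`.
#' @export
distance_bins <- function(edges_kb = c(0, 2.5, 5, 7.5, 10, 20, 30, 40, 50,
                                       60, 70, 80, 90, 100, 200, 300, 400, 500)) {
  stopifnot(length(edges_kb) >= 2L, edges_kb[1] == 0,
            !is.unsorted(edges_kb, strictly = TRUE))
  fmt <- function(x) sub("\\.0+$", "", formatC(x, format = "f", digits = 1))
  labels <- c(paste0("< ", fmt(edges_kb[2])),
              if (length(edges_kb) > 2L)
                paste(fmt(edges_kb[-c(1L, length(edges_kb))]), "-",
                      fmt(edges_kb[-(1:2)])))
  structure(list(edges_kb = edges_kb,
                 edges_bp = edges_kb * 1000,
                 labels = labels,
                 n_bins = length(edges_kb) - 1L,
                 cap_bp = edges_kb[length(edges_kb)] * 1000),
            class = "distance_bins")
}

#' Assign distances to distance bins
#'
#' @param distance vector of pair distances in bp, each in `(0, cap]`.
#' @param scheme a [distance_bins()] scheme.
#' @return integer bin indices (1-based). A boundary value falls in the
#'   upper bin; a distance equal to the cap falls in the last bin.
#' @export
assign_bin <- function(distance, scheme = distance_bins()) {
  stopifnot(inherits(scheme, "distance_bins"))
  if (any(distance <= 0 | distance > scheme$cap_bp))
    stop("distance out of range (0, ", scheme$cap_bp, "]")
  pmin(findInterval(distance, scheme$edges_bp), scheme$n_bins)
}

#' Enumerate marker pairs within a distance cap
#'
#' Sliding-window enumeration over position-sorted markers: all pairs
#' `i < j` on the panel's chromosome with `0 < pos_j - pos_i <=
#' max_distance`, emitted in `(i, j)` order. Linear in the number of
#' emitted pairs — the full quadratic enumeration is never formed.
#'
#' @param panel a [haplotype_panel()] (or a numeric position vector).
#' @param max_distance cap in bp (default 500000).
#' @return data.frame with columns `i`, `j`, `distance`.
#' @export
enumerate_pairs <- function(panel, max_distance = 500000) {
  pos <- if (inherits(panel, "haplotype_panel")) panel$markers$pos else panel
  m <- length(pos)
  if (m < 2L) return(data.frame(i = integer(), j = integer(), distance = numeric()))
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted, strictly increasing")
  jmax <- findInterval(pos + max_distance, pos)
  cnt <- pmax(jmax - seq_len(m), 0L)
  i <- rep.int(seq_len(m), cnt)
  j <- i + sequence(cnt)
  data.frame(i = i, j = j, distance = pos[j] - pos[i])
}

#' Distance-binned summary of r-squared (LD-decay profile)
#'
#' For each distance bin: number of pairs, mean, sample standard deviation
#' (n - 1 denominator) and median of r2. Summaries are permutation
#' invariant; the SD is reported `NA` when a bin holds fewer than two pairs
#' and mean/median are `NA` for empty bins.
#'
#' @param ld data.frame with columns `distance` and `r2`
#'   (from [ld_pair_table()], possibly filtered to one chromosome).
#' @param scheme a [distance_bins()] scheme.
#' @param scope label describing what the profile covers (a group name such
#'   as `"CA"`, `"MA"`, `"CAN"`, or any custom label).
#' @param chromosome optional chromosome label for per-chromosome profiles
#'   (`NA` means genome-wide).
#' @return data.frame of class `decay_profile`: one row per bin with
#'   columns `bin`, `bin_label`, `n_pairs`, `mean_r2`, `sd_r2`,
#'   `median_r2`, `scope`, `chromosome`.
#' @export
build_decay_profile <- function(ld, scheme = distance_bins(), scope = "ALL",
                                chromosome = NA_character_) {
  stopifnot(all(c("distance", "r2") %in% names(ld)))
  bin <- assign_bin(ld$distance, scheme)
  out <- data.frame(bin = seq_len(scheme$n_bins),
                    bin_label = scheme$labels,
                    n_pairs = 0L, mean_r2 = NA_real_, sd_r2 = NA_real_,
                    median_r2 = NA_real_,
                    scope = scope, chromosome = chromosome,
                    stringsAsFactors = FALSE)
  if (nrow(ld)) {
    tab <- tabulate(bin, nbins = scheme$n_bins)
    out$n_pairs <- tab
    sp <- split(ld$r2, factor(bin, levels = seq_len(scheme$n_bins)))
    out$mean_r2 <- vapply(sp, function(x) if (length(x)) mean(x) else NA_real_,
                          numeric(1))
    out$sd_r2 <- vapply(sp, function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_,
                        numeric(1))
    out$median_r2 <- vapply(sp, function(x) if (length(x)) stats::median(x) else NA_real_,
                            numeric(1))
  }
  class(out) <- c("decay_profile", "data.frame")
  rownames(out) <- NULL
  out
}
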