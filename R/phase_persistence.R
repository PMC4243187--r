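#' Match LD pairs shared by two groups
#'
#' Inner join of two pairwise LD tables on (chromosome, pos_i, pos_j).
#' Pairs present in only one table are dropped and their counts reported in
#' a message. Both tables must have been computed under the identical
#' allele orientation — signed r is meaningless otherwise — which is
#' enforced by comparing the orientation digests attached by
#' [ld_pair_table()] over the markers the two tables share.
#'
#' @param ld_a,ld_b data.frames from [ld_pair_table()] for the two groups.
#' @return data.frame with columns `chrom`, `pos_i`, `pos_j`, `distance`,
#'   `signed_r_a`, `signed_r_b`, `r2_a`, `r2_b`.
#' @export
shared_pairs <- function(ld_a, ld_b) {
  oa <- attr(ld_a, "orientation")
  ob <- attr(ld_b, "orientation")
  if (!is.null(oa) && !is.null(ob)) {
    shared <- intersect(oa, ob)
    pos_a <- sub("^([^:]*:[^:]*):.*$", "\\1", oa)
    pos_b <- sub("^([^:]*:[^:]*):.*$", "\\1", ob)
    clash <- intersect(setdiff(pos_a, sub("^([^:]*:[^:]*):.*$", "\\1", shared)),
                       pos_b)
    if (length(clash))
      stop("allele orientation differs between groups at ",
           length(clash), " marker position(s); signed r is not comparable")
  }
  key_a <- paste(ld_a$chrom, ld_a$pos_i, ld_a$pos_j)
  key_b <- paste(ld_b$chrom, ld_b$pos_i, ld_b$pos_j)
  idx <- match(key_a, key_b)
  hit <- !is.na(idx)
  message(sprintf("shared_pairs: %d matched; %d only in A, %d only in B",
                  sum(hit), sum(!hit), nrow(ld_b) - sum(hit)))
  data.frame(chrom = ld_a$chrom[hit],
             pos_i = ld_a$pos_i[hit],
             pos_j = ld_a$pos_j[hit],
             distance = ld_a$distance[hit],
             signed_r_a = ld_a$signed_r[hit],
             signed_r_b = ld_b$signed_r[idx[hit]],
             r2_a = ld_a$r2[hit],
             r2_b = ld_b$r2[idx[hit]],
             stringsAsFactors = FALSE)
}

#' Persistence of LD phase between two groups
#'
#' Per distance bin, the product-moment correlation (PL) of signed r
#' between the two groups over the shared pairs in that bin. By default
#' the correlation is uncentered (`sum(xy) / sqrt(sum(x^2) sum(y^2))`):
#' because a per-marker allele-orientation flip applied to both groups
#' negates both coordinates of the affected pairs, the uncentered form is
#' exactly invariant to the arbitrary choice of reference allele, whereas
#' the centered Pearson form is only asymptotically so. Genome-wide,
#' signed r has mean very near zero within a bin, so the two forms agree
#' closely; `center = TRUE` selects the strictly centered Pearson variant.
#'
#' A bin with fewer than `min_pairs` shared pairs, or zero variance of
#' signed r in either group, is reported undefined (`NA`). The profile
#' also carries the unweighted mean of the defined per-bin PL values (the
#' headline "overall" figure) and the pair-weighted mean as an attribute.
#'
#' @param matched data.frame from [shared_pairs()].
#' @param scheme a [distance_bins()] scheme.
#' @param min_pairs minimum shared pairs for a defined bin (default 3).
#' @param center use the centered Pearson correlation instead of the
#'   orientation-invariant uncentered form (default `FALSE`).
#' @return data.frame of class `phase_persistence_profile`: one row per bin
#'   with `bin`, `bin_label`, `n_shared_pairs`, `pl`; attributes
#'   `overall_mean_pl` (unweighted bin mean) and `pairwise_mean_pl`
#'   (pair-count-weighted).
#' @export
persistence_profile <- function(matched, scheme = distance_bins(),
                                min_pairs = 3L, center = FALSE) {
  stopifnot(all(c("distance", "signed_r_a", "signed_r_b") %in% names(matched)))
  ok <- is.finite(matched$signed_r_a) & is.finite(matched$signed_r_b)
  matched <- matched[ok, , drop = FALSE]
  bin <- if (nrow(matched)) assign_bin(matched$distance, scheme) else integer()
  out <- data.frame(bin = seq_len(scheme$n_bins),
                    bin_label = scheme$labels,
                    n_shared_pairs = tabulate(bin, nbins = scheme$n_bins),
                    pl = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in seq_len(scheme$n_bins)) {
    sel <- bin == b
    if (sum(sel) >= min_pairs) {
      x <- matched$signed_r_a[sel]
      y <- matched$signed_r_b[sel]
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        out$pl[b] <- if (center) stats::cor(x, y)
                     else sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  defined <- !is.na(out$pl)
  attr(out, "overall_mean_pl") <-
    if (any(defined)) mean(out$pl[defined]) else NA_real_
  attr(out, "pairwise_mean_pl") <-
    if (any(defined)) stats::weighted.mean(out$pl[defined],
                                           out$n_shared_pairs[defined]) else NA_real_
  class(out) <- c("phase_persistence_profile", "data.frame")
  out
}
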