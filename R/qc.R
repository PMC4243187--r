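#' Quality-control thresholds
#'
#' Defaults follow common practice for high-density bovine SNP panels:
#' samples and SNPs with call rate below 0.90 are removed, SNPs failing an
#' exact Hardy-Weinberg test at p < 1e-4 are removed, and SNPs with minor
#' allele frequency below 0.05 are removed (extreme MAF reduces the power to
#' estimate LD and phase persistence).
#'
#' @param min_sample_call_rate,min_snp_call_rate fraction in (0, 1].
#' @param hwe_alpha HWE exact-test significance threshold in (0, 1].
#' @param min_maf minimum minor allele frequency in \[0, 0.5\].
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.90,
                          min_snp_call_rate = 0.90,
                          hwe_alpha = 1e-4,
                          min_maf = 0.05) {
  stopifnot(min_sample_call_rate > 0, min_sample_call_rate <= 1,
            min_snp_call_rate > 0, min_snp_call_rate <= 1,
            hwe_alpha > 0, hwe_alpha <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 hwe_alpha = hwe_alpha,
                 min_maf = min_maf),
            class = "qc_thresholds")
}

#' Per-sample call rate
#'
#' Fraction of markers at which a sample has both haplotype entries
#' non-missing.
#'
#' @param panel a [haplotype_panel()].
#' @return numeric vector (one fraction per sample) in \[0, 1\].
#' @export
sample_call_rate <- function(panel) {
  if (n_markers(panel) == 0L) stop("panel has no markers")
  G <- panel_genotypes(panel)
  rowMeans(!is.na(G))
}

#' Per-marker call rate
#'
#' Fraction of samples with a complete (both haplotypes non-missing)
#' genotype at each marker.
#'
#' @param panel a [haplotype_panel()].
#' @return numeric vector of length `n_markers(panel)`.
#' @export
marker_call_rate <- function(panel) {
  G <- panel_genotypes(panel)
  colMeans(!is.na(G))
}

#' Per-marker minor allele frequency
#'
#' `min(p, 1 - p)` where `p` is the alternate-allele frequency over
#' non-missing haplotypes.
#'
#' @param panel a [haplotype_panel()].
#' @param markers optional marker index; defaults to all markers.
#' @return numeric vector in \[0, 0.5\]; `NA` for all-missing markers.
#' @export
marker_maf <- function(panel, markers = NULL) {
  H <- panel$haplotypes
  if (!is.null(markers)) H <- H[, markers, drop = FALSE]
  p <- colMeans(H, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (no mid-p correction). Probabilities follow the hypergeometric-type
#' distribution of the heterozygote count under random mating and are
#' computed by the standard recurrence.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote). Vectors are recycled to a common
#'   length and the test applied element-wise.
#' @return p-value(s) in (0, 1\].
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(n_hom_ref, n)
  n_het <- rep_len(n_het, n)
  n_hom_alt <- rep_len(n_hom_alt, n)
  vapply(seq_len(n), function(k)
    hwe_exact_one(n_hom_ref[k], n_het[k], n_hom_alt[k]), numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("total genotype count must be >= 1")
  n_a <- 2L * n_aa + n_ab
  rare <- min(n_a, 2L * n - n_a)      # rare-allele count
  if (rare == 0L) return(1.0)
  hets <- seq(rare %% 2L, rare, by = 2L)   # feasible heterozygote counts
  # unnormalised probabilities by recurrence, anchored at the smallest
  # feasible het count; P(h+2)/P(h) = [ (rare-h)(2n-rare-h) ] / [ (h+2)(h+1) ]
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    lp[k] <- lp[k - 1L] +
      log(rare - h) + log(2 * n - rare - h) - log(h + 2) - log(h + 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- min(n_ab, rare)   # observed het count in terms of the rare allele
  p_obs <- p[match(obs, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Apply sample and SNP quality-control filters
#'
#' Samples are filtered first on call rate; SNP filters are then recomputed
#' on the surviving samples in the fixed order call rate, HWE, MAF, each SNP
#' being attributed to the first filter it fails. The HWE test runs on
#' collapsed genotypes (haplotype pairs).
#'
#' @param panel a [haplotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `panel` (the filtered panel) and `report`, a
#'   list of class `qc_report` holding input/output dimensions, per-filter
#'   removal counts and the per-marker statistics (call rate, HWE p-value,
#'   MAF) computed on the surviving samples.
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n_samples_in <- n_samples(panel)
  n_snps_in <- n_markers(panel)

  scr <- sample_call_rate(panel)
  keep_s <- scr >= thresholds$min_sample_call_rate
  p2 <- if (all(keep_s)) panel else subset_panel(panel, samples = keep_s)

  cr <- marker_call_rate(p2)
  G <- panel_genotypes(p2)
  hwe_p <- hwe_marker_pvalues(G)
  maf <- marker_maf(p2)

  fail_cr <- cr < thresholds$min_snp_call_rate
  fail_hwe <- !fail_cr & !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha
  fail_maf <- !fail_cr & !fail_hwe &
    (is.na(maf) | maf < thresholds$min_maf)
  keep_m <- !(fail_cr | fail_hwe | fail_maf)

  out <- subset_panel(p2, markers = keep_m)
  if (n_markers(out) == 0L) warning("no markers survived quality control")

  report <- structure(list(
    n_samples_in = n_samples_in,
    n_samples_out = n_samples(out),
    n_snps_in = n_snps_in,
    n_snps_out = n_markers(out),
    removed_samples_call_rate = sum(!keep_s),
    removed_snps_call_rate = sum(fail_cr),
    removed_snps_hwe = sum(fail_hwe),
    removed_snps_maf = sum(fail_maf),
    thresholds = thresholds,
    marker_stats = data.frame(id = p2$markers$id,
                              chrom = p2$markers$chrom,
                              pos = p2$markers$pos,
                              call_rate = cr,
                              hwe_p = hwe_p,
                              maf = maf,
                              kept = keep_m,
                              stringsAsFactors = FALSE)),
    class = "qc_report")
  list(panel = out, report = report)
}

hwe_marker_pvalues <- function(G) {
  n_aa <- colSums(G == 0L, na.rm = TRUE)
  n_ab <- colSums(G == 1L, na.rm = TRUE)
  n_bb <- colSums(G == 2L, na.rm = TRUE)
  tot <- n_aa + n_ab + n_bb
  out <- rep(NA_real_, length(tot))
  ok <- tot >= 1L
  if (any(ok)) {
    # markers share few distinct count triples on clean data; memoise
    key <- paste(n_aa[ok], n_ab[ok], n_bb[ok])
    uk <- !duplicated(key)
    pv <- hwe_exact_pvalue(n_aa[ok][uk], n_ab[ok][uk], n_bb[ok][uk])
    out[ok] <- pv[match(key, key[uk])]
  }
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality-control report\n")
  cat(sprintf("  samples: %d in, %d out (%d removed: call rate < %.2f)\n",
              x$n_samples_in, x$n_samples_out, x$removed_samples_call_rate,
              x$thresholds$min_sample_call_rate))
  cat(sprintf("  SNPs: %d in, %d out\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("    call rate < %.2f : %d\n", x$thresholds$min_snp_call_rate,
              x$removed_snps_call_rate))
  cat(sprintf("    HWE p < %g       : %d\n", x$thresholds$hwe_alpha,
              x$removed_snps_hwe))
  cat(sprintf("    MAF < %.2f       : %d\n", x$thresholds$min_maf,
              x$removed_snps_maf))
  invisible(x)
}

#' Serialise a QC report to TSV
#'
#' Writes the per-filter summary and the per-marker statistics table.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output TSV path (per-marker table goes to
#'   `<path>.markers.tsv`).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  summ <- data.frame(
    metric = c("n_samples_in", "n_samples_out", "n_snps_in", "n_snps_out",
               "removed_samples_call_rate", "removed_snps_call_rate",
               "removed_snps_hwe", "removed_snps_maf"),
    value = c(report$n_samples_in, report$n_samples_out, report$n_snps_in,
              report$n_snps_out, report$removed_samples_call_rate,
              report$removed_snps_call_rate, report$removed_snps_hwe,
              report$removed_snps_maf))
  utils::write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$marker_stats, paste0(path, ".markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
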