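#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` holds the phased alleles of `N` diploid samples at `M`
#' biallelic SNPs on a single chromosome. Haplotype rows `2k - 1` and `2k`
#' belong to sample `k`; entries are `0` (reference allele), `1` (alternate
#' allele) or `NA` (missing). The panel is the substrate of every LD
#' computation in the package.
#'
#' @param haplotypes integer matrix, `2N x M`, entries in `{0, 1, NA}`.
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per column of `haplotypes`, sorted by `pos`
#'   (strictly increasing) and all on one chromosome.
#' @param sample_ids character vector of length `N`.
#' @param groups character vector of per-sample group labels (length `N`),
#'   e.g. two genetic groups of a composite breed; defaults to
#'   `"UNASSIGNED"`.
#' @param phased logical flag; `TRUE` when rows are resolved parental
#'   haplotypes (phased VCF or simulator output). LD from unphased data must
#'   go through [em_haplotype_freqs()].
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `haplotypes`, `markers`, `sample_ids`, `groups`, `phased`.
#' @export
haplotype_panel <- function(haplotypes, markers, sample_ids,
                            groups = NULL, phased = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype row count must be even (two rows per sample)")
  n <- nrow(haplotypes) / 2L
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(haplotypes)/2")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("haplotype entries must be 0, 1 or NA")
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers)))
  if (nrow(markers) != ncol(haplotypes))
    stop("nrow(markers) must equal ncol(haplotypes)")
  if (nrow(markers)) {
    if (length(unique(markers$chrom)) != 1L)
      stop("a panel holds one chromosome; got: ",
           paste(unique(markers$chrom), collapse = ", "))
    if (any(markers$pos < 1)) stop("positions must be >= 1 (1-based)")
    if (is.unsorted(markers$pos, strictly = TRUE))
      stop("marker positions must be strictly increasing")
    if (any(markers$ref == markers$alt))
      stop("ref and alt alleles must differ (biallelic SNPs only)")
  }
  if (is.null(groups)) groups <- rep("UNASSIGNED", n)
  if (length(groups) != n) stop("length(groups) must equal the sample count")
  markers$chrom <- as.character(markers$chrom)
  rownames(markers) <- NULL
  structure(list(haplotypes = haplotypes,
                 markers = markers,
                 sample_ids = as.character(sample_ids),
                 groups = as.character(groups),
                 phased = isTRUE(phased)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples (%d haplotypes) x %d SNPs, chr %s\n",
              length(x$sample_ids), nrow(x$haplotypes), ncol(x$haplotypes),
              if (nrow(x$markers)) x$markers$chrom[1] else "?"))
  cat(sprintf("  phased: %s; groups: %s\n", x$phased,
              paste(sprintf("%s (%d)", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a panel
#' @param panel a [haplotype_panel()].
#' @return integer sample count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Number of markers in a panel
#' @param panel a [haplotype_panel()].
#' @return integer marker count.
#' @export
n_markers <- function(panel) ncol(panel$haplotypes)

#' Subset a panel by markers and/or samples
#'
#' @param panel a [haplotype_panel()].
#' @param markers integer or logical index over marker columns.
#' @param samples integer or logical index over samples (haplotype row pairs
#'   follow the sample selection).
#' @return a new `haplotype_panel`.
#' @export
subset_panel <- function(panel, markers = NULL, samples = NULL) {
  H <- panel$haplotypes
  mk <- panel$markers
  sid <- panel$sample_ids
  grp <- panel$groups
  if (!is.null(samples)) {
    idx <- seq_along(sid)[samples]
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    H <- H[rows, , drop = FALSE]
    sid <- sid[idx]
    grp <- grp[idx]
  }
  if (!is.null(markers)) {
    H <- H[, markers, drop = FALSE]
    mk <- mk[markers, , drop = FALSE]
  }
  haplotype_panel(H, mk, sid, grp, panel$phased)
}

#' Split a panel into one panel per group label
#'
#' @param panel a [haplotype_panel()].
#' @return named list of `haplotype_panel`, one per distinct group label.
#' @export
split_panel_by_group <- function(panel) {
  labs <- sort(unique(panel$groups))
  out <- lapply(labs, function(g) subset_panel(panel, samples = panel$groups == g))
  names(out) <- labs
  out
}

#' Collapse haplotypes to diploid genotype dosages
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix `N x M` of alt-allele dosages 0/1/2; `NA` where
#'   either haplotype entry is missing.
#' @export
panel_genotypes <- function(panel) {
  H <- panel$haplotypes
  n <- nrow(H) / 2L
  H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

# Orientation key used to guarantee that signed r is compared across groups
# under one allele orientation: one string per marker.
orientation_key <- function(panel) {
  with(panel$markers, paste(chrom, pos, ref, alt, sep = ":"))
}
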