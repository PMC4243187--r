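#' Read phased genotypes from a VCF file
#'
#' Loads a VCF (plain text or gzipped) and returns one [haplotype_panel()]
#' per chromosome encountered. Only biallelic SNP records are kept;
#' multiallelic or non-SNP records, records without a position, and sex
#' chromosomes are dropped with a message reporting the counts. Duplicate
#' positions keep the first record seen. The panel's `phased` flag is `TRUE`
#' only when every genotype separator in the file is `"|"`; data loaded with
#' any `"/"` separator must be analysed through the EM route
#' ([em_haplotype_freqs()]).
#'
#' @param path path to a VCF file with a GT field.
#' @param group_map optional data.frame with columns `sample_id`, `group`
#'   (see [read_group_map()]). Samples absent from the map get group
#'   `"UNASSIGNED"`; map entries absent from the VCF raise a warning.
#' @param drop_sex_chromosomes drop markers on X/Y/MT style chromosome
#'   labels (default `TRUE`).
#' @return named list of [haplotype_panel()], one per chromosome, in the
#'   order chromosomes first appear.
#' @export
read_vcf_panels <- function(path, group_map = NULL, drop_sex_chromosomes = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 1L || !any(grepl("GT", v@gt[, 1L])))
    stop("VCF has no GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(gt)

  keep <- rep(TRUE, nrow(fix))
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT)
  n_multi <- sum(!is_snp, na.rm = TRUE) + sum(is.na(is_snp))
  keep <- keep & !is.na(is_snp) & is_snp
  no_pos <- is.na(fix$POS) | fix$POS == "."
  keep <- keep & !no_pos
  sex <- grepl("^(chr)?(X|Y|MT|M)$", fix$CHROM, ignore.case = TRUE)
  n_sex <- sum(sex & keep)
  if (drop_sex_chromosomes) keep <- keep & !sex
  if (n_multi > 0L || sum(no_pos) > 0L || n_sex > 0L)
    message(sprintf("read_vcf_panels: dropped %d multiallelic/non-SNP, %d without position, %d sex-chromosome records",
                    n_multi, sum(no_pos), n_sex))
  if (!any(keep)) stop("no biallelic SNP records left after filtering")

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  pos <- as.integer(fix$POS)

  # split genotype strings once; phase flag from the separators actually seen
  gt_chr <- as.vector(gt)
  phased_all <- !any(grepl("/", gt_chr, fixed = TRUE), na.rm = TRUE)
  a1 <- substr(gt_chr, 1L, 1L)
  a2 <- substr(gt_chr, 3L, 3L)
  to_code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "0"] <- 0L
    out[x == "1"] <- 1L
    out
  }
  M <- nrow(gt); N <- ncol(gt)
  A1 <- matrix(to_code(a1), nrow = M, ncol = N)
  A2 <- matrix(to_code(a2), nrow = M, ncol = N)

  groups <- group_lookup(sample_ids, group_map)

  chroms <- unique(fix$CHROM)
  panels <- lapply(chroms, function(ch) {
    sel <- which(fix$CHROM == ch)
    sel <- sel[order(pos[sel])]
    dup <- duplicated(pos[sel])
    if (any(dup)) {
      warning(sprintf("chromosome %s: %d duplicate-position markers dropped (first kept)",
                      ch, sum(dup)))
      sel <- sel[!dup]
    }
    # haplotype rows: sample k's alleles in rows 2k-1, 2k
    H <- matrix(NA_integer_, nrow = 2L * N, ncol = length(sel))
    H[seq(1L, 2L * N, by = 2L), ] <- t(A1[sel, , drop = FALSE])
    H[seq(2L, 2L * N, by = 2L), ] <- t(A2[sel, , drop = FALSE])
    ids <- fix$ID[sel]
    ids[is.na(ids) | ids == "."] <- paste0(ch, ":", pos[sel][is.na(ids) | ids == "."])
    mk <- data.frame(id = ids, chrom = ch, pos = pos[sel],
                     ref = fix$REF[sel], alt = fix$ALT[sel],
                     stringsAsFactors = FALSE)
    haplotype_panel(H, mk, sample_ids, groups, phased = phased_all)
  })
  names(panels) <- chroms
  panels
}

#' Read a sample-to-group assignment table
#'
#' @param path two-column TSV (`sample_id`, `group`), with or without a
#'   header row.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_group_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("group map needs two columns: sample_id, group")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  data.frame(sample_id = as.character(tab[[1]]),
             group = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}

group_lookup <- function(sample_ids, group_map) {
  if (is.null(group_map)) return(rep("UNASSIGNED", length(sample_ids)))
  stopifnot(all(c("sample_id", "group") %in% names(group_map)))
  missing_from_data <- setdiff(group_map$sample_id, sample_ids)
  if (length(missing_from_data))
    warning("group map samples absent from the data: ",
            paste(missing_from_data, collapse = ", "))
  idx <- match(sample_ids, group_map$sample_id)
  out <- group_map$group[idx]
  out[is.na(idx)] <- "UNASSIGNED"
  out
}

#' Read genotypes from PLINK text files (PED/MAP)
#'
#' PED carries no phase information, so the returned panels have
#' `phased = FALSE`. Allele letters are mapped to 0/1 by declaring the
#' first-observed allele at each marker as the reference, unless an explicit
#' `allele_ref` table fixes the orientation (mandatory when signed r is to be
#' compared across files).
#'
#' @param ped_path path to the PED file (6 leading columns, then two allele
#'   columns per marker; `0` denotes a missing allele).
#' @param map_path path to the MAP file (chrom, id, cM, pos).
#' @param group_map optional sample-to-group table (see [read_group_map()]).
#' @param allele_ref optional data.frame with columns `id`, `ref`, `alt`
#'   fixing the allele orientation per marker; alleles observed in the data
#'   but absent from the table raise an error naming the marker.
#' @inheritParams read_vcf_panels
#' @return named list of [haplotype_panel()], one per chromosome.
#' @export
read_plink_panels <- function(ped_path, map_path, group_map = NULL,
                              allele_ref = NULL, drop_sex_chromosomes = TRUE) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("MAP file needs 4 columns: chrom, id, cM, pos")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  M <- nrow(map)
  if (ncol(ped) != 6L + 2L * M)
    stop(sprintf("PED/MAP mismatch: PED has %d genotype columns, MAP lists %d markers",
                 ncol(ped) - 6L, M))
  sample_ids <- ped[[2]]
  N <- nrow(ped)
  allele <- as.matrix(ped[, -(1:6), drop = FALSE])
  allele[allele == "0"] <- NA_character_

  H <- matrix(NA_integer_, nrow = 2L * N, ncol = M)
  ref <- alt <- character(M)
  for (m in seq_len(M)) {
    a1 <- allele[, 2L * m - 1L]
    a2 <- allele[, 2L * m]
    # "0 x" half-missing genotypes are treated as fully missing
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- a2[half] <- NA_character_
    obs <- c(rbind(a1, a2))
    seen <- unique(obs[!is.na(obs)])
    if (!is.null(allele_ref)) {
      row <- match(map$id[m], allele_ref$id)
      if (is.na(row)) stop("allele_ref has no entry for marker ", map$id[m])
      r <- allele_ref$ref[row]; a <- allele_ref$alt[row]
      bad <- setdiff(seen, c(r, a))
      if (length(bad))
        stop(sprintf("marker %s: allele(s) %s not in allele_ref (%s/%s)",
                     map$id[m], paste(bad, collapse = ","), r, a))
    } else {
      if (length(seen) > 2L)
        stop("marker ", map$id[m], " has more than two alleles")
      r <- if (length(seen) >= 1L) seen[1] else "A"
      a <- if (length(seen) == 2L) seen[2] else setdiff(c("A", "C"), r)[1]
    }
    ref[m] <- r; alt[m] <- a
    code <- function(x) ifelse(is.na(x), NA_integer_,
                               ifelse(x == a, 1L, ifelse(x == r, 0L, NA_integer_)))
    H[seq(1L, 2L * N, by = 2L), m] <- code(a1)
    H[seq(2L, 2L * N, by = 2L), m] <- code(a2)
  }

  groups <- group_lookup(sample_ids, group_map)
  map$chrom <- as.character(map$chrom)
  keep_chrom <- unique(map$chrom)
  if (drop_sex_chromosomes)
    keep_chrom <- keep_chrom[!grepl("^(chr)?(X|Y|MT|M)$", keep_chrom,
                                    ignore.case = TRUE)]
  panels <- lapply(keep_chrom, function(ch) {
    sel <- which(map$chrom == ch & !is.na(map$pos) & map$pos > 0)
    sel <- sel[order(map$pos[sel])]
    dup <- duplicated(map$pos[sel])
    if (any(dup)) {
      warning(sprintf("chromosome %s: %d duplicate-position markers dropped (first kept)",
                      ch, sum(dup)))
      sel <- sel[!dup]
    }
    mk <- data.frame(id = map$id[sel], chrom = ch, pos = as.integer(map$pos[sel]),
                     ref = ref[sel], alt = alt[sel], stringsAsFactors = FALSE)
    haplotype_panel(H[, sel, drop = FALSE], mk, sample_ids, groups, phased = FALSE)
  })
  names(panels) <- keep_chrom
  panels
}

#' Write haplotype blocks as a BED file
#'
#' Internal positions are 1-based (VCF convention); BED output is 0-based
#' half-open, so a block whose first SNP sits at position `s` and last SNP at
#' position `e` becomes the interval `[s - 1, e)`.
#'
#' @param blocks data.frame of blocks as returned by [select_blocks()] /
#'   [find_blocks()] (columns `chrom`, `start_pos`, `end_pos`, `n_snps`),
#'   sorted by chromosome then start.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tblock_id\tn_snps", con)
  if (!is.null(blocks) && nrow(blocks)) {
    lines <- sprintf("%s\t%d\t%d\tblock_%d\t%d",
                     blocks$chrom,
                     as.integer(blocks$start_pos) - 1L,
                     as.integer(blocks$end_pos),
                     seq_len(nrow(blocks)),
                     as.integer(blocks$n_snps))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write one or more panels to a phased VCF
#'
#' All panels must share the same samples (in the same order); panels on
#' different chromosomes are concatenated record-wise. Genotypes are written
#' with the `"|"` separator when the panels are phased, `"/"` otherwise,
#' so the file round-trips through [read_vcf_panels()].
#'
#' @param panels a [haplotype_panel()] or list of panels.
#' @param path output VCF path.
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panels, path) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  sids <- panels[[1]]$sample_ids
  for (p in panels)
    if (!identical(p$sample_ids, sids))
      stop("all panels must share the same samples")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ldphase",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sids), collapse = "\t")), con)
  for (p in panels) {
    H <- p$haplotypes
    sep <- if (p$phased) "|" else "/"
    n <- length(sids)
    a1 <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    a2 <- H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), sep,
                        ifelse(is.na(a2), ".", a2)),
                 nrow = n)
    body <- apply(gt, 2L, paste, collapse = "\t")
    lines <- paste(p$markers$chrom, p$markers$pos, p$markers$id,
                   p$markers$ref, p$markers$alt, ".", "PASS", ".", "GT",
                   body, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
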