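#' Pipeline run configuration
#'
#' Aggregates every stage's parameters. Input can be a phased VCF plus a
#' group map, or a [sim_config()] for a fully synthetic run; exactly one of
#' the two must be supplied.
#'
#' @param vcf path to a phased VCF (or `NULL` when simulating).
#' @param group_map path to the sample-to-group TSV (or `NULL`).
#' @param sim a [sim_config()] for synthetic input (or `NULL`).
#' @param out_dir output directory for the result tables.
#' @param thresholds a [qc_thresholds()].
#' @param bins a [distance_bins()] scheme.
#' @param gabriel a [gabriel_params()].
#' @param groups optional character vector of two group labels to compare;
#'   defaults to the two most frequent labels present.
#' @param joint_label label of the pooled group (default `"CAN"`-style
#'   concatenation of the two group labels when they are the simulator
#'   defaults, else `"JOINT"`).
#' @param run_blocks partition the pooled panel into haplotype blocks
#'   (default `TRUE`).
#' @param emit_pairs also write the full pairwise LD dumps (large; default
#'   `FALSE`).
#' @param seed RNG seed recorded in the manifest and used for simulation.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, group_map = NULL, sim = NULL,
                       out_dir = "ldphase_out",
                       thresholds = qc_thresholds(),
                       bins = distance_bins(),
                       gabriel = gabriel_params(),
                       groups = NULL,
                       joint_label = NULL,
                       run_blocks = TRUE,
                       emit_pairs = FALSE,
                       seed = 1L) {
  if (is.null(sim) && is.null(vcf))
    stop("supply either a VCF path or a sim_config")
  if (!is.null(sim) && !is.null(vcf))
    stop("supply a VCF path or a sim_config, not both")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- seed
  }
  structure(list(vcf = vcf, group_map = group_map, sim = sim,
                 out_dir = out_dir, thresholds = thresholds, bins = bins,
                 gabriel = gabriel, groups = groups,
                 joint_label = joint_label, run_blocks = run_blocks,
                 emit_pairs = emit_pairs, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full LD pipeline
#'
#' Stages: load or simulate phased panels; per-group and pooled quality
#' control; pairwise LD within the distance cap; distance-binned decay
#' profiles per group and pooled; persistence of LD phase between the two
#' groups; Gabriel haplotype blocks on the pooled panel. Writes the
#' decay/persistence table (`table_decay_pl.tsv`), the per-chromosome block
#' summary (`table_blocks.tsv`), the block BED, the QC reports and a JSON
#' run manifest (configuration, package version, input digests), and
#' returns everything invisibly as a list.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with elements `panels`, `qc`, `ld`, `decay`,
#'   `persistence`, `blocks`, `block_summary`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  stage <- "input"
  result <- tryCatch({

  if (!is.null(config$sim)) {
    panels_raw <- simulate_panels(config$sim)
  } else {
    gm <- if (!is.null(config$group_map)) read_group_map(config$group_map)
    by_chrom <- read_vcf_panels(config$vcf, gm)
    # regroup: per group, a list of single-chromosome panels
    panels_raw <- list()
    for (pn in by_chrom) {
      for (sp in split_panel_by_group(pn)) {
        g <- sp$groups[1]
        panels_raw[[g]] <- c(panels_raw[[g]], list(sp))
      }
    }
  }

  # normalise to: named list group -> list of single-chromosome panels
  as_panel_list <- function(x) if (inherits(x, "haplotype_panel")) list(x) else x
  panels_raw <- lapply(panels_raw, as_panel_list)
  grp_names <- config$groups
  if (is.null(grp_names)) {
    counts <- vapply(panels_raw, function(pl) length(pl[[1]]$sample_ids), integer(1))
    grp_names <- names(sort(counts, decreasing = TRUE))[seq_len(min(2L, length(counts)))]
  }
  if (length(grp_names) < 2L)
    stop("phase persistence needs two groups; found only: ",
         paste(names(panels_raw), collapse = ", "))
  missing_grp <- setdiff(grp_names, names(panels_raw))
  if (length(missing_grp))
    stop("group(s) not present in the input: ", paste(missing_grp, collapse = ", "))
  joint <- config$joint_label
  if (is.null(joint))
    joint <- if (identical(sort(grp_names), c("CA", "MA"))) "CAN" else "JOINT"

  stage <- "qc"
  qc_out <- list()
  panels <- list()
  for (g in grp_names) {
    pl <- panels_raw[[g]]
    done <- lapply(pl, apply_qc, thresholds = config$thresholds)
    panels[[g]] <- lapply(done, `[[`, "panel")
    qc_out[[g]] <- lapply(done, `[[`, "report")
  }
  # pooled group: merge samples chromosome-wise before QC
  pool <- lapply(seq_along(panels_raw[[grp_names[1]]]), function(k) {
    pa <- panels_raw[[grp_names[1]]][[k]]
    pb <- panels_raw[[grp_names[2]]][[k]]
    if (!identical(pa$markers, pb$markers))
      stop("groups disagree on the marker map; cannot pool")
    haplotype_panel(rbind(pa$haplotypes, pb$haplotypes), pa$markers,
                    c(pa$sample_ids, pb$sample_ids),
                    c(pa$groups, pb$groups),
                    pa$phased && pb$phased)
  })
  done <- lapply(pool, apply_qc, thresholds = config$thresholds)
  panels[[joint]] <- lapply(done, `[[`, "panel")
  qc_out[[joint]] <- lapply(done, `[[`, "report")

  for (g in names(qc_out)) {
    f <- file.path(config$out_dir, sprintf("qc_%s.tsv", g))
    write_qc_report(qc_out[[g]][[1]], f)   # first chromosome; others appended
    if (length(qc_out[[g]]) > 1L)
      for (k in seq_along(qc_out[[g]])[-1])
        utils::write.table(qc_out[[g]][[k]]$marker_stats,
                           paste0(f, ".markers.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE, append = TRUE)
    files <- c(files, f)
  }

  stage <- "ld"
  cap <- config$bins$cap_bp
  ld <- lapply(panels, function(pl) {
    tabs <- lapply(pl, ld_pair_table, max_distance = cap)
    out <- do.call(rbind, tabs)
    attr(out, "orientation") <- unlist(lapply(tabs, attr, "orientation"),
                                       use.names = FALSE)
    out
  })

  stage <- "decay"
  decay <- lapply(names(ld), function(g)
    build_decay_profile(ld[[g]], config$bins, scope = g))
  names(decay) <- names(ld)

  stage <- "persistence"
  matched <- shared_pairs(ld[[grp_names[1]]], ld[[grp_names[2]]])
  persistence <- persistence_profile(matched, config$bins)

  tab1 <- data.frame(distance_kb = config$bins$labels, check.names = FALSE)
  for (g in c(grp_names, joint)) {
    d <- decay[[g]]
    tab1[[paste0(g, "_pairs")]] <- d$n_pairs
    tab1[[paste0(g, "_mean_r2")]] <- d$mean_r2
    tab1[[paste0(g, "_sd_r2")]] <- d$sd_r2
    tab1[[paste0(g, "_median_r2")]] <- d$median_r2
  }
  tab1$PL <- persistence$pl
  f1 <- file.path(config$out_dir, "table_decay_pl.tsv")
  write_tsv_stable(tab1, f1)
  files <- c(files, f1)

  if (config$emit_pairs)
    for (g in names(ld)) {
      f <- file.path(config$out_dir, sprintf("pairs_%s.tsv", g))
      write_ld_table(ld[[g]], f)
      files <- c(files, f)
    }

  blocks <- NULL
  block_summary <- NULL
  if (isTRUE(config$run_blocks)) {
    stage <- "blocks"
    blocks_l <- lapply(panels[[joint]], find_blocks, params = config$gabriel)
    blocks <- do.call(rbind, blocks_l)
    block_summary <- do.call(rbind, Map(summarize_blocks, blocks_l, panels[[joint]]))
    fb <- file.path(config$out_dir, "blocks.bed")
    write_blocks_bed(blocks, fb)
    f2 <- file.path(config$out_dir, "table_blocks.tsv")
    write_tsv_stable(block_summary, f2)
    files <- c(files, fb, f2)
  }

  stage <- "manifest"
  manifest <- list(
    package = "ldphase",
    version = as.character(utils::packageVersion("ldphase")),
    seed = config$seed,
    groups = grp_names,
    joint_label = joint,
    thresholds = unclass(config$thresholds),
    bins_kb = config$bins$edges_kb,
    gabriel = unclass(config$gabriel),
    sim = if (!is.null(config$sim)) unclass(config$sim)[
      !vapply(unclass(config$sim), is.null, logical(1))],
    inputs = if (!is.null(config$vcf)) {
      h <- tools::md5sum(c(config$vcf, config$group_map))
      as.list(stats::setNames(h, basename(names(h))))
    },
    outputs = {
      h <- tools::md5sum(files)
      as.list(stats::setNames(h, basename(names(h))))
    })
  fm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, fm)

  list(panels = panels, qc = qc_out, ld = ld, decay = decay,
       persistence = persistence, blocks = blocks,
       block_summary = block_summary, files = files)

  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  invisible(result)
}

# deterministic TSV writer: fixed number formatting, no quoting
write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (k in which(num))
    df[[k]] <- ifelse(is.na(df[[k]]), "",
                      formatC(df[[k]], format = "g", digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
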