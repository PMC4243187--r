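#' Configuration of the two-group admixture simulator
#'
#' The simulator emulates the history the analysis assumes: a neutral
#' founder population at drift-recombination equilibrium splits into two
#' diverged founder breeds; a composite population is then formed by
#' sampling founder chromosomes in fixed proportions (default 5/8 : 3/8),
#' bred inter se for a few generations, and finally split into two genetic
#' groups that drift independently before sampling. All variation is
#' standing founder polymorphism assigned by the infinite-sites rule on a
#' random coalescent genealogy of the starting haplotypes — no recurrent
#' mutation — so every marker is biallelic by construction and the
#' zero-recombination limit keeps all pairs free of the fourth gametic
#' type.
#'
#' @param seed integer; fully determines the output.
#' @param n_markers markers to emit after ascertainment (default 2000).
#' @param chromosome_length chromosome length in bp (default 5e6).
#' @param Ne_founder diploid effective size of every simulated population
#'   (default 100).
#' @param burn_in_gens generations of Wright-Fisher burn-in before the
#'   founder split (default `4 * Ne_founder`).
#' @param founder_divergence_gens generations the two founder breeds drift
#'   apart (default 80).
#' @param admixture_props founder proportions of the composite,
#'   summing to 1 (default `c(0.625, 0.375)`).
#' @param post_admixture_gens generations the composite breeds inter se
#'   (default 12).
#' @param group_split_gens generations of independent drift between the two
#'   output groups (default 8).
#' @param n_samples_per_group diploid samples drawn per group
#'   (default `c(100, 100)`; at most `Ne_founder` each).
#' @param recomb_rate per-bp per-generation crossover rate (default 1e-7).
#' @param hotspots optional data.frame with columns `position`,
#'   `multiplier`: windows of width `hotspot_width` centred at `position`
#'   whose rate is multiplied.
#' @param hotspot_width hotspot window width in bp (default 25000).
#' @param oversample markers simulated per marker emitted (default 20).
#'   With standing founder variation only, drift fixes a large share of
#'   markers before emission; oversampling keeps `n_markers` ascertainable.
#' @param init_freq_range derived-allele frequency window of the founder
#'   polymorphism (default `c(0.05, 0.95)`): mutations are placed only on
#'   genealogy branches subtending that fraction of haplotypes, emulating a
#'   common-SNP genotyping array and keeping survival to emission high.
#' @param group_names labels of the two output groups
#'   (default `c("CA", "MA")`).
#' @param chrom chromosome label (default `"1"`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_markers = 2000L, chromosome_length = 5e6,
                       Ne_founder = 100L,
                       burn_in_gens = 4L * Ne_founder,
                       founder_divergence_gens = 80L,
                       admixture_props = c(0.625, 0.375),
                       post_admixture_gens = 12L,
                       group_split_gens = 8L,
                       n_samples_per_group = c(100L, 100L),
                       recomb_rate = 1e-7,
                       hotspots = NULL,
                       hotspot_width = 25000,
                       oversample = 20,
                       init_freq_range = c(0.05, 0.95),
                       group_names = c("CA", "MA"),
                       chrom = "1") {
  stopifnot(abs(sum(admixture_props) - 1) < 1e-12,
            length(admixture_props) == 2L,
            n_markers > 0, chromosome_length > 0, Ne_founder > 1,
            burn_in_gens >= 0, founder_divergence_gens >= 0,
            post_admixture_gens >= 0, group_split_gens >= 0,
            length(n_samples_per_group) == 2L,
            all(n_samples_per_group >= 1L),
            all(n_samples_per_group <= Ne_founder),
            recomb_rate >= 0, oversample >= 1,
            length(init_freq_range) == 2L, init_freq_range[1] > 0,
            init_freq_range[2] < 1, init_freq_range[1] < init_freq_range[2],
            length(group_names) == 2L)
  structure(as.list(environment()), class = "sim_config")
}

# piecewise-constant recombination map; total = expected crossovers/meiosis
build_recomb_map <- function(config) {
  L <- config$chromosome_length
  breaks <- c(0, L)
  mult <- c(1)
  hs <- config$hotspots
  if (!is.null(hs) && nrow(hs)) {
    for (k in seq_len(nrow(hs))) {
      lo <- max(0, hs$position[k] - config$hotspot_width / 2)
      hi <- min(L, hs$position[k] + config$hotspot_width / 2)
      breaks <- c(breaks, lo, hi)
    }
    breaks <- sort(unique(breaks))
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    mult <- rep(1, length(mids))
    for (k in seq_len(nrow(hs))) {
      lo <- max(0, hs$position[k] - config$hotspot_width / 2)
      hi <- min(L, hs$position[k] + config$hotspot_width / 2)
      mult[mids > lo & mids < hi] <- hs$multiplier[k]
    }
  }
  rates <- config$recomb_rate * mult
  seglen <- diff(breaks)
  cum <- c(0, cumsum(rates * seglen))
  list(breaks = breaks, rates = rates, cum = cum,
       total = cum[length(cum)])
}

# sample k crossover positions from the map intensity
map_sample <- function(map, k) {
  u <- stats::runif(k, 0, map$total)
  stats::approx(map$cum, map$breaks, xout = u, ties = "ordered")$y
}

# infinite-sites initial haplotypes: each marker's derived allele is a clade
# of a random coalescent genealogy, drawn with probability proportional to
# branch length among branches whose clade size lies in freq_range
# (common-SNP ascertainment). Tree consistency guarantees at most three
# gametic types per pair at initialisation.
init_tree_haplotypes <- function(n_hap, m, freq_range = c(0.05, 0.95)) {
  tr <- ape::rcoal(n_hap)
  tr <- stats::reorder(tr, "postorder")
  desc <- vector("list", n_hap + tr$Nnode)
  for (i in seq_len(n_hap)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1L]]] <- c(desc[[tr$edge[e, 1L]]], desc[[tr$edge[e, 2L]]])
  csize <- vapply(tr$edge[, 2L], function(nd) length(desc[[nd]]), integer(1))
  wt <- tr$edge.length
  wt[csize < freq_range[1] * n_hap | csize > freq_range[2] * n_hap] <- 0
  if (!any(wt > 0)) wt <- tr$edge.length   # degenerate tiny trees: no filter
  pick <- sample.int(nrow(tr$edge), m, replace = TRUE, prob = wt)
  H <- matrix(0L, n_hap, m)
  for (k in seq_len(m)) H[desc[[tr$edge[pick[k], 2L]]], k] <- 1L
  H
}

# one discrete Wright-Fisher generation with recombination; non-recombinant
# gametes are bulk-copied by row indexing, crossovers applied per gamete
wf_generation <- function(H, pos, map) {
  n_hap <- nrow(H)
  n_ind <- n_hap %/% 2L
  par <- sample.int(n_ind, n_hap, replace = TRUE)
  nx <- if (map$total > 0) stats::rpois(n_hap, map$total) else integer(n_hap)
  swap <- stats::runif(n_hap) < 0.5
  r1 <- 2L * par - 1L + swap
  out <- H[r1, , drop = FALSE]
  for (g in which(nx > 0L)) {
    r2 <- 2L * par[g] - swap[g]
    x <- sort(map_sample(map, nx[g]))
    odd <- findInterval(pos, x) %% 2L == 1L
    out[g, odd] <- H[r2, odd]
  }
  out
}

wf_evolve <- function(H, pos, gens, map) {
  for (g in seq_len(gens)) H <- wf_generation(H, pos, map)
  H
}

# marker positions: uniform over the chromosome, deduplicated, sorted
draw_positions <- function(config) {
  m <- ceiling(config$oversample * config$n_markers)
  pos <- sort(unique(round(stats::runif(m, 1, config$chromosome_length))))
  while (length(pos) < m) {
    extra <- round(stats::runif(m - length(pos), 1, config$chromosome_length))
    pos <- sort(unique(c(pos, extra)))
  }
  as.integer(pos)
}

as_sim_panel <- function(H, pos, keep, config, sample_idx, group) {
  rows <- as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
  mk <- data.frame(id = sprintf("snp%06d", seq_along(pos)[keep]),
                   chrom = config$chrom, pos = pos[keep],
                   ref = "A", alt = "C", stringsAsFactors = FALSE)
  haplotype_panel(H[rows, keep, drop = FALSE], mk,
                  sample_ids = sprintf("%s_%03d", group, seq_along(sample_idx)),
                  groups = rep(group, length(sample_idx)),
                  phased = TRUE)
}

# drop markers fixed over the pooled rows, then subsample to n_markers
ascertain_markers <- function(Hpool, n_markers) {
  p <- colMeans(Hpool)
  poly <- which(p > 0 & p < 1)
  if (length(poly) < n_markers)
    stop(sprintf(paste("only %d of the requested %d markers remain polymorphic;",
                       "increase Ne_founder, oversample, or shorten the drift phases"),
                 length(poly), n_markers))
  sort(sample(poly, n_markers))
}

#' Simulate a single equilibrium population
#'
#' Runs the coalescent-initialised Wright-Fisher burn-in only and samples
#' one panel — a neutral population with known effective size and
#' recombination rate, the configuration under which observed LD decay can
#' be compared against Sved's expectation `E[r2] = 1 / (1 + 4 Ne c)`.
#'
#' @param config a [sim_config()]; uses `n_samples_per_group[1]` samples.
#' @return a phased [haplotype_panel()] with group label `"POP"`.
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- build_recomb_map(config)
  pos <- draw_positions(config)
  H <- init_tree_haplotypes(2L * config$Ne_founder, length(pos), config$init_freq_range)
  H <- wf_evolve(H, pos, config$burn_in_gens, map)
  idx <- sort(sample.int(config$Ne_founder, config$n_samples_per_group[1]))
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  keep <- ascertain_markers(H[rows, , drop = FALSE], config$n_markers)
  as_sim_panel(H, pos, keep, config, idx, "POP")
}

#' Simulate two diverged founder populations
#'
#' Burn-in to approximate drift-recombination equilibrium, then split into
#' two populations of size `Ne_founder` that drift apart for
#' `founder_divergence_gens` generations (the stand-ins for the two founder
#' breeds of a composite). Markers fixed in the pooled pair are dropped;
#' both panels share the surviving marker map.
#'
#' Sets the RNG from `config$seed`; [admix_and_split()] continues the
#' stream, so `simulate_founders |> admix_and_split` is reproducible
#' end-to-end.
#'
#' @param config a [sim_config()].
#' @return list with elements `A`, `B` (full-population
#'   [haplotype_panel()]s) and `raw` (internal state consumed by
#'   [admix_and_split()]).
#' @export
simulate_founders <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- build_recomb_map(config)
  pos <- draw_positions(config)
  H <- init_tree_haplotypes(2L * config$Ne_founder, length(pos), config$init_freq_range)
  H <- wf_evolve(H, pos, config$burn_in_gens, map)
  HA <- wf_evolve(H, pos, config$founder_divergence_gens, map)
  HB <- wf_evolve(H, pos, config$founder_divergence_gens, map)
  pbar <- colMeans(rbind(HA, HB))
  keep <- which(pbar > 0 & pbar < 1)
  if (!length(keep))
    stop("all markers fixed across the founder pair; increase Ne_founder or shorten founder_divergence_gens")
  all_idx <- seq_len(config$Ne_founder)
  list(A = as_sim_panel(HA, pos, keep, config, all_idx, "FOUNDER_A"),
       B = as_sim_panel(HB, pos, keep, config, all_idx, "FOUNDER_B"),
       raw = list(HA = HA, HB = HB, pos = pos, map = map))
}

#' Form the composite population and split it into two groups
#'
#' The composite's starting haplotypes are drawn from the two founder
#' populations with the admixture proportions, bred inter se
#' (Wright-Fisher) for `post_admixture_gens` generations, copied into two
#' groups that drift independently for `group_split_gens` generations, and
#' sampled. Marker ascertainment: markers fixed across the union of both
#' sampled groups are dropped and the survivors subsampled to `n_markers`
#' exactly — emulating a genotyping array's common-SNP bias.
#'
#' Continues the RNG stream started by [simulate_founders()] (no reseed).
#'
#' @param founders result of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return named list of two phased [haplotype_panel()]s
#'   (names `config$group_names`) sharing one marker map.
#' @export
admix_and_split <- function(founders, config) {
  raw <- founders$raw
  pos <- raw$pos
  n_hap <- 2L * config$Ne_founder
  from_a <- stats::runif(n_hap) < config$admixture_props[1]
  src_a <- sample.int(nrow(raw$HA), n_hap, replace = TRUE)
  src_b <- sample.int(nrow(raw$HB), n_hap, replace = TRUE)
  H <- raw$HA[src_a, , drop = FALSE]
  H[!from_a, ] <- raw$HB[src_b[!from_a], , drop = FALSE]
  H <- wf_evolve(H, pos, config$post_admixture_gens, raw$map)
  HG1 <- wf_evolve(H, pos, config$group_split_gens, raw$map)
  HG2 <- wf_evolve(H, pos, config$group_split_gens, raw$map)
  idx1 <- sort(sample.int(config$Ne_founder, config$n_samples_per_group[1]))
  idx2 <- sort(sample.int(config$Ne_founder, config$n_samples_per_group[2]))
  rows1 <- as.vector(rbind(2L * idx1 - 1L, 2L * idx1))
  rows2 <- as.vector(rbind(2L * idx2 - 1L, 2L * idx2))
  keep <- ascertain_markers(rbind(HG1[rows1, , drop = FALSE],
                                  HG2[rows2, , drop = FALSE]),
                            config$n_markers)
  out <- list(as_sim_panel(HG1, pos, keep, config, idx1, config$group_names[1]),
              as_sim_panel(HG2, pos, keep, config, idx2, config$group_names[2]))
  names(out) <- config$group_names
  out
}

#' Simulate the default two-group composite panel pair
#'
#' Convenience wrapper: [simulate_founders()] then [admix_and_split()].
#'
#' @param config a [sim_config()].
#' @return named list of two phased [haplotype_panel()]s.
#' @export
simulate_panels <- function(config = sim_config()) {
  admix_and_split(simulate_founders(config), config)
}

#' Write simulated panels as a VCF fixture plus group map
#'
#' Merges the groups into one phased VCF (samples concatenated) and writes
#' the matching two-column group map, both readable by
#' [read_vcf_panels()] / [read_group_map()]; the files round-trip exactly.
#'
#' @param panels named list of [haplotype_panel()]s sharing a marker map
#'   (e.g. from [simulate_panels()]).
#' @param dir output directory (created if absent).
#' @return named character vector with paths `vcf` and `groups`.
#' @export
write_fixture <- function(panels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mk <- panels[[1]]$markers
  for (p in panels[-1])
    if (!identical(p$markers, mk)) stop("panels must share one marker map")
  H <- do.call(rbind, lapply(panels, `[[`, "haplotypes"))
  merged <- haplotype_panel(H, mk,
                            sample_ids = unlist(lapply(panels, `[[`, "sample_ids"),
                                                use.names = FALSE),
                            groups = unlist(lapply(panels, `[[`, "groups"),
                                            use.names = FALSE),
                            phased = all(vapply(panels, `[[`, logical(1), "phased")))
  vcf <- file.path(dir, "panel.vcf")
  grp <- file.path(dir, "groups.tsv")
  write_panel_vcf(merged, vcf)
  utils::write.table(data.frame(sample_id = merged$sample_ids,
                                group = merged$groups),
                     grp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  c(vcf = vcf, groups = grp)
}
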