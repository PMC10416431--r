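#' Configuration for the synthetic negative-control simulator
#'
#' Defines the study conditions the simulator emulates: panels of
#' CUT&RUN negative controls whose background is random MNase digestion
#' (uniform fragment placement) plus a set of shared high-signal artifact
#' regions, each enriched in a random subset of samples at a controllable
#' prevalence, plus sample-specific (cell-type-like) artifacts, PCR
#' duplicates, and realistic fragment lengths.
#'
#' Defaults: a compact 2 x 10 Mb genome plus a 16 kb mitochondrial
#' chromosome; 20 samples (the published panel size); background 2
#' fragments/kb; 25 artifact regions of mean 3 kb placed with >= 20 kb
#' separation, at 50-fold enrichment, cycling through prevalence classes
#' {1.0, 0.6, 0.4, 0.2, 0.05}; 2 sample-specific artifacts per sample;
#' fragment length 150 +- 30 bp; duplicate rate 0.10.
#'
#' @param seed integer seed; fixes all outputs exactly.
#' @param layout a [genome_layout].
#' @param n_samples panel size.
#' @param background_rate expected background fragments per kb.
#' @param n_artifacts number of shared artifact regions.
#' @param artifact_mean_size mean artifact region size in bp.
#' @param artifact_fold enrichment of artifact regions over background.
#' @param prevalence numeric vector in (0, 1], recycled across artifact
#'   regions: per-region probability that a sample is enriched.
#' @param n_sample_specific sample-specific artifact regions per sample.
#' @param fragment_mean,fragment_sd fragment length distribution (bp).
#' @param duplicate_rate expected fraction of emitted fragments that are
#'   PCR duplicates.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       layout = genome_layout(c("chr1", "chr2", "chrM"),
                                              c(1e7, 1e7, 16000)),
                       n_samples = 20,
                       background_rate = 2,
                       n_artifacts = 25,
                       artifact_mean_size = 3000,
                       artifact_fold = 50,
                       prevalence = c(1.0, 0.6, 0.4, 0.2, 0.05),
                       n_sample_specific = 2,
                       fragment_mean = 150,
                       fragment_sd = 30,
                       duplicate_rate = 0.10) {
  stopifnot(inherits(layout, "genome_layout"),
            n_samples >= 1, background_rate >= 0, n_artifacts >= 0,
            artifact_fold >= 0, all(prevalence > 0), all(prevalence <= 1),
            duplicate_rate >= 0, duplicate_rate < 1)
  if (sum(layout$length) < 1e5) stop("degenerate layout: genome too small")
  structure(list(seed = as.integer(seed), layout = layout,
                 n_samples = n_samples, background_rate = background_rate,
                 n_artifacts = n_artifacts,
                 artifact_mean_size = artifact_mean_size,
                 artifact_fold = artifact_fold, prevalence = prevalence,
                 n_sample_specific = n_sample_specific,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 duplicate_rate = duplicate_rate),
            class = "sim_config")
}

# Sub-seeding rule: stream s of base seed gets its own set.seed() value.
# Documented so panels are stable when n_samples changes: sample i always
# uses stream i, region placement stream 0, target-mode streams >= 9000.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 8191) %%
               2147483629) + 1L
}

#' Place random non-overlapping regions on a layout
#'
#' Regions are placed uniformly on the non-mitochondrial chromosomes with
#' a minimum separation, by rejection sampling; sizes are normal around
#' `mean_size` (sd = mean/4, floor 500 bp).
#'
#' @param layout a [genome_layout].
#' @param n number of regions.
#' @param mean_size mean region size (bp).
#' @param min_gap minimum separation between placed regions (bp).
#' @param avoid optional [GenomicRanges::GRanges] the new regions must
#'   also keep `min_gap` away from.
#' @param seed integer seed.
#' @param chrM mitochondrial chromosome name to exclude from placement.
#' @return A sorted [GenomicRanges::GRanges].
#' @export
place_random_regions <- function(layout, n, mean_size = 3000,
                                 min_gap = 20000, avoid = NULL, seed = 1,
                                 chrM = "chrM") {
  if (n == 0L) return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
  set.seed(seed)
  chroms <- setdiff(layout$chrom, chrM)
  lens <- layout$length[chroms]
  placed <- avoid
  out <- vector("list", n)
  for (i in seq_len(n)) {
    size <- max(500, round(stats::rnorm(1, mean_size, mean_size / 4)))
    for (try in seq_len(1000)) {
      chrom <- sample(chroms, 1, prob = lens / sum(lens))
      start1 <- sample.int(max(1, layout$length[chrom] - size), 1)
      cand <- GenomicRanges::GRanges(
        seqnames = factor(chrom, levels = layout$chrom),
        ranges = IRanges::IRanges(start1, width = size),
        seqinfo = as_seqinfo(layout))
      clear <- is.null(placed) || length(placed) == 0L ||
        !any(GenomicRanges::countOverlaps(
          cand, placed, maxgap = min_gap, ignore.strand = TRUE) > 0)
      if (clear) break
    }
    out[[i]] <- cand
    placed <- if (is.null(placed)) cand else c(placed, cand)
  }
  sort_layout(do.call(c, out))
}

# Fragments with midpoints uniform in [lo1, hi1] (1-based inclusive bounds
# of a region) on one chromosome; lengths normal, clamped to [20, 2000]
# and to the chromosome.
random_fragments <- function(n, chrom, lo1, hi1, chrom_len, cfg) {
  if (n == 0L) return(NULL)
  mid <- lo1 + floor(stats::runif(n) * (hi1 - lo1 + 1))
  len <- pmin(pmax(round(stats::rnorm(n, cfg$fragment_mean,
                                      cfg$fragment_sd)), 20), 2000)
  st <- pmax(1, mid - floor(len / 2))
  en <- pmin(chrom_len, st + len - 1)
  data.frame(chrom = chrom, start = st, end = en)
}

# One sample's fragments given its enriched regions; all randomness from
# the caller-set RNG stream. base_rate is the per-kb rate multiplied by
# artifact_fold inside enriched regions; it defaults to the background
# rate, falling back to 1 fragment/kb when background is switched off so
# that enriched regions still receive signal (fragments then appear only
# in enriched regions).
sample_fragments <- function(cfg, enriched,
                             base_rate = if (cfg$background_rate > 0)
                               cfg$background_rate else 1) {
  layout <- cfg$layout
  parts <- list()
  # background: Poisson count per chromosome, uniform placement
  for (chrom in layout$chrom) {
    len <- layout$length[chrom]
    n_bg <- stats::rpois(1, cfg$background_rate * len / 1000)
    parts[[length(parts) + 1L]] <-
      random_fragments(n_bg, chrom, 1, len, len, cfg)
  }
  # artifact enrichment: extra density = fold x background rate
  if (!is.null(enriched) && length(enriched)) {
    for (i in seq_along(enriched)) {
      chrom <- as.character(GenomicRanges::seqnames(enriched[i]))
      st <- GenomicRanges::start(enriched[i])
      en <- GenomicRanges::end(enriched[i])
      n_art <- stats::rpois(1, cfg$artifact_fold * base_rate *
                              (en - st + 1) / 1000)
      parts[[length(parts) + 1L]] <-
        random_fragments(n_art, chrom, st, en, layout$length[chrom], cfg)
    }
  }
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L) {
    return(list(fragments = GenomicRanges::GRanges(
      seqinfo = as_seqinfo(layout)), n_duplicates = 0L))
  }
  df <- do.call(rbind, parts)
  n_dup <- 0L
  if (cfg$duplicate_rate > 0 && nrow(df) > 0) {
    n_dup <- round(nrow(df) * cfg$duplicate_rate / (1 - cfg$duplicate_rate))
    if (n_dup > 0)
      df <- rbind(df, df[sample.int(nrow(df), n_dup, replace = TRUE), ])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = layout$chrom),
    ranges = IRanges::IRanges(df$start, df$end),
    seqinfo = as_seqinfo(layout))
  list(fragments = sort_layout(gr), n_duplicates = n_dup)
}

#' Simulate a panel of negative-control samples
#'
#' Generates `n_samples` fragment sets over the configured layout. Each
#' sample receives uniform background fragments (Poisson at
#' `background_rate` per kb); each shared artifact region is enriched in
#' the sample with probability equal to its prevalence (membership drawn
#' once per sample and recorded in the ground truth, so realized support
#' can differ from expectation); sample-specific artifact regions are
#' always enriched in their own sample; duplicates are appended at
#' `duplicate_rate`. Fully reproducible given the config seed.
#'
#' @param config a [sim_config()].
#' @return List with `samples` (named list of fragment
#'   [GenomicRanges::GRanges]) and `truth`: `artifacts` (GRanges with
#'   `prevalence` and `support` = realized number of enriched samples),
#'   `membership` (regions x samples logical matrix),
#'   `sample_specific` (per-sample GRanges), `n_duplicates` (per sample).
#' @export
simulate_negative_panel <- function(config) {
  cfg <- config
  layout <- cfg$layout
  artifacts <- place_random_regions(layout, cfg$n_artifacts,
                                    cfg$artifact_mean_size,
                                    seed = derive_seed(cfg$seed, 0))
  prevalence <- rep_len(cfg$prevalence, length(artifacts))
  S4Vectors::mcols(artifacts)$prevalence <- prevalence

  samples <- vector("list", cfg$n_samples)
  names(samples) <- sprintf("nc%02d", seq_len(cfg$n_samples))
  membership <- matrix(FALSE, nrow = length(artifacts), ncol = cfg$n_samples,
                       dimnames = list(NULL, names(samples)))
  sample_specific <- vector("list", cfg$n_samples)
  names(sample_specific) <- names(samples)
  n_dup <- integer(cfg$n_samples)

  for (i in seq_len(cfg$n_samples)) {
    set.seed(derive_seed(cfg$seed, i))
    member <- stats::runif(length(artifacts)) < prevalence
    membership[, i] <- member
    ss <- place_random_regions(layout, cfg$n_sample_specific,
                               cfg$artifact_mean_size,
                               avoid = artifacts,
                               seed = derive_seed(cfg$seed, 100000 + i))
    set.seed(derive_seed(cfg$seed, 200000 + i))
    enriched <- c(artifacts[member], ss)
    res <- sample_fragments(cfg, enriched)
    samples[[i]] <- res$fragments
    sample_specific[[i]] <- ss
    n_dup[i] <- res$n_duplicates
  }
  S4Vectors::mcols(artifacts)$support <- as.integer(rowSums(membership))
  list(samples = samples,
       truth = list(artifacts = artifacts, membership = membership,
                    sample_specific = sample_specific,
                    n_duplicates = stats::setNames(n_dup, names(samples))))
}

#' Simulate a target-versus-control experiment
#'
#' A target sample (optionally replicated) carries true binding sites at
#' `site_fold` enrichment plus the full set of shared artifact regions; a
#' matched negative control carries the artifacts only. Target and
#' control share the seed-derived artifact placement exactly, emulating
#' the evaluation of peak calling against a negative control with and
#' without suspect-list filtering.
#'
#' @param config a [sim_config()].
#' @param n_sites number of true binding sites (0 gives a pure-artifact
#'   target).
#' @param site_fold enrichment of binding sites over background.
#' @param n_replicates target replicates to generate.
#' @param sites optional pre-placed site [GenomicRanges::GRanges]
#'   (otherwise placed disjoint from the artifacts).
#' @param stream_offset offset added to the simulation streams, letting
#'   callers generate several independent targets over the same artifact
#'   placement.
#' @return List with `targets` (named list of fragment GRanges),
#'   `control` (fragment GRanges) and `truth` (`sites`, `artifacts`).
#' @export
simulate_target_experiment <- function(config, n_sites = 30, site_fold = 100,
                                       n_replicates = 1, sites = NULL,
                                       stream_offset = 0) {
  cfg <- config
  layout <- cfg$layout
  artifacts <- place_random_regions(layout, cfg$n_artifacts,
                                    cfg$artifact_mean_size,
                                    seed = derive_seed(cfg$seed, 0))
  if (is.null(sites)) {
    sites <- place_random_regions(layout, n_sites, 1000, avoid = artifacts,
                                  seed = derive_seed(cfg$seed,
                                                     9000 + stream_offset))
  }
  site_cfg <- cfg
  site_cfg$artifact_fold <- site_fold

  targets <- vector("list", n_replicates)
  names(targets) <- sprintf("target_rep%d", seq_len(n_replicates))
  for (j in seq_len(n_replicates)) {
    set.seed(derive_seed(cfg$seed, 9100 + stream_offset + j))
    art_part <- sample_fragments(cfg, artifacts)
    set.seed(derive_seed(cfg$seed, 9200 + stream_offset + j))
    # site fragments only (suppress the background of the second draw)
    site_only_cfg <- site_cfg
    site_only_cfg$background_rate <- 0
    site_part <- sample_fragments(site_only_cfg, sites,
                                  base_rate = if (cfg$background_rate > 0)
                                    cfg$background_rate else 1)
    targets[[j]] <- sort_layout(c(art_part$fragments, site_part$fragments))
  }
  set.seed(derive_seed(cfg$seed, 9999 + stream_offset))
  control <- sample_fragments(cfg, artifacts)$fragments
  list(targets = targets, control = control,
       truth = list(sites = sites, artifacts = artifacts))
}
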