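#' Remove exact-coordinate duplicate fragments
#'
#' Collapses fragments with identical chromosome, start and end to a
#' single copy, the stringent deduplication applied to negative controls
#' before artifact identification (so artifacts are identified regardless
#' of PCR duplication rates). The number of removed fragments is attached
#' as attribute `n_removed` and reported via message.
#'
#' @param frags fragment [GenomicRanges::GRanges].
#' @param quiet suppress the message.
#' @return Deduplicated [GenomicRanges::GRanges].
#' @export
dedup_fragments <- function(frags, quiet = TRUE) {
  dup <- duplicated(frags)
  out <- frags[!dup]
  if (!quiet) message("dedup_fragments: removed ", sum(dup), " of ",
                      length(frags), " fragments")
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Remove fragments overlapping suspect regions
#'
#' Drops every fragment sharing at least one basepair with any region of
#' the list (the `bedtools intersect -v` semantics used for suspect-list
#' filtering of alignments before peak calling); all other fragments are
#' untouched.
#'
#' @param frags fragment [GenomicRanges::GRanges].
#' @param sl a `suspect_list` (or a plain [GenomicRanges::GRanges] of
#'   regions).
#' @return The surviving fragments.
#' @seealso [subtract_peaks()] for peak-level removal after calling.
#' @export
filter_fragments <- function(frags, sl) {
  regions <- suspect_regions(sl)
  if (length(frags) == 0L || length(regions) == 0L) return(frags)
  IRanges::subsetByOverlaps(frags, regions, invert = TRUE,
                            ignore.strand = TRUE)
}

#' Remove called peaks overlapping suspect regions
#'
#' Retrospective filtering of a peak set: peaks sharing at least one
#' basepair with any suspect region are removed whole (no trimming).
#'
#' @param peaks peak [GenomicRanges::GRanges].
#' @param sl a `suspect_list` or region [GenomicRanges::GRanges].
#' @return The surviving peaks.
#' @export
subtract_peaks <- function(peaks, sl) {
  regions <- suspect_regions(sl)
  if (length(peaks) == 0L || length(regions) == 0L) return(peaks)
  IRanges::subsetByOverlaps(peaks, regions, invert = TRUE,
                            ignore.strand = TRUE)
}

suspect_regions <- function(sl) {
  if (inherits(sl, "suspect_list")) sl$regions else sl
}

#' Fraction of fragments in regions (FRIP)
#'
#' FRIP is the total number of fragments mapping to (overlapping by at
#' least one basepair) the given regions, divided by the total number of
#' mapped fragments. Used here to quantify how much of a dataset's signal
#' falls in suspect-list regions.
#'
#' @param frags fragment [GenomicRanges::GRanges] (non-empty).
#' @param sl a `suspect_list` or region [GenomicRanges::GRanges].
#' @return List with `frip`, `total_fragments`, `fragments_in_regions`.
#' @export
frip <- function(frags, sl) {
  if (length(frags) == 0L) stop("no mapped fragments")
  regions <- suspect_regions(sl)
  n_in <- if (length(regions) == 0L) 0L else
    sum(GenomicRanges::countOverlaps(frags, regions,
                                     ignore.strand = TRUE) > 0)
  list(frip = n_in / length(frags),
       total_fragments = length(frags),
       fragments_in_regions = as.integer(n_in))
}

#' Pairwise Spearman correlation of samples over genomic bins
#'
#' Correlates each pair of sample rows of a binned count matrix with
#' Spearman's rank correlation (ties get average ranks). A sample with
#' zero variance across bins has undefined correlations, reported as `NA`
#' (never coerced to 0) and flagged in attribute `undefined_samples`.
#'
#' @param bm a `binned_matrix` from [bin_counts()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(bm) {
  if (nrow(bm$counts) < 2L) stop("need >= 2 samples")
  cm <- suppressWarnings(stats::cor(t(bm$counts), method = "spearman"))
  diag(cm) <- 1
  flat <- apply(bm$counts, 1, function(r) stats::var(r) == 0)
  attr(cm, "undefined_samples") <- bm$sample_ids[flat]
  cm
}

#' Principal component analysis of samples over genomic bins
#'
#' PCA of the samples x bins count matrix after per-bin mean-centering
#' (samples are observations, no scaling), with the eigenvalue spectrum
#' and percent variance per component for scree analysis. Bins
#' overlapping an optional exclusion list are dropped before the
#' analysis, the mechanism used to ask how much leading-component
#' variance shared artifact regions absorb.
#'
#' @param bm a `binned_matrix`.
#' @param exclude optional `suspect_list` (or regions) whose overlapping
#'   bins are removed first.
#' @return Object of class `pca_scree`: `scores` (samples x components),
#'   `eigenvalues`, `percent_variance`, `n_bins_used`.
#' @export
pca_scree <- function(bm, exclude = NULL) {
  if (nrow(bm$counts) < 2L) stop("need >= 2 samples")
  counts <- bm$counts
  if (!is.null(exclude)) {
    drop <- GenomicRanges::countOverlaps(bm$bins, suspect_regions(exclude),
                                         ignore.strand = TRUE) > 0
    counts <- counts[, !drop, drop = FALSE]
  }
  if (ncol(counts) < 2L) stop("fewer than 2 bins after exclusion")
  pc <- stats::prcomp(counts, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 n_bins_used = ncol(counts)),
            class = "pca_scree")
}

#' @export
print.pca_scree <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("PCA over", x$n_bins_used, "bins,", nrow(x$scores), "samples\n")
  cat("  % variance:",
      paste(sprintf("PC%d=%.1f", seq_len(k), x$percent_variance[seq_len(k)]),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.pca_scree <- function(x, ...) {
  graphics::barplot(x$percent_variance, names.arg =
                      paste0("PC", seq_along(x$percent_variance)),
                    ylab = "% variance", main = "Scree plot", ...)
  invisible(x)
}

#' Inter- versus intra-target distance ratio
#'
#' Euclidean distances between sample rows of the binned matrix,
#' averaged over pairs with the same target label (intra) and pairs with
#' different labels (inter), plus their ratio. An increase of this ratio
#' after suspect-list filtering indicates that the removed regions were
#' inflating similarity between unrelated samples.
#'
#' @param bm a `binned_matrix`.
#' @param labels character vector of target labels, one per sample
#'   (>= 2 distinct labels).
#' @return List with `intra`, `inter`, `ratio` (inter / intra).
#' @export
distance_ratio <- function(bm, labels) {
  if (length(labels) != nrow(bm$counts))
    stop("labels must match sample count")
  if (length(unique(labels)) < 2L) stop("need >= 2 distinct labels")
  d <- as.matrix(stats::dist(bm$counts))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  intra_pairs <- d[ut & same]
  inter_pairs <- d[ut & !same]
  if (length(intra_pairs) == 0L)
    stop("no intra-target pairs (every label has a single sample)")
  intra <- mean(intra_pairs)
  inter <- mean(inter_pairs)
  if (intra == 0) stop("intra-target distance is zero; ratio undefined")
  list(intra = intra, inter = inter, ratio = inter / intra)
}

#' Fraction of the genome covered by a suspect list
#'
#' @param sl a `suspect_list` or region [GenomicRanges::GRanges].
#' @param layout a [genome_layout].
#' @return Total region basepairs divided by total genome basepairs.
#' @export
genome_fraction <- function(sl, layout) {
  regions <- suspect_regions(sl)
  if (length(regions) == 0L) return(0)
  sum(GenomicRanges::width(merge_intervals(regions))) / sum(layout$length)
}

#' Compare two region lists
#'
#' Region-level counts (a region is shared when it overlaps any region of
#' the other list by >= 1 bp) plus basepair-level intersection totals and
#' per-list genome fractions.
#'
#' @param a,b `suspect_list`s or region [GenomicRanges::GRanges] on the
#'   same layout.
#' @param layout a [genome_layout].
#' @return Object of class `list_comparison`.
#' @export
compare_lists <- function(a, b, layout) {
  ra <- suspect_regions(a); rb <- suspect_regions(b)
  shared_a <- sum(GenomicRanges::countOverlaps(ra, rb,
                                               ignore.strand = TRUE) > 0)
  shared_b <- sum(GenomicRanges::countOverlaps(rb, ra,
                                               ignore.strand = TRUE) > 0)
  inter_bp <- sum(GenomicRanges::width(
    GenomicRanges::intersect(merge_intervals(ra), merge_intervals(rb),
                             ignore.strand = TRUE)))
  structure(list(
    n_a = length(ra), n_b = length(rb),
    unique_a = length(ra) - shared_a, unique_b = length(rb) - shared_b,
    shared_a = shared_a, shared_b = shared_b,
    bp_a = sum(GenomicRanges::width(ra)), bp_b = sum(GenomicRanges::width(rb)),
    bp_shared = inter_bp,
    fraction_a = genome_fraction(ra, layout),
    fraction_b = genome_fraction(rb, layout)
  ), class = "list_comparison")
}

#' @export
print.list_comparison <- function(x, ...) {
  cat("list comparison\n")
  cat(sprintf("  A: %d regions (%s bp, %.4f%% of genome), %d shared, %d unique\n",
              x$n_a, format(x$bp_a, big.mark = ","), 100 * x$fraction_a,
              x$shared_a, x$unique_a))
  cat(sprintf("  B: %d regions (%s bp, %.4f%% of genome), %d shared, %d unique\n",
              x$n_b, format(x$bp_b, big.mark = ","), 100 * x$fraction_b,
              x$shared_b, x$unique_b))
  cat(sprintf("  shared basepairs: %s\n", format(x$bp_shared, big.mark = ",")))
  invisible(x)
}

#' Average signal profile over a set of regions
#'
#' Each region, grown by `flank` basepairs on both sides, is rescaled to
#' `nbins` equal positions and the coverage averaged across regions per
#' position (a numeric meta-profile). Regions whose flanked window would
#' exceed the chromosome are truncated and flagged in attribute
#' `truncated`.
#'
#' @param track a per-chromosome [IRanges::RleList].
#' @param regions non-empty [GenomicRanges::GRanges].
#' @param layout a [genome_layout].
#' @param flank basepairs added on each side before rescaling.
#' @param nbins number of profile positions.
#' @return Numeric vector of length `nbins` of mean signal.
#' @export
average_profile <- function(track, regions, layout, flank = 0, nbins = 100) {
  if (length(regions) == 0L) stop("regions must be non-empty")
  prof <- matrix(NA_real_, nrow = length(regions), ncol = nbins)
  truncated <- logical(length(regions))
  for (i in seq_along(regions)) {
    chrom <- as.character(GenomicRanges::seqnames(regions[i]))
    len <- layout$length[chrom]
    st <- GenomicRanges::start(regions[i]) - flank
    en <- GenomicRanges::end(regions[i]) + flank
    if (st < 1 || en > len) {
      truncated[i] <- TRUE
      st <- max(st, 1); en <- min(en, len)
    }
    v <- as.numeric(S4Vectors::window(track[[chrom]], start = st, end = en))
    idx <- ceiling(seq_along(v) / length(v) * nbins)
    prof[i, ] <- vapply(seq_len(nbins), function(b) mean(v[idx == b]), 0)
  }
  out <- colMeans(prof)
  attr(out, "truncated") <- which(truncated)
  out
}

#' Flag suspect regions of low mappability
#'
#' Given a mappability track (values in [0, 1]), flags each region whose
#' mean mappability falls below `cutoff` (default 0.5).
#'
#' @param sl a `suspect_list`.
#' @param mappability per-chromosome [IRanges::RleList] of mappability.
#' @param cutoff mean-mappability threshold below which a region is
#'   flagged.
#' @return The `suspect_list` with logical region column `low_mappability`
#'   and numeric column `mean_mappability`.
#' @export
flag_low_mappability <- function(sl, mappability, cutoff = 0.5) {
  regions <- sl$regions
  mm <- vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions[i]))
    r <- mappability[[chrom]]
    if (is.null(r)) return(NA_real_)
    mean(as.numeric(S4Vectors::window(r, start = GenomicRanges::start(regions[i]),
                                      end = GenomicRanges::end(regions[i]))))
  }, 0)
  S4Vectors::mcols(regions)$mean_mappability <- mm
  S4Vectors::mcols(regions)$low_mappability <- !is.na(mm) & mm < cutoff
  sl$regions <- regions
  sl
}
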