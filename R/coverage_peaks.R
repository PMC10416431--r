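#' Pile fragments into a per-basepair coverage track
#'
#' The value at basepair p is the number of fragments whose interval
#' contains p (the pileup that `bedtools genomecov` with paired-end
#' settings computes from a fragment BAM).
#'
#' @param frags fragment [GenomicRanges::GRanges].
#' @param layout a [genome_layout].
#' @return A per-chromosome [IRanges::RleList] in layout order.
#' @export
fragments_to_coverage <- function(frags, layout) {
  si <- as_seqinfo(layout)
  if (length(frags) == 0L) return(empty_track(layout))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomicRanges::seqnames(frags)),
                      levels = layout$chrom),
    ranges = IRanges::ranges(frags), seqinfo = si)
  validate_gr(gr, layout, "fragment")
  GenomicRanges::coverage(gr)[layout$chrom]
}

#' Find contiguous signal blocks in a coverage track
#'
#' A signal block is a maximal run of strictly positive coverage (flanked
#' by zero coverage or a chromosome edge), the unit on which SEACR-style
#' peak calling operates. Each block carries its AUC (sum of the coverage
#' value over its basepairs) and its maximum height.
#'
#' @param track a per-chromosome [IRanges::RleList].
#' @param layout a [genome_layout].
#' @return A sorted [GenomicRanges::GRanges] with metadata columns `auc`
#'   and `max_height`.
#' @export
find_signal_blocks <- function(track, layout) {
  out <- vector("list", length(layout$chrom))
  for (i in seq_along(layout$chrom)) {
    chrom <- layout$chrom[i]
    r <- track[[chrom]]
    if (is.null(r)) next
    v <- IRanges::slice(r, lower = 0, includeLower = FALSE)
    if (length(v) == 0L) next
    out[[i]] <- GenomicRanges::GRanges(
      seqnames = factor(chrom, levels = layout$chrom),
      ranges = IRanges::IRanges(start = IRanges::start(v),
                                end = IRanges::end(v)),
      auc = as.numeric(IRanges::viewSums(v)),
      max_height = as.numeric(IRanges::viewMaxs(v)),
      seqinfo = as_seqinfo(layout))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    g <- GenomicRanges::GRanges(seqinfo = as_seqinfo(layout))
    S4Vectors::mcols(g)$auc <- numeric(0)
    S4Vectors::mcols(g)$max_height <- numeric(0)
    return(g)
  }
  sort_layout(do.call(c, out))
}

# rank-based cutoff shared by both peak callers: value of the n-th largest
# element (ties at the cutoff are kept by the >= comparison at call sites)
rank_cutoff <- function(x, n) {
  sort(x, decreasing = TRUE)[min(n, length(x))]
}

#' Call peaks by numeric top-fraction threshold
#'
#' SEACR-style numeric-threshold calling: with threshold `t`, the top
#' `ceiling(t * B)` signal blocks ranked by AUC are retained (B = number of
#' blocks), keeping every block tied with the cutoff AUC. In `stringent`
#' mode a block must additionally reach the same-rank cutoff of the
#' max-height distribution; `relaxed` mode applies the AUC rule only. The
#' published suspect lists use `threshold = 0.001` in stringent mode to
#' keep the highest 0.1% of signals.
#'
#' @param blocks signal blocks from [find_signal_blocks()].
#' @param threshold numeric fraction in (0, 1).
#' @param mode `"stringent"` or `"relaxed"`.
#' @return A coordinate-sorted [GenomicRanges::GRanges] of peaks with
#'   `auc` and `max_height` columns.
#' @export
call_peaks_numeric <- function(blocks, threshold = 0.001,
                               mode = c("stringent", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  B <- length(blocks)
  if (B == 0L) {
    warning("no signal blocks; returning empty peak set")
    return(blocks)
  }
  n <- ceiling(threshold * B)
  auc <- S4Vectors::mcols(blocks)$auc
  keep <- auc >= rank_cutoff(auc, n)
  if (mode == "stringent") {
    mh <- S4Vectors::mcols(blocks)$max_height
    keep <- keep & (mh >= rank_cutoff(mh, n))
  }
  sort_layout(blocks[keep])
}

#' Call peaks against a negative-control sample
#'
#' Control-calibrated calling: the AUC cutoff is the empirical (1 - t)
#' quantile (inverse-ECDF) of the control's block AUCs, optionally scaled
#' so that control and target total signal match (`normalize`); target
#' blocks with AUC strictly above the cutoff are retained. Stringent mode
#' additionally applies the analogous max-height cutoff.
#'
#' @param target_blocks,control_blocks signal blocks from
#'   [find_signal_blocks()] over the same layout.
#' @inheritParams call_peaks_numeric
#' @param normalize scale control AUCs by total target / total control
#'   signal before taking the quantile.
#' @return A coordinate-sorted [GenomicRanges::GRanges] of target peaks.
#' @export
call_peaks_vs_control <- function(target_blocks, control_blocks,
                                  threshold = 0.01,
                                  mode = c("stringent", "relaxed"),
                                  normalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  if (length(control_blocks) == 0L) stop("control has no signal")
  c_auc <- S4Vectors::mcols(control_blocks)$auc
  c_mh <- S4Vectors::mcols(control_blocks)$max_height
  t_auc <- S4Vectors::mcols(target_blocks)$auc
  t_mh <- S4Vectors::mcols(target_blocks)$max_height
  if (normalize) {
    tot_c <- sum(c_auc)
    if (tot_c <= 0) stop("control has no signal")
    scale <- sum(t_auc) / tot_c
    c_auc <- c_auc * scale
    c_mh <- c_mh * scale
  }
  cut_auc <- stats::quantile(c_auc, probs = 1 - threshold, type = 1,
                             names = FALSE)
  keep <- t_auc > cut_auc
  if (mode == "stringent") {
    cut_mh <- stats::quantile(c_mh, probs = 1 - threshold, type = 1,
                              names = FALSE)
    keep <- keep & (t_mh > cut_mh)
  }
  sort_layout(target_blocks[keep])
}

#' Count fragments per genomic bin across samples
#'
#' Builds the samples x bins fragment-count matrix used for correlation,
#' PCA and distance analyses. A fragment is assigned to the bin containing
#' its midpoint (half-open rule: a midpoint exactly on a boundary goes to
#' the right bin), so row sums equal per-sample fragment counts. In bins
#' mode the genome is tiled with fixed-width bins (the last bin of a
#' chromosome may be short); in regions mode the supplied intervals are
#' the bins.
#'
#' @param frag_sets named list of fragment [GenomicRanges::GRanges], one
#'   per sample.
#' @param layout a [genome_layout].
#' @param bin_size bin width in basepairs (default 10000, the default of
#'   the genome-summary tools used for this analysis in the field).
#' @param regions optional [GenomicRanges::GRanges]; when given, counts
#'   are tallied over these intervals instead of genome tiles.
#' @return An object of class `binned_matrix`: list with `bins` (GRanges),
#'   `counts` (samples x bins integer matrix with sample ids as rownames)
#'   and `sample_ids`.
#' @export
bin_counts <- function(frag_sets, layout, bin_size = 10000, regions = NULL) {
  if (is.null(names(frag_sets)))
    names(frag_sets) <- paste0("sample", seq_along(frag_sets))
  if (is.null(regions)) {
    if (bin_size <= 0) stop("bin_size must be positive")
    bins <- GenomicRanges::tileGenome(as_seqinfo(layout),
                                      tilewidth = bin_size,
                                      cut.last.tile.in.chrom = TRUE)
  } else {
    bins <- regions
  }
  counts <- matrix(0L, nrow = length(frag_sets), ncol = length(bins),
                   dimnames = list(names(frag_sets), NULL))
  for (i in seq_along(frag_sets)) {
    counts[i, ] <- GenomicRanges::countOverlaps(
      bins, fragment_midpoints(frag_sets[[i]], layout))
  }
  structure(list(bins = bins, counts = counts, sample_ids = names(frag_sets)),
            class = "binned_matrix")
}

# Internal: width-1 GRanges at each fragment's midpoint,
# mid0 = floor((start0 + end0) / 2) in 0-based coordinates.
fragment_midpoints <- function(frags, layout) {
  if (length(frags) == 0L)
    return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
  mid0 <- floor((GenomicRanges::start(frags) - 1 +
                   GenomicRanges::end(frags)) / 2)
  GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomicRanges::seqnames(frags)),
                      levels = layout$chrom),
    ranges = IRanges::IRanges(start = mid0 + 1, width = 1),
    seqinfo = as_seqinfo(layout))
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("binned_matrix:", nrow(x$counts), "samples x", ncol(x$counts),
      "bins;", format(sum(x$counts), big.mark = ","), "fragments total\n")
  invisible(x)
}

#' Write a binned count matrix as TSV
#'
#' One row per bin (`chrom`, `start`, `end` in 0-based half-open
#' coordinates) followed by one column per sample.
#'
#' @param bm a `binned_matrix` from [bin_counts()].
#' @param path output path.
#' @export
write_binned_matrix <- function(bm, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(bm$bins)),
    start = GenomicRanges::start(bm$bins) - 1L,
    end = GenomicRanges::end(bm$bins))
  for (i in seq_along(bm$sample_ids))
    dt[[bm$sample_ids[i]]] <- bm$counts[i, ]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
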