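#' Minimum sample support implied by a reproducibility fraction
#'
#' The consensus rule keeps a region when it is present in strictly more
#' than a fraction `r` of the N panel samples: the smallest integer k with
#' k/N > r. With the published panel size and fraction (N = 20, r = 0.30)
#' this gives k = 7, the ">= 7 of 20" rule.
#'
#' @param n_samples panel size N (>= 1).
#' @param min_frac reproducibility fraction r in (0, 1).
#' @return Integer k.
#' @examples
#' min_support(20, 0.30)  # 7
#' @export
min_support <- function(n_samples, min_frac) {
  stopifnot(n_samples >= 1, min_frac > 0, min_frac < 1)
  x <- n_samples * min_frac
  # snap near-integer products so 20 * 0.30 is treated as exactly 6
  if (abs(x - round(x)) < 1e-9) x <- round(x)
  as.integer(floor(x) + 1)
}

#' Extend peaks symmetrically, clamped to chromosome bounds
#'
#' Grows each interval by `extension` basepairs on both sides (the
#' published lists use 1000 bp, to capture peaks slightly shifted between
#' datasets). Output may overlap and is deliberately not merged here.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param extension basepairs to add on each side (>= 0).
#' @param layout a [genome_layout].
#' @return The extended [GenomicRanges::GRanges], metadata preserved.
#' @export
extend_peaks <- function(peaks, extension, layout) {
  stopifnot(extension >= 0)
  if (length(peaks) == 0L) return(peaks)
  st <- pmax(GenomicRanges::start(peaks) - extension, 1)
  en <- pmin(GenomicRanges::end(peaks) + extension,
             layout$length[as.character(GenomicRanges::seqnames(peaks))])
  out <- peaks
  IRanges::ranges(out) <- IRanges::IRanges(start = st, end = en)
  out
}

#' Merge overlapping or touching intervals
#'
#' Unions intervals that overlap or touch (end of one equals start of the
#' next in half-open coordinates); with `gap > 0`, intervals within `gap`
#' basepairs of each other are also unioned. Output is sorted.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param gap basepairs of separation still merged (default 0, the default
#'   of the standard merge tool).
#' @return A sorted, non-overlapping [GenomicRanges::GRanges].
#' @export
merge_intervals <- function(gr, gap = 0) {
  stopifnot(gap >= 0)
  GenomicRanges::reduce(sort_layout(gr), min.gapwidth = gap + 1,
                        ignore.strand = TRUE)
}

#' Segment the genome by cross-sample peak support
#'
#' Each sample's peaks are merged internally (within-sample overlap counts
#' once), then the genome is segmented at every peak boundary and each
#' covered segment is annotated with the number of distinct samples whose
#' peaks cover it.
#'
#' @param peak_sets list of per-sample peak [GenomicRanges::GRanges]
#'   (typically after [extend_peaks()]).
#' @param layout a [genome_layout].
#' @return A sorted [GenomicRanges::GRanges] of maximal constant-support
#'   segments with metadata column `support` (>= 1).
#' @export
count_support <- function(peak_sets, layout) {
  si <- as_seqinfo(layout)
  cov <- NULL
  for (ps in peak_sets) {
    red <- merge_intervals(ps)
    g <- GenomicRanges::GRanges(
      seqnames = factor(as.character(GenomicRanges::seqnames(red)),
                        levels = layout$chrom),
      ranges = IRanges::ranges(red), seqinfo = si)
    ci <- GenomicRanges::coverage(g)
    cov <- if (is.null(cov)) ci else cov + ci
  }
  if (is.null(cov)) stop("no peak sets given")
  seg <- GenomicRanges::bindAsGRanges(support = cov[layout$chrom])
  seg <- seg[S4Vectors::mcols(seg)$support > 0]
  S4Vectors::mcols(seg)$support <- as.integer(S4Vectors::mcols(seg)$support)
  GenomeInfoDb::seqinfo(seg) <- si
  sort_layout(seg)
}

#' Build a consensus suspect list from per-sample peak sets
#'
#' The consensus procedure: extend each sample's peaks by `extension` bp on
#' both sides, merge within samples, segment the genome by cross-sample
#' support, keep segments supported by at least [min_support()] samples
#' (strictly more than `min_frac` of the panel), and merge touching or
#' overlapping kept segments into final regions. The mitochondrial
#' chromosome is appended wholesale as one policy region by default, since
#' mitochondrial signal is a deliberate inclusion in such lists rather
#' than a thresholded call.
#'
#' @param peak_sets list of per-sample peak [GenomicRanges::GRanges]
#'   (>= 2 samples).
#' @param layout a [genome_layout].
#' @param extension basepairs of symmetric peak extension (default 1000).
#' @param min_frac reproducibility fraction r, strict inequality
#'   (default 0.30).
#' @param include_chrM append the full mitochondrial chromosome as a
#'   policy region (default TRUE).
#' @param chrM name of the mitochondrial chromosome in the layout.
#' @return An object of class `suspect_list`: fields `regions` (sorted
#'   non-overlapping [GenomicRanges::GRanges] with columns `support` = max
#'   segment support within the region and `chrM_policy`), `params`,
#'   `n_samples` and `layout`.
#' @seealso [reproducibility_curve()], [filter_fragments()], [frip()]
#' @export
build_suspect_list <- function(peak_sets, layout, extension = 1000,
                               min_frac = 0.30, include_chrM = TRUE,
                               chrM = "chrM") {
  n <- length(peak_sets)
  if (n < 2L) stop("consensus requires multiple samples")
  k <- min_support(n, min_frac)
  ext <- lapply(peak_sets, extend_peaks, extension = extension,
                layout = layout)
  seg <- count_support(ext, layout)
  kept <- seg[S4Vectors::mcols(seg)$support >= k]
  regions <- merge_intervals(kept)
  if (length(regions)) {
    hits <- GenomicRanges::findOverlaps(regions, kept)
    sup <- tapply(S4Vectors::mcols(kept)$support[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    S4Vectors::mcols(regions)$support <- as.integer(sup)
  } else {
    S4Vectors::mcols(regions)$support <- integer(0)
  }
  S4Vectors::mcols(regions)$chrM_policy <- rep(FALSE, length(regions))
  if (include_chrM && chrM %in% layout$chrom) {
    regions <- regions[as.character(GenomicRanges::seqnames(regions)) != chrM]
    m <- GenomicRanges::GRanges(
      seqnames = factor(chrM, levels = layout$chrom),
      ranges = IRanges::IRanges(1, layout$length[chrM]),
      support = NA_integer_, chrM_policy = TRUE,
      seqinfo = as_seqinfo(layout))
    regions <- sort_layout(c(regions, m))
  }
  new_suspect_list(regions, layout,
                   params = list(extension = extension, min_frac = min_frac,
                                 min_support = k, include_chrM = include_chrM),
                   n_samples = n)
}

new_suspect_list <- function(regions, layout, params = list(),
                             n_samples = NA_integer_) {
  structure(list(regions = regions, layout = layout, params = params,
                 n_samples = n_samples),
            class = "suspect_list")
}

#' Construct a suspect list from pre-built regions
#'
#' Wraps an existing set of regions (e.g. a published list read from BED)
#' as a `suspect_list` so it can be used with the filtering and QC
#' functions. Regions are merged and sorted.
#'
#' @param regions a [GenomicRanges::GRanges] or a BED path.
#' @param layout a [genome_layout].
#' @return A `suspect_list`.
#' @export
as_suspect_list <- function(regions, layout) {
  if (is.character(regions)) regions <- read_bed(regions, layout)
  regions <- merge_intervals(regions)
  S4Vectors::mcols(regions)$support <- rep(NA_integer_, length(regions))
  S4Vectors::mcols(regions)$chrM_policy <- rep(FALSE, length(regions))
  new_suspect_list(regions, layout)
}

#' @export
print.suspect_list <- function(x, ...) {
  cat("suspect_list:", length(x$regions), "regions,",
      format(sum(GenomicRanges::width(x$regions)), big.mark = ","),
      "bp total\n")
  if (!is.na(x$n_samples))
    cat("  built from", x$n_samples, "samples; min support",
        x$params$min_support,
        sprintf("(> %.0f%% of panel);", 100 * x$params$min_frac),
        "extension", x$params$extension, "bp\n")
  gf <- genome_fraction(x, x$layout)
  cat(sprintf("  genome fraction: %.4f%%\n", 100 * gf))
  invisible(x)
}

#' @export
summary.suspect_list <- function(object, ...) {
  w <- GenomicRanges::width(object$regions)
  pol <- S4Vectors::mcols(object$regions)$chrM_policy
  out <- list(
    n_regions = length(object$regions),
    n_policy_regions = sum(pol %in% TRUE),
    total_bp = sum(w),
    mean_width = if (length(w)) mean(w) else NA_real_,
    genome_fraction = genome_fraction(object, object$layout),
    support_table = table(S4Vectors::mcols(object$regions)$support,
                          useNA = "ifany"),
    params = object$params
  )
  class(out) <- "summary.suspect_list"
  out
}

#' @export
print.summary.suspect_list <- function(x, ...) {
  cat("suspect_list summary\n")
  cat("  regions:        ", x$n_regions,
      if (x$n_policy_regions) paste0(" (incl. ", x$n_policy_regions,
                                     " policy region(s))") else "", "\n",
      sep = "")
  cat("  total bp:       ", format(x$total_bp, big.mark = ","), "\n", sep = "")
  cat(sprintf("  mean width:      %.0f bp\n", x$mean_width))
  cat(sprintf("  genome fraction: %.4f%%\n", 100 * x$genome_fraction))
  cat("  support counts:\n")
  print(x$support_table)
  invisible(x)
}

#' @export
as.data.frame.suspect_list <- function(x, ...) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x$regions)),
    start = GenomicRanges::start(x$regions) - 1L,
    end = GenomicRanges::end(x$regions),
    as.data.frame(S4Vectors::mcols(x$regions)),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.suspect_list <- function(x, ...) {
  w <- GenomicRanges::width(x$regions)
  graphics::hist(log10(w), breaks = 30,
                 main = "Suspect region widths",
                 xlab = "log10 width (bp)", ...)
  invisible(x)
}

#' Write a suspect list to BED (optionally with annotation columns)
#'
#' @param sl a `suspect_list`.
#' @param path output path.
#' @param annotated also write available annotation columns (support,
#'   category, nearest gene/TSS distance, mappability flag) after the
#'   three BED columns.
#' @export
write_suspect_list <- function(sl, path, annotated = FALSE) {
  cols <- NULL
  if (annotated) {
    have <- colnames(S4Vectors::mcols(sl$regions))
    cols <- intersect(c("support", "category", "nearest_gene",
                        "tss_distance", "low_mappability"), have)
  } else if ("support" %in% colnames(S4Vectors::mcols(sl$regions))) {
    cols <- "support"
  }
  write_bed(sl$regions, path, extra_columns = cols)
}

#' Reproducibility curve and knee of a peak-set panel
#'
#' For each support level m = 1..N, counts the merged candidate regions
#' present in at least m samples. The knee is the m whose point on the
#' (m, count) polyline lies farthest (perpendicular distance) from the
#' chord joining m = 1 and m = N; for the published 20-sample panels this
#' knee sits at 7 of 20. A constant curve has no knee and is reported as
#' m = 1 with `constant = TRUE`.
#'
#' @param peak_sets list of per-sample (extended) peak
#'   [GenomicRanges::GRanges].
#' @param layout a [genome_layout].
#' @return Object of class `repro_curve`: `m`, `count`, `knee`, `constant`.
#' @export
reproducibility_curve <- function(peak_sets, layout) {
  n <- length(peak_sets)
  seg <- count_support(peak_sets, layout)
  sup <- S4Vectors::mcols(seg)$support
  count <- vapply(seq_len(n), function(m)
    length(merge_intervals(seg[sup >= m])), 0L)
  structure(list(m = seq_len(n), count = count,
                 knee = knee_point(seq_len(n), count),
                 constant = length(unique(count)) == 1L),
            class = "repro_curve")
}

# m maximizing perpendicular distance from the chord between the first and
# last point of the (m, count) polyline; ties broken toward smaller m.
knee_point <- function(m, count) {
  n <- length(m)
  if (n < 3L || length(unique(count)) == 1L) return(1L)
  x1 <- m[1]; y1 <- count[1]; x2 <- m[n]; y2 <- count[n]
  d <- abs((y2 - y1) * m - (x2 - x1) * count + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  m[which.max(d)]
}

#' @export
print.repro_curve <- function(x, ...) {
  cat("reproducibility curve over", length(x$m), "samples\n")
  cat("  regions at support >= m:\n")
  print(stats::setNames(x$count, paste0("m=", x$m)))
  cat("  knee estimate: m =", x$knee,
      if (x$constant) "(constant curve; knee undefined)" else "", "\n")
  invisible(x)
}

#' @export
plot.repro_curve <- function(x, ...) {
  graphics::plot(x$m, x$count, type = "b", xlab = "datasets (m)",
                 ylab = "regions with support >= m", ...)
  graphics::abline(v = x$knee, lty = 2)
  invisible(x)
}

#' Write a reproducibility curve as TSV
#' @param curve a `repro_curve`.
#' @param path output path.
#' @export
write_repro_curve <- function(curve, path) {
  data.table::fwrite(data.table::data.table(m = curve$m,
                                            region_count = curve$count),
                     path, sep = "\t")
  invisible(path)
}

#' Annotate suspect regions with genomic context
#'
#' Labels each region with the highest-precedence overlapping category
#' (promoter > exon > intron > intergenic), where the promoter window is
#' TSS - 1000 bp to TSS + 100 bp (strand-aware, the convention of the
#' standard annotation tool), and assigns the closest TSS by minimal
#' distance from the region midpoint. The distance is signed with respect
#' to the gene's strand: negative means the region midpoint lies upstream
#' of the TSS.
#'
#' @param sl a `suspect_list`.
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate), `strand` (`"+"`/`"-"`), `gene`. May be `NULL`.
#' @param exons,introns optional [GenomicRanges::GRanges] of exon and
#'   intron intervals.
#' @return The `suspect_list` with region metadata columns `category`,
#'   `nearest_gene`, `tss_distance`.
#' @export
annotate_regions <- function(sl, tss = NULL, exons = NULL, introns = NULL) {
  regions <- sl$regions
  n <- length(regions)
  if (is.null(tss) && is.null(exons) && is.null(introns)) {
    S4Vectors::mcols(regions)$category <- rep("unannotated", n)
    sl$regions <- regions
    return(sl)
  }
  category <- rep("intergenic", n)
  layout <- sl$layout
  if (!is.null(introns) && length(introns))
    category[GenomicRanges::countOverlaps(regions, introns) > 0] <- "intron"
  if (!is.null(exons) && length(exons))
    category[GenomicRanges::countOverlaps(regions, exons) > 0] <- "exon"
  if (!is.null(tss) && nrow(tss)) {
    plus <- tss$strand != "-"
    prom0_start <- ifelse(plus, tss$pos - 1000, tss$pos - 100)
    prom0_end <- ifelse(plus, tss$pos + 100, tss$pos + 1000)
    len <- layout$length[as.character(tss$chrom)]
    prom0_start <- pmax(prom0_start, 0)
    prom0_end <- pmin(prom0_end, len)
    prom <- gr_from_bed0(tss$chrom, prom0_start, prom0_end, layout,
                         context = "promoter window")
    category[GenomicRanges::countOverlaps(regions, prom) > 0] <- "promoter"

    # nearest TSS from region midpoint, per chromosome
    mid0 <- floor((GenomicRanges::start(regions) - 1 +
                     GenomicRanges::end(regions)) / 2)
    chrom_r <- as.character(GenomicRanges::seqnames(regions))
    nearest_gene <- rep(NA_character_, n)
    tss_distance <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      j <- which(as.character(tss$chrom) == chrom_r[i])
      if (!length(j)) next
      d <- mid0[i] - tss$pos[j]
      jj <- j[which.min(abs(d))]
      nearest_gene[i] <- as.character(tss$gene[jj])
      raw <- mid0[i] - tss$pos[jj]
      tss_distance[i] <- if (tss$strand[jj] == "-") -raw else raw
    }
    S4Vectors::mcols(regions)$nearest_gene <- nearest_gene
    S4Vectors::mcols(regions)$tss_distance <- tss_distance
  }
  S4Vectors::mcols(regions)$category <- category
  sl$regions <- regions
  sl
}
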