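#' Read sequenced fragments from a fragment BED or a paired-end BAM
#'
#' A fragment set is one sample's paired-end fragments, one genomic interval
#' per sequenced fragment. From a fragment BED the first three columns are
#' taken verbatim (0-based half-open). From a coordinate-sorted BAM, each
#' properly paired read pair yields the interval from the leftmost mate
#' start to the rightmost mate end; the pair is read off the leftmost mate
#' (positive TLEN), secondary and supplementary alignments are ignored, and
#' improper/unpaired reads are skipped with a reported count.
#'
#' @param path path to the input file.
#' @param layout a [genome_layout]; all fragments must fall inside it.
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @return A [GenomicRanges::GRanges] of fragments (duplicates permitted;
#'   this is the pre-deduplication state). The number of skipped improper
#'   pairs, for BAM input, is attached as attribute `skipped_pairs`.
#' @seealso [dedup_fragments()], [write_bed()]
#' @export
read_fragments <- function(path, layout, format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (format == "bed") read_fragments_bed(path, layout)
  else read_fragments_bam(path, layout)
}

read_fragments_bed <- function(path, layout) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
  }
  if (ncol(dt) < 3L) stop("fragment BED needs >= 3 columns: ", path)
  gr_from_bed0(dt[[1]], dt[[2]], dt[[3]], layout, context = "fragment")
}

read_fragments_bam <- function(path, layout) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  so <- unname(sub("^.*SO:", "",
                   grep("SO:", unlist(hdr$text["@HD"]), value = TRUE)))
  if (length(so) && !identical(so[1], "coordinate"))
    stop("BAM must be coordinate-sorted: ", path)
  flag_proper <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag_proper,
                                   what = c("rname", "pos", "isize"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  # leftmost mate of each proper pair has positive template length
  left <- !is.na(rec$isize) & rec$isize > 0
  chrom <- as.character(rec$rname[left])
  start1 <- rec$pos[left]
  end1 <- start1 + rec$isize[left] - 1L

  flag_all <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                     isSupplementaryAlignment = FALSE,
                                     isUnmappedQuery = FALSE)
  n_total <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(flag = flag_all))$records
  skipped <- ceiling((n_total - 2L * sum(left)) / 2)
  if (skipped > 0)
    message("read_fragments: skipped ", skipped,
            " unpaired/improper read pair(s) in ", basename(path))

  gr <- gr_from_bed0(chrom, start1 - 1L, end1, layout, context = "fragment")
  attr(gr, "skipped_pairs") <- skipped
  gr
}

#' Write intervals to a BED file
#'
#' Standard tab-delimited BED (0-based half-open), newline-terminated, with
#' deterministic byte output for identical input. Input must already be
#' sorted in layout order then start.
#'
#' @param gr a sorted [GenomicRanges::GRanges].
#' @param path output path.
#' @param extra_columns character vector of metadata column names of `gr` to
#'   append after the first three BED columns (e.g. `"support"`).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, extra_columns = NULL) {
  if (is.unsorted(GenomicRanges::order(gr)))
    stop("intervals must be sorted in layout order before writing")
  cols <- list(
    as.character(GenomicRanges::seqnames(gr)),
    format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE)
  )
  for (nm in extra_columns) {
    v <- S4Vectors::mcols(gr)[[nm]]
    if (is.null(v)) stop("no such metadata column: ", nm)
    cols <- c(cols, list(vapply(v, function(z) format(z, scientific = FALSE,
                                                      trim = TRUE), "")))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path path to a BED3+ file (0-based half-open).
#' @param layout a [genome_layout].
#' @param keep_extra keep columns beyond the third as metadata columns
#'   `V4`, `V5`, ...
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path, layout, keep_extra = FALSE) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
  if (ncol(dt) < 3L) stop("BED needs >= 3 columns: ", path)
  gr <- gr_from_bed0(dt[[1]], dt[[2]], dt[[3]], layout, context = "region")
  if (keep_extra && ncol(dt) > 3L) {
    for (j in 4:ncol(dt))
      S4Vectors::mcols(gr)[[paste0("V", j)]] <- dt[[j]]
  }
  gr
}

#' Read and write bedgraph coverage tracks
#'
#' A coverage track is a stepwise per-basepair signal with bedgraph
#' semantics: within each chromosome the records are non-overlapping
#' 0-based half-open runs carrying a value. On reading, basepairs absent
#' from the file are implicitly zero; on writing, zero-valued runs are
#' omitted (the dialect produced by `bedtools genomecov -bg` and consumed
#' by SEACR).
#'
#' @param path file path.
#' @param layout a [genome_layout].
#' @return `read_bedgraph` returns a per-chromosome
#'   [IRanges::RleList] in layout order; `write_bedgraph` invisibly
#'   returns `path`.
#' @export
read_bedgraph <- function(path, layout) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) > 0L && ncol(dt) < 4L)
    stop("bedgraph needs 4 columns: ", path)
  if (nrow(dt) == 0L) {
    return(empty_track(layout))
  }
  gr <- gr_from_bed0(dt[[1]], dt[[2]], dt[[3]], layout, context = "bedgraph run")
  val <- as.numeric(dt[[4]])
  if (any(is.na(val))) stop("non-numeric bedgraph value in ", path)
  # overlap check within chromosomes
  o <- GenomicRanges::order(gr)
  gs <- gr[o]
  same <- as.character(GenomicRanges::seqnames(gs))[-1] ==
    as.character(GenomicRanges::seqnames(gs))[-length(gs)]
  if (length(gs) > 1 &&
      any(same & GenomicRanges::start(gs)[-1] <=
            GenomicRanges::end(gs)[-length(gs)]))
    stop("overlapping bedgraph records in ", path)
  cov <- GenomicRanges::coverage(gr, weight = val)
  cov[layout$chrom]
}

#' @rdname read_bedgraph
#' @param track a per-chromosome [IRanges::RleList] as returned by
#'   [fragments_to_coverage()] or [read_bedgraph()].
#' @export
write_bedgraph <- function(track, path, layout) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in layout$chrom) {
    r <- track[[chrom]]
    if (is.null(r)) next
    v <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    keep <- v != 0
    if (!any(keep)) next
    writeLines(paste(chrom,
                     format(starts[keep], scientific = FALSE, trim = TRUE),
                     format(ends[keep], scientific = FALSE, trim = TRUE),
                     vapply(v[keep], format_signal, ""),
                     sep = "\t"), con)
  }
  invisible(path)
}

# Deterministic numeric formatting: integers print without decimal point,
# reals with up to 15 significant digits (round-trips typical signal values).
format_signal <- function(x) {
  if (!is.na(x) && x == floor(x) && abs(x) < 1e15)
    format(x, scientific = FALSE, trim = TRUE)
  else format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

empty_track <- function(layout) {
  out <- IRanges::RleList(lapply(layout$length, function(l)
    S4Vectors::Rle(0, l)))
  names(out) <- layout$chrom
  out
}

#' Write the layout as a chrom.sizes file
#'
#' @param layout a [genome_layout].
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(layout$chrom,
                   format(layout$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
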