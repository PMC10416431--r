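#' Genome layout: ordered chromosome names and lengths
#'
#' A `genome_layout` is the coordinate universe for everything else in the
#' package: an ordered set of chromosome names with their lengths in
#' basepairs. The order is stable and defines the sort order of every
#' interval output (chromosomes are never reordered lexicographically).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in basepairs (> 0).
#' @return An object of class `genome_layout` with fields `chrom` and
#'   `length` (named integer vector in layout order).
#' @examples
#' layout <- genome_layout(c("chr1", "chr2", "chrM"), c(1e7, 1e7, 16000))
#' layout
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("no chromosomes")
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(
    list(chrom = chrom, length = stats::setNames(as.double(length), chrom)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout with", length(x$chrom), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp total\n")
  n <- min(length(x$chrom), 8L)
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s\n", x$chrom[i],
                format(x$length[i], big.mark = ",", scientific = FALSE)))
  if (length(x$chrom) > n) cat("  ...\n")
  invisible(x)
}

#' @export
format.genome_layout <- function(x, ...) {
  paste0("genome_layout<", length(x$chrom), " chromosomes>")
}

#' Read a UCSC chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name and integer length.
#' The file order is preserved and becomes the layout (and output sort)
#' order.
#'
#' @param path path to a chrom.sizes file.
#' @return A [genome_layout].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  chrom <- character(length(lines))
  len <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) < 2L)
      stop("malformed chrom.sizes line ", i, ": ", lines[i])
    l <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(l) || l != floor(l))
      stop("non-integer length on chrom.sizes line ", i, ": ", lines[i])
    if (l <= 0)
      stop("non-positive length on chrom.sizes line ", i, ": ", lines[i])
    chrom[i] <- fields[1]
    len[i] <- l
  }
  if (anyDuplicated(chrom)) {
    dup <- unique(chrom[duplicated(chrom)])
    bad <- which(chrom %in% dup)[2]
    stop("duplicate chromosome name on chrom.sizes line ", bad, ": ", chrom[bad])
  }
  genome_layout(chrom, len)
}

#' Convert a genome layout to a Seqinfo object
#'
#' @param layout a [genome_layout].
#' @return A [GenomeInfoDb::Seqinfo] carrying the layout's chromosome order
#'   and lengths.
#' @export
as_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$length))
}

# Internal: build a GRanges from 0-based half-open coordinates, validating
# against the layout. Used at every file/user boundary so the 1-based closed
# GRanges convention never leaks into file formats.
gr_from_bed0 <- function(chrom, start0, end0, layout, context = "interval") {
  chrom <- as.character(chrom)
  start0 <- as.numeric(start0)
  end0 <- as.numeric(end0)
  bad_chrom <- !(chrom %in% layout$chrom)
  if (any(bad_chrom)) {
    i <- which(bad_chrom)[1]
    stop(context, " on unknown chromosome '", chrom[i], "' (record ", i, ")")
  }
  len <- layout$length[chrom]
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0 | end0 > len
  if (any(bad)) {
    idx <- utils::head(which(bad), 5L)
    stop(context, " outside genome layout or malformed: ",
         paste(sprintf("%s:%s-%s (record %d)", chrom[idx],
                       format(start0[idx], scientific = FALSE),
                       format(end0[idx], scientific = FALSE), idx),
               collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = layout$chrom),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    seqinfo = as_seqinfo(layout)
  )
  gr
}

# Internal: sort in layout order then start (GRanges sort already respects
# seqlevels order, which we pin to the layout).
sort_layout <- function(gr) {
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# Internal: check intervals are within the layout (1-based GRanges side).
validate_gr <- function(gr, layout, context = "interval") {
  len <- layout$length[as.character(GenomicRanges::seqnames(gr))]
  bad <- GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > len
  if (any(bad)) {
    idx <- utils::head(which(bad), 5L)
    stop(context, " outside chromosome bounds: ",
         paste(as.character(gr[idx]), collapse = ", "))
  }
  invisible(gr)
}
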