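# Independent per-basepair brute-force oracles. Everything here works on
# plain data.frames of 0-based half-open intervals and explicit per-basepair
# vectors (vec[p + 1] is the value at 0-based basepair p), never on the
# interval machinery the package itself uses.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# -- conversions between the oracle world and the package world -----------

gr0 <- function(df, layout) {
  if (nrow(df) == 0) return(GRanges(seqinfo = as_seqinfo(layout)))
  GRanges(seqnames = factor(df$chrom, levels = layout$chrom),
          ranges = IRanges(start = df$start + 1, end = df$end),
          seqinfo = as_seqinfo(layout))
}

as_bed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

track_vec <- function(track, chrom) as.numeric(track[[chrom]])

# -- random instance generators -------------------------------------------

rand_layout <- function(n_chrom = 2, max_len = 10000) {
  genome_layout(paste0("chr", seq_len(n_chrom)),
                sample(seq(1000, max_len), n_chrom, replace = TRUE))
}

rand_intervals <- function(layout, n, max_width = 400) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[chrom]
  width <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n) * pmax(1, len - width))
  data.frame(chrom = chrom, start = start,
             end = pmin(start + width, len), stringsAsFactors = FALSE)
}

# -- per-basepair oracles --------------------------------------------------

# pileup: value at bp p = number of intervals containing p
o_pileup <- function(df, layout) {
  out <- lapply(layout$length, function(l) numeric(l))
  for (i in seq_len(nrow(df))) {
    idx <- (df$start[i] + 1):df$end[i]
    out[[df$chrom[i]]][idx] <- out[[df$chrom[i]]][idx] + 1
  }
  out
}

# maximal positive runs of a per-bp vector -> blocks with auc and max
o_blocks <- function(vec) {
  pos <- vec > 0
  if (!any(pos)) return(data.frame(start = integer(0), end = integer(0),
                                   auc = numeric(0), max = numeric(0)))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- r$values
  data.frame(
    start = starts[keep] - 1L, end = ends[keep],
    auc = vapply(which(keep), function(j)
      sum(vec[starts[j]:ends[j]]), 0),
    max = vapply(which(keep), function(j)
      max(vec[starts[j]:ends[j]]), 0))
}

# support: per-bp count of samples (list of interval dfs) covering it
o_support <- function(dfs, layout) {
  out <- lapply(layout$length, function(l) integer(l))
  for (df in dfs) {
    covered <- lapply(layout$length, function(l) logical(l))
    for (i in seq_len(nrow(df)))
      covered[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
    for (chrom in layout$chrom)
      out[[chrom]] <- out[[chrom]] + covered[[chrom]]
  }
  out
}

# union of intervals as merged runs (touching intervals fuse automatically)
o_merge <- function(df, layout) {
  res <- list()
  for (chrom in layout$chrom) {
    covered <- logical(layout$length[chrom])
    sub <- df[df$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    if (!any(covered)) next
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    keep <- r$values
    res[[chrom]] <- data.frame(chrom = chrom, start = starts[keep] - 1L,
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(res)) return(data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0)))
  do.call(rbind, unname(res))
}

# does interval i of a overlap (>= 1 bp) any interval of b?
o_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, TRUE)
}

# midpoint bin assignment: bin j (1-based) of fixed-width tiling
o_bin_index <- function(df, layout, bin_size) {
  mid <- floor((df$start + df$end) / 2)
  bins_per_chrom <- ceiling(layout$length / bin_size)
  offset <- c(0, cumsum(bins_per_chrom))[match(df$chrom, layout$chrom)]
  offset + floor(mid / bin_size) + 1
}

# expected per-sample FRIP over planted regions given simulator rates:
# fragments with midpoint in an enriched region ~ (1 + fold) x background
# there; FRIP ~ enriched bp x (1 + fold) / (genome + enriched bp x fold)
analytic_frip <- function(cfg, enriched_bp) {
  g <- sum(cfg$layout$length)
  enriched_bp * (1 + cfg$artifact_fold) /
    (g + enriched_bp * cfg$artifact_fold)
}
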