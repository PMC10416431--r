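layout_qc <- genome_layout("chr1", 10000)

test_that("deduplication collapses exact coordinate duplicates only", {
  fr <- gr0(data.frame(chrom = "chr1", start = c(100, 100, 100, 300),
                       end = c(250, 250, 260, 400)), layout_qc)
  out <- dedup_fragments(fr)
  expect_equal(length(out), 3L)
  expect_equal(attr(out, "n_removed"), 1L)
  distinct <- gr0(data.frame(chrom = "chr1", start = c(1, 2), end = c(5, 6)),
                  layout_qc)
  expect_equal(length(dedup_fragments(distinct)), 2L)
})

test_that("fragment filtering removes >= 1 bp overlaps, keeps touching", {
  regions <- as_suspect_list(gr0(data.frame(chrom = "chr1", start = 1000,
                                            end = 2000), layout_qc),
                             layout_qc)
  # shares exactly 1 bp with the region -> removed
  touching1bp <- gr0(data.frame(chrom = "chr1", start = 1999, end = 2100),
                     layout_qc)
  expect_equal(length(filter_fragments(touching1bp, regions)), 0L)
  # ends where the region starts (half-open): no shared bp -> kept
  abutting <- gr0(data.frame(chrom = "chr1", start = 900, end = 1000),
                  layout_qc)
  expect_equal(length(filter_fragments(abutting, regions)), 1L)

  set.seed(71)
  for (i in 1:5) {
    layout <- rand_layout()
    fdf <- rand_intervals(layout, 200, max_width = 150)
    rdf <- rand_intervals(layout, 10, max_width = 800)
    sl <- as_suspect_list(gr0(rdf, layout), layout)
    kept <- filter_fragments(gr0(fdf, layout), sl)
    oracle_kept <- fdf[!o_overlaps_any(fdf, rdf), ]
    rownames(oracle_kept) <- NULL
    got <- as_bed0(GenomicRanges::sort(kept, ignore.strand = TRUE))
    oracle_kept <- oracle_kept[order(oracle_kept$chrom, oracle_kept$start,
                                     oracle_kept$end), ]
    rownames(oracle_kept) <- NULL
    got <- got[order(got$chrom, got$start, got$end), ]
    rownames(got) <- NULL
    expect_equal(got, oracle_kept)
    # filtering partitions the input: survivors + removed = total
    expect_equal(length(kept) + sum(o_overlaps_any(fdf, rdf)), nrow(fdf))
  }
})

test_that("peak subtraction removes whole overlapping peaks", {
  sl <- as_suspect_list(gr0(data.frame(chrom = "chr1", start = 1000,
                                       end = 2000), layout_qc), layout_qc)
  inside <- gr0(data.frame(chrom = "chr1", start = 1200, end = 1300),
                layout_qc)
  expect_equal(length(subtract_peaks(inside, sl)), 0L)
  disjoint <- gr0(data.frame(chrom = "chr1", start = 3000, end = 3100),
                  layout_qc)
  expect_equal(length(subtract_peaks(disjoint, sl)), 1L)
  # straddling the boundary: removed whole, never trimmed
  straddle <- gr0(data.frame(chrom = "chr1", start = 900, end = 1100),
                  layout_qc)
  expect_equal(length(subtract_peaks(straddle, sl)), 0L)
})

test_that("FRIP is the overlap fraction and is zero after filtering", {
  sl <- as_suspect_list(gr0(data.frame(chrom = "chr1", start = 1000,
                                       end = 2000), layout_qc), layout_qc)
  fr <- gr0(data.frame(chrom = "chr1",
                       start = c(1100, 1500, 1999, 5000),
                       end = c(1200, 1600, 2100, 5100)), layout_qc)
  res <- frip(fr, sl)
  expect_equal(res$frip, 0.75)
  expect_equal(res$fragments_in_regions, 3L)

  all_in <- gr0(data.frame(chrom = "chr1", start = c(1100, 1200),
                           end = c(1150, 1300)), layout_qc)
  expect_equal(frip(all_in, sl)$frip, 1)

  expect_error(frip(fr[0], sl), "no mapped fragments")

  # composition identity on random inputs
  set.seed(83)
  for (i in 1:10) {
    layout <- rand_layout()
    fdf <- rand_intervals(layout, 150)
    rsl <- as_suspect_list(gr0(rand_intervals(layout, 8, max_width = 600),
                               layout), layout)
    kept <- filter_fragments(gr0(fdf, layout), rsl)
    if (length(kept) > 0) expect_identical(frip(kept, rsl)$frip, 0)
  }
})

test_that("Spearman matrix matches rank-then-Pearson and flags flat samples", {
  set.seed(91)
  counts <- matrix(rpois(5 * 200, 10), nrow = 5,
                   dimnames = list(paste0("s", 1:5), NULL))
  counts[2, ] <- counts[1, ]                   # identical pair
  counts[3, ] <- max(counts[1, ]) - counts[1, ] # rank reversal
  bins <- GenomicRanges::tileGenome(as_seqinfo(genome_layout("chr1", 2e5)),
                                    tilewidth = 1000,
                                    cut.last.tile.in.chrom = TRUE)
  bm <- structure(list(bins = bins, counts = counts,
                       sample_ids = rownames(counts)),
                  class = "binned_matrix")
  cm <- spearman_matrix(bm)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  # definitional oracle: average ranks then Pearson
  direct <- stats::cor(apply(t(counts), 2, rank))
  expect_equal(unclass(cm)[1:5, 1:5], direct, tolerance = 1e-12,
               ignore_attr = TRUE)

  counts[4, ] <- 7  # zero variance
  bm$counts <- counts
  cm2 <- spearman_matrix(bm)
  expect_true(all(is.na(cm2[4, -4])))
  expect_equal(cm2[4, 4], 1)
  expect_equal(attr(cm2, "undefined_samples"), "s4")
})

test_that("PCA centers per bin and excluding artifact bins shrinks PC1", {
  layout <- genome_layout("chr1", 2e5)
  bins <- GenomicRanges::tileGenome(as_seqinfo(layout), tilewidth = 1000,
                                    cut.last.tile.in.chrom = TRUE)
  set.seed(101)
  # 6 samples of pure noise plus one dominant shared-artifact bin
  counts <- matrix(rpois(6 * length(bins), 5), nrow = 6,
                   dimnames = list(paste0("s", 1:6), NULL))
  counts[, 10] <- counts[, 10] + rpois(6, 40) * c(9, 1, 8, 2, 7, 3)
  bm <- structure(list(bins = bins, counts = counts,
                       sample_ids = rownames(counts)),
                  class = "binned_matrix")
  pc <- pca_scree(bm)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_equal(sum(pc$percent_variance), 100)
  # eigenvalue sum equals total centered variance
  expect_equal(sum(pc$eigenvalues),
               sum(apply(counts, 2, function(col)
                 sum((col - mean(col))^2))) / (nrow(counts) - 1))

  excl <- as_suspect_list(bins[10], layout)
  pc2 <- pca_scree(bm, exclude = excl)
  expect_lt(pc2$percent_variance[1], pc$percent_variance[1])
  expect_equal(pc2$n_bins_used, length(bins) - 1L)

  # two samples: PC1 explains all nonzero variance
  bm2 <- bm; bm2$counts <- counts[1:2, ]; bm2$sample_ids <- c("s1", "s2")
  expect_equal(pca_scree(bm2)$percent_variance[1], 100)
})

test_that("distance ratio separates labeled clusters and is symmetric", {
  bins <- GenomicRanges::tileGenome(as_seqinfo(genome_layout("chr1", 4000)),
                                    tilewidth = 1000,
                                    cut.last.tile.in.chrom = TRUE)
  counts <- rbind(a1 = c(0, 0, 0, 0), a2 = c(3, 0, 0, 0),
                  b1 = c(100, 100, 0, 0), b2 = c(100, 104, 0, 0))
  bm <- structure(list(bins = bins, counts = counts,
                       sample_ids = rownames(counts)),
                  class = "binned_matrix")
  res <- distance_ratio(bm, c("A", "A", "B", "B"))
  # hand-computed: intra = (3 + 4) / 2; inter = mean of 4 cross distances
  expect_equal(res$intra, 3.5)
  expect_equal(res$inter, mean(c(
    sqrt(100^2 + 100^2), sqrt(100^2 + 104^2),
    sqrt(97^2 + 100^2), sqrt(97^2 + 104^2))))
  expect_equal(res$ratio, res$inter / res$intra)
  expect_gt(res$ratio, 10)

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  bmp <- bm; bmp$counts <- counts[perm, ]; bmp$sample_ids <- rownames(counts)[perm]
  resp <- distance_ratio(bmp, c("B", "A", "B", "A"))
  expect_equal(resp$ratio, res$ratio)

  same <- bm; same$counts <- counts[c(1, 1, 1, 1), ]
  expect_error(distance_ratio(same, c("A", "A", "B", "B")), "undefined")
  expect_error(distance_ratio(bm, c("A", "B", "C", "D")), "intra")
  expect_error(distance_ratio(bm, c("A", "A")), "labels")
})

test_that("genome fraction and list comparison are exact on known lists", {
  layout <- genome_layout("chr1", 1e6)
  expect_equal(genome_fraction(GenomicRanges::GRanges(
    seqinfo = as_seqinfo(layout)), layout), 0)
  one <- gr0(data.frame(chrom = "chr1", start = 0, end = 1000), layout)
  expect_equal(genome_fraction(one, layout), 0.001)

  a <- gr0(data.frame(chrom = "chr1", start = c(0, 5000),
                      end = c(1000, 6000)), layout)
  cmp_same <- compare_lists(a, a, layout)
  expect_equal(cmp_same$unique_a + cmp_same$unique_b, 0L)
  expect_equal(cmp_same$shared_a, 2L)
  expect_equal(cmp_same$bp_shared, 2000)

  b <- gr0(data.frame(chrom = "chr1", start = 20000, end = 21000), layout)
  cmp_disj <- compare_lists(a, b, layout)
  expect_equal(cmp_disj$shared_a + cmp_disj$shared_b, 0L)

  set.seed(113)
  for (i in 1:5) {
    la <- rand_intervals(layout, 20, max_width = 2000)
    lb <- rand_intervals(layout, 20, max_width = 2000)
    cmp <- compare_lists(gr0(la, layout), gr0(lb, layout), layout)
    expect_equal(cmp$shared_a, sum(o_overlaps_any(la, lb)))
    expect_equal(cmp$shared_b, sum(o_overlaps_any(lb, la)))
  }
})

test_that("average profile is flat on constant signal and linear in it", {
  layout <- genome_layout("chr1", 10000)
  fr <- gr0(data.frame(chrom = "chr1", start = rep(0, 3), end = rep(10000, 3)),
            layout)
  track <- fragments_to_coverage(fr, layout)
  regions <- gr0(data.frame(chrom = "chr1", start = c(1000, 4000),
                            end = c(2000, 5000)), layout)
  prof <- average_profile(track, regions, layout, flank = 0, nbins = 20)
  expect_equal(unname(prof), rep(3, 20), ignore_attr = TRUE)

  set.seed(131)
  frags <- gr0(rand_intervals(layout, 300), layout)
  t1 <- fragments_to_coverage(frags, layout)
  t2 <- fragments_to_coverage(c(frags, frags), layout)  # doubled coverage
  p1 <- average_profile(t1, regions, layout, nbins = 10)
  p2 <- average_profile(t2, regions, layout, nbins = 10)
  expect_equal(unname(p2), unname(2 * p1), ignore_attr = TRUE)

  # single region, no flank: profile equals the region's binned coverage
  reg <- regions[1]
  v <- as.numeric(S4Vectors::window(t1[["chr1"]], 1001, 2000))
  oracle <- vapply(1:10, function(b) mean(v[(100 * (b - 1) + 1):(100 * b)]), 0)
  expect_equal(unname(average_profile(t1, reg, layout, nbins = 10)), oracle,
               ignore_attr = TRUE)

  # flank exceeding the chromosome is truncated and flagged
  edge <- gr0(data.frame(chrom = "chr1", start = 0, end = 100), layout)
  pe <- average_profile(t1, edge, layout, flank = 500, nbins = 5)
  expect_equal(attr(pe, "truncated"), 1L)
})

test_that("low-mappability flagging thresholds the regional mean", {
  layout <- genome_layout("chr1", 4000)
  regions <- gr0(data.frame(chrom = "chr1", start = c(0, 1100, 2200),
                            end = c(1000, 2100, 3200)), layout)
  sl <- as_suspect_list(regions, layout)
  # mappability: 0 over region 1, 1 over region 2, a 0.25/0.75 mix over 3
  mapp <- IRanges::RleList(chr1 = S4Vectors::Rle(
    c(0, 1, 0, 0.25, 0.75, 0), c(1000, 1100, 100, 500, 500, 800)))
  fl <- flag_low_mappability(sl, mapp, cutoff = 0.5)
  expect_equal(fl$regions$mean_mappability, c(0, 1, 0.5))
  expect_equal(fl$regions$low_mappability, c(TRUE, FALSE, FALSE))
})
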