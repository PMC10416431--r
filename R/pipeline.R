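#' Build a suspect list end-to-end from fragment inputs
#'
#' The full generation workflow: deduplicate each sample's fragments,
#' pile them into coverage, call peaks with the numeric-threshold caller
#' (default: stringent mode at threshold 0.001, the highest 0.1% of
#' signals), then build the consensus list (default: 1000 bp extension,
#' regions present in strictly more than 30% of samples). Also computes
#' the reproducibility curve of the extended peak sets.
#'
#' @param fragments named list of fragment [GenomicRanges::GRanges], or a
#'   character vector of fragment BED / BAM paths (>= 2 samples).
#' @param layout a [genome_layout].
#' @param threshold numeric peak-calling threshold.
#' @param mode `"stringent"` or `"relaxed"`.
#' @param extension consensus extension in bp.
#' @param min_frac reproducibility fraction (strict inequality).
#' @param include_chrM append the mitochondrial chromosome as a policy
#'   region.
#' @param dedup deduplicate fragments first.
#' @param out_dir optional directory; when given, writes
#'   `suspect_list.bed`, `suspect_list_annotated.tsv`,
#'   `reproducibility_curve.tsv` and `manifest.json` there.
#' @return A `suspect_list` with the `repro_curve` attached as element
#'   `curve` and per-sample peak counts as `peak_counts`.
#' @export
run_build <- function(fragments, layout, threshold = 0.001,
                      mode = "stringent", extension = 1000,
                      min_frac = 0.30, include_chrM = TRUE, dedup = TRUE,
                      out_dir = NULL) {
  input_paths <- NULL
  if (is.character(fragments)) {
    input_paths <- fragments
    nm <- make.unique(sub("\\.(bed|bam)$", "", basename(fragments),
                          ignore.case = TRUE))
    fragments <- lapply(fragments, read_fragments, layout = layout)
    names(fragments) <- nm
  }
  if (length(fragments) < 2L) stop("consensus requires multiple samples")
  if (is.null(names(fragments)))
    names(fragments) <- paste0("sample", seq_along(fragments))

  peak_sets <- lapply(fragments, function(fr) {
    if (dedup) fr <- dedup_fragments(fr)
    blocks <- find_signal_blocks(fragments_to_coverage(fr, layout), layout)
    call_peaks_numeric(blocks, threshold = threshold, mode = mode)
  })
  sl <- build_suspect_list(peak_sets, layout, extension = extension,
                           min_frac = min_frac, include_chrM = include_chrM)
  ext <- lapply(peak_sets, extend_peaks, extension = extension,
                layout = layout)
  sl$curve <- reproducibility_curve(ext, layout)
  sl$peak_counts <- vapply(peak_sets, length, 0L)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_suspect_list(sl, file.path(out_dir, "suspect_list.bed"))
    ann <- as.data.frame(sl)
    data.table::fwrite(ann, file.path(out_dir, "suspect_list_annotated.tsv"),
                       sep = "\t")
    write_repro_curve(sl$curve, file.path(out_dir,
                                          "reproducibility_curve.tsv"))
    write_manifest(
      file.path(out_dir, "manifest.json"),
      params = list(threshold = threshold, mode = mode,
                    extension = extension, min_frac = min_frac,
                    min_support = sl$params$min_support,
                    include_chrM = include_chrM, dedup = dedup,
                    n_samples = length(fragments)),
      inputs = input_paths)
  }
  sl
}

#' Evaluate a suspect list on a panel of samples
#'
#' Computes the validation statistics before and after suspect-list
#' filtering: per-sample FRIP over the list, Spearman correlation
#' matrices (genome-wide bins and restricted to the list regions), PCA
#' with scree, and (given target labels) the inter-/intra-target distance
#' ratio. The after-filtering side removes the fragments overlapping the
#' list and drops the bins overlapping the list from the summary matrix
#' (blacklist semantics; retaining emptied bins would inject concordant
#' ties into the rank statistics).
#'
#' @param fragments named list of fragment [GenomicRanges::GRanges].
#' @param sl a `suspect_list`.
#' @param layout a [genome_layout].
#' @param bin_size genome-wide bin width (default 10000).
#' @param labels optional per-sample target labels for the distance
#'   ratio.
#' @param out_dir optional directory for `evaluation.json`.
#' @return Object of class `suspect_eval` with elements `frip`
#'   (per-sample), `before` and `after` (each with `spearman`,
#'   `mean_spearman`, `pca`, and optionally `distance`), and
#'   `spearman_in_list` / `mean_spearman_in_list` (pre-filtering,
#'   list-restricted).
#' @export
run_evaluate <- function(fragments, sl, layout, bin_size = 10000,
                         labels = NULL, out_dir = NULL) {
  if (is.null(names(fragments)))
    names(fragments) <- paste0("sample", seq_along(fragments))
  frips <- vapply(fragments, function(fr) frip(fr, sl)$frip, 0)
  bm <- bin_counts(fragments, layout, bin_size = bin_size)
  filtered <- lapply(fragments, filter_fragments, sl = sl)
  # after-side matrix: filtered fragments, with bins overlapping the list
  # dropped (the blacklist treatment of the genome-summary tools; keeping
  # the emptied bins would add spurious concordant ties to rank statistics)
  bm_f <- drop_list_bins(bin_counts(filtered, layout, bin_size = bin_size),
                         sl)

  side <- function(b) {
    cm <- spearman_matrix(b)
    out <- list(spearman = cm,
                mean_spearman = mean(cm[upper.tri(cm)], na.rm = TRUE),
                pca = pca_scree(b))
    if (!is.null(labels)) out$distance <- distance_ratio(b, labels)
    out
  }
  before <- side(bm)
  after <- side(bm_f)
  in_list <- NULL
  if (length(sl$regions)) {
    bm_list <- bin_counts(fragments, layout, regions = sl$regions)
    in_list <- spearman_matrix(bm_list)
  }
  out <- structure(list(
    frip = frips, before = before, after = after,
    spearman_in_list = in_list,
    mean_spearman_in_list = if (!is.null(in_list))
      mean(in_list[upper.tri(in_list)], na.rm = TRUE) else NA_real_,
    bin_size = bin_size, labels = labels), class = "suspect_eval")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rep <- list(
      frip = as.list(frips),
      mean_spearman_before = before$mean_spearman,
      mean_spearman_after = after$mean_spearman,
      mean_spearman_in_list = out$mean_spearman_in_list,
      pc1_percent_before = before$pca$percent_variance[1],
      pc1_percent_after = after$pca$percent_variance[1],
      bin_size = bin_size)
    if (!is.null(labels)) {
      rep$distance_ratio_before <- before$distance$ratio
      rep$distance_ratio_after <- after$distance$ratio
    }
    jsonlite::write_json(rep, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.suspect_eval <- function(x, ...) {
  cat("suspect-list evaluation (", length(x$frip), " samples, bin ",
      x$bin_size, " bp)\n", sep = "")
  cat(sprintf("  FRIP over list:        mean %.3f (range %.3f-%.3f)\n",
              mean(x$frip), min(x$frip), max(x$frip)))
  cat(sprintf("  mean Spearman, genome: %.3f before -> %.3f after filtering\n",
              x$before$mean_spearman, x$after$mean_spearman))
  if (!is.na(x$mean_spearman_in_list))
    cat(sprintf("  mean Spearman in list: %.3f\n", x$mean_spearman_in_list))
  cat(sprintf("  PC1 %% variance:        %.1f before -> %.1f after\n",
              x$before$pca$percent_variance[1],
              x$after$pca$percent_variance[1]))
  if (!is.null(x$before$distance))
    cat(sprintf("  inter:intra distance:  %.2f:1 before -> %.2f:1 after\n",
                x$before$distance$ratio, x$after$distance$ratio))
  invisible(x)
}

drop_list_bins <- function(bm, sl) {
  regions <- suspect_regions(sl)
  if (length(regions) == 0L) return(bm)
  drop <- GenomicRanges::countOverlaps(bm$bins, regions,
                                       ignore.strand = TRUE) > 0
  bm$bins <- bm$bins[!drop]
  bm$counts <- bm$counts[, !drop, drop = FALSE]
  bm
}

# Run manifest: tool version, resolved parameters, input digests, timestamp.
write_manifest <- function(path, params, inputs = NULL) {
  digests <- if (is.null(inputs)) "in-memory" else
    as.list(tools::md5sum(inputs))
  jsonlite::write_json(
    list(tool = "suspectr",
         version = as.character(utils::packageVersion("suspectr")),
         parameters = params,
         input_md5 = digests,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
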