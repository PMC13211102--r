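#' Call candidate regions from a thresholded window profile
#'
#' Maximal runs of consecutive unmasked windows whose smoothed statistic
#' exceeds the threshold are merged into one region spanning from the first
#' window's start to the last window's end; overlapping windows (step <
#' window) merge naturally, and spatially overlapping spans from distinct
#' runs are merged so the returned set is disjoint. A masked or
#' sub-threshold window ends a run unless `max_gap_windows` allows bridging
#' (default 0, no bridging). Region coordinates snap to window boundaries.
#'
#' @param profile A window profile from [smooth_profile()].
#' @param threshold A numeric threshold, or a `bsa_thresholds` object (for
#'   the delta method the threshold at `level` is used).
#' @param level Confidence level picked from a delta `bsa_thresholds`.
#' @param source_method Label stored in the `source_method` column;
#'   defaults to the profile's statistic.
#' @param variant_type Label stored in the `variant_type` column.
#' @param max_gap_windows Number of consecutive sub-threshold (unmasked)
#'   windows a run may bridge.
#' @return A `candidate_regions` `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `source_method`, `variant_type`
#'   and `peak_value` (max window statistic inside); disjoint and sorted.
#' @export
call_regions <- function(profile, threshold, level = 0.95,
                         source_method = NULL, variant_type = "combined",
                         max_gap_windows = 0) {
  if (inherits(threshold, "bsa_thresholds")) {
    threshold <- if (threshold$method == "ed") threshold$threshold
    else {
      i <- match(TRUE, abs(threshold$levels - level) < 1e-9)
      if (is.na(i)) stop("requested level not present in thresholds")
      unname(threshold$thresholds[i])
    }
  }
  if (is.null(source_method))
    source_method <- if (identical(attr(profile, "stat"), "ed")) "ed" else "delta"
  sig <- !profile$masked & !is.na(profile$stat_mean) &
    profile$stat_mean > threshold
  out <- list()
  for (ch in unique(profile$chrom)) {
    wi <- which(profile$chrom == ch)
    s <- sig[wi]
    if (!any(s)) next
    # Run-length grouping with optional gap bridging over unmasked windows.
    grp <- integer(length(wi))
    cur <- 0L
    gap <- Inf
    for (j in seq_along(wi)) {
      if (s[j]) {
        if (gap > max_gap_windows) cur <- cur + 1L
        grp[j] <- cur
        gap <- 0L
      } else {
        gap <- if (profile$masked[wi[j]]) Inf else gap + 1L
      }
    }
    for (g in unique(grp[grp > 0])) {
      jj <- wi[grp == g & s]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = min(profile$start[jj]),
        end = max(profile$end[jj]),
        peak_value = max(profile$stat_mean[jj])
      )
    }
  }
  if (length(out) == 0) {
    regions <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), source_method = character(0),
                          variant_type = character(0), peak_value = numeric(0))
  } else {
    regions <- do.call(rbind, out)
    gr <- GenomicRanges::reduce(.regions_to_granges(regions))
    merged <- .granges_to_regions(gr)
    # Recompute peaks over the merged spans.
    merged$peak_value <- vapply(seq_len(nrow(merged)), function(i) {
      inside <- profile$chrom == merged$chrom[i] &
        profile$start < merged$end[i] & profile$end > merged$start[i] & sig
      max(profile$stat_mean[inside])
    }, 0)
    regions <- merged
    regions$source_method <- source_method
    regions$variant_type <- variant_type
    regions <- regions[, c("chrom", "start", "end", "source_method",
                           "variant_type", "peak_value")]
  }
  regions <- regions[order(regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  class(regions) <- c("candidate_regions", "data.frame")
  regions
}

.regions_to_granges <- function(regions, seqlevels = NULL) {
  sq <- if (is.null(seqlevels)) unique(regions$chrom) else seqlevels
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = sq),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

.granges_to_regions <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Combine candidate-region sets across methods and variant types
#'
#' Base-pair-level interval algebra over two or more region sets:
#' `intersect` returns the positions present in every set, `union` the
#' merged positions of any set. Output regions are disjoint and sorted;
#' under `intersect`, pieces shorter than `min_overlap_bp` are dropped.
#'
#' @param sets A non-empty list of `candidate_regions` (or data.frames with
#'   `chrom`, `start`, `end`).
#' @param mode `"intersect"` or `"union"`.
#' @param min_overlap_bp Minimum length of an intersection piece.
#' @param variant_type Label for the output `variant_type` column.
#' @return A `candidate_regions` data.frame with `source_method`
#'   `"combined"`; total spans in bp and Mb are attached as attributes
#'   `span_bp` and `span_mb`.
#' @export
combine_region_sets <- function(sets, mode = c("intersect", "union"),
                                min_overlap_bp = 1, variant_type = "combined") {
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) == 0 || is.data.frame(sets))
    stop("'sets' must be a non-empty list of region sets")
  all_chr <- unique(unlist(lapply(sets, function(s) as.character(s$chrom))))
  grs <- lapply(sets, function(s)
    GenomicRanges::reduce(.regions_to_granges(s, seqlevels = all_chr)))
  acc <- grs[[1]]
  for (g in grs[-1]) {
    acc <- if (mode == "intersect")
      GenomicRanges::intersect(acc, g, ignore.strand = TRUE)
    else GenomicRanges::union(acc, g, ignore.strand = TRUE)
  }
  if (mode == "intersect")
    acc <- acc[GenomicRanges::width(acc) >= min_overlap_bp]
  regions <- .granges_to_regions(acc)
  regions$source_method <- rep("combined", nrow(regions))
  regions$variant_type <- rep(variant_type, nrow(regions))
  regions$peak_value <- rep(NA_real_, nrow(regions))
  regions <- regions[order(regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  attr(regions, "span_bp") <- sum(regions$end - regions$start)
  attr(regions, "span_mb") <- round(sum(regions$end - regions$start) / 1e6, 2)
  class(regions) <- c("candidate_regions", "data.frame")
  regions
}

#' Summarize a candidate-region set
#'
#' Reports the region count, total span, the largest region, and each
#' chromosome's percent share of the total span
#' (`span_chr / span_total * 100`, two decimals). Spans in Mb use
#' `Mb = 1e6 bp`, two decimals. An empty set gives an all-zero summary.
#'
#' @param regions A `candidate_regions` data.frame.
#' @return A list with `n_regions`, `span_bp`, `span_mb`, `largest`
#'   (one-row data.frame or `NULL`), and `per_chrom` (a data.frame with
#'   `chrom`, `n_regions`, `span_bp`, `span_mb`, `share_pct`).
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(list(n_regions = 0L, span_bp = 0, span_mb = 0, largest = NULL,
                per_chrom = data.frame(chrom = character(0),
                                       n_regions = integer(0),
                                       span_bp = numeric(0),
                                       span_mb = numeric(0),
                                       share_pct = numeric(0))))
  }
  width <- regions$end - regions$start
  total <- sum(width)
  per <- stats::aggregate(list(span_bp = width),
                   by = list(chrom = regions$chrom), FUN = sum)
  per$n_regions <- as.integer(table(regions$chrom)[per$chrom])
  per$span_mb <- round(per$span_bp / 1e6, 2)
  per$share_pct <- round(per$span_bp / total * 100, 2)
  per <- per[order(-per$span_bp), c("chrom", "n_regions", "span_bp",
                                    "span_mb", "share_pct")]
  rownames(per) <- NULL
  list(
    n_regions = nrow(regions),
    span_bp = total,
    span_mb = round(total / 1e6, 2),
    largest = regions[which.max(width), , drop = FALSE],
    per_chrom = per
  )
}

#' Write candidate regions as BED
#'
#' BED uses the same 0-based half-open convention as the region tables.
#'
#' @param regions A `candidate_regions` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = paste0(regions$source_method, "_",
                                  regions$variant_type, "_",
                                  seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
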