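#' Per-site SNP-index, delta-index and Euclidean distance
#'
#' For each informative site the index of a bulk is the fraction of its
#' reads carrying the mutant-parent allele, so the index of the bulk
#' selected for the mutant phenotype rises towards 1 near a causal locus.
#' `delta_index` is `index_high - index_low` (signed; thresholding uses its
#' absolute value) and `ed` is the Euclidean distance between the two
#' bulks' allele-frequency vectors over both alleles, optionally raised to
#' `ed_power`. For a biallelic site `ed = (sqrt(2) * |delta_index|)^ed_power`.
#'
#' @param variants An informative-site variant table
#'   (see [select_informative_sites()]).
#' @param ed_power Exponent applied to the ED statistic (1 keeps the plain
#'   distance; 4 or 5 are common peak-sharpening choices).
#' @return A `data.frame` with columns `chrom`, `pos`, `variant_type`,
#'   `depth_low`, `depth_high`, `index_low`, `index_high`, `delta_index`
#'   and `ed`. Sites with zero depth in either bulk are skipped with a
#'   message.
#' @export
compute_indices <- function(variants, ed_power = 1) {
  mut_is_alt <- sub("|", "/", variants$gt_parent_mut, fixed = TRUE) %in%
    c("1/1")
  mut_low <- ifelse(mut_is_alt, variants$ad_alt_bulk_low, variants$ad_ref_bulk_low)
  mut_high <- ifelse(mut_is_alt, variants$ad_alt_bulk_high, variants$ad_ref_bulk_high)
  depth_low <- variants$ad_ref_bulk_low + variants$ad_alt_bulk_low
  depth_high <- variants$ad_ref_bulk_high + variants$ad_alt_bulk_high
  ok <- depth_low > 0 & depth_high > 0
  if (any(!ok))
    message(sum(!ok), " sites with zero bulk depth skipped")
  idx_low <- mut_low[ok] / depth_low[ok]
  idx_high <- mut_high[ok] / depth_high[ok]
  delta <- idx_high - idx_low
  out <- data.frame(
    chrom = variants$chrom[ok], pos = variants$pos[ok],
    variant_type = variants$variant_type[ok],
    depth_low = depth_low[ok], depth_high = depth_high[ok],
    index_low = idx_low, index_high = idx_high,
    delta_index = delta,
    ed = (sqrt(2) * abs(delta))^ed_power
  )
  attr(out, "ed_power") <- ed_power
  rownames(out) <- NULL
  out
}

# Sliding-window grid, 0-based half-open, spacing = step_size.
.window_grid <- function(chrom_lengths, window_size, step_size) {
  if (window_size < step_size)
    stop("'window_size' must be >= 'step_size'")
  grids <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_size)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  })
  do.call(rbind, grids)
}

# For each window, indices of the sites it contains (start <= pos-1 < end).
.window_site_map <- function(windows, chrom, pos) {
  hits_by_window <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(chrom == ch)
    if (length(si) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = windows$start[wi] + 1L, end = windows$end[wi]),
      IRanges::IRanges(start = pos[si], width = 1L)
    )
    sp <- split(si[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    hits_by_window[wi[as.integer(names(sp))]] <- sp
  }
  hits_by_window
}

#' Smooth a per-site statistic in sliding windows
#'
#' Averages a per-site statistic (`|delta_index|` or `ed`) over a sliding
#' window along each chromosome (defaults: 1 Mb windows advanced in 100 kb
#' steps). Windows are 0-based half-open and a site at 1-based position
#' `pos` belongs to windows with `start <= pos - 1 < end`. Windows holding
#' fewer than `min_variants` sites are masked: they are excluded from
#' thresholding and never seed candidate regions.
#'
#' @param indexed Output of [compute_indices()].
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param stat `"delta"` (uses `|delta_index|`) or `"ed"`.
#' @param window_size Window width in bp.
#' @param step_size Step between window starts in bp; must not exceed
#'   `window_size`.
#' @param min_variants Minimum sites per window; emptier windows are masked.
#' @param agg Window aggregation, arithmetic `"mean"` (default) or
#'   `"median"`.
#' @return A window profile `data.frame`: `chrom`, `start`, `end`,
#'   `stat_mean`, `n_variants`, `masked`; the statistic and grid parameters
#'   are attached as attributes.
#' @export
smooth_profile <- function(indexed, chrom_lengths,
                           stat = c("delta", "ed"),
                           window_size = 1e6, step_size = 1e5,
                           min_variants = 10,
                           agg = c("mean", "median")) {
  stat <- match.arg(stat)
  agg <- match.arg(agg)
  aggfun <- if (agg == "mean") mean else stats::median
  windows <- .window_grid(chrom_lengths, window_size, step_size)
  values <- if (stat == "delta") abs(indexed$delta_index) else indexed$ed
  map <- .window_site_map(windows, indexed$chrom, indexed$pos)
  windows$n_variants <- vapply(map, length, 0L)
  windows$stat_mean <- vapply(map, function(i)
    if (length(i) == 0) NA_real_ else aggfun(values[i]), 0)
  windows$masked <- windows$n_variants < min_variants
  windows <- windows[, c("chrom", "start", "end", "stat_mean",
                         "n_variants", "masked")]
  rownames(windows) <- NULL
  attr(windows, "stat") <- stat
  attr(windows, "window_size") <- window_size
  attr(windows, "step_size") <- step_size
  attr(windows, "agg") <- agg
  windows
}

#' Delta-index significance thresholds by null simulation
#'
#' Builds the null distribution of `|delta_index|` for two undifferentiated
#' bulks and returns its upper quantiles at the requested confidence
#' levels. The default null is depth- and bulk-aware, in the style of
#' QTL-seq confidence intervals: per site and iteration, each bulk's allele
#' frequency is drawn from F2 segregation in a bulk of `bulk_size`
#' individuals (`Binomial(2 * bulk_size, 0.5) / (2 * bulk_size)`), then
#' mutant-allele reads are drawn as `Binomial(observed depth, f)`
#' independently per bulk. Setting `bulk_size = Inf` fixes both allele
#' frequencies at 0.5, leaving read sampling as the only noise source.
#'
#' With `pool = "site"` (default) null values are pooled at the site level
#' across all sites and iterations; the windowed observed profile is then
#' compared against this per-site quantile, which is deliberately
#' conservative because window averaging shrinks noise in the observed
#' track but not in the threshold. With `pool = "window"` the null values
#' are first averaged over the same sliding-window grid as the observed
#' profile and the quantiles are taken over pooled window values
#' (`chrom_lengths` is then required).
#'
#' Quantiles use the inverse empirical distribution function (`type = 1`),
#' so for discrete nulls they converge to the exact distribution quantile.
#'
#' @param indexed Output of [compute_indices()] (depths are taken from it).
#' @param n_permutations Number of null iterations (values below 100 log a
#'   warning).
#' @param levels Confidence levels for the reported thresholds.
#' @param seed Integer seed; thresholds are deterministic given it.
#' @param bulk_size Individuals per bulk for the segregation part of the
#'   null; `Inf` disables it.
#' @param pool `"site"` or `"window"` pooling of null values.
#' @param chrom_lengths,window_size,step_size,min_variants Window grid for
#'   `pool = "window"`, as in [smooth_profile()].
#' @return An object of class `bsa_thresholds` with elements `method`
#'   (`"delta"`), `thresholds` (named by confidence level), and the null
#'   settings.
#' @export
delta_threshold_permutation <- function(indexed, n_permutations = 1000,
                                        levels = c(0.90, 0.95, 0.99),
                                        seed = 1L, bulk_size = 32,
                                        pool = c("site", "window"),
                                        chrom_lengths = NULL,
                                        window_size = 1e6, step_size = 1e5,
                                        min_variants = 10) {
  pool <- match.arg(pool)
  if (n_permutations < 100)
    warning("fewer than 100 permutation iterations; thresholds will be noisy")
  stopifnot(all(levels > 0 & levels < 1))
  m <- nrow(indexed)
  if (m == 0) stop("no sites to permute")
  set.seed(seed)
  dl <- indexed$depth_low
  dh <- indexed$depth_high
  sim_delta <- function(n_iter) {
    k <- m * n_iter
    f_of <- function() {
      if (is.finite(bulk_size))
        stats::rbinom(k, 2 * bulk_size, 0.5) / (2 * bulk_size)
      else 0.5
    }
    low <- stats::rbinom(k, rep.int(dl, n_iter), f_of()) / rep.int(dl, n_iter)
    high <- stats::rbinom(k, rep.int(dh, n_iter), f_of()) / rep.int(dh, n_iter)
    matrix(abs(high - low), nrow = m)
  }
  if (pool == "site") {
    chunk <- max(1L, min(n_permutations, floor(4e6 / m)))
    vals <- vector("list", ceiling(n_permutations / chunk))
    done <- 0L
    for (i in seq_along(vals)) {
      nit <- min(chunk, n_permutations - done)
      vals[[i]] <- as.numeric(sim_delta(nit))
      done <- done + nit
    }
    pooled <- unlist(vals, use.names = FALSE)
  } else {
    if (is.null(chrom_lengths))
      stop("'chrom_lengths' is required for pool = \"window\"")
    windows <- .window_grid(chrom_lengths, window_size, step_size)
    map <- .window_site_map(windows, indexed$chrom, indexed$pos)
    keep <- vapply(map, length, 0L) >= min_variants
    if (!any(keep)) stop("no unmasked windows for pool = \"window\"")
    idx <- unlist(map[keep], use.names = FALSE)
    wid <- rep.int(seq_len(sum(keep)), vapply(map[keep], length, 0L))
    A <- Matrix::sparseMatrix(i = wid, j = idx, x = 1, dims = c(sum(keep), m))
    A <- A / Matrix::rowSums(A)
    chunk <- max(1L, min(n_permutations, floor(2e6 / m)))
    vals <- list()
    done <- 0L
    while (done < n_permutations) {
      nit <- min(chunk, n_permutations - done)
      vals[[length(vals) + 1L]] <- as.numeric(A %*% sim_delta(nit))
      done <- done + nit
    }
    pooled <- unlist(vals, use.names = FALSE)
  }
  thr <- stats::quantile(pooled, probs = levels, type = 1, names = FALSE)
  structure(list(method = "delta",
                 thresholds = stats::setNames(thr, format(levels)),
                 levels = levels, n_permutations = n_permutations,
                 pool = pool, bulk_size = bulk_size, seed = seed),
            class = "bsa_thresholds")
}

#' Genome-wide ED threshold: median + k standard deviations
#'
#' The ED significance threshold is the median of the smoothed window
#' values plus `k` sample standard deviations (denominator `n - 1`),
#' computed genome-wide over all unmasked windows.
#'
#' @param profile An ED window profile from [smooth_profile()].
#' @param k Number of standard deviations above the median (default 3).
#' @return An object of class `bsa_thresholds` with elements `method`
#'   (`"ed"`), `threshold`, `median`, `sd` and `k`.
#' @export
ed_threshold <- function(profile, k = 3) {
  vals <- profile$stat_mean[!profile$masked]
  if (length(vals) < 2)
    stop("ed_threshold requires at least 2 unmasked windows")
  med <- stats::median(vals)
  s <- stats::sd(vals)
  structure(list(method = "ed", threshold = med + k * s,
                 median = med, sd = s, k = k),
            class = "bsa_thresholds")
}

#' @exportS3Method base::print
print.bsa_thresholds <- function(x, ...) {
  if (x$method == "delta") {
    cat("delta-index thresholds (", x$pool, "-pooled null, ",
        x$n_permutations, " iterations):\n", sep = "")
    print(round(x$thresholds, 4))
  } else {
    cat(sprintf("ED threshold: median %.4f + %g x SD %.4f = %.4f\n",
                x$median, x$k, x$sd, x$threshold))
  }
  invisible(x)
}
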