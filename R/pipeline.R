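#' Run the full BSA-seq association pipeline
#'
#' Chains hard filtering, informative-site selection, per-site index
#' computation, sliding-window smoothing, thresholding and region calling
#' for the delta-index and ED methods, separately per variant type (SNPs
#' and InDels), and combines the resulting region sets by base-pair
#' interval algebra (default: strict intersection of every method x type
#' set).
#'
#' @param variants A raw variant table (see [read_bsa_vcf()] or
#'   [simulate_f2()]).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param filter A [filter_config()].
#' @param variant_types Variant types analysed separately; types with no
#'   sites are skipped with a message. Use `"combined"` to pool all sites
#'   into one set.
#' @param window_size,step_size,min_variants Window grid, as in
#'   [smooth_profile()].
#' @param ed_power ED exponent, as in [compute_indices()].
#' @param level Delta-index confidence level used for region calling.
#' @param n_permutations,bulk_size,pool Null settings for
#'   [delta_threshold_permutation()].
#' @param ed_k SD multiplier of [ed_threshold()].
#' @param combine_mode `"intersect"` (default) or `"union"` combination of
#'   the per-method/type region sets.
#' @param seed Seed for the threshold null simulation.
#' @return A list: `variants` (informative sites), `indices`, `profiles`,
#'   `thresholds`, `regions` (per `<method>_<type>`), `combined`
#'   (candidate regions), and `summary` (from [summarize_regions()]).
#' @export
run_bsa_pipeline <- function(variants, chrom_lengths,
                             filter = filter_config(),
                             variant_types = c("SNP", "InDel"),
                             window_size = 1e6, step_size = 1e5,
                             min_variants = 10, ed_power = 1,
                             level = 0.95, n_permutations = 1000,
                             bulk_size = 32, pool = c("site", "window"),
                             ed_k = 3,
                             combine_mode = c("intersect", "union"),
                             seed = 1L) {
  pool <- match.arg(pool)
  combine_mode <- match.arg(combine_mode)
  hf <- apply_hard_filters(variants, filter)
  inf <- select_informative_sites(hf, filter)
  profiles <- list()
  thresholds <- list()
  regions <- list()
  indices <- list()
  for (vt in variant_types) {
    sub <- if (vt == "combined") inf else inf[inf$variant_type == vt, , drop = FALSE]
    if (nrow(sub) == 0) {
      message("no ", vt, " sites after filtering; type skipped")
      next
    }
    idx <- compute_indices(sub, ed_power = ed_power)
    indices[[vt]] <- idx
    p_delta <- smooth_profile(idx, chrom_lengths, stat = "delta",
                              window_size = window_size,
                              step_size = step_size,
                              min_variants = min_variants)
    p_ed <- smooth_profile(idx, chrom_lengths, stat = "ed",
                           window_size = window_size,
                           step_size = step_size,
                           min_variants = min_variants)
    t_delta <- delta_threshold_permutation(
      idx, n_permutations = n_permutations,
      levels = sort(unique(c(0.90, 0.95, 0.99, level))),
      seed = seed, bulk_size = bulk_size, pool = pool,
      chrom_lengths = chrom_lengths, window_size = window_size,
      step_size = step_size, min_variants = min_variants)
    t_ed <- ed_threshold(p_ed, k = ed_k)
    profiles[[paste0("delta_", vt)]] <- p_delta
    profiles[[paste0("ed_", vt)]] <- p_ed
    thresholds[[paste0("delta_", vt)]] <- t_delta
    thresholds[[paste0("ed_", vt)]] <- t_ed
    regions[[paste0("delta_", vt)]] <-
      call_regions(p_delta, t_delta, level = level,
                   source_method = "delta", variant_type = vt)
    regions[[paste0("ed_", vt)]] <-
      call_regions(p_ed, t_ed, source_method = "ed", variant_type = vt)
  }
  if (length(regions) == 0) stop("no variant type yielded any sites")
  combined <- combine_region_sets(regions, mode = combine_mode)
  list(variants = inf, indices = indices, profiles = profiles,
       thresholds = thresholds, regions = regions, combined = combined,
       summary = summarize_regions(combined))
}

#' Manhattan-style plot of a smoothed BSA profile
#'
#' Draws the window-averaged statistic along each chromosome with an
#' optional threshold line and shaded candidate regions.
#'
#' @param profile A window profile from [smooth_profile()].
#' @param threshold Optional numeric or `bsa_thresholds`; delta thresholds
#'   draw one line per confidence level.
#' @param regions Optional `candidate_regions` to shade.
#' @return A ggplot object.
#' @export
plot_bsa_profile <- function(profile, threshold = NULL, regions = NULL) {
  df <- profile[!profile$masked, , drop = FALSE]
  df$mid <- (df$start + df$end) / 2 / 1e6
  stat <- attr(profile, "stat")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$stat_mean)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mb)",
      y = if (identical(stat, "ed")) "windowed ED"
          else "windowed |Δ index|"
    ) +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "bsa_thresholds")) {
      if (threshold$method == "ed") threshold$threshold else threshold$thresholds
    } else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "red")
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    rg <- as.data.frame(regions)
    rg$xmin <- rg$start / 1e6
    rg$xmax <- rg$end / 1e6
    p <- p + ggplot2::geom_rect(
      data = rg,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  p
}
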