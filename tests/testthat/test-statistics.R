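# Small end-to-end helper: simulate and index informative sites.
sim_indexed <- function(seed, chroms = c(chr1 = 1e7), density = 100,
                        qtls = NULL, depth = 30, ...) {
  if (is.null(qtls))
    qtls <- data.frame(chrom = names(chroms)[1],
                       pos = floor(chroms[[1]] / 2), effect = 3)
  cfg <- simulation_config(chromosomes = chroms, marker_density = density,
                           qtls = qtls, population_size = 300,
                           bulk_size = 32, mean_depth = depth,
                           indel_fraction = 0, seed = seed, ...)
  sim <- simulate_f2(cfg)
  idx <- compute_indices(suppressMessages(select_informative_sites(
    suppressMessages(apply_hard_filters(sim$variants)))))
  list(idx = idx, cfg = cfg, truth = sim$truth)
}

test_that("per-site indices follow the allele-fraction arithmetic", {
  v <- make_variants(
    make_variant(pos = 1L, ad_ref_bulk_high = 3L, ad_alt_bulk_high = 27L,
                 ad_ref_bulk_low = 27L, ad_alt_bulk_low = 3L),
    make_variant(pos = 2L, ad_ref_bulk_high = 15L, ad_alt_bulk_high = 15L,
                 ad_ref_bulk_low = 10L, ad_alt_bulk_low = 10L),
    make_variant(pos = 3L, ad_ref_bulk_high = 0L, ad_alt_bulk_high = 30L,
                 ad_ref_bulk_low = 30L, ad_alt_bulk_low = 0L)
  )
  idx <- compute_indices(v)
  expect_equal(idx$index_high, c(0.9, 0.5, 1.0))
  expect_equal(idx$index_low, c(0.1, 0.5, 0.0))
  expect_equal(idx$delta_index, c(0.8, 0.0, 1.0))
  expect_equal(idx$ed, c(sqrt(0.8^2 + 0.8^2), 0, sqrt(2)), tolerance = 1e-12)
})

test_that("polarization follows the mutant parent's allele", {
  # When the mutant parent is homozygous REF, the index counts REF reads.
  v <- make_variant(gt_parent_wt = "1/1", gt_parent_mut = "0/0",
                    ad_ref_bulk_high = 27L, ad_alt_bulk_high = 3L,
                    ad_ref_bulk_low = 3L, ad_alt_bulk_low = 27L)
  idx <- compute_indices(v)
  expect_equal(idx$index_high, 0.9)
  expect_equal(idx$delta_index, 0.8)
})

test_that("ed equals sqrt(2)*|delta| on biallelic sites, any ed_power", {
  s <- sim_indexed(4, chroms = c(chr1 = 2e6), density = 200)
  expect_equal(s$idx$ed, sqrt(2) * abs(s$idx$delta_index), tolerance = 1e-12)
  v <- suppressMessages(select_informative_sites(
    simulate_f2(s$cfg)$variants))
  idx4 <- compute_indices(v, ed_power = 4)
  expect_equal(idx4$ed, (sqrt(2) * abs(idx4$delta_index))^4,
               tolerance = 1e-12)
})

test_that("windowed means equal a brute-force recomputation", {
  s <- sim_indexed(8, chroms = c(chr1 = 3e6, chr2 = 2e6), density = 80)
  for (stat in c("delta", "ed")) {
    prof <- smooth_profile(s$idx, c(chr1 = 3e6, chr2 = 2e6), stat = stat,
                           window_size = 1e6, step_size = 2.5e5,
                           min_variants = 1)
    vals <- if (stat == "delta") abs(s$idx$delta_index) else s$idx$ed
    oracle <- oracle_window_means(s$idx, vals, c(chr1 = 3e6, chr2 = 2e6),
                                  1e6, 2.5e5)
    expect_equal(prof$chrom, oracle$chrom)
    expect_equal(prof$start, oracle$start)
    expect_equal(prof$stat_mean, oracle$stat_mean)
    expect_equal(prof$n_variants, oracle$n_variants)
  }
})

test_that("windows honour the boundary convention and masking", {
  idx <- data.frame(chrom = "chr1", pos = c(1L, 100000L, 100001L),
                    delta_index = c(0.2, 0.4, 0.6), ed = 0)
  prof <- smooth_profile(idx, c(chr1 = 2e5), stat = "delta",
                         window_size = 1e5, step_size = 1e5,
                         min_variants = 1)
  # pos 1 and 100000 fall in [0, 1e5); pos 100001 in [1e5, 2e5)
  expect_equal(prof$stat_mean, c(mean(c(0.2, 0.4)), 0.6))
  one <- smooth_profile(idx, c(chr1 = 2e5), stat = "delta",
                        window_size = 2e5, step_size = 2e5,
                        min_variants = 1)
  expect_equal(one$stat_mean[1], 0.4)  # mean of 0.2, 0.4, 0.6
  masked <- smooth_profile(idx, c(chr1 = 4e5), stat = "delta",
                           window_size = 1e5, step_size = 1e5,
                           min_variants = 1)
  expect_true(all(masked$masked[3:4]))  # windows with zero sites
  expect_error(smooth_profile(idx, c(chr1 = 2e5), window_size = 1e4,
                              step_size = 1e5), "window_size")
})

test_that("delta thresholds are monotone in level and reproducible by seed", {
  s <- sim_indexed(6, chroms = c(chr1 = 2e6), density = 150)
  t1 <- delta_threshold_permutation(s$idx, 300, seed = 5, bulk_size = 32)
  t2 <- delta_threshold_permutation(s$idx, 300, seed = 5, bulk_size = 32)
  expect_identical(t1$thresholds, t2$thresholds)
  expect_true(all(diff(t1$thresholds) >= 0))
  expect_warning(delta_threshold_permutation(s$idx, 50, seed = 1),
                 "fewer than 100")
})

test_that("read-sampling thresholds vanish as depth grows", {
  idx <- data.frame(chrom = "chr1", pos = 1:200, depth_low = 10000L,
                    depth_high = 10000L, delta_index = 0, ed = 0)
  thr <- delta_threshold_permutation(idx, 500, seed = 3, bulk_size = Inf)
  expect_lt(thr$thresholds[["0.95"]], 0.03)
})

test_that("pooled null quantiles match the exact 31x31 enumeration at depth 30", {
  idx <- data.frame(chrom = "chr1", pos = 1:500, depth_low = 30L,
                    depth_high = 30L, delta_index = 0, ed = 0)
  thr <- delta_threshold_permutation(idx, 1000, seed = 19, bulk_size = Inf,
                                     levels = c(0.90, 0.95, 0.99))
  dist <- exact_abs_delta_null(30)
  expect_equal(unname(thr$thresholds),
               vapply(c(0.90, 0.95, 0.99), function(q)
                 exact_quantile(dist, q), 0),
               tolerance = 1e-12)
})

test_that("permutation thresholds converge across reseeds", {
  s <- sim_indexed(12, chroms = c(chr1 = 1e6), density = 300)
  q95 <- vapply(1:10, function(r)
    delta_threshold_permutation(s$idx, 1000, seed = r,
                                bulk_size = 32)$thresholds[["0.95"]], 0)
  expect_lt(stats::sd(q95) / mean(q95), 0.05)
})

test_that("window-pooled null is available and behaves sanely", {
  s <- sim_indexed(14, chroms = c(chr1 = 2e6), density = 200)
  thr <- delta_threshold_permutation(
    s$idx, 200, seed = 7, bulk_size = Inf, pool = "window",
    chrom_lengths = c(chr1 = 2e6), window_size = 5e5, step_size = 2.5e5,
    min_variants = 5)
  # Window averaging shrinks the null spread below the site-level one.
  site <- delta_threshold_permutation(s$idx, 200, seed = 7,
                                      bulk_size = Inf)
  expect_lt(thr$thresholds[["0.95"]], site$thresholds[["0.95"]])
})

test_that("ED threshold follows the median + k*SD convention", {
  prof <- data.frame(chrom = "chr1", start = 0:4 * 1e5,
                     end = 1:5 * 1e5, stat_mean = c(0, 0, 0, 0, 10),
                     n_variants = 20L, masked = FALSE)
  thr <- ed_threshold(prof)
  x <- c(0, 0, 0, 0, 10)
  sd_manual <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(thr$threshold, 0 + 3 * sd_manual)
  # all equal -> threshold equals the common value
  prof$stat_mean <- rep(0.7, 5)
  expect_equal(ed_threshold(prof)$threshold, 0.7)
  # translation equivariance
  prof$stat_mean <- c(0.1, 0.5, 0.3, 0.2, 0.4)
  base <- ed_threshold(prof)$threshold
  prof$stat_mean <- prof$stat_mean + 2
  expect_equal(ed_threshold(prof)$threshold, base + 2)
  prof$masked <- c(FALSE, rep(TRUE, 4))
  expect_error(ed_threshold(prof), "unmasked")
})

test_that("profile maxima localize a strong QTL within 1 Mb", {
  hits <- vapply(1:20, function(s) {
    si <- sim_indexed(100 + s)
    ok <- TRUE
    for (stat in c("delta", "ed")) {
      prof <- smooth_profile(si$idx, c(chr1 = 1e7), stat = stat)
      prof <- prof[!prof$masked, ]
      w <- prof[which.max(prof$stat_mean), ]
      qpos <- 5e6 - 1
      dist <- max(0, w$start - qpos, qpos - (w$end - 1))
      ok <- ok && dist <= 1e6
    }
    ok
  }, TRUE)
  expect_gte(sum(hits), 19)
})
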