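#' Simulation configuration for an F2 bulk-segregant experiment
#'
#' Bundles and validates the parameters of the forward simulator. Defaults
#' emulate a desk-scale version of a soybean-type BSA-seq design: a 20
#' chromosome genome, an F2 of 322 individuals segregating for a quantitative
#' trait with one additive QTL, extreme bulks of 32 individuals each, and
#' pooled short-read sequencing at ~30x per bulk.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param marker_density Informative markers per Mb.
#' @param qtls `data.frame` with columns `chrom`, `pos` (bp) and `effect`
#'   (additive effect per mutant allele, in trait units).
#' @param trait_baseline Trait value of the wild-type homozygote.
#' @param env_sd Environmental (residual) standard deviation, trait units.
#' @param population_size Number of F2 individuals.
#' @param bulk_size Individuals per extreme bulk (truncation selection).
#' @param mean_depth Mean sequencing depth per site per bulk.
#' @param depth_dispersion Negative binomial dispersion (`size`) of per-site
#'   depth; `Inf` gives Poisson depths.
#' @param error_rate Per-read allele-flip probability, in `[0, 0.5)`.
#' @param cm_per_mb Recombination rate in cM per Mb (Haldane map function,
#'   no interference).
#' @param indel_fraction Fraction of simulated markers emitted as InDels
#'   (the rest are SNPs).
#' @param parent_depth Sequencing depth of the error-free parental samples.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(chromosomes = stats::setNames(rep(10e6, 20), sprintf("chr%02d", 1:20)),
                              marker_density = 50,
                              qtls = data.frame(chrom = "chr18", pos = 5e6, effect = 3),
                              trait_baseline = 17.98,
                              env_sd = 1,
                              population_size = 322,
                              bulk_size = 32,
                              mean_depth = 30,
                              depth_dispersion = 8,
                              error_rate = 0.01,
                              cm_per_mb = 1,
                              indel_fraction = 0.15,
                              parent_depth = 60,
                              seed = 1L) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a named vector of lengths")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be positive")
  if (marker_density <= 0) stop("'marker_density' must be positive")
  stopifnot(is.data.frame(qtls))
  if (nrow(qtls) > 0) {
    if (!all(c("chrom", "pos", "effect") %in% names(qtls)))
      stop("'qtls' needs columns chrom, pos, effect")
    bad <- !(qtls$chrom %in% names(chromosomes)) |
      qtls$pos < 1 | qtls$pos > chromosomes[qtls$chrom]
    if (any(bad)) stop("all QTL positions must lie on declared chromosomes")
  }
  if (env_sd < 0) stop("'env_sd' must be non-negative")
  if (bulk_size > population_size / 2)
    stop("'bulk_size' must not exceed population_size / 2")
  if (mean_depth <= 0) stop("'mean_depth' must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("'error_rate' must be in [0, 0.5)")
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("'indel_fraction' must be in [0, 1]")
  if (cm_per_mb <= 0) stop("'cm_per_mb' must be positive")
  n_markers <- sum(pmax(1, round(marker_density * chromosomes / 1e6)))
  if (n_markers < 1) stop("configuration yields zero markers")
  structure(list(
    chromosomes = chromosomes, marker_density = marker_density, qtls = qtls,
    trait_baseline = trait_baseline, env_sd = env_sd,
    population_size = as.integer(population_size),
    bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, error_rate = error_rate,
    cm_per_mb = cm_per_mb, indel_fraction = indel_fraction,
    parent_depth = as.integer(parent_depth), seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [simulation_config()];
#' `chromosomes` is a mapping of name to length and `qtls` a list of
#' `{chrom, pos, effect}` mappings.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chromosomes)) y$chromosomes <- unlist(y$chromosomes)
  if (!is.null(y$qtls))
    y$qtls <- do.call(rbind, lapply(y$qtls, as.data.frame))
  do.call(simulation_config, y)
}

# One chromosome of F2 gametes: n x M 0/1 matrix, Markov chain along the
# marker map with Haldane recombination fractions between adjacent markers.
.sim_gametes <- function(n, pos, cm_per_mb) {
  m <- length(pos)
  g <- matrix(0L, n, m)
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1) {
    d_morgan <- diff(pos) / 1e6 * cm_per_mb / 100
    r <- 0.5 * (1 - exp(-2 * d_morgan))
    for (j in 2:m) {
      rec <- stats::rbinom(n, 1L, r[j - 1])
      g[, j] <- (g[, j - 1] + rec) %% 2L
    }
  }
  g
}

.rand_alleles <- function(m, indel_fraction) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  type <- rep("SNP", m)
  is_indel <- stats::runif(m) < indel_fraction
  if (any(is_indel)) {
    ins <- is_indel & stats::runif(m) < 0.5
    del <- is_indel & !ins
    extra <- sample(bases, m, replace = TRUE)
    alt[ins] <- paste0(ref[ins], extra[ins])
    ref[del] <- paste0(ref[del], extra[del])
    alt[del] <- substr(ref[del], 1, 1)
    type[is_indel] <- "InDel"
  }
  list(ref = ref, alt = alt, type = type)
}

.gt_from_fraction <- function(frac) {
  gt <- rep("0/1", length(frac))
  gt[frac < 0.2] <- "0/0"
  gt[frac > 0.8] <- "1/1"
  gt[is.na(frac)] <- "./."
  gt
}

#' Forward-simulate an F2 bulk-segregant sequencing experiment
#'
#' Simulates marker genotypes for each F2 individual by Mendelian segregation
#' with recombination between adjacent markers (Haldane map function at a
#' fixed cM/Mb rate), computes phenotypes as
#' `trait_baseline + sum(effect * dosage) + N(0, env_sd)`, forms the high and
#' low bulks by truncation selection of the `bulk_size` most extreme
#' individuals (ties broken by individual id, so the draw is reproducible),
#' and samples pooled reads per site per bulk: total depth is negative
#' binomial with the configured mean and dispersion and mutant-allele reads
#' are binomial at the bulk allele frequency perturbed by `error_rate`.
#' Parents are emitted error-free and homozygous for opposite alleles
#' (the wild-type parent carries the REF allele). QTL positions are included
#' in the marker map so each QTL coincides with a simulated variant.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `variants` (a variant table, one row per
#'   site, with GATK-style site annotations and per-role genotype and
#'   allele-depth columns) and `truth` (class `sim_truth`: QTLs, phenotypes,
#'   QTL genotype dosages, bulk memberships, and per-site true bulk allele
#'   frequencies before read sampling).
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$population_size

  marker_list <- lapply(names(config$chromosomes), function(ch) {
    len <- config$chromosomes[[ch]]
    m <- max(1L, round(config$marker_density * len / 1e6))
    pos <- sort(sample.int(len, m))
    pos <- sort(unique(c(pos, config$qtls$pos[config$qtls$chrom == ch])))
    data.frame(chrom = ch, pos = pos)
  })
  markers <- do.call(rbind, marker_list)
  if (nrow(markers) == 0) stop("configuration yields zero markers")

  # Dosage of the mutant-parent allele (0/1/2) per individual x marker.
  dosage <- matrix(0L, n, nrow(markers))
  off <- 0L
  for (mk in marker_list) {
    m <- nrow(mk)
    dosage[, off + seq_len(m)] <-
      .sim_gametes(n, mk$pos, config$cm_per_mb) +
      .sim_gametes(n, mk$pos, config$cm_per_mb)
    off <- off + m
  }

  qtl_idx <- integer(0)
  if (nrow(config$qtls) > 0)
    qtl_idx <- match(paste(config$qtls$chrom, config$qtls$pos),
                     paste(markers$chrom, markers$pos))
  genetic <- if (length(qtl_idx) > 0)
    as.numeric(dosage[, qtl_idx, drop = FALSE] %*% config$qtls$effect)
  else rep(0, n)
  phenotype <- config$trait_baseline + genetic +
    stats::rnorm(n, 0, config$env_sd)

  ids <- seq_len(n)
  bulk_low <- ids[order(phenotype, ids)][seq_len(config$bulk_size)]
  bulk_high <- ids[order(-phenotype, ids)][seq_len(config$bulk_size)]

  freq_low <- colMeans(dosage[bulk_low, , drop = FALSE]) / 2
  freq_high <- colMeans(dosage[bulk_high, , drop = FALSE]) / 2

  m <- nrow(markers)
  sample_reads <- function(freq) {
    depth <- if (is.finite(config$depth_dispersion))
      stats::rnbinom(m, size = config$depth_dispersion, mu = config$mean_depth)
    else stats::rpois(m, config$mean_depth)
    f <- freq * (1 - config$error_rate) + (1 - freq) * config$error_rate
    alt <- stats::rbinom(m, depth, f)
    list(ref = depth - alt, alt = alt)
  }
  rd_low <- sample_reads(freq_low)
  rd_high <- sample_reads(freq_high)

  al <- .rand_alleles(m, config$indel_fraction)
  variants <- data.frame(
    chrom = markers$chrom, pos = markers$pos,
    ref = al$ref, alt = al$alt, variant_type = al$type,
    qual = round(pmax(stats::rnorm(m, 60, 15), 0), 2),
    qd = round(pmax(stats::rnorm(m, 25, 8), 0), 2),
    mq = round(stats::rnorm(m, 55, 6), 2),
    fs = round(stats::rexp(m, 1 / 10), 3),
    n_alt_alleles = 1L + stats::rbinom(m, 1L, 0.01),
    gt_parent_wt = "0/0",
    ad_ref_parent_wt = config$parent_depth, ad_alt_parent_wt = 0L,
    gt_parent_mut = "1/1",
    ad_ref_parent_mut = 0L, ad_alt_parent_mut = config$parent_depth,
    gt_bulk_low = .gt_from_fraction(rd_low$alt / pmax(rd_low$ref + rd_low$alt, 1)),
    ad_ref_bulk_low = rd_low$ref, ad_alt_bulk_low = rd_low$alt,
    gt_bulk_high = .gt_from_fraction(rd_high$alt / pmax(rd_high$ref + rd_high$alt, 1)),
    ad_ref_bulk_high = rd_high$ref, ad_alt_bulk_high = rd_high$alt,
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL

  truth <- structure(list(
    qtls = config$qtls,
    phenotypes = data.frame(id = ids, phenotype = phenotype),
    qtl_dosage = dosage[, qtl_idx, drop = FALSE],
    bulk_low_ids = bulk_low, bulk_high_ids = bulk_high,
    true_allele_freq = data.frame(
      chrom = markers$chrom, pos = markers$pos,
      freq_low = freq_low, freq_high = freq_high
    )
  ), class = "sim_truth")
  list(variants = variants, truth = truth)
}

#' Simulate companion gene models, expression contrasts and metabolite table
#'
#' Builds fixtures for the annotation and integration stages around a
#' simulated F2 experiment: gene models tiling the simulated chromosomes
#' (each with two CDS segments), a per-contrast differential-expression
#' table in which `n_planted` genes nearest the first QTL are planted as
#' consistently down-regulated in the mutant (log2FC <= -1, FDR < 0.01 in
#' every contrast), and a two-line metabolite abundance table including at
#' least one compound detected in only one line. The generator guarantees
#' that no non-planted gene is differentially expressed in all contrasts,
#' so the planted set is recoverable exactly.
#'
#' @param config A [simulation_config()]; must declare at least one QTL.
#' @param truth The `sim_truth` returned by [simulate_f2()].
#' @param genes_per_mb Gene models per Mb per chromosome.
#' @param contrasts Character vector of contrast labels
#'   (default: the six tissue-stage combinations `L/S x V2/R2/R4`).
#' @param n_planted Number of always-down genes planted near the first QTL.
#' @param planted_window Half-width (bp) around the QTL within which planted
#'   genes are chosen.
#' @param de_rate Per-contrast probability that a background gene is
#'   differentially expressed.
#' @return A list with `genes` (a `gene_models` object, see
#'   [read_gff3_genes()]), `de` (feature_id, contrast, log2fc, fdr),
#'   `metabolites` (compound, abundance_wt, abundance_mut, detected_wt,
#'   detected_mut) and `planted_genes` (character vector of planted ids).
#' @export
simulate_companion_tables <- function(config, truth,
                                      genes_per_mb = 10,
                                      contrasts = c("L.V2", "L.R2", "L.R4",
                                                    "S.V2", "S.R2", "S.R4"),
                                      n_planted = 3,
                                      planted_window = 1e6,
                                      de_rate = 0.15) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "sim_truth"))
  if (length(contrasts) == 0) stop("at least one contrast must be declared")
  if (nrow(truth$qtls) == 0 && n_planted > 0)
    stop("planting genes requires at least one QTL")
  set.seed(config$seed + 1L)

  gene_len <- 3000
  gl <- lapply(names(config$chromosomes), function(ch) {
    len <- config$chromosomes[[ch]]
    ng <- max(1L, round(genes_per_mb * len / 1e6))
    spacing <- len / ng
    start <- pmin(round((seq_len(ng) - 0.5) * spacing), len - gene_len)
    data.frame(
      gene_id = sprintf("gene_%s_%04d", ch, seq_len(ng)),
      chrom = ch, start = start, end = start + gene_len,
      strand = rep_len(c("+", "-"), ng), stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, gl)
  rownames(genes) <- NULL
  # Two CDS segments per gene; total length divisible by 3.
  cds <- rbind(
    data.frame(gene_id = genes$gene_id, start = genes$start + 200,
               end = genes$start + 1100, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, start = genes$start + 1600,
               end = genes$start + 2800, stringsAsFactors = FALSE)
  )
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$start), ]
  rownames(cds) <- NULL
  gene_models <- structure(list(genes = genes, cds = cds),
                           class = "gene_models")

  planted <- character(0)
  if (n_planted > 0) {
    q <- truth$qtls[1, ]
    mid <- (genes$start + genes$end) / 2
    near <- genes$chrom == q$chrom & abs(mid - q$pos) <= planted_window
    cand <- genes$gene_id[near][order(abs(mid[near] - q$pos))]
    if (length(cand) < n_planted)
      stop("not enough genes within 'planted_window' of the first QTL")
    planted <- sort(cand[seq_len(n_planted)])
  }

  ng <- nrow(genes)
  nc <- length(contrasts)
  de <- data.frame(
    feature_id = rep(genes$gene_id, each = nc),
    contrast = rep(contrasts, ng),
    log2fc = round(stats::rnorm(ng * nc, 0, 0.4), 4),
    fdr = round(stats::runif(ng * nc, 0.02, 1), 6),
    stringsAsFactors = FALSE
  )
  is_de <- stats::runif(ng * nc) < de_rate
  de$log2fc[is_de] <- round(sample(c(-1, 1), sum(is_de), replace = TRUE) *
                              stats::runif(sum(is_de), 1, 3), 4)
  de$fdr[is_de] <- round(stats::runif(sum(is_de), 1e-8, 0.009), 8)
  pl <- de$feature_id %in% planted
  de$log2fc[pl] <- round(-stats::runif(sum(pl), 1.5, 3), 4)
  de$fdr[pl] <- round(stats::runif(sum(pl), 1e-8, 1e-3), 8)
  # Guard: no background gene may be DE in every contrast.
  flag <- de$fdr < 0.01 & abs(de$log2fc) >= 1
  all_de <- tapply(flag, de$feature_id, all)
  offenders <- setdiff(names(all_de)[all_de], planted)
  if (length(offenders) > 0) {
    first_row <- match(offenders, de$feature_id)
    de$fdr[first_row] <- 0.5
  }

  met <- .sim_metabolites()
  list(genes = gene_models, de = de, metabolites = met,
       planted_genes = planted)
}

# Two-line hormone-style abundance table: jasmonates/salicylates/auxins down
# in the mutant, one cytokinin exclusive to it, one compound undetected in
# both lines, and neutral fillers.
.sim_metabolites <- function() {
  down <- data.frame(
    compound = c("jasmonic acid", "methyl jasmonate", "jasmonoyl-isoleucine",
                 "salicylic acid", "salicylic acid glucoside",
                 "IAA-aspartate", "tryptamine"),
    abundance_wt = c(120, 45, 30, 200, 150, 80, 60),
    abundance_mut = c(24, 9, 6, 98, 49.5, 16, 12)
  )
  up <- data.frame(compound = c("trans-zeatin riboside"),
                   abundance_wt = 10, abundance_mut = 25)
  excl <- data.frame(compound = "cis-zeatin",
                     abundance_wt = NA_real_, abundance_mut = 18)
  none <- data.frame(compound = "gibberellin A53",
                     abundance_wt = NA_real_, abundance_mut = NA_real_)
  filler <- data.frame(
    compound = sprintf("compound_%02d", 1:20),
    abundance_wt = round(stats::runif(20, 20, 200), 1)
  )
  filler$abundance_mut <- round(filler$abundance_wt *
                                  stats::runif(20, 0.7, 1.4), 1)
  met <- rbind(down, up, excl, none, filler)
  met$detected_wt <- !is.na(met$abundance_wt)
  met$detected_mut <- !is.na(met$abundance_mut)
  rownames(met) <- NULL
  met
}
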