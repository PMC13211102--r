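#' Hard-filter thresholds for BSA variant sets
#'
#' Defaults follow standard GATK-style hard filtering for BSA-seq:
#' `QUAL >= 30`, `QD >= 2.0`, `MQ >= 40`, `FS <= 60.0`, biallelic sites
#' only, and a minimum total read depth of 4 in each bulk for the
#' informative-site stage. All boundaries are inclusive.
#'
#' @param min_qual Minimum Phred-scaled site quality.
#' @param min_qd Minimum quality-by-depth.
#' @param min_mq Minimum RMS mapping quality.
#' @param max_fs Maximum Fisher-strand Phred score.
#' @param require_biallelic Keep only sites with a single ALT allele.
#' @param min_bulk_depth Minimum total (ref + alt) depth in each bulk.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, min_qd = 2.0, min_mq = 40,
                          max_fs = 60.0, require_biallelic = TRUE,
                          min_bulk_depth = 4) {
  if (any(c(min_qual, min_qd, min_mq, max_fs, min_bulk_depth) < 0))
    stop("all thresholds must be >= 0")
  structure(list(min_qual = min_qual, min_qd = min_qd, min_mq = min_mq,
                 max_fs = max_fs, require_biallelic = require_biallelic,
                 min_bulk_depth = min_bulk_depth),
            class = "filter_config")
}

#' Apply hard quality filters to a variant table
#'
#' Retains biallelic sites with `QUAL >= min_qual`, `QD >= min_qd`,
#' `MQ >= min_mq` and `FS <= max_fs` (boundaries inclusive). Sites missing
#' any required annotation are dropped and counted, not raised as errors.
#' Input order is preserved. Per-stage drop counts are attached as the
#' `"filter_audit"` attribute (see [filter_audit()]) and reported with
#' [message()].
#'
#' @param variants A variant table (see [read_bsa_vcf()]).
#' @param config A [filter_config()].
#' @return The filtered variant table.
#' @export
apply_hard_filters <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n_in <- nrow(variants)
  ann <- cbind(variants$qual, variants$qd, variants$mq, variants$fs)
  missing_ann <- apply(is.na(ann), 1, any)
  pass <- !missing_ann &
    variants$qual >= config$min_qual &
    variants$qd >= config$min_qd &
    variants$mq >= config$min_mq &
    variants$fs <= config$max_fs
  fail_quality <- !missing_ann & !pass
  not_biallelic <- rep(FALSE, n_in)
  if (config$require_biallelic) {
    not_biallelic <- pass & variants$n_alt_alleles != 1
    pass <- pass & !not_biallelic
  }
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  audit <- data.frame(
    stage = c("input", "missing_annotation", "fail_quality",
              "not_biallelic", "retained"),
    n = c(n_in, sum(missing_ann), sum(fail_quality), sum(not_biallelic),
          nrow(out))
  )
  prev <- attr(variants, "filter_audit")
  attr(out, "filter_audit") <- rbind(prev, audit)
  message(sprintf(
    "hard filters: %d in, %d missing annotation, %d failed quality, %d not biallelic, %d retained",
    n_in, sum(missing_ann), sum(fail_quality), sum(not_biallelic), nrow(out)))
  out
}

#' Select informative sites for bulk-segregant association
#'
#' An informative site is one that can be polarized by parental origin: the
#' two parents are called homozygous for opposite alleles, and both bulks
#' have adequate total coverage (`>= min_bulk_depth`, inclusive). Sites with
#' missing parental genotypes are dropped and counted. Applies after
#' [apply_hard_filters()]; input order is preserved and drop counts are
#' appended to the `"filter_audit"` attribute.
#'
#' @inheritParams apply_hard_filters
#' @return The filtered variant table.
#' @export
select_informative_sites <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n_in <- nrow(variants)
  homo <- c("0/0", "1/1", "0|0", "1|1")
  norm <- function(gt) sub("|", "/", gt, fixed = TRUE)
  gt_wt <- norm(variants$gt_parent_wt)
  gt_mut <- norm(variants$gt_parent_mut)
  missing_parent <- is.na(gt_wt) | is.na(gt_mut) |
    gt_wt %in% c("./.", ".") | gt_mut %in% c("./.", ".")
  polymorphic <- !missing_parent & gt_wt %in% homo & gt_mut %in% homo &
    gt_wt != gt_mut
  not_polymorphic <- !missing_parent & !polymorphic
  depth_low <- variants$ad_ref_bulk_low + variants$ad_alt_bulk_low
  depth_high <- variants$ad_ref_bulk_high + variants$ad_alt_bulk_high
  deep <- !is.na(depth_low) & !is.na(depth_high) &
    depth_low >= config$min_bulk_depth & depth_high >= config$min_bulk_depth
  low_depth <- polymorphic & !deep
  pass <- polymorphic & deep
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  audit <- data.frame(
    stage = c("informative_input", "missing_parent_gt", "not_parent_polymorphic",
              "low_bulk_depth", "informative_retained"),
    n = c(n_in, sum(missing_parent), sum(not_polymorphic), sum(low_depth),
          nrow(out))
  )
  prev <- attr(variants, "filter_audit")
  attr(out, "filter_audit") <- rbind(prev, audit)
  message(sprintf(
    "informative sites: %d in, %d missing parent GT, %d not polymorphic, %d low bulk depth, %d retained",
    n_in, sum(missing_parent), sum(not_polymorphic), sum(low_depth), nrow(out)))
  out
}

#' Retrieve the filter audit table
#'
#' @param variants A variant table returned by [apply_hard_filters()] or
#'   [select_informative_sites()].
#' @return A `data.frame` of per-stage site counts, or `NULL` when the
#'   table has not been filtered.
#' @export
filter_audit <- function(variants) attr(variants, "filter_audit")
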