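#' Flag differentially expressed features
#'
#' A feature is differentially expressed in a contrast when `fdr <
#' fdr_max` (strict) and `|log2fc| >= min_abs_log2fc` (inclusive).
#' Direction is the sign of `log2fc`. Records with a missing FDR are
#' skipped with a logged count.
#'
#' @param expression A data.frame with columns `feature_id`, `contrast`,
#'   `log2fc`, `fdr`.
#' @param fdr_max Strict FDR cutoff.
#' @param min_abs_log2fc Inclusive absolute log2 fold-change cutoff.
#' @return The subset of DE records with a `direction` column
#'   (`"up"`/`"down"`).
#' @export
flag_degs <- function(expression, fdr_max = 0.01, min_abs_log2fc = 1) {
  missing_fdr <- is.na(expression$fdr)
  if (any(missing_fdr))
    message(sum(missing_fdr), " records with missing FDR skipped")
  x <- expression[!missing_fdr, , drop = FALSE]
  keep <- x$fdr < fdr_max & abs(x$log2fc) >= min_abs_log2fc
  out <- x[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Overlap candidate genes with DE calls per contrast
#'
#' @param candidate_genes Character vector of candidate gene ids.
#' @param degs A flagged DE table from [flag_degs()] (must cover every
#'   contrast of interest).
#' @param contrasts Contrast labels defining the matrix columns; defaults
#'   to those present in `degs`.
#' @return A list with `counts` (per contrast: `n_up`, `n_down` among the
#'   candidates) and `matrix` (a gene x contrast data.frame of
#'   `"up"`/`"down"`/`""`, one row per candidate gene).
#' @export
overlap_candidates_with_degs <- function(candidate_genes, degs,
                                         contrasts = NULL) {
  if (is.null(contrasts)) contrasts <- sort(unique(degs$contrast))
  genes <- sort(unique(candidate_genes))
  mat <- matrix("", nrow = length(genes), ncol = length(contrasts),
                dimnames = list(genes, contrasts))
  sub <- degs[degs$feature_id %in% genes & degs$contrast %in% contrasts, ,
              drop = FALSE]
  if (nrow(sub) > 0)
    mat[cbind(sub$feature_id, sub$contrast)] <- sub$direction
  counts <- data.frame(
    contrast = contrasts,
    n_up = vapply(contrasts, function(ct) sum(mat[, ct] == "up"), 0L),
    n_down = vapply(contrasts, function(ct) sum(mat[, ct] == "down"), 0L),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL
  list(counts = counts,
       matrix = as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Genes consistently differentially expressed across all contrasts
#'
#' @param de_matrix A gene x contrast direction matrix (data.frame of
#'   `"up"`/`"down"`/`""`) as returned by
#'   [overlap_candidates_with_degs()]`$matrix`.
#' @param require_same_direction Require an identical direction in every
#'   contrast (default), not just DE status.
#' @return Sorted character vector of gene ids.
#' @export
consistent_genes <- function(de_matrix, require_same_direction = TRUE) {
  if (ncol(de_matrix) == 0) stop("zero contrasts declared")
  if (nrow(de_matrix) == 0) return(character(0))
  m <- as.matrix(de_matrix)
  de_all <- apply(m != "", 1, all)
  if (require_same_direction) {
    same <- apply(m, 1, function(r) length(unique(r)) == 1)
    de_all <- de_all & same
  }
  sort(rownames(m)[de_all])
}

#' Call differential metabolites between two lines
#'
#' A compound is differential when its mutant/wild-type fold change is
#' `>= fc_high` or `<= fc_low` (boundaries inclusive), or when it is
#' detected in exactly one line, in which case it is flagged `exclusive`
#' (direction towards the detecting line) and counted as differential.
#' Compounds detected in neither line are excluded with a logged count.
#'
#' @param metabolites A data.frame with columns `compound`,
#'   `abundance_wt`, `abundance_mut`, `detected_wt`, `detected_mut`.
#' @param fc_high,fc_low Inclusive fold-change thresholds
#'   (mutant / wild-type).
#' @return A data.frame with `fold_change` (`NA` when undefined),
#'   `exclusive`, `differential` and `direction`
#'   (`"up_in_mutant"`/`"down_in_mutant"`).
#' @export
differential_metabolites <- function(metabolites, fc_high = 2.0,
                                     fc_low = 0.5) {
  none <- !metabolites$detected_wt & !metabolites$detected_mut
  if (any(none))
    message(sum(none), " compounds undetected in both lines excluded")
  x <- metabolites[!none, , drop = FALSE]
  both <- x$detected_wt & x$detected_mut
  fc <- ifelse(both, x$abundance_mut / x$abundance_wt, NA_real_)
  exclusive <- xor(x$detected_wt, x$detected_mut)
  differential <- exclusive | (both & (fc >= fc_high | fc <= fc_low))
  direction <- rep(NA_character_, nrow(x))
  direction[differential & !exclusive] <-
    ifelse(fc[differential & !exclusive] >= fc_high, "up_in_mutant",
           "down_in_mutant")
  direction[exclusive] <- ifelse(x$detected_mut[exclusive],
                                 "up_in_mutant", "down_in_mutant")
  out <- data.frame(compound = x$compound, fold_change = fc,
                    exclusive = exclusive, differential = differential,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ranked candidate-gene report
#'
#' Synthesizes the pipeline's endpoints into one deterministic table: one
#' row per candidate gene with its region, high-impact variant counts, DE
#' consistency score (fraction of contrasts in which the gene is DE),
#' dominant direction, and rank. Genes are ranked by consistency score,
#' then frameshift and nonsynonymous counts (all descending), then gene
#' id. Differential metabolite calls, which have no gene mapping, travel
#' as the `"metabolites"` attribute.
#'
#' @param regions A `candidate_regions` data.frame.
#' @param models A `gene_models` object (to place genes in regions).
#' @param de_matrix Gene x contrast direction matrix from
#'   [overlap_candidates_with_degs()].
#' @param prioritized Optional output of [prioritize_candidates()];
#'   omitted counts default to zero.
#' @param metabolite_calls Optional output of
#'   [differential_metabolites()].
#' @return A data.frame with one row per candidate gene: `rank`,
#'   `gene_id`, `region`, `frameshift`, `nonsynonymous`,
#'   `de_consistency`, `direction`.
#' @export
final_report <- function(regions, models, de_matrix, prioritized = NULL,
                         metabolite_calls = NULL) {
  genes <- genes_in_regions(regions, models)
  if (length(genes) == 0) {
    out <- data.frame(rank = integer(0), gene_id = character(0),
                      region = character(0), frameshift = integer(0),
                      nonsynonymous = integer(0), de_consistency = numeric(0),
                      direction = character(0))
    attr(out, "metabolites") <- metabolite_calls
    return(out)
  }
  gtab <- models$genes[match(genes, models$genes$gene_id), ]
  gr_genes <- GenomicRanges::GRanges(gtab$chrom,
                                     IRanges::IRanges(gtab$start + 1, gtab$end))
  hit <- GenomicRanges::findOverlaps(gr_genes, .regions_to_granges(regions),
                                     select = "first")
  region_label <- ifelse(is.na(hit), NA_character_,
                         sprintf("%s:%s-%s", regions$chrom[hit],
                                 format(regions$start[hit], scientific = FALSE, trim = TRUE),
                                 format(regions$end[hit], scientific = FALSE, trim = TRUE)))
  fs <- ns <- stats::setNames(integer(length(genes)), genes)
  if (!is.null(prioritized)) {
    i <- match(genes, prioritized$gene_id)
    fs[!is.na(i)] <- prioritized$frameshift_total[i[!is.na(i)]]
    ns[!is.na(i)] <- prioritized$nonsynonymous_total[i[!is.na(i)]]
  }
  m <- as.matrix(de_matrix)
  cons <- dirn <- NULL
  cons <- vapply(genes, function(g)
    if (g %in% rownames(m)) mean(m[g, ] != "") else 0, 0)
  dirn <- vapply(genes, function(g) {
    if (!g %in% rownames(m)) return("")
    d <- m[g, ][m[g, ] != ""]
    if (length(d) == 0) return("")
    if (all(d == "down")) "down" else if (all(d == "up")) "up" else "mixed"
  }, "")
  out <- data.frame(gene_id = genes, region = region_label,
                    frameshift = as.integer(fs), nonsynonymous = as.integer(ns),
                    de_consistency = cons, direction = dirn,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$de_consistency, -out$frameshift, -out$nonsynonymous,
                   out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "gene_id", "region", "frameshift", "nonsynonymous",
                 "de_consistency", "direction")]
  rownames(out) <- NULL
  attr(out, "metabolites") <- metabolite_calls
  out
}
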