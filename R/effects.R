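#' Genes overlapping candidate regions
#'
#' A gene is a candidate when its interval overlaps any region by at least
#' one bp (default), or lies entirely inside a region when
#' `containment = TRUE`. Each gene is reported once, in genomic order.
#'
#' @param regions A `candidate_regions` data.frame.
#' @param models A `gene_models` object.
#' @param containment Require full containment instead of any overlap.
#' @return Character vector of gene ids.
#' @export
genes_in_regions <- function(regions, models, containment = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  if (nrow(regions) == 0 || nrow(genes) == 0) return(character(0))
  sq <- unique(c(regions$chrom, genes$chrom))
  gr_regions <- .regions_to_granges(regions, seqlevels = sq)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = sq),
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(
    gr_genes, gr_regions,
    type = if (containment) "within" else "any"
  )
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  ord <- idx[order(genes$chrom[idx], genes$start[idx])]
  genes$gene_id[ord]
}

# Spliced CDS of a gene in genomic order plus a genomic-position ->
# CDS-offset lookup. ref_seq is a DNAStringSet named by chromosome.
.spliced_cds <- function(gene, segs, ref_seq) {
  chrseq <- ref_seq[[gene$chrom]]
  segs <- segs[order(segs$start), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(segs)), function(i)
    Biostrings::subseq(chrseq, start = segs$start[i] + 1, end = segs$end[i]))
  seq <- do.call(Biostrings::xscat, pieces)
  offsets <- cumsum(c(0, segs$end - segs$start))
  list(seq = seq, segs = segs, offsets = offsets)
}

# 1-based offset of genomic position pos within the genomic-order spliced
# CDS, or NA when pos is not coding.
.cds_offset <- function(splice, pos) {
  p0 <- pos - 1
  for (i in seq_len(nrow(splice$segs))) {
    if (p0 >= splice$segs$start[i] && p0 < splice$segs$end[i])
      return(splice$offsets[i] + (p0 - splice$segs$start[i]) + 1)
  }
  NA_integer_
}

# Plain genetic-code lookup; deliberately not translate(), whose initiator
# rules would rewrite the first codon of a fragment.
.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa) || is.na(aa)) "X" else aa
}

#' Classify the coding effect of a variant
#'
#' SNPs inside a CDS are classified by translating the affected codon
#' before and after the substitution (reverse-complemented for minus-strand
#' genes): an identical amino acid is `synonymous`, anything else --
#' including stop gains and losses -- is `nonsynonymous`. InDels inside a
#' CDS are `frameshift` when the net length change is not a multiple of 3
#' and `inframe_indel` otherwise; InDels straddling a CDS boundary are
#' conservatively classified `noncoding` with a warning. Variants inside a
#' gene but outside its CDS are `noncoding`; variants outside all genes are
#' `intergenic`.
#'
#' @param variant A one-row data.frame (or list) with `chrom`, `pos`
#'   (1-based), `ref` and `alt`.
#' @param models A `gene_models` object.
#' @param ref_seq A [Biostrings::DNAStringSet] of chromosome sequences,
#'   named by chromosome. The variant's REF allele must match it; a
#'   mismatch is an error naming the site.
#' @return A one-row data.frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`
#'   (`NA` for intergenic) and `effect`.
#' @export
classify_effect <- function(variant, models, ref_seq) {
  stopifnot(inherits(models, "gene_models"))
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  if (!chrom %in% names(ref_seq))
    stop("no reference sequence for chromosome ", chrom)
  chrseq <- ref_seq[[chrom]]
  ref_end <- pos + nchar(ref) - 1
  if (ref_end > length(chrseq) ||
      as.character(Biostrings::subseq(chrseq, pos, ref_end)) != ref)
    stop(sprintf("REF allele mismatch with reference at %s:%d (%s)",
                 chrom, pos, ref))

  genes <- models$genes
  hit <- which(genes$chrom == chrom & genes$start < ref_end &
                 genes$end >= pos)
  result <- function(gene_id, effect)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               gene_id = gene_id, effect = effect, stringsAsFactors = FALSE)
  if (length(hit) == 0) return(result(NA_character_, "intergenic"))
  gene <- genes[hit[1], ]
  segs <- models$cds[models$cds$gene_id == gene$gene_id, , drop = FALSE]
  if (nrow(segs) == 0) return(result(gene$gene_id, "noncoding"))

  is_snp <- nchar(ref) == 1 && nchar(alt) == 1
  if (is_snp) {
    splice <- .spliced_cds(gene, segs, ref_seq)
    off <- .cds_offset(splice, pos)
    if (is.na(off)) return(result(gene$gene_id, "noncoding"))
    L <- length(splice$seq)
    if (gene$strand == "-") {
      coding <- Biostrings::reverseComplement(splice$seq)
      coding_pos <- L - off + 1
      sub_base <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(alt)))
    } else {
      coding <- splice$seq
      coding_pos <- off
      sub_base <- alt
    }
    codon_idx <- ceiling(coding_pos / 3)
    codon_start <- (codon_idx - 1) * 3 + 1
    if (codon_start + 2 > L) {
      warning("variant falls in an incomplete terminal codon of ",
              gene$gene_id, "; classified noncoding")
      return(result(gene$gene_id, "noncoding"))
    }
    before <- as.character(Biostrings::subseq(coding, codon_start,
                                              codon_start + 2))
    within <- coding_pos - codon_start + 1
    after <- before
    substr(after, within, within) <- sub_base
    aa_before <- .translate_codon(before)
    aa_after <- .translate_codon(after)
    effect <- if (aa_before == aa_after) "synonymous" else "nonsynonymous"
    return(result(gene$gene_id, effect))
  }

  # InDel: affected bases are the anchor for insertions, the deleted bases
  # for deletions.
  net <- nchar(alt) - nchar(ref)
  if (net > 0) affected <- c(pos) else affected <- (pos + 1):ref_end
  in_cds <- vapply(affected, function(p)
    any(p - 1 >= segs$start & p - 1 < segs$end), TRUE)
  if (!any(in_cds)) return(result(gene$gene_id, "noncoding"))
  if (!all(in_cds)) {
    warning(sprintf(
      "InDel at %s:%d spans a CDS boundary in %s; classified noncoding",
      chrom, pos, gene$gene_id))
    return(result(gene$gene_id, "noncoding"))
  }
  effect <- if (abs(net) %% 3 != 0) "frameshift" else "inframe_indel"
  result(gene$gene_id, effect)
}

#' Classify coding effects for a table of variants
#'
#' Row-wise wrapper around [classify_effect()].
#'
#' @param variants A variant table with `chrom`, `pos`, `ref`, `alt`.
#' @param models A `gene_models` object.
#' @param ref_seq A [Biostrings::DNAStringSet] named by chromosome.
#' @return A data.frame with one row per variant: the variant key,
#'   `gene_id` and `effect`.
#' @export
classify_effects <- function(variants, models, ref_seq) {
  rows <- lapply(seq_len(nrow(variants)), function(i)
    classify_effect(variants[i, ], models, ref_seq))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prioritize candidate genes by high-impact variant content
#'
#' Tallies nonsynonymous and frameshift variants per gene separately for
#' each variant provenance set (e.g. parent-vs-parent and bulk-vs-bulk
#' calls). Genes carrying at least one high-impact (nonsynonymous or
#' frameshift) variant in any set are flagged `primary`. The table is
#' sorted by total frameshift count, then total nonsynonymous count
#' (both descending), then gene id.
#'
#' @param genes Character vector of candidate gene ids (all are reported,
#'   including genes with no qualifying variants).
#' @param effects A data.frame of classified variants with columns
#'   `gene_id`, `effect`, and `contrast_set` naming the provenance
#'   (defaults to a single set `"all"` when the column is absent).
#' @return A data.frame with per-set `nonsynonymous_*` and `frameshift_*`
#'   counts, totals, and a logical `primary` column.
#' @export
prioritize_candidates <- function(genes, effects) {
  if (is.null(effects$contrast_set)) effects$contrast_set <- "all"
  sets <- unique(effects$contrast_set)
  out <- data.frame(gene_id = sort(unique(genes)), stringsAsFactors = FALSE)
  for (s in sets) {
    for (eff in c("nonsynonymous", "frameshift")) {
      sub <- effects[effects$contrast_set == s & effects$effect == eff &
                       !is.na(effects$gene_id), , drop = FALSE]
      counts <- table(sub$gene_id)
      cnt <- as.integer(counts[out$gene_id])
      cnt[is.na(cnt)] <- 0L
      out[[paste0(eff, "_", s)]] <- cnt
    }
  }
  ns_cols <- grep("^nonsynonymous_", names(out), value = TRUE)
  fs_cols <- grep("^frameshift_", names(out), value = TRUE)
  out$nonsynonymous_total <- if (length(ns_cols))
    as.integer(rowSums(out[, ns_cols, drop = FALSE])) else 0L
  out$frameshift_total <- if (length(fs_cols))
    as.integer(rowSums(out[, fs_cols, drop = FALSE])) else 0L
  out$primary <- out$nonsynonymous_total + out$frameshift_total > 0
  out <- out[order(-out$frameshift_total, -out$nonsynonymous_total,
                   out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment with BH-FDR
#'
#' For each term in the map, tests over-representation among the candidate
#' genes against the background using the upper-tail hypergeometric
#' probability `P(X >= k)`, then controls the FDR across terms with
#' Benjamini-Hochberg.
#'
#' @param candidate_genes Character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector (the gene universe).
#' @param term_map A data.frame with columns `gene_id` and `term_id`;
#'   only background genes are counted.
#' @param fdr_alpha Terms with `fdr < fdr_alpha` are flagged significant.
#' @return A data.frame with `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr` and `significant`, ordered by p-value.
#' @export
hypergeometric_enrichment <- function(candidate_genes, background_genes,
                                      term_map, fdr_alpha = 0.05) {
  candidate_genes <- unique(candidate_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(candidate_genes, background_genes)
  if (length(outside) > 0)
    stop("candidate genes absent from background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  term_map <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  n <- length(candidate_genes)
  N <- length(background_genes)
  terms <- unique(term_map$term_id)
  res <- lapply(terms, function(t) {
    with_term <- unique(term_map$gene_id[term_map$term_id == t])
    K <- length(with_term)
    k <- length(intersect(candidate_genes, with_term))
    data.frame(term_id = t, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
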