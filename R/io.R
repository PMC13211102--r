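#' @importFrom utils write.table read.delim
NULL

.bsa_roles <- c("parent_wt", "parent_mut", "bulk_low", "bulk_high")

#' Write a variant table as VCF v4.2
#'
#' Emits a four-sample VCF (wild-type parent, mutant parent, low bulk, high
#' bulk) with `GT` and `AD` FORMAT fields, 1-based positions, and the site
#' annotations `QD`, `MQ` and `FS` in INFO. Multi-allelic sites
#' (`n_alt_alleles > 1`) are written with padded ALT alleles so the allele
#' count survives a round trip.
#'
#' @param variants A variant table as produced by [simulate_f2()] or
#'   [read_bsa_vcf()].
#' @param path Output file path.
#' @param contigs Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @param sample_names Names used for the four sample columns, in the order
#'   wild-type parent, mutant parent, low bulk, high bulk.
#' @return `path`, invisibly.
#' @export
write_bsa_vcf <- function(variants, path, contigs = NULL,
                          sample_names = .bsa_roles) {
  stopifnot(length(sample_names) == 4)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (Phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  alt <- variants$alt
  pad <- !is.na(variants$n_alt_alleles) & variants$n_alt_alleles > 1
  if (any(pad)) {
    idx <- which(pad)
    alt[idx] <- vapply(idx, function(i) {
      b <- setdiff(c("A", "C", "G", "T"), substr(variants$alt[i], 1, 1))[1]
      paste(c(variants$alt[i], rep(b, variants$n_alt_alleles[i] - 1)),
            collapse = ",")
    }, "")
  }
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  info <- paste0("QD=", fmt_num(variants$qd), ";MQ=", fmt_num(variants$mq),
                 ";FS=", fmt_num(variants$fs))
  sample_field <- function(role) {
    ad <- paste0(variants[[paste0("ad_ref_", role)]], ",",
                 variants[[paste0("ad_alt_", role)]],
                 ifelse(pad, strrep(",0", pmax(variants$n_alt_alleles - 1, 0)), ""))
    paste0(variants[[paste0("gt_", role)]], ":", ad)
  }
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, alt,
                fmt_num(variants$qual), "PASS", info, "GT:AD",
                sample_field("parent_wt"), sample_field("parent_mut"),
                sample_field("bulk_low"), sample_field("bulk_high"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a BSA variant table
#'
#' Parses a VCF (via \pkg{vcfR}) and maps its samples onto the four BSA
#' roles. Only the first ALT allele is retained; the total ALT allele count
#' is kept in `n_alt_alleles` for the biallelic filter. Missing `QD`, `MQ`
#' or `FS` annotations become `NA` (such sites are dropped, and counted, by
#' [apply_hard_filters()]).
#'
#' @param path Path to a VCF file.
#' @param sample_roles Named character vector mapping the roles
#'   `parent_wt`, `parent_mut`, `bulk_low`, `bulk_high` to sample names in
#'   the VCF. Defaults to samples named after the roles themselves.
#' @return A variant table (`data.frame`), one row per site.
#' @export
read_bsa_vcf <- function(path, sample_roles = stats::setNames(.bsa_roles, .bsa_roles)) {
  stopifnot(all(.bsa_roles %in% names(sample_roles)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt_full <- fix[, "ALT"]
  n_alt <- lengths(strsplit(alt_full, ",", fixed = TRUE))
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
    ad <- matrix(ad, nrow = 1, dimnames = list(NULL, names(ad)))
  }
  missing_samples <- setdiff(sample_roles, colnames(gt))
  if (length(missing_samples) > 0)
    stop("samples not found in VCF: ", paste(missing_samples, collapse = ", "))
  ref <- fix[, "REF"]
  alt1 <- vapply(strsplit(alt_full, ",", fixed = TRUE), `[`, "", 1L)
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt1,
    variant_type = ifelse(nchar(ref) == 1 & nchar(alt1) == 1, "SNP", "InDel"),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    qd = info_num("QD"), mq = info_num("MQ"), fs = info_num("FS"),
    n_alt_alleles = as.integer(n_alt),
    stringsAsFactors = FALSE
  )
  for (role in .bsa_roles) {
    s <- sample_roles[[role]]
    ad_split <- strsplit(ifelse(is.na(ad[, s]), ".,.", ad[, s]), ",", fixed = TRUE)
    out[[paste0("gt_", role)]] <- ifelse(is.na(gt[, s]), "./.", gt[, s])
    out[[paste0("ad_ref_", role)]] <-
      suppressWarnings(as.integer(vapply(ad_split, `[`, "", 1L)))
    out[[paste0("ad_alt_", role)]] <-
      suppressWarnings(as.integer(vapply(ad_split, function(x)
        if (length(x) >= 2) x[2] else NA_character_, "")))
  }
  rownames(out) <- NULL
  out
}

#' Construct a set of gene models
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand` (`+`/`-`).
#' @param cds `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open CDS segments, non-overlapping, inside the gene).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, cds) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!all(cds$gene_id %in% genes$gene_id))
    stop("CDS segments reference unknown genes")
  for (g in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == g, ]
    seg <- seg[order(seg$start), ]
    if (any(seg$start >= seg$end)) stop("CDS start must be < end (", g, ")")
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping CDS segments in ", g)
    gb <- genes[genes$gene_id == g, ]
    if (min(seg$start) < gb$start || max(seg$end) > gb$end)
      stop("CDS outside gene bounds in ", g)
    if (sum(seg$end - seg$start) < 3)
      stop("total CDS length must be >= 3 in ", g)
  }
  structure(list(genes = genes, cds = cds[order(match(cds$gene_id, genes$gene_id),
                                                cds$start), ]),
            class = "gene_models")
}

#' Write gene models as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to GFF3's 1-based inclusive convention; CDS phase is derived from the
#' cumulative coding length in translation order.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(g$chrom, "bsaqtl", "gene", g$start + 1, g$end,
                            ".", g$strand, ".", paste0("ID=", g$gene_id),
                            sep = "\t"))
    seg <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start, decreasing = (g$strand == "-")), ]
    phase <- cumsum(c(0, (seg$end - seg$start)[-nrow(seg)])) %% 3
    phase <- (3 - phase) %% 3
    for (j in seq_len(nrow(seg)))
      lines <- c(lines, paste(g$chrom, "bsaqtl", "CDS", seg$start[j] + 1,
                              seg$end[j], ".", g$strand, phase[j],
                              paste0("ID=", g$gene_id, ".cds", j,
                                     ";Parent=", g$gene_id),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `CDS` features (via \pkg{rtracklayer}) and returns
#' them in the package's 0-based half-open convention. When a gene carries
#' several transcripts only the first set of CDS segments per gene is used.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` object.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- tolower(as.character(gr$type)) == "gene"
  g <- gr[is_gene]
  genes <- data.frame(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    stringsAsFactors = FALSE
  )
  cd <- gr[tolower(as.character(gr$type)) == "cds"]
  parent <- vapply(as.list(cd$Parent), function(p)
    if (length(p) > 0) sub("^(transcript|mRNA):", "", p[[1]]) else NA_character_, "")
  # Map transcript parents back to genes where necessary: keep entries whose
  # parent matches a gene id directly.
  keep <- parent %in% genes$gene_id
  cds <- data.frame(
    gene_id = parent[keep],
    start = GenomicRanges::start(cd)[keep] - 1L,
    end = GenomicRanges::end(cd)[keep],
    stringsAsFactors = FALSE
  )
  gene_models(genes, cds)
}
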