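# Shared fixtures: hand-built variant rows, a tiny annotated genome, and
# brute-force oracles kept deliberately independent of the package's
# vectorized implementations.

# One fully specified variant-table row; override any field via ...
make_variant <- function(...) {
  row <- data.frame(
    chrom = "chr1", pos = 1000L, ref = "A", alt = "G", variant_type = "SNP",
    qual = 60, qd = 20, mq = 55, fs = 5, n_alt_alleles = 1L,
    gt_parent_wt = "0/0", ad_ref_parent_wt = 40L, ad_alt_parent_wt = 0L,
    gt_parent_mut = "1/1", ad_ref_parent_mut = 0L, ad_alt_parent_mut = 40L,
    gt_bulk_low = "0/1", ad_ref_bulk_low = 15L, ad_alt_bulk_low = 15L,
    gt_bulk_high = "0/1", ad_ref_bulk_high = 15L, ad_alt_bulk_high = 15L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# A 10 kb chromosome with two genes (one per strand), each with two CDS
# segments, plus the reference sequence. Gene structures mirror each other
# so strand symmetry can be checked.
tiny_genome <- function(seed = 42) {
  set.seed(seed)
  n <- 10000
  seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
  ref <- Biostrings::DNAStringSet(c(chrA = seq))
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chrA",
    start = c(1000L, 6000L),
    end = c(4000L, 9000L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  cds <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    start = c(1200L, 2400L, 6200L, 7400L),
    end = c(1800L, 3000L, 6800L, 8000L),
    stringsAsFactors = FALSE
  )
  list(models = gene_models(genes, cds), ref = ref)
}

# Oracle: translate the entire spliced CDS before and after applying a
# variant to the chromosome sequence, then compare proteins.
oracle_effect <- function(variant, models, ref) {
  chrseq <- as.character(ref[[variant$chrom]])
  genes <- models$genes
  ref_end <- variant$pos + nchar(variant$ref) - 1
  gi <- which(genes$chrom == variant$chrom & genes$start < ref_end &
                genes$end >= variant$pos)
  if (length(gi) == 0) return("intergenic")
  g <- genes[gi[1], ]
  segs <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
  segs <- segs[order(segs$start), ]
  in_cds <- function(p) any(p - 1 >= segs$start & p - 1 < segs$end)
  if (nchar(variant$ref) == 1 && nchar(variant$alt) == 1) {
    if (!in_cds(variant$pos)) return("noncoding")
    mutated <- chrseq
    substr(mutated, variant$pos, variant$pos) <- variant$alt
    protein <- function(s) {
      spliced <- paste(vapply(seq_len(nrow(segs)), function(i)
        substr(s, segs$start[i] + 1, segs$end[i]), ""), collapse = "")
      d <- Biostrings::DNAString(spliced)
      if (g$strand == "-") d <- Biostrings::reverseComplement(d)
      as.character(Biostrings::translate(d, if.fuzzy.codon = "X",
                                         no.init.codon = TRUE))
    }
    if (protein(chrseq) == protein(mutated)) "synonymous" else "nonsynonymous"
  } else {
    net <- nchar(variant$alt) - nchar(variant$ref)
    affected <- if (net > 0) variant$pos else (variant$pos + 1):ref_end
    hits <- vapply(affected, in_cds, TRUE)
    if (!any(hits)) return("noncoding")
    if (!all(hits)) return("noncoding")
    if (abs(net) %% 3 != 0) "frameshift" else "inframe_indel"
  }
}

# Oracle: per-window mean by direct double loop over windows and sites.
oracle_window_means <- function(indexed, values, chrom_lengths,
                                window_size, step_size) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_size)
    starts <- starts[starts < len]
    for (s in starts) {
      e <- min(s + window_size, len)
      inside <- which(indexed$chrom == ch & indexed$pos - 1 >= s &
                        indexed$pos - 1 < e)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = s, end = e,
        stat_mean = if (length(inside)) mean(values[inside]) else NA_real_,
        n_variants = length(inside))
    }
  }
  do.call(rbind, out)
}

# Exact null distribution of |X/d - Y/d| for X, Y ~ Binomial(d, 0.5):
# support and probabilities by full enumeration.
exact_abs_delta_null <- function(depth) {
  px <- dbinom(0:depth, depth, 0.5)
  grid <- expand.grid(x = 0:depth, y = 0:depth)
  val <- abs(grid$x - grid$y) / depth
  p <- px[grid$x + 1] * px[grid$y + 1]
  agg <- tapply(p, val, sum)
  data.frame(value = as.numeric(names(agg)), prob = as.numeric(agg))
}

exact_quantile <- function(dist, q) {
  cdf <- cumsum(dist$prob[order(dist$value)])
  v <- sort(dist$value)
  v[match(TRUE, cdf >= q - 1e-12)]
}

default_six_contrasts <- c("L.V2", "L.R2", "L.R4", "S.V2", "S.R2", "S.R4")
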