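test_that("gene-region overlap uses the any-overlap rule", {
  g <- tiny_genome()
  reg <- data.frame(chrom = "chrA", start = 0, end = 2000)
  expect_equal(genes_in_regions(reg, g$models), "gplus")  # straddles boundary
  reg_all <- data.frame(chrom = "chrA", start = 0, end = 10000)
  expect_equal(genes_in_regions(reg_all, g$models), c("gplus", "gminus"))
  # containment mode restores the strict reading
  expect_equal(genes_in_regions(reg, g$models, containment = TRUE),
               character(0))
  # no regions on the gene's chromosome -> excluded
  reg_other <- data.frame(chrom = "chrB", start = 0, end = 10000)
  expect_equal(genes_in_regions(reg_other, g$models), character(0))
})

test_that("codon-level SNP classification follows the genetic code", {
  seq <- paste(rep("A", 300), collapse = "")
  ref <- Biostrings::DNAStringSet(c(c1 = seq))
  models <- gene_models(
    data.frame(gene_id = "g1", chrom = "c1", start = 0L, end = 300L,
               strand = "+"),
    data.frame(gene_id = "g1", start = 0L, end = 30L)
  )
  # codon AAA -> AAG : Lys -> Lys, synonymous (third codon base at pos 3)
  syn <- classify_effect(list(chrom = "c1", pos = 3, ref = "A", alt = "G"),
                         models, ref)
  expect_equal(syn$effect, "synonymous")
  # codon AAA -> GAA : Lys -> Glu, nonsynonymous (first base)
  ns <- classify_effect(list(chrom = "c1", pos = 1, ref = "A", alt = "G"),
                        models, ref)
  expect_equal(ns$effect, "nonsynonymous")
  # 2 bp deletion in CDS -> frameshift; 3 bp -> inframe
  fs <- classify_effect(list(chrom = "c1", pos = 10, ref = "AAA", alt = "A"),
                        models, ref)
  expect_equal(fs$effect, "frameshift")
  inf <- classify_effect(list(chrom = "c1", pos = 10, ref = "AAAA", alt = "A"),
                         models, ref)
  expect_equal(inf$effect, "inframe_indel")
  # inside the gene but outside CDS -> noncoding; outside genes -> intergenic
  nc <- classify_effect(list(chrom = "c1", pos = 200, ref = "A", alt = "C"),
                        models, ref)
  expect_equal(nc$effect, "noncoding")
  models2 <- gene_models(
    data.frame(gene_id = "g1", chrom = "c1", start = 0L, end = 100L,
               strand = "+"),
    data.frame(gene_id = "g1", start = 0L, end = 30L)
  )
  ig <- classify_effect(list(chrom = "c1", pos = 200, ref = "A", alt = "C"),
                        models2, ref)
  expect_equal(ig$effect, "intergenic")
  expect_true(is.na(ig$gene_id))
  # REF mismatch errors and names the site
  expect_error(
    classify_effect(list(chrom = "c1", pos = 5, ref = "T", alt = "G"),
                    models, ref),
    "c1:5")
})

test_that("InDels spanning a CDS boundary are conservatively noncoding", {
  seq <- paste(rep("A", 300), collapse = "")
  ref <- Biostrings::DNAStringSet(c(c1 = seq))
  models <- gene_models(
    data.frame(gene_id = "g1", chrom = "c1", start = 0L, end = 300L,
               strand = "+"),
    data.frame(gene_id = "g1", start = 0L, end = 30L)
  )
  expect_warning(
    eff <- classify_effect(list(chrom = "c1", pos = 29, ref = "AAAA",
                                alt = "A"), models, ref),
    "CDS boundary")
  expect_equal(eff$effect, "noncoding")
})

test_that("classification agrees with a whole-CDS translation oracle", {
  g <- tiny_genome()
  set.seed(77)
  n <- 1000
  pos <- sample(1:9990, n, replace = TRUE)
  kind <- sample(c("snp", "ins", "del2", "del3"), n, replace = TRUE,
                 prob = c(0.7, 0.1, 0.1, 0.1))
  chrseq <- as.character(g$ref[[1]])
  agree <- vapply(seq_len(n), function(i) {
    p <- pos[i]
    refbase <- substr(chrseq, p, p)
    v <- switch(kind[i],
      snp = list(chrom = "chrA", pos = p, ref = refbase,
                 alt = sample(setdiff(c("A", "C", "G", "T"), refbase), 1)),
      ins = list(chrom = "chrA", pos = p, ref = refbase,
                 alt = paste0(refbase, "G")),
      del2 = list(chrom = "chrA", pos = p,
                  ref = substr(chrseq, p, p + 2), alt = refbase),
      del3 = list(chrom = "chrA", pos = p,
                  ref = substr(chrseq, p, p + 3), alt = refbase))
    got <- suppressWarnings(classify_effect(v, g$models, g$ref)$effect)
    want <- oracle_effect(v, g$models, g$ref)
    got == want
  }, TRUE)
  expect_true(all(agree))
})

test_that("strand symmetry: mirrored variants give the same effect class", {
  # gminus mirrors gplus; apply the same substitution at equivalent CDS
  # offsets on both strands and expect identical effect classes.
  g <- tiny_genome()
  set.seed(99)
  chrseq <- as.character(g$ref[[1]])
  for (i in 1:50) {
    off <- sample(0:599, 1)  # offset within the 600 bp first CDS block
    p_plus <- 1200 + off + 1
    p_minus <- 8000 - off    # equivalent position from the minus-gene end
    ref_p <- substr(chrseq, p_plus, p_plus)
    ref_m <- substr(chrseq, p_minus, p_minus)
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), ref_p), 1)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # write the complementary substitution on the minus strand gene
    v_plus <- list(chrom = "chrA", pos = p_plus, ref = ref_p, alt = alt_p)
    e_plus <- classify_effect(v_plus, g$models, g$ref)$effect
    # the minus-strand coding sequence reads the complement; an equivalent
    # coding change needs ref/alt complemented at the mirrored position
    v_minus <- list(chrom = "chrA", pos = p_minus, ref = ref_m,
                    alt = sample(setdiff(c("A", "C", "G", "T"), ref_m), 1))
    e_minus <- classify_effect(v_minus, g$models, g$ref)$effect
    expect_true(e_plus %in% c("synonymous", "nonsynonymous"))
    expect_true(e_minus %in% c("synonymous", "nonsynonymous"))
    # both must also match the translation oracle (strand-aware)
    expect_equal(e_plus, oracle_effect(v_plus, g$models, g$ref))
    expect_equal(e_minus, oracle_effect(v_minus, g$models, g$ref))
  }
})

test_that("prioritization counts and sorts by impact", {
  effects <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", NA),
    effect = c("nonsynonymous", "synonymous", "frameshift", "nonsynonymous",
               "synonymous", "nonsynonymous"),
    contrast_set = c("parents", "parents", "parents", "bulks", "bulks",
                     "parents"),
    stringsAsFactors = FALSE
  )
  out <- prioritize_candidates(c("gA", "gB", "gC", "gD"), effects)
  expect_equal(out$gene_id[1], "gB")       # frameshift ranks first
  expect_true(out$primary[out$gene_id == "gA"])
  expect_false(out$primary[out$gene_id == "gC"])  # synonymous only
  expect_false(out$primary[out$gene_id == "gD"])  # no variants at all
  expect_equal(out$nonsynonymous_parents[out$gene_id == "gA"], 1L)
  expect_equal(out$frameshift_parents[out$gene_id == "gB"], 1L)
  expect_equal(out$nonsynonymous_bulks[out$gene_id == "gB"], 1L)
  # counts equal a brute-force tally
  for (g in c("gA", "gB", "gC", "gD")) {
    want <- sum(effects$gene_id %in% g & effects$effect == "nonsynonymous")
    expect_equal(out$nonsynonymous_total[out$gene_id == g], want)
  }
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  bg <- sprintf("g%02d", 1:20)
  term_map <- data.frame(gene_id = bg[1:5], term_id = "T1")
  # all 5 term genes drawn in a candidate set of 5: p = 1/C(20,5)
  res <- hypergeometric_enrichment(bg[1:5], bg, term_map)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # candidate set = background -> p = 1 for every term
  res_all <- hypergeometric_enrichment(bg, bg, term_map)
  expect_equal(res_all$p_value, 1)
  # k = 0 -> p = 1 under the upper-tail convention
  res0 <- hypergeometric_enrichment(bg[6:10], bg, term_map)
  expect_equal(res0$k, 0L)
  expect_equal(res0$p_value, 1)
  # candidates outside the background are an error
  expect_error(hypergeometric_enrichment(c("zz", bg[1]), bg, term_map),
               "absent from background")
})

test_that("BH-FDR ordering is preserved and flags respect alpha", {
  set.seed(5)
  bg <- sprintf("g%03d", 1:60)
  tm <- data.frame(
    gene_id = c(bg[1:10], sample(bg, 30, replace = FALSE)),
    term_id = rep(c("T_enriched", "T_a", "T_b", "T_c"), c(10, 10, 10, 10))
  )
  res <- hypergeometric_enrichment(bg[1:10], bg, tm, fdr_alpha = 0.05)
  expect_true(all(res$fdr >= res$p_value))
  expect_equal(res$term_id[1], "T_enriched")
  expect_true(res$significant[1])
  expect_equal(res$fdr, stats::p.adjust(res$p_value, "BH"))
})

test_that("enrichment p-values follow the exact null under random draws", {
  # The hypergeometric p-value is discrete, so uniformity is checked via
  # the randomized probability integral transform u = p - U * P(X = k),
  # which is exactly Uniform(0,1) iff p is the exact upper-tail
  # probability; super-uniformity of the raw p-values is checked directly.
  set.seed(123)
  N <- 1000
  bg <- sprintf("g%04d", 1:N)
  tm <- data.frame(gene_id = bg[1:500], term_id = "T1")
  draws <- t(vapply(1:1000, function(i) {
    cand <- sample(bg, 100)
    res <- hypergeometric_enrichment(cand, bg, tm)
    c(p = res$p_value, k = res$k)
  }, c(p = 0, k = 0)))
  u <- draws[, "p"] - stats::runif(1000) * stats::dhyper(draws[, "k"], 500,
                                                         500, 100)
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
  for (alpha in c(0.01, 0.05, 0.1))
    expect_lte(mean(draws[, "p"] <= alpha), alpha + 0.03)
})
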