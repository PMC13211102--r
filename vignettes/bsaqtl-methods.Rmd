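---
title: "Methods: BSA-seq QTL mapping in bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-seq QTL mapping in bsaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The experiment being modelled

Bulk segregant analysis by sequencing maps a quantitative trait by
sequencing pooled DNA from the two phenotypic extremes of a segregating
population. The design modelled here is an F2 between two inbred lines —
a wild-type reference parent and a mutant parent differing in a
quantitative trait such as main-stem node number — with truncation
selection of the top and bottom tails into a "high" and a "low" bulk,
plus the two parents sequenced individually. At any marker where the
parents are homozygous for opposite alleles, pooled reads can be
polarized by parental origin, and allele-frequency skew between the bulks
measures linkage to the selected trait.

# The forward simulator

`simulate_f2()` is a first-class, tested component, not a fixture
generator. It draws, per chromosome, marker positions uniformly at the
configured density, then simulates each F2 gamete as a Markov chain along
the marker map with Haldane recombination fractions
`r = (1 − e^{−2d})/2` at a fixed rate (default 1 cM/Mb, configurable).
Genotype dosage (0/1/2 copies of the mutant-parent allele) is the sum of
two independent gametes; the phenotype is
`baseline + Σ effect·dosage + N(0, env_sd)`. Bulks are the `bulk_size`
highest- and lowest-phenotype individuals, with ties broken by individual
id so the draw is reproducible. Read data per site and bulk use a
negative binomial total depth (mean `mean_depth`, dispersion
`depth_dispersion`; `Inf` recovers Poisson) and binomial sampling of
mutant-allele reads at the bulk allele frequency perturbed by a per-read
allele-flip probability `error_rate`. Parents are emitted error-free and
homozygous-opposite, matching the informative-site definition used
downstream. Everything is deterministic given the seed.

Defaults mirror the study design the package targets, at desk scale: 20
chromosomes of 10 Mb, 50 markers/Mb, an F2 of 322 with bulks of 32, 30×
mean bulk depth, one additive QTL of 3 trait units per allele against an
environmental SD of 1, trait baseline 17.98. The bulk size follows the
sequencing-design figure (32); where a source reports 33 elsewhere it is
a parameter, not a constant. `error_rate = 0.01` represents combined
sequencing and mapping error; `depth_dispersion = 8` gives the mild
overdispersion typical of pooled libraries. GATK-style site annotations
(QUAL, QD, MQ, FS) are drawn from distributions under which a few percent
of sites fail the hard filters, so the filtering stage does real work on
simulated data.

What the simulator does **not** emulate: read-level errors correlated
along fragments, mapping artefacts, reference bias, segregation
distortion, dominance and epistasis, and linkage disequilibrium beyond
the marker map. Passing tests on simulated data therefore demonstrate the
statistical machinery, not robustness to alignment pathology.

`simulate_companion_tables()` adds gene models tiling the chromosomes
(two CDS segments per gene, total length divisible by 3), a
differential-expression table over six tissue–stage contrasts in which
`n_planted` genes nearest the first QTL are planted as consistently
down-regulated (log2FC ≤ −1, FDR < 0.01 everywhere), and a two-line
hormone-style abundance table with jasmonate/salicylate/auxin-like
compounds reduced in the mutant, one cytokinin-like compound detected
only in the mutant, and one compound undetected in both lines. A guard
re-sets one contrast of any background gene that would otherwise be DE in
all contrasts, so the planted set is recoverable *exactly* — this keeps
the integration tests sharp at the cost of a slightly sub-natural tail of
the background DE distribution.

# Filtering

`apply_hard_filters()` keeps biallelic sites with QUAL ≥ 30, QD ≥ 2.0,
MQ ≥ 40 and FS ≤ 60.0 — all boundaries inclusive, matching standard GATK
hard-filter practice. Sites missing an annotation are dropped and
counted, never imputed. `select_informative_sites()` then requires the
parents to be called homozygous for opposite alleles (the standard
informative configuration for an F2; heterozygous-parent sites cannot be
polarized) and total depth ≥ 4 in **both** bulks — the conservative
reading where a single-bulk rule would also be defensible. Both stages
append to a per-stage audit table (`filter_audit()`), report the
parent-polymorphism and coverage stages separately, and are idempotent.

# Association statistics and thresholds

`compute_indices()` counts the **mutant-parent** allele, so the index of
the bulk selected for the mutant phenotype rises towards 1 over a causal
locus and Δ = index_high − index_low peaks positive; the signed value is
kept for directionality and thresholding uses |Δ|. The ED statistic is
the Euclidean distance between the bulks' allele-frequency vectors over
both alleles — `sqrt(2)·|Δ|` for a biallelic site — with an optional
exponent (`ed_power`, default 1; 4–5 are common peak-sharpening choices
elsewhere and are supported but not default, since the plain distance is
what the threshold rule below is calibrated against).

`smooth_profile()` averages the per-site statistic in 1 Mb windows
stepped every 100 kb (0-based half-open; a site at 1-based position `pos`
belongs to windows with `start ≤ pos − 1 < end`). Windows with fewer than
`min_variants = 10` sites are masked: they are excluded from thresholding
and can never seed a region. Mean aggregation is the default; median is
available (`agg = "median"`). An O(sites × windows) brute-force
recomputation backs the implementation in the tests.

**Delta thresholds.** The null asks: how large can the windowed |Δ| get
with *no* bulk differentiation? Two noise sources matter. Read sampling
contributes binomial variance `p(1−p)/depth` per bulk; bulk composition
contributes the variance of an F2 allele frequency averaged over
`bulk_size` individuals, `1/(8·bulk_size)` per bulk — at 32 individuals
and 30× these are comparable (SD ≈ 0.09 and ≈ 0.06 per bulk), so a null
that resamples reads at a fixed frequency of 0.5 is materially
anti-conservative for real bulk data. The default null in
`delta_threshold_permutation()` therefore draws, per site and iteration,
each bulk's allele frequency from F2 segregation in a finite bulk
(`Binomial(2·bulk_size, ½)/(2·bulk_size)`) and then reads as
`Binomial(observed depth, f)` — the standard QTL-seq-style simulated
confidence interval. Pure read-sampling nulls remain available with
`bulk_size = Inf`.

Null values are pooled at the **site** level by default (`pool = "site"`)
and the window-averaged observed profile is compared against the
site-level quantile. This is deliberately conservative: window averaging
shrinks noise in the observed track but not in the threshold, which is
what makes a genome-wide scan with ~2,000 windows produce *zero* regions
under the null rather than the ~5% of windows a window-level quantile
would pass by construction. Window-level pooling is implemented
(`pool = "window"`) for users who want a per-window false-positive rate
instead of a scan-level one. Quantiles use the inverse empirical CDF
(`type = 1`), so for discrete nulls (all depths equal) they converge to
the exact enumerated quantile — the tests assert equality against a full
31 × 31 enumeration at depth 30. Thresholds are reported at the 0.90,
0.95 and 0.99 confidence levels from 1000 iterations by default and are
deterministic given the seed.

**ED threshold.** The genome-wide rule `median + 3·SD` over unmasked
window values, with the *sample* SD (n − 1 denominator) — stated
explicitly because the rule is convention-sensitive. It assumes the
overwhelming majority of windows are unlinked background; see
limitations.

# Region calling and combination

`call_regions()` turns maximal runs of consecutive unmasked
above-threshold windows (strict `>`) into regions spanning from the first
window's start to the last window's end, snapped to window boundaries —
no sub-window refinement, matching the resolution of the method. No gap
bridging is done by default; `max_gap_windows` allows sensitivity
analysis. Because windows overlap when `step < window`, spans from
distinct runs can themselves overlap; such spans are merged so each
returned set is disjoint and sorted. `combine_region_sets()` performs
base-pair-level intersection or union over any number of sets (backed by
`GenomicRanges`); the default pipeline combination is the strict
intersection of both methods and both variant types, which is equivalent
to intersecting methods within each type and then across types.
`summarize_regions()` reports counts, spans (Mb = 10⁶ bp, two decimals)
and each chromosome's percent share of the total span, two decimals.

# Annotation and integration

`genes_in_regions()` uses any-overlap inclusion (≥ 1 bp) so boundary
genes are not silently lost; `containment = TRUE` restores the strict
"located within" reading. `classify_effect()` translates the affected
codon before and after a CDS SNP (reverse-complementing minus-strand
genes) using a plain genetic-code lookup — deliberately not a
full-sequence `translate()`, whose initiator-codon rules would rewrite
the first codon of a fragment. Stop gains and losses are folded into
`nonsynonymous`, matching a two-class prioritization. CDS InDels are
`frameshift` iff the net length change is not a multiple of 3, else
`inframe_indel`; InDels straddling an intron–exon boundary are
conservatively `noncoding` with a warning (a documented limitation — a
splice-aware annotator would refine these). Only the first CDS model per
gene is used. A whole-CDS translate-before/after oracle backs the
classifier on 1,000 random variants in the tests.

`hypergeometric_enrichment()` computes upper-tail probabilities
`P(X ≥ k)` with BH-FDR across terms; term maps are user-supplied
two-column tables, never a database call. `flag_degs()` applies
FDR < 0.01 strictly and |log2FC| ≥ 1 inclusively — exactly as such
cutoffs are conventionally printed. Metabolite fold changes are
mutant/wild-type, so "down-regulated in the mutant" maps to FC ≤ 0.5;
compounds detected in exactly one line are `exclusive` and counted as
differential toward the detecting line. `final_report()` ranks candidate
genes by DE-consistency score (fraction of contrasts DE), then frameshift
and nonsynonymous counts, then gene id — fully deterministic.

# Problem sizes used in tests and the acceptance script

The test-suite simulations use one 20 Mb chromosome with 2,000 markers
(single-locus designs, threshold calibration) and 20 × 10 Mb genomes with
30–60 markers/Mb (genome-scan behaviour), 300–322 F2 individuals, bulks
of 32 and 30× depth; stochastic properties are evaluated over 20 seeds.
`scripts/acceptance.R` re-runs the recovery and null-control loops at the
same sizes.

# Known limitations

* **ED's `median + 3·SD` needs a background.** The rule calibrates the
  threshold from the genome-wide window distribution, implicitly assuming
  most windows are unlinked to the trait. On a single-chromosome design
  20 cM long, every window is within ~20 cM of the QTL, the whole profile
  is elevated in a smooth gradient, and for any such gradient the maximum
  lies *below* `median + 3·SD` — the rule then calls nothing at all, and
  an intersection with the delta regions is empty. This is a property of
  the published rule, not of its implementation here; the delta-index
  permutation thresholds do not share it. Genome-scale (multi-chromosome)
  designs, where the QTL chromosome is a small fraction of all windows,
  are the intended regime; the package's genome-scan tests use 20
  chromosomes.
* **Sparse variant classes fragment.** With `min_variants = 10` per 1 Mb
  window, a variant class thinner than ~10 sites/Mb (e.g. InDels at low
  simulated marker density) masks most windows and its region set
  fragments; a strict four-way intersection then under-calls. Lower
  `min_variants`, raise the window, or combine with
  `combine_mode = "union"` across types in that situation.
* The permutation null conditions on observed depths and assumes
  independent sites; LD between nearby markers makes window-level nulls
  slightly narrower than reality, one more reason the site-level pooling
  default is the safer scan-level control.
* Bulk genotyping error is modelled as a symmetric per-read flip; strand
  or reference bias is not simulated, so polarization on real data should
  be sanity-checked against the parents (the filters require them).
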