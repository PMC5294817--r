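---
title: "Methods: integrating a consensus cistrome with GWAS variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating a consensus cistrome with GWAS variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrovar)
```

# The question and the model

Most trait-associated SNPs are non-coding, and a natural hypothesis for a
given transcription factor is that part of its biology is read out by
genetic variation falling inside its binding sites. `cistrovar`
formalizes one way of testing this: build a consensus cistrome from
several ChIP-seq datasets, expand GWAS lead SNPs into their
linkage-disequilibrium (LD) neighborhoods, count which SNPs fall under
binding loci, and ask, phenotype by phenotype, whether that count is
larger than chance.

The statistical core is deliberately simple. Let N be the deduplicated
universe of lead + proxy SNPs, K the SNPs associated with one phenotype,
n the SNPs under binding loci and k the phenotype's SNPs under loci.
Under the null that the phenotype's SNPs are an exchangeable subset of
the universe, k follows a hypergeometric distribution and the evidence
for enrichment is the upper tail

$$P(X \ge k) \;=\; \sum_{j=k}^{\min(K,n)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

computed in log space (`lchoose` with max-subtraction) so it is stable up
to N ≈ 10⁷. Bonferroni correction multiplies by the number m of
phenotypes tested. The assumptions worth stating:

* **Exchangeability of SNPs.** The null treats all universe SNPs as
  equally likely to land under a peak. Real SNPs are correlated through
  LD and unevenly distributed with respect to genes and chromatin; the
  test is therefore anti-conservative in principle when a phenotype's
  SNPs cluster in a few LD blocks. We partially counter this by counting
  *deduplicated* SNPs (a SNP proxying several leads or traits counts
  once toward N and n, once per trait toward K), but a permutation null
  matched on LD structure is out of scope and noted as future work.
* **Choice of m.** By default m counts phenotypes with at least one SNP
  under the peak set under test (`m_policy = "tested"`), which mirrors
  correcting across the phenotypes actually examined; `m_policy = "all"`
  corrects across every catalog phenotype. The choice lands in the run
  manifest.
* **Direction.** Ranking and significance use the upper (enrichment)
  tail; the lower tail is computed and reported alongside because
  under-representation is also of interest.

Both the implementation and its tests treat the tail sum as the
contract: the suite checks agreement to < 1e-12 relative error against
an exact big-integer rational enumeration (via python's `fractions`) on
a randomized grid, plus monotonicity in k and the (K, n) symmetry.

# Interval conventions

All coordinates are 0-based half-open (BED-native); VCF and catalog
positions (1-based) are converted on read, and chromosome names are
normalized to the `chr`-prefixed dialect. A SNP is a 1-bp interval at
its position; an insertion/deletion is represented by its anchor base.
Two consequences are deliberate and tested:

* abutting intervals ([0,100) and [100,200)) share zero base pairs and
  are **not** merged by consensus construction — "non-overlapping" means
  zero shared bp;
* a SNP at position p belongs to locus [s, e) iff s ≤ p < e, so a SNP at
  the exclusive end coordinate is outside.

Consensus merging, SNP assignment and fractional intersection are built
on GenomicRanges/IRanges, with property tests pinning them to naive
O(n²) oracles. Cistrome intersection uses a fractional rule: a query
locus is shared when at least `min_fraction` (default 0.25) of its
length is overlapped, *inclusively* — a 100-bp locus with exactly 25 bp
overlapped passes at 0.25. The fraction is assessed on the query side
because the underlying phrase "the peak region" does not say which peak;
a `reciprocal = TRUE` mode requires the criterion in both directions,
and the choice is recorded in the manifest.

# LD expansion

Proxies are sought within ±500 kb of each lead ("a 500 kb region
surrounding" is ambiguous between span and half-window; we take the
half-window reading and expose it as `window_bp`). The r² estimator is
the gametic one from phased haplotypes, r² = D²/(p₁q₁p₂q₂) with
D = f₁₁ − p₁p₂ — equivalently the squared Pearson correlation of the 0/1
haplotype columns, which the tests exploit as an independent oracle. A
squared dosage-correlation fallback (`method = "dosage"`) is provided
for effectively unphased data. Thresholds default to r² ≥ 0.8
(inclusive, since the source material writes both "> 0.8" and "0.8")
and MAF ≥ 0.05; the MAF filter applies to proxies only, because catalog
leads have already been vetted by their studies. Monomorphic sites make
r² undefined and return `NA`, never 0. Multi-allelic panel sites are
split into biallelic records on read, with a logged count.

# DR3 motif model and allele scoring

The canonical high-affinity element for the vitamin D receptor class of
nuclear receptors is a direct repeat of two hexamer half sites separated
by 3 bp (DR3). The shipped model (editable JASPAR-like text file,
`inst/extdata/dr3_halfsite.pwm`) is built from the degenerate half-site
consensus RGKTSA with 0.85 probability mass on the consensus base(s) per
column and the remainder spread uniformly. This is a transparent stand-in
for a fitted matrix: the de novo matrix behind published hit scores is
not printed anywhere we can consume, so scan scores here are *analogous
to*, not comparable with, those scores. Numerical choices:

* log-odds base 2 (bits), background uniform 0.25 (overridable);
* pseudocount 0.01 added to each PWM cell (then renormalized) so no
  log-odds is −∞;
* spacer columns carry uniform weights, hence contribute exactly 0 — a
  SNP in the spacer has ΔLOD exactly 0 by construction;
* the default hit threshold is 80% of the maximum attainable score;
  windows containing N are skipped; both strands are scanned and
  overlapping hits are allowed;
* scanning defaults to ±100 bp around each locus midpoint (mirroring
  summit-centred annotation practice); whole-locus scanning via
  `flank_from_midpoint = NULL`.

ΔLOD = score(alt window) − score(ref window) is computed by rescoring
the full window, with the documented sign convention (negative favours
the reference allele); for scored columns this provably collapses to the
single-column log-odds difference, which the tests assert on both
strands. The reference allele must match the supplied genome, otherwise
the call is rejected with the position named.

In-motif SNP positions are 1-based in the hit's reading orientation: for
a minus-strand hit of width w, a SNP at genomic offset o from the hit
start has position w − o.

# Regulatory-score annotation

"Likely to affect transcription factor binding" is implemented as the
explicit category set {1a–1f, 2a, 2b, 2c} — not numeric parsing of the
labels — applied to a packaged TSV; nothing is fetched from a live
service, for reproducibility. The score-distribution table, the
co-binding TF frequency table (set semantics per SNP; descending count,
ties lexicographic) and the genotype-stratified binding summary
(per-class n/mean/sd plus a dosage-monotonicity flag) are plain
data.frames written as TSV; the wordcloud that such TF frequencies
usually feed is intentionally out of scope.

# What the generators emulate — and what they do not

Every pipeline input has a seeded generator, and fixtures are written in
the same external formats the pipeline reads, so the pipeline cannot
tell fixtures from real data. One master seed drives named substreams
(one per generator, derived by a small string hash), so adding a
generator never perturbs existing outputs; all generators are pure
functions of (config, seed) and the suite asserts bit-identical reruns.

* **Haplotype panel** — independent LD blocks laid end to end; within a
  block every site is a copy of a founder column with per-site mutation
  probability 0.02, giving provably high within-block and null
  cross-block r²; founder frequencies are drawn from (0.02, 0.5) so site
  MAFs straddle the 0.05 filter. This block-copy model was chosen over
  coalescent simulation because the tests need *controlled* LD, not
  realism: there are no recombination gradients, hotspots, or
  demographic structure, so passing tests say nothing about performance
  on real human LD maps.
* **Catalog and peaks** — trait SNP sets partition the panel sites (the
  deduplicated universe size is exact); background peaks are uniform on
  the genome but rejection-sampled away from the planted trait's SNPs,
  which instead receive covering peaks independently with probability
  `enrichment_factor ×` the background coverage probability. At factor 1
  the planted trait is covered at exactly the background rate — this is
  what makes the type-I calibration test meaningful. With
  `plant_ld_neighborhood = TRUE` the planting extends to every site in
  the planted trait's LD blocks, so the signal survives proxy expansion;
  the default keeps lead-only planting for calibration studies.
* **Sequences** — i.i.d. uniform background with exact consensus DR3
  15-mers planted at recorded positions and strands, optionally placed
  over catalog SNPs to exercise in-motif annotation and ΔLOD. Real
  genomic background is neither uniform nor independent, so the false
  positive rates measured here are the i.i.d. ones.
* **Genotype-dependent signal** — Hardy–Weinberg genotypes and signal
  `base × (2 − dosage)/2 + noise`, so alternate homozygotes lose binding
  entirely at zero noise.

Ground-truth side files accompany each generator and are computed by
independent linear scans, so every stage's expected output can be
checked without using the stage itself.

# Problem sizes and numerical tolerances

The test suite and acceptance script use deliberately compact study
sizes chosen to exercise every code path with tight statistical checks:
interval oracles on 100 random fixtures of up to ~120 intervals; the
exact-enumeration hypergeometric grid at N ≤ 200 (tolerance 1e-12
relative, the practical limit of correctly rounded double conversion);
null calibration pooled over 20 phenotypes × ~1,000 replicates against
the bound 0.05 + 2·SE (the discrete test is conservative, and the
observed rate sits well below nominal); power at the planted-trait
configuration K = 50, N = 20,000, ~2.5% background coverage,
enrichment factor 10, 200 replicates with a ≥95% top-rank criterion;
motif recall on 100 planted sequences with the background false-hit rate
bounded by the exact i.i.d. convolution of the column score
distribution. Fractional-overlap boundary checks use a 1e-9 bp slack so
an exact 25% overlap is inclusive despite floating-point products.

# Known limitations

* The enrichment null ignores LD clustering (see above); corrected
  p-values for traits whose SNPs sit in few blocks are optimistic.
* One haplotype panel per run; merging panels (e.g. two reference
  cohorts) is done by unioning runs on SNP id, and conflicting duplicate
  records between panels are not reconciled.
* The DR3 matrix is a consensus-derived stand-in; absolute hit scores
  and thresholds should be re-derived if a fitted matrix is available
  (the threshold is fully configurable for this reason).
* Peak calling, read alignment, de novo motif discovery and live
  annotation services are out of scope; the pipeline starts from BED
  peaks and packaged annotation tables.
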