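---
title: "Detecting Hox/Pbx–Meis composite clusters and testing promoter-set enrichment"
author: "cisclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Hox/Pbx–Meis composite clusters and testing promoter-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisclust)
```

## The problem

Hox transcription factors gain DNA-binding specificity by dimerizing with
TALE-class cofactors: a Hox–Pbx (PBC) dimer binds a composite element with
a `TGATTNAT`-like core, and a nearby Meis site (`TGACAG` core) allows a
trimeric Hox/Pbx/Meis complex to assemble. In cnidarians such as the sea
anemone *Nematostella vectensis*, Hox and TALE products co-occur in the
endoderm, which predicts that promoters of endoderm-expressed genes should
be enriched in such composite elements relative to ectoderm-expressed
genes. `cisclust` implements the in-silico side of that prediction as a
reusable, fully tested pipeline:

1. position-specific scoring matrix (PSSM) scanning of repeat-masked DNA
   on both strands, with p-values read from the exact theoretical score
   distribution;
2. composite-cluster detection — a Hox/Pbx *anchor* hit with at least one
   Meis *partner* hit within a 40-nt spacing window;
3. cluster densities per unmasked kilobase over arbitrary region sets;
4. enrichment comparison of labeled promoter sets against three null
   controls (random gene sets, column-permuted matrices, Markov-model
   backgrounds);
5. a seeded synthetic-data generator that produces every input the
   pipeline needs, with planted ground truth.

## Score model and exact p-values

A site model is a 4×w count matrix. With pseudocount $q$ (default 0.25
per cell, a uniform-prior convention) and order-0 background $b$, the
log-odds score is

$$ s_i(x) \;=\; \log_2 \frac{(c_i(x)+q) \,/\, \sum_y (c_i(y)+q)}{b(x)} . $$

A window's score is the sum over positions. Under the iid background the
exact null distribution of the total score is computed by position-wise
convolution over a discretized score grid (`score_distribution()`), and a
site p-value is the upper-tail probability $P(S \ge s)$.

**Conservative rounding.** Column scores are *floored* onto a
`bin_width` grid (default 0.001 log2 units), so every word's binned
score is at most its exact score; look-ups compensate by querying one
bin per column lower. The reported p-value is therefore provably
$\ge$ the exact enumeration p-value, with excess bounded by the
probability mass lying within $w \times \text{bin\_width}$ below the
query score. At the default grid this excess is well under 1% of the
p-value itself for width-8 matrices, which keeps scans calibrated: on
iid background generated from the scan's own background model, the
per-window hit rate at threshold $\alpha$ sits inside the 99% binomial
interval of $\alpha$ (this is an acceptance test). A coarser grid
(e.g. 0.01) preserves correctness but depresses hit rates by several
percent — enough to fail a calibration check — which is why the finer
default was chosen.

Calibration additionally presumes a near-continuous score support.
Matrices with heavily tied small-integer counts have a coarse set of
achievable p-values, and the hit rate at $\alpha$ then undershoots
$\alpha$ for purely combinatorial reasons; the calibration test
therefore uses continuous (gamma-distributed) column counts, the regime
of real-valued SELEX frequency matrices. The enumeration tests cover the
tied case.

**Backgrounds.** p-value theory is order-0 throughout, even when the
sequences themselves come from a higher-order Markov model — one
theoretical curve, as in the analysis this package operationalizes. The
default background is estimated from the scanned set itself (masked
positions excluded, +1 smoothing) and strand-symmetrized by averaging
complementary base frequencies, so a single distribution serves both
strands; a non-symmetric background triggers a separate reverse-strand
distribution instead.

## Matrices are inputs

The SELEX-derived Hox/Pbx class I/II/III matrices used in the original
analysis were never published as numbers, so matrices are user-supplied
inputs (JASPAR-like text, `read_count_matrix()`). `default_matrices()`
provides consensus-derived stand-ins built from the probe cores
`TGATTGAT` / `TGATTAAT` / `TGATTTAT` (anterior/central/posterior site
classes, one diagnostic core position apart) and a `TGACAG` Meis matrix,
each with consensus frequency 0.97 per position
(`consensus_pwm(..., concentration = 97)`). These stand-ins are labeled
synthetic; any conclusions drawn with them are about the pipeline, not
about the original matrices.

## Scanning, masking and clusters

Lowercase letters and `N` are repeat-masked: any window touching a
masked position is unscoreable, and masked positions are excluded from
all rate denominators and from the kilobases used for densities.
Reverse-strand hits are reported in forward coordinates.

A composite cluster is one anchor hit with $\ge 1$ partner hit at
edge-to-edge gap $\le W$ (default 40 nt) on either side; overlap counts
as gap 0, an anchor with several partners forms a single cluster, and no
orientation or side constraint is imposed (none is stated for the
original analysis; center-to-center distance is available as an option).
Cluster density is clusters per unmasked kilobase.

**Site-calling threshold.** The default for cluster analyses is
$\alpha = 10^{-4}$, but it is clamped per matrix at the matrix's minimum
attainable p-value: a width-6 Meis matrix cannot reach $10^{-4}$ at all
(its perfect site has $p \approx 2.4\times10^{-4}$ under a uniform
background), and a literal threshold would silently discard every
partner site. With the clamp, an exact-consensus site always qualifies.

## Enrichment curves, controls and the verdict

For a promoter set, the headline statistic is the per-window site rate:
the fraction of scannable windows (both strands) with site p-value
$\le \alpha$, traced over a threshold grid (default $10^{-1}$ to
$10^{-6}$ in half-decade steps). Under the null this curve tracks the
identity; signal bends it upward. A per-promoter best-hit curve is
provided as a secondary statistic.

Three controls are implemented:

* **random gene sets** — rates of repeated draws from a promoter pool;
* **column-permuted matrices** — the same promoters rescanned with
  seeded column permutations (default 100), which destroy the binding
  word but leave the theoretical score distribution exactly unchanged
  (the binned distribution is a convolution over the multiset of
  columns, so permutation invariance is exact, not approximate);
* **Markov backgrounds** — replicate sequence sets sampled from an
  order-k model trained on the promoters, preserving each promoter's
  length and repeat-mask layout. Results depend on k, which is exposed
  as a parameter rather than fixed.

The original analysis reported enrichment graphically; `cisclust`
operationalizes it: a set is **enriched** when its observed curve lies
strictly above the 97.5th percentile of its permuted-matrix band at
*every* grid threshold between $\alpha^\* = 10^{-3}$ and the matrix's
minimum attainable p-value. Thresholds below that floor are excluded
because both observed and null rates are identically zero there — a
width-8 matrix cannot produce $p < \sim1.5\times10^{-5}$, so comparisons
at $10^{-6}$ are vacuous and would make the verdict unreachable for any
input. Both labeled sets use the same permutation substream, so swapping
the set labels swaps the verdicts exactly. Under the complete null this
rule flags at most ~5% of runs (joint exceedance across correlated
thresholds against the band maximum); the acceptance suite checks
$\le 10\%$ over 50 seeded replicates.

## The synthetic world

`make_promoter_sets()` generates two labeled sets of 38 promoters of
1 kb (or 2 kb) — matching the published study design — plus an optional
background pool for random-set controls:

* **Background**: order-2 Markov chain trained on a bundled 100-kb
  synthetic genome, itself order-0 with a mild AT bias (A=T=0.30,
  C=G=0.20, roughly AT-rich like real invertebrate non-coding DNA),
  all seed-fixed. Using order-2 deliberately mismatches the order-0
  p-value theory, exercising the robustness the Markov-background
  control is meant to probe.
* **Planting** (endoderm set only): per promoter, a fixed count
  (default 1) or Poisson number of anchor+partner pairs; spacing uniform
  on [0, 40] nt edge-to-edge; partner upstream or downstream with equal
  probability; each site's strand uniform; words are the exact consensus
  (default) or sampled from the matrix. Planted intervals are emitted as
  ground truth and never overwritten by later insertions.
* **Repeats**: optional lowercase tracts of geometric length (mean
  150 nt) up to a target masked fraction, never covering planted sites.
  The generator can thereby copy the "number and positions" statistics
  that the Markov control needs.

What a green end-to-end test establishes: that planted consensus-level
signal at one cluster per kilobase separates cleanly from these nulls,
and that no signal means no verdict. What it does not establish:
performance on real promoter composition (CpG structure, tandem repeats,
binding-site turnover), on degenerate real matrices, or at weaker
planting rates.

## Numerical choices and degeneracies

* Log base 2 everywhere; bin width 0.001 (see above); pseudocount 0.25.
* A column that is all zeros with pseudocount 0 is an error
  ("degenerate column"), not a silent fix.
* Sequences shorter than the matrix width yield zero hits, no error.
* Hit ordering is (seq_id, start, strand) with `+` before `-`; identical
  (start, strand) duplicates are impossible for one matrix.
* All randomness flows from one root seed through named substreams
  (per-stage, per-replicate), so enlarging one stage never perturbs
  another, and every generator restores the caller's RNG state.
* Promoters truncated at contig edges are kept (with a warning and a
  record); genes on missing contigs are skipped with a warning.
* The promoter is a fixed window strictly upstream of the TSS with no
  neighbor-exclusion rule (none is stated in the source analysis).

## The hexapeptide scanner

`hx_scan()` applies the published sequence rule for the hexapeptide (HX)
motif that mediates Hox–PBC interaction: an invariant tryptophan with a
lysine or arginine at offset +2 to +5. The "hydrophobic context"
requirement has no precise published definition, so it is reported as a
flag (≥1 of the residues at −1/+1 in {A,V,L,I,M,F,Y,P}, configurable)
rather than used as a filter — divergent single-tryptophan motifs are
thus never silently discarded. Homeodomain positions are user-provided
annotations; the W-to-HD distance is reported, not thresholded.

## Known limitations

* p-values are order-0 only; no higher-order-background DP.
* No motif discovery, no conservation scoring, no inter-site orientation
  constraints, no HMM-style CRM models.
* The 76-vs-72 gene-count discrepancy in the source description is
  passed through: the pipeline takes whatever labeled sets it is given
  and reports their sizes.
* Consensus-derived default matrices are sharper than real SELEX
  matrices; sensitivity estimates obtained with them are optimistic.

## A worked example

```{r example, eval = FALSE}
library(cisclust)
mats <- default_matrices()
sets <- make_promoter_sets(
  n_per_set = 38, length = 1000,
  background = default_background_model(),
  planting = planting_spec(mats$hox_class_II, mats$meis,
                           clusters_per_promoter = 1, window = 40),
  seed = 1)
res <- compare_sets(sets$endoderm, sets$ectoderm,
                    mats$hox_class_II, mats$meis,
                    n_perms = 100, seed = 1)
print(res)
```

The same analysis is available from the command line via
`Rscript -e 'cisclust::cisclust_cli()' simulate|scan|clusters|enrich|density|hx-scan ...`.
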