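---
title: "Methods: differential translation and rescue-screen analysis with riboscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential translation and rescue-screen analysis with riboscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscreen)
```

## The experimental design this package models

Ribosome profiling pairs two sequencing libraries per sample: total RNA
(`RNA`) measuring transcript abundance, and ribosome-protected fragments
(`RPF`) measuring how much of each transcript is being translated. The
analyses here target a four-condition rescue design built around an E3
ubiquitin-ligase / RNA-binding-protein axis: wild type (`WT`), ligase
knock-out (`KO`), and each of those with an additional knock-down of the
RBP (`WT_KD`, `KO_KD`). If the knock-out phenotype of a gene is caused by
unrestrained RBP activity, co-depleting the RBP should *rescue* it — and
genes with that signature are the axis's downstream targets. We use
explicit condition names throughout rather than numbering the arms, since
numbered-arm conventions are easy to permute silently.

Replication defaults to biological duplicates (`replicates = 2` in
`sim_spec()`), matching how such profiling experiments are typically run;
statistical power at duplicates is intrinsically limited, and several of
our own validation simulations deliberately use 3–4 replicates where a
property is about the statistic rather than the design (each such test
says so).

## Read pre-processing

`run_prep()` applies, in order: quality filtering, duplicate collapsing,
adapter trimming, UMI extraction, and footprint-length selection. The
order matters: collapsing runs on raw sequences so that the embedded
4-nt UMIs at both ends participate in the identity key (two molecules
with the same insert but different UMIs remain distinct), and only then
is the 3' adapter removed and the dual UMI stripped.

Key parameters (`prep_config()`):

* `min_base_accuracy_frac = 0.70`, `min_base_phred = 20` — a read is kept
  when at least 70% of its bases have ≥ 99% accuracy. Phred 20 is the
  standard encoding of 99% base accuracy (`P(error) ≤ 0.01`, Phred+33).
  The boundary is inclusive: exactly 70% accurate bases keeps the read.
* `adapter` (21 nt by default) — matching is semi-global
  (read suffix vs adapter prefix), leftmost match wins, with
  `adapter_max_error_rate = 0.1` and `adapter_min_overlap = 3`. These are
  the conventional trimmer defaults; the adapter itself must be supplied
  for real libraries. An `N` base never matches the adapter.
* `umi_len_each_end = 4` — UMI extraction stores the concatenated 8-mer
  and is a no-op on reads whose UMI is already populated, which makes the
  stage idempotent. Reads with no interior after UMI removal are
  discarded and counted.
* `min_len = 26`, `max_len = 34` — the monosome footprint range. In the
  lab this is a gel-extraction step, so the filter is optional
  (`apply_length_filter = FALSE` for RNA libraries).

Duplicate collapsing is sequence-identity based, not position-aware: the
pipeline runs before alignment, so mapping coordinates are unavailable by
construction. Users with aligned data who want position-aware
deduplication should collapse after alignment instead.

Adapter trimming cannot be made strictly idempotent: after a correct
trim, a read whose insert happens to end in ≥ 3 adapter-prefix-like bases
would be trimmed again. This is inherent to suffix matching without a
placeholder and affects roughly `1/4^3` of reads per extra pass; the test
suite checks idempotence on reads without that coincidence.

## Differential abundance: a simplified NB Wald test

The reference pipelines delegate per-gene testing to DESeq2. Re-implementing
DESeq2's GLM machinery (IRLS fitting, dispersion shrinkage, Cook's
outlier handling) is explicitly out of scope here; `wald_test()` instead
uses a transparent moment-based approximation whose claims are
calibration and effect recovery on synthetic data, not numeric identity
to DESeq2:

* **Normalization** — median-of-ratios size factors (`size_factors()`),
  computed over genes with all-positive counts and rescaled to geometric
  mean 1. The method assumes most genes are unchanged between samples;
  designs where nearly every gene responds will bias all fold changes
  (our own recovery tests plant effects in ≤ 20% of genes for this
  reason). Note that under the geometric-mean-1 constraint, multiplying
  one sample's counts by *k* scales its factor *relative to the others*
  by exactly *k*; the absolute factor moves by `k^(1-1/m)`.
* **Dispersion** — per-gene method-of-moments estimates of the NB
  overdispersion `alpha` (`Var = mu + alpha mu^2`) within each
  condition's replicate group, combined by group size. At 2–3 replicates
  this per-gene estimate is very noisy, and plugging it into the Wald SE
  inflates the test's type-I error to ~0.09. The default
  `method = "pooled"` therefore replaces each gene's estimate by the
  mean over its expression bin (10 rank bins of mean normalized count) —
  a trended common dispersion in the spirit of edgeR's trended/common
  estimators. With it, the empirical type-I error at nominal 0.05 is
  ~0.053–0.057 in our null simulations. The raw per-gene estimate stays
  available as `method = "moments"`.
* **Test** — `lfc = log2((m_test + c)/(m_ref + c))` with pseudocount
  `c = 0.5` (smallest half-count; keeps fold changes finite at zero),
  delta-method SE
  `se^2 = (1/ln 2)^2 * sum_groups(1/(n(m+c)) + alpha/n)`, Wald statistic
  `lfc/se` against the standard normal, two-sided.
* **Multiplicity** — Benjamini–Hochberg step-up (`bh_adjust()`), applied
  to all tested genes. No independent filtering is done; genes that are
  all-zero across samples are dropped (with a count) before testing.
* **Direction call** — `up` iff `padj < alpha` *and* `lfc >= 1` (two-fold,
  boundary included), `down` symmetric, else `ns`.

## Translation efficiency and event classes

Apparent translation efficiency is the ratio of normalized footprint to
normalized mRNA abundance per condition,
`TE = (mean RPF + c)/(mean RNA + c)` (`translation_efficiency()`), using
group means rather than per-replicate ratios — at duplicate-level
replication per-replicate ratios are dominated by the noisier layer.

`classify_events()` partitions genes by their per-layer direction calls
into five classes: `concordant`, `rna_only`, `rpf_only` (the
translationally regulated class: footprints move at constant mRNA),
`discordant`, and `none`. The five-class scheme is this package's
definition — pie-chart "event" categories are rarely spelled out in
publications — and is deliberately config-free; a gene is counted once
per contrast.

## The three-criterion rescue screen

`select_targets()` consumes six wild-type-referenced contrasts (KO,
KO+KD, KD-alone; each on RNA and RPF) and evaluates, per gene and per
layer:

1. **Criterion I** — `|lfc_KO| >= 1` on the tested layer, with
   `padj < 0.05` allowed to come from *either* layer (the design's
   "significant on RNA and/or RPF" clause).
2. **Criterion II** — rescue fraction
   `(lfc_KO - lfc_KO_KD)/lfc_KO >= 0.25`, computed on log2 fold changes.
   The log2 scale treats up- and down-regulated genes symmetrically
   (negating every fold change leaves the target set unchanged); a
   linear-scale variant is available via
   `screen_config(rescue_scale = "linear")`. No p-value gating — the
   rescue comparison is included on fold change alone.
3. **Criterion III** — the KD-alone response is opposite in sign to the
   KO response *or* "has no effect". "No effect" is unquantified in
   informal usage; we define it as `|lfc_WT_KD| < log2(1.5) ≈ 0.585`, the
   midpoint class between a null and the two-fold response threshold,
   exposed as `null_lfc`.

A gene is a target when any single layer passes all three; criteria II
and III are evaluated on the same layer that supplied the fold change in
criterion I (mixing layers across criteria would make the rescue
fraction incoherent). Raising `rescue_min` or lowering `alpha` can only
shrink the target set.

Under the default synthetic conditions (below), sensitivity for planted
rescued genes is ≳ 0.95 and the false-discovery proportion fluctuates
around 0.13–0.16 across seeds, dominated by non-rescued responders whose
noisy rescue-fraction estimate (SD ≈ 0.18 at duplicates) crosses the 25%
threshold on one of the two layers. This is the honest operating point
of the published thresholds at duplicate-level replication; more
replicates shrink it quickly.

## Gene-set overlap and motif enrichment

`overlap_test()` reports the overlap count and the upper-tail
hypergeometric p-value `P(X >= k)` within an explicit universe. The
choice of universe (all detected genes vs all annotated genes) changes
the p-value materially and is left to the caller; the significance test
itself is this package's addition — published overlap figures are often
descriptive percentages.

`motif_instances()` counts possibly-overlapping IUPAC-pattern matches
with `U ≡ T` and a strict `N`-matches-nothing rule on *both* sides: an
`N` in the sequence defeats any window containing it, and a pattern `N`
can never be satisfied. This intentionally differs from the lenient
IUPAC convention (where `N` means "any base"): in this context `N` is a
sequencing ambiguity, and counting ambiguous windows as motif instances
would overstate enrichment. Because general-purpose matchers implement
the lenient rule, matching is implemented directly and verified against
an independent regex-based oracle.

`motif_enrichment()` compares per-kilobase instance densities between a
query and a background group with a two-sided rank-sum test. For small
groups the p-value is the exact permutation tail over all label
assignments (with the usual 0.5-per-tie convention in U); the normal
approximation is used only when the enumeration would exceed 20,000
assignments. This matters at the n ≤ 10 group sizes typical of candidate
lists, where approximation error is large. This instance-counting scheme
is a deliberate simplification of database-driven PWM scanning (such as
oRNAment-style analyses): motif definitions are user-supplied, with
`TCCCW` shipped as a default poly-C-class KH-domain element.

## Coverage profiles and the pausing statistic

`coverage_profile()` turns transcript-space footprint intervals into a
per-nucleotide reads-per-million profile. Each read contributes at a
single assigned position — by default its 5' end, matching plain
interval-intersection counting; a fixed P-site offset (`p_site`, default
+12 nt, clipped to the read) is available where the protocol's offset is
known. Sums are conserved: profile total × library size / 1e6 equals the
number of assigned reads.

`window_count()` counts *distinct* read ids (unique reads, i.e.
post-UMI-collapse molecules) whose assigned position falls in the
symmetric 1-based inclusive window `[center − 12, center + 12]` — 25 nt
at the default halfwidth, the window size used for focal-position
ribosome-accumulation analyses. Windows are truncated at transcript ends
with a warning. Centers are interpreted in whatever coordinate system
the position table uses (transcript or CDS); the package does not
translate between them.

`pause_test()` normalizes raw window counts to per-million of each
library and compares conditions with a two-sided pooled-variance
Student's t (df = nA + nB − 2); Welch's form is behind `welch = TRUE`.
(The normalization applies to the *counts*, not to p-values — published
methods prose sometimes elides this.) Degenerate inputs are flagged
rather than mangled: zero variance with equal means gives t = 0, p = 1;
zero variance with unequal means reports p = 0 with `degenerate = TRUE`.
At duplicate-level replication the pooled t has 2 degrees of freedom and
a 0.05-level critical value of 4.30, capping achievable power near 66%
even for 3-fold enrichments — our power demonstrations therefore use 4
replicates, while null calibration holds at any replication.

`scan_pauses()` generalizes the single-position test to a transcript-wide
scan: windowed rpm coverage per position, replicate-averaged per
condition, candidate positions where the B/A ratio (pseudocount 0.1 rpm
on both means) reaches `min_ratio` and is a local maximum (strictly
above the left neighbour, at least the right — so a flat-topped plateau
yields its leftmost position). Each candidate carries its `pause_test()`
result.

## What the synthetic generators emulate — and what they do not

`generate_counts()` draws per-gene baseline means log-uniformly over
[20, 2000] (per-million scale), applies class-defined condition
multipliers, scales to the library size, and draws NB counts. Condition
means: `WT` baseline; `KO` × `2^lfc_ko`; `WT_KD` × `2^lfc_wtkd`;
`KO_KD` × `2^(lfc_ko(1 − rescue) + lfc_wtkd)`. The default spec is
5,000 genes, duplicates, 5e6-read libraries, dispersion 0.05, 4% rescued
genes (|lfc| = 2 on both layers, 60% true rescue) and 4% non-rescued
responders; signs are drawn per gene. `generate_positions()` draws
footprint 5' ends from a uniform background with a fold-elevated window
(default 3× within ±12 nt of nt 442 of a 1,500-nt transcript, 20,000
reads per sample) in the peak-carrying conditions.
`generate_fastq()` assembles reads as
`UMI(4) + insert(26–34) + UMI(4) + adapter` with exact-copy duplicates at
a configurable rate, optional planted low-quality reads (half the bases
at Phred 10 — guaranteed below the 70% rule) and optional uniform base
errors. Every generator returns a ground-truth table and is
deterministic given the spec's seed, restoring the caller's RNG state.

Deliberately *not* modeled: alignment artifacts, multi-mapping, rRNA
contamination, 3-nt codon periodicity, length-dependent P-site offsets,
GC or positional bias, and gene–gene correlation. Passing tests
demonstrate that the statistics behave as designed under their own
assumptions — NB counts with common dispersion, uniform backgrounds —
not that those assumptions hold in any particular real library.

## Numerical choices and problem sizes

* Pseudocounts: 0.5 (half-count) on group means in fold changes and TE;
  0.1 rpm on scan ratios. Both config-exposed.
* Dispersion floor 1e-8; BH adjusted values capped at 1.
* Exact permutation cutoff: 20,000 label assignments.
* Validation problem sizes, chosen to exercise each property at
  meaningful scale: 10,000 genes × 3 replicates for null calibration;
  5,000 genes × duplicates for the screen; 2,000 genes × 3 replicates
  for TE recovery; 1,000 random instances per oracle-equivalence check;
  200 simulations for scan localization; 1,000 for pause-test null
  calibration; 2,000 reads for the end-to-end prep check.

## Known limitations

The Wald test is an approximation: no shrinkage of fold changes, no
outlier handling, normal rather than t reference for the statistic. The
rescue fraction is a ratio of noisy estimates and its threshold behaves
accordingly at duplicates (see above). The screen's "either layer may
supply significance" rule follows the published phrasing but mixing
significance across layers is ambiguous in the source; criteria II/III
are kept same-layer. Whether a focal pause coordinate refers to the
transcript or the CDS must be resolved by the user's position table.
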