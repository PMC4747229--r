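---
title: "Methods: burden, repeat-context and MSI prediction in msimut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden, repeat-context and MSI prediction in msimut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimut)
```

`msimut` reimplements, as composable functions over tabular cohorts, the
comparison of somatic mutational profiles between microsatellite-stable
(MSS) and MSI-high (MSI-H) colorectal tumors sequenced on a small hotspot
panel. This vignette records the models, parameter choices and numerical
conventions, in particular where a design question was genuinely open.

## Data model and burden

A cohort is a pair of tables: one row per tumor (`samples`) and one row per
somatic call (`mutations`). Two conventions matter downstream:

* **Zero-mutation tumors are first-class.** Burden denominators are tumor
  counts, not mutation-bearing-tumor counts, so tumors enter via a samples
  side-table even when they contribute no mutation rows. Without this, all
  group means would be biased upward.
* **MSI-Low collapses into MSS.** The analysis contrasts MSS against MSI-H
  only; MSI-L is biologically and operationally grouped with MSS here.

Four variant classes are counted: non-synonymous substitutions, deletions,
insertions/duplications, and splice-site mutations. The burden of a tumor
given an exclusion gene set and a class set is a plain filtered count;
the "uncommon" burden excludes the nine genes most commonly mutated in
colorectal cancer (`common_crc_genes()`). Group summaries report the
sample (n − 1) standard deviation by default — the convention is not
universal, so it is configurable (`sd_type = "population"`); displayed
burdens round to one decimal and displayed operating points to two, with
full precision retained in the numeric columns.

Whether the total-burden prediction rule should count all four classes or
only non-synonymous substitutions is not pinned down by the analysis it
mirrors; the default counts all four (the `classes` argument of
`tumor_burden()` makes this configurable), since the histogram-style
summaries the rules are read off also count all four.

Unknown levels of a clinical covariate (site, stage, specimen, sex) are
excluded from that covariate's percentages and test denominator only —
they never silently shrink another covariate's table.

## HGVS subset and coordinates

`parse_hgvs_c()` covers the subset a hotspot panel emits: substitution,
deletion, duplication, insertion and deletion–insertion on coding
positions. Intronic offsets, UTR positions and inversions are rejected
explicitly rather than mis-mapped: they have no coordinate on a coding
sequence. HGVS coordinates stay 1-based inclusive at the interface, as in
the notation itself; interval arithmetic inside the run scanner is plain
integer stepping, so no half-open conversion leaks out.

Frameshift protein notation `fs*N` yields N foreign residues; nonsense and
missense yield 0; a frameshift whose extent is unannotated (`fs`, `fs*?`)
yields `NA` — deliberately distinct from 0, since "unknown extent" and "no
foreign sequence" have opposite implications for neoepitope reasoning.

## Repeat-context annotation

An indel is flagged as repeat-involving when its inserted/deleted sequence
equals k ≥ 1 copies of a unit u of 1–6 nt and the maximal reference run of
tandem u-copies containing (deletions/duplications) or flanking
(insertions) the change has at least 2 copies. The ≥ 2-copy rule is chosen
because the motivating contexts include a two-copy tetranucleotide block
((TACT)2) and a two-copy dinucleotide context (dupTT); a ≥ 3-copy rule
would miss both. "Homopolymer region" in the tally tables means any
flagged repeat, mono- through hexanucleotide, matching the field's mixed
usage.

Two tie-break conventions:

* **Smallest unit wins.** A `TT` duplication in a `TT` context is scored
  as unit `"T"`, 2 copies; the 1-copy `"TT"` reading is kept in the
  annotation notes. Any larger whole-multiple unit implies the smaller one
  (a run of ≥ 2 u²-copies is a run of ≥ 4 u-copies), so this never misses
  a repeat.
* **Run-phase unit.** The unit is reported in the phase at which the run
  starts (leftmost aligned copy), so a TACT deletion from a (TACT)2 block
  reports `"TACT"` rather than its lexicographically minimal rotation
  `ACTT`; the canonical rotation is added to the notes for identity
  comparisons across phases.

Because the run is located from the reference, annotation is invariant to
where within a run the indel is written (left/right alignment) and to any
sequence outside the run; the suite checks both, plus exhaustive agreement
with an independent global run-enumeration oracle on small alphabets.

Reference sequences are shipped as small synthetic fixtures
(`pten_reference()`, `reference_fixtures()`), not transcripts: a period-7
background (which contains no tandem repeat of unit ≤ 6) with the relevant
repeat contexts planted at the coordinates their HGVS descriptions name.
They are stand-ins, clearly synthetic, sufficient for repeat-context logic
but carrying no other biological content.

## Neoepitope expectation

After a frameshift, modelling out-of-frame codons as i.i.d. uniform gives a
stop probability p = 3/64 per codon; the codon count until and including
the first stop is geometric with mean 1/p = 64/3 ≈ 21.3. The alternative
convention (1 − p)/p ≈ 20.3 counts only pre-stop codons; 1/p is the
default because the ~21-residue figure quoted for frameshift neoepitopes
corresponds to including the terminating codon. `p_stop` is a parameter
(0 < p ≤ 1) rather than a constant, since codon usage is not uniform in
real transcripts.

## Prediction rules and the assay call

`rule_spec()` expresses the three rule families (total ≥ K, uncommon ≥ K,
repeat-indels ≥ K). "More than 1 indel in homopolymeric regions" is
implemented as K = 2. Sensitivity and specificity come from the confusion
matrix against the MSI assay label; raising K can only shrink the
predicted-positive set, so sensitivity is non-increasing and specificity
non-decreasing in K — asserted as a property test.

The assay call itself (`msi_assay_call()`) is the ≥ 2-unstable rule over
the five mononucleotide loci (BAT-25, BAT-26, NR-21, NR-24, MONO-27); the
two pentanucleotide loci are specimen-identity controls, recorded and
never counted. Electropherogram-level modelling is out of scope — the
simulator stops at locus-level stable/unstable calls.

## Statistics

* **Fisher exact (two-sided):** point-probability convention — the sum of
  hypergeometric probabilities of all tables (margins fixed) whose point
  probability is ≤ the observed one, with relative slack 1e−7 to absorb
  floating-point ties, accumulated in log space via `dhyper(log = TRUE)`.
  This is the common reference convention and is verified exhaustively
  against a `choose()`-ratio enumeration oracle for every 2×2 table with
  n ≤ 40, and against `stats::fisher.test()` on random tables.
* **Chi-square:** Pearson, df 1, continuity correction off by default
  (configurable). The exact and asymptotic p-values are close in the
  significance tail but legitimately differ by several percent at
  mid-range p even with expected cells ≥ 10; the suite asserts agreement
  within 0.01 only where min(p) ≤ 0.01.
* **Student t:** pooled-variance by default, Welch via `var_equal =
  FALSE`. Degenerate zero-variance input: equal means give p = 1, unequal
  means p = 0, each with a warning — the limit of the t statistic as the
  pooled variance vanishes.
* **Degenerate 2×2 tables** (a zero margin) return p = 1 with a warning
  rather than erroring: a margin of zero carries no information about
  association, and pipelines over many gene sets must not die on an
  empty set.
* **No multiple-testing correction** is applied anywhere, deliberately
  mirroring the analysis style this package reproduces; gene-set tables
  expose both the Fisher and chi-square p so the reader can see when the
  two conventions disagree at the printed precision.

Gene-set membership is counted at tumor level — a tumor with two PTEN
mutations contributes once to the PTEN row — and the mTOR set is the union
membership of *PIK3CA*, *PTEN*, *AKT1*.

## The synthetic-cohort generator

`simulation_params()` fixes the study conditions: 113 MSS and 29 MSI-H
tumors; total burden 2.4 ± 1.6 (MSS) and 3.7 ± 2.2 (MSI-H) mutations per
tumor; per-gene tumor-level mutation probabilities from the bundled
gene-count table; variant-class probabilities from the per-class totals
(229/33/3/4 of 269 for MSS; 92/12/3/1 of 108 for MSI-H); a 1000-fold
slippage ratio between runs of 6 and runs of 2; and a hypermutator
probability of 1/113 (one CRC131-like outlier per 113 MSS tumors).

**Burden decomposition.** Per tumor, gene-level presence is Bernoulli at
the group's per-gene probability; the remaining burden is a background
count drawn from a negative binomial moment-matched to the *residual*
moments (group mean minus the sum of gene probabilities; group variance
minus the Bernoulli variance sum), with a logged Poisson fallback when the
residual is underdispersed. This makes the generated total burden match
the requested mean and SD exactly in expectation — the 5% parameter
recovery property holds by construction rather than approximately — while
keeping per-gene frequencies exactly Bernoulli. The cost is that the
background component carries nearly all the overdispersion, so its tail is
long: extreme burdens (above mean + 5 SD) occur at ~0.4% per tumor even
without hypermutators. That heavy tail is consistent with the conditions
being emulated, where the uncommon burden's SD (0.8) is four times its
mean (0.2); a light-tailed single negative binomial could not show both
the requested moments and exact Bernoulli gene frequencies.

**Slippage placement.** Simulated indels land on mononucleotide runs of
the gene's reference sequence. For MSI-H tumors, run r of length L is
chosen with weight `ratio^((min(L, 6) − 2)/4)` — a log-linear
interpolation of the single known anchor (1000× for length 6 vs length 2);
this interpolation is a modelling choice, not an observed dose–response.
MSS indels are placed uniformly across runs. One known consequence: the
simulated MSS repeat-indel *fraction* is far below the ~65% seen in real
panel data (where indel calls themselves cluster at homopolymers); the
discriminating signal the rules use — repeat-indel *counts* per tumor —
is preserved.

**Randomness.** All randomness flows from one `set.seed()` at the start of
`generate_cohort()`; generation is sequential, so identical parameters and
seed give identical cohorts, labels and assay calls. Per-locus assay
instability probabilities (default 0.90 per locus for MSI-H, 0.02 for MSS)
are placeholders — no published per-locus rates back them — and should be
replaced with assay-validation estimates where available.

**What passing tests do and do not show.** The generator emulates group
sizes, burden moments, tumor-level gene frequencies, class mix and
run-length-dependent slippage. It does not model variant allele fractions,
tumor purity, panel footprint differences between genes, co-mutation
structure beyond independence, or clonal evolution. Pipeline results on
synthetic cohorts therefore validate the *machinery* (counting, annotation,
tests, rule evaluation), not biological claims about real cohorts.

## Problem sizes and tolerances in the suite

The suite runs at desk scale: exhaustive Fisher-vs-oracle over all 2×2
tables with n ≤ 40 (~135,000 tables); exhaustive annotator-vs-scanner over
all {A,C} sequences of length ≤ 8 with all deletions of length ≤ 4, plus
200 random mixed-alphabet cases; moment recovery on 2,500 + 2,500 tumors;
power properties over 20–50 seeds with thresholds set ~3 SE below their
enumerated or simulated expectations, so seed-to-seed variation does not
produce false alarms.

## Known limitations

* The HGVS subset is deliberately narrow; no transcript database is
  consulted, so protein consequences are taken from the `p.` column, never
  re-predicted from the nucleotide change.
* Repeat annotation requires a reference coding sequence per gene; genes
  without one annotate as `NA` and are reported, not dropped.
* The VCF reader handles minimal single-allele records with INFO-carried
  annotations; multi-sample genotype semantics beyond carrier detection
  and symbolic ALTs are out of scope.
* The per-tumor profile table feeds rules directly; no ROC-style threshold
  optimization is provided, by design.
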