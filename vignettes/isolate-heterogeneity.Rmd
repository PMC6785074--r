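---
title: "Measuring inter-individual genomic heterogeneity in population isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-individual genomic heterogeneity in population isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Population isolates — small groups separated from their neighbours by
geography or language — are classically pictured as genetically homogeneous:
founder effects, drift and sustained inbreeding should make their members
look alike. `isohet` implements an analysis framework that asks a different
question: not how diverse an isolate is on average, but how *unevenly* that
diversity is spread across its members. Recent introgression of outside
ancestry, or cryptic subdivision, shows up as inflated **variance of
per-individual diversity measures** within a population even when the means
look ordinary — and that heterogeneity matters, for example, as an
unmodelled confounder in disease-association studies run in isolates.

## The framework

Every analysis follows the same two-level recipe:

1. compute a **per-individual** measure of genomic diversity;
2. summarise each population by the **unbiased sample variance** of those
   individual values, and compare variances between populations and between
   the open/isolated groups.

The per-individual measures are:

* **HOM** — proportion of homozygous calls among non-missing genotypes;
* **IBS** — mean (or, for variance scans, median) of the individual's
  pairwise identity-by-state proportions against all members of its own
  population;
* **RoH-NSEG / RoH-KB** — number and total length (kb) of runs of
  homozygosity, called by the PLINK-style two-phase scanning algorithm;
* **F_ROH** — fraction of the SNP-covered autosomal extent lying in RoH
  (optionally after masking centromeres), used as the inbreeding
  coefficient;
* **ADX_HET** — for ancestry proportions $q_{i1},\dots,q_{iK}$ from an
  ADMIXTURE-style Q matrix, $\frac1K\sum_k (q_{ik}-\bar q_{Pk})^2$, the mean
  squared deviation from the population's mean ancestry profile;
* **CHR_P** — total genetic length of haplotype chunks copied from
  same-population donors under a Li & Stephens copying model (median over
  donors).

Populations are compared pairwise with the **Brown–Forsythe Levene test**
(absolute deviations from the group median, F reference with $(k-1, N-k)$
degrees of freedom), Bonferroni-corrected per measure over the pairs
actually tested. Following the convention used for count summaries of such
scans, a comparison is credited to a focal population only when it is
significant *and* that population's standard deviation is the larger one
(`sd_ratio > 1`), so each pair credits at most one side. Group-level
contrasts (isolated vs open) use a two-sided Mann–Whitney U test on the
population-level variance values — exact enumeration up to a combined
n of 20 without ties, midrank normal approximation with tie correction (and
no continuity correction) otherwise.

## Quality control

`qc_pipeline()` applies the conventional array-QC chain: SNP call rate
(strictly greater than 0.90), individual call rate (strictly greater than
0.92), exact Hardy–Weinberg exclusion at $p < 10^{-6}$, and relatedness
pruning at PI_HAT > 0.185 with one member of each related pair removed by a
seeded random choice. Strict inequalities mean boundary samples/variants are
removed. The HWE exact test is the standard conditional enumeration over
heterozygote counts, implemented with a mode-anchored ratio recurrence;
whether it is applied per population (default: a variant is dropped if it
fails in any population) or cohort-wide is a documented option, since either
convention is defensible for multi-population panels. PI_HAT is the
method-of-moments IBS-decomposition estimator from cohort allele
frequencies; the small-sample bias-correction factors some implementations
apply are omitted, so frequency estimates should come from a reasonably
sized cohort (monomorphic variants are skipped, missing genotypes excluded
pairwise everywhere — nothing is imputed).

## Runs of homozygosity

`call_roh()` reproduces the two-phase scanning logic of PLINK's
`--homozyg` with the settings used for array data of this density:

| parameter | default | meaning |
|---|---|---|
| `window_snp` | 50 | SNPs per scanning window |
| `window_kb` | 5000 | maximal window span (kb); wider windows are skipped |
| `window_het` | 1 | heterozygous calls tolerated per homozygous window |
| `window_missing` | 5 | missing calls tolerated per homozygous window |
| `window_threshold` | 0.05 | minimal homozygous-window hit fraction per SNP |
| `min_kb` | 500 | minimal emitted segment span |
| `min_snp` | 14 | minimal emitted segment SNP count |
| `density_kb` | 50 | maximal kb per SNP within a segment |
| `max_gap_kb` | 1000 | maximal gap between consecutive segment SNPs |

Segment boundaries are the first and last RoH-eligible SNP positions (no
extension to window edges). `n_snps` counts every SNP in the emitted run,
the PLINK convention; `count_mode = "homozygous"` restricts the count (and
the 14-SNP minimum) to homozygous calls for users who read the minimum as
"14 homozygous SNPs". Two numerical caveats discovered while validating
against an exhaustive window-enumeration oracle are worth knowing:

* the algorithm is **not monotone** under added heterozygosity once the
  density filter is active — splitting a long, too-sparse run can create
  pieces that pass the 50 kb/SNP constraint. Monotonicity does hold for the
  eligible-SNP set and for raw run length with the segment-level filters
  disabled, and that is what the property tests assert;
* with evenly spaced SNPs the density constraint implies a hard floor on
  usable marker spacing (strictly below 50 kb/SNP), which is why the
  synthetic map uses 50 kb spacing, matching the effective density of a
  ~90k-SNP array genome.

## Haplotype painting

`paint_recipient()` is a deliberately simplified reimplementation of the
copying-model coancestry idea: a hidden Markov chain whose state is the
donor haplotype being copied, with switch mass $1 - e^{-N_e d / D}$ over an
interval of $d$ Morgans spread uniformly across the $D$ donors, and emission
$1-\theta$ / $\theta$ on allele match/mismatch. Forward–backward gives, per
donor, the expected number of copied chunks (expected donor switches plus
one per chromosome, apportioned by posterior mass) and the expected copied
genetic length (posterior mass times half-interval map weights — lengths sum
exactly to the painted map length). `em_fit_parameters()` alternates these
expectations with closed-form/1-D maximisation updates for $\theta$ and
$N_e$, by convention on a subset of chromosomes for 10 iterations, after
which the parameters are fixed. Uniform donor priors are used and
chromosomes are combined by plain summation; numerical parity with the
ChromoPainter/ChromoCombine toolchain is explicitly *not* a goal — the
target is the downstream CHR_P heterogeneity pattern. Within-population
painting excludes self-copying, and the per-individual CHR_P value is the
median (optionally mean) over donors of total copied length.

`switch_error_rate()` quantifies phasing quality as the fraction of
consecutive heterozygous-site pairs whose relative phase differs between a
truth and an inferred haplotype pair; the orientation indicator makes the
count invariant under a global haplotype swap. Note that a fully
alternating-vs-constant comparison scores 1 under this definition, not 0.5.

## Switch-count admixture dating

A single admixture pulse $g$ generations ago with proportion $\alpha$ leaves
ancestry along a haplotype as a two-state Markov process with expected
switch density $2 g \alpha (1-\alpha)$ per Morgan. Inverting gives the
moment estimator implemented by `estimate_admixture_date()`:

$$\hat g = \frac{S}{2\,\alpha(1-\alpha)\,L\,H}$$

with $S$ the observed ancestry-switch count (chromosome ends are not
switches), $L$ the per-haplotype map length in Morgans and $H$ the number of
haplotypes contributing to $S$ (2 per diploid; exposed explicitly because
conventions differ). $\alpha$ is taken from tract lengths rather than from a
Q matrix, for internal consistency. The estimator is symmetric in
$\alpha \leftrightarrow 1-\alpha$, returns 0 with a warning when $S = 0$,
and is undefined at $\alpha \in \{0, 1\}$. Because the source publications
do not print a closed formula for this dating approach, validation is by
simulation recovery: across $g \in \{3, 6, 10\}$, $\alpha \in \{0.1, 0.3,
0.5\}$ at $L = 35$ Morgans and 30 diploids, cohort-mean estimates land
within $\max(1, 0.2g)$ of the truth.

## The synthetic scenario

No suitable genotype panel for this design is publicly deposited, so the
package ships a seed-deterministic generator whose **default scenario is the
study design itself**: 8 open populations (n = 20, Balding–Nichols drift
0.02, expected autozygosity 0.005) and 4 isolates (n = 24, drift 0.08,
autozygosity 0.04), with half of the first isolate (12 of 24 individuals)
carrying a pulse of outside ancestry from the first open population's
lineage, 5 generations old with $\alpha = 0.3$.

Free parameters of the generator were fixed once, on design grounds:

* **map**: 6 chromosomes of 150 cM / 150 Mb at 1 cM/Mb with 3000 evenly
  spaced SNPs each (50 kb spacing — the marker density at which the RoH
  caller's density constraint behaves as it does on a ~90k array genome;
  18,000 variants and 256 samples keep a full end-to-end run around ten
  seconds on one core);
* **per-individual inbreeding**: $F_i$ truncated-normal around the
  population's autozygosity with a coefficient of variation of 0.35 —
  individuals of an isolate differ in pedigree inbreeding, which is what
  gives isolates their elevated RoH variance relative to open populations;
* **autozygous segments**: exponential lengths (mean 5 cM) implanted by a
  debiased stopping rule so the expected total matches $F_i \cdot L$;
* **introgressed individuals** carry no implanted autozygosity: a pulse a
  handful of generations ago breaks up the inbreeding loops that generate
  long autozygous segments, and this contrast — heterogeneous ancestry plus
  eroded autozygosity in half the population — is precisely the signature
  the framework is designed to detect;
* the **truth Q matrix** has K = 2 columns (own vs introgressing-source
  ancestry) derived from tract lengths, bypassing any clustering software.

Sites are drawn independently given ancestry, so the genotypes carry no
background LD. That is adequate for HOM/IBS/RoH/ADX_HET/dating, whose
statistics only depend on site-wise frequencies and the implanted segment
and tract structure, but it would make painting trivial; painting tests use
`simulate_copying_pool()`, which builds haplotypes as mosaics of a shared
founder pool so genuine chunk structure exists. Consequently, passing the
scenario-level tests demonstrates that the statistical machinery detects
the designed heterogeneity structure — it does not demonstrate robustness
to LD, array ascertainment bias, genotyping error, or real demographic
history, none of which are simulated.

On this scenario the package reproduces the qualitative headline of the
analysis it implements: the introgressed isolate attains the largest
variance for the diversity measures and by far the largest count of
Bonferroni-significant Levene comparisons with `sd_ratio > 1`; removing its
heterogeneous-ancestry (HTA) half — identified by the 99%
village-specific-ancestry split of the Q matrix — collapses that count;
isolates as a group exceed open populations in RoH-KB and RoH-NSEG variance
(Mann–Whitney p < 0.05) while IBS stays comparable; inbreeding and ancestry
heterogeneity correlate strongly and positively across an
isolation gradient; and switch-count dating recovers the implanted pulse
ages, including in a synthetic stand-in for the classic three-population
African-American calibration design.

## Numerical and degenerate-case conventions

* Undefined-by-construction results (all-missing sample, singleton
  population, pair with no co-typed variants, zero ADX_HET median in the
  mean/median ratio) return `NA` with a warning rather than erroring.
* A Levene test in which every group has zero spread returns `NA` with a
  warning; if only one side has zero spread the statistic diverges and p is
  0, and an infinite SD ratio is handled by the scan.
* Forward–backward uses per-site scaling; posteriors sum to 1 to 1e-9 and
  copied lengths to the map length to 1e-6 relative, which the tests
  assert.
* The Bonferroni family defaults to per-measure over the pairs actually
  tested and is configurable, since reasonable analyses differ on whether
  sub-group comparisons belong in the denominator.
* All generators require an explicit integer seed; identical seeds give
  byte-identical outputs.

## Known limitations

* ADMIXTURE/CLUMPP clustering, SHAPEIT phasing and RFMix local-ancestry
  inference are consumed, never run: Q matrices, phased haplotypes and
  per-site ancestry calls are inputs (or simulated truths).
* The painting model is a single-parameter-pair simplification; its
  coancestry values are not comparable unit-for-unit with ChromoPainter
  output, only their within-population contrasts are meaningful.
* The dating estimator assumes a single pulse; continuous migration or
  multiple waves bias $\hat g$ toward intermediate values.
* The generator's truth Q is two-component; multi-way admixture and
  ancestry-specific drift are out of scope.
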