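---
title: "Calling differential methylation regions and epigenetic control regions from two-colour promoter tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential methylation regions and epigenetic control regions from two-colour promoter tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`medipdmr` implements an analysis pipeline for two-colour MeDIP-Chip
promoter tiling arrays. The input is a set of comparative hybridizations:
on each array, methylated-DNA-enriched material from a treatment lineage
(Cy3) competes against the corresponding control (Cy5), across every probe
of a promoter tiling design. The pipeline identifies differential DNA
methylation regions (DMRs), characterizes their genomic features, selects
differentially expressed (DE) genes from a companion expression matrix,
and searches for chromosomal clusters of DE genes — candidate epigenetic
control regions (ECRs). A synthetic-data generator produces inputs with
known planted signal so that every stage can be validated by parameter
recovery.

## The methylation model, stage by stage

Per probe and hybridization the two channels are reduced to
$M = \mathrm{Cy5} - \mathrm{Cy3}$ and $A = (\mathrm{Cy5} + \mathrm{Cy3})/2$
on the log2 scale. $M$ is the methylation log-ratio of interest; $A$ is
the average intensity, against which dye bias expresses itself.

**GC-grouped within-array loess.** Probes are split into GC-content groups
(deciles by default; the group count is a free parameter) and, within each
group and hybridization, a loess curve of $M$ on $A$ is fitted and
subtracted, so each GC group receives its own normalization curve. We fit
a degree-2 robust (symmetric-family) loess with span 0.4. Degree 2
matters: intensity-dependent dye bias is curved, the tails of the $A$
distribution are sparse, and a local-linear smoother measurably
undercorrects there — in our simulations the residual trend at the extreme
percentiles of $A$ was ~0.16 with a local-linear fit and ~0.03 with local
quadratics, against a target of keeping any refit trend below 0.05.
Groups smaller than 200 probes fall back to the pooled curve; a group with
(near-)constant $A$ falls back to subtracting its median $M$.

**A-quantile across arrays.** The distribution of $A$ is forced to be
identical across arrays (each probe's $A$ becomes the mean of the $A$
values at its rank), leaving every probe's $M$ untouched. This is the
standard "Aquantile" contract for two-colour arrays and is computed by
limma.

**600 bp windowed median smoothing.** Each probe's $M$ is replaced by the
median of the probe $M$ values within a 600 bp window around it, and $A$
is smoothed the same way. If fewer than 3 distinct probe positions fall in
the window, *no value is assigned*: the probe is flagged invalid and is
excluded from all downstream statistics. Positions, not measurements, are
counted, so pooling arrays cannot rescue an isolated probe.

Two smoothing choices deserve explanation because the procedure only
prescribes "a 600 bp window":

* *Boundary-corrected anchoring.* Windows are probe-centered but clamped
  to stay inside the contiguous run of tiled probes. A promoter tiled at
  100 bp spacing gives interior probes 7 window members but edge probes
  only 4–5 under naive probe-centered anchoring; the windowed medians of
  edge probes then carry visibly higher variance, and the probe Z-score
  below — which scales all probes by one empirical standard deviation —
  becomes anticonservative exactly at promoter edges (we measured roughly
  a seven-fold inflation of the $p<10^{-5}$ tail, concentrated at the
  first and last probes of promoters). Clamping the window, as in any
  boundary-corrected moving average, equalizes occupancy and restores
  calibration. Runs shorter than the window use the whole run.
* *Per-array smoothing by default.* Pooling all arrays into one median
  makes the smoothed $M$ identical across hybridizations, which collapses
  the per-hybridization probe statistics and with them the all-pairs
  intersection below: all pairwise site counts become equal and the
  intersection retains any probe whose noise happens to align across the
  raw hybridizations. Per-array smoothing keeps the three hybridizations
  statistically distinct (their pairwise counts differ, as they should)
  and is the default; pooling remains available via `pool_arrays = TRUE`.

**Probe significance.** Within each hybridization the valid smoothed $M$
values are compared to a normal distribution scaled to their empirical
mean and standard deviation: $z = (M - \hat\mu)/\hat\sigma$, two-sided
normal $p$, significant at $p < 10^{-5}$. The analysis is then performed
in pairs of comparative hybridizations: a probe is retained only when it
is significant in *all* pairwise comparisons, which is equivalent to
significance in every hybridization. This is deliberately stringent; the
pairwise set sizes are reported alongside.

**Region building and filters.** Retained probes are clustered by joining
consecutive probes within 600 bases of each other whose mean $M$ values
share a sign; the region interval spans the outermost probe extents, its
direction is the shared sign (+1 hypermethylated in the Cy5 channel's
terms), and its $p$-value is the *least favorable* member-probe $p$ — the
most conservative choice, since the procedure only promises "a $p$-value
associated with each region". Regions are annotated with the overlapping
promoter (largest overlap; ties break to the lexicographically smaller
gene id) and their CpG content, then filtered: average intensity
(mean $A$) must exceed 9.5 on the log scale, strictly, and CpG density
must be at least 1 CpG/100 bp.

## Genomic features of DMR sets

CpG density histograms use 1-unit bins of CpG/100 bp with an open final
bin at 11; DMR sets from methylation studies of this kind concentrate in
the 1–4 CpG/100 bp "CpG desert" bins. Motif incidence — the fraction of
sequences with at least one hit — is computed by exact IUPAC consensus
matching (ambiguity codes expand on the motif side only; an N in a
sequence never matches a non-N consensus position) or by PWM log-odds
scoring, on both strands, and compared between a DMR promoter set and a
size-matched random promoter background with a two-proportion z-test
(Fisher's exact test when any expected cell is below 5). The package
ships a synthetic placeholder consensus for demonstrations
(`default_motif()`); any consensus or PWM can be supplied. Cross-set DMR
overlap reports all interval pairs overlapping by at least a configurable
number of bases.

## Differential expression selection

Each gene's un-logged signals are tested with an additive two-factor
linear model on the log2 scale, treatment plus batch; the reported
$p$-value is the marginal F-test for treatment, and the model degrades to
one-way when only one batch is present. A gene is selected when all three
gates pass: $p < 0.05$, fold change $> 1.2$ (the larger of the un-logged
group-mean ratio and its reciprocal), and un-logged mean difference
$> 10$. Fold change is computed on un-logged means for consistency with
the mean-difference gate. No multiple-testing correction is applied — the
three-gate rule is itself the filter, and the fixed thresholds are the
selection rule being reproduced. The original study corrected batch
effects with a proprietary variance-components implementation; the
explicit fixed-effects model used here is a standard equivalent for the
selection rule, which is the reusable computation.

## ECR detection

Gene bodies are assigned to 2 Mb windows laid at a 50 kb stride
(half-open, by gene-body midpoint, so every gene counts once per window).
Each window with at least one gene is tested with a one-proportion
z-statistic of its DE fraction against the genome-wide DE fraction
$\pi_0$, one-sided (over-representation only), at $\alpha = 0.05$.
Consecutive flagged windows merge into ECR clusters; typical recovered
spans are 2–5 Mb. No correction is made across windows: adjacent windows
share genes and are strongly dependent, which inflates the family-wise
rate but leaves the per-window level near nominal — the null calibration
contract is therefore a bound of 0.08 on the flagged fraction rather than
the nominal 0.05. DMRs are associated with clusters by gap distance
(within 2 Mb), and DMR–expression correlation distinguishes *direct*
pairs (the DMR's promoter gene is itself DE) from *distal* pairs (DMR
within 2 Mb of a DE gene body, direct pairs excluded).

## The synthetic-data generator

The generator emulates the geometry of a 720K-style promoter tiling
platform at desk scale (about a 35× linear reduction): 2 chromosomes of
10 Mb, 400 non-overlapping promoters spanning 3,880 bp upstream to 970 bp
downstream of the TSS (strand-reflected), tiled with 48 probes each
(50–75-mer, 100 bp midpoint spacing) for ~19,200 probes, with
per-promoter CpG densities drawn from a mixture concentrated at 1–4
CpG/100 bp and a small high-density class.

Hybridizations share a per-probe log2 abundance (mean 10, sd 0.5 — so
typical regions clear the 9.5 intensity filter), add the planted DMR
shift ±ΔM to $M$ consistently across hybridizations, an optional smooth
dye bias (a low-order polynomial in $A$ and GC fraction, amplitude 1 by
default — the minimal structure that makes GC-grouped loess non-trivial),
and independent Gaussian noise (sd 0.3). The raw-signal distribution of
real scanners is not documented for this platform; Gaussian-on-log2 is a
stand-in, and results that depend on tail shape should be read
accordingly. Planted DMRs are runs of 6–10 consecutive probes inside a
promoter, accepted only where the realized CpG density meets the region
filter, with |ΔM| defaulting to 1.2 = 4 × noise sd; their probes'
abundance is floored so the region mean $A$ cannot fall under the 9.5
filter by chance — planted regions are *defined* as recoverable.
Expression uses a paired batch design (one control and one treated sample
per batch, 3 batches), log-normal noise, and planted DE genes whose
un-logged group-mean ratio equals their multiplier (2 by default); genes
inside a planted 1 Mb cluster interval are DE with 10× the background
probability of 0.05. Promoter sequences match promoter length and CpG
placement, with the motif planted in a recorded subset and Bernoulli
background occurrences elsewhere.

What the generator does **not** emulate: immunoprecipitation chemistry,
fragment-size effects, probe cross-hybridization, spatial array
artifacts, or the heavy-tailed intensity distributions of real scanners.
Passing the recovery and calibration suite demonstrates that the
implementation is faithful and internally calibrated under these
idealized conditions, not that the thresholds are optimal for any real
data set.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; strand affects only
  promoter and gene-body construction.
* Two-sided probe p-values (regions are called in both directions);
  one-sided window p-values (only over-representation is sought).
* An exact-zero mean $M$ at clustering is broken toward +1 and logged
  (a measure-zero event in practice).
* Empirical $\hat\mu, \hat\sigma$ are per hybridization over valid probes
  only; a pooled-moments option exists. Invalid probes can never seed or
  join a region.
* $\pi_0$ for the window test is the genome-wide DE fraction; a
  chromosome-wide reference can be passed explicitly.
* The two-proportion z-test is uncorrected (its printed-formula z is the
  contract); it agrees with Fisher's exact test within ~10% on tables
  with hundreds of sequences per set, and the exact test takes over
  automatically for small expected cells.
* The normal tail of the window z-test degrades beyond the decision
  region; its factor-of-two agreement with the exact binomial is
  maintained where $p \gtrsim 10^{-3}$, which brackets the
  $\alpha = 0.05$ rule.
* All randomness flows from one root seed through fixed per-stage
  offsets; re-runs are byte-identical.

## Problem sizes used in validation

The test and acceptance suites run the generator at its default desk
scale (19,200 probes, 3 hybridization pairs, 400 genes); null
calibrations use 10 seeds, oracle-equivalence checks run on instances up
to 5,000 probes / 1,000 genes / 200 regions, chosen so the whole suite
completes in a few minutes while keeping every check at the scale its
bound was stated for.

## Known limitations

* The fixed $10^{-5}$ probe threshold is not FDR-controlled; none is
  prescribed by the procedure being reproduced.
* Region p-values are max-of-members and should be read as conservative
  labels, not calibrated tail probabilities.
* With only 3 samples per group the per-gene F-test has 2 residual
  degrees of freedom; genuine 1.2-fold effects near the noise floor are
  detected unreliably, which is a property of the design, not the code.
* The ECR windows are strongly overlapping; cluster boundaries extend
  beyond the underlying enriched interval by up to about one window width
  on each side.
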