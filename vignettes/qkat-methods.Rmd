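---
title: "Copy-number typing of KIR genes from multiplex qPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number typing of KIR genes from multiplex qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qkatr)
library(dplyr)
```

## The problem

The killer-cell immunoglobulin-like receptor (KIR) cluster on chromosome 19
varies not only allelically but in gene content: non-allelic homologous
recombination produces haplotypes carrying different subsets of the ~15 KIR
genes, so individuals differ in how many copies (0–4 and occasionally more)
of each gene they carry. Presence/absence typing hides this dosage. qKAT is
a quantitative workaround: ten multiplex real-time PCR reactions, each
amplifying two KIR targets and the fixed-copy reference gene *STAT6* from
the same well, typed in quadruplicate on 384-well plates. Because each well
contains one DNA aliquot, the within-well difference of quantification
cycles, $\Delta C_q = C_q^{KIR} - C_q^{STAT6}$, is independent of the amount
of input DNA; copy number follows from relative quantification
($\Delta\Delta C_q$).

This package implements the computational half of that workflow: the assay
panel as validated data, $C_q$ extraction from amplification curves,
copy-number calling, linkage-disequilibrium (LD) consistency checks,
gene-content haplotype imputation, and a synthetic cohort generator that
stands in for the wet lab.

## The quantification model

For a sample $s$ with $k$ copies of a target and a calibrator anchored at
$(\Delta C_q^0, CN^0)$:

$$\Delta\Delta C_q = \Delta C_q^{(s)} - \Delta C_q^{0}, \qquad
\widehat{CN} = CN^0 \cdot 2^{-\Delta\Delta C_q},$$

assuming doubling per cycle. The integer call rounds
half-away-from-zero, so an estimate of exactly 0.5 calls one copy: copy
number zero has a *qualitative* signature (no amplification in the presence
of a successful STAT6 reaction), never a quantitative one. Estimates above a
hard cap (default 8) are flagged implausible and suppressed. A per-call
confidence, $\max(0,\,1 - 2\,|\widehat{CN} - CN|/\max(CN, 1))$, measures
distance to the nearest integer; it is this package's own definition, not an
instrument vendor's.

Replicates are aggregated before calling: if at least half of a sample's
valid quadruplicate wells show no KIR amplification the aggregate is
dropout (a zero call); otherwise the median of the non-dropout $\Delta C_q$
values is used, with the raw median absolute deviation as a dispersion
diagnostic. Wells whose STAT6 channel failed are invalid — a reference
failure, excluded from aggregation and flagged, never interpreted as copy 0.

## Calibration

Two anchoring modes are provided, mirroring common copy-number analysis
software:

* **Calibrator sample** — a sample of known copy number anchors each locus.
  Loci at which the calibrator's known copy number is zero cannot be
  anchored by it (nothing amplifies) and fall back to the second mode. This
  fallback is unavoidable: no single biologically valid haplotype pair
  carries all 20 measurements, since 2DS4FL and 2DS4Del are alternative
  forms and the A/A pairs that cover both lack all B-specific genes.
* **Most frequent copy number** — each locus is anchored so that the
  plate's most common class sits at the default copy number observed in
  European-origin cohorts (packaged with the panel; 1 or 2 per locus).

The most-frequent mode deserves detail because the naive implementation (a
plate median) is fragile. Copy-number classes form a rigid log2 ladder in
$\Delta C_q$: adjacent classes are $\log_2(2/1) = 1$, $\log_2(3/2) = 0.585$
and $\log_2(4/3) = 0.415$ cycles apart. For loci such as 2DL3 the modal
class holds only ~54% of amplified samples, so a plate median sits a
coin-flip from the class boundary; for 2DS4Del the two amplified classes
are ~60/40. We therefore choose the anchor by **integer-ladder scoring**:
every observed $\Delta C_q$ is a candidate anchor assigned the default copy
number; each candidate is scored by the total misfit of all plate samples
to integer copy estimates (with amplified samples forbidden from rounding
to zero); ties are resolved by parsimony — an anchor one rung too high
doubles every call, so the candidate implying the smallest maximum copy
number wins — and then by the size of the implied default class. The final
anchor is the median $\Delta C_q$ of that class. On noise-free plates this
is exact for every class structure the simulator can produce, and it is
insensitive to class balance under noise. Gap-based clustering and
median-seeded partition refinement were both tried and discarded: the first
merges classes 0.585 cycles apart at realistic noise, the second collapses
when the seed median falls midway between two classes.

Calibration is per plate: each plate carries its own controls, and
inter-plate normalisation beyond that is out of scope. Mode-2 requires at
least five non-dropout samples per locus per plate.

## Cq extraction

Two methods are implemented, matching the options in instrument software:

* **Second-derivative maximum.** The $C_q$ is the point of maximal
  acceleration of the amplification curve. Finite differences at one-cycle
  spacing cannot localise this skewed peak to sub-0.1-cycle accuracy (every
  refinement we measured — three-point quadratic interpolation, Richardson
  extrapolation, spline second derivatives, local polynomial fits — lands
  0.15–0.38 cycles early on a noiseless logistic), so the curve is smoothed
  with a Savitzky–Golay local cubic (window 5) and a four-parameter
  logistic $b + P/(1 + e^{-k(c - m)})$ is fitted by Levenberg–Marquardt;
  the maximum is analytic at $m - \ln(2+\sqrt3)/k$. The discrete
  quadratic-interpolation estimator is retained as a fallback when the fit
  does not converge. The analytic location on a noiseless logistic serves
  as the test oracle (tolerance 0.05 cycles).
* **Fit points.** A log-linear line through the first three cycles above a
  user-set noise band, reported at its band crossing. On a pure exponential
  the crossing is exact, and doubling the band costs exactly one cycle.

Curves are classified flat (no $C_q$) when the total rise above the
baseline median is less than five baseline standard deviations (baseline =
cycles 3–12, strict inequality). Both methods are translation-equivariant,
and the constant offset between them cancels in $\Delta\Delta C_q$ as long
as calibrator and samples are called with the same method. Pre-computed
$C_q$ tables (the instrument-export path) and raw curves are both accepted.

## The synthetic cohort generator

The simulator emulates the experimental design, not the chemistry:

* **Haplotype pairing.** Samples draw two haplotypes independently with
  probability proportional to reference frequency (Hardy–Weinberg random
  mating). Truth profiles are per-locus sums.
* **Built-in reference table.** The published European reference list is
  not redistributable, so the package ships a small synthetic table —
  labelled synthetic everywhere — with the two A-group haplotypes (2DS4
  full-length and deleted forms) and four common B-group gene contents.
  Frequencies (0.45/0.20/0.12/0.12/0.08/0.03) were chosen once for European
  realism: A-group ≈ 65% with ~70% of A haplotypes carrying the 2DS4
  deletion, and every locus's most frequent amplified class agreeing with
  the packaged default copy numbers, as the defaults table asserts for
  European cohorts. Real analyses should supply their own table
  (`read_haplotype_table()`).
* **Plate geometry.** Each sample occupies one 96-well source position and
  is dispensed in quadruplicate onto the 2×2 block of the corresponding
  384-well positions, one plate per reaction.
* **Cq model.** A well with $k$ copies reads
  $C_q = b_{KIR} - \log_2 k + d + \varepsilon$ (dropout when $k = 0$), and
  STAT6 reads $b_{ref} + d + \varepsilon$. Defaults: one-copy baseline
  $b_{KIR} = 28$, $b_{ref} = 24$ — mid-twenties values typical of ~10 ng
  template. $\varepsilon \sim N(0, \sigma)$ is per-channel noise (default
  $\sigma = 0.1$ cycles); $d \sim N(0, 0.3)$ is DNA-concentration drift,
  shared by all wells and channels of a sample because they are fed from
  one aliquot. Neither magnitude is a published value; both are
  configuration chosen once as realistic. Shared drift cancels exactly in
  $\Delta C_q$ — the design reason the assay tolerates concentration
  variation — and an optional per-channel drift mode breaks that
  cancellation to reproduce the concentration-artefact failure mode.
* **Curves.** Optionally, each well becomes a 40-cycle logistic curve whose
  midpoint is positioned so the chosen $C_q$-calling method recovers the
  target $C_q$ (analytically for the second-derivative method, by root
  finding for fit points); dropout wells are flat baseline plus noise.

What the simulator does **not** model: PCR efficiency below 100%, probe
cross-hybridisation, allele dropout from primer-site polymorphism (the
panel's "alleles possibly missed" annotations are carried as data only),
and inter-plate batch effects. Passing round-trip tests therefore
demonstrates the correctness of the calling arithmetic and plumbing under
the stated error model — not robustness to every artefact of real plates.

## LD quality checks

Ten arithmetic relations between locus copy numbers, observed in
European-origin populations, serve as per-sample consistency checks:
framework loci (3DL3, 3DP1, 2DL4, 3DL2 by both exon assays) equal 2;
2DS2 = 2DL2; 2DL2 + 2DL3 = 2; 2DP1 = 2DL1; exon-4 = exon-9 for 3DL1 and
3DL2; 3DL1 + 3DS1 = 2; 2DS3 + 2DS5 = 2DL5; 3DS1 = 2DS1;
2DS1 + 2DS4Total = 2; 2DS4FL + 2DS4Del = 2DS4Total. The mutual-exclusion
wording of the 2DS1/2DS4 relation is implemented as its printed arithmetic
form. Rules are data (CSV-loadable), because cohorts from other populations
need different, typically stricter, checks. Every single-locus ±1
perturbation of a valid profile violates at least one rule — verified
exhaustively over all built-in haplotype pairs — which is what makes the
table usable as QC. Violations flag samples for manual re-checking; they do
not suppress imputation (the report travels alongside), and missing loci
make the affected rules "not evaluable" rather than violated.

## Haplotype imputation

Given a called profile and a reference table, the imputer enumerates all
unordered haplotype pairs (self-pairs included) whose per-locus sums equal
the profile over all 20 measurements; exhaustive enumeration over a few
hundred reference haplotypes *is* the algorithm, and an independently coded
brute-force enumerator serves as the test oracle. Each pair carries a
combined Hardy–Weinberg frequency $f_1 f_2$ (homozygous) or $2 f_1 f_2$
(heterozygous); the factor 2 is this package's reading of "combined
frequency" and is stated in the output. Three files are written: all
consistent pairs, the trimmed best (ties retained), and the unassignable
samples — candidates for miscalls or novel haplotypes. NA loci make a
sample unassignable unless explicitly wildcarded. Recovery is tested two
ways: the true pair of every noise-free simulated sample must appear in the
all-pairs file, and the fraction of samples whose trimmed-best entry equals
the truth is compared with the frequency-weighted posterior (Bayes) rate
computed by the oracle — with a three-standard-error allowance, because the
trimmed-best rule *is* the Bayes rule, so the observed fraction fluctuates
around that rate rather than sitting above it.

## Problem sizes and numerical choices

The validation suite uses cohorts of 24–192 samples; exactness claims use a
96-sample noise-free cohort (with an A/A calibrator and one
2DL5-duplicated B/B control so that copies 0–4 all occur), and the noise
study uses 20 cohorts of 96 at $\sigma = 0.1$. Under that noise the
per-seed accuracy ordering — copies ≤ 2 called at least as reliably as
copies ≥ 3 — reflects the log2 compression of the ladder at high copy
number: the CN 3→4 separation (0.415 cycles) is less than three aggregate
noise SDs. Other fixed choices: GC% and copy calls round half away from
zero (the convention that reproduces every printed panel value); the
amplicon span convention is 1-based inclusive (`rev end − fwd start + 1`,
with the outermost forward primer for the two-primer 3DL3 assay); STAT6 has
no published coordinates, so its 129-bp amplicon is stored as a literal and
never recomputed; melting temperatures are annotations, never validated,
because the printed values' thermodynamic model is unstated.

## Known limitations

* The built-in haplotype table is synthetic; imputation against it
  validates the machinery, not European haplotype biology.
* The per-channel Cq noise model is Gaussian and homoscedastic; real
  late-cycle noise is not.
* The second-derivative maximum is defined here via a fitted symmetric
  logistic; instruments use proprietary variants, so absolute $C_q$ values
  may differ by a constant that cancels in $\Delta\Delta C_q$.
* Efficiency-corrected quantification (for assays amplifying at less than
  doubling) and inter-plate normalisation are out of scope.
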