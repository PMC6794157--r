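# qkatr

Copy-number typing of killer-cell immunoglobulin-like receptor (**KIR**)
genes from multiplex real-time PCR, after the qKAT assay design.

The KIR cluster on chromosome 19 varies in *gene content*: haplotypes carry
different subsets of the ~15 KIR genes, so individuals hold 0–4 (sometimes
more) copies of each. qKAT types all of them with ten multiplex qPCR
reactions, each amplifying two KIR targets plus the fixed-copy reference
gene *STAT6* from the same well, in quadruplicate on 384-well plates. This
package implements the analysis half of that workflow for immunogeneticists
and disease-association studies:

* the published assay panel (primers, probes, reaction/channel layout,
  default European copy numbers) as validated, queryable data;
* Cq extraction from amplification curves by the second-derivative-maximum
  and fit-points methods;
* integer copy-number calling by relative quantification — for a sample
  with within-well ΔCq = Cq(KIR) − Cq(STAT6) and an anchor
  (ΔCq⁰, CN⁰):

  CN̂ = CN⁰ · 2^−(ΔCq − ΔCq⁰),

  with calibrator-sample or most-frequent-copy-number calibration,
  dropout-aware replicate aggregation, and per-call confidence;
* the ten European linkage-disequilibrium consistency rules as data-driven
  QC (e.g. framework genes = 2, 2DL2 + 2DL3 = 2, 2DS4FL + 2DS4Del =
  2DS4Total);
* gene-content haplotype-pair imputation against a reference haplotype
  table, with the three standard output files (all pairs / best pairs /
  unassigned);
* plate-export parsing, per-reaction splitting on the 96→384 quadruplicate
  geometry, and a one-call pipeline;
* a synthetic qPCR cohort generator (Hardy–Weinberg haplotype pairing,
  log2 copy-number Cq shifts, dropout at copy 0, shared
  DNA-concentration drift) used throughout the tests.

## Worked example

Simulate a 96-sample cohort (95 random samples plus an A/A control) under
realistic noise, call copy numbers, run QC and impute haplotypes:

```r
library(qkatr)

panel <- load_assay_panel()
panel
#> qKAT assay panel: 10 multiplex reactions, 20 KIR measurements + STAT6
#>   reaction  1: 3DP1 + 2DL2
#>   reaction  2: 2DS2 + 2DL3
#>   ...
#>   reaction 10: 2DS5 + 2DS4Total

truth <- simulate_cohort(95, seed = 42,
                         fixed_pairs = list(CAL = c("A_2DS4del", "A_2DS4del")))
cq    <- synthesize_cq(truth, panel, cq_noise_sd = 0.1, drift_sd = 0.3, seed = 43)
calls <- call_copy_numbers(cq, panel, calibration = "most_frequent_cn")
glance(calls)
#> # A tibble: 1 × 5
#>   n_samples n_loci mean_confidence frac_dropout frac_flagged
#> 1        96     20           0.935        0.240            0

profiles <- build_profiles(calls, panel)
profiles[1:3, c("sample_id", "3DL3", "2DS2", "2DL2", "2DL3", "3DS1", "2DL5")]
#>   sample_id 3DL3 2DS2 2DL2 2DL3 3DS1 2DL5
#> 1 CAL          2    0    0    2    0    0
#> 2 S001         2    2    2    0    1    3
#> 3 S002         2    1    1    1    1    2

glance(check_ld(profiles))
#> # A tibble: 1 × 4
#>   n_samples n_conforming frac_conforming n_violations
#> 1        96           96               1            0

glance(impute_all_pairs(profiles))
#> # A tibble: 1 × 4
#>   n_samples n_assigned n_unassigned mean_pairs_per_assigned
#> 1        96         96            0                    1.14
```

Reading the numbers: `frac_dropout = 0.24` is the fraction of
(sample, locus) groups with no amplification — true zero-copy genotypes,
e.g. 3DS1-negative A/A homozygotes, not failures. Mean confidence 0.94
means estimates sit close to integers at this noise level (0.1 cycles per
channel). Every called profile satisfies all ten LD rules, every sample
receives at least one consistent haplotype pair, and on this run every call
matches the simulated truth (`mean(called == truth)` is `1`). Flagged calls
(low confidence, high replicate dispersion, reference failure, conflicts)
are annotated per locus in `profiles$flags`.

Raw instrument-style exports go through the same path:

```r
files <- write_plate_export(cq, "exports")          # tab-delimited, one per plate
res <- run_pipeline(exports = files$path, out_dir = "out")
# out/: calls.csv, profiles.csv, ld_report.csv, qc_by_sample.csv,
#       haplotypes.{all,best,unassigned}.csv
```

A thin command-line front end with `simulate`, `callcq`, `calltype`, `qc`,
`impute` and `pipeline` subcommands is installed at
`system.file("cli", "qkat.R", package = "qkatr")`.

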