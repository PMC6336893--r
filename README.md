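# norpop

Post-variant-calling population genomics for small, closely related
populations — modelled on whole-genome resequencing studies of native
cattle breeds, but applicable to any diploid resequencing panel.

Starting from a filtered VCF (or from the built-in coalescent simulator),
`norpop` covers the full downstream analysis:

* **Variant QC and accounting** — GATK-style hard filters for SNPs and
  indels; shared/private set decomposition across populations; Ts/Tv,
  het/hom, novelty against a known-sites catalogue, and concordance with
  genotyping-array calls.
* **Functional annotation** — ANNOVAR-style classification of every variant
  against a gene model (splicing > exonic > UTR > intronic >
  up/downstream > ncRNA > intergenic), codon-level SNP effects
  (synonymous / nonsynonymous / stopgain / stoploss) and indel effects
  (frameshift / non-frameshift / stop changes), plus per-gene
  nonsynonymous-burden gene selection.
* **Diversity and spectra** — nucleotide diversity π, Watterson's
  θ̂<sub>W</sub> = S / (a<sub>n</sub> L), folded one- and two-population
  site-frequency spectra with hypergeometric projection, dadi-format I/O,
  and genotype PCA.
* **Sweep scan** — a SweepFinder-style composite likelihood ratio (CLR)
  test on a 5-kb grid: at distance d from a sweep with intensity α per bp,
  lineages escape with probability 1 − e<sup>−αd</sup>, which deterministically
  distorts the background frequency spectrum; the scan maximizes the CLR
  over α at each grid point, flags the top 0.5% of points per chromosome,
  and reports genes within 150-kb windows around outliers.
* **GO enrichment** — one-sided Fisher exact tests against the annotated
  universe with Bonferroni correction, excluding terms with fewer than 5
  mapped study genes.
* **Demographic inference** — maximum-likelihood fit of a five-parameter
  two-population model (ancestral size change at T<sub>a</sub>, split at
  T<sub>d</sub> into demes of relative sizes ν<sub>1F</sub>, ν<sub>2Y</sub>,
  ancestral relative size ν<sub>a</sub>) to the folded joint SFS, with
  Monte-Carlo expected spectra, profile-θ estimation of N<sub>A</sub>,
  Fisher-information confidence intervals, and conversion to diploid sizes
  and years.
* **A generator with truth records** — independent-site structured
  coalescent simulation under the same model family, a toy annotated
  genome, GO maps, known-site catalogues and array extracts, so every
  estimator is testable against known truth.

See the vignette (`vignettes/norpop-methods.Rmd`) for the statistical
model and the numerical choices.

## Quick start

```r
library(norpop)

# simulate a two-population panel with known truth
cfg <- sim_config(n_pops = 2, seq_length = 1e5, seed = 11)
sim <- simulate_neutral(cfg)
gm  <- sim$matrix

# diversity (generating theta per site is 0.001)
nucleotide_diversity(gm, "pop1")
#> [1] 0.001051333
watterson_theta(segregating_sites(gm, "pop1"), 10, gm$l_eff)
#> [1] 0.001141759

# demographic fit from the folded joint SFS (truth: 2, 0.4, 0.05, 1, 0.5;
# at 1e5 sites the intervals are wide — see the acceptance tests for the
# calibration study)
js  <- build_joint_sfs(gm, "pop1", "pop2")
fit <- fit_demography(js, seed = 1, n_starts = 2, n_reps = 5000,
                      n_reps_final = 5e4, n_reps_hessian = 2e5)
round(fit$par, 3)
#>   nua    Ta    Td  nu1F  nu2Y
#> 3.330 1.103 0.086 2.829 0.691
round(to_physical_units(fit$par, Na = fit$Na, g = 5)$years["Td"])
#>    Td
#> 12265

# sweep scan on a planted sweep
phi <- fold_spectrum(1 / (1:9), 10); phi <- phi / sum(phi)
sw   <- simulate_sweep_field(
  sim_config(n_pops = 1, seq_length = 1e6, seed = 3, n_sites = 1e5,
             sweep = list(alpha_true = 1e-4, center_bp = 5e5)), phi)
scan <- clr_scan(sw$matrix, chrom_length = 1e6)
scan$pos[which.max(scan$CLR)]
#> [1] 5e+05
```

Or run everything as a pipeline:

```r
run_pipeline(pipeline_config("out_dir", seed = 42))
# writes out_dir/{simulate,filter,summarize,annotate,diversity,
#                 sweep,enrich,demography}/..., pipeline.log, report.json
```

`run_pipeline()` also accepts a YAML file with the same fields.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "norpop", load_package = "installed")'
```

The suite includes `tests/testthat/test-acceptance.R`, which checks the
headline claims end to end: estimator calibration (π̂ and θ̂<sub>W</sub>
within 3 replicate standard errors of the generating θ = 0.001), sweep
localization power (≥ 90% of planted sweeps localized within 100 kb) and
neutral false-positive rate, exact agreement of the sweep spectrum with
exhaustive enumeration, ≥ 8/10 coverage of the demographic 95% confidence
intervals at the truth, brute-force-verified annotation on both strands,
and exact hypergeometric enrichment p-values.

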