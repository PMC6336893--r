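---
title: "Methods: population-genomic analysis of structured populations with norpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic analysis of structured populations with norpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(norpop)
```

`norpop` implements a complete whole-genome resequencing analysis for a pair
(or trio) of closely related populations: variant filtering and summary,
functional annotation against a gene model, diversity and site-frequency
statistics, a composite-likelihood scan for selective sweeps, gene-set
enrichment, and maximum-likelihood fitting of a two-population demographic
model. Because real resequencing data cannot ship with a package, `norpop`
also contains a coalescent generator that produces data under the same model
family the inference targets, with full truth records, so every estimator can
be validated end to end.

This vignette documents the statistical model, the estimators, and the
numerical choices, in the order the pipeline runs them.

## The demographic model

All inference is organized around a five-parameter history for two
populations, F and Y, descending from a common ancestor of diploid effective
size $N_A$. Backward in time (time in units of $2 N_A$ generations):

* the two contemporary demes have constant sizes $\nu_{1F} N_A$ and
  $\nu_{2Y} N_A$;
* at time $T_d$ they merge into a single ancestral deme of size
  $\nu_a N_A$;
* at time $T_a > T_d$ the ancestral deme reverts to size $N_A$.

This captures the common situation of an ancestral expansion (or
contraction) followed by a recent split. The per-site scaled mutation rate is
$\theta = 4 N_A \mu$; defaults ($\mu = 1.1\times10^{-8}$,
$N_A = 22{,}727$) give $\theta \approx 0.001$ per site, typical of
livestock genomes.

`demographic_params()` builds and validates a parameter set;
`to_physical_units()` converts to diploid sizes $\nu N_A$ and years
$T \cdot 2 N_A g$ with generation time $g$; `na_from_theta()` recovers
$N_A = \theta / (4 \mu L)$ from a genome-wide Watterson estimate.

## The generator

`simulate_neutral()` draws independent-site genealogies under the structured
coalescent for this model with `sim_config()` controlling sample sizes, the
sequence length, mutation weighting and the seed. Sites are independent (no
linkage), mutations are placed as a single biallelic hit per segregating
site, and transition/transversion identity is drawn with a configurable
weight (default 2:1 in favour of transitions). Every simulation returns a
`truth` block: generating parameters, per-population minor-allele counts,
and (for sweep fields) the planted sweep location, so tests never have to
re-derive the truth from the data.

The generator is deliberately minimal where realism does not affect the
estimators under test: there is no linkage, no sequencing error model beyond
the array-concordance error injection, and indels are generated only to
exercise the filtering and annotation paths. What it does reproduce
faithfully is the sampling distribution of the joint site-frequency spectrum
under the five-parameter model, which is what the downstream inference
consumes.

```{r simulate}
cfg <- sim_config(n_pops = 2, seq_length = 5e4, seed = 11)
sim <- simulate_neutral(cfg)
n_sites(sim$matrix)
```

`make_gene_model()` builds a toy annotated genome (protein-coding genes with
in-frame, stop-free CDS, UTRs and introns, plus ncRNA genes) used by the
annotation and enrichment stages; `make_go_map()` attaches genes to terms;
`make_array_genotypes()` produces a genotyping-array extract with a known
error rate for concordance checks.

## Variant I/O and hard filtering

`read_vcf()`/`write_vcf()` round-trip sites, genotypes and the INFO fields
needed for filtering. `apply_hard_filters()` implements conventional
hard-filter rules with separate SNP and indel thresholds (quality by depth,
strand bias, mapping-quality-zero fraction, homopolymer run length), records
one named reason per failed rule, and is idempotent. Thresholds are
arguments, not constants, and the defaults follow standard short-read
practice.

## Variant summaries

`venn_counts()`/`venn_percentage()` decompose sharing among populations;
`tstv_ratio()`, `het_hom_counts()`, `novel_fraction()` (against a
known-sites list, allele-aware) and `genotype_concordance()` (against array
genotypes) compute the standard per-callset quality summaries.

```{r summaries}
tstv_ratio(sim$matrix)
```

## Diversity and the site-frequency spectrum

`nucleotide_diversity()` computes $\pi$ as the average pairwise difference
per effective site with complete-case handling of missing genotypes;
`watterson_theta()` is $S / (a_n L)$. `build_folded_sfs()` and
`build_joint_sfs()` tabulate the folded 1D and 2D spectra;
`project_sfs()` hypergeometrically projects to smaller sample sizes, and
`write_sfs_dadi()`/`read_sfs_dadi()` exchange spectra in the standard dadi
text format. `genotype_pca()` gives the usual covariance-based principal
components for population structure.

Folding conventions matter for the joint spectrum: a cell and its complement
are pooled into the cell with the smaller total derived count, ties are
split evenly, and a mask marks the cells that are not identifiable after
folding. `fold_joint_matrix()` is exported so tests can verify the
convention directly.

## Sweep scan

The scan is a composite-likelihood-ratio test in the SweepFinder family.
Under the sweep model, a site at distance $d$ from a sweep centred with
compound parameter $\alpha$ (selection intensity per bp) escapes the sweep
with probability $p_e = 1 - e^{-\alpha d}$. Lineages that do not escape
coalesce into the sweeping background, which transforms the background
frequency spectrum $\phi$ into a distance-dependent spectrum: the number of
escaping lineages is Binomial$(n, p_e)$, and conditional on $i$ of $n$
lineages escaping, a derived allele at background count $B$ survives at a
count given by hypergeometric sampling plus the ancestral lineage carrying
the allele with probability $i/n$-type weights. `sweep_spectrum()` computes
the folded version of this spectrum exactly; an exhaustive enumeration
oracle validates it to $10^{-12}$ for $n \le 6$.

`clr_scan()` evaluates, on a 5-kb grid, twice the maximized log ratio of the
sweep model to the background model, maximizing over $\alpha$ by a coarse
log-grid followed by golden-section refinement. Two numerical choices keep a
chromosome scan fast:

* per-site likelihood contributions depend only on $t = \alpha d$ and the
  folded frequency class, so the scan precomputes a 16,384-point table of
  log-likelihood-ratio contributions over $t \in [0, -\log 10^{-6}]$ and
  linearly interpolates; the induced error is far below the golden-section
  tolerance;
* sites with $\alpha d > -\log 10^{-6}$ contribute nothing (escape
  probability within $10^{-6}$ of 1) and are excluded by binary search, so
  each grid point only touches sites inside its effective window.

`call_outliers()` flags the top fraction (default 0.5%) of grid points per
chromosome, keeping ties at the cutoff; `annotate_windows()` reports genes
within a window (default 150 kb) centred on each outlier.

## GO enrichment

`enrich()` performs the one-sided Fisher exact test (hypergeometric upper
tail) per term against the annotated universe, with Bonferroni adjustment
over the terms actually tested. Terms with fewer than `min_mapped` study
mappings (default 5) are excluded before testing, matching standard
annotation-tool behaviour; the Bonferroni denominator counts only tested
terms.

## Demographic inference

`fit_demography()` fits the five-parameter model to the folded joint SFS by
maximum composite likelihood. Expected spectra come from Monte-Carlo
integration of expected branch lengths under the structured coalescent
(`expected_joint_sfs()`), with common random numbers across parameter values
so the likelihood surface is smooth in the parameters for a fixed seed. The
multinomial likelihood over unmasked cells is maximized with `optim` (BFGS on
log parameters, multiple starts); $\theta$, and hence $N_A$, is profiled out
analytically as the ratio of observed segregating sites to expected tree
length.

Standard errors use the expected Fisher information in Gauss-Newton form,
$I_{ij} = S \sum_k \partial_i p_k \, \partial_j p_k / p_k$, computed from
central differences of the Monte-Carlo cell probabilities. This form is
positive semidefinite by construction, which matters: a direct numerical
Hessian of a Monte-Carlo likelihood surface is frequently indefinite at
realistic replication levels, whereas the Gauss-Newton form only needs first
derivatives, which are much better conditioned. Confidence intervals are
Wald intervals on the natural scale.

```{r fit, eval = FALSE}
js <- build_joint_sfs(sim$matrix, "pop1", "pop2")
fit <- fit_demography(js, seed = 1, n_starts = 2, n_reps = 5000,
                      n_reps_final = 5e4, n_reps_hessian = 2e5)
fit$par
fit$ci
to_physical_units(fit$par, Na = fit$Na, g = 5)$years
```

Monte-Carlo replication is an accuracy/time dial: `n_reps` for the search,
`n_reps_final` for re-evaluating candidate optima, `n_reps_hessian` for the
information matrix. The defaults favour accuracy; the values shown above
are sufficient for calibrated 95% intervals at $10^5$ sites and run in
under two minutes.

## Pipeline

`run_pipeline()` chains the stages (simulate, filter, summarize, annotate,
diversity, sweep, enrich, demography) from a `pipeline_config()` list or a
YAML file, writes one artifact directory per stage plus a log and a JSON
report, derives per-stage seeds deterministically from the master seed, and
enforces stage dependencies (enrichment needs annotation and the sweep
scan).

```{r pipeline, eval = FALSE}
out <- run_pipeline(pipeline_config(tempfile("run"), seed = 42))
```

## Validation strategy

Every statistical routine in the package is tested against either an
independent oracle (brute-force mutant-genome translation for annotation,
exhaustive enumeration for the sweep spectrum, explicit hypergeometric tails
for enrichment, hand-computed pairwise differences for $\pi$) or a
closed-form expectation of the generating model (constant-size spectra,
$2/k$ branch lengths, planted sweeps and planted GO terms with known
locations). The acceptance suite additionally checks estimator calibration:
$\hat\pi$ and $\hat\theta_W$ against the generating $\theta$, sweep
localization power and neutral false-positive rate, and coverage of the
demographic confidence intervals at the truth.
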