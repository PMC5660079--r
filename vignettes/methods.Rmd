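---
title: "Models and design decisions in assocpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in assocpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocpipe)
```

`assocpipe` packages several association-testing designs — main-effect
scans, interaction tests, phenome-wide scans, CNV burden and enrichment,
and rare-variant burden — around one regression engine and one pipeline
interface. This vignette records the statistical models, the conventions,
and the design decisions taken where more than one reasonable choice
existed, so that results are interpretable and reproducible.

## Data conventions

**Coordinates.** All positions, CNV rectangles, and region spans are
1-based and fully inclusive. A CNV from 1001 to 2000 covers 1000 bp; two
intervals overlap iff `max(starts) <= min(stops)`. Standard BED files are
0-based half-open, so `read_regions(..., one_based = FALSE)` converts on
input.

**Allele orientation.** Genotype calls are stored as counts of a *counted
allele* per marker. At load time the counted allele is always `allele2`
(ALT in VCF, A2 in binary PLINK, the lexicographically larger observed
allele in text PLINK; a monomorphic marker gets `allele1 = "0"`, mirroring
PLINK's absent minor allele, and its single observed allele is counted).
Loading therefore never depends on allele frequencies and is
side-effect-free; `recode_minor_allele()` is the one operation that
re-orients calls to minor-allele counts, flipping `g -> 2 - g` where the
counted-allele frequency exceeds 0.5 and keeping the current orientation at
an exact 0.5 tie. It is idempotent and preserves missingness and MAF.

**Trait typing.** A non-numeric column is `categorical`; a numeric column
with at most two distinct non-missing values is `binary`; anything else is
`continuous`. Categorical covariates of N observed levels contribute N-1
indicator columns with the first sorted level as reference.

## The regression engine

Three families are implemented directly (so that behaviour under
separation and non-convergence is explicit rather than inherited):

* **linear** — closed-form least squares via the QR decomposition;
  Wald p-values from t-tests on `n - p` degrees of freedom.
* **logistic** — iteratively reweighted least squares, converged when the
  deviance changes by less than 1e-8, capped at 50 iterations, with
  step-halving to keep the likelihood monotone.
* **firth** — the Jeffreys-prior penalized likelihood maximised through
  the modified score `U*(b) = X'(y - mu + h(1/2 - mu))`, which yields
  finite estimates under complete or quasi-complete separation. The
  reported log-likelihood of a Firth fit is the *penalized* one, so an LRT
  between two Firth fits is a penalized LRT.

**Separation.** A logistic deviance plateau at ~0 is a perfectly
separating fit, not convergence, so the solver keeps iterating in that
regime until the boundary is detectable; a fit whose probabilities reach
within 1e-10 of 0 or 1 is flagged `separation_detected`, reported as
non-converged, and its Wald p-values are withheld. The engine deliberately
does **not** fall back to Firth regression automatically: the two tests
have different small-sample behaviour, and the user opts in explicitly.

**Complete cases.** A sample missing any column of a model — outcome,
either term, the product's factors, or a covariate — is excluded from both
the full and the reduced fit. The likelihood-ratio test refuses fits with
different sample counts, because a silent N mismatch between nested models
is the classic interaction-test bug. The degenerate identity case (full
and reduced coincide, 0 df) returns stat 0 and p 1 rather than an error. A
zero-variance predictor (for example a product column that is identically
zero) is rejected as a degenerate design; inside a scan this is recorded
on the result row without aborting the other models.

**Permutation p-values.** The outcome vector alone is permuted against the
intact design — covariates stay attached to their samples — and the
returned value is the *proportion* of permutations whose p-value is
strictly smaller than the observed one, so 0 is attainable. Permuted fits
that fail count as p = 1 (they cannot beat the observed fit). Permuting
the outcome rather than residuals is a deliberate simplification; under
strong covariate effects it is only approximately exchangeable, which is a
documented limitation.

## Scans and multiple testing

`enumerate_models()` fixes the model order (pairs are lexicographic, ids
`A×B`), and `run_scan()` fits each model independently, so per-model
failures never abort a scan. Corrections — Bonferroni `min(1, p*m)` and
Benjamini–Hochberg FDR via `stats::p.adjust` — are computed over the tests
actually performed, i.e. `m` counts the converged fits of the scan.
Interaction scans are summarised by the LRT p; everything else by the
term-of-interest Wald p.

QC thresholds are strict inequalities (call rate *above* 99%, MAF *above*
5% survive, a marker at exactly the threshold is dropped), whereas the CNV
call filter is inclusive (`>= 10` supporting SNPs, `>= 1` kb). Filter
statistics are computed once on the dataset as passed in — a pipeline of
explicitly chained filter steps, not an iterative re-filtering.

## CNV burden and enrichment

Burden sums inclusive call lengths per sample and state; copy-number depth
does not matter (a homozygous deletion counts its span once), and
overlapping calls within a sample are summed without merging. The
enrichment test builds a binary sample×gene matrix (≥ 1 bp overlap; a gene
hit twice by one sample still scores 1), computes the carrier-proportion
ratio, and ranks the observed score among itself plus `n_perm` scores from
permuted phenotype labels. One permuted label vector scores *all* genes in
each iteration, which conserves carrier totals and keeps the cost at
O(n_perm × genes). Ties count against the observed score (it ranks after
equal permuted scores), making the test conservative; with zero control
carriers the score is `+Inf` rather than pseudo-count smoothed, because
the rank only needs an ordering and the eligibility filter (at least 10
case and 10 control carriers by default) makes the sentinel rare. No
multiplicity correction is applied to these p-values, whose floor is
`1/(n_perm + 1)`.

Because carrier counts are integers, permuted scores tie with the observed
one noticeably often in small cohorts, and the tie rule then shifts the
null p distribution visibly above uniform. The null-uniformity test
therefore uses a large cohort (6000 samples, 800 genes, carrier
probability 0.5) where ties are rare and the discrete-uniform expectation
applies; in small cohorts users should expect the test to be conservative,
not anti-conservative.

## Rare-variant bins

A variant joins a region bin if its position lies in the span and its MAF
is strictly below the threshold (default 0.05). Weights follow the
Madsen–Browning scheme: `q = (m+1)/(2*n_controls + 2)` from control allele
counts with pseudo-counts (all samples are used, with a message, when no
controls are available), and `w = 1/sqrt(n_total * q * (1-q))` with
`n_total` the samples genotyped at the variant. A missing genotype inside
a bin contributes 0 copies — deterministic and conservative; mean
imputation was rejected because it makes scores depend on cohort
composition. Overlapping regions are allowed and bins are tested
independently.

## The pipeline interface

Analyses are sequences of verbs (`load-data`, `recode-alleles`,
`filter-maf`, ..., `logistic`, `regress-auto`, `concordance`,
`output-data`) over one shared state. The parser normalises runs of dashes
(so the occasional `---covariates` typo parses), rejects unknown verbs and
flags by listing the valid ones, and `--correction` takes a comma list.
`--exclude-markers` (and, equivalently, running a regression verb with no
genotype data loaded) switches to trait-only models in which burden
variables from the trait table are the predictors. Identical pipelines on
identical inputs produce byte-identical outputs.

Result files are tab-delimited with one header row, `NA` for missing
statistics, and p-values in scientific notation with six significant
digits, so files diff cleanly across runs.

## The synthetic-data generators

`simulate_genotypes()` draws independent markers in Hardy–Weinberg
equilibrium at specified MAFs with optional uniform missingness;
`simulate_phenotype()` builds outcomes from the regression model the tests
target, `Y = b0 + b1*G + b2*E + b3*G*E` (Gaussian noise or Bernoulli
through the logit); `simulate_cnv_calls()` draws Poisson call counts with
log-uniform lengths between 1 kb and 1 Mb and supports enriching a target
region in cases. Every generator is a pure function of its arguments and
seed, restoring the global RNG state afterwards.

These cohorts deliberately omit linkage disequilibrium, population
structure, relatedness, and realistic MAF spectra. Passing tests therefore
demonstrate the correctness of the estimators, the test statistics and
their operating characteristics under independence — not robustness to
confounding, which the surrounding QC pipeline (PCA, relatedness pruning)
is expected to handle upstream.

## Test problem sizes

The test suite measures operating characteristics at sizes chosen to make
the Monte-Carlo error small relative to the asserted bounds: coefficient
agreement with reference implementations on 50 random designs; the
interaction-LRT type-I error over 1000 null cohorts of n = 500 (asserted
within the binomial 95% band around 0.05); G×E recovery over 100 cohorts
of n = 2000 at b3 = 0.8 (power above 0.8, estimates within 3 SE); the
enrichment null over 800 genes in a cohort of 6000; and rare-variant
burden recovery in a cohort of 700 with a dozen injected risk variants.
All of these run under fixed seeds and complete in well under a minute
each on one core.

## Known limitations

* Permutation of the outcome (not residuals) is approximate under strong
  covariate effects.
* The Firth LRT is a penalized LRT; its null distribution is treated as
  chi-square, which is a common but approximate choice.
* Multi-allelic VCF sites are skipped (with a warning), not decomposed.
* The enrichment permutation test is conservative under heavy score ties
  (small cohorts, few distinct carrier counts).
* Bin membership is positional only; functional annotation, pathway-level
  and multi-level binning are out of scope, as are knowledge-base model
  generation, CNV calling, and upstream QC such as HWE tests, relatedness,
  and PCA.
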