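---
title: "Windowed rare-variant C-alpha testing with biased-urn permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed rare-variant C-alpha testing with biased-urn permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarewin)
```

## The problem

Single-marker logistic regression detects common variants (CVs, sample minor
allele frequency $\ge 0.05$) but is underpowered for rare variants (RVs,
MAF $< 0.05$). One strategy is to let the common variants point the way:
rank CVs by a covariate-adjusted association scan, then pool the rare
variants found in fixed windows around the top-ranked index markers and test
each pooled set jointly. `rarewin` implements this design for case-control
cohorts, with the C-alpha overdispersion test as the pooled statistic, a
biased-urn permutation null that accounts for population stratification, and
a Fisher's-exact comparison of windows whose index markers fall inside genes
(anywhere in the 5'-to-3' UTR span) versus outside.

## The C-alpha statistic

For variant $i$ in a window let $n_i$ be the total number of minor-allele
copies in the sample (a homozygote contributes two) and $y_i$ the number
carried by cases. With $p_0$ the proportion of cases among subjects, the
null hypothesis is that every copy falls in a case with probability $p_0$,
i.e. $y_i \sim \mathrm{Bin}(n_i, p_0)$. The statistic contrasts the observed
squared deviation with its binomial expectation:

$$T = \sum_i \left[(y_i - n_i p_0)^2 - n_i p_0 (1-p_0)\right],$$

with null variance obtained by exact enumeration,

$$c = \sum_i \sum_{u=0}^{n_i} \mathrm{Bin}(u; n_i, p_0)
      \left[(u - n_i p_0)^2 - n_i p_0(1-p_0)\right]^2 .$$

$Z = T/\sqrt{c}$ is asymptotically standard normal, upper tail only: a
mixture of deleterious ($p_i > p_0$) and protective ($p_i < p_0$) variants
inflates $T$ upward, which is exactly why C-alpha keeps power where burden
tests (which assume one direction of effect) lose it. Because windows hold
few variants, the primary p-value is by permutation, not the normal
approximation: $p = (1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(1 + B)$, ties
counting against rejection.

Two conventions worth stating. First, $p_0$ is the case share of
*subjects*, not of chromosomes. Second, singletons ($n_i = 1$) are removed
before testing, and a window retaining $\le 1$ rare variants is reported as
"n/a" rather than tested: a single rare variant carries essentially no
overdispersion information and its "test" would only add noise to the
downstream gene comparison.

## Stratification and the biased urn

Uniform case/control relabeling assumes exchangeable subjects. With latent
subpopulations that differ both in allele frequencies and in disease rate,
that null is wrong and the naive permutation test is anticonservative. The
package's remedy re-labels cases non-uniformly: each subject gets a weight
$w_j = \hat\pi_j / (1 - \hat\pi_j)$, the fitted odds from a logistic model
of case status on the first $k$ principal components of an LD-pruned
genotype panel plus the clinical covariates (smoking, blood-pressure
medication, age at first visit, sex; $k = 5$ by default). A permuted case
set $S$ of the observed size $K$ is drawn with probability proportional to
$\prod_{j \in S} w_j$ — the multivariate Fisher noncentral hypergeometric
(conditional Bernoulli) law. Sampling is exact and sequential via the
elementary-symmetric-polynomial recursion in log space, never by rejection,
so every draw has exactly $K$ cases and the sampler can be validated against
full subset enumeration. With equal weights the scheme reduces to the
uniform permutation, draw for draw.

Principal-component scores use the standard frequency standardization
(centre by $2f$, scale by $\sqrt{2f(1-f)}$), with component signs fixed by
the largest-magnitude coordinate so results are platform-reproducible.

## The pipeline

`run_pipeline()` chains the stages: VCF/BED/TSV ingestion; data cleaning
(variants with three or more alleles excluded; Hardy-Weinberg exact test at
$p < 0.01$ on all subjects pooled, the exact conditional test being the
appropriate choice at $n \approx 100$; any-visit collapsing of the
longitudinal hypertension/smoking/medication indicators to 1/2 codes); a
Wald logistic scan of CVs adjusted for the four clinical covariates, with
no multiple-testing correction (the scan only *ranks* markers); selection
of the top $k = 10$ index markers (ties broken by position, then id);
window extraction at half-widths 1, 5 and 25 kb; C-alpha with $B = 1000$
urn samples per window; and per-width Fisher comparisons of in-gene versus
not-in-gene significance at $\alpha = 0.05$. Subjects missing status or any
covariate are dropped before the urn/testing stage and the retained count
is reported, mirroring designs where the PCA panel further restricts the
usable subjects.

Numerical choices: logistic fits run IRLS to gradient tolerance $10^{-8}$,
with separation flagged (never silently reported); urn probabilities are
clipped to $[10^{-6}, 1 - 10^{-6}]$ before the odds transform; the
two-sided Fisher p uses the probability-mass rule with a $10^{-7}$ relative
tolerance on the comparison; "window size" is read as half-width (a
"1-kb window" spans $\pm 1$ kb around the index marker), the common
convention for windows *around* a position.

## The synthetic cohort generator

Restricted-access cohorts cannot ship with a package, so `rarewin` is
developed and validated against `simulate_cohort()`, which generates the
statistical structure the method assumes:

* **Population structure.** Subjects are assigned to `n_subpops` latent
  subpopulations; each variant's subpopulation frequencies are
  Balding-Nichols beta draws around an ancestral frequency with divergence
  `fst`, and genotypes follow Hardy-Weinberg proportions within
  subpopulation. Balding-Nichols is the standard one-parameter divergence
  model and reproduces stratification confounding when a per-subpopulation
  liability shift (`subpop_shift`) is also set.
* **Variant layout.** Common variants (ancestral frequency 0.1-0.5) spread
  over the chromosome; around each of `n_rv_clusters` index positions, a
  cluster of rare variants (ancestral frequency 0.002-0.03, so the expected
  sample MAF is safely below 0.05) within a configurable span.
* **Effects.** Each cluster's index CV carries odds ratio `or_common`
  (default 2.5 — chosen so an index marker is detectable, though not
  guaranteed top-ranked, in a cohort of about a hundred subjects); cluster
  RVs are apportioned deterministically (largest remainder) among
  deleterious (OR 3), protective (OR 1/3) and neutral classes at the
  configured mix, with the class-to-variant assignment randomized within
  the cluster.
* **Phenotypes.** The collapsed any-visit status is primary: liability =
  intercept + covariate terms + genetic terms + subpopulation shift, with
  the intercept calibrated by root-finding so the expected case fraction
  matches the target (default 60/94, the case share of the motivating
  design). Per-visit indicators are then derived from the collapsed status
  with visit-level noise — the analysis only ever uses the collapsed
  coding, so simulating visits the other way round would add nothing but
  would break the calibration.
* **Seeds.** One master seed; each stage (genotypes, phenotypes) derives a
  child stream, so stages regenerate independently and all outputs are
  byte-identical under a fixed seed.

`write_fixture()` emits VCF + BED + TSV, with rare-variant clusters
assigned alternately to in-gene and not-in-gene spans (ten clusters give a
5/5 split, the balanced design that minimizes bias in the gene
comparison).

What the generator does **not** emulate: linkage disequilibrium within and
between clusters (variants are independent given subpopulation), relatedness,
genotyping/sequencing error, missingness patterns, and quantitative traits.
Passing calibration and power checks on these cohorts therefore validates
the statistical machinery — exact sampling laws, permutation calibration,
stratification correction — not robustness to LD or data artifacts in any
particular real cohort.

## Validation studies shipped in the test suite

The test suite regenerates every number it asserts. The main studies, with
the problem sizes the package adopts:

* **Exactness.** C-alpha $T$ and $c$ against brute-force accumulation and
  ungrouped enumeration (exhaustive over windows of up to 4 variants with
  up to 4 copies each); the Hardy-Weinberg exact test against a direct
  factorial enumeration oracle (all genotype tables up to 20 subjects);
  two-sided Fisher p against hypergeometric enumeration (all 2x2 tables
  with total up to 30); the urn sampler against complete subset enumeration
  (8 subjects choose 4, total-variation distance over 20,000 draws).
* **Calibration.** 400 null cohorts (103 subjects, one 20-RV cluster, no
  effects, no structure), windowed C-alpha at $B = 500$: rejection at the
  nominal 0.05 within [0.03, 0.07].
* **Stratification.** 300 confounded cohorts (two subpopulations,
  `fst` 0.1, subpopulation log-odds shift $\mp 1$, 500-CV panel for the
  PCs): the naive permutation rejects well above nominal, the urn-adjusted
  test does not. The PCA panel is used unpruned here: the simulated panel
  is already independent given ancestry, and at $r^2 \le 0.01$ with
  $n \approx 100$ the empirical-correlation threshold would strip the very
  markers that carry the ancestry signal (pruning earns its keep on real,
  LD-rich panels, for which `ld_prune()` is the pipeline default).
* **Power.** Clusters mixing 50% deleterious / 20% protective / 30%
  neutral RVs: permutation C-alpha power at 0.05 exceeds 0.5 by
  $n = 1000$ subjects and exceeds the matched null rejection rate at every
  size tested — the mixed-direction setting burden statistics handle
  poorly.

A packaged reference table of window-level results from a published-scale
chromosome-3 hypertension analysis (ten index markers, five in genes) is
used to check the comparison stage: at 25 kb the 2x2 table (1, 4, 3, 2)
gives two-sided Fisher $p = 0.5238$, and at 5 kb the table (0, 5, 1, 4)
gives $p = 1$. The corresponding 1-kb comparison in that source ($p =
0.4667$) is *not* reproducible from the printed table under either
inapplicable-window rule this package offers (exclusion gives 0.4286,
counting as non-significant gives 0.4444); the discrepancy is left
unresolved rather than forced, and the 1-kb value is not asserted anywhere.

## Known limitations

* Windows are distance-based and per-index; overlapping windows from
  nearby index markers are tested separately, so their results are
  correlated.
* The asymptotic $Z$ is a diagnostic only; with few variants per window its
  normal approximation is poor, which is why the permutation p is primary.
* The urn adjustment is only as good as the fitted weights: a PCA panel
  that fails to capture the confounding axes leaves residual inflation.
* No LD-aware collapsing: correlated rare variants would violate the
  independent-binomial variance enumeration used for $c$ (the permutation
  p-value, which conditions on the observed genotypes, remains valid).
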