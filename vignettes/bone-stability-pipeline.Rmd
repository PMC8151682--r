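---
title: "Methods: SNP discovery and effect annotation for bone-stability traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP discovery and effect annotation for bone-stability traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It covers the statistical procedure stage by stage,
the tunable parameters with their defaults and units, what the synthetic
data generator does and does not emulate, the numerical conventions, and
the known limitations.

## The problem

Bone breaking strength (BBS, newtons, from a three-point bending test)
and bone mineral density (BMD, g/cm², from dual-energy X-ray
absorptiometry) of the tibiotarsus and humerus are heritable, polygenic
traits in laying hens. The population of interest consists of four
purebred layer lines (brown- vs white-egg origin crossed with high vs
moderate laying performance) measured over two generations, with
paternal half-sib families (hens nested within sires, sires within
lines). The analysis goal is to find SNPs carrying information about
these traits, attach them to nearby protein-coding genes, quantify each
locus's mode of action (additive vs dominant), and test candidate gene
lists for functional coherence.

## Genotype QC, orientation and imputation

`apply_qc()` filters in a fixed, logged order: non-autosomal SNPs
(anything outside chromosomes 1–28) are dropped first, then SNPs with a
call rate below 99%, then animals with a call rate below 95%. The order
is a convention — SNP-level before animal-level matches common
array-QC practice — and is exposed in the step report so deviations
would be visible. QC is idempotent, and the step counts always satisfy
`n_in = n_removed + n_retained`.

Monomorphic SNPs pass QC (there is no MAF filter) but are flagged, and
the selection and effect stages skip zero-variance SNPs with a warning.

`orient_minor_allele()` makes the genotype code count copies of the
minor allele, the *effect allele* (EA): codes at SNPs whose B allele is
the major allele are flipped `c -> 2 - c`. The EA frequency
`(n_AB + 2 n_BB) / 2N` then always lies in [0, 0.5]. An exact tie at 0.5
is broken towards the lexicographically smaller allele string so the
result cannot depend on file ordering.

`naive_impute()` draws each missing call from the SNP's empirical
genotype distribution *within the animal's layer line* (lines differ
systematically in allele frequency, so pooling would bias imputed
genotypes toward the majority line), falling back to the overall
distribution with a warning when a SNP has no observed call in a line.
This is deliberately a simple frequency sampler: reference-panel
imputation is a pipeline in its own right and out of scope here; with
the sub-1% missingness that survives the call-rate filters, the choice
of imputation scheme has negligible influence downstream.

## Phenotype adjustment

For each trait `fit_adjustment_model()` fits, by REML via `lme4`,

    y_ijkl = mu + G_i + LL_j + S_k + e_ijkl

with fixed generation (`G`, 2 levels) and layer line (`LL`, 4 levels)
effects and a random sire intercept `S_k ~ N(0, sigma_s^2)`. The
*conditional* residuals `y - X beta - Z u` (sire BLUP subtracted) are
the adjusted phenotypes used as the selection response. Conditional
rather than marginal residuals are the default because the sire effect
is a structural confounder: half-sib family means would otherwise leak
into the response and the selector would partly rediscover pedigree
rather than marker effects. Marginal residuals remain available via
`residual_type = "marginal"`.

Reporting conventions: level effects are presented as deviations from
their unweighted level mean and the intercept is converted to a grand
least-squares mean, so the summaries do not depend on the treatment
reference level. With a single observed level a factor drops out; with a
degenerate sire factor the model reduces to OLS with sire variance 0.
Conditional residuals are exactly orthogonal to the fixed-effect design
(`X' V^{-1}` annihilates them), which the tests verify; they sum to zero
within each generation level and each line level, but *not* within
generation × line cells, since the additive fixed-effect model does not
contain the interaction.

## Boruta SNP selection

`boruta_run()` is an all-relevant feature selector written from scratch
around a random-forest regressor (`ranger`). One iteration:

1. `make_shadow()` appends one *shadow attribute* per active SNP — an
   independent row permutation of that SNP's codes, which preserves the
   marginal genotype distribution while severing any link to the
   response.
2. A forest (default 500 trees, impurity importance, square-root
   feature subsampling over the doubled matrix) is fitted to the
   adjusted residuals.
3. `iteration_hits()` scores a *hit* for every real SNP whose importance
   strictly exceeds the `perc`-th percentile (default 99, linear
   interpolation between order statistics, `quantile` type 7) of that
   iteration's shadow importances.
4. `decide_statuses()` treats each undecided SNP's hit count as
   Binomial(iterations, ½) under the null: confirmed when the upper
   tail falls below `alpha/2` divided by the number of active SNPs,
   rejected when the lower tail does, tentative otherwise. Rejected
   SNPs leave the forest; confirmed SNPs stay so importances remain
   comparable.

Key parameter choices, all in `boruta_config()`:

* `perc = 99` (percentile of shadows a SNP must beat). With hundreds of
  shadows this approximates "beat the best shadow" while being robust to
  a single extreme permutation.
* `alpha = 0.05`, two-sided, Bonferroni-corrected by the number of
  still-active features. The correction therefore *relaxes* as SNPs are
  rejected — this matches the reference behaviour of shadow-attribute
  selectors, and its consequences are discussed under Limitations.
* `max_iter = 100` (default). Eight is the mathematical minimum for the
  exact binomial tail to reach 0.025.
* `n_trees = 500`, square-root feature subsampling. Full-feature
  subsampling (`mtry = Inf`) concentrates importance on causal SNPs and
  suppresses chance-correlated proxies, but is quadratically more
  expensive on wide matrices; the default favours desk-scale runtime
  and is configurable.
* Per-iteration seeds are derived from the master seed and the iteration
  index (`derive_seed()`), so the history is reproducible and any prefix
  of the run is identical regardless of when the loop stops.
* Tentative SNPs at `max_iter` stay tentative and are *not* reported as
  confirmed (`resolve_tentative = "exclude"`); an optional median rule
  (confirm when the median importance exceeds the median of the shadow
  maxima) is provided but off by default, since downstream stages only
  consume confirmed SNPs.

The regression forest (not a classifier) is used because the response —
adjusted residuals — is continuous.

### Calibration behaviour

Two properties are verified by simulation in the test suite. *Power*: a
response that copies one SNP's codes among 50 noise SNPs (n = 200) is
confirmed in ≥ 95/100 seeds. *Null behaviour*: on a pure-noise response
with 100 SNPs (n = 200) the mean number of confirmed SNPs over 50 seeds
stays at or below one at a 20-iteration budget, i.e. the fraction of
false confirmations is well below `alpha`.

The null calibration deserves honesty about its budget dependence. On a
*fixed* dataset, a SNP whose realized in-sample correlation with the
noise response happens to be large (the maximum over 100 SNPs at
n = 200 is typically |r| ≈ 0.15–0.2) is genuinely informative for the
forest every iteration, while shadows redraw their correlations each
time. Given enough iterations such data-lucky SNPs accumulate hits and
eventually clear the shrinking Bonferroni bar: the mean confirmed count
grows from ≈ 0.5 at 15 iterations to ≈ 2 at 50. Twenty iterations is
the natural horizon at which the Bonferroni-corrected rejection test
can decide every null feature (12–19 zero-hit iterations are needed at
a 100-SNP correction), and that is the budget the calibration check
uses. Interpreting confirmed lists from much longer runs on small
samples should keep this selection-over-realized-correlations effect in
mind.

## Gene-window annotation

A SNP is attached to a gene when its position lies in
`[gene_start - 5000, gene_end + 5000]`, endpoints inclusive, 1-based
coordinates as in VCF/GFF3. This "gene body expanded by 5 kb" rule is
equivalent to a SNP-centric distance-to-gene ≤ 5 kb and yields the
intragenic / upstream / downstream labels naturally; upstream means the
SNP lies on the gene's 5′ side with respect to strand (unstranded
records are treated as `+`, documented here because the convention is
not universal). Ties are not collapsed: a SNP equidistant from two genes
reports both hits. `venn_counts()` enumerates all `2^k - 1` disjoint
membership regions of the per-trait gene lists; the counts always sum
to the size of the union.

## SNP effect decomposition

Both per-SNP models add the SNP to the adjustment model's fixed part,
keeping the random sire intercept:

* **Single marker regression** (`fit_smr()`): the genotype code (0/1/2
  copies of the effect allele) enters as a covariate; its coefficient is
  the allele substitution effect per effect-allele copy, in trait units.
  The standardised variant z-scores both response and code first, giving
  the effect in phenotypic standard deviations.
* **Dominant-recessive model** (`fit_drm()`): genotype enters as a
  three-level class variable (AA = major-allele homozygote, AB, BB =
  effect-allele homozygote). Least-squares means average the fixed
  design *equally* over generation and line levels (an unweighted
  reference grid, verified against `emmeans` in the tests); the a/d
  contrasts

      a = (mu_AA - mu_BB) / 2,   d = mu_AB - (mu_AA + mu_BB) / 2

  are linear contrasts of the same fit, so the identities hold exactly
  and are invariant to the averaging weights (the nuisance parts of the
  LSM contrast vectors cancel).

Inference conventions: t-tests use residual degrees of freedom
(`n_used` minus the rank of the fixed design); Satterthwaite or
Kenward-Roger approximations are deliberately not used, which makes
p-values slightly anti-conservative for small sire numbers and is a
possible source of discrepancy with software that adjusts degrees of
freedom. Pairwise genotype contrasts carry a Bonferroni factor of
exactly 3 (the three genotype pairs at one locus); there is no
cross-SNP correction, mirroring per-locus candidate reporting.
Significance letters are assigned by insert-and-absorb, with the letter
sets ordered canonically so the display is deterministic; the tests
check them against brute-force maximal-clique lettering.

When a genotype class is unobserved the corresponding LSM is missing
and a/d are flagged non-estimable rather than silently dropped.

## Over-representation analysis

`enrich()` computes the hypergeometric upper tail
`P(X >= k)` for `X ~ Hypergeometric(N, K, n)` per term, with the
universe defaulting to the union of all term genes (an explicit
universe file mirrors "all known genes" semantics when supplied). Query
genes outside the universe are dropped with a logged count.
Benjamini–Hochberg is the default adjustment, Bonferroni optional;
tool-specific simulation-calibrated corrections used by web services
are intentionally not reimplemented, so adjusted p-values are
comparable across runs and environments.

## The synthetic data generator

`simulate_genotypes()` / `simulate_phenotypes()` emulate the features of
the study the analysis actually relies on:

* the nested design — hens split evenly over four lines and two
  generations, sires nested within line, hens assigned round-robin so
  families are balanced and model (fixed + random) effects estimable;
* line-specific allele frequencies (per SNP and line, drawn uniformly
  from a configurable range within (0, 0.5]) with Hardy–Weinberg
  genotypes within line — this is what makes adjustment for line
  structure non-optional;
* trait construction: overall mean + generation effect + line effect +
  sire effect `N(0, sigma_s^2)` + planted QTL effects + residual
  `N(0, sigma_e^2)`. A QTL's genotype-coded value is `+a` for zero
  effect-allele copies, `d` for one and `-a` for two, matching the sign
  convention of the a/d contrasts (AA, the major-allele homozygote,
  carries `+a`);
* missingness injected uniformly at random (QC filters are rate-based
  only, so richer missingness mechanisms would add nothing testable);
* a truth record (`synthetic_truth`) holding every realized component —
  QTL ids and effects, per-hen QTL genotypes, sire effects — so that
  with `resid_sd = 0` the trait values are reconstructed exactly
  (`truth_expected_values()`), and recovery tests compare estimates
  against truth rather than against other estimates.

Default trait-scale parameters are chosen to look like a BBS trait:
mean 150 N, line shifts of up to ±15 N, generation shift 8 N, sire SD
6 N and residual SD 25 N, giving a sire-model heritability
`4 sigma_s^2 / (sigma_s^2 + sigma_e^2)` of ≈ 0.22, in the range reported
for hen bone traits. The BMD-scale defaults in `demo_fixture()` scale
everything to a 0.25 g/cm² mean. Phenotypes are generated from the
complete (pre-missingness) genotype codes, one trait per call; the
demonstration fixture merges two calls (BBS- and BMD-scale) over the
same genotypes.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: linkage disequilibrium (each
SNP is drawn independently, so there is no LD-induced redundancy among
confirmed SNPs and no tag-SNP behaviour), genotyping-batch or
plate artefacts, selection or non-random mating within lines, dam and
pen effects, non-normal residuals, and genotype-environment
interaction.

Problem sizes: unit tests run at 30–400 hens and tens of SNPs;
calibration checks use 2 000 hens for parameter recovery and 100–200
samples for selector calibration; the demonstration pipeline uses 524
hens × 2 000 SNPs, 5 planted QTL per trait, 40 genes and 10 gene sets.
These sizes are the package's chosen desk-scale defaults — the
algorithms themselves are scale-free — and the demonstration effect
sizes (a = 12 N against a 25 N residual SD) were calibrated once so the
planted QTL are recoverable at that scale, then pinned with the seed.

## Numerical and reproducibility conventions

* Coordinates are 1-based with inclusive endpoints everywhere
  (VCF/GFF3 convention); window logic is integer arithmetic.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7), documented because shadow thresholds sit exactly
  at order-statistic boundaries in small pools.
* All randomness flows from one master seed through `derive_seed()`
  (a label hash combined with the seed modulo a prime below 2^31), so
  every stage — and every Boruta iteration — is independently
  reproducible; `run_all()` writes an MD5 manifest and reruns are
  hash-identical.
* REML fits that estimate the sire variance at the zero boundary are
  accepted with a warning (the singular fit is a legitimate estimate),
  never an error.
* Ties in minor-allele orientation break lexicographically; letter-set
  ordering in significance displays is canonical; TSV/JSON writers
  avoid timestamps so outputs hash stably.

## Known limitations

* The selector's confirmed count on finite samples depends on the
  iteration budget (see the calibration section); confirmed lists are
  *candidate* sets, not error-controlled discoveries.
* Impurity importance is biased toward high-variance features; with
  0/1/2 codes of varying MAF this mildly favours intermediate-frequency
  SNPs. Permutation importance would trade this for noise and runtime.
* Degrees-of-freedom conventions differ across mixed-model software;
  reported p-values for small sire numbers are approximate.
* The naive imputation ignores LD entirely and is only suitable for the
  sub-1% missingness left after call-rate QC.
* Published genotype-count tables shipped with the package are used as
  printed; one locus's counts sum to 527 rather than the reported 524
  animals, and frequencies are computed from counts as supplied.
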