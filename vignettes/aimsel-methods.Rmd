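---
title: "Selecting ancestry-informative marker panels with aimsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting ancestry-informative marker panels with aimsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimsel)
```

## The problem

Ancestry-informative markers (AIMs) are genetic markers whose distributions
differ enough between populations to assign an individual to its ancestral
group. A handful of SNPs separates continental groups easily, but closely
related populations (the classic example being Han Chinese and Japanese
panels) are barely distinguishable from any small SNP set. Gene-expression
(GE) intensities are themselves heritable and population-differentiated, and
they carry information largely complementary to genotypes. `aimsel` builds
minimal marker panels from SNP genotypes, GE probes, or both, by forward
stepwise selection inside a cross-validated discriminant analysis, and
reports how well the resulting panels classify held-out samples.

## The model

### Flexible discriminant analysis by optimal scoring

Let $Y$ be the $n \times K$ indicator matrix of population labels and $X$
the $n \times p$ matrix of encoded features, column-centered. SNP calls are
encoded additively as the count of the B allele (AA $\to$ 0, AB $\to$ 1,
BB $\to$ 2); GE intensities enter untransformed; missing values are imputed
with per-feature training means that travel with the fitted model.

Optimal scoring finds score vectors $\theta_\ell$ and coefficient vectors
$\beta_\ell$ minimizing $\lVert Y\theta_\ell - X\beta_\ell \rVert^2$ subject
to $\theta_\ell^\top D_\pi \theta_\ell = 1$, where $D_\pi$ holds the class
proportions. Computationally:

1. regress $Y$ on $X$: $B = (X^\top X + \varepsilon I)^{-1} X^\top Y$;
2. eigen-decompose $D_\pi^{-1/2}\,(Y^\top \hat{Y}/n)\,D_\pi^{-1/2}$ with
   $\hat{Y} = XB$, giving eigenvalues $\alpha_\ell^2$ and scores
   $\theta_\ell$;
3. keep the at most $K-1$ non-null dimensions; the discriminant variates are
   $\eta_\ell(x) = (x - \bar{x})^\top B\,\theta_\ell$.

A sample is assigned to the class with the nearest centroid in discriminant
space under the canonical coordinate weights
$w_\ell = 1/\bigl(\alpha_\ell^2(1-\alpha_\ell^2)\bigr)$. With a linear
regression basis this weighted nearest-centroid rule equals the Mahalanobis
(pooled within-class covariance) nearest-mean rule up to a class-independent
term, i.e. prior-free LDA — the package's test suite verifies the
equivalence against an independently written LDA oracle on thousands of
samples before anything else is trusted.

### Forward stepwise selection

Within a training fold, markers are added greedily. With the current set
$S$, every remaining candidate $m$ is evaluated by refitting the FDA on
$S \cup \{m\}$ and recomputing training accuracy. The candidate with the
largest accuracy wins; ties are broken by the smallest univariate
$SSW/SSB$ — within-population over between-population sum of squares of the
candidate's own values —

$$\mathrm{SSW} = \sum_k \sum_{i \in k} (x_i - \bar{x}_k)^2, \qquad
  \mathrm{SSB} = \sum_k n_k (\bar{x}_k - \bar{x})^2,$$

and any remaining tie lexicographically by marker id. Selection stops when
training accuracy reaches `target_accuracy` (default 1.0), when the best
increment falls below `min_increment` (default 0.001; the offending
candidate is not added), or at `max_markers`. The first marker is always
added, with its increment measured against the majority-class baseline —
the natural accuracy of the empty model. Testing accuracy never influences
selection.

### Cross-validation and the best model

Samples are partitioned into $k$ folds (default 10), stratified so that
within every population fold sizes differ by at most one. Each fold serves
once as the test set, yielding $k$ candidate models with testing accuracies
and a selection trace each. The best model has the highest testing
accuracy; ties prefer fewer markers, then the marker set selected by the
most folds (cross-validation consistency), then the lowest fold index. The
full ranking table is part of the output, because testing accuracy alone is
deliberately not the only defensible criterion.

## Marker quality control

SNPs are removed when any of these trigger (reasons are recorded as a
union, not a cascade, so the report is auditable):

* call rate below `min_call_rate` (default 0.9);
* minor allele frequency at or below `min_maf_exclusive` (default 0 —
  exactly the monomorphic markers);
* Hardy–Weinberg disequilibrium: FDR-adjusted (Benjamini–Hochberg)
  permutation p-value below `hwe_alpha` (default 0.05);
* location on a sex chromosome (X, Y, XY).

The HWE test statistic is the absolute deviation of the heterozygote count
from its exact expectation under random mating,
$n_A n_B / (2N - 1)$ for allele counts $n_A, n_B$ in $N$ diploids. Each
permutation shuffles the pool of $2N$ alleles and re-pairs them
consecutively; the p-value uses the add-one correction
$(1 + \#\{\text{extreme}\})/(1 + n_{\mathrm{perm}})$ and is therefore never
zero. Monomorphic markers short-circuit to $p = 1$ (the statistic is
degenerate, and the MAF rule removes them anyway). Each marker's
permutation stream is seeded by hashing the run seed with the marker id, so
a marker's p-value does not depend on which other markers share the run —
this is what makes QC idempotent at a fixed seed. The permutation inner
loop is compiled (Rcpp) and driven by R's RNG, so `set.seed()` governs it.

HWE is computed on the pooled samples of the current population
combination. Pooling across truly differentiated populations induces a
Wahlund-effect heterozygote deficit, so strongly ancestry-informative
markers can fail pooled HWE; with the default 1,000 permutations and
genome-scale marker counts the FDR adjustment rarely lets single markers
reject, which mirrors practice. Restrict to one population before QC if
within-population testing is wanted.

GE probes are removed when not RefSeq-derived, on a sex chromosome, or
lacking a gene symbol; probes with no annotation record count as lacking
gene information (with a warning).

## The simulator

`simulate_dataset()` produces a stated, fully seeded world for tests and
demonstrations:

* **Noise SNPs** share one allele frequency across populations, drawn
  uniformly from `base_freq_range` (default 0.2–0.8), and genotypes are
  Binomial(2, p) — i.e. they sit in Hardy–Weinberg equilibrium and carry no
  ancestry signal. Their HWE permutation p-values are verified to reject at
  the nominal 5% rate across 2,000 markers.
* **Informative SNPs** take per-population frequencies either given
  explicitly or drawn under the Balding–Nichols model:
  $p_k \sim \mathrm{Beta}\bigl(p(1-F)/F,\ (1-p)(1-F)/F\bigr)$, with mean
  $p$ and variance $F p (1-p)$. The default $F_{ST} = 0.15$ is a typical
  between-continent human value.
* **Expression** is Gaussian on a log-intensity-like scale (baseline means
  $\mathcal{N}(7, 1)$, residual sd `ge_sd = 1`). Informative probes shift
  their mean by `ge_shift` standard deviations between consecutive
  populations. Since the classifier is affine-invariant, the absolute scale
  is immaterial; only the standardized shift matters.
* **Missingness** is call-wise uniform at `missing_rate` (default 0.01,
  a realistic array-scale rate given the 0.9 call-rate QC threshold).
* **Annotation**: configurable fractions of noise markers/probes are
  labeled chrX, non-RefSeq, or gene-less to exercise QC. Informative
  markers are always autosomal and RefSeq so planted signal is never
  removed by QC and recovery tests stay interpretable.

The `hapmap_preset()` mirrors the four-population HapMap II panel shape
(CHB 45, JPT 45, CEU 60, YRI 60) at reduced marker counts (5,000 SNPs,
2,000 probes by default).

What the simulator does **not** model: linkage disequilibrium between SNPs,
eQTL coupling between SNPs and expression, batch effects, or
population-specific missingness. A green recovery test therefore
establishes that the selection machinery finds planted independent signal
at realistic noise levels — not that the method is robust to correlated
markers or confounded expression data.

## Numerical choices

* **Ridge** $\varepsilon = 10^{-8}$ on the centered Gram matrix absorbs
  rank deficiency (duplicated or constant markers must not crash a refit
  during selection). Exposed as an argument; equivalence tests against the
  LDA oracle run at $\varepsilon = 0$ on full-rank data.
* **Degenerate fits** (no usable variation; all eigenvalues numerically
  zero) predict the majority class, earliest sorted label on ties, rather
  than erroring.
* **Tie tolerances**: accuracy ties in selection use an absolute $10^{-12}$
  tolerance; classification distance ties use a relative $10^{-8}$
  tolerance before the deterministic earliest-sorted-class rule. Exact
  midpoint ties are common with 0/1/2-coded genotypes, and bitwise
  comparisons would make results platform-dependent.
* **Discriminant dimensions** with eigenvalues below $10^{-9}$ are dropped;
  weights are clamped away from the $\alpha^2 \in \{0, 1\}$ poles.
* **Seeds**: one master seed drives the fold partition; QC derives
  per-marker seeds by hashing. All randomness is reproducible, and repeated
  runs write byte-identical outputs.

## Design choices where the design was open

* The spec's source material never states whether its FDA used a nonlinear
  basis; the linear basis is assumed (single-marker forward selection gives
  nonlinear bases little to work with, and the linear case admits an exact
  LDA oracle).
* "Highest testing accuracy or highest cross-validation consistency" does
  not fix a precedence; testing accuracy is primary here, with CVC as a
  later tie-break, and the full criteria table is always reported.
* The tie-breaking $SSW/SSB$ is the candidate's own univariate ratio, not
  the joint set's: the rule attributes the ratio to "the marker".
* Pooled-vs-within-population HWE is exposed by simply restricting the
  input; pooled is the default.
* The run manifest is JSON rather than YAML (no YAML parser in the target
  environment; the content is the contract, not the syntax).

## Known limitations

* Per-fold testing accuracy from the same cross-validation that selected
  the markers is an optimistic estimate of generalization; there is no
  nested cross-validation (by design, matching the procedure modeled).
* Forward selection refits FDA from scratch for every candidate at every
  step — correct but $O(\text{steps} \times \text{pool})$ fits; the
  optional `prescreen` cap (top candidates by univariate $SSB/SSW$) is the
  intended escape hatch for genome-scale pools and is off by default.
* Half-calls and phased genotypes are not modeled; calls are strictly
  AA/AB/BB/missing.
* `predict` returns hard labels only; no posterior calibration.
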