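---
title: "Multi-SNP fine mapping by stochastic shotgun search"
author: "shotgunfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-SNP fine mapping by stochastic shotgun search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunfm)
```

## The problem

Dense genotyping of a disease-associated region leaves two obstacles between
an association signal and a short list of candidate causal variants. First,
linkage disequilibrium (LD): many variants are so strongly correlated
(r² approaching 1) that statistics cannot tell them apart, and in regions
with little historical recombination |D′| between markers is near 1 even
when r² is modest. Second, a region may contain several causal variants, so
the common simplification of one causal variant per region — and the
stepwise habit of conditioning on the top SNP — can give genuinely wrong
answers: when causal variants are correlated, the single best-fitting SNP
may be a "middle tag" that is itself causal for nothing.

`shotgunfm` treats fine mapping as Bayesian variable selection over all
multi-SNP additive models, in four steps:

1. **Tag** — cluster variants at r² > 0.99 into *tagsets* (complete-linkage
   hierarchical clustering on 1 − r², cut so every within-cluster pair
   exceeds the threshold) and keep one *tag* per set, the member with the
   highest mean r² to the others. Extreme LD otherwise destabilises joint
   model fits; the removed variants are restored in step 4.
2. **Search** — explore models over the tags. Small spaces are enumerated
   exhaustively; otherwise a seeded multi-chain Metropolis–Hastings walk
   with add/drop/swap proposals (0.4/0.4/0.2) visits models in proportion
   to their posterior support and records every model it evaluates.
3. **Retain** — keep the `n_keep` (default 30,000) best models by
   `log BF + log prior`.
4. **Expand** — substitute every tag in every retained model by each member
   of its tagset (a Cartesian product per model), rescore every expanded
   model individually on the full panel, and normalise.

## Model scoring

For a model $m$ (a set of SNPs) the fit is an additive GLM: linear
regression for quantitative traits, logistic for case/control, always
including the intercept and any covariates (categorical covariates are
reference-coded; the null model contains them too). Evidence against the
null model is the BIC-approximate Bayes factor,

$$\mathrm{BIC}_m = -2(\log L_m - \log L_0) + (k_m - k_0)\log n,
\qquad \mathrm{BIC}_m = -2\log \mathrm{BF}_m,$$

so $\log \mathrm{BF}_m = (\log L_m - \log L_0) - \tfrac{k_m - k_0}{2}\log n$
in natural logs. Intercept, covariate and (for the Gaussian family)
residual-variance parameters cancel in $k_m - k_0$, which equals the model
size $N_m$. For the Gaussian family this has the closed form
$\log \mathrm{BF} = -\tfrac{n}{2}\log(\mathrm{RSS}_m/\mathrm{RSS}_0) -
\tfrac{N_m}{2}\log n$, which the test suite asserts to 1e-8. One score is
used both inside the search and at expansion rescoring, so search ranking
and final posteriors are mutually consistent and checkable against an
exhaustive oracle; exact g-prior Bayes factors are out of scope.

Fits that do not converge, or that trip the separation guard (any
coefficient beyond ±30 on the linear-predictor scale after IRLS with at
most 100 iterations), are excluded by assigning $\log \mathrm{BF} = -\infty$
rather than aborting a search.

The prior on a model depends only on its size:
$\pi_m = q^{N_m}(1-q)^{N-N_m}$ with $q = n_\mathrm{exp}/N$, so the induced
prior on the *number* of causal variants is Binomial$(N, q)$ with mean
$n_\mathrm{exp}$ (default 3; benchmark results are also run at 5, since
performance degrades when the expectation is below the truth but not when
it is above). On panels with fewer than $2\,n_\mathrm{exp}$ variants the
default expectation is capped at $N/2$ to keep the binomial proper; an
explicit `prior_spec()` always requires $n_\mathrm{exp} < N$. Posteriors
are normalised in log space: $\mathrm{PP}_m \propto \mathrm{BF}_m \pi_m$
over all scored models plus the null.

Because the Bayes factors are prior-free, `reweight_prior()` re-derives the
posterior under any other $n_\mathrm{exp}$ without refitting, and reports
the support ratio between declared model families — the package's
sensitivity analysis for "how many causal variants did you expect?".

## SNP groups: credible sets with multiple causal variants

Posterior mass is diluted across near-interchangeable SNPs, so per-SNP
marginal posterior probabilities of inclusion (MPPI, the summed posterior
of models containing the SNP) understate the evidence. `snp_picker()`
re-aggregates: seed with the highest-MPPI unassigned SNP; order the rest by
decreasing r² with the seed; exclude SNPs that *co-occur* with the seed in
models (joint MPPI > 0.02 — co-occurrence marks a distinct signal, not a
substitutable one); walk outward adding SNPs until r² < 0.5 or two SNPs in
a row fall below MPPI 0.001 (sub-floor SNPs are never added, and the run
counter resets at each passing SNP); remove the group and repeat while any
unassigned SNP has MPPI > 0.01. The r² stop is evaluated before the
MPPI-run stop on each candidate (it is cheaper and defines the ordering);
all ties break by genomic position, then id, so the output is
deterministic. A group's support is its gMPPI — the summed posterior over
models containing *at least one* member, each model counted once (never a
sum of MPPIs, which double-counts co-occurrence).

Model-averaged effect estimates follow
$\beta_i = \sum_m I(i \in m)\,\beta_i(m)\,\mathrm{PP}_m$ on the
linear-predictor scale (exponentiate for odds ratios).

## The stochastic search and its oracle

The original evolutionary Monte Carlo searcher is treated as a pluggable
component whose contract is "return the most likely models among those
visited". Here each of 3 chains (seeded `seed + chain`) runs a
Metropolis–Hastings walk over model space targeting
$\mathrm{BF}_m \pi_m$; proposal densities are accounted for exactly, and
every distinct model scored — accepted or not — enters the visited set.
Model size is capped at `min(10, N)`; the size prior already penalises
large models. Chain agreement is summarised by the mean pairwise Jaccard
overlap of the chains' top-20 models, with a warning below 0.5.

The default effort (`n_iter = 3000` per chain) was fixed by an
oracle-equivalence requirement rather than by mimicking any particular
searcher's settings: on 50 reference panels of ≤ 12 tags (n = 500, two
causal variants), the visited set must carry ≥ 99% of the exhaustively
enumerated posterior mass and reproduce the exhaustive top-10 exactly; at
3000 iterations the observed minimum mass is 0.994 with 50/50 top-10
agreement. Monotonicity (more iterations never capture less mass) is a
property test.

## The synthetic cohort

No individual-level genotypes ship with the package, so benchmarks run on a
mosaic-of-founders simulator built to emulate the LD texture of a
fine-mapping region: `n_founders` (8) binary founder haplotypes whose
alleles run in blocks (re-drawn between adjacent variants with probability
`founder_flip_rate` = 0.1); each sample haplotype copies a founder,
switching to a random founder between adjacent variants with probability
`mosaic_switch_rate` = 0.005 — the recombination analogue. With a switch
rate of zero every variant pair is in complete disequilibrium (|D′| = 1),
the regime of a recombination-free region; increasing it decays r²
monotonically. The defaults were chosen so that r² > 0.99 tagging removes
roughly a quarter to a third of a 200-variant panel, the reduction seen on
real dense panels of this kind.

Phenotypes are Gaussian and additive: 2–5 causal variants drawn uniformly
among SNPs with MAF > 0.01, equal per-allele raw effects (a Gaussian-draw
option exists), the genetic score rescaled so the causal variants jointly
explain 10% of phenotypic variance in the realised sample, plus N(0, 1−v)
noise. Default scaling leaves the noise draw its sampling variability
(realistic replicate-to-replicate spread); `exact_fraction = TRUE`
orthogonalises and rescales the noise so the realised fraction is exact —
used where tests need a sharp identity. Across 1,000 replicates the mean
regression R² of phenotype on causal dosages is within half a percentage
point of the 10% target.

What the simulator does *not* reproduce: coalescent-grade allele-frequency
spectra, MAF-dependent LD pruning, imputation uncertainty (dosages are hard
calls), population structure, or case/control ascertainment. Passing
benchmarks therefore demonstrate correct method behaviour under controlled
LD and effect structure, not performance guarantees on any particular real
cohort.

## Benchmarking against stepwise selection

`forward_stepwise()` is the conventional baseline: repeatedly add the SNP
with the smallest 1-df likelihood-ratio addition p-value until it exceeds
α. Selected index SNPs get pseudo credible sets — all variants at
r² > 0.8 with the index — which, unlike `snp_picker()` groups, may overlap.
`evaluate_discovery()` scores both the same way: discovery rate = fraction
of true causal variants inside ≥ 1 selected group; FDR = fraction of
selected groups containing no causal variant (defined as 0 when nothing is
selected, keeping threshold curves well-defined). `benchmark_methods()`
sweeps gMPPI thresholds (0.5, 0.9), stepwise α (1e-6, 1e-8) and prior
expectations (3, 5) across seeded replicates.

The reference comparison in the test suite uses 200 replicates of a
50-variant panel at n = 2,000 with two causal variants: groups selected at
gMPPI > 0.9 must match or beat stepwise at p < 1e-8 on discovery while
staying within 0.02 absolute of its FDR. The test suite's problem sizes
(500–2,000 samples, 10–200 variants, 50–1,000 replicates per property) were
chosen as the smallest at which the Monte-Carlo error is comfortably below
each assertion's tolerance.

## Numerical and design choices

* **Genotype r², not haplotype r²** for both tagging and groups: it is
  defined for fractional imputed dosages and is the common fine-mapping
  convention. |D′| (diagnostic only) comes from a two-locus genotype EM on
  hard calls.
* **Missing dosages** are mean-imputed per variant after MAF/variance
  filtering (MAF ≤ 0.005 or zero variance removed; MAF is recorded on the
  observed, pre-imputation data), keeping every regression design complete.
* **Multi-allelic records are rejected**, keeping "dosage" unambiguous;
  split them upstream.
* **Determinism**: one master seed; chain c uses seed + c; the phenotype
  stream is seeded at an offset of the genotype stream so the two are
  decoupled but jointly reproducible; every tie anywhere (tag choice,
  group seeds, stepwise, top-model cuts) breaks by position then id.
* **Quantitative fits** inside the search are solved from precomputed
  cross-products after residualising on covariates (Frisch–Waugh), so a
  model score is a k×k solve; coefficients and log-likelihoods equal the
  full joint fit's (asserted to 1e-8 against `lm`). Logistic models are
  refit per model.
* **Expansion guard**: if a pathological input would expand past 5×10⁶
  models, expansion is limited to top models carrying cumulative posterior
  0.9999. Priors at rescoring use the *full* panel size N by default (the
  prior is about the region's SNPs, not the tags); pass `prior` to
  override.
* **Degenerate inputs**: empty panels, all-filtered panels, perfect
  separation, constant columns and infeasible sensitivity grids all raise
  early, named errors rather than propagating NaNs.

## Limitations

Single-region, single-trait only: no trans effects, no statistical
interaction terms (in a |D′| ≈ 1 regime three of four two-SNP haplotypes
exist and interactions are inestimable anyway; regions with recombination
would need them), no relatedness/mixed-model adjustment, no imputation of
untyped variants, and no enrichment or colocalisation layer. The BIC
approximation is asymptotic in n and shares the usual caution for rare
variants in small samples.
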