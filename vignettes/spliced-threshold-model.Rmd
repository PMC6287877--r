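---
title: "Modeling clone size distributions with a discrete Gamma-GPD spliced threshold model"
author: "clonetail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clone size distributions with a discrete Gamma-GPD spliced threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetail)
```

## The problem

High-throughput sequencing of the T cell receptor (TCR) repertoire yields,
per sample, a vector of read counts: one positive integer per clonotype,
the clone size. These distributions have a characteristic shape: a large
bulk of small, rare clonotypes, and a heavy, approximately power-law upper
tail produced by clones expanded during an active immune response. Tail-only
power-law fits discard the small clones, while classical count models
(Poisson, lognormal mixtures) underweight the tail. `clonetail` models the
**whole** distribution with a spliced threshold model and builds a
comparative-analysis toolkit on top of it.

## The model

Clone sizes are integers, so everything is discrete. A continuous density
$\psi$ with distribution function $\Psi$ is quantized at unit intervals,

$$\Pr(X = x) = \Psi(x + 1) - \Psi(x),$$

i.e. the censoring interval is fixed at $d = 1$. Applying this to a
Gamma$(\alpha, \beta)$ (shape, rate) gives the *discrete Gamma* bulk pmf
$h$, and to the generalized Pareto distribution GPD$(u, \sigma, \xi)$ the
*discrete GPD* tail pmf

$$g(x) = \Bigl(1 + \xi\tfrac{x - u}{\sigma}\Bigr)^{-1/\xi} -
         \Bigl(1 + \xi\tfrac{x + 1 - u}{\sigma}\Bigr)^{-1/\xi},$$

supported on $x \ge u$ for $\xi \ge 0$ and on
$u \le x \le \lfloor u - \sigma/\xi \rfloor$ for $\xi < 0$. The spliced
model glues the two at an integer threshold $u$, with $\phi$ the tail mass
fraction:

$$f(x) = \begin{cases}
  (1 - \phi)\, h(x) / Z_{\text{bulk}} & x \le u - 1,\\
  \phi\, g(x) & x \ge u.
\end{cases}$$

The parameters have direct immunological readings: $u$ separates clones
attributable to active response from baseline noise; $\xi$ measures tail
weight (heavier tail = repertoire more dominated by expanded clones) and is
inversely related to the type-I Pareto shape $\alpha_d$ through the exact
identity GPD$(u, u/\alpha_d, 1/\alpha_d) \equiv$ Pareto$(u, \alpha_d)$;
$\phi$ is the fraction of responding clonotypes.

### The bulk support starts at 1

A clonotype observed with zero reads is not observed at all, so by default
the bulk is truncated on both sides: support $\{1, \dots, u-1\}$ with
normalizer $Z_{\text{bulk}} = H(u-1) - h(0)$. The literal one-sided
normalizer $H(u-1)$, which allocates (unobservable) mass at zero, is
available via `bulk_includes_zero = TRUE`; with default settings the two
differ only through the small Gamma mass below 1.

## Estimation

Maximum likelihood with profile-likelihood threshold selection
(`fit_spliced()`):

1. Candidate thresholds are **every unique observed clone size** at or
   above the empirical 75% quantile of the sample (`quantile` argument).
   Candidates leaving fewer than `min_tail = 10` clones in the tail or
   `min_bulk = 10` in the bulk are excluded: both component MLEs need data.
2. At a candidate $u$, $\hat\phi = n_u / n$ is the plug-in tail fraction
   (its own MLE), and the likelihood then factorizes, so
   $(\alpha, \beta)$ and $(\sigma, \xi)$ are maximized independently —
   exact, faster, and better conditioned than a joint 4-d search.
3. $\hat u$ is the profile argmax; ties break toward the smallest $u$
   (the larger tail). $\xi < 0$ solutions whose implied upper support
   bound falls below the observed maximum have zero likelihood and are
   never selected.

### Numerical choices

* **Optimizer.** Nelder-Mead on $(\log\alpha, \log \text{mean})$ for the
  bulk (the log-mean coordinate keeps the Gamma likelihood valley
  axis-aligned) and $(\log\sigma, \xi)$ for the tail, from deterministic
  starts: method-of-moments for the bulk, a Hill-type estimate mapped
  through the Pareto-GPD identity for the tail, and one fixed fallback
  each. The whole fit is deterministic and permutation invariant.
* **Warm starts across the grid.** Neighbouring thresholds warm-start each
  other; the tail start is mapped through the threshold-stability identity
  $(u, \sigma, \xi) \to (u', \sigma + \xi(u' - u), \xi)$, which is exact
  for GPD data. The bulk, whose MLE drifts only as fast as clones cross
  the threshold, is fully re-optimized once its clone count has grown by
  1% (or every 250 candidates) and updated incrementally in between; the
  selected threshold is always re-polished with the full start set.
* **Stability.** $(1+\xi z/\sigma)^{-1/\xi}$ is evaluated through
  `log1p`/`expm1`; for $|\xi| < 10^{-8}$ the exponential limit branch is
  used (the two branches agree to $10^{-8}$ at $\xi = \pm 10^{-9}$).
  Discrete Gamma masses are differenced on whichever tail of the
  distribution is small — far above the mean, the lower-tail difference
  $\Psi(x+1) - \Psi(x)$ cancels catastrophically to 0.
* **Infinite sums** (normalization checks, divergence supports) are
  truncated where the closed-form remaining tail mass drops below
  tolerance, never at a fixed cap: heavy tails make fixed caps wrong.

## The comparator: KS-selected type-I Pareto tail

`fit_desponds()` implements the tail-only comparator: for every unique
clone size $u_i$, the Pareto shape closed form
$\hat\alpha_d = n_i \,[\sum_j \ln(x_j/u_i)]^{-1}$ and the
Kolmogorov-Smirnov statistic against $F(x) = 1 - (u_i/x)^{\alpha_d}$; the
KS-minimizing threshold wins. Ties in counts are handled by evaluating
both one-sided empirical-cdf gaps at each unique value. The same
`min_tail = 10` guard applies (the original procedure does not state one).

## Diversity statistics

`richness`, `shannon` ($H = -\sum p_i \ln p_i$, nats by default),
`clonality` ($C = 1 - H/\ln S$, i.e. 1 − Pielou's evenness), and
`proportion_stimulated` (reads in clones at or above a threshold over all
reads — with the fitted $\hat u$, the share of the repertoire in the
power-law regime). A single-clonotype sample has $C = 1$ by convention:
the expression is 0/0 there and a one-clone repertoire is the fully clonal
limit.

## Comparative analysis

`jsd_spliced()` evaluates the Jensen-Shannon divergence
$\tfrac12[\sum P\ln(P/M) + \sum Q\ln(Q/M)]$, $M = (P+Q)/2$, between two
fitted spliced pmfs over their joint integer support, truncated where both
remaining tail masses fall below `tol = 1e-10`. For heavy tails
($\xi$ near 1) that truncation point can exceed $10^{10}$, so clone sizes
beyond `exact_limit = 1e6` are aggregated over a fine geometric binning
(edge ratio 1.0005) with bin masses from the closed-form cdfs; the binned
stretch carries a vanishing share of the mass, and halving `tol` moves the
result by far less than $10^{-6}$ on moderate parameterizations. The
divergence itself (not its square root) is the default distance, matching
how the quantity is defined; `sqrt = TRUE` gives the metric form.

`jsd_desponds()` is the continuous generalization for Pareto fits, trading
the sum for an integral (adaptive quadrature, relative tolerance
$10^{-8}$; each density is 0 below its own threshold, so the
non-overlapping stretch contributes in closed form).

`cluster_samples()` applies Ward agglomeration. "Ward's method" on a
dissimilarity admits two conventions; the squared-update textbook variant
(`ward.D2`) is used. `embed_mds()` wraps non-metric MDS
(`MASS::isoMDS`, classical-scaling initialization, fixed seed) and
reports Kruskal stress-1.

## The simulator

`simulation_design()` describes a full-factorial cohort over
$\alpha \in \{3, 5, 10\}$, $\xi \in \{0.25, 0.5, 0.75, 1.1\}$,
$\phi \in \{0.1, 0.15, 0.2, 0.25\}$ at $\beta = 0.15$ — 48 cells of
$n = 20{,}000$ clonotypes by default. Per cell, the threshold is the
Gamma quantile $u = \lfloor Q_{\alpha,\beta}(1-\phi)\rfloor$ and the tail
scale is $\sigma = \alpha/\beta$, the bulk mean (`sigma_rule = "mean"`).
The scale rule is stated ambiguously in the literature this design
follows ("$\sigma = \alpha\beta$" can read as a product or as a fraction
whose slash was lost in typesetting); the bulk-mean reading puts the tail
scale on the same footing as the bulk and the induced threshold, whereas
the product (0.45–1.5 here) would not, so the mean is the default and
`sigma_rule = "product"` preserves the alternative.

`generate_repertoire()` draws each clone independently — bulk with
probability $1-\phi$ by inverse cdf on the tabulated truncated bulk,
otherwise tail by the closed-form discrete GPD quantile on uniforms —
exactly reproducible under a seed. `downsample_reads()` subsamples the
read pool without replacement (multivariate hypergeometric across
clonotypes), dropping clonotypes that reach zero; `equalize_depth()`
brings a cohort to its minimum total depth (a fixed common depth can be
supplied instead).

What the generator emulates is the *statistical* shape of repertoires:
bulk/tail mixture, heavy tails, depth effects under subsampling. It does
not simulate sequencing error, PCR amplification bias, or V(D)J
generation probabilities, so passing tests demonstrate correct recovery
of the model's own structure, not robustness to those real-data artifacts.

## What the test suite exercises

* Exactness properties at tolerance $10^{-10}$: the discrete
  threshold-stability identity
  $[F(x{+}u{+}1) - F(u)]/[1 - F(u)] = F(x; 0, \sigma{+}\xi, \xi)$
  (including $\xi < 0$), and the Pareto-GPD equivalence.
* Oracle agreement: pmfs versus floored-continuous-draw histograms,
  closed-form shape estimates, brute-force KS, high-precision divergence
  summation and quadrature.
* Recovery under the study conditions: per design cell, the median fitted
  $\hat\xi$ over 20 replicate cohorts of $n = 20{,}000$ stays within 0.1
  of the generating $\xi$; fitted and generating shapes co-rank across
  the grid.
* Depth robustness: on a six-sample cohort with well-separated tail
  shapes, the $\hat\xi$ ranking and the JSD/Ward two-group clustering are
  unchanged at 100/80/60/40/20% of reads.
* The clonality-$\xi$ experiment: the 48-sample cohort, depth-equalized,
  yields a strong positive Spearman correlation between clonality and the
  generating $\xi$ (recomputed by `scripts/acceptance.R`; the suite
  requires $\rho \ge 0.85$ across five master seeds).

These problem sizes (48 cells, 20 replicates, $n = 20{,}000$) are the
reference design of the validation study and are used as-is.

## Limitations

* The profile search assumes enough clones on both sides of every
  candidate threshold; very shallow samples (or repertoires without a
  bulk/tail split) are rejected rather than fitted badly.
* Parameter uncertainty (standard errors, confidence intervals) is not
  provided; the model is a descriptive and comparative device.
* Clone sizes are raw read counts; no frequency normalization or
  clonotype-calling from raw sequence is performed (AIRR-style tables are
  aggregated per clonotype key on input).

## A worked example

```{r example, eval = FALSE}
m <- spliced_model(alpha = 3, beta = 0.15, u = 20, sigma = 20,
                   xi = 0.5, phi = 0.15)
s <- generate_repertoire(m, n_clones = 20000, seed = 42)
fit <- fit_spliced(s)
fit
diversity_table(list(s), thresholds = fit$model$u)
```
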