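# clonetail

Model-based analysis of T cell receptor (TCR) repertoire **clone size
distributions**: a discrete Gamma-GPD spliced threshold model with
data-driven threshold selection, a type-I Pareto comparator, repertoire
diversity statistics, and Jensen-Shannon-distance comparative analysis
across samples, plus a cohort simulator for validation.

## Who this is for

Immunologists and computational biologists quantifying immune repertoires
from TCR (or BCR) sequencing. Each sample reduces to a vector of clone
sizes — reads per clonotype. The shape of that distribution carries the
biology: a bulk of rare clonotypes plus a heavy, power-law-like tail of
clones expanded by antigen-driven proliferation. `clonetail` fits that
shape explicitly and turns the fitted models into comparable, clusterable
objects.

## The model

Clone sizes are integers, so continuous laws are quantized at unit
intervals, `Pr(X = x) = Psi(x+1) - Psi(x)`. The spliced model is

```
f(x) = (1 - phi) * h(x) / Z_bulk    for x <= u - 1   (discrete Gamma bulk)
f(x) = phi * g(x)                   for x >= u       (discrete GPD tail)
```

with `h ~` discrete Gamma(`alpha`, `beta`), `g ~` discrete
GPD(`u`, `sigma`, `xi`), and `phi` the tail mass fraction. The threshold
`u` is chosen by maximizing the profile likelihood `L_p(u)` over every
unique observed clone size at or above the sample's 75% quantile, with
`phi-hat = n_u / n` plugged in and the bulk/tail parameters maximized
independently at each candidate.

Interpretation: `u` marks where active immune response begins; `xi` is
tail weight (heavier = more dominated by expanded clones; inversely
related to the type-I Pareto shape via GPD(u, u/a_d, 1/a_d) = Pareto(u,
a_d)); `phi` is the fraction of responding clonotypes. Because the GPD is
threshold-stable — above a higher cut the shape `xi` is unchanged — the
fitted shape is robust to sequencing depth, which is what makes
cross-sample comparison meaningful.

Also included:

* `fit_desponds()` — the tail-only type-I Pareto comparator with
  KS-minimizing threshold selection.
* `richness()`, `shannon()`, `clonality()`, `proportion_stimulated()` —
  ecological estimators plus the model-derived fraction of reads in the
  stimulated regime.
* `jsd_spliced()` / `jsd_desponds()`, `pairwise_distances()`,
  `cluster_samples()` (Ward), `embed_mds()` (non-metric MDS) — cohort
  comparison.
* `simulation_design()`, `build_design_cohort()`, `downsample_reads()`,
  `equalize_depth()` — simulation and depth-robustness tooling.
* `read_clone_table()` (two-column or AIRR-style TSV), fit-record JSON
  serialization, and a shell interface (`repertoire_cli()`, wrapped by
  `inst/scripts/clonetail`).

## Worked example

```r
library(clonetail)

m   <- spliced_model(alpha = 3, beta = 0.15, u = 20, sigma = 20,
                     xi = 0.5, phi = 0.15)
s   <- generate_repertoire(m, n_clones = 20000, seed = 42)
fit <- fit_spliced(s)
fit
#> Spliced threshold model fit for 'sim' (20000 clonotypes, 388,796 reads)
#>   u = 20  alpha = 2.879  beta = 0.1395  sigma = 19.15  xi = 0.5254  phi = 0.14765
#>   log-likelihood = -70228.2519 over 242 candidate thresholds

diversity_table(list(s), thresholds = fit$model$u)
#>   label richness  shannon  clonality prop_stimulated
#> 1   sim    20000 9.149449 0.07613872       0.4867746

fit_desponds(s)
#> Type-I Pareto tail fit for 'sim'
#>   u = 54  alpha_d = 1.619  KS = 0.021892  (n_tail = 831 of 20000 clones)
```

The profile search recovers the generating threshold (`u = 20`) and tail
shape (`xi-hat = 0.53` vs 0.5). About 49% of reads sit in clones at or
above the fitted threshold (`prop_stimulated`). The Pareto comparator,
which must place its threshold where a pure power law starts, keeps only
the top 831 clones and maps to a similar tail weight (`1/alpha_d = 0.62`).
For a cohort, `pairwise_distances()` on the fitted models followed by
`cluster_samples()` or `embed_mds()` gives the comparative picture.

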