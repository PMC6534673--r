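# driftpulse

Forward-time Wright–Fisher simulation and resampling-based model selection
for a single Y-chromosome haplogroup, built around one question: can
genetic drift alone explain a haplogroup that is absent in one population
(0 of 2677 sampled Indo-European-speaking neighbours), present at ~4% in
Hungarian Seklers (4 of 95), and at ~13% in Southern Ural/West Siberian
populations (124 of 957) — or is admixture from the Ural/Siberian source
required, and how much?

The package is for population geneticists who want a small, fully
reproducible drift/admixture testbed: each population is a haploid
Wright–Fisher deme of constant size *N* (default 5000 lineages) carrying a
biallelic marker (carrier vs non-carrier), pulses replace a proportion α
of a recipient's gene pool with the source's, and simulated final samples
are matched to observations within a tolerance of two standard errors,

```
tol = 2 · sqrt( p(1−p) / 2n ),     p = 0  →  p = 1/(n+1).
```

Three demographic models are scored:

* **Model A** — pure drift from a shared uniform(0,1) ancestor, 100
  generations; simulations retained when the Ural/Siberian sample matches,
  successful when the Sekler and Indo-European samples also match.
* **Model B** — one shared pulse from the source into both carrier-free
  European populations 30 generations before present; retained on the
  Ural/Siberian and Sekler matches, successful on the Indo-European match.
* **Model C** — independent pulses into the two recipients; draws accepted
  only when all three samples match, giving a rejection-sampling (ABC)
  posterior for the starting source frequency, both admixture proportions
  and the final source-population frequency.

Models A/B run as 100 blocks × 100 conditioned simulations
(`replicate_success_rate()`); Model C is the fitting function
(`fit_admixture_abc()`), with `print`, `summary`, `coef`, `confint`,
`plot` and `as.data.frame` methods.

## Worked example

```r
library(driftpulse)

fit <- fit_admixture_abc(n_accepted = 1000, seed = 13)
print(fit)
#> <admixture_abc> rejection-sampling fit: 1000 accepted draws, raw acceptance 0.000391
#> Posterior means (95% percentile interval), %:
#>   p0                     13.3  (5.6 - 23.6)
#>   alpha_hun              43.7  (8.1 - 91.0)
#>   alpha_ie                3.7  (0.1 - 15.3)
#>   source_final_freq      12.8  (10.3 - 15.6)
#>   source_sample_freq     12.8  (11.5 - 14.4)
#>   sekler_sample_freq      4.1  (2.1 - 6.3)
#>   ie_sample_freq          0.0  (0.0 - 0.1)
```

Read: only about 4 in 10,000 random parameter draws reproduce all three
observed samples.  Among those that do, the source population ends at
~12.8% carriers; the Seklers received on average ~44% of their gene pool
from the source — but the 8–91% interval shows this is weakly identified
— while the Indo-European contribution is pinned near zero (~3.7%, upper
bound ~15%).  The drift-only and shared-pulse alternatives fail outright:

```r
replicate_success_rate(model_config("A"), seed = 11)
#> <drift_replication> Model A: mean success rate 0.06% (sd 0.24%) over 100 blocks of 100 conditioned simulations
#>   total raw attempts: 334300 (conditioning acceptance 0.0299)
replicate_success_rate(model_config("B"), seed = 12)
#> <drift_replication> Model B: mean success rate 0.89% (sd 0.87%) over 100 blocks of 100 conditioned simulations
#>   total raw attempts: 891938 (conditioning acceptance 0.0112)
```

Count tables (tab-separated: `population`, `group`, `n`, `carriers`) are
read with `read_counts()`, pooled with `pool_counts()` and converted to
match targets with `as_observed()`; `generate_counts()` simulates tables
with known ground truth for testing, and `system.file("extdata", package
= "driftpulse")` holds small examples.  A command-line wrapper lives at
`inst/scripts/driftpulse.R` (sub-commands `simulate`, `fit`,
`make-fixtures`).

## The methods vignette

`vignettes/drift-admixture-models.Rmd` documents the model and its
assumptions, the tolerance and zero-adjustment conventions, the open
design choices (pre-pulse source drift, interval conventions, success
definitions) and the limits of what the synthetic-data tests demonstrate.
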