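# polarmeta

Tools for studying how **metacognitive insight** relates to **belief
polarization** over contested science, for researchers in computational
cognitive science and judgment & decision making.

In the underlying task, participants read balanced sets of short texts
endorsing or rejecting a scientific proposition, rate the direction of the
evidence on a 17-point scale (−8..+8) with a 6-level confidence judgment
(50%..100%), and report prior and posterior beliefs on the same 17-point
scale. `polarmeta` turns such trial tables into the four statistics the
design revolves around:

- **Task sensitivity** `d′ = Z(TP rate) − Z(FP rate)` and criterion
  `c = −(Z(TP) + Z(FP))/2`, with the log-linear correction
  `(count + 0.5)/(n + 1)`. Ratings above 0 count as endorsement, below 0
  as rejection, and 0 as incorrect in both directions.
- **Metacognitive sensitivity** `meta-d′`: the object-level d′ an ideal
  observer would have needed, given the same relative bias `c/d′`, to
  produce the observed confidence data. Estimated per participant by
  maximum likelihood over the type-2 response×confidence table, with a
  pooled and an empirical-Bayes hierarchical (normal over log M-ratio)
  group option.
- A **belief-updating taxonomy** — depolarizer, no-change, flip, opinion
  creation, polarizer — partitioning every (prior, posterior) pair, and
  the **polarizer proportion** `G_pol` with its relative Gaussian error
  `ΔG = G_pol/√n`.
- **Prior-influence regressions** `Interpretation_i = α + γ·Prior_i + ε_i`
  (per direction of evidence, on per-participant mean ratings), with
  mean-split moderation on d′ and meta-d′, 3σ-region parameter
  comparison, and trial-level Fisher-z correlation intervals.

A synthetic participant generator with known ground truth
(`sim_config()` / `generate_dataset()`) backs every estimator with
parameter-recovery tests, and `run_pipeline()` runs the whole analysis
end to end with CSV/JSON reports.

## Worked example

Simulate a contested-topic study at the reference study scale (354 is the reference
N; 120 here for speed), analyze it, and read the main tables:

```r
library(polarmeta)
dat <- generate_dataset(sim_config(n_participants = 120,
                                   topic_profile = "contested",
                                   n_endorse = 4, n_reject = 4, seed = 42))
res <- analyze_study(dat$trials, dat$participants)

res$polarizers[res$polarizers$group == "all", ]
#>      topic group   n n_pol    g_pol  delta_g
#>  contested   all 120     7 5.833333 0.532508

subset(res$regressions, group == "all")
#>      topic group direction     alpha  se_alpha     gamma   se_gamma      rse   n
#>  contested   all endorsing  3.626876 0.1458139 0.2568944 0.02422116 1.203475 120
#>  contested   all rejecting -3.810035 0.1650373 0.2220089 0.02741435 1.362135 120
```

Reading this: 7 of 120 simulated participants (5.83% ± 0.53%) ended up
with a posterior more extreme than their prior in the same direction.
Endorsing texts were read as endorsing on average (α = 3.63 rating
points), and each point of prior belief pulled the interpretation about a
quarter point in its own direction (γ = 0.26) — close to the generator's
ground truth (α_gen = 4 before scale compression, γ around 0.28 for this
population once the metacognition coupling is included).

Single estimators are available directly:

```r
dprime(list(tp = 4, fp = 0, n_signal = 4, n_noise = 4))
#> d' = 2.563, c = -0.000 (TP rate 0.900, FP rate 0.100)
```

2.563 is the ceiling an error-free participant reaches on 4+4 texts under
the log-linear correction (1.935 on 2+2 texts).

For shell use, `inst/scripts/polarmeta-cli.R` wraps the pipeline in
`simulate` / `analyze` / `reproduce` subcommands; `reproduce` accepts an
editable column-mapping file (`inst/extdata/deposit_column_mapping.json`)
so deposited datasets with foreign column names run unchanged.

## Package layout

- `R/sim-config.R`, `R/simulate.R` — synthetic study generator
- `R/sdt.R` — response coding, SDT counts, d′/c
- `R/metad.R`, `R/metad-group.R` — meta-d′ MLE and group estimators
- `R/belief.R` — updating taxonomy and polarizer statistics
- `R/moderation.R` — OLS, mean splits, 3σ comparison, Fisher-z CIs
- `R/pipeline.R`, `R/validate.R` — end-to-end analysis, input validation
- `vignettes/metacognition-and-polarization.Rmd` — models, assumptions,
  numerical choices, and what the synthetic validation does and does not
  show
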