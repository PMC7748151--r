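# vitropt

Surrogate modelling and evolutionary optimization of plant tissue-culture
media.

Composing an in vitro culture medium is a multi-objective problem: the
mineral and hormone levels that maximize shoot proliferation of a woody
rootstock are rarely the ones that maximize shoot length or plantlet
quality, and they often aggravate shoot-tip necrosis and hyperhydricity.
vitropt implements, as tested reusable R functions, the complete workflow
used for optimizing pear-rootstock (OHF 69 and Pyrodwarf) proliferation
media from a six-factor Box–Behnken experiment, and it ships the published
surrogate models of that study as evaluable fixtures. It is aimed at plant
tissue-culture researchers and at anyone who wants a compact, inspectable
alternative to black-box response modelling:

* **Design** — the six-factor, three-level Box–Behnken design (48 edge
  runs) with coded/actual conversion for the medium components
  (KNO3, NH4NO3, grouped meso- and micro-nutrients in ×MS units; BA and
  IBA in mg/l).
* **Surrogates** — gene expression programming (Karva-encoded symbolic
  regression over a 16-operator function set, protected arithmetic,
  random numerical constants, RRSE fitness
  `sqrt(sum((O - P)^2) / sum((O - mean(O))^2))`) and M5′ model trees
  (splits maximizing the standard deviation reduction
  `SDR = sd(T) - sum(|Ti|/|T| sd(Ti))`, complexity-penalized pruning,
  ordered first-match rule sets).
* **Input ranking** — the Gamma test: regress half mean squared output
  differences on mean squared k-nearest-neighbour input distances; the
  intercept Γ estimates the noise variance, and leave-one-out masks rank
  the components by importance.
* **Optimization** — a real-coded mono-objective GA, NSGA-II, and MOPSO
  with an external crowding-pruned archive (velocity update
  `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`), plus a weighted
  scalarization to pick one representative medium from a Pareto front.
* **Synthetic data** — quadratic truth surfaces with known coefficients,
  declared-irrelevant factors and replicate noise, so every stage is
  testable end to end.

## Worked example

Evaluate a published model at its reported optimum — the Pyrodwarf
proliferation equation at the mono-objective GA optimum reproduces the
printed 13.00432 shoots per explant:

```r
library(vitropt)
m <- get_model("Pyrodwarf", "PR", "GEP")
evaluate_expression(m, c(A = 1.5637, B = 1.188, C = 1.7548,
                         D = 3.2834, E = 2.0792, F = 0.1311))
#> [1] 13.0045
```

Predict all five responses of OHF 69 on the reported swarm-optimized
medium (1.00 NH4NO3, 0.50 KNO3, 2.32 Mesos, 2.32 Micros ×MS, 2.10 BA,
0.20 IBA mg/l); the printed values are 12.41, 5.61, 4.27, 0.00, 2.13:

```r
predict_media_response("OHF", c(NH4NO3 = 1.00, KNO3 = 0.50, Mesos = 2.32,
                                Micros = 2.32, BA = 2.10, IBA = 0.20))
#>    PR    SL    QI   STN Vitri
#> 12.40  5.60  4.24  0.00  2.15
```

(necrosis is clamped at zero: the raw model value is negative). Rank the
components of a simulated BA-dominated response by the Gamma test — BA's
leave-one-out Γ towers over the rest, so it is ranked most important:

```r
d <- generate_bbd(6)
X <- design_actual(d)
set.seed(1)
y <- 4 * X[, "BA"] + 0.4 * X[, "KNO3"] + rnorm(48, 0, 0.3)
rank_inputs(mask_scan(X, y, loo_masks(6), p = 10, allow_ties = TRUE),
            colnames(X))
#>    input index loo_gamma full_gamma
#> 1     BA     5     27.76      0.307
#> 2    IBA     6      3.03      0.307
#> ...
```

A full run — simulate, fit, rank, optimize, write reports — is one call:

```r
run_pipeline(run_config(seed = 1, out_dir = "demo-run"))
```

The methods vignette (`vignettes/media-optimization.Rmd`) documents the
models, every tunable parameter, the numerical choices, and a transcription
appendix for the published fixtures.

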