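# matenet

Metrics of assortative mating by mating success on bipartite sexual
networks, for behavioural ecologists studying sexual selection and sperm
competition.

When females mate multiply, males keep competing after mating: a male's
reproductive success depends both on his number of partners (mating
success, *M* = node degree in the mating network) and on how much sperm
competition his ejaculates face inside each partner. Whether
high-*M* males tend to mate high-*M* (polyandrous) females — assortative
mating by mating success — therefore shapes the strength of precopulatory
sexual selection. `matenet` implements the three metric families used to
measure it, and the regression machinery linking them to Bateman
gradients:

- **Newman's assortativity** *r*: Pearson correlation of the degrees at
  the two ends of each edge, directed (each copulation counted once,
  male→female) or undirected (each link read from both ends).
- **NODF nestedness** (0–100): percentage overlap under strictly
  decreasing fill across ordered row and column pairs; high NODF is the
  nested, disassortative pattern.
- **SCIC**: the association between a male's *M* and his sperm
  competition intensity SCI — the harmonic mean of his partners' mating
  successes, i.e. the reciprocal of his mean fair-raffle paternity share
  *s*ᵢ = (1/*M*ᵢ) Σⱼ 1/*k*ⱼ.
- **Bateman decomposition**: the exact least-squares identity
  β_M = β_{M·SCI} + b_{SCI∼M} · β_{SCI·M}, splitting the Bateman gradient
  into a mating-success component and a sperm-competition component.
- A **uniform simulator** of random mating networks with fixed size, sex
  ratio and mating density in which every individual mates at least once,
  plus the three-axis sensitivity **study** (size, sex ratio, density;
  1,000 replicates per level) with Spearman/Pearson summary tables and a
  density-matched NODF null-model z-score.

## Worked example

A male `A` mates two females: `x` (monandrous) and `y`, who also mates
males `B` and `C`. Under a fair raffle `A`'s expected paternity shares are
1 and 1/3, so his mean share is 2/3 and his SCI is the harmonic mean 1.5
of his partners' mating successes (1 and 3):

```r
library(matenet)
net <- from_edge_list(data.frame(
  male_id   = c("A", "A", "B", "C"),
  female_id = c("x", "y", "y", "y")))
sperm_competition_intensity(net)$sci
#>   A   B   C
#> 1.5 3.0 3.0
metric_report(net)
#> metric_report (density 0.667 )
#>   r_newman_u  -0.667
#>   r_newman_d  -0.577
#>   nodf        75.000
#>   scic_corr   -1.000
#>   scic_slope  -0.800
```

Every correlation metric is negative — the high-*M* male has the
low-competition partners — and NODF is high: `B` and `C`'s partner sets
nest inside `A`'s neighbourhood structure. On monogamous or single-sex
-variance networks these metrics return explicit undefined states
(`NA:no-male-degree-variance` etc.) instead of `NaN`.

Simulated random mating and the selection analysis:

```r
sim <- random_mating_network(20, 20, 0.5, seed = 1)
d   <- degrees(sim)
sci <- sperm_competition_intensity(sim)$sci
T_i <- fair_raffle_paternity(sim, 10, "multinomial", seed = 2)$T
bateman_decomposition(T_i, d$male_degrees, sci)
#> Bateman decomposition (mean-relative standardisation)
#>   beta_M                0.7927
#>   beta_M.SCI            0.8110
#>   beta_SCI.M           -0.2161 (negative, as theory predicts)
#>   SCIC slope            0.0849
#>   identity gap        4.88e-15
```

The gradient on mating success (0.79) is slightly *below* its
competition-controlled value (0.81) because in this random population SCIC
is weakly positive: successful males face marginally more sperm
competition, which costs them reproductive success (β_SCI·M < 0).

The sensitivity study (`run_axis_experiment`, `study_axes`,
`metric_parameter_correlation`, `metric_metric_correlation`) reproduces
the known behaviours of these metrics under random mating: NODF tracks
mating density almost perfectly but is decoupled from population size; the
undirected Newman coefficient turns strongly negative at skewed sex
ratios; directed Newman and SCIC agree strongly everywhere and are biased
negative in small populations.

## Command line

```sh
Rscript inst/cli/matenet.R compute --input edges.csv --out report.json
Rscript inst/cli/matenet.R bateman --edges edges.csv --fecundity fec.csv --mode multinomial --seed 7
Rscript inst/cli/matenet.R simulate --males 20 --females 20 --density 0.5 --reps 100 --seed 1 --out sims/
Rscript inst/cli/matenet.R experiment --axis all --reps 1000 --seed 1 --out study/
```

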