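---
title: "Measuring assortative mating by mating success on sexual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring assortative mating by mating success on sexual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matenet)
```

## The problem

In polyandrous populations a male's reproductive success depends not only on
how many females he mates (his mating success $M$) but on how many rival
ejaculates his sperm must outcompete inside each partner. If the males with
the highest mating success also tend to mate the most polyandrous females,
their paternity share per female shrinks, and population-level sexual
selection on mating success is weaker than a simple count of partners
suggests. Quantifying this *assortative mating by mating success* is
therefore a prerequisite for interpreting Bateman gradients in any system
with female remating.

`matenet` treats a mating population as a bipartite network: male and female
nodes, edges for copulating pairs, stored as an $m \times f$ incidence
matrix (males are rows) with optional copulation counts as weights. Node
degree is mating success. Three metric families quantify the association
between a male's $M$ and the $M$ of his partners.

## The metrics

**Newman's assortativity** is the Pearson correlation of the degrees at the
two ends of an edge, over edges:

$$ r = \frac{\sum j_i k_i - E^{-1}\sum j_i \sum k_i}
{\sqrt{\left[\sum j_i^2 - E^{-1}(\sum j_i)^2\right]
       \left[\sum k_i^2 - E^{-1}(\sum k_i)^2\right]}} $$

The *directed* form counts each copulation once, male to female. The
*undirected* form reads every link from both ends, implemented by
concatenating the pair list with its coordinate swap — no second formula
path exists, so the two modes can only differ through that doubling. We use
the population-moment form as written; Pearson correlation is
scale-invariant, so this is identical to any consistent sample
normalisation (the suite verifies equality with `stats::cor` to 1e-12 on
the full 2×2 space and random 3×3 matrices). When the degrees on one side
of all edges are constant, the correlation is undefined; the package
returns an explicit `metric_value` with a reason code rather than `NaN`.

**NODF** measures nestedness — the disassortative pattern where partners of
low-degree individuals are subsets of the partners of high-degree
individuals. Rows and columns are ordered by decreasing degree; each ordered
pair contributes its percentage overlap when fill strictly decreases and 0
on ties. Because tied pairs contribute 0 regardless of order, the tie-break
among equal-degree rows is irrelevant, and the metric is invariant to input
permutations (tested by shuffling). Degrees are integers, so the tie rule
uses exact comparison, no epsilon. A pair whose lower member has degree 0
would divide by zero; such individuals are excluded before computation (see
below), and the guard defines PO = 0 in case a caller constructs one
directly.

**SCI and SCIC.** Under a fair raffle — every competing male has the same
fertilisation probability per ovum — a male's expected paternity share with
female $j$ is $1/k_j$, so his mean share is
$s_i = \frac{1}{M_i}\sum_j 1/k_j$ and his sperm competition intensity is
the harmonic mean $\mathrm{SCI}_i = 1/s_i$, bounded by his partners' minimum
and maximum degrees. SCIC is the association of $M_i$ with
$\mathrm{SCI}_i$ across males. Two standardisations are exposed:

* `correlation` (default): Pearson $r(M, \mathrm{SCI})$, the form obtained
  when both variables are z-scored like phenotypic selection gradients.
* `slope`: least-squares slope of mean-standardised SCI on
  mean-standardised $M$, the Bateman-gradient convention.

The source text never states which form produced its summary table; we
default to the correlation because the table's perfectly assorted block
population shows SCIC = 1.000 alongside $r = 1.000$, the signature of a
correlation-type statistic, and because the correlation is the
scale-free choice. The slope form is retained because it is the term the
decomposition identity below requires; conflating the two is the one
silent error this API is designed to prevent.

A weighted variant treats each copulation as a raffle ticket:
$s_i = \frac{1}{M_i}\sum_j w_{ij}/W_j$, so remating with a female raises a
male's share with her above $1/k_j$.

## The Bateman decomposition

With reproductive success $T$, the Bateman gradient $\beta_M$ is the slope
of $T$ on $M$. Adding SCI as a second predictor,

$$ T_i = \beta_{M\cdot SCI} M_i + \beta_{SCI\cdot M}\,\mathrm{SCI}_i +
\varepsilon_i, $$

ordinary least-squares algebra gives the exact identity

$$ \beta_M = \beta_{M\cdot SCI} + b_{SCI\sim M}\,\beta_{SCI\cdot M}, $$

where $b_{SCI\sim M}$ is the simple slope of SCI on $M$ — the slope form of
SCIC. The identity is the omitted-variable decomposition of a two-predictor
regression and holds for any standardisation that rescales each variable by
a constant; both the `raw` and the default `mean-relative` convention
(divide $T$, $M$, SCI by their means) qualify. `bateman_decomposition()`
reports the gap as a numerical check; it is ~1e-15 on non-degenerate data
and the acceptance suite requires < 1e-10 over 1,000 simulated populations.
When $M$ and SCI are collinear (common in tiny networks, where SCI is often
an affine function of $M$) the partial slopes are not identifiable and the
function stops with the predictor correlation in the message. Constant SCI
is handled as the natural degenerate limit: the SCI term drops out and
$\beta_{M\cdot SCI} = \beta_M$.

`fair_raffle_paternity()` generates $T$ under the null model, either as
expected values $T_i = \sum_j f_j w_{ij}/W_j$ (deterministic; with unit
fecundities this makes $T_i = M_i/\mathrm{SCI}_i$ exactly, which the suite
asserts) or by one independent multinomial draw per female (sampled;
conserves total fecundity by construction; seed recorded in the output).

## What the simulator states, and why

`random_mating_network(m, f, density)` draws uniformly from all binary
$m \times f$ matrices with exactly $E = \mathrm{round}(density \cdot m f)$
edges and every row and column sum at least 1 ("everyone mates at least
once"). The generator draws $E$ distinct cells uniformly and rejects draws
that leave anyone unmated; conditioning a uniform distribution on an event
preserves uniformity, so the accepted networks are exactly uniform on the
constrained space — a property a constructive repair scheme would not
obviously have, and the reason rejection sampling was chosen. The suite
verifies uniformity by exhaustively enumerating the 2×3, $E = 4$ space
(12 valid matrices of the 15 four-cell subsets) and applying a chi-square
test to 12,000 draws. At the study's densities (0.25 and up) rejection
rates are negligible; very sparse configurations can starve and abort with
the rejection count after `max_rejections` draws.

The defaults of the study axes are the stated world of the sensitivity
experiment: 1,000 replicates per level; sizes 6×6, 20×20, 80×80 at density
0.5; sex ratios 10×50, 30×30, 50×10 (levels encoded as males/females: 0.2,
1, 5) at density 0.5; densities 0.25, 0.5, 0.75 at 20×20. Axis levels are
encoded as total individuals for the size axis — the source does not state
its coding, and total individuals matches the "population size" framing.
Per-replicate seeds are a deterministic function of the base seed and the
(axis, level, replicate) position, in disjoint blocks so no two replicates
of a study share a seed stream.

What the generator emulates is random mating under three global
constraints — size, sex ratio, density — and nothing else: no behaviour, no
spatial or temporal structure, no repeated copulations, no unmated
individuals. A green study property therefore establishes how the *metrics*
behave under null mating, not how real populations mate; in particular the
negative small-population bias of the directed assortativity is a property
of the constrained random space itself.

## Undefined values and degree-0 individuals

Strict monogamy, pure polygyny and similar structures lack the variance a
correlation needs. Every correlation-type metric returns an explicit
undefined state (`NA:no-male-degree-variance`,
`NA:no-female-degree-variance`, `NA:no-edge-end-variance`) instead of a
number; NODF is always defined, with 0 a meaningful value. The study keeps
undefined replicates as `NA` rows with reason codes and drops them only
from analyses involving that metric, mirroring how the original analyses
excluded them. The correlation-form SCIC is undefined when SCI is constant
across males; that arises from constant partner mating success, so it
carries the `no-female-degree-variance` code.

Individuals that never mated are permitted in the data model (empirical
data contain non-maters) but are excluded from all metric computations:
they carry no edges, would only dilute degree variances, and the
conditions for assortment are stated over mating individuals. The exclusion
is tested: padding a network with unmated individuals changes no metric.

## Numerical choices

* Newman's formula uses population moments; equality with `stats::cor` is
  asserted to 1e-12 rather than exactly, the cost of different summation
  orders.
* `round()` (half-even) maps density to edge count; every stock
  configuration yields an integer, so the rule never actually fires.
* The worked SCI example prints 0.667 and then 1.499 competitors; the
  second figure is `1/0.667` re-rounded, not `1/(2/3) = 1.5`. The package
  computes exact values and the acceptance report reproduces the printed
  ones by applying the same two-step rounding at print time.
* The decomposition rejects predictor collinearity at `1 - r^2 < 1e-12`.

## Known limitations

* NODF rises mechanically with mating density; `nodf_null_zscore()`
  re-expresses it against a density-matched uniform null, at the price of
  changing the interpretation to departure-from-randomness. The null is the
  package's own constrained-uniform generator; degree-sequence-preserving
  nulls (swap/curveball) are out of scope.
* The fair raffle assumes equal competitive value per mating (or per
  copulation in weighted mode); raffle loading by mating order, ejaculate
  size or cryptic female choice is not modelled.
* Same-sex edges, unipartite networks and temporal structure are out of
  scope by design.

## A worked session

```{r example}
net <- from_edge_list(data.frame(
  male_id   = c("A", "A", "B", "C"),
  female_id = c("x", "y", "y", "y")))
sperm_competition_intensity(net)$sci
metric_report(net)

dec_net <- random_mating_network(20, 20, 0.5, seed = 1)
d <- degrees(dec_net)
sci <- sperm_competition_intensity(dec_net)$sci
T_i <- fair_raffle_paternity(dec_net, 10, "multinomial", seed = 2)$T
bateman_decomposition(T_i, d$male_degrees, sci)
```
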