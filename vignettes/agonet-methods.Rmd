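---
title: "Methods: significant dyads and agonistic network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: significant dyads and agonistic network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`agonet` studies a methodological question in animal social network
analysis: if a dominance relationship is only accepted when the win/loss
record of a pair is *significantly* asymmetric, how much do the results
of a network analysis change?  This vignette documents the statistical
machinery, the modelling assumptions of the synthetic data generator,
and the design decisions taken where the methodology is genuinely open.

## Data model

The observational unit is the *agonistic interaction*: a fight or
displacement with physical contact, a clear initiator and receiver, and
a clear winner and loser.  Interactions are recorded per pen during
daytime observation blocks; nights are unobserved and all temporal
quantities run on *observed hours since mixing*, skipping the pauses.
Two schedule presets cover the usual designs: 28 observed hours for
weaned piglets (day 1: 12:00–18:00, days 2–3: 07:00–18:00) and 17 for
fattening pigs and gilts (day 1 + day 2 only).

Records without a clear initiator/receiver or winner/loser cannot enter
the analysis; `read_event_log()` drops them but always reports the count
(a data-reduction step of this kind must stay auditable).  Structural
contradictions — an animal fighting itself, an outcome pair that does
not match the contestants, an animal missing from the pen roster — are
errors, not silent repairs.

A fight is timestamped by its start; a fight straddling a window or
block boundary belongs to the window containing its start.  Expanding
windows are closed on the right: "the first hour" includes an event at
exactly 60 minutes.  Both conventions matter only for a measure-zero
set of events but are fixed so results are bit-reproducible.

## Dyad significance

For each unordered pair $(i, j)$ let $w_i$ and $w_j$ be the fights won
against each other, $n = w_i + w_j$, $d = |w_i - w_j|$.

**Dyad-individual limit.** Under the null that every fight is a fair
coin, $\max(w_i, w_j) \sim$ the maximum of a Binomial$(n, 1/2)$; the
dyad is significant at level $\alpha$ when the one-sided exact tail
$P(X \ge \max(w_i, w_j)) < \alpha$.  At $\alpha = 0.05$ the smallest
significant records are $5\!:\!0$, $6\!:\!0$, $7\!:\!0$, $7\!:\!1$,
$8\!:\!1$, … — at least five strictly unidirectional fights are
required.  No multiple-testing correction is applied across dyads and
no continuity correction is used; the test is exact and conservative
(attained size below $\alpha$ because the binomial is discrete).

**Pen-individual limit.** The dyad rule ignores how much a particular
group fights.  The pen rule instead asks whether a dyad is unusually
asymmetric *for its pen*: over all dyads with $n \ge 1$ (zero
differences retained — dropping them would bias the limit upward), take
the sign-test confidence interval of the median of $d$, and flag dyads
with $d$ strictly greater than the upper limit.  The CI uses order
statistics: $[x_{(k)}, x_{(n+1-k)}]$ covers the median with probability
$1 - 2\,P(B_{n,1/2} \le k - 1)$; since only finitely many levels are
achievable, the bounds are linearly interpolated between the bracketing
achievable intervals, the standard sign-test CI interpolation.  For
samples too small for any order-statistic pair to reach the requested
level, the full range is returned with its achieved confidence.

Two places here are genuinely underdetermined and are exposed as
options rather than hidden choices:

* *CI sidedness.* The pen rule is described in the field both as a
  one-sided test and through a 95% confidence interval; the two cannot
  both hold literally.  We use the two-sided 95% interval (the
  explicitly stated quantity) by default and expose
  `sides = "one"` for the alternative reading.
* *Exceedance.* Significance requires $d$ strictly greater than the
  upper limit: values inside the CI are consistent with a median of
  that size and therefore not extreme.

**Data sets.** `ALL` keeps every interacting dyad; `PEN` and `DYAD`
keep the significant ones under the respective rule (both directions of
a kept dyad, including reversals).  Pairs with no interaction are
labelled `unknown`.  The roster is never reduced: excluded animals
appear downstream as isolated nodes, which is itself a finding (an
animal whose position cannot be determined), not missing data.

**Per-window recomputation.** In the temporal analysis the labels are
recomputed inside each window from that window's events by default —
the only self-consistent reading when each window is analysed as a
network in its own right.  `labels = "final"` freezes the
full-observation labels instead and applies them to every window; the
two policies coincide at the final window.

## Networks and metrics

Edges point initiator → receiver and carry the fight count as weight.
Repeated fights collapse onto one edge; *all metrics operate on the
unweighted topology* (density and degree are explicitly proportions of
possible edges/neighbours; weights are retained for export and
visualisation only).  Isolates stay in the node set, so every
standardisation divides by full pen size.

With $N$ nodes and $E$ distinct directed edges:

* density $= E / N(N-1)$;
* weak components by connectivity on the symmetrised graph, strong
  components by Kosaraju's two-pass algorithm;
* fragmentation $= 1 - \sum_k n_k(n_k-1) / N(N-1)$ over weak-component
  sizes $n_k$: the fraction of node pairs with no semipath;
* in-/out-degree centrality: distinct neighbours $/ (N-1)$;
* closeness, component-corrected for disconnected digraphs: with $r$
  the number of other nodes reaching $v$ (in) or reached from $v$
  (out) and $S$ the sum of those BFS distances,
  $C(v) = \frac{r}{N-1}\cdot\frac{r}{S}$, and $0$ when $r = 0$.  This
  keeps the measure finite and in $[0,1]$ on fragmented networks, at
  the cost of mixing reachability and distance information;
* betweenness: directed geodesic betweenness via Brandes' dependency
  accumulation, all shortest paths weighted equally, normalised by
  $(N-1)(N-2)$; unreachable pairs contribute nothing.

These are the standard topological definitions; they are also the only
set consistent with the qualitative behaviour expected of the system
(fragmentation falling to 0 while density stays midrange; isolates
scoring exactly 0 on every centrality).  The whole metric layer is
implemented from first principles and is pinned, in the test suite, to
brute-force oracles (transitive closure, Floyd–Warshall, geodesic
counting) on hundreds of seeded random digraphs and cross-checked
against igraph.

## Comparison machinery

Spearman's $r_S$ is the Pearson correlation of midranks; p-values use
the $t$ approximation, replaced by a full $n!$ permutation enumeration
for $n \le 8$.  A constant margin makes the correlation undefined and
is reported as `NA` with a warning — never silently.

For data-set comparisons, observations are paired by pen for general
network parameters and by (pen, animal) for centralities, at each
window length.  Isolated animals, with zero centrality, are *included*
in the centrality correlations: exclusion would condition on the
outcome of the filtering being compared.  Pens are pooled within an age
group at fixed window length.

Age-group differences in fight rate use the tie-corrected
Kruskal–Wallis test (delegated to `stats::kruskal.test`, with an
optional exact permutation p for tiny designs) and Dunn's post hoc z
tests on midranks, Bonferroni-adjusted by default (the adjustment is a
configurable choice, recorded in the output).

## The synthetic generator

No farm video data are shipped; the generator produces event logs with
the statistical structure the analysis assumes, so the pipeline is
testable end to end:

* each pen gets a latent strict hierarchy (uniform random permutation
  of ranks);
* each dyad fights at times from an inhomogeneous Poisson process with
  rate $\lambda_0 e^{-\kappa t}$ over observed hours, mapped back into
  the day/night schedule;
* the higher-ranked animal wins each fight with probability
  $\operatorname{logit}^{-1}(\beta\,\Delta r / (N-1))$, where
  $\Delta r$ is the rank gap — normalising by $N - 1$ gives $\beta$ a
  scale-free meaning across pen sizes;
* the winner initiates with probability $\gamma$, otherwise the
  initiator is uniform on the pair.  Initiation is deliberately
  decoupled from outcome because edges follow initiator/receiver while
  significance follows winner/loser.

Cohort presets encode the three standard mixing events: pen sizes
drawn from rounded normals ($8.9 \pm 0.6$ weaned piglets,
$20.9 \pm 1.7$ fattening pigs, $20.8 \pm 3.4$ gilts), schedules of 28
or 17 observed hours, and target fight rates of 12.3, 5.9 and 5.3
fights per animal-hour.  $\lambda_0$ is calibrated per pen so the
*expected* rate over the pen's full schedule hits the target:
$\lambda_0 = f\,N\,T / (D\,I)$ with $D = N(N-1)/2$ dyads and
$I = (1 - e^{-\kappa T})/\kappa$.

Defaults, chosen once on subject-matter grounds: $\kappa = 0.15$/h
(post-mixing fighting decays with a half-life of ≈ 4.6 observed hours,
matching the rapid settling of rank fights after regrouping);
$\beta = 2$ (a moderate hierarchy: adjacent ranks are near-even
contests, the extremes win ≈ 88% of fights); $\gamma = 0.8$ (attackers
usually win).  $\beta = 0$ is the exchangeable 50/50 null used for
calibration tests; $\beta \gtrsim 100$ saturates the logistic and
yields strictly unidirectional dyads, the deterministic limit used for
parameter-recovery tests.

**What the generator does not emulate — and what that means for the
tests.**  The Poisson process gives every dyad of a pen the same
expected fight count.  Real pens are strongly overdispersed: a few
dyads fight constantly, many hardly at all.  At the preset piglet rate
(12.3 fights/animal-hour for 28 h) the homogeneous model yields ≈ 86
fights for *every* dyad, so simulated ALL networks saturate — density
reaches 1, every animal is connected, and between-pen correlations of
ALL-based parameters become undefined (constant across pens).
Empirical values from sparse, heterogeneous field data (density ≈ 0.5
at 28 h, ≈ 10% significant dyads, PEN flagging more conservatively than
DYAD) are therefore *not* reproduced by the simulator, and passing
tests demonstrate correctness of the computations and calibration of
the tests under the stated model — not fidelity of that model to farm
data.  A per-dyad rate multiplier (e.g. gamma-distributed frailties, or
familiarity effects between previously acquainted animals) is the
natural extension point and is deliberately left out of the default
model rather than half-specified.

## Numerical and degenerate-input conventions

* Window membership uses a $10^{-9}$ h tolerance at boundaries; event
  clock times are whole minutes, so exact-boundary events are
  well-defined.
* Empty windows, edge-less networks and pens whose filtered network has
  no edges are valid inputs everywhere (metrics of an empty network:
  density 0, fragmentation 1, all centralities 0).  A pen with *no*
  interacting dyads has no pen limit; its dyads are all `unknown` and
  the PEN data set is empty, without error.
* `dyad_limit_significant(0, 0)` is not significant; the CI of a
  constant sample is that constant.
* Betweenness needs $N \ge 3$, density/closeness $N \ge 2$; violations
  are errors rather than NA.
* All tie handling is midranks; geodesic ties share dependency weight
  equally; no randomised tie-breaking exists anywhere, which together
  with seed-controlled simulation makes the full pipeline byte-stable.

## Problem sizes

The shipped tests run the metric layer against oracles on 200 random
digraphs of up to 12 nodes, the CI against enumeration on 100 samples
of up to 30 values, calibration checks on ≥ 500 simulated dyads, and
full pipelines on cohorts of 2–10 pens — sizes at which the brute-force
oracles are exact and fast while every code path (isolates, fragmented
components, saturated hierarchies, empty windows) is exercised.

## Known limitations

* The homogeneous dyadic Poisson process (above) is the binding
  simplification; winner/loser and bystander effects, spatial pen
  geometry and inter-mixing familiarity are out of scope.
* The closeness variant and the betweenness normalisation are the
  standard choices, but other variants exist; results for fragmented
  networks depend on that choice.
* Pen limits from very few interacting dyads (< 6) cannot reach 95%
  coverage; the achieved confidence is reported and should be checked
  before interpreting such pens.
* The exact permutation p for Spearman is limited to $n \le 8$ and the
  Kruskal–Wallis enumeration to ≈ 10 observations; beyond that the
  asymptotic approximations are used.
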