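---
title: "An optimality model for the size of collective infectious units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optimality model for the size of collective infectious units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciuevol)
```

## The question

Many viruses do not transmit one genome per particle. Polyploid virions,
membrane vesicles packed with virions, baculovirus occlusion bodies and
virion aggregates all deliver several genomes to a host cell as a single
infective entity -- a *collective infectious unit* (CIU). `ciuevol` asks when
natural selection favours such collectives over singleton transmission, and
what size of collective it favours, using an optimality argument: among pure
strategies "package $k$ genomes per unit", which integer $k$ maximises the
expected number of future infected cells?

## The fitness model

A cell infected by a strategy-$k$ virus produces a genome budget $n_g(k)$ and
therefore $n_g(k)/k$ infectious units. Each unit independently founds
$s_{\mathrm{eff}}(k)$ future cellular infections in expectation (scaled to a
maximum of 1). Fitness is

$$W(k) = \frac{n_g(1)\, g(k)}{k}\; s_{\mathrm{eff}}(k),$$

the product of an *opportunity cost* (fewer, larger units: the $1/k$ factor,
the exact analogue of the offspring size--number trade-off) and a per-unit
*benefit*. The candidate evolutionarily stable strategy $k^*$ is the smallest
integer maximiser of $W$; CIUs are favoured exactly when $k^* > 1$, i.e. when
some collective strategy is *strictly* better than singleton transmission.
Only integer sizes are considered; superinfection, mixed strategies,
trans-complementation between defective genomes and multi-generation dynamics
of interfering genomes are outside the model.

### Group-benefit curves

The per-unit success of delivering $j$ complete genomes is $s(j)$, with
$s(0) = 0$, $s(1) = \rho$, and saturation $s(j) = 1$ for $j \ge k_t$:
delivering more than $k_t$ complete genomes buys nothing further. Between the
anchors the package offers

* **diminishing** returns,
  $s(j) = \rho + (1-\rho)\,\dfrac{1 - e^{-(j-1)/a}}{1 - e^{-(k_t-1)/a}}$ --
  concave, with the scale $a$ (`shape`) interpolating from a step-like curve
  (small $a$) to the straight line between the anchors (large $a$);
* a **threshold** (sigmoidal) curve -- a logistic in $j$ with midpoint
  $(1+k_t)/2$ and width `shape`, rescaled to the same anchors; and
* a **constant** curve $s(j) = \rho$, the null form used to isolate
  efficiency and mutation effects.

These specific algebraic forms are this package's own choices; the
qualitative results depend only on the anchors, monotonicity and curvature
class, which the forms pin down. Saturation at $k_t$ is enforced exactly
(the code assigns 1 rather than trusting floating-point cancellation), which
is why `success(curve, k_t) == 1` holds to the last bit.

### Efficiency gains

If the resource cost of a unit scales with surface area while capacity scales
with volume, a size-$k$ unit saves up to a factor $k^{1/3}$ (spherical,
isometric growth; rods that elongate in one dimension save nothing). When
savings are re-invested in replication the genome budget gains a multiplier
$g(k) = k^{(1-\alpha)\epsilon}$, with $\epsilon \in [0, 1/3]$ the geometry
exponent and $\alpha \in [0,1]$ the fraction of the saving *not* converted
($\alpha = 0$ is the full cube-root law). Because
$(1-\alpha)\epsilon \le 1/3 < 1$, the ratio $g(k)/k$ is strictly decreasing:
efficiency gains can never outrun the opportunity cost on their own, so with
a flat success curve $k^* = 1$ always. They act as an amplifier of group
benefits, never as an independent cause.

### Defective and interfering progeny

A proportion $\mu$ of progeny genomes are defective (they fill packaging
slots but contribute nothing); a fraction $\iota$ of defectives are also
interfering, and one interfering genome zeroes a unit's success outright --
the model's deliberately extreme caricature of interference. With classes
drawn independently per genome, the effective success is the binomial
mixture

$$s_{\mathrm{eff}}(k) = \sum_{j=0}^{k} \binom{k}{j} (1-\mu)^j
  \left[\mu(1-\iota)\right]^{k-j} s(j)
  = (1-\mu\iota)^k\; \mathbb{E}\!\left[s(J)\right],
  \quad J \sim \mathrm{Bin}\!\left(k, \tfrac{1-\mu}{1-\mu\iota}\right).$$

The factorisation is the implementation: the escape factor $(1-\mu\iota)^k$
(all interference cost enters through the product $\mu\iota$) times a
binomial expectation collapsed over the curve's flat tail through `pbinom`,
so each evaluation costs $O(k_t)$ and stays stable for $k$ well past $10^4$
(`dbinom`/`pbinom` work in logs). $\mu = 1$ is handled as the exact
degenerate limit $s_{\mathrm{eff}} = 0$. Two independent oracles guard this
path in the tests: exhaustive enumeration of all $3^k$ per-genome class
assignments for $k \le 12$ (agreement to $10^{-12}$) and a multinomial
Monte-Carlo sampler (`effective_success_mc`).

Defectives push the useful size upward: to deliver $k_t$ complete genomes a
unit must package roughly $k_t/(1-\mu)$ of them, and the relevant landmark is
the *secondary threshold* $k_t'(\mu, \epsilon)$, the smallest $k$ with
$P(\mathrm{Bin}(k, 1-\mu) \ge k_t) \ge 1-\epsilon$ (`kt_prime`, default
$\epsilon = 0.001$ as a quantification of "almost surely"; computed by
bracketing and bisecting the monotone binomial tail).

## Numerical choices

* **Tie-break.** `which.max` takes the smallest maximiser, so "favoured"
  means strictly better than $k = 1$. This is the conservative reading; an
  exact tie (constructible, e.g. $s(1) = 0.5,\ s(2) = 1$) counts as not
  favoured.
* **Search bound.** The landscape is scanned over $k = 1..k_{max}$ (default
  1000). With $\mu > 0$ the optimum tracks $k_t'$, which can dwarf $k_t$, so
  the bound is automatically widened to
  $\max(k_{max},\ 10\,k_t'(\mu, 0.001))$; an optimum that still lands on the
  bound raises a warning and a `boundary_flag`.
* **Scale invariance.** $n_g(1)$ multiplies $W$ uniformly, so $k^*$ never
  depends on it; a property test asserts this over random models.
* **Monte-Carlo standard errors.** For points where the true effective
  success is of order $1/n_{\mathrm{draws}}$ or below, the empirical
  standard error can degenerate to 0 (every draw scores zero). Agreement
  checks therefore use $\max(\widehat{se},\ \sqrt{p(1-p)/n})$, the Bernoulli
  upper bound on the estimator's true standard error for scores in $[0,1]$.

## What the sweeps emulate

The bundled configurations (`fixture_config("fig1c")` etc., plain YAML under
`inst/extdata/`) are synthetic study conditions chosen once to exhibit every
qualitative regime of the model; axis ranges are
$\rho \in [10^{-3}, 1]$ (log-spaced, 25 points), `shape` $\in [0.1, 20]$
(25 points), $\mu \in [0, 0.95]$, $\iota \in \{0, 10^{-4}, 10^{-3}, 10^{-2},
10^{-1}\}$, with $k_t = 5$ throughout. The two mutation sweeps fix
$\rho = 0.05$ (fig3c additionally sweeps the diminishing `shape`; fig3d fixes
`shape` = 5), a regime where group benefits favour CIUs at $\mu = 0$ so the
mutation effects act on an existing collective. These grids are cartoons of
parameter space, not fits to any virus: passing tests show the model's
internal logic -- they say nothing about whether a real virus's success curve
is diminishing or threshold, which is an empirical question about
dose--response data that is explicitly out of scope.

```{r sweep, eval = FALSE}
cfg <- load_config(fixture_config("fig3d"))
grid <- sweep_optimal_k(cfg$model, cfg$sweep$axis1, cfg$sweep$axis2)
as.data.frame(grid) |> head()
render_heatmap(grid, "fig3d.png")
```

The numbered scripts under `analysis/` run these sweeps end to end (about
ten seconds each on one CPU; landscapes scan $k$ up to 1000, extended
automatically under mutational load) and write long-format CSVs and heatmaps
under `results/`.

## Behaviour worth knowing about

* **Thresholds can lose CIUs as $\mu$ rises.** On diminishing curves the
  optimum is numerically nondecreasing in $\mu$ wherever CIUs are favoured
  at $\mu = 0$ (and $\mu$ alone never creates CIUs -- if $k^* = 1$ at
  $\mu = 0$ then $s(k) \le k\,s(1)$, which forces
  $W(k) \le W(1)$ for every $\mu$). Sharp threshold curves are different: a
  collective favoured at $\mu = 0$ can drop straight to $k^* = 1$ at moderate
  $\mu$, because the smeared-out effective curve no longer clears the bar at
  any size. Among sizes where the collective survives, the optimum still
  only grows.
* **Fixture contrast.** On the matched $\rho \times$ `shape` grids, the
  diminishing form favours CIUs over at least as much of the space, while
  the threshold form's favoured units are larger on average -- the
  likelihood-versus-size trade-off that runs through all of these results.
* **Degenerate inputs.** $k_t = 1$ yields the already-saturated curve
  ($s(k) = 1$ for $k \ge 1$); `kt_prime` errors for $\mu = 1$ with
  $\epsilon < 1$ (no finite size works) and returns 1 for $\epsilon = 1$.

## Limitations

The model is a deliberate caricature: one generation, pure strategies, total
interference, no trans-complementation, no superinfection, and within-unit
genome classes drawn independently. It generates comparative predictions
(which conditions make CIUs more likely, larger, or impossible), not
quantitative estimates for any particular virus.
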