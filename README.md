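# ciuevol

Many viruses transmit their genomes in groups: polyploid virions, virion
aggregates, membrane vesicles and occlusion bodies all deliver several
genomes to a host cell as one infective entity — a **collective infectious
unit (CIU)**. `ciuevol` implements an optimality model for the number of
genomes $k$ such a unit should contain, for anyone studying viral social
evolution, defective interfering particles, or bloc transmission.

## The model

Among pure strategies "package $k$ genomes per unit", fitness is the
expected number of future infected cells,

$$W(k) \;=\; \frac{n_g(1)\,g(k)}{k}\; s_{\mathrm{eff}}(k),$$

combining

- the **opportunity cost** $1/k$ — fewer units can be made if each carries
  more genomes (the offspring size–number trade-off);
- **group infection benefits**: per-unit success $s(j)$ rises with the
  number of complete genomes $j$ delivered, from $s(1)=\rho$ up to exact
  saturation $s(j)=1$ at a threshold size $k_t$, with diminishing-returns,
  sigmoidal-threshold, or constant forms;
- **efficiency benefits**: surface-to-volume packaging savings inflate the
  genome budget by $g(k)=k^{(1-\alpha)\epsilon}$,
  $\epsilon \le 1/3$ (cube-root law for spheres; nothing for rods);
- **mutational load**: a proportion $\mu$ of progeny genomes is defective, a
  fraction $\iota$ of those is defective interfering (DI), and one DI genome
  zeroes a unit. Exactly,
  $s_{\mathrm{eff}}(k) = (1-\mu\iota)^k\,\mathbb{E}[s(J)]$ with
  $J \sim \mathrm{Bin}(k,\tfrac{1-\mu}{1-\mu\iota})$.

The candidate ESS $k^*$ is found by scanning integer sizes (bound extended
automatically under mutational load, where the optimum tracks the secondary
threshold $k_t'$); CIUs are favoured when $k^* > 1$. Two-dimensional
parameter sweeps map the favoured regimes, driven directly or through YAML
configurations. See `vignettes/ciu-optimality.Rmd` for the full account.

## Worked example

```r
library(ciuevol)

# sigmoidal group benefits: lone virions almost never succeed (rho = 0.05),
# five genomes saturate the benefit
crv <- group_benefit_curve("threshold", rho = 0.05, k_t = 5, shape = 0.5)
model <- ciu_model(crv)

round(fitness(model, 1:8), 4)
#> [1] 0.0500 0.0749 0.1750 0.2251 0.2000 0.1667 0.1429 0.1250
optimal_k(model)
#> [1] 4
```

Four genomes per unit is optimal: $W(4) = 0.225$, four and a half times the
singleton's $0.05$ — the collective's success outweighs producing a quarter
as many units. Note $k^* < k_t$: the last genome toward saturation is not
worth its opportunity cost. Mutational load then reshapes the optimum:

```r
optimal_k(set_model_param(model, "mutation.mu", 0.5))   # defectives only
#> [1] 8
optimal_k(ciu_model(crv, mutation = mutation_model(0.5, 0.1)))  # 10% of them DI
#> [1] 6
```

When half of all progeny genomes are defective the favoured unit doubles to
8, insuring delivery of enough complete genomes; when 10% of those
defectives interfere, the optimum shrinks back toward 6 because each extra
genome risks packaging a DI genome that destroys the unit.

The numbered scripts under `analysis/` run the full study — success-curve
anatomy (`01`), when group benefits favour CIUs and at what size (`02`),
why efficiency gains amplify but never cause CIUs (`03`), and how defective
and interfering genomes enlarge or erase them (`04`) — writing long-format
CSVs and heatmaps under `results/`:

```sh
Rscript analysis/02_group_benefit_sweeps.R
```

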