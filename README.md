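# cqmodel

Simulation and bifurcation analysis of the cubic-quadratic (C-Q)
spiking-neuron model — a planar phenomenological neuron whose
membrane-potential nullcline is a cubic (spike upstroke) and whose
recovery nullcline is a quadratic (repolarisation):

    dW/dt     = -W^3 + 30 W - Z + E
    tau dZ/dt = 5 (W + v)^2 - Z

with membrane potential `W`, recovery variable `Z`, input current `E`,
recovery offset `v` and recovery time constant `tau` (all
dimensionless).  The package is for computational neuroscientists and
dynamical-systems practitioners who want the complete phase-plane
story of this model as reproducible code:

* **Equilibria and stability** — all real roots of the steady-state
  cubic `h(W) = -W^3 - 5W^2 + (30-10v)W + (E-5v^2)`, with Jacobian
  eigenvalues and node/focus/saddle classification
  (`cq_find_equilibria()`).
* **Bifurcations** — saddle-node (fold), Andronov-Hopf (the trace
  condition pins the abscissa at `W* = ±sqrt((30-1/tau)/3)`) and
  focus/node eigenvalue-type boundaries along one-parameter sweeps in
  `v` or `E`, each with verifiable non-degeneracy and transversality
  residuals (`cq_find_saddle_node()`, `cq_find_hopf()`,
  `cq_find_focus_node_boundary()`, `cq_branch_diagram()`).
* **Limit-cycle diagnostics** — compiled fixed-step RK4 integration,
  Poincaré-section cycle detection with period/amplitude convergence
  guards, winding numbers, numerical trapping-region verification,
  and a global-flow classifier for saddle-node-on-invariant-circle
  (SNIC) versus off-cycle folds (`cq_integrate()`,
  `cq_detect_limit_cycle()`, `cq_verify_trapping_region()`,
  `cq_classify_saddle_node_globality()`).
* **Periodic forcing** — the rescaled `v = 3` system driven by
  `E(t) = F sin(wt) + 70`, with stroboscopic bifurcation diagrams,
  Benettin largest-Lyapunov-exponent estimation and
  interspike-interval based classification of quiescent / spiking /
  bursting / chaotic regimes (`cq_forced_simulate()`,
  `cq_sweep_diagram()`, `cq_largest_lyapunov()`,
  `cq_classify_regime()`).

See `vignettes/cq-model-dynamics.Rmd` for the model, the numerical
choices and the package's own findings (including where they depart
from published claims and why).

## Worked example

```r
library(cqmodel)

cq_find_equilibria(cq_params(E = 70, v = -10))
#> 1 equilibrium point(s) of the autonomous C-Q model
#>    E   v tau        W       Z re_lambda1 im_lambda1 re_lambda2 im_lambda2
#> 1 70 -10   1 -15.3187 3205.19  -0.623998          0   -674.368          0
#>     stability
#> 1 stable_node
```

At `v = -10` the model has a single hyperpolarised rest state: both
eigenvalues are real and negative (a stable node), with the fast rate
`-674` reflecting the steep cubic at that abscissa.  Sweeping `v` at
`E = 70` locates the two folds and the Hopf point that organise the
transition from rest through bistability to tonic firing:

```r
cq_find_saddle_node("v", cq_params(E = 70), c(-12, 6))
#> 2 bifurcation point(s)
#> saddle_node at v = -9.35947  (W*, Z*) = (4.96477, 96.5666)
#> saddle_node at v = 2.33036  (W*, Z*) = (-3.90495, 12.3966)
cq_find_hopf("v", cq_params(E = 70), c(3, 6))
#> 1 bifurcation point(s)
#> hopf at v = 4.27369  (W*, Z*) = (-3.10913, 6.7811)
```

Past the upper fold the model fires tonically; the attractor is a
stable limit cycle around the unstable equilibrium:

```r
cq_detect_limit_cycle(cq_params(E = 70, v = 3), c(0, 0))
#> limit cycle: period 6.46892, W in [-6.288, 6.087], converged: TRUE
```

Under sinusoidal forcing at amplitude `F = 10`, the drive frequency
selects the firing regime — slow drive groups spikes into bursts
(bimodal interspike intervals), drive at the natural frequency
entrains clock-regular spiking:

```r
tr <- cq_forced_simulate(10, 1.56, t_end = 300)
cq_classify_regime(tr[tr$t >= 150, ])
#> firing regime: bursting (spikes: 112, ISI CV: 0.593, LLE: NA)

tr <- cq_forced_simulate(10, 5.75, t_end = 300)
cq_classify_regime(tr[tr$t >= 150, ])
#> firing regime: spiking (spikes: 137, ISI CV: 1.42e-07, LLE: NA)
```

`cq_reproduce()` re-runs the whole catalogue of tabulated phase-plane
scenarios (equilibria, eigenvalues, critical values of both sweeps)
and prints a pass/fail table against the quoted values.

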