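---
title: "Dynamics of the cubic-quadratic spiking-neuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of the cubic-quadratic spiking-neuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqmodel)
```

## The model

The package implements a planar phenomenological neuron,
$$\frac{dW}{dt} = -W^3 + 30W - Z + E, \qquad
  \tau\,\frac{dZ}{dt} = 5(W+v)^2 - Z,$$
with membrane potential $W$, recovery variable $Z$, input current $E$,
recovery offset $v$ and recovery time constant $\tau$ (all
dimensionless; there is no unit-conversion layer, and the model is
analysed in its own time scale throughout).  The cubic $W$-nullcline
$Z = -W^3 + 30W + E$ carries the spike upstroke — $-W^3$ confines the
voltage, $30W$ drives depolarisation — and moves vertically with $E$;
the quadratic $Z$-nullcline $Z = 5(W+v)^2$ models recovery (potassium
channel activation) and moves horizontally with $v$.  Equilibria are
the nullcline intersections, i.e. the real roots of the steady-state
cubic
$$h(W) = -W^3 - 5W^2 + (30 - 10v)\,W + (E - 5v^2).$$

`cq_params()` builds a validated parameter set, `cq_vector_field()`,
`cq_nullclines()` and `cq_jacobian()` expose the pure functions, and
everything downstream — equilibria, bifurcation curves, trajectories,
forced simulations — is deterministic given its inputs.

## Equilibria and stability

`cq_steady_state_roots()` solves $h(W) = 0$ with the Jenkins–Traub
solver (`polyroot()`) rather than by transcribing the closed-form
radical branches: the published Cardano expressions mix real and
imaginary parts and are easy to get wrong, so they are kept as an
*independent test oracle* (together with a companion-matrix eigenvalue
solve) and the package asserts agreement to $10^{-6}$–$10^{-7}$ over
a thousand random parameter draws instead.  A root where $|h'(W)|$
falls below a scaled $10^{-6}$ is reported once with multiplicity 2
(the degenerate equilibrium of a fold); at the tolerance boundary the
generic, distinct-root reading wins.

Eigenvalues come from the quadratic formula on the Jacobian trace and
determinant, which preserves conjugate symmetry exactly, and are
ordered by descending real part, then descending imaginary part, so
printed $(\lambda_1,\lambda_2)$ pairs compare deterministically.
`cq_classify_stability()` labels node/focus/saddle, with real parts
within `zero_tol` ($10^{-6}$ by default) of zero reported as
non-hyperbolic.  Bifurcation detection never relies on such exact
zeros; it locates sign changes instead.

Two reproducibility caveats worth knowing when comparing against
four-decimal published tables.  First, a handful of quoted recovery
coordinates and eigenvalues were evidently evaluated at the *rounded*
equilibrium abscissa: the rounding of $W$ at $5\times10^{-5}$ is
amplified by the local derivatives (about $6|W|$ into the eigenvalues,
$10|W+v|$ into $Z$), which at $W \approx -15.3$ means $4\times10^{-3}$.
The test suite therefore compares the abscissa directly and evaluates
the derived quantities at the quoted abscissa.  Second, one tabulated
eigenvalue ($v=-5$, lower branch, quoted $+404.59$) has a sign typo —
a stable node cannot carry a positive eigenvalue — and one quoted
fold abscissa ($4.9967$ at the lower fold of the $v$-sweep) is
inconsistent with the simultaneous conditions $h = h' = 0$, which give
$4.965$; the computed values are treated as authoritative and the
tests assert them.

## Bifurcation detection

For this model the codimension-one conditions collapse to low-order
polynomial systems, so the finders solve them directly instead of
bisecting a scalar condition (which the residual-based tests would
accept equally): folds come from $h = h' = 0$ — a quadratic in $W$ for
the $E$-sweep, a quartic after eliminating $v$ for the $v$-sweep — and
the Hopf condition $\mathrm{tr}\,J = -3W^2 + 30 - 1/\tau = 0$ pins the
abscissa at $W_\star = \pm\sqrt{(30 - 1/\tau)/3}$ (at $\tau = 1$,
$\pm\sqrt{29/3} \approx \pm 3.1091$), from which the critical
parameter follows in closed form; candidates with $\det J \le 0$ are
saddles, not Hopf points, and are discarded.  Every returned point
carries its back-substitution residuals plus the non-degeneracy
($\tfrac12 h'' \ne 0$) and transversality margins, so a user can audit
each detection.  The focus/node boundary
($\mathrm{tr}^2 - 4\det = 0$) genuinely lives on an equilibrium
branch, so it is found by continuation (nearest-abscissa matching over
a fine grid) with bisection refinement, and reports which branch it
sits on.

One subtlety the caption values of the equilibrium diagram gloss over:
on the upper branch of the $v$-sweep at $E = 70$, the boundary near
$v = 1.176$ is a discriminant zero (node
$\leftrightarrow$ focus), but the boundary near $v = 2.053$ is a
*trace* zero with positive determinant — an upper-branch Andronov-Hopf
point (at a trace zero the discriminant equals $-4\det J < 0$, so no
discriminant zero can sit there).  `cq_find_focus_node_boundary()`
reports only genuine discriminant zeros; `cq_find_hopf()` finds
$v = 2.0529$ in that bracket, and the suite asserts both.

## Trajectories and limit cycles

The default integrator is fixed-step classical RK4 in compiled code
with $dt = 10^{-3}$: equilibrium eigenvalues reach $|\lambda| \approx
674$ in the analysed parameter ranges, and explicit RK4 needs
$dt \lesssim 2.8/|\lambda| \approx 4\times10^{-3}$ there, so the
default keeps a factor-four margin while staying fast and exactly
reproducible.  An adaptive mode (`method = "adaptive"`, via
`deSolve::ode()`) is available for stiffer settings such as
$\tau \ll 1$.  States beyond $|W| > 10^3$ are treated as divergence
and raise a typed condition carrying the last valid state.

`cq_detect_limit_cycle()` discards half the horizon as transient and
reads the period off successive upward crossings of the Poincaré
section $W = W_{\mathrm{eq}}$ (the equilibrium abscissa nearest the
post-transient orbit mean).  Two guards keep the answer honest: a
trajectory that has settled onto an equilibrium returns nothing, and
so does a damped spiral, whose per-cycle amplitude keeps shrinking —
successive periods *and* amplitudes must agree to the stated relative
tolerance ($10^{-4}$ and $10^{-3}$) before a cycle is reported.
`cq_winding_number()` checks that a reported orbit actually encloses
the unstable equilibrium once.

The existence argument for the tonic cycle at $E = 70, v = 3$ is
verified numerically by `cq_verify_trapping_region()`: exactly one
interior equilibrium, unstable; field strictly inward at every
boundary sample; no equilibrium on the boundary.  The default test
rectangle is $W \in [-9, 6.5]$, $Z \in [-5, 500]$.  The choice is
deliberate: a rectangle hugging the orbit (say $W \in [-8,8]$,
$Z \in [0,260]$) *fails* the strict pointwise normal test, because on
its top edge beyond $W \approx 4.2$ the recovery flow still points
upward ($5(W+3)^2 > Z$) even though trajectories re-enter immediately
— the honest surrogate needs the top edge above
$5(W_{\max}+3)^2$, the right edge at $W$ large enough that the cubic
inflow dominates, and the bottom edge slightly below $Z = 0$ so the
parabola's vertex does not graze it.  The suite asserts both the pass
and that instructive failure.

Where "all initial conditions" are examined, the package uses the
fixed ten-point set `cq_standard_ics()`, chosen once to straddle both
attraction basins of the bistable regime (five states along $Z = 0$,
five at elevated recovery).

## The fold and the invariant circle

`cq_classify_saddle_node_globality()` separates a saddle-node on an
invariant circle (SNIC) from a fold off the cycle using global flow
evidence: a periodic attractor that already coexists with the
node–saddle pair just before the critical value means the fold happens
off the cycle; otherwise the attractor just past the fold (offset
$10^{-2}$) is integrated from the vanished pair's location, and it is
labelled on-circle when its orbit threads a neighbourhood of the fold
point (radius 0.5 in $(W, Z/30)$ coordinates — the recovery variable
spans roughly thirty times the potential's range on these orbits).

Applying the classifier to the upper fold of the $v$-sweep at
$E = 70$ gives an answer worth stating plainly: the fold is a SNIC for
*every* recovery time constant we examined ($\tau = 0.152$, $1$,
$6.6$).  In all three cases the emerging cycle passes within $10^{-2}$
scaled distance of the fold ghost, the period diverges like
$\mathrm{offset}^{-1/2}$ (quartering the offset doubles the period —
the suite asserts the ratio), and no coexisting periodic attractor
exists on the three-equilibrium side from any of the standard or
near-equilibrium starts even over horizons of several thousand time
units.  At $\tau = 0.152$ the upper equilibrium is still a *stable*
focus until a Hopf at $v \approx 2.344$, slightly past the fold, so
there is bistability between cycle and focus just past criticality —
but the circle through the fold exists all the same.  What does change
with fast recovery is the onset amplitude: at $\tau = 0.152$ the cycle
is born smaller and its amplitude grows with $v$, which the suite
verifies on a five-point grid.

## Periodic forcing, regimes and chaos

The forced system rescales the recovery variable of the $v = 3$ model
and drives it with $E(t) = F\sin(\omega t) + 70$:
$$\frac{dW}{dt} = -W^3 + 30W - 10Z + F\sin(\omega t), \qquad
  \frac{dZ}{dt} = 5(W+3)^2 - 10Z - 70.$$
The resting input level 70 appears exactly once, absorbed into the
$-70$ of the recovery equation.  Composing the same constants with the
drive written as $F\sin(\omega t) + 70$ adds the baseline a second
time; that composition parks the system at a strongly stable focus
near $W \approx 3.37$ (leading rate $\approx -7$) where no firing is
possible at any examined amplitude or frequency.  Because the
unforced system is supposed to sit on its tonic-spiking limit cycle —
and because the rescaled system's natural frequency,
$2\pi/1.09 \approx 5.76$, coincides with the quoted "wake" drive
frequency $5.75$ — the package uses the single-counted baseline as its
default (`drive = "rescaled"`) and keeps the double-counted
composition available as `drive = "printed"` for completeness; the
printed form's $F = 0$ sink and its Lyapunov exponent (equal to the
sink's leading eigenvalue real part, a useful oracle) are tested
against it.

With the default drive and $F = 10$, slow forcing
($\omega = 1.56$) groups spikes into bursts with a clearly bimodal
interspike-interval (ISI) distribution, and forcing at the natural
frequency ($\omega = 5.75$) entrains one spike per cycle with ISI
coefficient of variation below $10^{-2}$.  `cq_classify_regime()`
encodes the decision rule: spikes are upward crossings of $W = 2$
re-armed below $W = 0$ (the orbit spikes above $W \approx 4$ and
rests near $-4$, so both levels sit in wide margins); no spikes means
quiescent; a converged largest Lyapunov exponent exceeding both zero
and its own convergence spread means chaotic; otherwise a largest
sorted-ISI gap ratio of at least 3 separates bursting from spiking.
The burst criterion is a stated convention of this package, not a
published definition.

`cq_largest_lyapunov()` is a Benettin two-trajectory estimator: both
copies share the drive phase (growth along the time direction is
excluded), separation $10^{-8}$, renormalisation every $0.5$ time
units, transient 200 and horizon 2000 by default, with the running
estimate returned so convergence (final-fifth spread below
$0.05\max(1,|\lambda|)$) is checkable rather than assumed.

On the high-frequency drive the package's measurements depart from
the claimed behaviour, and the departure is robust: at
$F = 10, \omega = 15.02$ the long-horizon exponent converges to
$-0.003 \pm 0.002$ — indistinguishable from zero — across initial
conditions, steps ($10^{-3}$ to $2.5\times10^{-4}$) and horizons up
to 3000 time units, while the stroboscopic section fills a band.
Band-filling samples with a zero exponent are a quasiperiodic torus,
not chaos; scans over $F \in [0.5, 20]$ and $\omega \in [6, 30]$
found no converged positive exponent anywhere (locking windows reach
$-0.12$ and below; short-horizon estimates fluctuate within about
$\pm 10^{-2}$ of zero on the torus and should not be read as chaos).
The corresponding acceptance checks are therefore expected to fail,
and are left failing on purpose: the package reports what the
dynamics do.  `cq_sweep_diagram()` reproduces the qualitative
bifurcation-diagram structure — period-1 locking, period-$n$ windows,
band-filling regions — over $F$ at step $0.1$ (the finer published
step $0.01$ is supported; the default keeps a sweep to seconds).

## Problem sizes and numerical choices in the tests

The suite runs the oracle comparisons at 1000 random parameter draws
(cubic solver vs companion matrix, trace/determinant identities), 100
draws for the radical-branch equivalence, RK4 order measurement over a
unit horizon against a $10^{-5}$-step reference, limit-cycle horizons
of 200–600 time units, fold-onset period measurements at offsets
$10^{-2}$–$2.5\times10^{-3}$, Lyapunov horizons of 150–1500 time
units, and a 200-point forcing sweep; these sizes were chosen so the
whole suite completes in about a minute while every assertion retains
an order-of-magnitude margin over its tolerance.

## Limitations

Stability classification is linear; no normal-form or first-Lyapunov
coefficient computation is attempted (so sub- vs supercritical Hopf
is inferred from simulated onset, not proved), two-parameter
continuation is out of scope, and the trapping-region check is a
sampled numerical surrogate on rectangles, not an interval-arithmetic
enclosure.  Noise, non-sinusoidal forcing and coupled populations are
out of scope.
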