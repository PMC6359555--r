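---
title: "Path-dependent hybrid-Hamiltonian sampling: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-dependent hybrid-Hamiltonian sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmd)
```

## The method

`pathmd` implements an enhanced-sampling scheme in which Langevin dynamics on a
model potential is driven by a bias built from *history-dependent action-path
variables*, optionally reweighted toward experimental distance restraints.
The ingredients:

1. **Action-path increments.** Along a trajectory the per-atom increment
   `dL(t) = (p + dp) o dq` is accumulated each step (elementwise product of the
   updated momentum and the displacement). Its per-atom scalar sum is a running
   path coordinate `sigma_ik`; the elementwise form feeds the adaptive bias.

2. **Adaptive bias (re-evaluated every `tau1ik`).** For each of `n_r` parallel
   biases `i` and atom `k`, the increments are accumulated over a window of
   length `tau1ik = i * tau1`. At the window boundary a frozen gradient
   `g_ik = gamma'' * zeta * (window sum) / tau1ik` is drawn, with `zeta` a
   standard normal and `gamma'' = 1e-4` a fluctuation constant. The original
   formulation of this component mixes time-derivative and window-derivative
   notation in a way that is not directly implementable; the
   implemented reading -- the window-mean rate of the accumulated increment,
   scaled by `gamma''` and a fresh normal draw per (bias, atom, window) -- keeps
   its structure (fluctuation-scaled, history-dependent, re-evaluated every
   `tau1ik`) while being implementable and testable. Because `gamma''` is held
   constant, its formal derivative term vanishes.

3. **Path metadynamics (deposited every `tau2ik`).** Repulsive Gaussians of
   height `W = 0.1` kJ/mol and width `delta sigma` are deposited at the current
   `sigma_ik` every `tau2ik = i * tau2`. Their force
   `Phi = W sum_c (sigma - sigma_c)/dsigma^2 exp(-(sigma - sigma_c)^2 / (2 dsigma^2))`
   is mapped back to atoms through the chain vector `(p + dp)`. The hills are
   independent one-dimensional kernels per (bias, atom): a joint kernel over
   all coordinates would essentially never be revisited, while per-coordinate
   hills produce the intended "keep exploring" pressure along each path
   variable.

4. **Renormalization.** Both bias gradients are rescaled against the unbiased
   gradient and combined as
   `grad H_C = grad H_A (1 + alpha_md) + b_ab alpha' |grad H_A|/|b_ab| + b_sigma alpha' |grad H_A|/|b_sigma|`,
   with `alpha_md = eta_md beta_md (1 - xi)` and `alpha' = eta' beta' (1 - xi')`
   redrawn each step from independent uniforms. Norms are global (one scalar
   per term). A zero-norm term is omitted. The bias enters the equations of
   motion only as a force (`force = -grad H_C`); reported potential energies
   are always the unbiased `V`.

5. **Restraint reweighting.** A distance restraint (target `d0`, groups of
   candidate atoms with the minimum-distance pair realizing the restraint) does
   *not* add a restraint potential. Instead each renormalized bias term on a
   restrained atom is scaled by `cos(Xi) * sign(d12 - d0)`, where `cos(Xi)` is
   the cosine between the bias gradient on that atom and the signed restraint
   direction (`+q12` for the group-1 atom, `-q12` for the group-2 atom). With
   the force = -gradient convention this attracts the pair when `d12 > d0` and
   repels it when `d12 < d0`, while `|cos| <= 1` guarantees the reweighted term
   never exceeds the raw one. `sign(0) = 0`: a restraint at exact fulfillment
   contributes no bias that step.

### Sign conventions

The method's original formulation mixes force-level and gradient-level
objects. `pathmd`
resolves this by working entirely at gradient level: the sigma-bias gradient is
`b_sigma = -Phi (p + dp)`, so the applied force `+Phi (p + dp)` pushes the path
coordinate away from deposited hills (the documented behaviour: the history
bias prevents revisiting), and the restraint factor then yields attraction for
violated distance restraints, matching the documented behaviour that a
crosslink target `d0` below the current distance produces an attractive bias.
The exported `sigma_chain_rule()` returns the chain-rule contraction
`sum_i Phi_ik (p+dp)_k` as printed; the engine negates it.

Two further ambiguities are resolved behind flags. First, `delta_e`
(1000 kJ/mol) is exposed as a well-tempered scaling (each deposit multiplied by
`exp(-Phi_acc/delta_e)`); it is OFF by default because the reference treatment
lists `W` and `delta E` only as constants. Second, the minimal-probability
reference of the free-energy formula `dF = -kBT ln(P/Pmin)` makes all values
positive; landscape figures conventionally show basins as negative, so the
default reference is `Pmax` (`ref = "min"` reproduces the literal form).

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `n_r` | number of parallel biases | 5 | - |
| `tau1` | adaptive-bias base window | 1 | ps |
| `tau2` | hill-deposition base period | 2.5 | ps |
| `beta_md`, `beta_prime` | coupling magnitudes | 1e-4 | - |
| `eta_md`, `eta_prime` | fluctuation ranges | 1 | - |
| `gamma_pp` | adaptive-bias fluctuation constant | 1e-4 | - |
| `hill_w` | Gaussian hill height | 0.1 | kJ/mol |
| `hill_dsigma` | hill width (0 = automatic) | 0 | sigma units |
| `delta_e` | well-tempered scale | 1000 | kJ/mol |
| `dt` | timestep | 0.002 | ps |
| `friction` | Langevin gamma | 2 | 1/ps |

Ladders are `tau1ik = i tau1`, `tau2ik = i tau2` (e.g. `n_r = 5`, `tau1 = 1`,
`tau2 = 2.5` gives 1..5 ps and 2.5..12.5 ps), converted to whole step counts by
rounding. Units are fixed package-wide: kJ/mol, nm, ps, amu, radians;
`kB = 0.0083144621` kJ/mol/K (so 1 amu nm^2/ps^2 = 1 kJ/mol).

**Automatic hill width.** The width of the sigma-space Gaussians is the one
scale the reference treatment leaves fully open. `pathmd` sets it to 5% of the
sigma distance traversed during the first deposition window (floor `1e-8`).
Since `sigma` advances at roughly `kB T` per dof per ps, hills are spaced about
one window-travel apart; a width a few percent of that spacing gives each
deposit a brief, well-defined repulsive pulse rather than a quasi-constant
offset, and the renormalization makes the resulting force magnitude independent
of the width anyway (only its on/off structure matters).

**Coupling for desk-scale systems.** The reference couplings
(`beta ~ 1e-4 .. 2.5e-4`) are calibrated against the *global* gradient norm of
systems with ~1e5 degrees of freedom; that norm is roughly `sqrt(3N)` times a
per-atom force, so the per-particle bias fraction realized there is far above
1e-4. For the package's built-in single-particle and few-bead studies,
`study_bias_params()` uses `beta_prime = 0.2` (mean `alpha' = 0.1`): an order
of magnitude below one, respecting the method's validity condition that the
coupling factors stay well below unity so the underlying partition is only
weakly perturbed, while still producing a measurable effect on one particle.
With this setting the biased double-well runs hold a mean kinetic temperature
about 25% above the thermostat target -- the path bias on a one-dimensional
system acts mainly as a controlled energy input along the momentum direction,
which is also the mechanism of its acceleration (see limitations).

## Engine and numerical choices

* **BAOAB splitting** for the Langevin integrator (accurate configurational
  averages at moderate `dt`); `friction = 0` reduces exactly to velocity
  Verlet, and the thermostat draw is consumed regardless so toggling friction
  does not shift the random stream.
* **Named random streams.** One master seed derives independent child streams
  (thermostat, coupling `xi`, adaptive `zeta`, fixtures, initialisation) via a
  SplitMix64 hash, so switching the bias off cannot shift the thermostat
  noise: with `beta_md = beta_prime = 0` a biased run is bit-identical to the
  plain engine (tested over 1e5 steps).
* The bias gradient is computed once per step from the state at the start of
  the step and held fixed across the BAOAB substeps.
* **Principal components** (optional, `use_pca`): per atom block, the
  covariance of the bias vectors over a `pca_window` (default `n_r * tau1`) is
  diagonalized; the unit eigenvector of the smallest eigenvalue (slowest mode)
  replaces the raw direction, magnitude preserved, sign fixed by making the
  first nonzero component positive, exact ties broken toward the lowest axis.
  A rank-deficient covariance falls back to the raw bias.
* **Transition detection** uses a dwell-confirmed (hysteresis) scheme: a
  crossing counts only after the series stays in the destination region for a
  configurable dwell (default 1 ps), since the bare region definition would
  double-count noise spikes.
* **Degenerate inputs**: coincident restrained atoms skip the restraint for
  that step; empty histogram bins are masked; a constant decay fitted with one
  mode drives the rate to zero; zero transitions give an explicit
  "no transitions" result rather than NaN.
* Multi-exponential fits use variable projection (linear amplitudes, numerical
  optimization over log rates) with ten seeded multi-starts.

## Model systems and what the fixtures emulate

`double_well_1d/2d` (quartic, barrier `a = 5` kJ/mol, wells at `+-0.5` nm),
the Mueller-Brown surface, a separable periodic two-angle surface (3 x 2
basins; a surrogate for a backbone-dihedral landscape -- the surface
coefficients are package constants, not a force field), and a restrainable
bead chain (harmonic bonds, `r0 = 0.38` nm as a coarse Calpha spacing, purely
repulsive WCA nonbonded term so that compaction is driven only by restraints
or bias). The restraint-fixture generator emulates the *shape* of
crosslink/NOE restraint sets -- groups of candidate atoms for one residue, a
single atom for the other, a shared target such as `d0 = 0.75` nm -- on beads
separated by at least three bonds. These synthetic tables reproduce the format
and statistics of experimental restraint inputs, not any particular protein's
restraint list.

Because the toy systems have no solvent, no force field, and O(10) degrees of
freedom, passing the built-in studies shows that the bias machinery, its
renormalization, and the restraint reweighting behave as specified -- it does
not certify folding behaviour or restraint fulfillment levels on proteins.

## Built-in studies (problem sizes)

* *Boltzmann recovery*: 1e7 unbiased steps (20 ns) for well populations with a
  batch-means standard error, plus 1e6 independent rejection draws for the
  per-bin free-energy comparison against the bin-integrated Boltzmann weight.
* *Acceleration*: 20 paired runs of 6e5 steps; transition times from
  dwell-confirmed crossings; paired one-sided t-test on log times. Typical
  result: every pair accelerated, mean rho about 1.3.
* *Restraint steering*: 20 paired biased runs of 2e5 steps on a 12-bead chain
  with one `d0 = 0.75` nm end-to-end restraint; the restrained runs reduce the
  time-averaged violation `Delta = d12 - d0` over the last quarter of each run
  by several standard errors.

These sizes were chosen so each study resolves its effect several standard
errors above noise while remaining desk-scale.

## Known limitations

* On few-dof systems the path variables contain little conformational
  information; the bias acts largely as a stochastic energy input along the
  momentum direction, and acceleration comes with measurable kinetic heating
  (documented above). On high-dimensional systems the same construction can
  concentrate on slow modes; that regime is out of scope here.
* The sigma coordinates grow monotonically for thermalized systems, so the
  hill history acts as a treadmill pressure rather than a conventional
  free-energy filler; no free-energy reconstruction from hill sums is
  provided (landscapes come from histograms).
* Restraint fulfillment statistics on the bead chain are qualitative
  properties (directional steering), not quantitative predictions of
  experimental fulfillment fractions.
* No constraints, barostat, neighbour lists, force-field input, or solvent
  models: systems are intentionally tiny.
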