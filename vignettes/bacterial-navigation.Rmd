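---
title: "Modeling bacterial navigation in chemical and non-chemical gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bacterial navigation in chemical and non-chemical gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runtumble)
```

## The model

*E. coli* navigates chemical gradients, pH, and temperature with one
signaling pathway: transmembrane chemoreceptor clusters (mainly Tar and Tsr)
modulate the autophosphorylation of the kinase CheA; phosphorylated CheY
binds the flagellar motors and raises the probability of clockwise rotation,
which triggers tumbles. Methylation of the receptors (CheR/CheB) slowly
restores the kinase activity to a set point, providing the short-term memory
that lets a swimming cell compare "now" against "a few seconds ago".

`runtumble` implements this pathway at three levels and connects them in
closed form.

**Receptor cluster (MWC).** The cluster is two-state with activity

$$a = \frac{1}{1 + e^{f}}, \qquad
  f = N\left[\alpha(T)\,(m_0 - m) + f_{\text{signal}}(S)\right],$$

where $N$ is the cooperativity, $m$ the average methylation level, and
$f_{\text{signal}}$ the signal-dependent free energy (in $k_BT$). The factor
$N$ is carried *inside* $f$ by every free-energy builder in this package —
a single convention that avoids double-counting the cooperativity. The
signal terms are log-ratios of saturation factors:

* chemoattractant: $\ln\!\frac{1 + L/K_I}{1 + L/K_A}$ with $K_I < K_A$;
* pH, per receptor type: $\ln\!\frac{1 + 10^{\,\mathrm{pH} - pK_I}}
  {1 + 10^{\,\mathrm{pH} - pK_A}}$, weighted by the Tar and Tsr fractions
  $f_a, f_s$;
* temperature: the methylation coefficient becomes
  $\alpha(T) = \alpha_0 + \alpha_1 (T - T_0)$.

Methylation adapts as $\dot m = k_m (a_0 - a)$ with $k_m$ normalized so the
linearized activity relaxation time is exactly `tau_m`.

**Motor.** The clockwise bias is an ultrasensitive Hill function
$B(a) = a^H / (a^H + K(T)^H)$; tumbles are entered at rate
$z_m = B/\tau_t$, and rotational diffusion adds a direction-decorrelation
rate $z_{rot} = 2 D_r$ in the 1D projection.

**Population.** In a closed 1D chamber the zero-flux steady state of the
two-direction run-and-tumble process is

$$P_s(x) \;\propto\; \frac{1}{v(x)}
  \exp\!\left(-\tfrac12 \int^x \frac{\Delta z(x')}{v(x')}\,dx'\right),$$

where $\Delta z = z_+ - z_-$ is the tumbling-rate difference between right-
and left-movers. The factor $\tfrac12$ arises because a tumble resamples the
direction uniformly, so only half of tumbles reverse it. The methylation
memory of the two sub-populations gives

$$\Delta a(x) = -\,\frac{2\,v\,a_0(1-a_0)}{z_{\mathrm{eff}} + 1/\tau_m}
  \left.\frac{\partial f}{\partial x}\right|_{m = m_{ss}(x)},$$

and $\Delta z = (dz_m/da)|_{a_0}\,\Delta a$. For a single attractant at
constant speed this collapses to

$$P_s(x) \propto \left[\frac{1 + L(x)/K_I}{1 + L(x)/K_A}\right]^{\chi},
\qquad
\chi = \underbrace{N a_0 (1 - a_0)}_{\text{receptor gain}}
      \times \underbrace{\frac{H (1 - B_0)}{a_0}}_{\text{motor gain}}
      \times \underbrace{\frac{z_m}{z_m + 2 D_r + 1/\tau_m}}_{\text{damping}}.$$

Two derivation choices deserve comment, because the package pins both with
permanent tests rather than trusting the algebra:

* The **constant in $\Delta a$** (the factor 2, and the $1/\tau_m$ term in
  the denominator). The $1/\tau_m$ term is the linearized adaptation rate;
  the textbook adiabatic result drops it, but at realistic run statistics
  ($z_{\mathrm{eff}}\tau_m \approx 15$) it is a 6–7% effect that the
  stochastic simulator resolves clearly, so the package keeps it.
  `test-acceptance.R` requires the general solver to reproduce the
  closed form with this $\chi$ to $10^{-8}$, and the agent-based simulation
  to match the analytic density (KL < 0.01) in every scenario family.
* **Rotational diffusion** enters the simulator as a Poisson direction
  reversal at rate $D_r$, i.e. a decorrelation rate of $2D_r$, matching the
  $z_{rot} = 2D_r$ used in $\chi$. The same factor convention on both sides
  is what the simulator-vs-analytic test actually verifies.

## Precision sensing

**pH.** Tar responds to a pH drop as to an attractant, Tsr oppositely. The
package encodes this as $pK_I > pK_A$ for Tar (its free-energy term
*decreases* with pH, so Tar-only populations accumulate at low pH — their
effective potential $U = -\ln P_s$ rises with pH) and $pK_I < pK_A$ for
Tsr. Their balance gives wild-type cells an interior preferred pH where the
effective potential has a well. The preferred pH moves log-linearly with
the Tar/Tsr ratio; the slope per decade is the tunability `eta`.

Three dissociation-constant regimes ship with `ph_regime()`:

| regime     | where the receptors operate                     | eta   |
|------------|--------------------------------------------------|-------|
| `subdued`  | both types in far exponential tails of titration | ~0.5  |
| `balanced` | Tar in its tail vs a softly saturating Tsr term  | ~1.0  |
| `tunable`  | all four pKs close to the preferred pH           | ~1.9  |

The regimes are package choices reproducing the qualitative trichotomy, not
measured constants. In the `balanced` regime the stationary distribution is
also the sharpest (smallest standard deviation on the pH axis): accuracy is
bought with moderate tunability.

**Temperature.** A single receptor type (Tar) inverts its thermal response
as methylation crosses a critical level: under the linear
$\alpha(T)$ form the critical methylation is $m_c = m_0$, and the critical
temperature $T_c$ solves $m_{ss}(T_c) = m_c$, equivalently $a_0(T_c) = 1/2$.
Below $T_c$ the receptor is a warm sensor, above it a cold sensor, so cells
accumulate around $T_c$ — provided $\mathrm{sign}(\alpha_1) =
\mathrm{sign}(da_0/dT)$. Since the adapted activity is observed to
*increase* with temperature, the package defaults to $\alpha_1 > 0$
(`dalpha_dT = 0.2` kT/°C/methyl); the opposite sign would make $T_c$ a
density *minimum*. $T_c$ depends only on receptor kinetics: motor
parameters cannot move it.

Two further channels act on thermotaxis. A temperature-dependent swimming
speed contributes the local $1/v(x)$ factor, dragging the accumulation
below $T_c$ when $dv/dT > 0$ — and it is the *only* channel left in
receptor-less mutants, whose density is exactly $\propto 1/v$. A
temperature-dependent motor threshold $K(T) = K_{ref}(1 + \kappa (T-T_0))$
enters only through $\chi(T)$ and barely moves the distribution when the
motor operates at a low clockwise bias — the same compensation that keeps
the motor in its sensitive range.

**Opposing gradients.** For Tar-only cells in a rising temperature gradient
with a falling attractant profile, the adapted methylation absorbs the local
ligand free energy, so the thermal drift term becomes
$(\alpha'/\alpha)\,[F_0(T) - N f_L(L(x))]\,T'(x)$ plus the usual chemotactic
term. A uniform attractant background already lowers the accumulation
temperature; steepening the opposing gradient pushes it lower still,
monotonically. At $L \equiv 0$ the machinery reduces exactly (to $10^{-10}$)
to the pure thermotaxis solution.

## Parameters and defaults

The quantitative defaults are literature-standard orders of magnitude,
chosen once and documented here; every one is configurable.

| parameter | default | meaning |
|---|---|---|
| `N` | 6 | receptor cooperativity (MeAsp/Tar cluster) |
| `alpha0` | 2 kT/methyl | methylation free energy at `T0` |
| `m0` | 1 | reference methylation; also `m_c` |
| `a0_ref` | 0.5 | adapted activity at `T0` |
| `tau_m` | 10 s | activity relaxation time |
| `KI`, `KA` | 18, 3000 µM | MeAsp dissociation constants |
| `dalpha_dT` | +0.2 kT/°C/methyl | thermal slope of `alpha` |
| `da0_dT` | +0.01 /°C | thermal slope of the set point |
| `T0` | 25 °C | reference temperature (so `T_c` = 25 °C) |
| `H` | 10 | motor Hill coefficient |
| `K_ref` | 0.605 | motor threshold (adapted CW bias ≈ 0.13) |
| `tau_tumble` | 0.1 s | tumble duration |
| `D_r` | 0.062 /s | rotational diffusion |
| `v0` | 20 µm/s | swimming speed |

`K_ref` is set where $\chi$ is stationary with respect to $K$ — the adapted
clockwise bias then is a realistic ~0.13 (about one tumble per second), and
the distribution becomes insensitive to the motor-threshold temperature
slope $\kappa$, which is what the thermal-robustness analysis requires. The
resulting population sensitivity is $\chi \approx 22$.

Scenario fixtures: a 400 µm chemotaxis channel with a 0→1 µM linear
gradient (density ratio ≈ 3 across the chamber, comfortably inside the
linear-response regime); an 800 µm pH channel spanning pH 5.8–8.2; a
500 µm thermal channel spanning 20–30 °C around $T_c = 25$; and the same
thermal channel with opposing attractant gradients of 0, 3, 5, 6 µM/cm at
a fixed midpoint concentration of 0.2 µM.

## The stochastic simulator and what agreement shows

The agent-based model advances `n_cells` independent cells with Euler
steps. Each cell's internal state is its deviation free energy
$g = f - F_0(x)$, where $F_0(x) = \ln(1/a_0(x) - 1)$ is the locally
adapted value, so $a = 1/(1+e^{F_0(x)+g})$ and $g = 0$ is the adapted
state. Per step: methylation kinetics relax $g$ toward zero at the
adaptation rate; transport through the gradient drives it by the perceived
signal change ($\partial f/\partial x$ at fixed methylation); the cell
tumbles with probability $z_m\,dt$ (new direction uniform), reverses with
probability $D_r\,dt$ (rotational diffusion), and advects with reflecting
walls. For chemical and pH signals this is an exact change of variables
from methylation dynamics. For thermal signals it encodes a modeling
choice stated explicitly here: the spatial variation of the adapted
activity $a_0(T(x))$ *re-references the cell's baseline adiabatically*
rather than acting as a perceived stimulus. The alternative reading — the
methylation level chasing the moving set point $a_0(T(x))$ — adds a drift
term $\propto dF_0/dT$ that, for the linear $\alpha(T)$ form, never
changes sign: it would push cells warm-ward everywhere and displace the
accumulation point from $T_c$ to $T_c + \alpha/\alpha_1$ (about +10 °C at
the defaults) regardless of how small $da_0/dT$ is, abolishing thermal
precision sensing altogether. The quasi-static treatment is the one under
which the warm/cold sensor inversion at $T_c$ translates into accumulation
at $T_c$, and it is adopted consistently in both the simulator and the
closed-form solver, so the simulator remains a genuine independent check
of the population-level derivation. The step
size must satisfy $dt \cdot z_{max} < 0.05$ with
$z_{max} = 1/\tau_t + 2D_r$ (`dt = 0.004` s by default). Cells start
uniformly with locally adapted methylation; the default horizon is 450 s
with a 200 s burn-in ($\geq 10\,\tau_m$, and longer than the slowest
diffusive relaxation mode of the default chambers). Histograms are
time-and-ensemble averages over the sampling window; stationarity is
declared when the two halves of the window agree within twice the
window-internal noise (bin occupancies are time-correlated, so Poisson
noise would be too optimistic — the noise floor is estimated from the last
two quarters instead).

Problem sizes used by the shipped tests — $10^4$ cells, a few hundred
simulated seconds per scenario, 64 histogram bins — were chosen so that
Monte-Carlo noise sits well below the 1% KL tolerance of the
analytic-vs-simulated comparison.

The closed form is a shallow-gradient (linear-response) result, and the
simulator shows exactly where that matters. Any density feature narrower
than the methylation memory length $\sqrt{D_{\mathrm{eff}}\,\tau_m}$
(≈ 50 µm at the defaults) is smeared in the simulation: the pH
accumulation well, for instance, matches the closed form only when the pH
gradient is gentle enough that the well is several memory lengths wide
(the shipped cross-check uses 1 pH unit per mm). Likewise, within a memory
length of a reflecting wall, freshly reflected cells carry
direction-mismatched memory and the simulated profile flattens relative to
the bulk closed form. The package therefore fits $\chi$ on simulated
histograms with a wall margin of $2\sqrt{D_{\mathrm{eff}}\,\tau_m}$
excluded (`trim` argument of `fit_chi()`); the interior slope then
recovers the analytic $\chi$ to within a few percent. The divergence
metrics, by contrast, are computed over the full chamber — the boundary
layers are part of the physics and small enough to pass the KL tolerance.

What passing simulator-vs-analytic tests does *not* show: the synthetic
scenarios have smooth one-dimensional profiles, no cell growth, no
consumption or secretion feedback, no hydrodynamics, and a 1D projection of
reorientation. Agreement validates the population-level closed form given
the single-cell model; it does not validate the single-cell model against
real cells.

## Numerical choices

* Exponent integrals use cumulative trapezoids in the log domain;
  normalization subtracts the maximum before exponentiating, so steep
  profiles cannot overflow. Densities integrate to 1 within $10^{-8}$
  (trapezoid rule); halving the default grid spacing moves them by less
  than $10^{-6}$ sup-norm.
* `adapted_methylation` evaluates the closed form and, by default,
  cross-checks a bracketed root solve to $10^{-10}$.
* `preferred_point` locates zero crossings of $d\ln P_s/dx$ (sensing drift
  minus the local speed term) by grid bracketing plus bisection; multiple
  interior maxima are reported with a warning, and a drift that never
  reverses is reported as boundary accumulation rather than a root.
* Degenerate configurations fail loudly: adapted activity or motor
  threshold leaving $(0,1)$, non-positive speeds, a critical-temperature
  search with no sign change, a constant chemotaxis kernel in `fit_chi`.
* The simulator draws one uniform per cell-step; tumble and rotational
  reversal are treated as mutually exclusive within a step (their
  coincidence has probability $O(dt^2)$). Identical seeds reproduce runs
  bit-for-bit.

## Known limitations

* All results are for closed (zero-flux) chambers; open geometries with
  through-flux are a different boundary-value problem.
* Receptor-type-specific methylation kinetics are averaged into a single
  `m`; only the total cluster activity is modeled.
* The $\Delta a$ expression is first order in the gradient; fits in very
  steep gradients under-read $\chi$ (this is also why the fitted
  population sensitivity falls with gradient steepness in closed chambers).
* Near chamber walls the bulk closed form is blurred over a memory length;
  see above.
* The tunability trichotomy depends on where the working pH window sits
  relative to the pK values; the shipped regimes illustrate the three
  qualitative classes rather than measured receptor constants.
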