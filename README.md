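# runtumble

Steady-state population distributions for bacterial taxis, computed from
intracellular signaling.

*E. coli* uses one signaling pathway — chemoreceptor clusters, the kinase
CheA/CheY, methylation-based adaptation, and ultrasensitive flagellar
motors — to climb chemical gradients and to home in on intermediate
preferred levels of pH and temperature (precision sensing). `runtumble`
implements a multiscale model of this system for closed one-dimensional
chambers and is aimed at quantitative microbiologists and biophysicists who
want to connect molecular parameters (receptor cooperativity, dissociation
constants, adaptation time, motor Hill coefficient) to population-level
observables (density profiles, preferred set points, accumulation
sharpness).

## The model in one screen

Receptor-cluster activity follows the Monod–Wyman–Changeux two-state form
`a = 1/(1 + e^f)` with free energy
`f = N[α(T)(m0 − m) + f_signal(S)]`, and methylation `m` slowly restores
`a` to a set point `a0` (timescale `tau_m`). The motor's clockwise bias is
`B(a) = a^H/(a^H + K^H)`; tumbles occur at rate `z_m = B/τ_t`, rotational
diffusion decorrelates direction at `2·D_r`. For a closed chamber the
zero-flux steady state is

    P_s(x) ∝ v(x)⁻¹ · exp( −½ ∫ Δz(x')/v(x') dx' )

where `Δz` is the tumbling-rate difference between right- and left-moving
cells carried by their methylation memory. For a single attractant this
collapses to `P_s ∝ [(1 + L/KI)/(1 + L/KA)]^χ` with the population
sensitivity

    χ = N·a0(1−a0) × H(1−B0)/a0 × z_m/(z_m + 2D_r + 1/τ_m).

The same machinery, with the appropriate free-energy term, yields pH taxis
(Tar/Tsr push–pull, tunable preferred pH), thermotaxis (warm→cold sensor
inversion at a critical temperature `T_c`), and navigation under opposing
chemical and thermal gradients. A stochastic agent-based run-and-tumble
simulator with per-cell methylation dynamics provides an independent check
of every analytic profile.

## Worked example

```r
library(runtumble)

fx  <- fixture_chemotaxis()        # 0 -> 1 uM linear MeAsp gradient, 400 um
chi <- sensitivity_chi(fx$receptor, fx$motor)
chi
#> Effective population sensitivity
#>   chi           : 22.26
#>   receptor gain : 1.5
#>   motor gain    : 17.41
#>   damping       : 0.8524

prof <- steady_state_density(fx$env, fx$receptor, fx$motor)
prof
#> Steady-state density profile: 513 grid points on [0, 400]
#>   peak at x = 400; density range [0.00129, 0.00426] per um
```

The population sensitivity χ ≈ 22 multiplies the log of the receptor
occupancy kernel: cells pile up at the high-attractant wall with a ~3.3-fold
density contrast across the chamber. Its three factors say where the gain
comes from: receptor cooperativity (1.5), motor ultrasensitivity (17.4),
and a mild loss to rotational diffusion and finite adaptation (0.85).

Precision sensing, in two lines each:

```r
ft <- fixture_thermo()             # 20 -> 30 degC over 500 um
preferred_point(ft$env, ft$receptor, ft$motor)$signal
#> [1] 25       # accumulation exactly at the critical temperature

fp <- fixture_ph()                 # pH 5.8 -> 8.2, wild-type Tar/Tsr
preferred_point(fp$env, fp$receptor, fp$motor)$signal
#> [1] 7.05     # interior preferred pH from the Tar/Tsr push-pull
```

And the independent stochastic check:

```r
sim <- simulate_population(fx$env, fx$receptor, fx$motor,
                           sim_config(seed = 1))
an  <- steady_state_density(fx$env, fx$receptor, fx$motor,
                            grid = sim$profile$x)
compare_profiles(sim$profile, an)$kl
#> [1] 0.00121   # 10^4 cells agree with the closed form to KL ~ 1e-3
```

A command-line front end ships in `inst/scripts/runtumble`
(`steady-state`, `simulate`, `scan`, `fixtures` subcommands over YAML
configs; examples in `inst/extdata/`). The methods vignette
(`vignettes/bacterial-navigation.Rmd`) documents the model, parameter
defaults, and numerical choices.

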