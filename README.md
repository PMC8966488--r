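# plastinorm

Evolution of a breeding-date reaction norm under hard selection with a cost
of plasticity — analytic selection gradients, equilibrium solvers, and an
individual-based validation simulator.

## The problem

In many birds and other seasonal breeders, well-nourished individuals breed
earlier *and* raise more offspring. Nutritional condition is then a
confounder of selection estimates on breeding date, and — less obviously —
it reshapes where the mean breeding date and the mean plastic response
(reaction-norm slope) settle at evolutionary equilibrium. This package
implements the quantitative-genetic model behind those results for
theoreticians and empiricists who want to compute, rather than eyeball, the
equilibria.

Breeding date follows a linear reaction norm on nutrition `n ~ N(0, σn²)`:

    y = i + b·n,    i = a_i + e_i,    b = a_b + e_b

with Gaussian breeding values and environmental deviations. Fitness is

    W = exp( α·n − (θ − y)² / (2ωy²) − b² / (2ωb²) ),    θ = A + B·n

combining a direct nutrition effect (α), stabilizing selection around a
nutrition-dependent optimum (width ωy²), and a direct cost of plasticity
(width ωb²). Because α and the environment-specific mismatch change mean
*absolute* fitness, environments contribute unequally to the next
generation (hard selection): the per-environment responses `Δμ(n) = Gβ(n)`
are averaged with weights `W̄(n)/W̄ · f(n)`. The package provides:

* exact closed-form `W̄(n)`, selection gradients, and fitness-weighted total
  responses (`env_mean_fitness()`, `selection_gradient_*()`,
  `total_response()`);
* a numeric equilibrium solver and four closed-form approximations,
  including the small-slope-variance cubic and the weak-mismatch forms
  (`solve_equilibrium_numeric()`, `approx_slope_ssv()`, ...);
* a vectorized individual-based Wright–Fisher simulator with
  infinitesimal-model inheritance (`run_simulation()`,
  `sweep_simulation()`) and experiment drivers (`run_figure3()`,
  `run_alpha_sweep()`, `run_price_recovery()`).

Headline model behavior, all reproduced by the package: plasticity evolves
*hypoplastic* (`B ≤ μb* ≤ 0`), the mean breeding date is displaced *before*
the optimum when α > 0, the equilibrium slope is non-monotone in B (maximal
at intermediate steepness), and with the slope fixed at −1 under a flat
optimum the mean breeding date exceeds the optimum by exactly `σn²·α`.

## Worked example

```r
library(plastinorm)

p <- model_params()        # σi² = σb² = σn² = α = 1, A = 0, B = −1, ω² = 20
solve_equilibrium_numeric(p)
#> Equilibrium (numeric_full): mu_i* = -0.51158993, mu_b* = -0.44975319
#>   converged: TRUE, residual 2.03e-18, 1114 iterations

approx_slope_ssv(p)        # small-slope-variance cubic
#> [1] -0.4846656
approx_slope_wm_ssv(p)     # weak mismatch + small slope variance = -20/41
#> [1] -0.4878049

res <- run_simulation(p, sim_config(pop_size = 2000, generations = 3000,
                                    window = 1500, seed = 5))
res
#> Simulation (N = 2000, 3000 generations, window 1500):
#>   mu_i = -0.5191 (MC-SE 0.0207)
#>   mu_b = -0.4575 (MC-SE 0.0085)
```

Reading the numbers: the optimum slope is −1 but the evolved mean slope is
only ≈ −0.45 (hypoplasticity: the cost of plasticity and hard selection
both bite), and the mean breeding date sits ≈ 0.51 days *before* the
optimum of the average environment. The simulation lands on the exact
numeric equilibrium within its Monte-Carlo error; the cubic closed form is
close but visibly approximate at unit slope variance. The fixed-slope
displacement check:

```r
run_price_recovery(seed = 2)
#> displacement: 0.9720 (MC-SE 0.0179), analytic 1.0000, z = -1.56
```

A thin command-line wrapper with the same functionality ships at
`inst/cli/plastinorm` (subcommands `equilibrium`, `simulate`, `sweep`,
`figure3`, `alpha-sweep`, `price-recovery`; CSV output via
`write_results()`).

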