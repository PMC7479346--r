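# fraclv

Simulation and stability analysis of **time-fractional Lotka-Volterra
models with constant-effort harvesting**, for theoretical ecologists
and modellers studying how *memory* — a Caputo time derivative of
order $\alpha \in (0,1]$ — and *harvesting pressure* shape the
stability of predator-prey systems.

Two models are covered, in dimensionless form:

**Two species** (prey $x$, predator $y$, Holling type II response):

$$ D^\alpha x = \rho x(1-x) - xy - \varepsilon_1 x, \qquad
   D^\alpha y = \frac{\psi x y}{1+\phi x} - y - \varepsilon_2 y $$

**Three species** (one prey, two predators hunting cooperatively —
mutualistic predation):

$$ D^\alpha x = \rho x(1-x) - x(y + \eta z + yz) - \varepsilon_1 x,\quad
   D^\alpha y = \frac{\psi x y(1+z)}{1+\phi x} - \varepsilon_2 y,\quad
   D^\alpha z = \frac{\beta x z(\eta+y)}{1+\phi_1 x} - \varepsilon_3 z $$

where $D^\alpha$ is the Caputo derivative with power-law memory kernel
$w(t) = t^{-\alpha}/\Gamma(1-\alpha)$, the $\varepsilon_i$ are scaled
constant-effort harvest rates, and the three-species couplings
$(1+z)$, $(\eta+y)$, $yz$ encode each predator boosting the other's
intake.  The package provides:

* **Fractional solver** — the Adams-Bashforth-Moulton
  predictor-corrector for Caputo initial-value problems
  (`solve_fde()`, full memory, compiled history sums, startup
  refinement for the $t^\alpha$ origin singularity), the
  Mittag-Leffler function (`mittag_leffler()`), and a classical
  adaptive reference integrator (`reference_solve()`).
* **Equilibria** — all stationary points in closed form with
  feasibility flags and residual checks (`equilibria2()`,
  `equilibria3()`), analytic Jacobians (`jacobian()`).
* **Fractional stability** — the Matignon sector condition
  $|\arg\lambda| > \alpha\pi/2$ (`matignon_check()`), critical order
  $\alpha^* = \min(1, \tfrac{2}{\pi}\min|\arg\lambda|)$
  (`critical_alpha()`), Routh-Hurwitz and cubic-discriminant
  machinery, per-equilibrium classification with closed-form condition
  cross-checks (`classify_equilibrium()`), and the oscillation
  criterion for the co-existence point (`check_condition_15()`).
* **Experiments** — scenario runner, damping/settling metrics, sweeps
  over the fractional order and the harvest efforts, and benchmark
  scenario reproduction (`run_scenario()`, `alpha_sweep()`,
  `harvest_sweep()`, `reproduce_figure()`), plus a thin command-line
  front end (`inst/cli/fraclv.R`).

## Worked example

```r
library(fraclv)

## harvested two-species benchmark
p  <- params2(rho = 1, psi = 15, phi = 2, eps1 = 0.4, eps2 = 1)
eq <- equilibria2(p)
eq$E3
#> E3: (0.18181818, 0.41818182)  feasible: TRUE  [co-existence]

classify_equilibrium(p, alpha = 0.9, eq$E3)
#> E3 @ alpha = 0.9: stable (critical order 1)
#>   eigenvalues: -0.090909+0.777862i, -0.090909-0.777862i
#>   closed-form conditions: omega_positive=TRUE, omega_below_prey_only=TRUE
#>   agreement with eigenvalue verdict: TRUE

sw <- alpha_sweep(scenario_config(p, alpha = c(1, 0.8), x0 = c(0.2, 0.25),
                                  settings = solver_settings(h = 0.01,
                                                             t_end = 100)))
as.data.frame(sw)
#>   alpha tail_amplitude settling_time extinct target
#> 1   1.0       0.002958         40.62   FALSE     E3
#> 2   0.8       0.000309          9.02   FALSE     E3
```

The co-existence point sits at prey density $\omega = 2/11$ with
predator density $\rho(1-\omega)-\varepsilon_1 \approx 0.418$; its
eigenvalues are a weakly damped complex pair in the left half plane,
so it is stable at every order (critical order 1).  Reducing the
order from 1 to 0.8 shrinks the residual oscillation amplitude over
$t\in[50,100]$ by an order of magnitude and cuts the 1%-band settling
time from 40.6 to 9.0 time units: memory damps the transient.

The three-species benchmark makes memory a *requirement*: its feasible
co-existence point has critical order

```r
p3 <- fig_fixture("fig3")$params
classify_equilibrium(p3, 0.9, equilibria3(p3)$E5)$critical_alpha
#> [1] 0.9739859
```

— unstable under the ordinary derivative, stable for any
$\alpha < 0.974$.  And harvesting stabilizes below its threshold:
prey harvest $\varepsilon_1 > \rho$ drives the system to the
extinction point, while moderate harvest damps the oscillations (see
`harvest_sweep()` and `reproduce_figure("fig4", ...)`).

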