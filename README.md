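# quadgait

Work-minimizing trajectory optimization of planar quadrupedal walking.

Cursorial quadrupeds walk with a stereotyped four-beat ("singlefoot")
pattern: individual footfalls, alternating double and triple support, duty
factors near 0.5, and double-hump vertical ground reaction forces. `quadgait`
tests which definition of mechanical work *predicts* that pattern when
minimized. The model is a planar rigid trunk (mass `m`, pitch inertia set by
the Murphy number `4I/(m·GAD²)`) carried on four massless telescoping limbs
that push along the foot-to-attachment axis, with contact decided by
complementarity (force only while a limb is no longer than its maximum
length). For a periodic, symmetric stride at fixed speed and stride length,
the package minimizes one of three per-stride costs:

* **Net COM Work** `NCW = ∫ [F_net · v_com]⁺ dt` — positive fluctuations of
  COM kinetic + gravitational potential energy;
* **Individual Limbs COM Work** `ILCW = Σ_i ∫ [F_i · v_com]⁺ dt`;
* **Limb Extension Work** `LEW = Σ_i ∫ [F_i · l̇_i]⁺ dt` — positive work of
  telescoping each limb strut,

plus a small force-rate regularization `c1 Σ_i ∫ (dF_i/dt')² dt'`
(`c1 = 3·10⁻⁵`). Gaits are transcribed by direct collocation
(Hermite–Simpson) over the half cycle with slack-variable smoothing of the
positive parts and relaxed complementarity, and solved by a multi-start
augmented-Lagrangian method with exact-Hessian Newton refinement and a
Gauss–Newton feasibility polish (see the methods vignette,
`vignettes/quadgait-methods.Rmd`). Post-processing produces work breakdowns,
Cavagna percent recovery, gait diagrams, duty factors, footfall-pattern
classification and power traces. A Warmblood horse preset
(`l_H = 1.38 m`, COM at 0.57 GAD from the hips, Murphy number 0.82,
`U' = 0.43`, `D' = 1.34`) and conservative toy systems (pendula, rolling
ball, passive four-bar vaulting) used as analytic oracles ship with the
package. Everything is nondimensional internally (`m = g = l_H = 1`), so
forces are in body weights and works in `m·g·l_H` per stride.

## Worked example

Optimize Limb Extension Work for the distributed-mass horse at a walk
(10 restarts; a few minutes on one CPU):

```r
library(quadgait)
hp <- horse_preset("distributed_mass")
spec <- transcription_spec(n_nodes = 16, c1 = hp$c1)
ms <- multistart(12, base_seed = 100, hp$body, hp$task, "lew", spec)
print(ms$best$works)
#> Work breakdown (m g l_H per stride)
#>   NCW  0.0230   NSW 0.0231
#>   ILCW 0.1377   LEW 0.1452
#>   Percent recovery 68.5%   force-rate penalty 0.00025
gd <- gait_diagram(ms$best$trajectory)
round(gd$phase, 2)
#>   LH   RH   LF   RF
#> 0.00 0.50 0.10 0.60
round(gd$duty, 2)
#>   LH   RH   LF   RF
#> 0.70 0.70 0.73 0.73
```

The LEW optimum is a four-beat walk: every limb touches down individually
(here with lateral fore–hind couplets at a phase offset of 0.10) with duty
factors near 0.7 and positive limb work concentrated around transfers of
support. The work-minimizing landscape holds several near-tied four-beat
optima that differ in phase offset (about 0.1–0.25) and force-profile shape;
which one a desk-scale restart bundle selects varies with the seeds, while
the LEW value itself is stable (0.11–0.15 m g l_H across bundles, against
roughly 0.25–0.32 for the gaits that minimize NCW or ILCW). Minimizing Net
COM Work
instead returns a compliant gait with duty factors near one and NCW within a
few thousandths of zero (percent recovery 96–100), and minimizing Individual
Limbs COM Work returns alternating single-stance vaulting. Cross-evaluating
the three solutions shows each objective is smallest in its own optimum
(each column minimized on the diagonal of `work_table()`).

A thin command-line wrapper is installed at
`system.file("cli", "quadgait.R", package = "quadgait")` with `solve` and
`validate` subcommands.

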