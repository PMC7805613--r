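# neuromc

Morphological computation across a neuro-muscular control hierarchy.

When a human arm makes a pointing movement or swings an elastic rod, part of
the "control work" is not done by neurons at all: muscle viscoelasticity,
limb inertia and the implement's own dynamics shape the movement by
themselves. `neuromc` quantifies this contribution — *morphological
computation* (MC) — at every level of a simulated motor-control hierarchy,
for researchers in computational motor control and bio-inspired robotics who
want the contribution of each control layer in actual units of bits.

The package contains:

* a layered neuro-musculoskeletal model of planar arm movements: two-link
  rigid-body dynamics, six Hill-type muscle–tendon units (four-element:
  contractile, parallel-elastic, tendon, serial damping), Hatze-type
  activation dynamics, an equilibrium-point controller with delayed
  stretch-reflex feedback (10 ms), a sinusoidal central pattern generator,
  and a hand-held vibrating rod tuned to 3.8 Hz resonance — integrated as
  one delay-differential system (`simulate_arm()`, `run_point_to_point()`,
  `run_oscillation()`);
* the discrete MC estimator: with world state `W`, action `A` and next
  world state `W'`,

  ```
  MC_W = Σ p(w', w, a) · log2 [ p(w'|w, a) / p(w'|a) ]
  ```

  a Kullback–Leibler divergence equal to the conditional mutual information
  I(W'; W | A), estimated by frequency counts over consecutive-sample
  triples (`discretize()`, `estimate_joint()`, `mc_w()`,
  `mc_w_state_dependent()`), with *selected* (one level as `A`, joint
  angles as `W`) and *accumulated* (clean cut through the hierarchy) level
  splits (`build_level_split()`, `mc_by_level()`);
* discrete Markov benchmarks with analytically known MC for estimator
  validation (`generate_discrete_benchmark()`, `kernel_mc()`);
* repeated-measures statistics over hierarchy levels: Shapiro–Wilk
  screening, RM-ANOVA, Bonferroni-corrected paired post-hoc grouping
  (`normality_screen()`, `rm_anova()`, `posthoc_bonferroni()`).

The methods vignette
(`vignettes/quantifying-morphological-computation.Rmd`) documents the
model, the discretization policy and its caveats.

## Worked example

Validate the estimator on a benchmark whose true value is known, then
quantify MC on one simulated pointing movement:

```r
library(neuromc)

b <- generate_discrete_benchmark("copy_world", n_w = 4, n_a = 4,
                                 T = 1e5, seed = 1)
c(analytic = b$analytic_mc, estimated = mc_w(estimate_joint(b)))
#>  analytic estimated
#>  2.000000  1.999936

sch <- sample_ep_variations(1, seed = 1)[[1]]   # jittered EP schedule
trace <- run_point_to_point(sch, seed = 1)      # ~10 s of wall time
tab <- mc_by_level(list(trace), "accumulated")
round(setNames(tab$mc_bits, as.character(tab$level)), 3)
#> u_central u_topdown         u         a      F_CE     F_MTU         T
#>     2.754     2.754     0.636     0.240     0.048     0.006     0.000
```

Read: the joint-angle evolution shares 2.75 bits with the rest of the
system when conditioning only on the central timing signal — the physics
below that cut does substantial work — and essentially 0 bits when the
whole control stack down to the joint torques is treated as the actuator:
the hierarchy's lower levels, muscle properties included, account for
almost all of the morphological computation. The decrease is monotone from
the top of the hierarchy to the bottom.

The numbered scripts under `analysis/` run the full studies and write
tables to `results/`: `01_validate_estimator.R` (benchmark convergence),
`02_point_to_point.R` (7 jittered repetitions, both split modes, the
statistics), `03_noise.R` (stimulation-noise trend reversal),
`04_oscillation.R` (14 rod-swinging runs and the driven-vs-free segment
analysis).

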