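---
title: "Quantifying morphological computation across a motor-control hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological computation across a motor-control hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Voluntary arm movements emerge from a stack of processing stages: a central
command that times the movement, muscle-specific top-down commands, spinal
reflex loops producing the stimulation signal, muscle biochemistry, fiber
contraction mechanics, tendon forces, joint torques, and finally the moving
skeleton. *Morphological computation* (MC) is the part of this control work
performed by the physical system itself — by muscle viscoelasticity acting as
a zero-delay "preflex", by inertia, by an attached elastic implement — rather
than by the controller. `neuromc` simulates a layered neuro-musculoskeletal
arm model in which every one of these signals is observable, and quantifies
MC at each level of the hierarchy.

## The measure

Write $W$ for the world state (everything physical), $A$ for the actuation
signal, and $W'$ for the next world state. If the world dynamics kernel
$\alpha(w' \mid w, a)$ collapses to an action-only kernel
$\tilde\alpha(w' \mid a)$, the behavior is fully dictated by the controller
and no morphological computation takes place. The divergence from that
assumption,

$$
MC_W \;=\; \sum_{w',w,a} p(w',w,a)\,
  \log_2 \frac{\alpha(w' \mid w,a)}{\tilde\alpha(w' \mid a)},
$$

is a Kullback–Leibler divergence and equals the conditional mutual
information $I(W'; W \mid A)$ in bits. On discrete data the joint
$p(w',w,a)$ is estimated by counting the $N = T-1$ consecutive-sample
triples $(w_{t+1}, w_t, a_t)$ (`estimate_joint()`), and the measure is the
probability-weighted sum of per-triple log-ratios (`mc_w()`). Evaluating the
log-ratio along the trajectory instead of summing gives the state-dependent
series $MC_W(t)$ (`mc_w_state_dependent()`), whose frequency-weighted mean
recovers the scalar — an identity the tests check to $10^{-10}$.

Two ways of splitting the hierarchy into $W$ and $A$ are implemented
(`build_level_split()`):

* **selected** — $A$ is exactly one level's signals and $W$ is the
  observable mechanical state (joint angles, plus the rod position in the
  oscillation task). This mirrors what an experimenter could record.
* **accumulated** — a clean cut: $A$ collects the chosen level and
  everything above it, $W$ everything below, down to the mechanical state.

## The model

The plant is a sagittal two-link arm (upper arm, forearm+hand) with
shoulder and elbow revolute joints, driven by six muscle–tendon units: four
monoarticular and two biarticular, in antagonistic pairs. Each MTU is a
Hill-type model with four elements: contractile element (CE) with a bell
force–length curve (width 0.45) and a hyperbolic force–velocity relation
(curvature 0.25, eccentric plateau 1.5, maximal shortening velocity
10 optimal lengths/s), a parallel elastic element, a linear tendon (4%
strain at $F_{max}$) and a serial damping element (dimensionless damping
0.3). Because both force–velocity branches are hyperbolic and the serial
side is linear in the fiber velocity, the force-equilibrium equation is a
quadratic per branch and the fiber velocity is obtained in closed form at
every step — no inner root-finding in the right-hand side. Below 0.7 optimal
lengths a compressive parallel term stops an unloaded fiber from collapsing,
a standard guard for slack-tendon episodes.

Activation is a first-order Hatze-type process:
$\dot a = (a_\infty(u, l_{CE}) - a)/\tau$ with $\tau = 20$ ms and a
closed-form stationary activity
$a_\infty = (q_0 + (\rho u)^3)/(1 + (\rho u)^3)$ whose gain $\rho$ grows
with normalized fiber length. The closed form is what the integration
oracle in the tests uses.

The controller is a hybrid equilibrium-point scheme. Each movement segment
holds a piecewise-constant top-down command: open-loop stimulations
$u^{open}$ and desired fiber lengths $\lambda$ (twelve channels switching
simultaneously); the segment index is the one-channel central timing signal.
The motor command per muscle is

$$
u_i = \left\{\, u^{open}_i + k_p\, l^{CE,opt}_i
 \left( l^{CE}_i(t-\delta) - \lambda_i \right) + u^{CPG}_i \,\right\}_0^1 ,
$$

a monosynaptic stretch reflex on time-delayed ($\delta = 10$ ms) fiber
lengths, clamped once to $[0,1]$. Stimulation rises when a fiber is
stretched beyond its desired length; with the opposite sign a held posture
is an unstable equilibrium — the arm runs away to a joint extreme — so the
stretch-positive orientation is the one under which the equilibrium-point
premise (each held command is a stable posture) holds. $\lambda$ for a
target posture is the fiber length at which the tendon is just taut
(`posture_lambda()`), and `closed_loop_equilibrium()` solves the loop's
statics independently of the simulation — the tests require every
point-to-point run to settle within 2 degrees of that root.

Defaults: $k_p = 80$, $u^{open} = 0.25$. The gain and co-contraction level
were calibrated once against two closed-loop requirements — a held EP must
be asymptotically stable against large (0.3 rad) perturbations, and
point-to-point movements must settle without residual oscillation — under
the 10 ms reflex delay; higher gains or lower co-contraction produce a
delay-induced limit cycle (muscle damping scales with baseline force, so
co-contraction is the physiological stabilizer here). Segment parameters
represent a generic adult male arm; all values are exposed in
`default_config()` and serializable to YAML.

For the oscillation task a point mass on a linear spring–damper slides
vertically at the hand: the vibrating rod. Its free resonance is set to
3.8 Hz ($k/m = (2\pi \cdot 3.8)^2$) with a quality factor of about 20, so
that after the drive stops the oscillation persists through the analysis
window (the free phase retains well above a quarter of the driven
amplitude). The pattern-generator drive is $\hat u \sin(2\pi f t + \phi_0)$
with $\hat u = 0.1$, $\phi_0 = 0$ for flexors and $\pi$ for extensors,
active for $0 \le t \le 4$ s.

Everything — arm, rod, six activations, six fiber lengths — is one global
delay-differential system integrated by `deSolve::dede` (adaptive lsoda,
rtol $10^{-6}$), sampled at 1 kHz.

## What the synthetic data emulates, and what it does not

The two protocols reproduce the study conditions: seven (scaled to three
for the routine checks) point-to-point repetitions whose start, peak-elbow
and target postures are jittered by a truncated normal of 2° — standing in
for the variability a single human shows across repetitions — and fourteen
(scaled to three) oscillation runs with drive frequencies uniform in
$3.8 \pm 0.2$ Hz, the spread observed in a human rod-swinging exercise.
The generator produces noise-free, perfectly synchronized multichannel
traces; real recordings would add sensor noise, marker-reconstruction
error and unobservable internal states. The noise experiment
(`add_stimulation_noise()`) probes exactly this gap: zero-mean uniform
noise of width 40/300 or 80/300 of each muscle's stimulation range is added
to the *recorded* stimulation channels (after the controller's clamp, with
re-clamping), leaving the loop itself untouched. Passing tests therefore
demonstrate properties of the model and estimator, not of any particular
experimental pipeline.

Separately from the arm model, `generate_discrete_benchmark()` produces
discrete Markov fixtures with analytically known $I(W'; W \mid A)$ —
an action-only kernel (0 bits), a copy-world kernel ($\log_2 |W|$ bits) and
random Dirichlet kernels (exhaustive summation) — used to validate the
estimator. The samples are independent transition draws
$w \sim \pi,\ a \sim p,\ w' \sim \alpha(\cdot \mid w,a)$ stored as explicit
triples: a copy-world chain run as a path would freeze at its initial
symbol and no estimator could recover the analytic value from it.

## Discretization

The estimator needs symbols. Channels are cut into uniform-width bins over
their observed range (left-closed, right-open, maximum in the last bin;
zero-variance channels collapse to one symbol), and a multi-channel state
is the occupied combination of per-channel bins. Resolution is set by a
group's role, not per level (`mc_binning_policy()`):

* selected-mode world state (2–3 channels): 30 bins/channel;
* selected-mode actuation level: 12 bins/channel for every level, so that
  per-channel resolution is equal and total resolution grows with channel
  count — the regime in which the two torque channels form a *coarser*
  conditioning state than the six force channels, which is what produces
  the torque exception in the results;
* accumulated-mode world group: the occupancy bound
  $\max(2, \lfloor (N/5)^{1/n} \rfloor)$ evaluated at the full hierarchy
  dimension ($n = 41$, giving 2), held identical for every cut so that the
  cut position is the only thing that differs between accumulated splits
  (the triple table scales as $|W|^2 |A|$, so world resolution dominates
  estimator occupancy);
* accumulated-mode actuator group: 15 bins/channel — fine enough to pin
  the oscillation phase during resonant driving (where the accumulated
  measure must vanish at the low cuts), coarse enough not to over-resolve
  the decaying free oscillation afterwards.

Bin edges are always computed on the full trace; windowed analyses (the
2–4 s driven vs 4–6 s free segments) re-estimate the joint on the window's
triples under those shared edges, so segment values are directly
comparable. The analysis grid is the 1 kHz simulation grid. These constants
are a declared analysis choice: absolute bit values depend on them, while
the qualitative findings (ordering across levels, the torque exception, the
noise reversal, the resonance zero) are the quantities the test suite pins
down. One caveat is documented rather than hidden: at the two uppermost
cuts of point-to-point runs the selected and accumulated values are a
structural near-tie (a point-to-point trajectory never revisits a region,
so the coarse accumulated world patterns and the finely binned joint-angle
state carry almost the same entropy given the 3-symbol schedule), and
individual jittered runs can put the accumulated value a fraction of a bit
above the selected one there. In the oscillation task, where the movement
is recurrent, the two modes separate cleanly at every cut.

## Statistics

Each run yields one MC value per level — a fully repeated design with run
as subject. `rm_anova()` fits `mc_bits ~ level + Error(run/level)` (F =
MS\_level / MS\_level×run), reporting the uncorrected p-value alongside a
Greenhouse–Geisser-corrected one since sphericity is not assumed;
`normality_screen()` applies Shapiro–Wilk per level at $\alpha = 0.1$
(liberal on purpose: the cost of a missed deviation is higher than a false
alarm here); `posthoc_bonferroni()` runs paired two-sided t-tests for all
level pairs with the raw p multiplied by the number of pairs, and groups
levels connected by non-significant links. Paired t-tests are the natural
post-hoc family for the repeated design; a signed-rank alternative would
lose too much power at n = 7.

## Numerical choices and degenerate inputs

Tightening the integrator tolerance is cheap insurance, not a result
changer; the contract adopted here is that reported MC values move by less
than 0.01 bits under a 10× tighter tolerance. Degenerate situations are
handled explicitly: a slack tendon transmits no force (and the reported
muscle–tendon force is floored at zero); stimulations outside $[0,1]$ are a
hard error in the muscle layer because clamping is the controller's job;
missing delay history (the first 10 ms) falls back to the initial fiber
lengths; an all-constant symbol sequence has zero MC by the $0\log 0$
convention; and tiny negative totals from floating-point cancellation are
floored at zero, the measure being a KL divergence.

## Problem sizes

The routine study sizes are three point-to-point and three oscillation runs
(the full seven and fourteen are kept for the analysis scripts), a 7-run
study for the statistics pipeline repeated over five seeds, and benchmark
sequences of $10^5$ transitions; one point-to-point run integrates 3 s of
the 18-state delay system, one oscillation run 6 s of the 20-state system.

## Known limitations

The model is planar, shoulder and wrist kinematics are reduced to single
revolute joints, muscle paths are cosine-wrapped constant-radius
approximations rather than via-point geometry, motor-unit structure and
fatigue are absent, and there is no velocity or force feedback. Absolute
bit values are functions of the discretization policy and are not
comparable across policies — only within one. The rod is a hand-fixed
one-dimensional oscillator; contact with anything else is out of scope.
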