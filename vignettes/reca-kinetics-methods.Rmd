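---
title: "Models and methods for RecA filament assembly kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for RecA filament assembly kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recakinetics)
```

# The measurement and its model

RecA polymerizes on double-stranded DNA by nucleation and growth: a few
monomers bind adjacent sites (one monomer per 3 bp) and the resulting domain
elongates at both ends. Binding extends the occupied contour by a factor of
about 1.5 and stiffens it (persistence length ~1200 nm against ~50 nm for
naked dsDNA). A force clamp holding the molecule at ~0.8 pN therefore sees
the tether lengthen as protein assembles, and the time course of the
end-to-end distance encodes the coverage kinetics.

`recakinetics` implements the full chain from raw force-clamp traces to rate
constants:

1. **Worm-like-chain (WLC) mechanics** — convert the trap-anchor distance
   into contour length and coverage fraction.
2. **Closed-form kinetics** — the fast-nucleation (many-nuclei) sigmoid and
   the slow-nucleation (single-domain) piecewise mean.
3. **A stochastic few-nuclei simulator** with asymmetric fronts.
4. **Trace decomposition** — piecewise-linear break-point fitting, collision
   scenario enumeration, and exact per-front velocity solving.
5. **Rate inference** — the free-length-integral (B_N) estimator of the
   nucleation density, and a chi-square grid scan of the simulator against
   ensemble-mean coverage.
6. **A synthetic-data generator** producing ground-truthed experiments.

## WLC conversion

For a chain at relative extension $z/L$ the clamp force is
$$F = \frac{k_BT}{A}\left[\frac{z}{L} + \frac{1}{4(1-z/L)^2} -
\frac14\right].$$
In the large-force regime each segment of a partially decorated filament
extends to $z_{seg} = L_{seg}(1 - C_{seg})$ with
$C_{seg} = \sqrt{k_BT/(4FA_{seg})}$, and the decorated contour length of a
mixed filament follows as
$$L_R = \frac{z - L(0)(1 - C_0)}{1/3 + (2/3)C_0 - C_R},\qquad
L(t) = L(0) + L_R/3 .$$
The square-root form of $C$ is forced by the large-force expansion of the
interpolation formula: it reproduces the known ~84% fractional extension of
naked dsDNA at 0.8 pN, and a regression test checks it against full
numerical inversion of the force relation per segment. Thermal energy is
computed from the temperature ($k_BT = 4.282$ pN nm at 310.15 K); the rise
of naked dsDNA is 0.34 nm/bp, so one 3-bp binding site is 1.02 nm and a
construct of naked length $L_0$ carries $L_0/a$ sites (about 11,800 at
12 um).

The trap-anchor distance is used directly as the end-to-end distance: the
bead radius, the bead displacement in the trap and the trap-height
correction largely cancel and sit below the measurement accuracy; a constant
offset parameter is available. The coverage fraction
$\phi = 2(L/L_0 - 1)$ is clipped to $[0,1]$ by default (noise pushes $L$
slightly past saturation), with an unclipped mode used wherever symmetric
noise around the physical bounds matters (see the chi-square fit below).

## Coverage kinetics in the limiting regimes

With many domains ($k_g/k_n \ll 1$) the mean-field system
$$\dot N = k_n(1-\phi) - k_g N^2/(1-\phi), \qquad \dot\phi = k_g N$$
is solved by the sigmoid $\phi = 1 - \exp(-\tfrac12 k_n k_g t^2)$ — the
collision term must carry the $1/(1-\phi)$ factor for this to hold, and a
unit test verifies the closed form against the integrated system to
$10^{-4}$. Front asymmetry enters through $k_g = k_g'(1+r)$, where $k_g'$
is the fast-front rate and $r \in [0,1]$ the slow/fast ratio; only the
product $k_nk_g$ is identifiable in this regime.

With a single domain ($k_g/k_n \gg 1$) nucleated at uniform position $x$,
coverage grows piecewise linearly, and averaging over $x$ gives a
three-branch mean with breakpoints at $1/k_g'$ and $1/(rk_g')$, continuous
at both. It describes one domain only: at small $r$ the slowly closing side
leaves free DNA where further nucleations occur, so the simulated mean
increasingly exceeds this curve as $r$ decreases — a property the tests
assert rather than suppress.

An optional nucleation-coverage term $k_n(1-\phi)$ in $\dot\phi$ (relevant
only when nuclei are no longer rare compared to binding sites) is available
behind a flag and off by default, matching the closed forms.

## The few-nuclei Monte-Carlo model

The simulator lives on a continuous unit substrate (positions are fractions
of the naked contour; site-level granularity adds nothing at ~10^4 sites
per molecule and the model is a continuum one). Per step `dt` (default
0.5 s, chosen so halving it moves the ensemble mean by well under 1%):

* a nucleation occurs with probability $k_n(1-\phi)\,dt$ at a uniform point
  of the undecorated set; the fast side is drawn at nucleation;
* every fast front advances $k_g'\,dt$ and every slow front $rk_g'\,dt$;
* fronts clip at the molecule ends and merge on contact (collision times
  interpolated within the step);
* the run stops at full coverage (capped at `t_max`; with $r = 0$ full
  coverage takes arbitrarily long).

Nuclei are created as zero-width points; growth supplies all length. While
the substrate is empty the waiting time to the first nucleation is drawn
geometrically — the per-step Bernoulli process with constant probability
$k_n\,dt$ has exactly that waiting-time law, so the shortcut changes no
distribution, only the cost of slow-nucleation ensembles. All randomness
flows through R's RNG (`set.seed()` gives bit-reproducible runs), and a
deterministic replay engine (`forced_scenario()`) reproduces any logged run
bitwise, which the tests use as an oracle.

A point worth stating explicitly: the many-nuclei sigmoid is an
infinite-substrate result. On a finite molecule with absorbing ends the
simulated mean lags it systematically — at $k_g/k_n = 0.1$ the supremum gap
is a few hundredths and it shrinks roughly like $\sqrt{k_g/k_n}$, a
convergence the test suite measures across $k_g/k_n = 0.1, 0.03, 0.01$.
This is physics of the finite molecule, not discretization: an
independently coded fine-step event simulation agrees with the engine to
Monte-Carlo error.

## Decomposing a single trace

Between events the length grows linearly, each slope being half the sum of
the active front velocities in naked-contour units (covering $dx$ of naked
contour adds $dx/2$ of total length). Events are break points: a slope
increase is a nucleation, a decrease a collision (front-front or
front-end). A complete trace with $Q$ breaks has $N_t = (Q-1)/2$ domains.

`fit_piecewise_linear()` refines user-seeded break times by continuous
two-segment least squares on each break's local window (coarse scan over at
most 80 candidate sample times, then golden-section refinement), iterating
until the breaks move by less than one sample. Break significance uses an
F-test of the two-segment fit against a single line at $\alpha = 0.01$ —
such break points have traditionally been classified by eye, so the
threshold is the package's own (tunable) choice. Raw kHz-rate traces should be block-averaged first
(`block_average()`, windows of order 2000 samples); the bundled generator
already produces effective 1-10 Hz traces, so the fitting default applies
no smoothing.

`enumerate_scenarios()` walks every spatial ordering of the domains and
every chronologically consistent assignment of collision breaks to the
$N_t+1$ gaps of the final configuration. Mirror-image scenarios are both
kept — a length trace cannot identify absolute orientation — and solve to
identical velocity sets. `solve_scenario()` builds the square linear system
(one equation per inter-break segment, one unknown per front), solves it
exactly, chains front travels into nucleation positions, and classifies the
scenario: negative velocities (which would mean disassembly, negligible
with a non-hydrolysable cofactor) or a nucleation falling on covered DNA
mark it infeasible. Several feasible scenarios are common on multi-domain
traces; `decompose_curve()` ranks them by the residual of the replayed
trace, explicitly as a heuristic, and returns all of them.

## Rate inference

**Nucleation density.** New nuclei appear at rate $n\,L_{free}(t)$, so the
count up to $t_N$ satisfies $N = n\,B_N$ with
$B_N = \int_{t_0}^{t_N} L_{free}\,dt$. `compute_bn()` integrates measured
free length by trapezoid; `fit_nucleation_density()` averages $B_N$ across
experiments per $N$ and reads $1/\bar n$ off the OLS slope. The tests
calibrate this against events generated by time rescaling (unit-rate
exponentials mapped through $B^{-1}$), an oracle independent of the
estimator.

**Joint fit.** `grid_scan_fit()` compares the experimental ensemble-mean
coverage with the simulator's mean by
$$\chi^2 = \sum_t \frac{(\bar\phi_{exp} - \bar\phi_{mod})^2}
{SE_{exp}^2 + SE_{mod}^2},$$
with both standard errors included (the model mean is itself a Monte-Carlo
estimate; zero combined variance is floored at $10^{-12}$). The
Monte-Carlo roughness of this surface defeats gradient optimizers, so the
minimum is located by an iterative grid scan — coarse map at $M = 10^3$,
then re-evaluation of everything within ~10% of the stage minimum (never
fewer than the best 20 cells, since at $M=10^3$ the chi-square noise can
exceed that band) at each larger $M$ in the schedule. Reported errors are
the local grid steps, upper bounds by construction. Defaults that matter:

* grids: logarithmic in $k_n$ and $k_g'$ (decade-scale prior uncertainty),
  linear in $r$ with step 0.05;
* alignment: $t = 0$ at the first nucleation event for simulator-generated
  curves (`align_phi = 0`), or at a small coverage threshold (default
  $\phi = 0.05$, located on a lightly smoothed curve) for noisy measured
  data; the model ensemble is aligned by the identical rule;
* the comparison grid is trimmed shortly after the experimental mean
  saturates — beyond that point the between-trace variance carries no
  kinetic information;
* each model run is conditioned on reaching full coverage within the
  comparison window, mirroring the selection of complete experimental
  traces before averaging (without this the unconditioned model's straggler
  tail biases $r$ low);
* common random numbers across grid cells, so the Monte-Carlo error of the
  surface varies smoothly in the parameters and cannot scramble the argmin.

On 5-trace synthetic ensembles at the reference parameters
($k_n = 1.05\times10^{-3}$ s$^{-1}$, $k_g' = 5.27\times10^{-4}$ s$^{-1}$,
$r = 0.10$) this protocol recovers $r = 0.10$ reliably and pins
$k_g$ tightly; $k_n$ is only weakly identified by a 5-trace mean (scatter
up to tens of percent across seeds), which is why the package reports
scan-step error bounds rather than pretending to confidence intervals.

**Energies.** Reaction-limited kinetics obey Arrhenius laws with prefactors
proportional to $L_0/a$ for nucleation and $a/L_0$ for growth, giving
$$\Delta E_{coop} = E_n - E_g^f
= k_BT\,\ln\!\Big(\frac{k_g}{(1+r)k_n}\,(L_0/a)^2\Big),
\qquad \Delta E_{asym} = E_g^s - E_g^f = -k_BT\ln r .$$
The first measures how much harder nucleation is than fast-front growth
(cooperativity, ~18 kBT here); the second the barrier difference between
the two fronts (~2.3 kBT at $r = 0.10$).

## The synthetic-data generator

`synth_spec()` fixes the study conditions: naked lengths uniform on
10-17 um (non-specific tethering gives variable lengths; the mean
corresponds to ~11,800 binding sites), rates defaulting to the reference
values above, a 0.8 pN clamp whose set-point error is a bounded random walk
re-centred at $\pm0.1$ pN (the operator re-adjusts the clamp at the band
edge), Gaussian position noise of 0.05 um on the trap-anchor distance, and
an effective sampling rate of 1 Hz. Raw 20 kHz acquisition is not emulated;
traces are generated directly at the effective rate the analysis consumes.
The per-trace noise amplitude is not independently constrained; 0.05 um makes the
decomposition succeed at roughly the reported fraction of analyzable
traces while keeping individual breaks visible by eye.

`make_experiment()` composes simulator ground truth, the length mapping,
the segment-wise WLC forward model at the jittered force, and additive
noise; the exact nucleation and collision log rides along, so every
pipeline stage can be checked against truth. What the generator does *not*
emulate — bead Brownian dynamics, photodiode nonlinearity, drift,
force-dependent binding rates — bounds what green tests mean: they
demonstrate correctness of the analysis on data from the stated model, not
robustness to every instrumental artifact of real recordings.

## Problem sizes and numerical choices

Test and example workloads are sized for a desk machine: ensemble means use
$M = 10^3$-$10^4$ runs (the reported standard error $\sigma/\sqrt M$ makes
the residual Monte-Carlo error explicit), the recovery scan uses a
5 x 5 x 20 grid with a two-stage $M = 10^3 \to 10^4$ zoom, and the
replicate studies use 100 seeded traces. The ODE integrator is `lsoda` at
relative tolerance $10^{-8}$ with $\phi$ capped at $1-10^{-12}$ to keep the
collision term finite; WLC inversion brackets to $10^{-10}$ relative; the
stochastic engine closes residual events at completion explicitly so
floating-point drift cannot drop the final collision from an event log.

## Known limitations

* The scenario enumeration grows factorially with the domain count; it is
  intended for the few-nuclei regime (up to ~4 domains), matching the data
  it is designed for.
* The chi-square fit uses the ensemble mean only; the between-run variance curve carries additional information about
  $r$ that is deliberately left unexploited.
* $A_R$ varies somewhat between molecules; it enters as a single scalar.
* Binding is treated as irreversible (non-hydrolysable cofactor);
  disassembly, ATP turnover and force dependence of the rates are out of
  scope.
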