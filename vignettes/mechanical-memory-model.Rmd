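---
title: "A bistable mechanical positive-feedback-loop model of fibroblast activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable mechanical positive-feedback-loop model of fibroblast activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(mechanopfl)
```

## The model

Cardiac fibroblasts activate into matrix-secreting myofibroblasts on stiff
substrates, and in late disease this transition appears irreversible: cells
transferred back to soft matrix stay activated. `mechanopfl` implements a
minimal dynamical explanation — a mutually reinforcing loop between integrin
β1 adhesion signaling and the Piezo1 mechanosensitive channel that forms a
bistable switch.

Three normalized activities are tracked: integrin β1 ($C_I$), Piezo1 ($C_P$)
and a lumped fibrotic-marker/activation level ($C_a$), each in $[0,1]$:

$$\frac{dC_I}{dt} = (1-u_I)\Big[k_{1f}S(t) + F(t)\frac{C_P^n}{1+C_P^n}\Big](1-C_I) - k_{1r}C_I$$
$$\frac{dC_P}{dt} = (1-u_P)\Big[k_{2f}S(t) + F(t)\frac{C_I^n}{1+C_I^n}\Big](1-C_P) - k_{2r}C_P$$
$$\frac{dC_a}{dt} = k_{3f}(C_I + C_P)(1-C_a) - k_{3r}C_a$$

Each species is activated linearly by the dimensionless stiffness drive
$S(t)$ and nonlinearly — through a Hill term with coefficient $n$ — by the
other arm of the loop, scaled by the feedback strength $F(t)$. The $(1-C)$
factors keep activities normalized; deactivation is first order. $C_a$ is a
slaved readout: it integrates $C_I + C_P$ but does not feed back, so the
switch lives entirely in the $(C_I, C_P)$ plane. Inhibitor occupancies
$u_I, u_P \in [0,1]$ multiply the whole activation bracket of their target
species — a blocking reagent stops activation from any source while leaving
deactivation untouched.

Defaults are $k_{1f}=k_{2f}=k_{3f}=1$, $k_{1r}=k_{2r}=k_{3r}=0.1$ per model
time unit. Time is treated as dimensionless with the convention that one unit
is one day: the protocols the model addresses run on a day scale and the
qualitative conclusions do not depend on the absolute rate scale, only on the
ratio $k_f/k_r$.

### Why $n = 2$

The Hill coefficient is exposed as a parameter with default 2. With the
default rates and a half-saturation of 1, $n = 1$ gives a monotone response
with a single stable state everywhere (a first-order loop cannot switch; the
origin only exchanges stability at $F = k_r$), while at $n \ge 4$ the Hill
term at realistic activities is too small to sustain a high state. $n = 2$ is
the smallest cooperative order that yields a robust bistable window, and it
is the value used throughout the package's calibration.

## Bistability and hysteresis

Because $C_a$ is slaved, equilibria are found in the $(C_I, C_P)$ subsystem
by damped Newton iteration with the analytic Jacobian from a $21\times 21$
grid of starts; stability comes from the block-triangular $3\times 3$
Jacobian (the $C_a$ eigenvalue $-(k_{3f}(C_I+C_P)+k_{3r})$ is always
negative). With symmetric rates all equilibria lie on the diagonal
$C_I = C_P$, where the problem reduces to a single equation — the package's
tests exploit this as an independent oracle.

```{r fixed-points}
p <- pfl_params()
find_fixed_points(p, pfl_drive(S = 0, F = 1))
```

At full feedback and zero stiffness the loop is bistable with stable states
near 0 and 0.79 separated by a saddle near 0.11. Sweeping $S$ at $F = 1$
collapses the quiescent branch in a saddle-node at $S \approx 2.8\times
10^{-3}$:

```{r fold}
bd <- bifurcation_sweep(p, pfl_drive(F = 1), axis = "S",
                        range = c(0, 6e-3), n = 13, starts = 11)
bd$folds
```

Folds are located by bisection on the number of stable equilibria (not the
total equilibrium count, which would misreport degenerate stability
exchanges such as the $n=1$ transcritical point as folds). A quasi-static
up-and-down stiffness sweep (`hysteresis_sweep()`) confirms the loop does not
retrace: past the fold the system commits to the high branch and stays there
when the drive is removed.

## Stiffness transduction

The model consumes a dimensionless drive $S$; experiments report substrate
Young's moduli in kPa (4 kPa "soft", 8 kPa "medium", 15 kPa "stiff"). The
package maps one to the other as

$$S = \sigma E^m, \qquad \sigma = 5\times10^{-5}\ \mathrm{kPa}^{-m},\quad m = 2.$$

The supralinear exponent is a deliberate calibration, and the reasoning is
worth recording. Two constraints act simultaneously:

* *Soft must sit inside the bistable window.* Mechanical memory requires the
  activated state to survive on 4 kPa at full feedback, i.e.
  $S_{soft} < S_{fold} \approx 2.8\times10^{-3}$.
* *Stiff must activate within one to two weeks.* Escape from the quiescent
  state onto the high branch passes a saddle-node ghost whose transit time
  scales like $\pi/\sqrt{S_{stiff} - S_{fold}}$; day-7 transfer must leave
  cells below the soft separatrix while day-14 transfer must leave them
  above it.

With a linear map the 15/4 kPa modulus ratio (3.75) cannot satisfy both: any
$\sigma$ that activates stiff substrates in under two weeks pushes the soft
drive far beyond the fold, and any $\sigma$ that keeps soft bistable makes
stiff activation take months. A quadratic transduction stretches the ratio
to 14 ($S_{soft} = 8\times10^{-4}$, $S_{stiff} = 1.125\times10^{-2}$), which
satisfies both with comfortable margins. Cooperative adhesion growth makes a
supralinear stiffness response biophysically reasonable, and both $\sigma$
and $m$ remain user-configurable.

## Feedback ramp

$F(t)$ models the gradual consolidation of the loop (receptor clustering,
adhesion maturation) rather than an instantaneous property of the substrate.
It ramps linearly at rate $1/\tau_F$ ($\tau_F = 14$ d) whenever
$S(t)$ is at or above a threshold (default: midpoint of the mapped soft and
stiff drives), freezes at its attained value otherwise, and saturates at
`F_max` (default 1). Seven days of stiff priming therefore yields $F = 0.5$,
fourteen days $F = 1$ — which is exactly what separates the reversible from
the irreversible transfer protocols below. Whether the feedback should decay
on soft substrates is biologically open; the package freezes it, which makes
the memory predictions conservative (decay would only ever help reversal).

## Mechanical memory protocols

Protocols are labelled `St<d1>So<d2>`: `d1` days on stiff, then `d2` days on
soft. The reversibility label comes from the marker trajectory: *reversible*
if the final $C_a$ is below the activation threshold (0.5, half-normalized —
the static low and high branches sit well below and above it);
*reactivated* if $C_a$ dipped below the threshold within the assessment
window and then re-exceeded it; *partially reversible* if the final value is
above threshold but reduced at least 25% from the pre-window peak;
*irreversible* otherwise.

```{r memory}
reversibility_assay(p, make_dose_schedule("St7So7"))$label
reversibility_assay(p, make_dose_schedule("St14So7"))$label
```

The mechanism: after 7 days the state is still below the soft separatrix and
feedback is only half-established, so transfer relaxes the cells back; after
14 days the state has crossed the separatrix with $F = 1$, the soft substrate
is bistable, and the activated state persists — memory.

## Treatment scenarios and phase diagrams

Five canonical interventions against an `St14`-primed culture are provided
(see `run_treatment_scenarios`): a no-memory reference with feedback held at
zero (line 1), softening alone (line 2), softening plus both inhibitors
(line 3), inhibitors alone on stiff substrate (line 4), and no intervention.
Defaults are $u = 0.6$ on both arms, treatment from transfer for 28 days,
and a horizon of priming + 56 days. The 28-day duration and 56-day horizon
follow from the model's intrinsic decay rate: marker clearance is bounded by
$k_{3r} = 0.1$/d, so meaningful reversal needs several weeks of treatment
and observation — shorter windows leave every arm in transit and blur the
ordering.

```{r scenarios}
run_treatment_scenarios(p, "St14")
```

Only the combined intervention (line 3) matches the no-memory reference;
either single intervention leaves the loop locked.

Two phase diagrams summarize this systematically. The **inhibitor diagram**
(`inhibitor_phase_diagram`) grids $u_I \times u_P$ with treatment starting at
day 56, when the activated state has fully consolidated — started earlier,
while the state is still in transit, even weak single inhibitors reverse it
and the diagram degenerates. Its structure: an irreversible region around the
origin, a reversible region in the upper right corner, and partially
reversible cells in between where one inhibitor dominates. Two model
properties shape it: (i) fully inhibiting *either* arm alone collapses the
loop given enough time, because the surviving arm's feedback input decays
with its partner — so the partial region is a band along the irreversible/
reversible boundary rather than the full length of the axes; and (ii) with a
fixed observation horizon, "partially reversible" captures cells still in
transit at assessment.

The **timing diagram** (`timing_phase_diagram`) grids treatment start `T1`
(measured from the start of priming) against duration `T2`, with both
inhibitors at $u = 0.6$ and transfer to soft at day 14. The untreated column
(`T2 = 0`) is uniformly irreversible; long treatment is reversible; and
early-but-brief treatment produces *reactivation*: the inhibitors suppress
the loop while applied, but feedback consolidation continues on the stiff
substrate, so after early withdrawal the cells activate after all. This is
the only place reactivation can occur in this model: once a culture is fully
activated on soft substrate, driving $C_a$ below threshold requires
$C_I + C_P < k_{3r}/k_{3f} = 0.1$, which is already below the soft
separatrix — so a dip below threshold followed by re-escape is impossible
there, and reactivation is intrinsically a treatment-timing phenomenon.

```{r timing, fig.alt = "Timing phase diagram"}
td <- timing_phase_diagram(p)
plot(td)
```

## Quantification formulas

The package also implements the closed-form readout formulas used alongside
such experiments, with strict input validation: the nuclear/cytoplasmic
intensity ratio $R_{nc}$ from summed mask intensities (explicit errors for
zero cytoplasm rather than `Inf`), the rheometry conversion
$G = \sqrt{G'^2 + G''^2}$, $E = 2G(1+\nu)$ (with $\nu = 0.5$, $E = 3G$), the
hydrogel swelling ratio $W_s/W_d$, and relative expression by the
$2^{-\Delta\Delta Ct}$ method normalized to a housekeeping gene and control
sample.

## Synthetic data and what the tests do (and do not) show

The synthetic layer generates what the analysis consumes: noisy marker time
courses (additive Gaussian on the normalized marker, $\sigma = 0.05$ by
default, clamped to $[0,1]$), elliptical cell-image fixtures with known
ground-truth $R_{nc}$, and lognormal fold-change panels
($\sigma = 0.2$) — dispersions chosen to resemble typical replicate scatter
in such readouts, not measured values. All generators are bit-reproducible
given a seed.

Passing tests on these fixtures demonstrate internal consistency — the
pipeline recovers what the generator embedded — under idealized conditions:
no segmentation error, no illumination gradients, no amplification-efficiency
variation, noise of known form. They do not validate the model against real
measurements, and the stiffness-transduction calibration above is a
model-internal choice, not a fitted quantity.

## Parameter recovery

`pfl_fit` closes the loop: given a marker time course and a schedule
skeleton, it recovers free parameters (feedback plateau `F_max`, Hill
coefficient `n`, transduction scale `sigma`, ramp constant `tau_F`) by
bounded Levenberg–Marquardt least squares from 8 Latin-hypercube starts. On
the reference design — an `St14So28` course, 200 time points, additive noise
$\sigma = 0.02$, truth $F_{max} = 0.8$, $n = 2$ — ten seeded repeats recover
both parameters with median relative error well under 10%; `n` is sharply
identified (the switch timing pins it), `F_max` more loosely (past the
switching threshold the trajectory depends on it only through the climb
rate).

## Numerical choices

* Integration: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$, piecewise
  over schedule segments (the feedback ramp is linear within each compiled
  piece, so no discontinuities cross an integrator step). States are
  renormalized into $[0,1]$ when the excursion is below $10^{-6}$; larger
  excursions are an error, not silently clamped.
* Root finding: damped 2-D Newton, residual acceptance $10^{-9}$,
  deduplication at $10^{-6}$; eigenvalues with $|\mathrm{Re}\,\lambda| <
  10^{-9}$ flagged as marginal.
* Continuation: plain warm-started relaxation (adequate for an effectively
  2-D monotone system); folds refined by bisection to $10^{-6}$ relative.
* Problem sizes: phase diagrams default to $11\times11$ grids; the recovery
  study uses 10 seeds of 200 observations. These keep a full run of the test
  suite and acceptance script to a few minutes on one core while leaving the
  qualitative structure unambiguous.

## Known limitations

* The stiffness transduction is a calibrated phenomenological map; only its
  qualitative consequences (which substrates are bistable, how fast stiff
  substrates activate) are constrained.
* Feedback consolidation is a deterministic ramp; cell-to-cell variability
  in memory acquisition is not modelled (no stochastic kinetics).
* Inhibitor occupancy is used directly; no dose-to-occupancy
  pharmacokinetics.
* The marker pool is a single lumped variable; individual markers with
  different turnover rates will deviate from it quantitatively.
* No spatial structure: matrix remodelling by the cells themselves (which
  would close a second, slower feedback loop through $S$) is out of scope.
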