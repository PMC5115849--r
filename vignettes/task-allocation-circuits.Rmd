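---
title: "Modelling wasp task allocation with coupled RLC circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wasp task allocation with coupled RLC circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological system and its electrical analogue

Swarm-founding *Metapolybia* wasps partition nest construction into four
sequential subtasks carried out by different groups: water foragers (WF)
collect water; storer wasps hold it in their crops, forming a communal
"common stomach" (CS) that doubles as a buffer and an information centre;
pulp foragers (PF) withdraw water to macerate plant fibre into pulp; and
builders (B) work the wet pulp into the nest, where the water finally
evaporates. The saturation level of the common stomach regulates how many
wasps engage in each task.

`taskcircuits` models each task group as a series RLC loop and the flow of
water as the flow of charge. For circuit $k$ with charge $q_k(t)$,

* the capacitance $C_k$ (farads) is the group's water-holding capacity,
  standing in for group size;
* the resistance $R_k$ (ohms) is its dissipative water use (drinking,
  cooling, and for builders the evaporation of water from fresh
  construction);
* the inductors $L$ (henries) are the coils through which neighbouring
  groups exchange water, and the mutual inductances $M$ couple the loops in
  the chain WF &harr; CS &harr; PF &harr; B.

Only the WF loop is driven: its battery
$V_\mathrm{batt}(t) = V + G(t)$ combines a steady supply $V = 1$ V with a
transient fluctuation $G(t) = \sin(1.5\,t)\,e^{-t}$ V, optionally plus a
step offset switched on at a configurable time (used to model sudden extra
water in the environment).

Kirchhoff's voltage law gives one second-order equation per loop, e.g. for
the water foragers

$$ W'' = \frac{M_{1}\,\mathcal{C} - R_1 W' - W/C_1 + V_\mathrm{batt}(t)}{L_1}, $$

where $\mathcal{C}$ is the common stomach's coupled term (see the next
section) and the CS and PF equations divide by their summed coil
inductances ($L_2 + L_3$ and $L_4 + L_5$). The WF--CS coupling is
directional: induction originating in the water foragers acts on the common
stomach with $M_{1a} = 0.1$ H, while the (stronger) back-influence of the
common stomach on the water foragers uses $M_{1b} = 0.2$ H — a step-up
asymmetry that makes perturbations elsewhere in the colony visible in the
driven WF loop. The CS--PF and PF--B couplings share $M_2 = 0.1$ H.

## Two readings of the coupling term

The induced-voltage term admits two self-consistent readings, and the
package implements both as `coupling_mode`:

* **`second_derivative`** — the induced term is $M\,q''_{nb}$, the
  neighbour's current change. Moving those terms to the left-hand side
  yields an implicit system $A\,q'' = f$ with a dimensionless $4\times4$
  matrix $A$ (`coupling_matrix()`), solved for $q''$ at every evaluation.
  At steady state every coupled term vanishes with the derivatives, so the
  equilibrium collapses to $(C_1 V, 0, 0, 0)$: the downstream circuits hold
  no charge.
* **`charge_equivalence`** (default) — the induced term is $M\,q_{nb}$, the
  neighbour's *charge*. This is the assumption that the change of current
  causing induction is equivalent to the charge on the adjacent circuit,
  and it is the only reading that sustains nonzero equilibria on CS, PF and
  B, i.e. ongoing construction. Setting all derivatives to zero gives the
  linear algebraic system

  $$ W = C_1 (V + M_{1b} C), \quad C = C_2 (M_{1a} W - M_2 P - d), \quad
     P = C_3 M_2 (C - B), \quad B = C_4 M_2 P, $$

  with $d$ the optional CS drain (volts); `equilibrium_charges()` solves it
  directly, and with the default parameters yields
  $(0.5442,\,0.4422,\,0.1020,\,0.1020)$ C. Note $C_4 M_2 = 1$ makes PF and
  B tie exactly.

With all $M = 0$ the two modes coincide (a tested invariant). Which reading
generated the original published figures is not decidable from the source
material; the default follows the reading whose equilibria look like the
published baseline trajectories.

The simulated baseline ordering is WF > CS > PF = B. The published
narrative describes builders above foragers and the common stomach above
both forager groups; no assignment of the published parameter values
reproduces that ordering in either mode, so the package asserts its
simulation against its own algebra (simulation-vs-closed-form agreement)
and reports the ordering as a diagnostic rather than asserting the
narrative.

## Integration

The state $x = (q, q')\in\mathbb{R}^8$ obeys
$x' = A_8 x + b + u\,V_\mathrm{batt}(t)$ — linear and time-invariant within
any span during which the parameters are fixed (`system_matrices()`).
`integrate_circuits()` therefore advances classical fixed-step RK4 through
a precomputed one-step propagator: with step $\mathrm{d}t$,

$$ x_{n+1} = T x_n + c_b + c_1 V(t_n) + c_2 V(t_n + \tfrac{\mathrm{d}t}{2})
   + c_3 V(t_n + \mathrm{d}t), $$

where $T = \sum_{j=0}^{4} (\mathrm{d}t\,A_8)^j / j!$ and the $c_i$ come
from expanding the four RK4 stages. This is algebraically identical to the
textbook stepper on this system (verified against a naive explicit-Euler
loop and against an adaptive external solver in the test suite) and keeps
multi-million-step runs fast in pure R. Fixed-step RK4 was chosen over
adaptive stepping deliberately: the system is small, smooth and linear, and
bit-reproducibility across platforms and reruns — every scenario report is
required to be bit-identical — matters more than adaptive efficiency.

Perturbation experiments are timed events (`perturbation_event()`): at the
event time the parameter changes as a step (no ramping) while charges and
currents carry over unchanged, and integration continues under the new
propagator. Event targets are validated before integration starts, and
event times snap to the step grid.

**Numerical choices.** Default `dt = 0.01` s (RK4 results at `dt` and
`dt/2` agree to $7\times10^{-12}$ C on a 300 s baseline span, so 0.01 s is
far inside the converged regime); baseline runs to `t_end = 3000` s and
perturbation runs to 4000 s with events at $t = 2000$ s; recording keeps at
most $10^5$ rows by default. Divergence (e.g. a step size outside the RK4
stability region) is detected as non-finite state and aborts with the
failure time. A degenerate zero-length trajectory, flat series, and
windows longer than the span all raise or skip with informative messages
rather than returning garbage.

## Time scales and initial conditions

The builders' loop is overdamped with roots
$-R_4/2L_6 \pm \sqrt{(R_4/2L_6)^2 - 1/(C_4 L_6)} = \{-1.99, -0.01005\}$
s$^{-1}$; the slowest eigenvalue of the fully coupled default system is
$-0.0118$ s$^{-1}$. Two consequences worth knowing:

* equilibria are independent of the initial charges, but only
  asymptotically: a unit initial difference still leaves $\approx 0.1$ C at
  $t = 200$ s and first drops below $10^{-6}$ C near $t \approx 1400$ s.
  The test suite asserts $10^{-6}$ C agreement for $t \ge 1500$ s.
* at the 2 % band the baseline run settles at $\approx 392$ s, while the
  slow mode's $e$-folding implies full relaxation on a $\sim 10^3$ s scale
  — consistent with the published claim of equilibrium "at approximately
  1200 seconds" even though no parameter in the model is tuned to that
  number.

## The perturbation scenario registry

Each named scenario applies exactly the published parameter change at
$t = 2000$ s (see `list_scenarios()`); `run_scenario()` averages each
circuit's charge over a 200 s window ending at the event (pre-equilibrium)
and over the final 200 s window (post-equilibrium), and classifies each
circuit's response, with relative changes below 0.5 % counting as
"unchanged". Where the source material was ambiguous the package makes
these choices:

* **Water-forager removal** uses $C_1: 0.5 \to 0.25$ F and
  $R_1: 5 \to 2\ \Omega$ (the figure caption's values; the body text's
  "from 2 to 1 $\Omega$" contradicts the baseline $R_1 = 5\ \Omega$).
* **Coupling reduction** is stated as "$M_1$ and $M_2$ reduced from 0.1 H"
  even though $M_{1b} = 0.2$ H. The printed targets (0.075 / 0.05 / 0.01 H)
  are applied to $M_{1a}$ and $M_2$, and $M_{1b}$ is scaled by the same
  fraction (0.15 / 0.10 / 0.02 H), preserving the step-up asymmetry while
  honouring the stated percentages.
* **Added water** enters as a $+0.5$ V step on the total battery voltage
  from the event time onward ($G$'s $e^{-t}$ envelope is numerically zero
  long before $t = 2000$ s, so adding to $G$ literally would do nothing).
  The polarity with which such a step should enter the WF loop is a wiring
  convention not derivable from the equations; `step_offset` is signed so
  either convention is available, and the default positive step *raises*
  the WF equilibrium.
* **Leaky common stomach** puts a constant $-0.05$ V term in the CS
  equation's numerator. With the default parameters $C_2 \cdot 0.05 =
  C_1 \cdot V$, so the post-leak equilibrium has the CS charge exactly zero
  and PF = B = 0 — a stronger collapse than the published narrative, and
  WF *falls* slightly (0.544 → 0.5 C) rather than rising. Response
  directions for this and the other direction-sensitive scenarios are
  recorded in the report's `signs` field as diagnostics, not asserted as
  invariants; the asserted directions are the ones that are robust across
  both coupling readings (coupling cuts lower PF and B; every removal
  lowers the removed circuit's own equilibrium).
* The two phase-plane scenarios follow the panel captions
  ($R_1 \to 10^{-6}\ \Omega$ for the WF--CS panel,
  $R_2 \to 10^{-6}\ \Omega$ for the PF--CS panel) where caption and body
  text disagree; they modify the configuration from $t = 0$ and carry no
  events.

## Trajectory diagnostics

* `tail_equilibrium()` — per-circuit mean over the final window (default
  200 s).
* `settling_time()` — earliest recorded time after which every circuit
  stays within `band_fraction` (default 0.02) of its net transition
  $|q_\infty - q_0|$ around its final value; a circuit whose transition is
  below $10^{-9}$ C carries no settling information and is skipped with a
  note; a series still outside its band at the end yields `NA`. The band is
  transition-normalised because the four equilibria differ by a factor of
  five.
* `rise_half_times()` — first crossing of the midpoint between initial and
  final value, linearly interpolated; on the baseline run the half-rise
  order WF (2.1 s) < CS (32.9 s) < PF (40.4 s) < B (115.0 s) reproduces the
  delayed cascade down the task chain.
* `phase_diagnostics()` — projects the run onto a charge--charge plane,
  estimates the point attractor from the trajectory tail (so the diagnostic
  also works for runs with events, where the algebraic equilibrium changes
  mid-run), and reports the contraction fraction: the share of consecutive
  steps whose distance to the attractor does not increase. A trajectory
  parked on the attractor counts as fully contracted (fraction 1) by
  convention. Under the default coupling mode the measured fractions are
  $\approx 0.50$ (WF vs CS) and $\approx 0.47$ (PF vs CS): the published
  qualitative contrast (PF--CS markedly more dissipative) is *not*
  reproduced, so the package reports both numbers instead of asserting the
  contrast.

## Problem sizes and what the tests show

The test suite and the acceptance script integrate the real model, not
stubs: the baseline check runs $1.5$–$3\times10^5$ RK4 steps, each
perturbation scenario $2\times10^5$ steps (`dt = 0.02` s to 4000 s, well
inside the converged regime), and the Euler cross-check $10^6$ steps at
$\mathrm{d}t = 10^{-4}$ s. These sizes make the whole suite run in well
under a minute while leaving every tolerance orders of magnitude of
headroom.

The model is deterministic and linear; there is no synthetic noise, no
seed-dependence, and consequently no statistical power question. What the
passing tests show is internal consistency (simulation vs closed form vs
two independent integrators) and fidelity of the encoded experiments to
their printed parameter changes. What they cannot show is biological
validity: charge is a proxy for group-level water content, wasp recruitment
after removals is deliberately absent (removed capacity is not replaced),
and the parameters were never fit to field data.

## Known limitations

* Group-level only — no individual wasps, no task-switching costs, no
  stochasticity.
* The coupling-term ambiguity is resolved by configuration, not by
  evidence; results that depend on the mode (response signs for some
  scenarios, phase-plane contraction) should be read as conditional on it.
* Linear circuit elements throughout; saturation of the common stomach is
  represented only by its large capacitance, not by a nonlinearity.
* No frequency-domain analysis or parameter fitting; the closed-form
  equilibria assume the long-run drive ($G$ transient ignored).
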