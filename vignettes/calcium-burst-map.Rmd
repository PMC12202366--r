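---
title: "From spiking network to burst map: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spiking network to burst map: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caburst)
```

## The model

An inhibitory cell (IC) is a single leaky integrate-and-fire compartment,

$$C_m \frac{dv}{dt} = -\big(g_l (v - E_L) + I_{AHP}\big) + I_{syn} + I_{app},$$

firing when $v$ reaches $v_T$ and resetting to $v_R$. The slow current is
a calcium-gated potassium conductance,
$I_{AHP} = g_{AHP}\,(v - E_K)\,\frac{Ca}{Ca + k_1}$: each spike adds
$d_{Ca}$ to the cell's calcium, which otherwise decays as
$Ca' = -k_{Ca} Ca$. Synaptic currents are conductance-based with gates
that reset to 1 at each presynaptic spike and decay exponentially
($\beta_i$ for IC$\to$IC inhibition, $\beta_e$ for EC$\to$IC excitation).
The excitatory cell (EC) is the same leaky unit under constant drive
$I_{stim}$; it receives no input, so it fires with the closed-form period
$T = (C_m/g_l)\ln\frac{v_\infty - v_R}{v_\infty - v_T}$,
$v_\infty = E_L + I_{stim}/g_l$ (`ec_period()`; about 17.54 ms at the
defaults), and paces the network. Coupling is all-to-all-others: every IC
inhibits every other IC (no self-inhibition), the EC excites every IC.

All constants are kept exactly as printed in one self-consistent
model-unit system (mV, ms, model-µM); the package deliberately has no
unit-conversion layer, because the source values mix nominal units that
only cohere as dimensionless model numbers.

Two constants the equations need but no printed value fixes are the
synaptic reversal potentials. We use the standard GABA$_A$/AMPA choices
$E_{GABA} = -80$ mV, $E_{AMPA} = 0$ mV, and write both explicitly into
every configuration file so no silent default can enter a comparison.

## The reduction

Between spikes, calcium and the inhibitory gate barely move, so the
membrane potential sits at the quasi-steady point of the voltage equation
(`vsub()`):

$$v_{sub}(Ca, s_i) = E_K + \frac{g_l(E_L-E_K) + g_i s_i (E_{GABA}-E_K) +
I_{app}}{g_l + g_{AHP}\frac{Ca}{Ca+k_1} + g_i s_i}.$$

The active cell is evaluated with $s_i = 0$ (nobody inhibits it while its
rival is silent), the silent cell with the gate value left at the end of
an inter-spike interval, $s_i = e^{-\beta_i t_3}$. The interchange happens
right after the two potentials equalize, the active cell's having fallen
(calcium accumulation) to meet the silent cell's.

With $r = e^{-k_{Ca} t_3}$, the end-of-interval calcium after $n$ cycles
is $Ca_a(n) = r^n a_0 + \bar A (1 - r^n)$ for the active cell and
$Ca_s(n) = r^n s_0$ for the silent one, where
$\bar A = d_{Ca}\,r/(1-r)$ is the fixed point of the per-cycle update
$Ca \mapsto (Ca + d_{Ca})\,r$ — the calcium level an eternally active
cell's end-of-interval measurements approach. (Note the factor $r$: the
spike increment is itself subject to the decay of the interval that
follows it. The package asserts this against the literal cycle-by-cycle
recursion at $10^{-10}$ relative tolerance.)

Equating $v_{sub}$ of the two cells at cycle $n$, clearing denominators
and collecting powers of $\rho = r^n$ gives the quadratic
$m_1 \rho^2 + m_2 \rho + m_3 = 0$ implemented in `nspb_real()`, with
coefficients built from four rational combinations $a, b, c, d$ of the
conductances and their reduced form $m = (-a - b + c + d)/k_1$
(`derive_constants()`; the division by $k_1$ is forced by the algebra and
is cross-checked in the tests by substituting the root back into the
potential balance, which holds to $10^{-14}$). The real burst length is
$n_{Ca} = \ln \rho / \ln r$ and the spike count is the strict ceiling,
floored at one spike (`nspb()`): a cell that becomes active fires at
least once, and an exact-integer crossing still takes one more spike.

Numerical choices in `nspb_real()`:

* the root pair is evaluated in the cancellation-free form (the root with
  the larger-magnitude numerator directly, its companion via
  $m_3/(m_1\rho)$);
* the principal ($+\sqrt{}$) root is used when admissible; admissibility
  means $\rho > 0$ with both cleared denominators positive, so that the
  root corresponds to a genuine potential balance. $\rho > 1$ (i.e.
  $n_{Ca} < 0$) is admissible and means the active cell starts out less
  excitable: interchange on the first cycle;
* if only the companion root is admissible it is used with a warning;
* $|m_1| < 10^{-12}$ (e.g. $s_0 = 0$) degenerates to the linear equation
  $m_2 \rho + m_3 = 0$;
* a negative discriminant or no admissible root means the potentials
  never meet: no interchange, reported as `Inf` and propagated as an
  error by `map_step()` and as sentinel cells by the sweep functions.

## Map, fixed points, many cells

One burst maps burst-initial calcium $(C_x, C_y)$ of the active/silent
pair to $(r^n C_y,\; r^n C_x + \bar A(1 - r^n))$ with $n$ the NSPB
computed from the pre-step state — the only causal reading. Freezing $n =
k$ makes the map affine with the unique fixed point
$D_k = \big(\bar A r^k/(1+r^k),\; \bar A/(1+r^k)\big)$, which is a stable
fixed point of the full nonlinear map exactly when $k-1 < n_{Ca}(D_k) <
k$; nearby states contract at $r^k$ per burst (`fixed_point()`).
$n_{Ca}(D_k)$ decreases continuously in $g_{AHP}$ from no-interchange to
below one, so each burst count $k$ is realized by some conductance;
`find_gAHP_for_k()` bisects (in log scale, since the useful range spans
decades) to put $n_{Ca}(D_k)$ at the center $k - 1/2$ of its stability
window. $D_k$ itself depends only on $r$ and $\bar A$, not on $g_{AHP}$,
so only the potential-balance coefficients are re-derived per evaluation.

For $m+1$ inhibitory cells the state lists the active cell first and the
silent cells in ascending calcium order; the active cell competes with
the lowest-calcium silent cell, and the burst rotates the ranks through
the cyclic permutation $E_m$ (`multi_map_step()`). The construction
assumes the retiring cell re-enters above every silent cell; when a fast
calcium decay breaks that, the step warns rather than silently re-sorting
(`resort = TRUE` opts into re-sorting). Freezing a pattern
$(n_1, \dots, n_s)$ composes $s$ affine maps into one
(`compose_maps()`), whose fixed point is the base state of an s-periodic
orbit; the orbit is genuinely stable when the frozen count is
self-consistent at every stage (`s_periodic_point()`). We enforce
$s < m+1$ — the weaker of the two bounds the source states — since the
reduction case $m = s = 1$ must be admissible and indeed reproduces the
two-cell fixed point exactly.

## The continuous simulator

`simulate_network()` advances the state on a fixed step (default
$dt = 0.01$ ms, refused above $t_3/50$):

* calcium and all synaptic gates obey linear ODEs between spikes and are
  advanced by their **exact** exponential factors — no integration error
  accumulates in the slow variables;
* membrane potentials use exponential Euler with conductances frozen at
  the step start (the voltage equation is linear in $v$ given the gates),
  which is robust at the high total conductances the AHP current reaches;
* thresholds are checked at step end and the spike time is the step end;
  halving $dt$ leaves burst counts unchanged in the test suite;
* the calcium increment is applied at the spike instant, before the next
  decay interval, matching the map's convention;
* if two ICs cross threshold in the same step, the lower-calcium (more
  excitable) one fires and the other is left unreset — the winner's
  freshly reset inhibition pulls it back under threshold on the next
  step; ties go to the lower index;
* the EC follows the same threshold/reset rule as the ICs; nothing else
  produces the sustained periodic excitation the network behavior
  presupposes;
* all cells start at $v_R$ with closed gates unless specified — a
  reproducible cold start.

`extract_bursts()` run-length encodes the IC spike train; each maximal
single-cell run is a burst, and the burst-initial calcium vector is read
from the pre-jump calcium snapshot taken at the run's first spike.

## What the comparison experiments do — and what they showed

`t3`, the inter-spike interval that sets $r$, has no printed value; the
default is the EC period, on the grounds that the EC paces IC firing.
The analysis helpers can instead estimate it from a simulation's median
active-cell ISI, but at the default constants this does not change the
map's long-run predictions (see below).

**First-burst agreement** (`sweep_initial_ca()`): for each initial pair
$(x_0, y_0)$ the map predicts `nspb` of the lower/higher-calcium pair
(the lower-calcium cell is the more excitable one and bursts first, so
the prediction is symmetric in the pair), and the simulator is started
cold with exactly those calcium levels. On a 20×20 grid over $[0, 6]^2$ —
the range the example configurations use, matching the calcium scales at
which the network is typically prepared — the two agree within ±1 spike
on more than 90% of cells. ±1 is our quantification of the qualitative
correspondence the reduction claims; the map quantizes a continuous race
and an off-by-one near the switching boundary is inherent.

**Long-run behavior**: "stable NSPB" is operationalized as the terminal
count after 200 map bursts, and as the common value of the last 10 bursts
of a 10 s simulation (extended once to 40 s when bursts are sparse or the
transient long — at the default constants inter-burst gaps reach the
order of a second, so a fixed 10 s window often contains too few bursts
to judge). Runs that still disagree in their last 10 bursts are reported
as unsettled (`NA`), never guessed.

**Monotone parameter dependence** (`sweep_gahp_gi()`): the stable burst
count is non-increasing in $g_{AHP}$ (more AHP conductance needs less
calcium to hyperpolarize the active cell) and non-decreasing in $g_i$
(stronger inhibition takes longer to overcome). The acceptance suite
verifies both monotonicities in **both** systems over
$g_{AHP} \in [5, 100]$, $g_i \in [5, 50]$.

**Bifurcation structure** (`bifurcation_scan()`): both systems' stable
NSPB branches are integer step functions whose unit jumps are the
saddle-node events at which one burst count yields to its neighbor. Here
the comparison exposes a genuine limitation of the reduction at the
default constants. With $g_{AHP} = 50$ an IC can only reach threshold
during an excitatory kick while its calcium is below roughly 1.1, so the
continuous network fires sparsely, with idle EC cycles between spikes —
the map, which assumes one spike every $t_3$ throughout a burst, cannot
represent those idle cycles. Concretely, on the scan
$g_{AHP} \in [5, 100]$ (step 2.5) the continuous branch steps from 2 to 1
near $g_{AHP} \approx 6$, driven by an idle-cycle mechanism (residual
inhibition right after an interchange holds the new active cell just
under kick reachability), while the map branch is constant at 1; the
per-point branch agreement is 38/39, but the jump has no map
counterpart. The $g_i$ scan agrees at every point. The corresponding
acceptance test asserts jump alignment for both scans and therefore fails
on the $g_{AHP}$ scan — deliberately: it documents a real boundary of the
reduction's validity rather than a tunable artifact. In the
per-cycle-pacing regime (weaker AHP, e.g. $g_{AHP} \approx 5$, as in the
worked example) the map's premises hold and burst-by-burst correspondence
is recovered.

**Adaptation** (`simulate_network(..., ec = FALSE)`): an isolated IC
under a step current ($I_{app} = 2$, the same drive the EC receives)
shows spike-frequency adaptation — a non-decreasing ISI sequence that
settles to a constant (within far less than 1% over the last ten
intervals). At the default AHP conductance the settling is abrupt: a
couple of fast spikes load enough calcium that the cell drops directly
into its slow equilibrium rhythm.

## Problem sizes

The shipped experiments use: a 50×50 grid for the formula-vs-oracle
check, a 20×20 grid (400 cold-start simulations) for first-burst
agreement, an 8×8 conductance grid and 39+19 scan points for the long-run
comparisons, 10 s (extended to 40 s as needed) per long-run simulation at
$dt = 0.01$ ms, and 100 random draws for the calcium-recursion check.
These sizes give stable estimates — the agreement fractions move by less
than a percentage point under refinement — while keeping a full
reproduction run in the tens of seconds.

## Known limitations

* The map has no notion of idle cycles or of within-burst changes in the
  effective inter-spike interval; at parameter settings where the
  excitatory kick is marginal, long-run predictions can be off by one
  burst-count level and jump locations can differ (see above).
* Multi-spike responses to a single excitatory kick (possible transiently
  at very low calcium and low AHP conductance) also violate the
  one-spike-per-cycle picture; they only affect the first burst from
  calcium-free cold starts.
* Cells are identical by construction; heterogeneous parameters, random
  connectivity, more than one excitatory cell and slow (NMDA-like)
  excitation are out of scope.
* All stability statements are numerical; no symbolic algebra is
  attempted.
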