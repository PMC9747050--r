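---
title: "Model and methods: theta-nested fast oscillations in fast-spiking interneuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ingsim)
```

## Scope

`ingsim` simulates networks of 100 fast-spiking, parvalbumin-positive (PV+)
inhibitory interneurons of medial entorhinal cortex layer 2/3 under a
theta-modulated optogenetic (channelrhodopsin-like) drive, and analyzes the
fast (~150-200 Hz) oscillations that nest within each theta cycle — the
interneuronal-network-gamma (ING) regime, in which mutual inhibition alone,
without excitatory feedback, paces the fast rhythm. The package covers the
single-cell model, the calibrated synthetic population, chemical and
electrical coupling, the network integrator, pulse-coupled phase-response
theory, and the wavelet/circular-statistics analysis chain.

## Single-cell model

Each cell is a single compartment with five state variables, the membrane
potential $V$ and four gating variables $m,h,n,a$:

$$C_M \frac{dV}{dt} = I_{app} + g_{Na} m^3 h (E_{Na}-V)
 + g_{Kv1} a^4 (E_K-V) + g_{Kv3} n^4 (E_K-V) + g_L (E_L-V)
 + I_{syn} + I_{gap} + I_{ChR}$$

with $E_{Na} = 50$ mV, $E_K = -90$ mV, and every conductance driving $V$
toward its own reversal. Units are mV, ms, nS, pA, pF throughout
(nS·mV = pA, pA/pF = mV/ms). The two delayed rectifiers divide the labor
typical of fast-spiking cells: the low-threshold Kv1 current ($a^4$, tens of
nS) sets the cutoff frequency below which repetitive firing cannot be
sustained (type-2 excitability), and the high-threshold Kv3 current ($n^4$,
hundreds of nS) drives the sub-millisecond repolarization that permits
firing at hundreds of Hz. Slow A-type adaptation currents are deliberately
omitted.

Activation gates use

$$\alpha_x(V) = \frac{k_1 (\theta_x - V)}{e^{(\theta_x - V)/\sigma_1} - 1},
\qquad \beta_x(V) = k_2 e^{V/\sigma_2},$$

with $dx/dt = \alpha_x (1-x) - \beta_x x$, and the removable singularity at
$V = \theta_x$ evaluated analytically as $k_1 \sigma_1$.

### The inactivation gate

The constants of the $h$ gate cannot be used in the activation-gate forms:
the $\alpha$ formula with $\sigma_1 = -20$ mV is negative at every voltage,
which makes any literal reading of the $h$ equation divergent. `ingsim`
therefore assigns the $h$ gate the functional forms of the original
Hodgkin-Huxley $h$ gate, with the same tabulated constants:

$$\alpha_h(V) = k_1 e^{V/\sigma_1} = 0.012\, e^{-V/20}, \qquad
  \beta_h(V) = \frac{k_2 (\theta_h - V)}{e^{(\theta_h - V)/\sigma_2} - 1},$$

i.e. an exponential recovery rate (compare Hodgkin-Huxley's
$0.07 e^{-V/20}$ — the same 20 mV slope factor) and a closing rate that
grows with depolarization. This is also exactly the scheme of the
Erisir-type fast-spiking interneuron models. It was adopted after testing
the alternative assignments: swapping which printed form serves as the
opening rate either destabilizes forward Euler at the model's 0.01 ms step
and produces sub-0.1 ms half-widths and ~56 mV amplitudes (outside the
calibration bands), or abolishes spiking through depolarization block. The
chosen variant places the steady-state inactivation midpoint a few mV below
$\theta_h$, is stable at dt = 0.01 ms, and reproduces the calibration
targets: ~40 mV spike amplitude above the -30 mV threshold, ~0.2-0.3 ms
half-width, ~20 mV AHP, 166-168 Hz firing at a constant 7 nS drive with a
free-running period within 1% of 5.97 ms.

### Action-potential features

Spikes are detected at upward crossings of -30 mV (interpolated between
steps, 1 ms lockout); -30 mV is also the phase-zero reference of the
phase-response analysis. Amplitude and half-width are referenced to this
fixed threshold. The after-hyperpolarization depth is instead measured from
the phase-plane spike onset (where the upstroke first exceeds 20 mV/ms,
around -50 mV) down to the post-spike trough: referencing the AHP to
-30 mV would report ~40 mV for cells whose trough sits near -70 mV, twice
the experimentally quoted ~20 mV, while the onset-referenced value
reproduces it. The mixed convention is what reproduces all three printed
feature centers simultaneously and is stated on `spike_features()`.

## Synthetic population

`sample_candidates()` draws 100 passive vectors (membrane time constant
3-7 ms, input resistance 50-150 MOhm, leak reversal -80..-60 mV; all
uniform) and 100 active vectors ($g_{Na}$ 6000-35000 nS, $g_{Kv1}$
15-150 nS, $g_{Kv3}/g_{Na}$ 0.03-0.05, and the four gate half-points) and
crosses them into 10,000 candidates, with $C_M = \tau_m / R_{input}$ and
$g_L = 1/R_{input}$.

`select_population()` screens candidates in a seeded random order: rheobase
is found on the experimental 25 pA grid (bracketing plus binary search,
exploiting the monotonicity of sustained firing in current for these
type-2 cells), the cutoff frequency is the steady rate at rheobase (mean
inverse ISI over the last half of a 500 ms step), and AP features are
measured at rheobase + 100 pA. Candidates pass if amplitude lies in
30-55 mV, half-width in 0.15-0.5 ms and AHP in 10-30 mV — bands centered
on the quoted experimental values, since only approximate centers are
given. The published selection algorithm is not specified; we use greedy
stratified sampling over a 10 x 10 grid of (cutoff, rheobase) bins, visited
round-robin, which maintains the spread of both quantities without an
unstated optimizer. Screening stops once 1.5 n candidates have passed
(~12% of candidates pass), making the build a pure function of the seed at
a desk-scale cost (~1.5 min).

## Coupling

**Chemical synapses** are GABA$_A$ conductances with a biexponential
waveform, decay $\tau_1 = 2$ ms, rise $\tau_2 = 0.3$ ms, normalized to unit
peak by the closed form $t_{peak} = \frac{\tau_1\tau_2}{\tau_1-\tau_2}
\ln(\tau_1/\tau_2)$, so that the synaptic weight is the peak conductance.
Reversal -75 mV models hyperpolarizing, -55 mV shunting inhibition.
Homogeneous networks use exactly 36 inputs per cell of 1.65 nS at a fixed
delay; heterogeneous networks connect each ordered pair with probability
0.36, draw weights lognormally (median 1 nS, $\sigma_{\log} = 1$; the
printed parameterization is read as natural-log scale) and delays uniformly
on 0.6-1.0 ms.

**Short-term depression** follows the depletion-only Tsodyks-Markram model:
the available fraction $x$ recovers as $1-(1-x_0)e^{-t/\tau_r}$
($\tau_r = 100$ ms) and each presynaptic spike transmits with amplitude
proportional to the pre-spike $x$, then depletes $x \leftarrow 0.7 x$
($U_{SE} = 0.3$). Because all synapses of one presynaptic cell see the same
spike train, $x$ is tracked per presynaptic neuron. Under periodic firing
at period $T$ the pre-spike value has the closed form
$x^* = (1-e^{-T/\tau_r})/(1-0.7 e^{-T/\tau_r})$, used as a test oracle.

**Gap junctions** use the candidate-partner procedure: each neuron draws 27
candidate partners; each new pair receives a bidirectional conductance,
1.2 nS with probability 0.25 (strong mode) or the positive half of a
zero-mean Gaussian with sd 0.4 nS (weak mode). A pairwise-Bernoulli(0.27)
construction is available as an alternative. Because passive properties
were measured with gap junctions intact, each accepted junction's
conductance is subtracted from the leak of both endpoints
(`apply_gap_compensation()`), keeping $R_{input} \approx 1/(g_L + \sum
g_{gap})$ unchanged; junctions that would push a leak below the 1.5 nS
floor are dropped, in draw order. The leak reversal is then reset to
preserve the isolated resting potential exactly: with the rest $V_r$
bisected to 0.01 mV from the steady-state current balance,
$E_L' = V_r + (g_L/g_L')(E_L - V_r)$. A caveat discovered in testing: cells
with a sizable persistent-sodium window current that are compensated down
to the floor can acquire leak reversals far below physiological values
(the leak then acts as a standing hyperpolarizing current), and their
quiescent state can become marginal. Network initialization therefore
always starts from the numerically computed resting potential rather than
from $E_L$.

**Theta drive.** The printed drive (a pure sine scaled by 14 nS)
contradicts the stated 0-14 nS range and the 7 nS "midpoint" used for the
phase-response work, so the drive is implemented as the raised cosine
$g(t) = \frac{g_{max}}{2}(1 - \cos 2\pi f t/1000)$: continuous, spanning
$[0, g_{max}]$, minimum at the cycle start, peak at the half-cycle. Theta
phase is defined analytically from this waveform with 0 at the conductance
peak, range $(-\pi, \pi]$.

## Network integration

`run_network()` advances all neurons by forward Euler (the method used to
produce the reference results; classical Runge-Kutta agrees on the
free-running period to <1% and is available for single-neuron runs). Each
presynaptic spike schedules a conductance onset at the first step with
$t \ge t_{spike} + \delta$, scaled by the depression state at spike time;
per-postsynaptic-cell conductances are maintained as two exponentially
decaying accumulators (decay $\tau_1$ and $\tau_2$), so simultaneous inputs
superpose linearly before the driving-force multiplication. Gap currents
use same-step voltages, consistent with the explicit scheme, and conserve
charge pairwise by construction. dt = 0.01 ms suffices for all runs without
heterogeneous gap junctions; with them the step is reduced (5e-4 ms for
production runs; desk-scale analyses use 2e-3 ms, checked once against
5e-4 ms for a <2% shift of the dominant frequency). A trajectory exceeding
|V| > 200 mV aborts with a diagnostic naming the neuron and step.

The population-frequency estimator (the reference text does not state one):
population spikes are clusters of at least half the network within 1 ms,
and the frequency is the median inverse interval between successive
population spikes after a 50 ms transient.

## Phase-response analysis

`compute_prc()` perturbs the free-running cell (constant 7 nS drive, the
theta midpoint) with the compound inhibition it would receive in global
synchrony — 36 unitary conductances at once — at 100 equally spaced phases,
phase 0 at the -30 mV crossing. First-order resetting
$f_1(\theta) = (P' - P_i)/P_i$ is the normalized change of the perturbed
cycle (delays positive); $f_2$ is the same for the following cycle. In
global synchrony with conduction delay $\delta$, inputs arrive at the
locking phase $\theta = \delta/P_i$; the locked period is
$P_i(1 + f_1(\theta))$, and a perturbation of one neuron decays per cycle
by $1 - f_1'(\theta)$, so a slope near one is maximally stabilizing while a
negative slope (short delays with shunting inhibition) is destabilizing.
First-order prediction is the default; the second order can be added
(`order = "1+2"`), but the first-order prediction is the one that matches
the simulated networks (hyperpolarizing: predicted 105.9 Hz vs simulated
109.4 Hz; shunting at 1.6 ms: predicted 233.5 Hz vs simulated 236.7 Hz —
both within the 5% consistency band).

Two conventions are worth stating. The locking phase is reported as
$\delta/P_i$ (0.8/5.97 = 0.134), not the rounded figure sometimes quoted
alongside it. And the constant-drive PRC-validation networks run without
short-term depression: depression at a ~110 Hz steady rhythm would scale
the compound input by ~0.25 and the full-strength PRC would no longer
describe the network; the depression-free simulation is what the
full-strength prediction matches. Theta-driven heterogeneous experiments
keep depression on.

For the shunting PRC, `prc_sign_change()` reports the interpolated zero
crossing of $f_1$, and `prc_slope_reversal()` the phase where the slope of
$f_1$ changes sign — the PRC minimum, which in this model sits at phase
~0.12, very near the action-potential trough (~0.14): early shunting
inputs land while the membrane is above the -55 mV reversal and act
hyperpolarizing, later ones land in the AHP and advance the next spike. In
this reconstruction $f_1$ itself is negative (phase advances) from phase 0
through ~0.78; how early the advance region begins depends sensitively on
the timing of the late downstroke relative to the synaptic rise, one of the
waveform details that the published constants underdetermine (see
Limitations).

## Oscillation metrics

The population rate is the 0.1 ms-binned spike count, flat-window smoothed,
normalized to spikes/s per neuron (its integral recovers the spike count
exactly). The scalogram is a Morlet continuous wavelet transform of order
$\omega_0 = 5$, per-frequency width $\omega_0 f_s / (2\pi f)$ samples,
frequencies 50 to 449 Hz in 3 Hz steps, power the squared coefficient
modulus with no cross-scale normalization; the FFT-based convolution is
verified in the tests against direct correlation sums. Per theta cycle the
analysis reports the maximum power, the frequency at that maximum, and the
theta phases where the power envelope crosses 0.3 x the maximum power from
below (onset) and from above (offset). The first four cycles are discarded
as transients, and cycles whose wavelet support would cross the simulation
boundary are excluded (a cone-of-influence guard; the reference is silent
on edges, and the simulated duration includes one guard cycle). The 0.3
threshold is referenced to the maximum power of the run (or network
instantiation); for comparisons across conditions — e.g. "no nested
oscillations with shunting synapses" — a threshold shared across the
compared runs must be used, and `cycle_metrics(threshold_power =)` exposes
it, since a within-run threshold retains cycles by construction.

Circular statistics use the mean resultant vector: circular mean = its
argument, circular SD = $\sqrt{-2\ln\bar R}$ (the quoted dispersion values
are treated as this standard quantity; the reference does not name its
measure). Equivariance under rotation and correct wrapping at $\pm\pi$ are
property-tested. Hypothesis testing of phase differences (Watson's U2) is
out of scope; the pipeline reports means and dispersions only.

## Experiment drivers and scale

`run_experiment()` reproduces the study's conditions from a declarative
config: homogeneous/heterogeneous populations, hyperpolarizing/shunting
reversal, gap-junction mode (none, calibrated-with-compensation, or strong
2 nS uncompensated — requesting compensation of the 2 nS case is refused,
as the leak cannot absorb it within the physiological input-resistance
range), depression on/off, delay mode and drive. Desk scale is 3 network
instantiations x 8 retained theta cycles (the production ensembles are
30 x 30); ensemble standard errors are therefore computed over
network-level circular means, because cycles within one network are
strongly correlated. With these sizes the complete test suite, including
the calibrated-population build and nine finely stepped (dt = 2e-3 ms)
theta runs, completes in a few minutes on one core.

## Reproduced quantities and known limitations

At desk scale the package reproduces, from scratch: the representative
cell's 168 Hz / 5.97 ms anchor (within 1%); the hyperpolarizing PRC
prediction of 106 Hz at a 0.8 ms delay (105.9 Hz) and the simulated 110 Hz
(109.4 Hz) with one-cycle convergence from random initial conditions;
shunting desynchronization at 0.8 ms from a single offset neuron and
synchronization at 1.6 ms; the rescue of theta-nested 150-200 Hz
oscillations in heterogeneous hyperpolarizing networks by calibrated gap
junctions, their absence with shunting inhibition, and tight
synchronization with strong uncompensated junctions; and the
depression-induced phase preference (pooled onset/offset -2.19/-1.27 rad
vs the quoted -2.21/-1.33).

Known limitations, all traceable to waveform details that the published
constants do not pin down (the exact inactivation-gate rates): the
simulated shunting network at 1.6 ms runs ~2% slow (236.7 vs 241.5 Hz) and
its first-order prediction ~5% slow (233.5 vs 247 Hz); the shunting PRC's
zero crossing and the AP trough phase sit ~0.04 of a cycle earlier than
quoted (the slope-reversal-near-trough relationship itself is reproduced);
the hyperpolarizing second-order resetting reaches ~6% near phase 0.9
(quoted <3%); and without depression our networks remain synchronized past
the theta peak instead of desynchronizing above ~250 Hz before it, so the
no-depression offset phase differs while the with-depression phases and
the strict depression-shifts-offset-earlier ordering are reproduced. The
synthetic population emulates the calibrated parameter distributions, not
raw recordings; passing tests demonstrate fidelity to the stated model,
not to new experimental data.
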