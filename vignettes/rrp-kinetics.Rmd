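---
title: "Estimating priming, depriming, and fusion rates of the readily releasable pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating priming, depriming, and fusion rates of the readily releasable pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrpkin)
```

## The model

Synaptic vesicles that are docked and molecularly primed form the readily
releasable pool (RRP). `rrpkin` describes this pool with a one-compartment
model: vesicles enter by priming at rate $k_1$ (vesicles/s) from an
effectively unlimited upstream pool, and each primed vesicle independently
leaves by depriming (rate $k_{-1}$, 1/s) or by spontaneous fusion (rate
$k_f$, 1/s),

$$\frac{dR}{dt} = k_1 - (k_{-1} + k_f)\,R(t),$$

with the closed-form solution
$R(t) = R_\infty + (R_0 - R_\infty)e^{-(k_{-1}+k_f)t}$ and steady state
$R_\infty = k_1/(k_{-1}+k_f)$. The steady-state miniature (mEPSC) rate is
$r_\mathrm{mini} = k_f R_\infty$.

Three observables identify the three rates in a cell held in voltage clamp:

1. the **RRP charge** released by a hypertonic sucrose pulse, which
   transiently drives the per-vesicle fusion rate up by a factor
   $N_\mathrm{suc}$ (for 0.5 M sucrose, $N_\mathrm{suc} > 5000$);
2. the **sucrose plateau**: once the pool has drained, sustained release is
   rate-limited by priming, so the plateau release rate approaches $k_1$;
3. the **resting mini rate**, which divided by the pool size gives $k_f$.

The closure is $k_f = r_\mathrm{mini}/R$, $k_1$ from the plateau, and
$k_{-1} = k_1/R - k_f$. A negative implied $k_{-1}$ is flagged, never
clipped: it signals observables inconsistent with a single pool.

### Finite sucrose drive and depletion corrections

With a finite $N_\mathrm{suc}$, the plateau is not $k_1$ itself but
$k_f N_\mathrm{suc} k_1 / (k_{-1} + k_f N_\mathrm{suc})$.
`estimate_rates_finite_nsuc()` solves the resulting two-equation system in
closed form and converges to the saturating closure as
$N_\mathrm{suc} \to \infty$. A sweep over the assumed $N_\mathrm{suc}$
(`estimate_rates_finite_nsuc()` is continuous and monotone in it) shows the
estimates of wildtype-like conditions depend more on the assumed value than
those of mutants with elevated resting $k_f$, because the latter are pushed
deeper into saturation by the same fold-increase.

The integrated sucrose transient also does not equal the standing pool
exactly: it measures $(R_0 - R_\mathrm{ss})\,k_f'/(k_{-1}+k_f')$ with
$k_f' = k_f N_\mathrm{suc}$, where $R_\mathrm{ss}$ is the small residual
pool sustained during the application (about 4% low for wildtype-like rates
at $N_\mathrm{suc} = 5000$). `estimate_rates_depletion()` removes this bias
by fixed-point iteration between the rate closure and the implied initial
pool; on noiseless forward-model observables the recovery is exact, which
the test suite verifies.

## Trace analysis

**Variance–mean baseline.** Hypertonic solutions shift the leak current, so
the raw plateau confounds synaptic release with a baseline change. Synaptic
release is shot noise: its variance grows linearly with its mean. The trace
is detrended with a 3-ms running average (short enough to track the
depletion transient, long enough to retain event-scale fluctuations), the
variance and mean are computed in 50-ms bins across the application, and a
line fitted to the variance–mean plot is back-extrapolated to the variance
of a quiescent pre-application stretch; the crossing current is the
corrected baseline. Because bin-variance estimates have sampling error
proportional to the variance itself, the line is fitted by iteratively
reweighted least squares with weights $1/\widehat{\mathrm{var}}^2$; plain
OLS would be dominated by the largest transient bins and systematically
steepen the slope. The quiescent reference variance is estimated robustly
from median absolute successive differences (insensitive to sparse events)
and scaled by the small factor the detrending removes from white noise. If
the fitted slope is not significantly positive in the shot-noise direction
the function falls back to the raw pre-application baseline and flags it.

**RRP charge.** The transient charge is the integral of the
baseline-subtracted current minus the plateau component. Two details
matter: (i) the corrected-baseline error cancels exactly in this quantity,
because it enters the integral and the plateau subtraction with opposite
signs; (ii) the leak shift develops over the solution-exchange time
constant (default 0.05 s, the speed of local perfusion onto an autaptic
micro-island), so integrating against a constant corrected baseline loses
$\mathrm{shift}\times\tau_\mathrm{exchange}$ of charge, which is restored
using the measured pre-application leak level.

**Mini detection.** Events are counted by Wiener deconvolution with a
unitary-event template (difference of exponentials, rise 0.5 ms, decay
3 ms): the detrended trace is deconvolved back to a near-impulse train and
local maxima above 6 noise SD, separated by at least 2 ms, are events.
Deconvolution resolves overlapping events far better than peak-finding on
the raw waveform, and the residual loss from the enforced 2-ms separation
is removed with the non-paralyzable dead-time correction
$r = r_\mathrm{obs}/(1 - r_\mathrm{obs}\tau)$. Counting validated against
generated event trains is accurate to well under 1% up to roughly 40
events/s and degrades gracefully above.

**Plateau modes.** `analyze_cell()` converts the plateau to a release rate
two ways. For sparse sustained release it counts plateau fusion events
directly — a baseline-free measurement. For dense release (wildtype-like,
hundreds of vesicles/s) counting saturates and the baseline-subtracted
plateau current divided by the unitary charge is used instead. The default
`"auto"` mode selects counting whenever the observed rate keeps the
dead-time correction small ($r_\mathrm{obs}\tau \le 0.1$). This hybrid is
why depriming rates of strongly saturated mutants are recovered with little
bias: their plateau (a few pA) is smaller than the residual uncertainty of
any baseline estimate, but their event rate is easily countable.

**Trains.** `train_summary()` back-extrapolates a linear fit to the
cumulative evoked charges over the late, steady part of a high-frequency
train; the intercept at time zero estimates the pool the train drew down
(RRP$_\mathrm{ev}$) and the slope the ongoing priming rate. Stimulus times
are placed at the end of each interstimulus interval so that a train
releasing only newly primed vesicles extrapolates to zero and is flagged
invalid (insufficient depletion) rather than returning the first response
as a pool. The back-extrapolated pool systematically excludes vesicles
primed during the depleting phase — the familiar reason train pools
underestimate sucrose pools — and with low release probability the method
is unreliable, which the validity flag reports. The paired-pulse ratio uses
responses 1 and 2 by default (25-ms interval at 40 Hz), on amplitudes when
supplied, otherwise on charges.

## The synthetic-data generator

`simulate_pool()` is an exact stochastic simulator of the one-pool
birth–death chain: priming is a Poisson source of intensity $k_1$ and every
vesicle carries independent depriming and fusion hazards. The time-varying
fusion hazard across the sucrose exchange ramp is handled by thinning
against a piecewise-constant upper bound, so no time discretization enters;
event statistics are exact. Steady-state initial pools are drawn from the
stationary Poisson law (mean $k_1/(k_{-1}+k_f)$) rather than set to the
deterministic mean, so no burn-in is needed and occupancy statistics (Fano
factor 1) are correct from $t = 0$.

`render_trace()` converts fusion events to current: baseline + ramped leak
shift + one inward unitary waveform per event + Gaussian noise. Defaults —
20 kHz sampling, 3 pA noise SD, 0.05 pC unitary charge, 0.5/3 ms
rise/decay, 30% amplitude CV (gamma-distributed) — are typical AMPA-mEPSC
and whole-cell recording scales; none is treated as ground truth by the
analysis except the unitary charge, which by design convention is the
vesicle/charge conversion factor.

What the generator deliberately omits: postsynaptic receptor kinetics and
saturation, dendritic filtering and series-resistance artifacts, vesicle
sub-pools (super-priming), calcium dynamics, and rundown. Passing
recovery tests therefore demonstrates that the estimation chain inverts the
one-pool generative model at realistic signal-to-noise — not that real
recordings are free of these further complications.

`simulate_train()` draws binomial release (probability $p_\mathrm{vr}$ per
primed vesicle per stimulus, with optional decaying facilitation) and
evolves the pool exactly between stimuli.

## Energy landscapes

Under the Arrhenius relation $k = A e^{-E_a/RT}$ with the prefactor $A$
assumed unchanged between conditions, a rate ratio converts to a barrier
difference $\Delta E_a = RT\,(\ln k_\mathrm{ref} - \ln k_\mathrm{mut})$.
Applying this sequentially to priming, depriming, and fusion rates — with
the pre-primed state anchored at equal energy in both conditions — yields
offsets of the priming transition state, the RRP state, and the fusion
transition state (`build_landscape()`). Only *differences* are ever
emitted: absolute barrier heights would require the unknown prefactor. The
prefactor assumption is most defensible for fusion (a conformational change
in a preformed complex); priming may involve collision rates, so priming
offsets carry a caveat note in the result. Energies are reported per
molecule ($k_BT$) and per mole (kJ/mol, with $RT = 2.479$ kJ/mol at
298.15 K); the temperature default reproduces that convention. Because
barrier comparisons can be made on raw rates (assuming unchanged pool size)
or on pool-normalized rates, both inputs are accepted — the caller chooses
which rates to supply, and the units columns make the choice explicit.

## Electrostatic triggering model

The fusion barrier is sensitive to the net charge $Z$ on the SNARE-complex
surface. `charge_model()` implements a saturating log-linear curve

$$k(Z) = \frac{K k_0 e^{\beta Z}}{K + k_0(e^{\beta Z} - 1)},
\qquad K = f\,k_\mathrm{max},$$

with $k_0$ the per-vesicle rate at $Z=0$ (default $2.9\times10^{-4}$ 1/s),
ceiling $K = 0.030 \times 6000 = 180$ 1/s, and sub-saturated sensitivity
$\beta$ (kBT per charge). Evoked release follows the same curve translated
by 35 positive charges. The exact historical parameterization of this curve
is not reproducible from published constants alone; this form is chosen to
honor the three published anchors and is recorded in the object. Two open
interpretation points are resolved as follows: the fraction $f$ is read as
a ceiling scaling (the reachable fraction of the maximal rate), and $\beta$
defaults to $\ln(22.47)/5.6 \approx 0.556$ — the value at which a
22.47-fold sub-saturated rate ratio corresponds to a separation of 5.6
charges. That default is a calibration, not a measurement, and is a plain
argument. The inverse `charge_at_rate()` is exact (closed form) on the open
range $(0, K)$, so measured rates can be placed on the charge axis by
interpolation; `downscale_peak_rate()` rescales a peak release rate by an
eEPSC amplitude ratio for conditions where deconvolution is unreliable.

## Numerical choices and degenerate inputs

* Rates must be non-negative; steady-state quantities require
  $k_{-1}+k_f>0$; energy comparisons require strictly positive rates.
  Invalid table rows are rejected with a message and reported, not dropped.
* The depletion fixed point iterates to $10^{-10}$ relative tolerance
  (typically 3–5 iterations).
* The double-exponential fit of cumulative evoked charge falls back to a
  single exponential (fraction 1, flagged) when the two time constants are
  within 1.5-fold or either component is below 1% of the total.
* FFT convolutions pad to highly composite lengths; the discretized mini
  kernel is normalized so one event integrates to exactly one unitary
  charge.
* All randomness flows through explicit per-cell seeds; nothing reads or
  mutates the global RNG state silently (`withr::with_seed`).

## Validation scale and limitations

The bundled validation (test suite and the acceptance script) simulates 50
cells per condition — each a 7-s sucrose recording (1.5 s pre, 5 s
application at $N_\mathrm{suc}=5000$, 0.5 s post) plus a 60-s spontaneous
segment at 20 kHz — for the wildtype and the two SNAP25 disease-mutant rate
presets with strongly elevated spontaneous fusion (V48F, D166Y), and
requires the mean recovered $k_1$, $k_{-1}$, and $k_f$ to fall within three
standard errors of the generating values. Known residual limitations:
wildtype $k_1$ retains a small negative bias (about 2%) from the
variance–mean extrapolation, the event counter undercounts beyond roughly
100 events/s faster than its dead-time model predicts, and back-extrapolated
train pools are structurally smaller than sucrose pools. The energy-domain
and electrostatic modules are deterministic arithmetic and are verified
against hand-computed values exactly.
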