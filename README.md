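# rrpkin

Kinetics and energy landscapes of synaptic vesicle priming and fusion.

Neurotransmitter release draws on a readily releasable pool (RRP) of primed
vesicles. Patch-clamp experiments probe this pool indirectly — spontaneous
miniature EPSC rates, the charge released by hypertonic sucrose pulses, and
responses to high-frequency action-potential trains. `rrpkin` turns those
observables into the rate constants of a one-pool kinetic model, compares
conditions (e.g. disease mutants of the SNARE protein SNAP25 against
wildtype) in the energy domain via the Arrhenius relation, and relates
per-vesicle fusion rates to the electrostatics of the SNARE-complex surface.
It is written for cellular neurophysiologists analyzing autaptic-culture
recordings, and for anyone who wants a fully simulated, testable version of
this analysis chain.

## The model

The RRP is a single compartment filled by priming and drained by depriming
and spontaneous fusion:

```
dR/dt = k1 − (k−1 + kf)·R(t)
```

with `k1` in vesicles/s and `k−1`, `kf` per-vesicle rates (1/s). At steady
state `R∞ = k1/(k−1 + kf)` and the mini rate is `kf·R∞`. A sucrose pulse
multiplies `kf` by `N_suc` (>5000 for 0.5 M), emptying the pool; the
transient charge measures the pool, the plateau measures the priming rate,
and `kf = mini rate / pool` closes the system. Between two conditions, rate
ratios convert to energy-barrier differences,
`ΔEa = RT·(ln k_ref − ln k_mut)`, giving a comparative energy landscape of
the priming transition state, the RRP state, and the fusion transition
state.

The package also ships an exact stochastic simulator (Gillespie-type
thinning on the birth–death chain) that renders vesicle-pool trajectories
as realistic 20-kHz current traces, so every analysis stage is testable
against known ground truth without any recording.

## Worked example

Energy landscape of the SNAP25 D166Y epilepsy mutation against its
wildtype, from the bundled reference rate constants:

```r
library(rrpkin)
library(dplyr)

tab <- reference_rates() |>
  filter(set == "D166Y") |>
  select(condition, k1, k_minus1, kf)

steady_state_rrp(tab$k1, tab$k_minus1, tab$kf)
#> [1] 4091.3075  583.1012          # vesicles: the mutant pool is ~7x smaller

build_landscape(tab, reference = "WT")
#>   condition reference d_priming_ts_kbt d_rrp_kbt d_fusion_ts_kbt ...
#> 1     D166Y        WT            2.496     1.164          -3.319
```

Read: relative to wildtype, D166Y raises the priming transition state by
2.50 kBT (slower priming), destabilizes the RRP state by 1.16 kBT, and
lowers the fusion barrier by 3.32 kBT relative to the pre-primed state —
a gain-of-function for spontaneous fusion coexisting with a priming defect.
`decompose_rrp_change(...)` splits the 7-fold pool reduction into the three
rate contributions, and `autoplot()` draws the landscape.

A full synthetic round trip — simulate cells, analyze the traces, recover
the rates:

```r
cfg <- run_config(list(conditions = list(
  WT = list(rates = c(385.6, 0.0903, 0.000844), seed = 1, n_cells = 10)
)))
res <- recover_rates(cfg)
condition_rates(res)[, c("condition", "k1_mean", "k_minus1_mean", "kf_mean")]
#> # A tibble: 1 x 4
#>   condition k1_mean k_minus1_mean  kf_mean
#>   <chr>       <dbl>         <dbl>    <dbl>
#> 1 WT           366.        0.0862 0.000868
```

`simulate_cells()` / `analyze_cells()` do the same through delimited-text
trace files with JSON sidecars and a manifest, and
`charge_model()` / `charge_at_rate()` place measured fusion rates on the
electrostatic charge axis (a 22.47-fold sub-saturated rate ratio spans
5.6 charges under the default calibration).

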