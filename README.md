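# pdmsdose

Partition-diffusion dosimetry for PDMS-based microfluidic devices.

PDMS — the elastomer most organ-on-chip and microphysiological-system
devices are cast from — absorbs hydrophobic small molecules. Steroid
hormones dosed into such devices (estradiol, progesterone) partition into
the channel walls and diffuse into the bulk polymer, so the concentration
cells actually experience can be severely depleted and dynamically
distorted relative to the nominal dose. `pdmsdose` is for device designers
and cell-culture experimentalists who need to know, quantitatively, whether
a given chemical / geometry / flow-rate combination delivers the dose they
intend.

## The model

Concentrations in solution (c_S) and PDMS (c_P) follow coupled
advection-diffusion / diffusion equations,

    dc_S/dt = D_S ∇²c_S − ∇·(c_S v),        dc_P/dt = D_P ∇²c_P,

joined at every solution-PDMS interface by a kinetic partition flux

    J = H (K_PS c_S − c_P),

where K_PS is the PDMS-solution partition coefficient, H an interfacial
mass-transfer coefficient, and the cosolvent dependence of K_PS follows a
log-linear mixing law in the DMSO volume fraction f:

    log10 K_PS = f · log10 K_PD + (1 − f) · log10 K_PW.

The package provides:

* `simulate_membrane()` — finite-volume forward model of two-chamber
  diffusion-through-membrane experiments (the measurement geometry for the
  interaction parameters), with a closed-form equilibrium oracle;
* `fit_membrane_experiment()` / `extrapolate_partition()` — bounded
  Levenberg-Marquardt estimation of (K_PS, D_P, H, D_S,eff) per DMSO
  fraction, with H reported as a lower bound when it is not rate-limiting,
  and regression extrapolation to the aqueous K_PW;
* `simulate_channel()` / `simulate_static_device()` — reduced 2-D solver
  for a channel embedded in a PDMS slab, static or under laminar perfusion,
  with transient and quasi-steady drivers and a complete mass ledger;
* `dose_metrics()` — pulse depletion, post-pulse release, delivered
  fraction of targeted exposure, outlet bioavailability, and phase shift
  for periodic dosing;
* `generate_membrane_dataset()` — synthetic membrane experiments with
  known ground truth for estimator validation;
* `run_pipeline()` and `inst/cli/pdmsdose.R` — a command-line surface for
  the whole workflow.

Bundled parameter sets (`chemical()`): progesterone (log K_PW = 3.30,
log K_PD = −7.20, log D_P = −1.90 mm²/h), estradiol (1.18, +0.03, −3.03)
and non-interacting aldosterone; log H ≥ 1.56 mm/h is a shared
non-rate-limiting lower bound.

## Worked example

A 1-hour progesterone pulse through a 10.55 × 1.5 × 0.1 mm channel in a
4-mm PDMS slab at 10 uL/min:

```r
library(pdmsdose)

dev <- device_preset("bioreactor", flow_rate_ul_min = 10)
ctl <- channel_control(quasi_steady = TRUE, dt_h = 0.005, save_dt_h = 0.005)
res <- simulate_channel(dev, chemical("progesterone"),
                        schedule_pulse(1, 0, 1), t_end_h = 4, ctl)
dose_metrics(res)
#> <dose_metrics>
#>   window: 0-1 h (run to 4 h)
#>   pulse depletion:              77 %
#>   post-pulse release:         9.61 %
#>   delivered fraction:         32.5 %
#>   outlet bioavailability:     3.97 %
```

Read: 77% of the hormone mass nominally dosed during the pulse never makes
it through the channel in that hour — the walls absorb it — and a further
9.6% of the pulse leaks back out of the PDMS over the following three
hours as a low-level tail. Only ~4% of the inlet concentration survives to
the outlet while the pulse is on.

Static culture is worse. Loading estradiol into a legacy static channel
(4.5 mm × 670 um × 250 um in a 10 × 10 × 0.75 mm slab) and waiting 24 h,
then refilling with fresh solution and waiting again:

```r
simulate_static_device(device_preset("regehr"), chemical("estradiol"),
                       c0 = 1, interval_h = 24, refills = 1)
#> # A tibble: 2 × 4
#>   interval loss_percent solution_mass_end pdms_mass_end
#>      <int>        <dbl>             <dbl>         <dbl>
#> 1        1         97.6            0.0185         0.735
#> 2        2         95.5            0.0342         1.45
```

Nearly everything is gone from solution after each load — the PDMS is
nowhere near saturation after one fill.

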