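# mollifit

Bloch-simulation-based reconstruction of myocardial T1 maps from MOLLI
(Modified Look-Locker Inversion recovery) data, for quantitative cardiac MR
researchers who need T1 values free of the standard method's systematic
underestimation.

## The problem and the model

MOLLI samples an inversion-recovery curve at 11 inversion times (three
inversions, 3-3-5 images on consecutive heartbeats) with single-shot b-SSFP
readouts. Standard post-processing fits

    S(TI) = A − B·exp(−TI/T1*)

to the TI-sorted samples and applies the Look-Locker correction
`T1 = T1*·(B/A − 1)`. That correction ignores T2 decay during the b-SSFP
pulse trains, deviations of the achieved flip angle α from nominal (B1+
inhomogeneity), and the imperfect efficacy η of the adiabatic inversion, so
the standard estimate is biased low — increasingly so at long T1.

`mollifit` instead propagates the Bloch equations through the whole
acquisition with affine operators `M' = A·M + B` (RF nutation, free
precession, relaxation), producing the sequence response
`f(T1, T2, η, α, t)` at the 11 TIs, and fits that forward model to the
measured samples with T1 as the only free nonlinear parameter
(Nelder-Mead; per-pixel amplitude solved in closed form). T2, η and α come
from their own measurements, all supported here: T2-prepared b-SSFP and
multi-echo spin-echo T2 fitting, a time-stepped Bloch simulation of the
10 ms hyperbolic-secant inversion pulse (η from B0/B1+ maps), and
Bloch-Siegert phase-to-flip-angle B1+ mapping. A Monte Carlo module
quantifies bias and per-bin coefficient of variation of both estimators,
and a digital tube phantom generates end-to-end test data without a
scanner.

## Worked example

Simulate a noiseless MOLLI acquisition at the in vivo myocardial operating
point (true T1 = 1410 ms, T2 = 41 ms, achieved flip angle 24°, inversion
efficacy 0.92, 60 bpm) and fit it both ways:

```r
library(mollifit)

p     <- molli_protocol(alpha_nominal = 24)   # 3-3-5, TI1 = 100, dTI = 80 ms
curve <- simulate_molli(tissue_params(t1 = 1410, t2 = 41), p, eta = 0.92)
sort_by_ti(curve)
#> <recovery_curve> 11 samples (signed)
#>      ti    signal
#> 1   100 -0.154920
#> 2   180 -0.129860
#> 3   260 -0.111720
#> ...
#> 11 4260  0.158430

fit_standard(curve)
#> <fit_result> standard: T1 = 1222.4 ms (converged: TRUE)

fit_simulation(curve, t2 = 41, eta = 0.92, alpha_actual = 24, protocol = p)
#> <fit_result> fit-sim: T1 = 1410.0 ms (converged: TRUE)
```

The standard fit returns 1222 ms — a 13.3% underestimate of the true
1410 ms — while the simulation-based fit recovers the input exactly. The
inversion efficacy used above is itself computed, not assumed:

```r
simulate_inversion(hs_pulse(), tissue_params(1180, 45))
#> eta = 0.925 (10 ms sech pulse, peak B1 16.1 uT, relaxation included)
```

`run_mc(mc_config())` reproduces the robustness picture: across
400-2400 ms the standard fit's bias grows from −8% to −20% with ~1.3%
dispersion, while the simulation-based fit stays within ±0.4% with per-bin
coefficients of variation of 1.4-3.2%, driven by the T2/flip-angle
measurement uncertainty rather than image noise.

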