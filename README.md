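# olivenmr

Proton NMR relaxation and relaxometry analysis of edible oils, built
around the workflow used to characterise extra virgin olive oils (EVOOs):
low-field relaxation where the whole spectrum relaxes as a sum of two
exponential components, high-field per-region mono-exponential
relaxation, and fast-field-cycling (FFC) T1 dispersion profiles fitted
with a composite motional model. It is aimed at NMR relaxometry and
food-science groups who need a reproducible, scriptable replacement for
ad hoc spreadsheet/MATLAB fitting of decay curves and NMRD profiles.

## What it computes

**Decay decomposition.** Inversion-recovery and CPMG/spin-echo curves are
fitted by weighted least squares with one or two exponential components,

    M_IR(tau) = sum_i a_i (1 - 2 eta exp(-tau/T1_i))
    M_CPMG(t) = sum_i a_i exp(-t/T2_i)

with grid-seeded multi-start Levenberg-Marquardt refinement, component
sorting (short = "a", long = "b"), amplitude-ratio extraction, and
AICc-based mono/bi selection.

**NMRD model.** R1(nu) dispersion profiles are fitted with the additive
composite model

    R1(nu) = A1 [J1(w) + 4 J1(2w)] + A2 [J2(w) + 4 J2(2w)] + R1_SD(nu),
    J(w) = tau / (1 + w^2 tau^2),   w = 2 pi nu,

two Bloembergen-Purcell-Pound rotational terms (slow tumbling + fast
axial reorientation) plus a translational self-diffusion term in the
force-free hard-sphere (Torrey-type) closed form, with the self-diffusion
constant D fixed at its independently measured value.

**Cohort screening.** Batch fitting of sample sets at 2 and 100 MHz with
fault isolation, per-group descriptive statistics, and a range-overlap
comparison between two groups of samples (deliberately descriptive — no
hypothesis test).

**Synthetic data.** Seeded, bit-reproducible generators for decay curves,
NMRD profiles, Lorentzian spectra and two-region cohorts, including a
fixture library with the reference sample's ("at_28") published
relaxation values. These stand in for instrument data, which are not
redistributable.

## Worked example

```r
library(olivenmr)
fx <- fixture_library()

# two-component T2 at 2 MHz: CPMG train, 200 us echo spacing, 1000 echoes
cv <- simulate_decay(fx$at28_t2_2mhz$components, "cpmg", cpmg_schedule(),
                     noise_spec("additive_gaussian", 0, seed = 1))
fit_decay(cv, n_components = 2)
#> <relaxation_fit> bi cpmg fit, 2 MHz (n = 1000)
#>   a: T = 43 ms (a = 1)
#>   b: T = 147 ms (a = 1)
#>   RSS = 1.206e-16, AICc = -3.546e+04
```

The short component (43 ms) is the rigid-proton pool, the long one
(147 ms) the mobile chain ends; both planted values are recovered
exactly from the noiseless train.

```r
# composite NMRD fit over 10 kHz - 400 MHz, D fixed from DOSY
prof <- simulate_dispersion(fx$at28_dispersion$params,
                            exp(seq(log(0.01), log(400), length.out = 30)),
                            noise_spec("additive_gaussian", 0, seed = 1))
fit_dispersion(prof, d_const = 7.7e-12)
#> <dispersion_fit>
#> <dispersion_model_params>
#>   BPP1: A = 1.08e+08 s^-2, tau = 1.5e-08 s
#>   BPP2: A = 3.15e+09 s^-2, tau = 2.15e-10 s
#>   SD:   a = 5e+06 s^-2, D = 7.7e-12 m^2/s, d = 1e-09 m (D fixed)
#>   RSS = 3.264e-27, reduced chi2 = 1.305e-28, starts = 8
```

The slow BPP term (tau = 15 ns) captures whole-molecule tumbling, the
fast term (0.215 ns) axial reorientation, and the SD term the
diffusion-driven low-frequency contribution.

```r
# two-region synthetic screening campaign (32 + 35 samples)
res <- run_cohort(simulate_cohort(seed = 1))
sg <- summarize_groups(res$table)
sg$overlap
#>       quantity   overlap
#> 1       t1a_ms 0.6827556
#> 2       t1b_ms 0.8387073
#> 3 t1_100mhz_ms 0.9255089
#> 4       t2a_ms 0.7402637
#> 5       t2b_ms 0.6644935
#> 6 t2_100mhz_ms 0.8068431
sg$verdict
#> [1] "similar"
```

Every relaxation quantity's range overlaps strongly between the two
regions, reproducing the empirical conclusion that EVOO relaxation values
are characteristic of the product rather than its growing region.

A command-line entry point wrapping the same functions ships at
`system.file("cli", "olivenmr", package = "olivenmr")` with subcommands
`fixtures`, `simulate-decay`, `simulate-nmrd`, `fit-decay`, `fit-nmrd`
and `cohort`.

See `vignettes/relaxation-analysis.Rmd` for the model assumptions,
fitting and calibration choices, and known limitations.

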