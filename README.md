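# lovewave

Modelling and signal processing for Love-wave (shear-horizontal surface
acoustic wave) delay-line sensors operated under viscous liquid loading —
the instrument class used to probe liquids and soft layers such as adherent
cell monolayers.

A Love wave is trapped by a slow overlayer (here an 8 µm SU-8 film) on a
fast substrate (LiNbO3 36Y-X). Two interdigital transducers (IDTs) launch
and receive it across a delay path; a liquid on the guiding surface loads
the wave, and the loading is read out as insertion loss and phase of the
transmission coefficient S21. The depth probed in a Newtonian liquid is the
shear penetration depth δ = √(η/(πρf)) — ~100 nm in water at 30 MHz —
so a low operating frequency reaches deeper into the sample.

The package implements, end to end:

* **materials** — characteristic shear impedance and propagation factor for
  rigid solids (`√(ρμ)`), Newtonian liquids (`√(jωρη)`, the Kanazawa
  loading) and viscoelastic solids (parallel elementary circuit
  C = μ/(ω²η²+μ²), G = ηω²/(ω²η²+μ²), L = ρ); glycerol–water
  calibration-liquid correlations (Cheng 2008 viscosity, Volk–Kähler 2018
  density) with inversion to a target viscosity; a packaged material
  library (`load_material()`).
* **transmission-line model** — impedance transformation
  Z = Zc(ZL + Zc tanh(γh))/(Zc + ZL tanh(γh)) through the layer stack and a
  transverse-resonance dispersion solver (`solve_dispersion()`): the guided
  mode is the complex in-plane wavenumber k_x at which the impedances
  looking up and down from a reference plane cancel. Verified against the
  classical two-layer dispersion relation tan(qh) = μ_s·s/(μ_l·q) by an
  independent bisection oracle.
* **IDT model** — Campbell cross-field circuit (radiation conductance
  Ga ∝ sinc²X, its Hilbert partner Ba, static capacitance), conversion loss
  into 50 Ω, and full delay-line S21 synthesis (`delay_line_s21()`), plus a
  fixture-grade triple-transit echo.
* **S-parameters** — Touchstone v1 two-port I/O (RI/MA/DB), band-limited
  time-domain gating (`time_gate()`), minimum-insertion-loss and
  fixed-frequency phase extraction, and sensorgram assembly over a
  time-ordered series (`build_sensorgram()`).
* **synthetic acquisitions** — `synth_series()` emulates a VNA step
  experiment (spectrum every 10 s, programmed liquid schedule, exponential
  mixing, feedthrough, echo, seeded noise) so the whole processing chain is
  testable without hardware.

Results come back as tibbles; `autoplot()` methods cover spectra, sweeps,
sensorgrams, IDT responses and dispersion curves, and `tidy()`/`glance()`
tidy a dispersion solution.

## Worked example

```r
library(lovewave)

# penetration depth in water at the 30 MHz design frequency
penetration_depth(1, 1000, 30e6)
#> [1] 1.030065e-07        # ~103 nm

# calibration liquids at 25 degC
glycerol_properties(c(0, 0.252, 0.4544), 25)
#>   mass_fraction temperature_c viscosity_cp  density_kgm3
#>          0.000            25       0.8927         996.9
#>          0.252            25       1.7998        1063.1
#>          0.4544           25       4.0002        1116.7

# guided mode of the reference stack loaded with water
sol <- solve_dispersion(reference_stack(top = load_material("water_25C")),
                        f = 30e6)
sol
#> <lw_dispersion> mode 0 at 30 MHz
#>   phase velocity: 4077.11 m/s
#>   attenuation:    4483.55 dB/m (0.6093 dB/wavelength)
#>   residual:       5.01e-11

# full delay-line transmission and its minimum insertion loss
dl <- delay_line_design()   # 12-finger IDTs, 144 um, 37-wavelength path
sp <- delay_line_s21(dl, reference_stack(top = load_material("water_25C")),
                     seq(10e6, 50e6, length.out = 2001))
extract_min_il(sp, c(20e6, 40e6))
#>   f_min_hz il_db
#>   28120000 -31.5
```

The water-loaded device transmits best near 28 MHz at −31.5 dB: two
conversion losses of ~10.7 dB each (cross-field model, untuned 50 Ω,
3 dB bidirectionality) plus the propagation loss of the lossy guide over
the 5.33 mm path. Sweeping the calibration liquids makes the minimum
insertion loss fall and the fixed-frequency phase shift negative as
viscosity rises — the sensor's calibration curves (see
`viscosity_sweep()`, `sensitivity()`, and the vignette).

A thin command-line wrapper over the same functions is installed at
`inst/cli/lovewave.R` with subcommands `dispersion`, `sweep`, `s21`,
`gate`, `track` and `synth`.

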