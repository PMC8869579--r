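---
title: "Modelling Love-wave delay-line sensors under viscous liquid loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Love-wave delay-line sensors under viscous liquid loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovewave)
```

## The sensing problem

A Love wave is a shear-horizontally polarized surface acoustic wave guided
by a slow overlayer on a faster substrate. In a delay-line sensor two
interdigital transducers (IDTs) launch and receive the wave across a delay
path; anything touching the guiding surface — a liquid, an adsorbed film, a
cell layer — loads the wave and shows up as extra insertion loss and a phase
shift of the transmission coefficient S21. The depth to which the device
probes a Newtonian liquid is the shear penetration depth

$$\delta = \sqrt{\frac{\eta}{\pi \rho f}},$$

about 100 nm in water at 30 MHz and 50 nm at 100 MHz
(`penetration_depth()`). Working at low frequency therefore trades
sensitivity for reach: a 30 MHz device can interrogate structures beyond the
first tens of nanometres — for adherent cells, beyond the focal-adhesion
zone — which is the design rationale of the reference device this package
models (LiNbO3 36Y-X substrate, 8 µm SU-8 guide, 144 µm wavelength,
30 MHz).

## The transmission-line model

For shear-horizontal motion in a stack of isotropic, homogeneous layers the
field pair (shear stress, particle velocity) obeys the telegrapher's
equations, so each medium maps onto a transmission-line section with a
characteristic impedance $Z_c$ and a propagation factor $k$
(`characteristic_impedance()`, `propagation_factor()`):

* rigid solid: $Z_c = \sqrt{\rho\mu}$, $k = \omega\sqrt{\rho/\mu}$;
* Newtonian liquid: $Z_c = \sqrt{j\omega\rho\eta}$ — the Kanazawa
  liquid-loading impedance of a semi-infinite liquid;
* viscoelastic solid, parallel elementary circuit with
  $C = \mu/(\omega^2\eta^2+\mu^2)$, $G = \eta\omega^2/(\omega^2\eta^2+\mu^2)$,
  $L = \rho$ (`viscoelastic_circuit()`), equivalent to the Kelvin–Voigt
  modulus $\mu_\mathrm{eff} = \mu + j\omega\eta$.

Sign conventions are fixed once and asserted by tests: time factor
$e^{+j\omega t}$, propagation $e^{-jk_x x}$, impedances on the
$\mathrm{Re}\,Z_c \ge 0$ branch (passivity), wavenumbers on the
$\mathrm{Im}\,k \le 0$ branch (decay). A guided mode with in-plane
wavenumber $k_x$ gives each medium a transverse wavenumber
$k_{y,i} = \sqrt{k_i^2 - k_x^2}$ and a transverse-line impedance
$Z_i = Z_{c,i}\,k_{y,i}/k_i$ (the stress/velocity ratio of the oblique
decomposition); half-spaces take the branch that decays away from the
guide. Finite layers are folded in with the standard line transformation

$$Z = Z_c\,\frac{Z_L + Z_c \tanh(\gamma h)}{Z_c + Z_L \tanh(\gamma h)},
\qquad \gamma = j k_y$$

(`transform_impedance()`), and a mode exists where the impedances looking up
and down from a reference plane cancel: $Z_\uparrow + Z_\downarrow = 0$
(`surface_impedance_up()`/`_down()`, `solve_dispersion()`). The root is
independent of where the plane is put; a property test moves it across every
interface of the stack.

### Root finding

The solver first strips losses from the stack (layer viscosities to zero,
liquid top replaced by vacuum), where the resonance function is purely
imaginary along real $k_x$, and scans phase velocity between the slowest
layer shear velocity and the substrate shear velocity (400 points plus a
geometric refinement toward the substrate edge, where thin-layer modes
cluster). Sign changes are bisected; pole crossings of $\tanh$ are rejected
by a relative-residual filter. Losses are then switched on and the root is
polished in the complex plane by damped Newton iteration (numerical
derivative, step halving), with a five-step viscosity-continuation fallback
for stubborn cases. Convergence is declared below a relative residual of
1e-8, the residual being normalized by the stack's own impedance scale so
it stays meaningful when one side of the plane is a vacuum. The solver is
cross-checked in the test suite against (a) the classical two-layer Love
dispersion relation $\tan(qh) = \mu_s s / (\mu_\ell q)$ solved by an
independent bisection oracle over 50 randomized lossless stacks, and (b) an
independently assembled exact three-media characteristic equation for the
full lossy substrate/viscoelastic-layer/liquid problem; both agree to the
stated tolerances.

`dispersion_curve()` traces the fundamental mode against the normalized
guide thickness $z = h/\lambda$. The reference operating point
$z = 8/144 \approx 0.056$ sits in the steep region of that curve, where
mass-loading sensitivity is high — a property test checks
$|dv/dz|(0.05) > |dv/dz|(0.005)$.

## The IDT model and S21 synthesis

The transducers are modelled with the cross-field equivalent circuit
(`idt_response()`): with $N_p$ finger pairs and
$X = N_p\pi(f-f_0)/f_0$,

$$G_a = 8K^2 f_0 C_s W N_p^2 \left(\frac{\sin X}{X}\right)^2,\qquad
B_a = G_a(f_0)\,\frac{\sin 2X - 2X}{2X^2},\qquad C_T = N_p C_s W,$$

and the conversion loss into an untuned resistive termination $R$ is
$-10\log_{10}\!\big(2G_aR / ((1+G_aR)^2 + ((B_a+\omega C_T)R)^2)\big)$,
plus an explicit 3 dB bidirectionality term per IDT (toggleable).
`delay_line_s21()` composes two conversion losses with the propagation loss
and phase of the guided mode over the delay path,
$|S_{21}|_\mathrm{dB} = -(CL_{in} + CL_{out} + \alpha L)$ and
$\arg S_{21} = -\mathrm{Re}(k_x)L$, solving the dispersion problem at 25
warm-started nodes across the band and spline-interpolating $k_x$.

Three electrical constants are not device-measurable from geometry and are
set to literature values for LiNbO3 36Y-X in
`substrate_electrical()`: $K^2 = 0.16$, $C_s = 5\times10^{-10}$ F/m per
finger pair, and the free-surface shear velocity
$v_0 = \sqrt{\mu/\rho} \approx 4308$ m/s, which puts $f_0 = v_0/\lambda$
at 29.9 MHz for the 144 µm period. "12 fingers" is read as 6 electrode
pairs; pass `n_pairs = 12` for the other reading found in the literature.
The delay path defaults to 37 wavelengths (5.33 mm), with any other value —
e.g. the 29-wavelength variant of the same device family — available
through `delay_line_design(delay_path = )`.

## Calibration liquids

Glycerol–water mixtures are the standard viscosity series for acoustic
sensors. `glycerol_properties()` implements the Cheng (2008)
exponent-blending viscosity correlation and the Volk–Kähler (2018) density
correlation (coefficients documented in the source); both are accurate to a
few tenths of a percent against the usual calibration tables at 25 °C, and
`solve_mass_fraction()` inverts the viscosity correlation by bisection to
design a liquid of prescribed viscosity. The five packaged liquids
(0.893–4 cP) span the viscosity range estimated for confluent cell
monolayers (~1.5–2.2 cP).

## S-parameter post-processing

`read_touchstone()`/`write_touchstone()` handle two-port Touchstone v1 in
all three encodings. `time_gate()` implements band-limited time gating: the
measured band is Tukey-tapered (10% default) to control the Gibbs ringing
of a band-limited impulse response, inverse-transformed, multiplied by a
cosine-edged gate (5% taper), transformed back and compensated for the band
taper across the interior of the band. The protocol default window,
0.2–1.9 µs, is the direct-transit window of the measured reference device.
Note a model-specific caveat: the modelled guide is strongly dispersive at
30 MHz (group velocity ≈ 2500 m/s), so the modelled transit over 5.33 mm is
≈ 2.1 µs and model-generated series should be gated with a window that
contains it (the examples use 0.2–3.5 µs). `build_sensorgram()` extracts,
per spectrum, the minimum insertion loss in a band and the phase at a fixed
frequency from the gated spectrum (set `gate = NULL` for raw reads), with
temporal phase unwrapping across the series — sensorgrams may legitimately
run beyond ±180°.

## Synthetic acquisitions

`synth_series()` emulates a step experiment: a spectrum every 10 s over a
programmed liquid schedule, with first-order exponential mixing between
liquids (τ = 30 s default — liquid exchange in a ~1 mL open well settles on
that scale), an optional triple-transit echo ($r^2 S_{21} e^{-2jk_xL}$), a
constant feedthrough floor and seeded complex Gaussian noise. The generator
reproduces what the model says, plus those acquisition artefacts; it does
not emulate temperature drift, electrical crosstalk variation, meniscus
effects or cell sedimentation, so passing end-to-end tests demonstrate the
correctness of the processing chain, not fidelity to any particular
physical device.

## Numerical choices and limitations

* Complex square roots: passive branch for impedances, decaying branch for
  wavenumbers; ties broken toward the physical sign. Finite layers may use
  either transverse branch (the line transformation is branch-even).
* The thin-layer band edge involves catastrophic cancellation in
  $\sqrt{k_s^2-k_x^2}$; the 1e-8 residual tolerance reflects what that
  conditioning supports.
* Fixed-frequency phase readings use the stored complex wavenumber of model
  spectra, avoiding wrap ambiguity over a 5.33 mm path (~40 guided
  wavelengths).
* The model deliberately omits piezoelectric stiffening and all electrical
  coupling between IDTs (the reference device grounds the delay path), as
  well as bulk-wave leakage, diffraction and in-transducer reflections.
  Against measured devices of this class, fixed-frequency phase responses
  to viscous loading computed by this family of models tend to come out
  stronger than observed; the insertion-loss minima of the full synthesized
  transfer function are the more robust observable, and they are what the
  acceptance workflow reports.
* Problem sizes in tests and the acceptance script (2001-point spectra, 25
  dispersion nodes, 0.1 cP sensitivity grids, ~40-sample series) were
  chosen as the smallest grids on which the reported quantities are
  grid-converged to well below their tolerances.
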