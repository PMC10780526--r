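---
title: "Synthetic databases and learned permittivity reconstruction for 2D microwave imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic databases and learned permittivity reconstruction for 2D microwave imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microwave (electromagnetic) medical imaging reconstructs the electrical
properties of tissue — chiefly the relative permittivity $\varepsilon_r$ —
from fields scattered by the body and measured outside it. The inverse
scattering problem is ill-posed, and learning-based solvers need training
data that clinical practice cannot supply: thousands of cases with exact
property maps as labels. `emtomo` builds such data synthetically, end to
end: it samples randomized dielectric phantoms, simulates the multistatic
acquisition with a 2D finite-difference time-domain (FDTD) solver, converts
the raw signals into normalized network inputs, trains an encoder–decoder
network to map signals to permittivity images, and scores reconstructions
with SSIM, NRMSE and PSNR.

## Phantom synthesis

The imaging scene is a square domain (500 mm side, 2 mm cells, so a
250×250 simulation grid) containing a circular imaging region of radius
130 mm, with 16 idealized line-source antennas evenly spaced on a 150 mm
ring. Everything outside the imaging circle — including the region under
the absorbing boundary — is a matching medium with
$(\varepsilon_r, \sigma) = (40, 0.1\,\mathrm{S/m})$, emulating the coupling
liquid used in practice. Note the two radii: objects are confined to the
130 mm circle so they never touch the antenna ring at 150 mm; both are
configurable.

A phantom superimposes 6–24 random shapes: ellipses with full axes uniform
on [50, 120] mm, and convex polygons with 3–6 edges. Polygons are built by
placing vertices at sorted uniform angles on the shape's ellipse, which
keeps their extent inside the same axis bounds. Each shape gets independent
uniform dielectric draws, $\varepsilon_r \in [10, 80]$ and
$\sigma \in [0.2, 2.5]$ S/m — the span of most human tissues from fat
through cerebrospinal fluid. Centers are uniform over the imaging disc and
shapes are clipped at the imaging circle.

Overlapping shapes add their property values; the covered cells are then
affinely rescaled, per case and per property, so the support minimum and
maximum land exactly on the configured intervals. This is the simplest rule
that keeps superimposed values inside the tissue range; a single shape
(support minimum = maximum) keeps its drawn value. The 256×256 ground-truth
label is rendered from the same analytic shape set at label resolution —
not resampled from the solver grid — so object boundaries stay crisp. The
same affine parameters are reused for the label so solver maps and labels
are consistent.

Databases are generated in ten equal groups with the per-case shape count
drawn from consecutive bands of [6, 24] ({6,7}, {8,9}, …, {24}), so
complexity rises across groups; generation is fully reproducible from one
seed. A simple-object mode (1–2 shapes per case) uses the same code path
for small validation sets.

## The FDTD solver

The solver advances the 2D transverse-magnetic mode ($E_z$, $H_x$, $H_y$)
on a staggered Yee grid with per-cell loss coefficients

$$C_a = \frac{1 - \sigma\Delta t/2\varepsilon}{1 + \sigma\Delta t/2\varepsilon},
\qquad
C_b = \frac{\Delta t/(\varepsilon\Delta x)}{1 + \sigma\Delta t/2\varepsilon},$$

a 4.72 ps time step and 5000 steps (23.6 ns of simulated time) on the 2 mm
mesh. Antennas are soft (additive) point sources on $E_z$, and receivers
sample $E_z$ at the same cells — the natural 2D reduction of Hertzian
dipoles. The excitation is a Gaussian-modulated sinusoid centered at
1.25 GHz whose envelope width is chosen in closed form so the −10 dB points
of its power spectrum sit at 0.5 and 2 GHz; the envelope is delayed 4.5
standard deviations so the waveform starts below $10^{-4}$ of its peak.

Stability is checked at run time against the 2D Courant bound
$\Delta t \le \Delta x\sqrt{\varepsilon_{\min}}/(c_0\sqrt{2})$ using the
minimum relative permittivity anywhere on the grid. This is why the
matching-medium background matters numerically as well as physically: with
vacuum anywhere on the grid the bound is 4.717 ps and the 4.72 ps step is
inadmissible, while the phantom grids built here have
$\varepsilon_{\min} \ge 10$ (bound 14.9 ps). The solver refuses unstable
configurations with an error naming the admissible step.

The grid is terminated by a convolutional perfectly matched layer (CPML)
with a cubically graded conductivity profile whose strength comes from a
$10^{-6}$ normal-incidence reflection target in the matching medium. Two
numerical choices were fixed after measuring reflections against oversized
reference grids: the complex-frequency-shift parameter is 0 by default
(any useful $\alpha$ puts the CPML's low-frequency cutoff inside the
0.5–2 GHz band and destroys absorption), and the layer is 16 cells thick —
on a 2 mm mesh a 10-cell layer is limited to about −55 dB by
discretization reflection regardless of profile tuning, while 16 cells
reach about −73 dB, comfortably below the −60 dB the package's invariants
demand.

Reciprocity of the discrete scheme makes the multistatic tensor symmetric
(transmit–receive pairs interchangeable), which the tests verify on
arbitrary phantoms, and the soft-source/receiver model admits an exact
frequency-domain reference: the field of a 2D line current,
$E_z(\omega) = -(\omega\mu_0/4)\,I(\omega)\,H_0^{(2)}(kr)$, with the
discrete source equivalence $I(t) = -\varepsilon\,s(t)\,\Delta x^2/\Delta t$
and a half-sample time alignment. The homogeneous-medium solver trace is
validated against this oracle; agreement is grid-dispersion limited, so the
test uses a medium ($\varepsilon_r = 10$) in which the mesh resolves the
full band at ≥23 cells per wavelength. In the densest media the 2 mm mesh
carries 2 GHz at ~12 cells per wavelength, a deliberate trade inherited
from the acquisition protocol.

The solver records the total field. Scattered-field data can be formed by
subtracting an empty-domain (matching-medium-only) run, provided as a
calibration utility, since the acquisition protocol does not define a
calibration run.

## Signal preprocessing

The raw tensor (16 transmitters × 16 receivers × 5000 samples) is stacked
transmitter-major into a 256×5000 map, decimated by 20 (keeping every 20th
column from phase 0 — pure decimation, matching the stated downsampling
rate; an averaging mode exists but is off by default), padded with 6
trailing zero columns to 256×256, and min–max normalized per row:
$X'_n = (X_n - X^n_{\min})/(X^n_{\max} - X^n_{\min})$. Padding precedes
normalization, so the zeros participate in each row's extremes; for signed
traces the padded columns therefore sit at the row's normalized zero level
rather than at 0. Rows that are constant before normalization (a 0/0 in
the formula) map to all zeros by convention. The row order, the decimation
phase, and trailing (rather than leading) padding are documented, tested
conventions; any fixed bijection would serve.

## The reconstruction network

The network is a U-net-style encoder–decoder: five resolution levels, two
5×5 stride-1 same-padded convolutions with rectified-linear activations per
level, 2×2 max-pooling between encoder levels, channel widths 8→128, 2×2
stride-2 transposed convolutions in the decoder with per-level skip
concatenation, and a final 1×1 convolution to one channel. A 256×256 input
reaches a 16×16×128 bottleneck. Stride-1 convolutions (rather than a
rectangular stride) are required to reproduce that shape chain together
with the pooling; skip connections are on by default and toggleable, since
"U-net" implies them.

Labels are mapped affinely from [10, 80] onto [0, 1] for training (better
conditioned mean-squared-error loss) and inverted at prediction. Training
uses the Adam optimizer at learning rate 5×10⁻⁴ with batch size 32 by
default; the epoch count is configuration, with no claim of equivalence to
any particular schedule. All parameters are He-initialized from a seed, and
batch sampling is seeded, so loss histories are reproducible on one
platform. The layers and their gradients are implemented natively
(im2col-based convolutions over BLAS), and backpropagation is verified
against central finite differences to 10⁻⁵ relative error; at exact
rectifier kinks (e.g. zero-initialized biases on all-zero inputs) the
implementation takes the standard subgradient relu′(0) = 0.

## Evaluation metrics

SSIM uses an 11×11 Gaussian window (σ = 1.5 px), constants
$(0.01L)^2, (0.03L)^2$, and a fixed dynamic range $L = 70$ — the
permittivity design range 80 − 10 — so scores are comparable across cases;
the mean is over fully overlapping windows. NRMSE divides the RMSE by the
reference's value range, and PSNR is $20\log_{10}(\text{peak}/\text{RMSE})$
with the same range as peak, capped at 100 dB for identical images to keep
summaries finite. Dataset summaries report means, sample standard
deviations, and the proportions above/below the conventional thresholds
(SSIM > 0.9, NRMSE < 0.2, PSNR > 30 dB).

## Scale, fixtures, and what the tests show

The package supports the full protocol — 25,000 grouped cases split
24,000/1,000 after a seeded shuffle, full-length 5000-sample acquisitions —
but its validation suite runs at deliberately reduced sizes chosen once:

* solver physics (analytic oracle, reciprocity, absorbing-boundary
  reflection, energy conservation, stability guard) on a 125×125 interior
  grid (250 mm domain);
* an end-to-end scaled-down run: 20 simple 1–2-shape phantoms on the
  reduced grid, 1250-step acquisitions decimated by 5, inputs and labels
  decimated to 32×32, and a channel-width 4–64 network trained 750 steps
  on 16 of them. Training must cut the MSE at least tenfold with a
  monotone smoothed early loss, the fitted predictions must beat an
  all-background baseline on mean SSIM, and reconstructions of the
  held-out cases that contain a high-permittivity region (objects can
  also be *below* the background, where the notion is undefined) must
  place visibly higher permittivity inside that region than over the true
  background.

Synthetic phantoms emulate the geometric and dielectric diversity of
tissue cross-sections, not their anatomy: there is no frequency dispersion
(properties are constant over the band), no noise model, no antenna feed
physics, and labels are piecewise-constant. Passing tests therefore
demonstrate the correctness of the simulation/learning machinery and the
learnability of the synthetic family — not clinical reconstruction
accuracy. Reproducing the full-scale image-quality tables requires the
complete 25,000-case database and full training (hundreds of CPU hours of
simulation), which is out of scope for the bundled checks.

## Known limitations

* 2D only; no dispersive (Debye/Cole–Cole) media.
* The case store serializes R objects per case with a JSON manifest; it is
  not a language-neutral container format.
* SSIM window/constants and the NRMSE normalization follow the common
  conventions stated above; other conventions shift absolute scores.
* The min–max normalization discards per-pair absolute amplitude, by
  design: distant, weak pairs are rescaled to the same range as strong
  ones.
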