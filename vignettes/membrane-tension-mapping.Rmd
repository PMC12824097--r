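---
title: "Membrane fluctuation tension mapping: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane fluctuation tension mapping: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctens)
```

# The physical model

The basal membrane of an adherent cell, held near the coverslip by
adhesion and cytoskeletal tethers, fluctuates in height. In the
Helfrich description each wavevector mode $q$ relaxes overdamped under
a restoring coefficient

$$E(q) = \kappa q^3 + \sigma q + \gamma / q,$$

with bending rigidity $\kappa$ (units of $k_BT$), effective tension
$\sigma$ (pN/µm) and confinement $\gamma$ (pN/µm³), and the temporal
power spectral density of the height of a point on the membrane is

$$\mathrm{PSD}(f) = \frac{4\eta_{\mathrm{eff}} A k_B T}{\pi}
\int_{q_{\min}}^{q_{\max}}
\frac{dq}{(4\eta_{\mathrm{eff}}\, 2\pi f)^2 + E(q)^2},$$

where $\eta_{\mathrm{eff}}$ is the effective viscosity of the
membrane-proximal cytoplasm and $A$ a dimensionless active-temperature
multiplier absorbing non-thermal driving. The confinement term enters
as $\gamma/q$ inside the squared bracket; the source rendering of the
formula is typographically ambiguous on this point and we follow the
established fluctuation framework. Each mode contributes a Lorentzian
in $f$ with corner frequency $E(q)/(8\pi\eta_{\mathrm{eff}})$, and the
stationary variance has the closed form
$\frac{A k_B T}{4\pi}\int dq/E(q)$, independent of viscosity
(`helfrich_variance()`), which the test-suite uses as a quadrature
oracle.

The "tension" reported throughout is this fluctuation tension: an
effective parameter including cytoskeletal contributions, not the bare
bilayer tension.

# The synthetic world

No raw movies are distributed with the source experiments, so every
pipeline input is generated with known ground truth. The generator
defaults *are* the stated experimental world:

| parameter | default | units | rationale |
|---|---|---|---|
| sampling presets | 2,048 frames @ 20 Hz; 8,192 @ 50 Hz | — | the two acquisition modes used for correlative and fast IRM movies |
| pixel size | 65 | nm | IRM pixel pitch of the correlative sets |
| $\sigma$ | 500 (tests: 100–2,000) | pN/µm | inside the measured cell operating window (600–2,100) |
| $\gamma$ | $10^3$ | pN/µm³ | $=10^9$ N/m³, the strongly-adhered end of reported membrane confinement; note $1\,\mathrm{pN/µm^3} = 10^6\,\mathrm{N/m^3}$ |
| $\eta_{\mathrm{eff}}$ | 100 | Pa·s | membrane-proximal cytoplasm, orders above water, within fitted literature ranges |
| $A$ | 1.5 | — | moderate active enhancement |
| $\kappa$ | 15 | $k_BT$ | fixed during fitting (degenerate with $\sigma,\gamma$ on a single spectrum) |
| $T$ | 310.15 | K | cells at 37 °C |
| $q$ range | $[\pi/5.2, \pi/0.065]$ | µm⁻¹ | adhered-patch scale to pixel scale; see below |

Two consistency checks anchor these choices: the resting SD_time they
produce is a few nanometers (matching what is observed for adherent
cells, and comfortably under the 15-nm validity cap), and the
relaxation knees $E(q)/8\pi\eta_{\mathrm{eff}}$ fall at 0.5–12 Hz,
inside the 20-Hz sampling band — a precondition for the published
$R^2>0.9$ fits to have been possible at all.

**Spectral synthesis.** `simulate_height_series()` draws complex
Gaussian Fourier coefficients with $E|X_k|^2 = n f_s S(f_k)/2$ and
inverse-transforms, so the series is exactly Gaussian, stationary
(circular) and has population spectrum equal to the model on the
discrete grid — no time-discretization bias, which is why it is
preferred over Langevin integration. Movies are generated per-pixel
independently; real neighboring pixels are correlated through shared
long-wavelength modes, so green tests establish correctness of
*per-pixel estimation*, not of spatial statistics.

**Height vs intensity.** Movies are generated in height units;
intensity-mode fixtures are produced by the inverse calibration
(`height_to_intensity()`), keeping `calibrate_intensity_to_height()`
and `intensity_to_height()` testable round-trip.

# Estimators and identifiability

**PSD estimation.** The periodogram-average estimator (rectangular
window, non-overlapping segments) is exactly Parseval-consistent and
has known per-bin $\chi^2_{2m}$ statistics — it is the oracle method in
every test. The autoregressive route uses Burg's forward–backward
method (`ar.burg`, order 16 by default); the covariance-family AR
estimator used with MATLAB's `pcov` has no base-R counterpart and
Burg is its standard stand-in.

**Why $A$ is fixed by default.** With $\kappa$ held, the map
$(\sigma,\gamma,\eta_{\mathrm{eff}},A)\to\lambda\cdot(\sigma,\gamma,\eta_{\mathrm{eff}},A)$
changes the model spectrum only through the $\kappa q^3$ term — in
practice by $\sim10^{-4}$ in $\log_{10}$ power across the sampled band,
two thousand times below per-bin estimation noise. A single spectrum
therefore cannot constrain the overall scale, and an unconstrained
4-parameter fit random-walks along this ridge. $A$ is the pure
amplitude direction, so `fit_helfrich()` holds it at a calibration
value by default (`fixed$a_active = NULL` frees it, which is the right
setting for noiseless model curves, where the global minimum is
unique). This mirrors the treatment of the FCS structural parameter
$S$, which single curves likewise leave unconstrained.

**Why $q_{\min}$ is the patch scale.** Setting $q_{\min}$ to
$\pi/(\text{region side})$ would treat a 4×4-pixel region as blind to
longer wavelengths, but long modes translate the whole region —
spatial averaging is a low-pass, not a high-pass. Physically the
long-wavelength cutoff is the adhered-patch/confinement scale
(default 5.2 µm). The choice also matters statistically: with the
narrow window $[12.1, 48.3]$ µm⁻¹ the Cramér–Rao bound for $\sigma$
exceeds 290% across the tested tension grid (no estimator could
recover it), while the patch-scale window brackets the
confinement–tension crossover $\sqrt{\gamma/\sigma}$ in-band and the
realized median error is well under 15%. Both bounds are configurable.

**Fitting.** Spectra span decades, so the fit pools the estimate into
36 log-spaced frequency bins (linear power averaging,
inverse-variance weights = pooled-ordinate counts) and minimizes the
weighted squared residual of $\log_{10}$ power, in log-parameter space,
from a coarse multi-start grid over $(\sigma,\gamma,\eta)$ (the
amplitude offset is matched in closed form where $A$ is free), refined
by L-BFGS-B within bounds ($\sigma\in[1,5\times10^4]$ pN/µm,
$\gamma\in[1,10^8]$ pN/µm³, $\eta\in[0.01,10^4]$ Pa·s,
$A\in[0.1,50]$) and polished by Nelder–Mead. Out-of-bounds proposals
are clamped, never silently accepted; non-convergence is flagged, not
raised. $r^2$ is defined on the fit's own $\log_{10}$-power domain
(the source does not define its $r^2$ domain).

**Validity filtering.** Pixel maps keep $r^2>0.9$,
$\sigma<5{,}000$ pN/µm, SD_time $<15$ nm (configurable); filtering is
idempotent and filtered pixels propagate as missing through line scans
and radial averages rather than being imputed.

# Correlative profiling choices

Registration is restricted to integer translations (stage drift only);
the returned shift is the drift of the moving frame, and
back-tracing subtracts it. Cluster detection is thresholded 8-neighbor
local maxima with a minimum separation, peaks sorted by brightness;
the source names no peak criterion, so these are package choices.
Line scans are 11 samples (half-length 5); profiles are normalized to
1 at the center *before* averaging, samples pooled by absolute offset
(the two same-distance samples of a scan are the same datum), SEM
taken over clusters. The surge statistic searches a Euclidean radius
of 5 px = 325 nm at the default 65 nm/px; the 10×10-window local mean
is normalized per-cluster against the same window of the baseline map
(the per-cell alternative reading of "normalized with respect to
baseline" is not implemented).

`mann_whitney_u()` enumerates all arrangements exactly for
$\min(n_1,n_2)\le 8$ without ties (its small-sample behavior is part
of the package's contract) and otherwise uses the tie-corrected normal
approximation with continuity correction, which matches
`stats::wilcox.test`.

# Colocalization choices

Local thresholding uses a 31-px moving-mean window with foreground at
$I > \bar I_{\mathrm{local}}(1+s)$, sensitivity $s=0.1$ by default —
the source names only "a proper sensitivity factor", and the noise
tests raise it to 0.5 because a mean-based threshold must clear the
noise floor. Despeckling is one erosion then one dilation with a 3×3
cross. The actin size cap defaults to 500 px (~8.5 µm² at 0.13 µm/px);
cortical actin presents as one large border-touching object and is
removed by the cap alone. Labeling is 2-D per slice with
8-connectivity (an own BFS implementation; an igraph flood fill is the
independent oracle in tests), counts are summed over slices, and one
touching pair yields one colocalized object — exactly what the
intersection-matrix construction implies. Equatorial slices are those
with ≥80% of the maximal cell-mask area (the source gives no
criterion). Manders coefficients are computed on the thresholded
channels.

# SAXS and FCS conventions

Guinier fits iterate the window $s R_g \le 1.3$ (globular convention;
the source's window is unstated) to convergence; fits are weighted by
$(I/\sigma_I)^2$ when uncertainties exist. The rod fit uses
$\ln(sI)$ vs $s^2$. Interparticle detection refits Guinier without the
$n_{\mathrm{low}}$ lowest points and flags suppression when the mean
relative deficit exceeds 5% with a one-sided sign test $p<0.05$ — a
quantitative stand-in for a qualitatively described effect. The
synthetic suppression factor $1-d\,e^{-(4 R_g s)^2}$ dies off well
inside the Guinier window so the round trip stays clean.

FCS fits hold $S$ at its calibration value by default and the triplet
term is optional ($K$ fixed at 0 when off). Beam-waist calibration
follows $\tau_D = \omega^2/4D$ with R6G ($D = 280$ µm²/s) as
reference; `oligomer_count()` is the bare cube of the diffusion-time
fold change, rounding left to the caller. Particle-number trends use a
one-sided Spearman test, exact for small samples without ties.

# Numerical details

Gauss–Legendre quadrature (128 nodes, Golub–Welsch, cached) evaluates
the model integral to better than $10^{-6}$ relative against adaptive
quadrature; the integrand is smooth on $[q_{\min},q_{\max}]$.
Registration ties break toward the smaller shift magnitude, then
lexicographically. Degenerate inputs are contracts, not crashes: empty
Manders masks yield `NA` coefficients, empty cytoplasm yields an `NA`
ratio, all-dropped scans raise an explicit empty-profile error,
non-converged fits return `converged = FALSE`. All generators are pure
functions of (arguments, seed) and restore the caller's RNG state.

# Time budgets

Stochastic suites are scaled to run on one CPU: parameter-recovery uses
2,048-frame series on a 4-point tension grid × 20 seeds (~20 s), the
end-to-end ring detection uses a 17×17-pixel field (~2.5 min), and the
full test suite completes in ~3 minutes.

# Known limitations

* Pixels are simulated independently; spatial correlations, optical
  image formation (interference fringes, PSF), photobleaching and
  detector noise beyond Gaussian are not modeled.
* Absolute $(\sigma,\gamma,\eta)$ from a single noisy spectrum remain
  correlated even with $A$ fixed; at the low-tension end (100 pN/µm,
  where confinement dominates the restoring term over most of the
  band) individual-fit errors of ~20% are expected, and spatial
  *contrasts* are more robust than absolute values.
* The AR estimator is Burg, not the covariance method; their spectra
  agree closely for the smooth targets used here but are not
  identical.
* Drift handling is linear-trend screening plus integer registration;
  subpixel alignment and cluster tracking across time points are out
  of scope.
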