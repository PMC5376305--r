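---
title: "Methods: dual-calibrated fMRI mapping of M, OEF and CMRO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-calibrated fMRI mapping of M, OEF and CMRO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quo2calib)
```

## The model

Dual-calibrated BOLD fMRI estimates resting oxygen metabolism by combining
two respiratory challenges acquired in one dual-echo pCASL session:
hypercapnia (HC, a vasodilatory stimulus assumed isometabolic) and hyperoxia
(HO, an arterial-content stimulus also treated as isometabolic). For an
epoch with fractional BOLD change $b$ and CBF ratio $f$, the calibrated-BOLD
signal equation is

$$ b = M \left( 1 - f^{\alpha}\, r(\mathrm{OEF}_0)^{\beta} \right), $$

where $M$ is the maximum BOLD signal increase (venous saturation
approaching 100%), $\alpha$ the flow–volume coupling exponent, $\beta$ the
field-strength exponent, and $r = [\mathrm{dHb}]/[\mathrm{dHb}]_0$ the
venous deoxyhemoglobin ratio. `quo2calib` computes $r$ from an O2 mass
balance at fixed oxygen consumption:

$$ C_vO_2 = C_aO_2^{epoch} - \mathrm{OEF}_0\, C_aO_2^{0} / f, \qquad
   S_vO_2 = C_vO_2 / (\phi\,[\mathrm{Hb}]/100), \qquad
   r = \frac{1 - S_vO_2}{1 - S_vO_2^{0}}. $$

Arterial content uses the Severinghaus saturation curve
$S_aO_2 = 1/(23400/(P^3 + 150P) + 1)$ plus dissolved O2
($\varepsilon = 0.0031$ ml O2/(dl·mmHg)), with end-tidal O2 as the PaO2
surrogate. Venous dissolved O2 is neglected — the standard simplification
for this model class.

Solving the signal equation for $M$ at each candidate $\mathrm{OEF}_0$
turns one epoch into a curve $M(\mathrm{OEF}_0)$; the HC and HO epochs give
two curves whose intersection is the voxel's $(M, \mathrm{OEF})$. CMRO2
follows as $\mathrm{OEF} \times \mathrm{CBF}_0 \times C_aO_2^0 \times k$
with $k = 44.6$ µmol O2 per ml O2 (ideal gas at STP). The HC curve is
nearly flat in OEF (hypercapnia barely changes arterial content), which is
why shifting the HO curve — e.g. by changing the inspired O2 level — moves
the intersection along an almost horizontal line and leaves $M$ essentially
unchanged. That O2-level invariance is the central property the test suite
and `gcm_sweep_combined()` verify quantitatively.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| $\alpha$ | 0.18 | – | common dual-calibrated value at 3 T; config-overridable, logged in provenance |
| $\beta$ | 1.5 | – | 3 T field-strength exponent, same lineage |
| [Hb] | 15 | g/dl | population normal; no blood test assumed |
| $\phi$ | 1.34 | ml O2/g | Hüfner constant |
| $\varepsilon$ | 0.0031 | ml O2/(dl·mmHg) | plasma solubility |
| $T_{1,\mathrm{ref}}$ | 1.65 | s | normoxic arterial blood T1 at 3 T |
| $dR_1/dP_aO_2$ | 1.361e-4 | s⁻¹/mmHg | two-point calibration through (112 mmHg, 1.65 s) and (369 mmHg, 1.56 s) |
| $k$ | 44.6 | µmol/ml | ideal-gas molar volume |
| labeling efficiency | 0.85 | – | standard pCASL |
| $\lambda$ | 0.9 | ml/g | standard blood–tissue partition |

The relaxivity slope deserves a note: rather than importing an external
animal-blood interpolation table, the linear $R_1(P_aO_2)$ model is
calibrated so it passes exactly through the adopted normoxic and 60%-O2
arterial T1 values; extrapolated to a 100%-O2 end-tidal level (654 mmHg) it
gives 1.47 s. This keeps the blood model internally consistent with the T1
values used elsewhere in the pipeline and is flagged here because the
underlying ex-vivo coefficients vary between preparations.

## Respiratory analysis decisions

The 18-minute default paradigm runs two cycles of 2-min HC, 1-min
normocapnia, 3-min HO, 3-min normoxia. Epoch averaging uses steady-state
windows: the last 60 s of each HC block, the last 120 s of each HO block,
and the 60 s immediately preceding each stimulus onset as baseline. Late
windows avoid transition ramps; with the simulator's 20-s wash-in time
constant a small carry-over remains in baseline windows that directly
follow a stimulus (about +0.8 mmHg on baseline ETCO2 per adjacent HC
block), which is physiological rather than algorithmic and disappears for
instantaneous transitions.

End-tidal extraction segments breaths at zero-crossings of the
rolling-mean-detrended CO2 trace (the robust respiratory clock; O2 can
reuse those boundaries) and takes the per-breath expiratory maximum (CO2)
or minimum (O2). Two numerical guards matter in noise: the trace is lightly
smoothed (1 s window, shorter than any expiratory plateau at 6–12
breaths/min) before extremum picking, because the raw max/min of noisy
samples is biased outward by extreme-value statistics; and an extremum
sitting on a breath-segment edge is discarded, because it marks an
epoch-transition flank rather than a plateau. Breaths closer than 2 s are
merged. The in-line filter correction is a single multiplicative gain per
gas, and dry fractions convert to partial pressure against
$P_B - 47$ mmHg (expired water vapor).

## ASL quantification and the hyperoxia T1 correction

CBF uses the single-compartment pCASL model
$\mathrm{CBF} = 6000\,\lambda\,\Delta M / (2\,\alpha_{inv}\,M_0\,D(T_1))$
with kernel $D(T_1) = T_1 (1 - e^{-\tau/T_1}) e^{-\mathrm{PLD}/T_1}$. The
2D readout acquires slice $i$ at $\mathrm{PLD} = 0.9 + i\,(1.986-0.9)/20$ s
(brain average 1.443 s over 21 slices). Dissolved O2 shortens arterial
blood T1 during HO; quantifying HO epochs with the normoxic T1 therefore
fabricates an apparent flow decrease. The slice-wise corrective factor
$D(T_{1,\mathrm{ref}})/D(T_{1,\mathrm{HO}})$ removes it (about 1.18 at the
100%-O2 T1 of 1.47 s at the average PLD — e.g. an apparent −17.5% GM
change corrects to about −2.7%). The perfusion series is built by surround
subtraction (control series linearly interpolated to label times); BOLD
comes from echo-2 control volumes only, avoiding label contamination.
Because the per-voxel HO flow response is below ASL noise in practice, a
single GM-probability-weighted HO CBF ratio is applied brain-wide.

## Solver numerics

The intersection is located by a 512-point sign-change scan of
$g(\mathrm{OEF}) = M_{HC}(\mathrm{OEF}) - M_{HO}(\mathrm{OEF})$ over
(0.005, 0.995) — bounds that avoid the singular venous-saturation endpoint —
followed by bisection to $10^{-6}$. Grid cells where either curve's
denominator $1 - f^\alpha r^\beta$ changes sign are poles, not roots, and
are excluded; cells where the venous mass balance turns nonphysical
(negative venous content, saturation ≥ 1) are masked. Multiple genuine sign
changes (noise-induced) return the lowest-OEF root flagged
`multiple_roots`; coincident curves are flagged the same way. A root with
$M \le 0$ reports `invalid_m`. Unsolved voxels carry these reason codes and
are excluded from ROI averaging.

## Repeatability statistics

For two tests per subject: dSD is the $n-1$ SD of per-subject differences,
wsSD $=$ dSD$/\sqrt2$, and wsCV $= 100\sqrt{\mathrm{mean}_i
(\mathrm{wsSD}/\bar{x}_i)^2}$ on the original scale or
$100(10^{\mathrm{wsSD}}-1)$ on the log10 scale; bsCV is the pooled-data CV.
The scale decision screens differences with Shapiro–Wilk and the
|difference|-vs-mean association with Kendall's τ (both at 0.05), moves to
log10 if either rejects, and falls back to the original scale if log10 also
fails. ROI contrasts use two-tailed paired t-tests with Holm–Bonferroni
family-wise correction (Holm dominates plain Bonferroni at the same
guarantee). When wsCVs are summarised "across ROIs", the package averages
per-ROI wsCVs, treating each ROI as one unit.

## The forward simulator

`synth_scene()` builds an ellipsoidal digital phantom (default 32×32×21,
matching a 21-slice readout) with a WM core, GM shell, GM-probability
field, and an optional anterior susceptibility wedge covering 12% of GM in
the lower slices — the order of magnitude of paranasal artifact coverage in
real data. Ground truth is drawn per tissue (GM M ≈ 0.06, OEF ≈ 0.35,
CBF0 ≈ 55; WM lower) inside physiological clamps. `forward_responses()`
applies the exact forward model: HC flow from a CO2 reactivity of 3%/mmHg
in GM (half in WM) on a +8 mmHg hypercapnic ETCO2 step, a uniform true HO
ratio of 0.98 (mild vasoconstriction; corrected in-vivo changes are near
zero, so this is config-exposed), and BOLD fractions from the signal
equation. Wedge voxels get a +2 s⁻¹ dR2* offset with artifact-consistent
(negative) BOLD, which renders them unsolvable by construction.
`forward_timeseries()` synthesises control/label-alternating dual-echo
volumes at TR 4.12 s with the slice-dependent PLD and the
epoch-appropriate blood T1, so the raw HO data carry the T1-shortening bias
exactly as acquired data would.

What the simulator does *not* emulate: physiological (cardiac/respiratory)
noise, motion, EPI distortion or ghosting, arterial transit delays, partial
voluming beyond the GM-probability field, and epoch transition dynamics in
the vascular response (flow and BOLD switch with the block labels). Passing
recovery tests therefore demonstrates correctness of the estimator chain,
not robustness to every in-vivo artifact.

Default noise settings are: 1 mmHg additive Gaussian on gas traces, zero on
responses and time series (noise there is opt-in per protocol spec, e.g.
σ_b = 0.002, σ_f = 0.03 in the Monte-Carlo recovery tests). All generators
are deterministic given (seed, config).

## Problem sizes and runtime choices

The shipped tests and the acceptance script use the default 32×32×21 scene
(~10,000 parenchymal voxels, solved in a few seconds via a vectorised
grid-plus-bisection pass), 12×12×6 scenes for full 4D time-series round
trips, 200 draws for the scale-decision Monte-Carlo at the study's cohort
size of n = 6 (where Kendall's τ is discrete and conservative), and 500
null simulations for the family-wise error check (7 ROIs, 10 subjects).
These sizes were chosen to give stable Monte-Carlo estimates while keeping
a full run comfortably interactive.

## Known limitations

* ETO2 is used as the PaO2 surrogate throughout; systematic end-tidal to
  arterial gradients propagate directly into CaO2 and the T1 estimate.
* The relaxivity slope is a two-point calibration; its uncertainty is not
  propagated.
* The uniform-HO-flow assumption trades regional fidelity for SNR, exactly
  as in the modelled acquisition.
* Hyperoxic CBF changes are treated as percent changes wherever they are
  reported.
* The scale decision is a screening heuristic; with n = 6 its power is
  limited and the original scale is retained by default.
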