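---
title: "Methods: ASL calibration, the kinetic model, and the digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASL calibration, the kinetic model, and the digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Arterial spin labeling (ASL) measures perfusion in arbitrary scanner units.
Absolute cerebral blood flow (CBF, mL/100 g/min) requires *calibration*:

$$\mathrm{CBF} = \frac{\mathrm{CBF}_{rel}}{\alpha\, M_{0a}} \times 6000,$$

where $\alpha$ is the labeling efficiency and $M_{0a}$ the equilibrium
magnetization of arterial blood. $M_{0a}$ is never measured directly; it is
extrapolated from the tissue equilibrium magnetization $M_{0t}$, and the
extrapolation involves a surprisingly long chain of post-processing choices.
This package implements that chain end to end — every mainstream variant of
it — together with a digital phantom that knows its own ground truth, so the
consequences of each choice can be measured rather than argued about.

## Generating $M_{0t}$

Three strategies are implemented:

* **LongTR** (`m0t_longtr`): a separately acquired proton-density scan,
  corrected for incomplete recovery by
  $M_{0t} = S / (1 - e^{-TR/T_{1,t}})$. The correction needs a tissue
  $T_1$ per voxel, taken as the PVE-weighted mix of the per-tissue
  constants. TRs short enough to amplify the signal more than 20-fold are
  refused.
* **CtrAvg** (`m0t_ctravg`): repeat-averaged control images at one TI,
  corrected by $M_{0t} = M_{ctrl} / (1 - A e^{-TI/T_{1,t}})$ with
  presaturation efficiency $A$ (default 0.90, the typical value the
  saturation-recovery fit returns for this kind of sequence). Requires a
  non-background-suppressed acquisition.
* **SatRec** (`m0t_satrec`): voxelwise fit of
  $M_{ctrl}(t) = M_{0t}(1 - A e^{-t/T_{1,t}})$ across all TIs, returning
  $M_{0t}$, $T_{1,t}$ and optionally $A$ (or fixing $A = 1$).

All three use *slice-time-corrected* effective times
$t_\mathrm{eff} = t_\mathrm{nominal} + (s-1)\,\Delta t_\mathrm{slice}$
for ascending 2D multi-slice readouts. The nominal-TI alternative would
mis-correct superior slices by up to half a second on an 11-TI schedule.

## Deriving $M_{0a}$

* **Reference tissue** (`m0a_reference_tissue`): a single value from the
  mean $M_{0t}$ over a homogeneous region,
  $M_{0a} = \langle M_{0t}\rangle_{rt}\,
  e^{TE(1/T^*_{2,rt} - 1/T^*_{2,a})} / \lambda_{rt}$. Masks come from PVE
  thresholds (`build_rt_mask`): restrictive ($\ge 0.9$) or extensive
  ($\ge 0.6$), with the CSF mask optionally intersected with the phantom's
  ventricle labels (the stand-in for an atlas ventricle mask).
* **Voxelwise** (`m0a_voxelwise`): $M_{0a}$ extrapolated in every voxel
  with PVE-weighted $T^*_2$ and a choice of partition coefficient
  ($\lambda_{pve}$ weighted by tissue fractions — the default;
  $\lambda_{avg} = 0.90$; or the majority-tissue $\lambda_{tspec}$,
  ties broken GM > WM > CSF because GM is the reporting tissue), followed
  by in-plane median smoothing (3×3 voxels = 10.5 mm default, 5×5, or
  none). Voxels below 10% of the brain-median $M_{0a}$ are masked so the
  final division cannot blow up.

Tissue constants (3T): $T_1$ = 1.3/1.0/4.3 s, $T^*_2$ = 60/50/400 ms,
$\lambda$ = 0.98/0.82/1.15 mL/g for GM/WM/CSF. Two quantities the
calibration formulas need but the literature table does not pin down are
exposed as configuration with documented defaults: arterial blood
$T^*_{2,a}$ = 50 ms (typical 3T value, identical to the WM entry) and
$\alpha$ = 0.98 (PASL) / 0.85 (pCASL), the consensus-recommendation values.
They are this package's defaults, not values asserted by any one study.

## Coil-sensitivity bias

Reference-tissue calibration breaks when the receive coil is inhomogeneous:
the mask samples one part of the field, the GM voxels another. The
voxelwise route cancels any multiplicative field exactly, because the same
field multiplies $\mathrm{CBF}_{rel}$ and $M_{0a}$ — the package's tests
verify this invariance to < 1% in interior voxels under a 1.3
peak-to-trough field. For the reference-tissue routes,
`estimate_bias_field` approximates the field from the data: each voxel's
expected intensity is predicted up to a global scale from its tissue
composition, $\lambda_{pve} e^{-TE/T^*_{2,pve}}$, and the log-ratio of
observed to predicted intensity is fit with a third-order polynomial
surface over the brain (strictly positive, mean 1, by construction). The
prediction assumes a saturation-free $M_{0t}$ map; running it on an
uncorrected CtrAvg/LongTR map degrades it, exactly as segmentation-based
estimators degrade on real uncorrected data.

# The kinetic model

Relative perfusion comes from fitting the multi-TI/PLD difference signal
(`fit_volume`). The model is the general kinetic model with a single
well-mixed tissue compartment plus a non-exchanging macrovascular box-car:

* tissue: $\Delta M(t) = 2 f \int_{att}^{\min(t,\,att+\tau)} c(s)\,
  e^{-(t-s)/T_{1,t}}\,ds$ with delivery $c(s) = e^{-s/T_{1b}}$ (pulsed) or
  $e^{-att/T_{1b}}$ (pseudo-continuous);
* arterial: amplitude $2\,\mathrm{aBV}$ on
  $att_{art} \le t < att_{art} + \tau$ with blood-$T_1$ decay.

The closed forms are verified against numerical quadrature to $10^{-6}$ in
the test suite. The apparent tissue decay uses the tissue $T_1$ without a
flow correction (a second-order effect at physiological perfusion). The
pulsed bolus duration follows the Q2TIPS truncation rule
($\tau = TI - 25$ ms below 1 s, 750 ms above). One caveat stated plainly:
studies of this design typically fit a Bayesian variational scheme with
spatial priors; this package substitutes bounded least squares, which is
deterministic and dependency-free but is *not* that estimator.

## How the fit is solved

The model is linear in $(f, \mathrm{aBV})$ at fixed arrival times, and the
arterial box-car makes the residual piecewise-constant in $att_{art}$
(only the set of sampled time points inside the box matters). The fitter
therefore enumerates the finitely many arterial designs exactly, projects
the amplitudes out by closed-form nonnegative least squares, and optimizes
only the transit time continuously (coarse grid, refinement of every local
minimum, then a fine sweep around the incumbent — the active arterial
plateau can switch within a bracket and carve narrow secondary dips that
golden-section search would skip). This replaces a generic trust-region
least squares, which stalls on the box-car discontinuities; amplitudes
remain exact linear solutions, and the procedure is deterministic.

With 11 pulsed-ASL TIs the noiseless fit recovers $(f, att, \mathrm{aBV})$
to solver tolerance. With only 6 pCASL PLDs the model admits genuine
aliases: configurations with different $(att, att_{art})$ that reproduce
all six noiseless samples to machine precision. The fitter resolves ties by
RSS and cannot distinguish exact aliases; on the phantom this affects a few
percent of voxels and moves the GM-mean by < 1%. This is a property of the
schedule, not of the optimizer, and is one reason multi-PLD protocols in
practice constrain the arterial component with priors.

# The digital phantom

`make_phantom` builds a concentric-shell brain (ventricular CSF core, WM
shell, GM rim, thin sulcal CSF film) on a 32×32×8 grid of
3.5×3.5×5 mm voxels — the 2D EPI protocol the package emulates. The layout
is columnar across slices so the ventricle survives partial-voluming on
5 mm slices. Binary labels are blurred (FWHM 3.5 mm = one in-plane voxel by
default) to emulate the partial volumes created by resampling sharp
segmentation boundaries onto the ASL grid; heavier blur makes "restrictive"
PVE ≥ 0.9 masks measurably impure and biases all reference-tissue methods —
a real effect worth studying, but not the regime in which reference-tissue
calibration is defined. Ground truth: CBF 60/20 mL/100 g/min (GM/WM),
ATT 0.7/1.0 s, aBV 1% of the GM fraction, arterial arrival 0.3 s before
tissue arrival, $M_{0t} = \lambda \cdot M_{0b}$ (which makes the
reference-tissue and voxelwise routes mutually consistent by construction),
and a centre-dark quadratic coil profile with configurable peak-to-trough
ratio (default 1.3, emulating a multi-channel array whose sensitivity is
lowest in the centre of the head — precisely where the ventricle mask
lives).

Simulation choices, stated once:

* **Noise** is Gaussian and additive per volume (not Rician): every
  quantitative test here runs at moderate-to-infinite SNR where the
  distinction is negligible, and magnitude-bias modeling is out of scope.
* **Background suppression** (pCASL flavour) is a single static attenuation
  factor (default 0.3) applied to the static tissue signal only; the
  attenuation of the labeled bolus itself is conventionally absorbed into
  $\alpha$. Applying the factor to the difference signal as well would make
  absolute CBF unrecoverable by *any* calibration method, which is not how
  background-suppressed ASL is quantified in practice. The separate
  calibration scan is never suppressed. Pulse-timing simulation is a
  non-goal, and the attenuation value is a config flag, not a measured
  quantity.
* **Slice timing**: ascending 2D multi-slice, effective time
  $t + (s-1)\Delta t$; recorded in the dataset metadata and honoured by
  both the simulator and every fitting/correction routine.

What a green test establishes — and what it does not: the phantom has
piecewise-constant anatomy, no motion, no physiological noise, no $B_0$
distortion, and tissue parameter maps that mix linearly with PVE (including
$T^*_2$, where real signal mixing is exponential per compartment). Green
round-trip tests demonstrate internal consistency of the full pipeline and
the *relative* behaviour of calibration options; they do not certify
absolute accuracy on scanner data, and reported test-retest CVs of real
cohorts are deliberately not reproduction targets (scanner noise is not
modeled — the reproducibility machinery is exercised on cohort-level
simulations instead).

# Reproducibility machinery

`cv_metrics` computes the standard coefficients of variation on
per-subject, per-session GM summaries: within-subject SD over subject mean
averaged across subjects (CV$_{intra}$), and SD of subject means over the
grand mean (CV$_{inter}$), both in percent. `jackknife_compare` forms
leave-one-subject-out replicates of each CV per method and runs pairwise
paired *t*-tests between methods on the replicates ($P < 0.05$,
unadjusted); an omnibus repeated-measures ANOVA is intentionally not
implemented. `option_sweep` evaluates the one-at-a-time option grid around
each method's defaults and reports GM CBF (mean and median — group
comparisons conventionally use the mean, CV analyses the median, so both
are always carried) plus percent deltas against the default of the same
method pair; deltas are only meaningful between runs differing in exactly
one option, which the grid enforces by construction.

# Numerical details and degenerate inputs

* Saturation-recovery fitting: bounded L-BFGS-B from (max signal, 1.3 s,
  0.9), $T_1 \in (0.2, 6)$ s, $A \in [0, 1.2]$. A flat series fits as
  $A \to 0$, $M_{0t}$ = the signal; all-zero voxels and non-converged fits
  are flagged, never silently zeroed.
* All-zero difference series: perfusion at the lower bound (0), flagged.
* Median smoothing operates in-plane on brain-masked neighbourhoods only —
  no mixing with background zeros at the brain edge.
* Masked or zero $M_{0a}$ voxels propagate as `NA` through Eq.-(1)
  division, never infinity.
* Echo times below 1 ms are rejected as a likely seconds/ms unit mix-up.

# File formats

No NIfTI library is assumed: volumes are exchanged as a JSON text format
(`write_volume_json`) whose metadata block carries the sidecar fields
(sequence, per-volume TI/PLD, bolus durations, TE, TR, slice time,
$\alpha$, $A$, background-suppression settings). `write_asl_dataset` /
`read_asl_dataset` and `write_m0_map` / `read_m0_map` round-trip datasets
and $M_0$ maps with full option provenance. A command-line entry point
(`inst/cli/aslcalib.R`) wraps simulation, fitting and both calibration
stages.
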