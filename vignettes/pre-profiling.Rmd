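---
title: "Methods: PRE profiling, solvent-PRE charge mapping, and the distance census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRE profiling, solvent-PRE charge mapping, and the distance census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premap)
```

## The problem premap addresses

Large flexible loops are hard to see. Crystal structures lose their
electron density, and classical relaxation experiments only report on the
ordered parts of a protein. Nitroxide spin-label paramagnetic relaxation
enhancement (PRE) fills this gap: an unpaired electron placed in the
middle of a mobile loop accelerates the transverse relaxation of every
NMR-visible nucleus within roughly 25 Å, attenuating its peak. Because
the effect scales as the ensemble average of r^-6, even a small
population of close approaches leaves a strong, detectable footprint.

`premap` implements the quantitative analysis chain for such experiments
on a homodimeric enzyme whose allosteric loop is probed by
methyl-detected spectra: intensity-ratio PRE profiles, two-time-point
PRE rates, effector-difference maps, dual-cosolute solvent-PRE
("effective net charge") maps with a significance filter, methyl
chemical-shift perturbations, and an inter-/intra-protomer distance
census over simulation snapshots. A synthetic forward model generates
every input with known ground truth, so each stage is validated by
parameter recovery rather than by eye.

## PRE intensity ratios

For each methyl peak matched between a diamagnetic and a paramagnetic
sample,

$$I_\mathrm{ratio} = \frac{I_\mathrm{dia}}{I_\mathrm{para}\cdot c},
\qquad c = \frac{[P]_\mathrm{para}}{[P]_\mathrm{dia}},$$

so a ratio of 1 means no PRE and larger values mean stronger broadening.
The uncertainty uses standard first-order propagation of the baseplane
noise of the two spectra,

$$\sigma_R = R\sqrt{(\sigma_\mathrm{dia}/I_\mathrm{dia})^2 +
(\sigma_\mathrm{para}/I_\mathrm{para})^2},$$

with the concentration correction treated as error-free. The test suite
checks this form against a seeded 10^5-draw Monte-Carlo propagation; for
noise up to 10% of the peak intensity the two agree to well under 5%
relative (the exact ratio distribution is slightly heavier-tailed than
the first-order estimate, an effect of order (σ/I)^2).

**Bleached peaks.** A paramagnetic peak below
`bleach_snr_threshold * noise_sigma` (default 3, a conventional
detection limit; the threshold is configurable) — or missing from the
paramagnetic table entirely — cannot yield a finite ratio. Such peaks
are flagged `bleached` and their ratio is stored as a *lower bound*
evaluated at the detection limit, never as a point estimate. For peaks
missing from the paramagnetic table the bound uses the median
paramagnetic-table noise, since baseplane noise is a property of the
spectrum, not the peak.

**Groups.** Profiles can be annotated with a proximal/distal residue
grouping (`pre_groups_default()`): residues near the labelled loop's
stubs and edges (group 1) versus distal residues whose PREs can only
arise from transient loop excursions (group 2). The grouping is a
configuration fixture, not a clustering — the distinction is structural,
and the default lists are editable.

## Two-time-point PRE rates

With intensities of the same peak at two evolution delays
$T_a < T_b$ in both samples, the PRE rate
$\Gamma_2 = R_{2,\mathrm{para}} - R_{2,\mathrm{dia}}$ follows exactly
from the two exponential decays sharing a diamagnetic baseline:

$$\Gamma_2 = \frac{1}{T_b - T_a}\,
\ln\frac{I_\mathrm{dia}(T_b)\,I_\mathrm{para}(T_a)}
{I_\mathrm{dia}(T_a)\,I_\mathrm{para}(T_b)}.$$

`gamma2_two_point()` is the exact inverse of this forward model; the
tests verify recovery of planted rates across 0–200 s^-1 to 1e-10 s^-1
on noiseless input. When any intensity reaches the noise floor the rate
becomes a lower bound, computed with the offending intensity clamped to
the floor — mirroring how strongly broadened peaks are reported in
practice.

## Effector-difference profiles

`delta_intensity()` forms per-peak differences of two ratio profiles
(e.g. activator-bound minus inhibitor-bound) with quadrature errors.
Differences are antisymmetric by construction. Pairs with a bleached
side are reported as sign-only records: a peak bleached under one
effector but finite under the other still tells you which state has the
stronger PRE, and that information is kept rather than dropped.

## Solvent-PRE effective net charge

Two freely diffusing nitroxide cosolutes of opposite charge broaden
peaks near oppositely charged surface patches. Running the ratio
analysis for each cosolute against a shared cosolute-free reference and
combining,

$$\phi = I_\mathrm{ratio}^{-} - I_\mathrm{ratio}^{+},\qquad
\sigma_\phi = \sqrt{\sigma_{I^+}^2 + \sigma_{I^-}^2},$$

gives a signed per-residue parameter: $\phi > 0$ marks a net positively
charged region (the negative cosolute accumulates there and broadens
more strongly). This sign order is the package default because it is
the one consistent with the ratio convention (larger ratio = stronger
PRE); the opposite order is available as a `convention` switch. $\phi$
is a proxy for the near-surface electrostatic environment, not a
potential in physical units, and residues whose peaks bleach under
either cosolute are excluded from $\phi$ but reported.

**pH differences and the significance filter.** For two constructs
measured at two pH values, `delta_phi()` forms
$\Delta\phi = \phi_{\mathrm{pH\,low}} - \phi_{\mathrm{pH\,high}}$ per
construct and `significance_filter()` computes
$\Delta\Delta\phi = |\Delta\phi_\mathrm{mut} - \Delta\phi_\mathrm{wt}|$.
A residue is called significant when

* $\Delta\Delta\phi \ge$ `ddphi_threshold` (default 0.4), and
* in **all four** underlying samples,
  $\sigma_\phi \le$ `sigma_fraction` $\cdot\,|\phi|$ (default 20%).

The absolute value in the second criterion keeps the filter well-defined
for negative $\phi$; the filter is applied to the four $\phi$ values
rather than the per-cosolute ratio errors, which is the most literal
well-defined reading of "all four samples". The filter is monotone in
the threshold (raising it never adds residues), residues missing any
sample are excluded with an explicit reason, and the full audit trail
(all four $\phi \pm \sigma_\phi$, both $\Delta\phi$, both flags) is
retained per residue.

## Chemical-shift perturbations

`csp()` uses the standard two-nucleus quadrature form
$\sqrt{\Delta\delta_H^2 + (0.133\,\Delta\delta_C)^2}$, compressing the
carbon axis by the conventional methyl scaling factor 0.133. No
significance cutoff is baked in: `csp_top()` ranks perturbations and
accepts a user cutoff, because a defensible threshold depends on the
shift dispersion of the particular spectra.

## The distance census

`distance_series()` measures, in every snapshot frame, the Euclidean
distance from the loop reference atom of each chain to the active-site
reference atom of each chain — four values per frame for a dimer, with
same-chain pairs classed `intra` and cross-chain pairs `inter`. The
default selectors target the S220 hydroxyl proton (loop) and the V197
methyl γ1 proton (active site), with ordered fallback to the parent
heavy atoms (Oγ, Cγ1) for heavy-atom-only snapshot sets; any fallback is
reported. Selector ambiguity (two atoms matching in one chain) is an
error, not a silent pick.

Summaries follow the counting conventions of the field:
`close_fraction()` uses the half-open window [5, 15) Å by exact integer
counts (15 Å being the conventional strong-PRE threshold, 5 Å a physical
lower bound for a non-clashing approach); `min_class_distance()` reports
the exact minimum, used to check that intra-protomer approaches never
enter the ~25 Å PRE-detectable range. Coordinates are taken as exported;
no periodic-boundary reconstruction is attempted — whole-molecule
imaging belongs to the trajectory exporter. Frames are equally weighted.

The census is verified against an independent brute-force double loop
(bit-identical on 20-frame sets) and is invariant under rigid
transformations of each frame to 1e-9 Å.

## The synthetic forward model

`loop_ensemble_model()` realizes the measurement physics the analyses
assume, with ground truth recorded for every draw:

* the spin label samples a weighted set of positions; the PRE rate at a
  probe is $\Gamma_2 = K \sum_i w_i r_i^{-6}$ (fast-exchange
  population-weighted averaging — appropriate for a highly flexible
  loop; exchange-regime modelling is out of scope);
* the full Solomon–Bloembergen prefactor is lumped into one constant
  $K$ (Å^6 s^-1). By default $K$ is calibrated so that
  $\Gamma_2(25\,\text{Å})\cdot t = 0.05$, i.e. a probe at the 25 Å
  observability ceiling is attenuated ~5% over the evolution time
  $t = 10$ ms — at or below the detection limit for ~1% peak noise;
* intensities are $I_\mathrm{dia} = I_0 + \varepsilon$ and
  $I_\mathrm{para} = I_0\,e^{-\Gamma_2 t}/c + \varepsilon$ with Gaussian
  $\varepsilon$, clipped at zero (clipping recorded in the truth table);
  defaults $I_0 = 10^5$, $\sigma = 10^3$ (1% noise, a typical
  well-resolved methyl SNR).

The r^-6 average makes minor populations dominate: 8% of the weight at
10 Å outweighs 92% at 40 Å by a factor of ~350 (the far population is a
~0.28% correction), which is precisely why transient loop excursions
are PRE-detectable. The tests assert this closed form exactly.

`surface_charge_model()` couples cosolute PRE rates to a planted signed
charge parameter $\psi$ Boltzmann-like,
$\Gamma_2^{\mp} = \gamma_0\, e^{\pm\kappa\psi}$ — the simplest monotone
model that preserves the sign logic the analysis tests. Defaults
$\gamma_0 = 5$ s^-1, $\kappa = 1$, 2% peak noise give recovered $\phi$
that track $\psi$ in sign and rank, as the tests verify.

`generate_snapshots()` plants the distance structure directly: per
frame, each inter-protomer loop–site distance is close
(uniform in 5–15 Å) with probability `f_close_inter` (default 0.08, the
activator-state condition; the inhibitor-state condition uses a
fraction below 1%) and far (uniform in 25–45 Å) otherwise, while both
intra-protomer distances are always far. The four distances are then
realized as explicit 3D coordinates (two chains, random rigid pose per
frame), so the census *measures* geometry rather than reading planted
numbers back. Four independently drawn distances among four points are
not always jointly embeddable in 3D; when the two triangle-inequality
windows on the site–site separation are disjoint, only the intra
distances are redrawn (still within the far range). The inter close/far
assignment — the statistic under test — is never altered, and the intra
contract (all > 25 Å) is preserved; the intra marginal distribution is
thereby very slightly biased, which no analysis in the package depends
on.

## What the generator does not emulate

Passing recovery tests demonstrates the correctness of the analysis
arithmetic and bookkeeping, not the realism of the physics. The
generator omits: spin-label rotamer distributions and correlation-time
physics (lumped into $K$); explicit electrostatics (the $\psi$ coupling
is phenomenological); chemical-shift changes (shift columns are left
empty); peak overlap, assignment errors, and non-Gaussian spectral
artefacts; and conformational exchange outside the fast limit. Results
on real spectra inherit all of those complications.

## Numerical and design choices

* **Ratio form.** The concentration correction divides the paramagnetic
  intensity (`I_dia / (I_para * c)`); the generator uses the matching
  convention, so planted ratios are recovered exactly and the
  correction cancels end-to-end.
* **Error model.** First-order propagation throughout, validated
  against Monte Carlo; the ratio error is treated as symmetric, which
  is adequate for σ/I ≤ 0.1.
* **Bleach threshold.** 3σ by default, configurable; at the threshold a
  peak is bleached (`<` comparison), and bounds are evaluated exactly at
  the limit.
* **Half-open windows.** `close_fraction()` counts `low <= d < high`,
  so a distance exactly at 15 Å is not "close"; counts are integers
  before any division.
* **Determinism.** Every generator takes a seed and is bit-reproducible;
  the pipeline writes content hashes of all inputs and outputs, echoes
  every effective parameter into its run log, and skips stages whose
  inputs and parameters are unchanged.
* **Problem sizes.** The test suite and the acceptance script run at
  desk scale: 100-point rate-recovery grids, 10^5-draw Monte Carlo,
  30-residue charge panels, and 600-frame snapshot sets (1200
  inter-protomer records), which keeps binomial recovery bounds tight
  (±1.6 percentage points at 2σ for a planted 8% fraction).

## Limitations

Bleached-peak bounds depend on the configured detection threshold and
on a spectrum-wide noise estimate for missing peaks. The two-time-point
rate estimator assumes clean exponential decay between exactly two
delays; fitting full decay curves is out of scope. $\phi$ ignores
specific cosolute binding (a recognized caveat of the dual-cosolute
method) and is not convertible to millivolts here. The census reads
exported snapshots only — it does not run or re-image simulations, and
R/T-state classification of frames is deliberately not attempted.
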