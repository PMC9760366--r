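---
title: "Methods: convergent dual-readout screening for exosome modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent dual-readout screening for exosome modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomod)
```

## The screening problem

Exosomes are 40–150 nm extracellular vesicles that bud as intraluminal
vesicles (ILVs) into multivesicular bodies (MVBs) and are released when the
MVB fuses with the plasma membrane. A compound can lower the amount of
exosomes a tumour cell sheds in two mechanistically distinct ways: by
blocking *release* (vesicles are still made, so they accumulate inside the
cell) or by blocking *biogenesis* (vesicles are never made). A single
extracellular measurement cannot tell these apart.

`exomod` implements a convergent analysis that combines two readouts taken
from the same treated wells:

* **Extracellular**: an AlphaScreen-type proximity assay on the culture
  supernatant (raw counts proportional to CD9/CD63 double-positive vesicles
  shed into the medium), normalized per nucleus.
* **Intracellular**: high-content imaging of LBPA, an atypical phospholipid
  enriched in MVB/ILV membranes, whose punctate immunofluorescence proxies
  the intracellular exosome precursor pool, quantified as granules per cell.

Crossing the two three-state readouts yields the mechanism call:
low outside + high inside = release inhibitor; low outside + low inside =
biogenesis inhibitor; high outside + high inside = biogenesis activator.

## Plate model and normalization

Each well record carries raw counts and a nuclei count. The pipeline:

1. **Per-nucleus signal** `alpha_counts / nuclei` (wells with zero nuclei
   are excluded with a message, never imputed).
2. **Percent of control**: division by the *mean* per-nucleus signal of the
   vehicle wells of the same cell-line context, ×100. Using the mean (not
   the median) makes the vehicle group average exactly 100 by construction,
   which the downstream cut-offs assume. Normalization is invariant to any
   global rescaling of the counts.
3. **Viability gate**: a condition whose mean nuclei fall below
   `1 - max_toxicity` of the vehicle mean is excluded from hit calling, and
   the exclusion is reported. The default `max_toxicity = 0.20` reflects the
   screen design (compounds dosed at less than 20% toxicity); a stricter
   0.15 is a one-argument change because both conventions are in use.

**Z'-factor.** Assay quality is summarised by
\[ Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|} \]
over the per-nucleus signals of the positive (exosome-enriched supernatant)
and negative (medium-only background) assay-control wells, using sample
standard deviations (n−1). Z' is at most 1, is symmetric in the two groups,
and values above 0.5 indicate an excellent assay; the synthetic default
plate is tuned to sit comfortably above 0.75.

## Hit calling and the decision table

A percent-of-control value is classified **LOW** strictly below 80%, **HIGH**
strictly above 120%, otherwise **UNCHANGED**; boundary values (exactly 80 or
120) are UNCHANGED. For the extracellular readout only the HIGH (activator)
side additionally requires Dunnett significance — a reduced signal below 80%
is a hit on its own; for the intracellular LBPA readout both directions
require significance. Both behaviours and both cut-offs are arguments.

The decision table is total over all nine state pairs:

| exo \\ LBPA | LOW | UNCHANGED | HIGH |
|---|---|---|---|
| **LOW** | biogenesis inhibitor | unclassified | release inhibitor |
| **UNCHANGED** | inactive | inactive | inactive |
| **HIGH** | unclassified | unclassified | biogenesis activator |

Two deliberately conservative choices: `(HIGH, LOW)` is *unclassified*
rather than a "release activator" — the screen defines only three mechanism
outcomes, and inventing a fourth label would overstate what the two readouts
support; `(HIGH, UNCHANGED)` is likewise *unclassified* (an extracellular
activator signal without intracellular corroboration), while any pair with
an UNCHANGED extracellular state is *inactive*. A screen "inhibitor" count
refers to test compounds with a LOW extracellular state, whatever their
mechanism call.

## Image pipeline

Per field (three 16-bit channels):

* **Nuclei** (Hoechst): Gaussian smoothing (σ = 2 px) → global Otsu
  threshold → removal of objects below `min_nucleus_area` (100 px) →
  distance-transform watershed to split touching nuclei. A blank,
  low-contrast field returns an empty mask rather than an error; the
  `min_contrast` floor (0.02 of the 16-bit range) prevents Otsu from
  hallucinating foreground in pure noise.
* **Cells** (phalloidin): foreground = smoothed channel above Otsu, united
  with the nucleus pixels; cells grow from the nucleus seeds by seeded
  propagation over the cytoplasm intensity (the seeded-watershed operator of
  the EBImage stack), so every cell label equals its seed nucleus label and
  adjacent cells split along the propagation boundary. A nucleus outside the
  cytoplasm foreground keeps a nucleus-only cell.
* **Granules** (FITC): white top-hat at the granule scale (disc radius 7 px)
  removes background and any constant offset; the top-hat image is
  thresholded at `median + 5·MAD` — a data-adaptive cut, so doubling all
  intensities changes nothing; merged spots are declumped by an intensity
  watershed (`split_tolerance` = 500 grey levels, deep enough that noise
  never splits a single spot); components are kept within
  `[min_granule_area, max_granule_area]` = [4, 400] px. Fields with more
  than half their pixels saturated are flagged low-confidence.
* **Linking**: each granule is assigned to the cell label under its
  intensity-weighted centroid; granules over background are extracellular
  artifacts, counted separately and excluded from every per-cell metric —
  this is the step that makes the intracellular readout robust to staining
  debris outside cells.

All operator choices and sizes are package parameters with the defaults
above; the reference analysis software for this assay is proprietary and
does not document its operators, so these are this package's own,
deliberately standard, choices.

**Well aggregation** pools all fields of a well before dividing: granules
per cell = total in-cell granules / total nuclei (a ratio of totals, robust
to fields with few cells), plus the fraction of granule-positive cells and
mean granule area/intensity. Area and intensity are reported but not used by
the classifier, which consumes only the count-based metric. LBPA percent of
control uses the same vehicle-mean anchoring as the plate readout.

## Statistics

* **Dunnett many-to-one**: every condition against the shared vehicle
  control, two-sided, pooled within-group variance, adjusted p =
  `1 − P(max|T| ≤ |t|)` under the multivariate t with correlation
  `sqrt(λ_i λ_j)`, `λ_i = n_i/(n_i+n_0)`, evaluated by the Genz–Bretz
  quasi-Monte-Carlo algorithm under a fixed seed (reproducible; the
  integration error ~1e-5 is negligible at screening scale). With a single
  comparison this reduces exactly to the pooled t-test. The two readouts are
  tested separately, each against its own control wells, per context.
* **One-way ANOVA** for the overall condition effect (equal-variance F).
* **Dose–response trend**: a Jonckheere–Terpstra ordered-alternative rank
  statistic against the dose order with a permutation null (default 10,000
  label permutations, seeded; p uses the add-one convention so its floor is
  1/(B+1)). The `monotone` flag marks a significant *decreasing* trend at
  α = 0.05, i.e. dose-dependent inhibition. Rank-based trend testing was
  chosen over fitting a four-parameter logistic because the screen ladders
  have few dose levels and the question is ordinal (is inhibition
  dose-dependent?), not parametric (what is the IC50?).

Significance is starred at the conventional 0.05/0.01/0.001 levels.

## What the synthetic data emulate — and what they do not

**Plates.** Wells are drawn as
`baseline · effect_multiplier · viability · LogNormal(1, cv)` with
independent log-normal noise on counts and nuclei (positive support,
multiplicative — the natural model for plate-reader noise; the source assay
reports no noise model). Defaults: 6 wells per condition, baseline 50,000
counts and 2,000 nuclei per well (the absolute scale of the plate reader is
arbitrary and cancels in normalization), `noise_cv = 0.04` — a realistic
well-to-well CV for an optimized AlphaScreen assay, and the value at which
the simulated assay-control separation yields Z' ≈ 0.83 on average,
matching the quality regime the assay is designed to operate in (> 0.75).
Positive/negative assay controls are simulated at 2× and 0.02× of the
vehicle signal (exosome-enriched supernatant vs medium-only background).

**The reference fixture** encodes the screen outcome the analysis must
reproduce: per-compound effect classes in two breast-cancer cell contexts
(four shared release inhibitors; dinaciclib an inhibitor only in MCF7;
the remaining panel members activators by the extracellular readout, a
subset with corroborating high LBPA), three mechanism reference compounds,
and MCF7 dose ladders in which biscurcumin falls monotonically across all
doses while docetaxel and primaquine show no dose trend. Effect *magnitudes*
are invented (the underlying screen reports them only graphically) and are
placed far enough from the 80/120 cut-offs that 4% well noise cannot flip a
class; the fixture uses an internal fixed RNG state, so it is bit-identical
on every call without a user seed. Because Dunnett testing needs a
within-group variance estimate, the fixture is noisy rather than noiseless.

**Images.** Cells are non-overlapping disks (radius 45 ± 10% px in a
500×500 field) each with one nucleus disk (radius 12 px); granules are
Gaussian spots (σ = 1.5 px, amplitude 8,000 grey levels) placed uniformly
in the cytoplasm with a Poisson(5) count per cell; artifacts are identical
spots outside every cell; all channels get a 400-level background and
Gaussian read noise (SD 40). This emulates the geometry and photon budget of
a 20×/sCMOS acquisition well enough to exercise segmentation, declumping and
linking, but deliberately omits optical PSF blur, illumination gradients,
cell-shape irregularity, out-of-focus light and subcellular texture — so
passing the recovery tests demonstrates the pipeline's internal correctness,
not its performance on real micrographs, whose parameters would need
re-tuning (principally `tophat_radius`, the area bounds and
`min_nucleus_area`).

## Numerical and degenerate-input conventions

Masks are integer matrices with 0 background and positive labels; centroids
are sub-pixel (intensity-weighted). Blank fields give empty masks/lists, not
errors; a well with no nuclei in any field is invalid; equal control means
make Z' undefined; all-zero within-group variance is a degenerate input for
the tests; a missing vehicle group errors naming the context. Percent
boundaries are strict inequalities. Generators reject non-finite
configuration values and restore the caller's RNG state after use.

## Problem sizes

The packaged tests run the full pipeline on the 240-well reference screen,
a complete 20-field well (≈200 cells) for granule recovery, 1,000 null
simulations for ANOVA calibration, and 20,000-permutation maxT checks —
sizes chosen so the whole suite completes in well under a test session on a
single core while keeping Monte-Carlo error far below the asserted
tolerances.

## Known limitations

* Granule declumping cannot separate spots closer than ~2.5 px; at the
  default density this biases counts down by ~2–3%, well inside the
  recovery tolerances, but dense clustering would need a different detector.
* No plate-effect (edge/drift) correction; wells are exchangeable by design.
* The classifier consumes only granule counts; area/intensity are emitted
  for audit only.
* Dose–response is tested ordinally; no IC50 estimation.
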