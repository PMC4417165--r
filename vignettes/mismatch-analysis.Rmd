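---
title: "Methods: structural analysis of mismatched B-DNA ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of mismatched B-DNA ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`mmduplex`, in the spirit of a methods section: what each quantity means,
why each default is what it is, and what the synthetic test bed does and
does not establish about real data.

## The reduced-atom duplex model

Every nucleotide carries the heavy atoms of its planar base (9-atom purine
or 6-atom pyrimidine ring plus the exocyclic O/N hydrogen-bond partners and
the thymine methyl carbon), the C1′ anchor, a pseudo-O4′ placed at build
time to realise a requested glycosidic torsion, and a single backbone P
pseudo-atom. This is the minimal chemistry that supports every analysis in
scope — frame fitting, hydrogen bonds, χ, groove widths — without modelling
the full sugar-phosphate backbone. Base geometries are the idealized planar
bases of the standard reference frame convention (origin near the pair
centre, x toward the major-groove edge, y toward the sugar of the owning
strand, z along the stack normal); they are versioned directly in the
package source (`R/base_geometry.R`). The P offset in the base frame,
(−5.00, 7.42, 1.60) Å, was calibrated once so that a straight fiber build
reproduces B-DNA groove dimensions (raw cross-strand P–P minima ≈ 11.7 Å
minor / 18.2 Å major, i.e. widths ≈ 5.9 / 12.4 Å after the 5.8 Å phosphate
radius correction).

## Helical parameter decomposition

Intra-pair and step parameters use one symmetric mid-frame (CEHS-style)
scheme. For two frames the z axes are rotated onto their bisector about the
hinge (z₁ × z₂), the twist-like angle is measured between the y axes about
the common z, the mid-frame y is the bisector of the two rotated y axes,
and the roll/tilt (propeller/buckle) pair is the hinge rotation resolved by
its phase angle against the mid-frame y. Translations are the origin
difference expressed in the mid-frame. The Crick frame is flipped 180°
about its x axis before pairing. The builder implements the closed-form
inverse of this decomposition, which gives the package's central contract:
**analysing a built structure reproduces every planted parameter to
~1e-12** (tested over thousands of random tables with translations up to
±3 Å and rotations up to ±60°). No agreement with any specific published
helical-analysis program is promised — mid-frame schemes differ in detail
between tools — only internal exactness and the standard symmetry
properties (strand relabelling negates exactly shear, buckle, shift and
tilt and preserves the other eight, verified numerically).

## Global descriptors

The helical bend of a snapshot is the angle between the mean local helix
axes (mid-step z vectors) of two terminal three-step windows, after
discarding the outermost step at each end against end effects. This is a
two-window axis angle, a deliberately simple substitute for curvilinear
axis fitting; it is exact for a single localized kink (a lone 20° roll
yields a 20.0° bend) and zero for straight builds. Total twist defaults to
the sum over **all** steps (12 × 36° = 432° for a fiber-like 13-mer); the
step range is exposed because published per-duplex twist totals depend on
unreported averaging windows, and no claim is made of matching any
particular table of values.

## Glycosidic states

χ is the signed dihedral O4′–C1′–N9–C4 (purines) or O4′–C1′–N1–C2
(pyrimidines). Conformer bins are declared explicitly, since the
conformational-region names are used loosely in the literature:
*anti* (120°, 180°] ∪ (−180°, −90°], *high-anti* (−90°, −30°],
*syn* (−30°, 90°], *other* (90°, 120°].

## Hydrogen bonds, schemes, breathing

The reduced model carries no hydrogens, so bonds are scored on heavy-atom
geometry: donor–acceptor distance ≤ 3.5 Å and a pseudo-hydrogen D–H…A angle
≥ 135°, with the hydrogen reconstructed from the donor's covalent
neighbours (external ring bisector for imino donors; the in-plane amine
position nearer the acceptor for amino donors). Pairing schemes are
editable YAML catalogs (one file per pair type, `inst/extdata/schemes/`)
listing donor→acceptor atom pairs by strand; a frame is labelled by the
scheme whose bond set is fully formed, ties resolved by bond count then
catalog order, with an explicit `unassigned` sink. Occupancies therefore
sum to one by construction. Sugar O4′ acceptors are permitted.

Breathing classifies a frame as open when the opening angle deviates from a
reference (by convention the canonical-control ensemble median at the same
position; the series median by default) by more than 45°, sustained for at
least 2 frames — the hysteresis suppresses single-frame flickers. Both
thresholds are configuration-exposed because no community-standard
criterion exists at this level of description; positive excursions are
major-groove by the opening sign convention. Summaries (occupancy %,
transitions, mean/max residence per direction) come from run-length
encoding and are tested to agree exactly with a brute-force per-frame scan.

## Grooves and the ion atmosphere

Minor groove width at pair i is the minimum distance from the Watson P of
pair i to the Crick P of pairs i−2 and i−3, minus 5.8 Å; the major groove
uses i+2..i+3. Windows that do not fit near the termini give NA, never
zero. Cation density maps accumulate ion counts in radial (0.5 Å) ×
angular (10°) bins of a ±1.7 Å slab (about half a helical rise) around the
plane of a chosen pair, in that pair's own frame (θ = 0 at the
major-groove centre). Molarity = count / (frames × bin volume ×
6.022·10⁻⁴ ions Å⁻³ M⁻¹); the inverse identity Σ molarity·V·6.022·10⁻⁴ =
mean in-slab count holds exactly and is asserted in the tests. The local
pair frame is a declared substitute for a curved global axis; for strongly
bent snapshots the slab tilts with the lesion pair.

## Ensemble statistics

The average structure iterates superposition-to-mean until the mean moves
by less than 1e-6 Å. Clustering is average-linkage on the pairwise fitted
RMSd matrix, cut at a user RMSd; the representative is the medoid of the
largest cluster with lowest-index tie-breaks, so the result is
deterministic. Stiffness constants use the univariate equipartition
relation k = k_BT / Var(x) with k_B fixed at 0.593/298 kcal · mol⁻¹ · K⁻¹
so that k_BT at 298 K equals the conventional 0.593 kcal/mol exactly (0.13%
from CODATA, far below sampling error of any variance estimate used here).
A full covariance (stiffness-matrix) treatment is out of scope because the
quantities of interest are three scalar constants per duplex. Angular
series use Fisher–Lee circular correlation; circular–linear pairs use
Mardia's coefficient, which is non-negative by construction.

## Lesion information transfer

For each (position, parameter) cell the mismatch ensemble is compared to a
control on the same grid: the absolute difference of means, SDs, naive and
autocorrelation-corrected SEs, an empirical two-sided tail probability (the
fraction of control samples deviating from the control mean by at least the
observed |Δmean|; no parametric form is assumed for the control
distribution), and a Welch unequal-variance mean test computed on effective
sample sizes n/τ, with the integrated autocorrelation time τ estimated by
the initial-positive-sequence rule. The correction matters because frames
from dynamics are serially correlated; for independent frames it is
neutral (τ→1), which keeps the null calibration exact — under mm ≡ control
the p-values are uniform (KS-tested) and the nominal type-I rate is
recovered. A cell is flagged when tail probability ≤ 0.05 **and** p ≤ 0.01;
the conjunction makes false flags essentially impossible under the null
while still firing for genuine shifts of ~2 control SDs or more. No
multiple-testing correction is applied by default (per-cell reporting);
Benjamini–Hochberg can be applied downstream to the returned p-values. The
transfer range is the largest |relative position| flagged.

## What the synthetic generator does and does not emulate

`sample_trajectory()` draws per-frame stacked parameter vectors
(6N intra + 6(N−1) inter + 2N χ) from a Gaussian with user mean and either
independent per-coordinate SDs or a full covariance, rebuilds atoms every
frame, plants breathing plateaus by overriding the lesion opening inside
declared windows, and scatters cations as a Poisson point process of known
molarity. Defaults emulate a stable B-like helix: rise 3.38 Å, twist 36°,
χ −117°, fluctuation SDs of MD-like magnitude (tenths of Å for
translations, a few degrees for rotations). Frames are temporally
independent unless a covariance says otherwise — real trajectories are
autocorrelated, anharmonic, sequence-dependent and solvent-mediated, none
of which the generator reproduces. Passing tests therefore establish the
**correctness of the estimators on known ground truth** (round-trip
exactness, calibration, planted-effect recovery), not the biophysical
accuracy of any simulated ensemble. Degenerate draws (rise ≤ 0.05 Å) are
redrawn deterministically and counted; a single master seed makes every
ensemble bit-reproducible.

## Study-scale choices in the checks

The shipped checks run at desk scale, chosen once: 1000 random tables for
round-trip exactness; n = 2000 frames for the planted-transfer recovery,
with the control twist SD set to 1.5° by power analysis so the planted
+3.7° shift sits near 2.5 control SDs — decisively inside the 5% tail-flag
region at that sample size (a spread putting the shift near 2σ would make
the flag a coin toss against the tail-estimate sampling noise); 1000
repeats at n = 500 for null calibration; 10⁴ series for breathing
bookkeeping; 10⁴ frames for the 1 M ion-molarity law; 10⁴-sample variance
recovery for stiffness. `scripts/acceptance.R` re-runs the same
computations at moderately reduced ensemble sizes and reports the measured
values.

## Known limitations

* No backbone torsions beyond χ and no sugar pucker; BI/BII analysis is
  out of scope of the reduced model.
* The two-window bend is not a curvilinear-axis bend; values for strongly
  S-shaped helices will differ from curvilinear tools.
* Hydrogen-bond geometry uses reconstructed hydrogens; protonation-state
  dependent pairings (e.g. A⁺·C) are represented only by their heavy-atom
  topology.
* Scheme catalogs shipped with the package are seeds, intended to be
  edited; per-scheme occupancies on real data depend on the catalog given.
* Ion maps bin in the local pair frame; no solvation-shell or residence
  analysis is provided.
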