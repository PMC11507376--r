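---
title: "Scoring transient complex poses against cryo-EM density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transient complex poses against cryo-EM density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcscore)
```

## The problem

Plastocyanin (Pc) is a small copper protein that shuttles electrons between
the cytochrome *b6f* complex and photosystem 1. Its complex with cytochrome
*f* (Cyt *f*) is transient: it lives long enough for electron tunneling
between the Cu and the heme Fe and then dissociates, so no crystal of the
bound state exists and the available structural evidence is heterogeneous —
NMR model ensembles, rigid-body Brownian-dynamics (BD) encounter sets,
all-atom molecular-dynamics (MD) frames, AI-predicted poses, and a cryo-EM
density map in which the Pc region is weak and featureless.

This package answers one question about any rigid pose of such a two-body
complex: *how well does the mobile protein's position as a whole agree with
the experimental density?* Voxel-level map–model correlation coefficients
are the wrong tool for that question — they reward exact placement of
individual atoms and collapse when side chains move, which is noise at the
pose level. The approach implemented here deliberately throws away
sub-residue detail in both inputs: smooth the map, then ask only where the
backbone sits.

## The EDC score

For a density grid $\rho$ the smoothed field is a centered moving average
over a $w \times w \times w$ voxel cube ($w = 5$ by default, i.e. 125
cells):

$$\bar\rho(c) \;=\; \frac{1}{|N_w(c)|} \sum_{c' \in N_w(c)} \rho(c'),$$

where $N_w(c)$ is the in-bounds part of the cube centered on cell $c$. The
electron-density compliance (EDC) score of a pose is the mean smoothed
density at its mobile-protein C$\alpha$ positions $r_1,\dots,r_n$:

$$\mathrm{EDC} \;=\; \frac{1}{n}\sum_{i=1}^{n} \bar\rho\big(\mathrm{cell}(r_i)\big).$$

The score inherits the (arbitrary) units of the deposited map; values are
never rescaled on read, so scores computed against the same map are
directly comparable. Higher means the backbone sits in stronger density.
`edcScore()` refuses an unsmoothed grid: the score is defined on the
smoothed field, and forcing the smoothing step through the API prevents a
silent switch to the atom-level quantity the method is designed to avoid.

### Numerical conventions

* **Boundary handling.** The moving average truncates to in-bounds cells
  (divisor $|N_w(c)|$, not $w^3$). Zero-padding would darken the map rim
  and make a constant map non-constant at its edges; with truncation a
  constant map is a fixed point of the filter for every window.
* **Point sampling.** `sampleAt()` returns the value of the voxel whose
  center is nearest to the query point. The smoothing step has already
  removed sub-voxel structure, so interpolation buys nothing for scoring;
  a trilinear mode (`mode = "trilinear"`) exists for sensitivity checks.
  Half-cell ties follow R's `round()`.
* **Out-of-bounds atoms** contribute 0.0 to the mean and are tallied in the
  `oobFraction` attribute; a pose fully outside the map scores exactly 0
  with fraction 1. Callers should treat scores with a substantial
  out-of-bounds fraction as meaningless rather than merely low.
* **Indexing.** Grids are canonical x,y,z arrays, 1-based as everywhere in
  R; the map origin is the Cartesian position of the *center* of cell
  `[1,1,1]`. The MRC reader honors the file's MAPC/MAPR/MAPS axis
  permutation and both the ORIGIN and start-index origin conventions.

## The common reference frame

All pairwise pose comparisons are made after aligning every complex onto
one reference heme protein (`alignComplexToReference()`): a single rigid
transform is fitted by Kabsch least squares on the anchor-protein heavy
atoms of residues that come within `hemeRadius` (default 8 Å) of the
reference heme Fe, and the *whole* complex — both proteins and both
cofactors — is moved by that transform. Reflections are excluded by the
usual determinant correction; fewer than three pairable atoms or collinear
fit sets are hard errors, not warnings.

Pairing of fit atoms is by residue number + atom name; when the anchor and
the reference differ in numbering or sequence (turnip vs spinach Cyt *f*),
residue numbers are remapped through a global pairwise alignment of the
one-letter sequences with identity scoring, and unpaired residues are
dropped. The same rule (`pairingMode`) drives C$\alpha$ pairing for RMSDs;
this is justified for this system because the homologs are same-length and
their substitutions sit away from the interface.

Two design points deserve emphasis:

* **No per-pair refitting.** The RMSD and center-of-mass entries of the
  comparison table are computed between poses as they sit in the common
  frame. Refitting each pair would measure conformational difference;
  without refitting the triangles measure what the table is for —
  differences in the mobile protein's *position and orientation*.
* **The fit-atom set is a parametrization.** "Residues near the heme" is
  implemented as the 8 Å heavy-atom rule above and exposed as
  `hemeRadius`; scores are insensitive at the ±0.005 level to reasonable
  choices of this radius because the smoothed field varies slowly.

Centers of mass use all non-hydrogen atoms, mass-weighted, including the
Cu (it is part of the mobile protein); an unweighted geometric-center mode
exists for sensitivity analysis. Waters are excluded at read time and
hydrogens from all metrics.

## Ensembles, central structures, time series

The central structure of an ensemble is the member with minimum average
C$\alpha$ RMSD to all other members; the self-distance is excluded from the
mean (this cannot change the argmin) and ties break to the lowest index so
the selection is deterministic and order-stable. `spreadStats()` reports
the maximum pairwise RMSD and the maximum and mean RMSD to the central
structure. Trajectory frames (multi-model PDB or file lists; native MD
formats are out of scope) are aligned frame-by-frame and scored into a
time series, with times defaulting to 1 ns spacing; `movingAverageSeries()`
applies the same truncated-window mean in 1-D (a 20-sample window for
20 ns smoothing of 1-ns-spaced data).

## What the synthetic generator emulates — and what it does not

The generators exist so that every pipeline stage is testable offline with
known ground truth:

* `makeToyComplex()` builds a mobile chain of 99 C$\alpha$ pseudo-atoms
  (the mature-plastocyanin length) as a self-avoiding smoothed random walk
  with 3.8 Å steps, plus one Cu near its interior; and an anchor chain of
  60 residues (a heme-proximal portion of a Cyt *f*-sized domain — enough
  anchor atoms to make the alignment well-conditioned) plus one heme Fe.
  The mobile body is placed with the Cu 8–14 Å from the Fe, inside the
  functional electron-transfer range.
* `simulateDensity()` blurs every atom with a spherical Gaussian
  (`kernelSigma` 1.5 Å on a 0.86 Å grid — the deposited map's voxel size)
  and adds seeded Gaussian noise. The kernel support is truncated at
  8σ, below double-precision visibility.
* `perturbPose()` rotates the mobile body about its center and translates
  it; `makeEnsemble()` draws perturbation magnitudes uniformly from
  [scale/2, scale] — a *comparable-magnitude* scatter. Magnitudes drawn
  from [0, scale] would routinely nest a member almost on top of the base
  pose, which makes "the base pose is the central structure" false
  surprisingly often; the bounded draw reflects the intended geometry of
  an ensemble scattered around a reference.

What passing tests on these fixtures shows: the geometry, bookkeeping and
statistics of the pipeline are correct, and the EDC score degrades
monotonically (on average) as a pose leaves the density that was generated
from it. What they cannot show: behavior on real maps — no atomic form
factors, B-factors, CTF, solvent, masking artifacts or resolution
anisotropy are modeled, and real experimental density around a weakly
bound partner is far noisier than a Gaussian-blurred backbone. The checks
against published values for the real system therefore require the
experimental files locally (see the README) and are reported as failures,
not skipped, when those files are absent.

## Problem sizes and determinism

The shipped test suite and the acceptance script run entirely on synthetic
data at desk scale: exhaustive smoothing oracles up to 9×9×9 grids, 100
seeded Kabsch recovery problems, 50 random ensembles of up to 8 members
for central-structure selection, and 200 seeded end-to-end recovery trials
(20 noise realizations at 10 % of the map peak × 10 perturbations of at
least 5 Å RMSD) on maps of roughly 600k voxels. All randomness flows
through explicit per-operation seeds; generators restore the caller's RNG
state, and re-running any pipeline with the same config and inputs yields
byte-identical CSV output.

## Known limitations

* Nearest-voxel sampling makes the score piecewise constant under
  sub-voxel pose shifts; use the trilinear mode if that matters.
* Whether atom positions outside the experimental map occurred in the
  original analysis is unknowable from the publication; the 0.0 convention
  is this package's explicit, tallied choice.
* The exact heme-surrounding atom set used in the original alignment is
  not printed in the source publication's main text; the 8 Å heavy-atom
  rule is an assumption exposed as a parameter.
* mmCIF files are read but never written; structure repair, protonation
  and missing-loop modeling are out of scope, as are map sharpening,
  Fourier filtering, FSC/correlation metrics, clustering of encounter
  sets, and any automatic fetching from PDB/EMDB.
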