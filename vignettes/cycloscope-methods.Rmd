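---
title: "Methods: geometry and physicochemistry of cyclodextrin inclusion complexes"
author: "cycloscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry and physicochemistry of cyclodextrin inclusion complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloscope)
```

cycloscope characterises beta-cyclodextrin (beta-CD) host-guest inclusion
complexes from four directions: crystal-structure geometry, molecular-dynamics
trajectory monitoring, Higuchi-Connors phase-solubility analysis, and MM/GBSA
binding-energy bookkeeping.  This vignette records the models the package
implements, the conventions and tunable parameters behind them, what the
synthetic-data generators emulate, and the design choices that were genuinely
open.

## The structural model

A beta-CD is a cyclic heptamer of alpha(1->4)-linked D-glucopyranose units.
Its cavity is a truncated cone: the narrow ("tail") rim carries the primary
O6 hydroxyls, the wide ("head") rim the secondary O2/O3 hydroxyls.  All
descriptors are computed from an annotated host (`annotate_cd()`), which maps
chemical roles (C1-C6, O2-O6) to atoms for each of the seven residues.

Annotation is connectivity-first: heavy atoms closer than 1.8 A are treated
as bonded, pyranose rings are six-cycles with exactly one ring oxygen, and
residues are ordered by walking the glycosidic linkage.  The package's
numbering convention is that O4(n) is bonded to C4(n) of its own residue and
to C1(n+1) of the next, so the near-coplanar quadruple flanking residue n is
O4(n-1), C1(n), C4(n), O4(n).  Deposited CIFs are label-heterogeneous, which
is why connectivity is the fallback whenever role-pattern labels
(`C1`/`C11`-style) are absent or ambiguous; when labels do resolve the rings,
substituents are still found by connectivity, since no label dialect marks
them reliably.

### Macrocycle descriptors

* **O4 heptagon** (`o4_polygon_metrics()`): distances of the seven glycosidic
  oxygens from their arithmetic centroid (`d_K`), adjacent O4-O4 distances
  (`d`), signed deviations from the O4 mean plane (`dev`), and the
  ellipticity `max(d_K)/min(d_K)`.  The centroid is the plain mean of the
  seven positions, not the plane-projected mean; for near-planar rings the
  two differ by under 1e-3 A.
* **Mean planes** (`fit_mean_plane()`): total least squares via
  eigen-decomposition of the point covariance; signed deviations sum to zero
  by construction.  Normal orientation is deterministic (largest-magnitude
  component positive) unless a host context orients it toward the primary
  rim.
* **Cavity axis** (`cd_axis()`): the O4-plane normal anchored at the O4
  centroid, oriented from the secondary toward the primary rim using the C6
  centroid as the primary-side reference.
* **Tilt angles** (`tilt_angle()`): the angle between the O4 mean plane and
  the plane through O4(n-1), C1(n), C4(n), O4(n), folded to [0, 90] degrees.
  The literature states what a positive tilt *means* (primary side leaning
  toward the axis) but not how to compute the sign; here it is the sign of
  the dot product between the residue-plane normal (oriented to the O6/C6
  side) and the inward radial direction at O4(n).
* **Primary-rim rotamers** (`rim_torsion_state()`): omega = O5-C5-C6-O6 and
  omega' = C4-C5-C6-O6 with the IUPAC sign convention.  States are assigned
  by the carbohydrate ideal pairs gg(-60, +60), gt(+60, 180), tg(180, -60)
  within a +/-30 degree window on both torsions; anything else is
  unclassified.  The field names the states without numeric bins, so the
  window is a documented package convention (configurable via `window`).
* **Ring puckering** (`ring_pucker()`): Cremer-Pople amplitude Q and angles
  (theta, phi) for the six ring atoms in the order O5-C1-C2-C3-C4-C5.  Under
  this ordering the 4C1 chair of a D-glucopyranose sits at the theta = 0
  pole; `is_4C1` uses a generous theta <= 30 degree chair window, again a
  package convention since the literature asserts 4C1 without a criterion.

### Assembly descriptors

`host_pair_geometry()` folds the interplanar angle of two O4 planes to
[0, 90] degrees and decomposes the centroid-centroid vector against the
bisector of the two oriented axes into an axial shift and a lateral offset.
Orientation classes use the oriented axes with dot-product thresholds at 0.5:
parallel axes give head-to-tail; antiparallel axes give tail-to-tail when the
primary rims face each other, head-to-head when the secondary rims do.
Oblique arrangements (|dot| < 0.5) raise a warning rather than a confident
class.  `guest_orientation()` reports the angle between a guest ring's
best-fit plane and the host O4 plane plus the signed penetration depth of
the ring centroid along the axis.  `packing_mode()` labels a stack as
channel (CH) packing when every successive perpendicular centroid shift is
at or below 3.2 A — a threshold chosen to cover the 2.7-3.1 A range typical
of channel-packed CD dimers, and overridable.

### Contacts

Crystal-mode hydrogen bonds (`find_hbonds()`) pair O/N donors and acceptors
at d(D...A) <= 3.4 A (inclusive); when the donor hydrogen is modelled,
d(H...A) <= 2.7 A and a D-H...A angle >= 120 degrees are additionally
required.  Donors without modelled hydrogens are screened on the
donor-acceptor distance alone, because deposited CD structures routinely
omit water hydrogens; the cost is that an oxygen that genuinely cannot
donate (e.g. a methylated one) is still paired when close enough — contact
lists are candidate lists, not chemical proofs.  Close contacts
(`find_close_contacts()`) use C-H...O at d(H...O) <= 2.9 A with angle >=
110 degrees, and H...H at <= 2.4 A (twice the hydrogen van der Waals
radius).  All cutoffs are arguments; the defaults are conventional
crystallographic values.  Trajectory-mode H-bond counting
(`hbond_count_series()`) uses the MD-style 3.5 A / 135 degree criteria
instead, with a running mean over a 100-frame default window.

### Trajectories

`rmsd_series()` follows the fit-then-measure convention with separate fit
and measure selections, so guest motion can be measured after superposing
on the host.  Superposition is a Kabsch fit (SVD with a determinant guard,
always a proper rotation).  Mass-weighting is off by default and available
as a flag.  Only text formats (multi-model PDB, XYZ) are read; timesteps are
supplied by the caller since neither format carries one.

## Phase-solubility analysis

For a 1:1 complexation equilibrium the dissolved guest concentration is
linear in the CD concentration, and the linear-portion slope gives

* Kc = slope / (S0 (1 - slope)), in inverse molar with S0 in molar, and
* CE = slope / (1 - slope), reported as percent.

`phase_solubility()` is the front door: it classifies the diagram, selects
the fitting range, runs the OLS fit, and applies both expressions.  Profile
classification is a designed rule set: a level falling more than 5% below
the curve maximum marks a B-type profile (B_s with at least two
near-maximum plateau levels before the decline, otherwise B_i); otherwise a
quadratic term t-test at alpha = 0.05 separates A_P/A_N from A_L.  The
linear portion of a B-type profile is the longest initial run of at least
three levels with R^2 >= 0.99.  These numeric rules are package conventions:
the field names the profile types and the "linear portion" without numeric
criteria.

S0 is always an explicit argument.  Poorly soluble guests give A_L diagrams
with negative fitted intercepts, and feeding such an intercept into the Kc
expression is exactly the mistake the explicit argument prevents.  Reported
uncertainties are first-order (delta-method) propagations of the slope
standard error: sd(Kc) = SE/(S0 (1-slope)^2) and sd(CE) = 100 SE/(1-slope)^2.
Published tables of this kind do not state whether their +/- values are
replicate SDs or regression SEs; the delta-method choice is documented
rather than claimed to reproduce them.

## MM/GBSA bookkeeping

The package combines energy components, it never computes them: force-field
terms, GB energies, SASA and normal-mode entropies are upstream outputs
consumed as data.  The identities are

* dE_MM = dE_vdW + dE_ele,
* dG_solvation = dG_GB + dG_nonpolar, with dG_nonpolar = gamma SASA + b
  (defaults gamma = 0.0072 kcal/mol/A^2, b = 0) applied only when SASA is
  supplied,
* dH = dE_MM + dG_solvation, and dG_binding = dH - TdS.

`combine_frames()` computes derived quantities per frame and then averages,
so the reported SDs are SDs of per-frame sums — the MM/GBSA convention.  For
correlated components this differs from the quadrature sum of component SDs,
and published tables show exactly that difference; the test suite
demonstrates the distinction on generated tables with and without
correlation.  TdS is stored with the sign convention of the printed tables
and subtracted as printed; when absent, only `dG_binding_no_entropy`
(= mean dH) is reported, reflecting the common practice of comparing
complexes without the entropy term.  `consistency_check()` evaluates each
identity from a published table's own operands and flags residuals above
0.015 kcal/mol — half a unit in the last digit of a two-decimal table.

## The synthetic-data generators

The generators produce every input class with known ground truth, which is
what makes closure testing (build with known parameters, measure them back)
possible.

* `build_ideal_cd()` places seven idealised 4C1 glucose templates (uniform
  1.52 A bonds, tetrahedral angles, C-O 1.43 A) over the edges of an O4
  heptagon.  The heptagon radius default of 5.0 A matches the beta-CD range;
  per-residue radii are modulated so the requested ellipticity is hit
  exactly at the vertex angles.  Tilts are rigid rotations of a residue
  about its O4-O4 edge, which leaves the O4 polygon untouched and makes tilt
  recovery a clean parameter-recovery test.  Rim torsions are set exactly to
  the ideal rotamer pairs.  Substituents (methyl, hydroxypropyl) are placed
  anti-periplanar across the ether bonds so neighbouring residues'
  substituents stay out of covalent range.
* `build_complex()` stacks hosts along +z in the requested orientations and
  threads a generic piperine-like guest (aromatic six-ring, short conjugated
  linker, nitrogen-containing chair ring).  The guest-ring angle is set by
  rotating the aromatic ring about its own centroid so the guest stays
  threaded at any angle.  Entity-entity clashes below 1.5 A raise a warning.
* `build_trajectory()` adds seeded isotropic Gaussian jitter and a
  deterministic per-frame drift on a selection.
* `gen_solubility()` draws multiplicative Gaussian replicate noise around
  exact A_L/B_s/B_i mean curves.  Defaults emulate the study conditions for
  a poorly soluble guest: S0 = 0.0378 mM, CD levels 1-15 mM for the
  aggregating native host (B-type, linear only up to 3 mM) and 1-60 mM for
  soluble derivatives, triplicate replicates.
* `gen_energy_frames()` draws correlated Gaussian components and then
  recentres/rescales each column so the sample means and SDs equal the
  specification exactly (the correlation stays approximate).

What the generators deliberately do not emulate: force-field-quality
geometry, thermodynamically realistic conformational ensembles, crystal
water networks, or the error structure of real UV-vis replicates (which is
unreported; Gaussian noise is a stand-in).  Passing closure tests therefore
demonstrates that the measurement code inverts the construction code at the
stated tolerances — not that real crystals or real solubility data behave
ideally.

## Numerical choices and degenerate inputs

Fractional-to-Cartesian conversion uses the a-along-x, b-in-xy convention
throughout; symmetry-operator translations are stored exactly as integer
twelfths, so repeated screw applications cannot drift.  Collinear point sets
are rejected by the plane fit and the Kabsch fit; zero-volume cells, slopes
outside (0, 1), negative SASA and non-positive-semi-definite correlation
matrices are rejected with informative errors.  Disordered sites are
analysed per `alt_site`, never occupancy-averaged.  Torsions live in
(-180, 180] and tests compare them circularly.

Problem sizes in the test suite are chosen for closure quality at desk
scale: 50 random rigid transforms for invariance properties, 200 seeded
replicates for the noisy-recovery study (2% relative noise, 10 levels),
10,000 frames for the SD-convergence demonstration.

## Known limitations

* Only heptameric (beta) cyclodextrins are built and annotated; alpha/gamma
  rings would need a generalised ring walk.
* The label-based annotation path covers the two common label dialects;
  anything else falls back to connectivity.
* H-free hydrogen-bond detection cannot distinguish a water oxygen lacking
  modelled hydrogens from an oxygen with no hydrogens to donate.
* Published deposit-derived values (interplanar angles, centroid shifts,
  guest-ring angles of the real crystal structures) can only be reproduced
  from the deposited CIF files themselves, which are not redistributable
  with the package; the workflow is exercised end-to-end on synthetic
  deposit-style CIFs instead.

## A worked example

```{r example}
cd <- build_ideal_cd(cd_build_spec(tilt = 10, substitution = "2,6-di-O-methyl"))
host <- annotate_cd(cd$structure)[[1]]
host
round(tilt_angle(host), 2)

g <- gen_solubility(solubility_gen_spec(profile = "B_s", slope = 0.0652,
                                        s0_mM = 0.0378, noise_rel = 0))
phase_solubility(g$dataset, s0_mM = 0.0378)

summarize_means(c(dE_vdW = -51.16, dE_ele = -11.09, dG_GB = 26.43,
                  dG_nonpolar = -5.49, TdS = -16.51))
```
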