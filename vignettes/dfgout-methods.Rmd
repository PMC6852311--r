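---
title: "Methods: conformational classification and chimeric template construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational classification and chimeric template construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfgout)
```

## Overview

`dfgout` generates ensembles of kinase catalytic-domain templates in the
inactive DFG-out state. Two components carry the science: geometric
classifiers that discretise the conformations of the A-loop, P-loop and
alphaC-helix (plus the DFG state itself), and a splicing engine that
fuses a DFG-in acceptor C-lobe with N-lobe and A-loop donors
representing each class combination. Everything is expressed in the
residue numbering of the PKAC-alpha structure 1ATP, which serves as the
common coordinate system of the kinase fold.

## Reference numbering

Any chain is mapped onto the packaged 1ATP catalytic-domain sequence
(residues 40–300 of mouse PKAC-alpha) by global pairwise alignment with
free end gaps (BLOSUM62, gap open 10, gap extend 0.5 — standard,
deterministic choices). A curated kinome master alignment would serve
the same purpose, but a direct pairwise alignment against one
well-anchored reference keeps the package self-contained; what matters
downstream is only that the anchor IDs land on the right residues, which
is verified explicitly: the G-loop pattern G-x-G-x-Phi-G at 50–55, Lys72,
Glu91, the catalytic-loop [HY]RD at 164–166 (PKA itself carries Tyr164,
hence the two-letter pattern), D-F-G at 184–186 and A-P-E at 206–208.
Motif mismatches warn and set a `noncanonical` flag rather than fail,
since mutant and atypical kinases are legitimate inputs. Residues the
alignment cannot match (insertions) carry no reference ID and are
invisible to the classifiers but retained in all structural output.

The alignment score floor (default 150) separates kinase domains from
composition-matched decoys: shuffled 120-mers drawn from the reference
composition score far below 100 in the empirical null (the test suite
recomputes this), while genuine kinase domains align in the high
hundreds.

## Classifier observables and rules

All observables are computed from coordinates only:

| feature | definition |
|---|---|
| `psi_gmotif_m1`, `psi_gmotif_p1` | backbone psi at IDs 49 and 56 |
| `xi_gmotif_p1_p2` | C-alpha pseudotorsion over IDs 55–58 |
| `d_phi__hrd_p4` | C-alpha distance 54–170 |
| `d_lys_glu` | minimal Lys72 NZ to Glu91 OE1/OE2 distance |
| `chi_glu` | Glu91 chi1 (configurable index) |
| `xi_dfg_m1_d`, `xi_dfg_f_g` | C-alpha pseudotorsions over 182–185 and 184–187 |
| `d_hrd_m4__dfg_p3` | C-alpha distance 160–189 |
| `dfg_pseudodihedral` | dihedral over (CA 183, CA 184, CG 184, centroid of the Asp184 delta oxygens) |

Angles are degrees in (-180, 180]; distances are Angstrom. A feature
whose defining atoms are absent is reported as *unavailable* with the
reason — never as a silent NaN — and each classifier has an explicit
policy for unavailable inputs (listed in the function documentation).

**alphaC**: d <= 4 A is *in*, d >= 8.5 A is *out*; between the two, chi
<= 100 degrees is *inter* and otherwise *in*. The thresholds are the
classical salt-bridge criterion and are inclusive at the boundary.

**P-loop**: each class (collapsed, stretched) is a set of four intervals,
one per observable; a class is assigned iff at least `min_conditions`
(default 3) of its 4 intervals are satisfied *and* its count strictly
exceeds the other class's. Equal qualifying counts are reported as
ambiguous. The 3-of-4 rule is structural; the interval endpoints are
configuration.

**A-loop**: each of the three classes is a box — two pseudotorsion
intervals and one distance interval. Configuration validation rejects
class boxes that overlap in all three dimensions, which guarantees at
most one class can match; classification is therefore order-independent.

**DFG**: the pseudodihedral falls in an out-interval (default
[-140, -40]), an in-interval (default [40, 140]), or neither
(unassigned). The published description of this classifier specifies
only that it is built from cross products over four atoms of the DFG
motif; the atom quadruple used here — CA of DFG-1, CA of Asp184, CG of
Asp184, and the centroid of the Asp delta oxygens — is this package's
concrete interpretation and is prominently configurable. Structures
whose residue 184 lacks delta atoms simply report the feature
unavailable.

### Which numbers are configuration

The interval endpoints for the A-loop and P-loop classes are shipped as
a versioned YAML default (`inst/extdata/default_config.yaml`), chosen
once from kinase-domain anatomy: closed A-loop conformations bring
DFG+3 within roughly 7–15 A of HRD-4 while open conformations sit beyond
15 A; collapsed P-loops fold the G-loop toward the C-lobe (smaller
54–170 distances, helical psi values) while stretched P-loops are
extended (psi > 60 degrees, larger distances). They are deliberately not
hard-coded: any user with a curated training set can replace the YAML
without touching code. The alphaC thresholds (4.0 / 8.5 / 100) and the
3-of-4 rule are literature constants and ship as defaults in the same
file.

Boundary comparisons carry an absolute guard of 1e-9 so that a value
posed exactly on an inclusive threshold classifies deterministically
despite floating-point rounding; the guard is six orders of magnitude
below any biologically meaningful difference.

## Template construction

Segment boundaries in reference numbering: N-lobe = IDs <= 120, A-loop
= 183–208 (DFG-1 through APE), C-lobe core = the rest. The boundaries
are configuration; the published construction specifies the segments
(C-lobe without the A-loop, an N-lobe, an A-loop) but not the numeric
hinge, so conventional kinase anatomy fixes the defaults. Donors are
superposed onto the acceptor by a Kabsch fit over the backbone (N, CA,
C, O) of the common C-lobe-core reference IDs — at least 20 are
required — and the A-loop donor is fitted over the same C-lobe core,
not over loop flanks, so the grafted loop lands where the donor's
C-lobe frame puts it. Splicing draws each residue from its segment's
source, orders by reference ID, and records per-residue provenance
which is emitted as REMARK 99 records with a fixed grammar.

Junction plausibility (C–N distance <= 2.5 A at each provenance switch)
is checked and flagged, not enforced: downstream modelling engines
rebuild junction geometry anyway. In place of the force-field
minimisation a modelling suite would run, the package performs
deterministic clash detection (heavy-atom pairs across provenance
segments closer than 2.5 A, excluding residues adjacent in reference
numbering) with an optional relief policy that truncates the clashing
*donor-side* side chain beyond C-beta and records the edit. Backbone
geometry is never moved; a backbone–backbone clash is flagged
fatal-for-template and the template is still emitted with a warning.

The ensemble enumerates the Cartesian product {collapsed, stretched} x
{in, inter, out} x {closed type 2, open DFG-out, closed A-under-P} in
the canonical HM 1–18 order (A-loop fastest, then alphaC, then P-loop),
yielding 18 templates per kinase. A failed template is recorded in the
manifest and never aborts the run.

## The synthetic scaffold generator

The generator exists so that every contract in the package can be
exercised with *exactly known* ground truth. A scaffold is a full
backbone (N, CA, C, O, plus C-beta and the feature side chains) over the
packaged reference sequence, built in torsion space over ideal bonded
geometry:

* The base C-alpha trace is a frozen self-avoiding serpentine — helical
  zigzag rods joined by solved turn bridges — with every virtual C-alpha
  bond exactly 3.804 A and no two non-neighbour C-alphas closer than
  4.4 A. Its internal coordinates are data (`R/fold_data.R`), derived
  once from an explicit Cartesian layout.
* Pseudotorsion targets are exact by construction: a posed C-alpha
  window (e.g. 184–187) *is* the NeRF torsion that places its last atom.
* Backbone psi targets are met by rotating the corresponding peptide
  plane about the local C-alpha axis (1-D root find, tolerance 1e-13).
* Long-range distances are solved numerically: the 54–170 distance by
  four backbone-torsion rotations at the hinge (residues 118–120), and
  the 160–189 distance by the five free A-loop pseudotorsions, each
  followed by a 1-D polish to machine precision. Both solvers carry
  soft clearance constraints that keep the moved segment at C-alpha
  separation >= 4.5–5 A from the rest of the fold, and the A-loop
  closure stage pulls residues 206–208 back onto their base anchors so
  the APE-side junction stays near-covalent where the pose allows it.
* The Lys72 NZ and Glu91 carboxylate are placed analytically so the
  minimal NZ–OE distance equals its target exactly; the DFG
  pseudodihedral is posed through NeRF placement of the Asp184 delta
  centroid.

A pose the solvers cannot reach (for instance a 160–189 distance beyond
the geometric reach of the loop) raises an "infeasible pose" error
naming the feature. Measured-equals-posed is asserted to 1e-6 (degrees /
Angstrom) inside `make_scaffold` itself, so a scaffold that exists is a
scaffold that is correct.

The labelled grid (`make_labeled_grid`) poses one scaffold per class
combination at the midpoints of the configured intervals (18 members),
plus boundary members at d = 4.0, 8.5 and chi = 100 exactly, and one
unassigned-band member per element. Because the labels come from the
generating intervals and the scaffolds from interval midpoints, 100%
classifier agreement on the grid is a *construction invariant* — it
validates the plumbing (features, wiring, configuration), not the
biological calibration of the intervals.

### What the scaffolds do and do not emulate

Scaffolds have ideal bonded geometry, correct sequence, verified motif
anchors and exactly posed observables, but they are not proteins: the
fold is a serpentine, there is no packing, no secondary-structure
context beyond the posed elements, and side chains exist only where a
feature needs them. Passing tests on scaffolds therefore demonstrates
the correctness of the geometry, classification, numbering and splicing
machinery — not that the default A-loop/P-loop intervals reproduce any
particular curated annotation of real PDB structures. Validating the
shipped intervals against labelled depositions (e.g. the ABL1 and KDR
type-II complexes with published class assignments) requires fetching
those structures, which the test suite deliberately does not do; the
acceptance suite contains that check and it reports as failing when the
files are absent.

## Problem sizes and runtime

The scaffolds span reference IDs 40–300 (261 residues, ~1100 atoms).
One scaffold builds in a few seconds (dominated by the two distance
solvers); the labelled grid (24 scaffolds) and donor library (9
scaffolds) are built once per test session and cached by the test
helpers. A full 18-template ensemble run, including alignments and
manifest, takes a few seconds on one CPU. These sizes were chosen so
that the complete suite, including two full ensemble builds for the
determinism check, runs comfortably as a routine check.

## Known limitations

* The DFG pseudodihedral atom quadruple is an interpretation (see
  above); against real DFG-annotated structures the out/in intervals may
  need recalibration through the config.
* A-loop and P-loop interval defaults are package choices, not fitted
  constants; treat them as a starting point for curation on real data.
* Scaffolds with strongly reposed A-loops can leave the APE-side splice
  junction longer than covalent (it is flagged in the manifest);
  modelling engines treat it as a chain break to rebuild.
* Insertion-code-bearing residues and alignment insertions are carried
  along but never classified; kinases whose catalytic domain diverges
  enough to break the score floor must be aligned with user-supplied
  scoring.
* mmCIF input is read-only; all output is PDB.
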