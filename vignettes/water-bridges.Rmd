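---
title: "Detecting protein-water bridges: model, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein-water bridges: model, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquabridge)
```

## The problem

Buried and surface water molecules participate directly in protein
structure and function: a water that donates one hydrogen bond to a
backbone carbonyl and accepts another from a lysine side chain couples
those two residues almost as tightly as a direct contact. A *water
bridge* is such a coupling — two protein residues connected through a
chain of one or more hydrogen-bonded waters. In crystal structures the
bridges are static; across NMR ensembles or molecular-dynamics
trajectories they flicker, and the biologically interesting signal is
which residue pairs are bridged *persistently*.

`aquabridge` detects these interactions in three settings — a single
structure, a multi-model ensemble, a topology plus DCD trajectory — and
aggregates them into per-pair statistics, matrices and color-coded
structures.

## Hydrogen-bond model

A candidate hydrogen bond is a donor heavy atom D (with a covalently
attached hydrogen H) and an acceptor heavy atom A. It is accepted when

* `dist(D, A) <= distDA`, and
* the angle at H between the H→D and H→A vectors lies inside the
  applicable range.

The angle vertex is always the *hydrogen*; a perfectly linear bond
scores 180°. Three independently tunable ranges cover the three bond
classes: `anglePDWA` (protein donor → water acceptor), `anglePAWD`
(water donor → protein acceptor) and `angleWW` (water → water).

Defaults (all user-overridable through `wb_criteria()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `distDA` | 3.5 | Å | canonical heavy-atom H-bond cutoff |
| `distWR` | 4.0 | Å | residue–water interaction shell (reporting only) |
| `anglePDWA`, `anglePAWD` | [100°, 180°] | deg | permissive protein–water geometry |
| `angleWW` | [140°, 180°] | deg | stricter near-linear water–water geometry |
| `maxDepth` | 2 | waters | bridges beyond two waters are rarely interpretable |
| valence caps | 2 + 2 | bonds | a water donates ≤ 2 and accepts ≤ 2 H-bonds |

`distWR` deliberately plays no role in bridge detection itself: it
defines the residue–water contact shell used when reporting which
residues surround a hydration site. Water–water edges are governed by
`distDA`/`angleWW` alone.

### Structures without hydrogens

Crystal structures usually lack hydrogens. Two mechanisms cover this:

1. **Angle-free mode** (`angle_mode = "angle-free"`, chosen
   automatically when the input has no hydrogens): the distance test
   alone decides. This accepts a superset of the with-hydrogens result
   on identical coordinates — a property the test suite verifies on
   1000 random placements.
2. **Minimal water protonation** (`place_missing_hydrogens()`): bare
   water oxygens get two hydrogens at 0.96 Å and 104.5°, the first
   aimed at the nearest acceptor within `distDA`, the second opened
   104.5° toward the second-nearest. Protein donors are never
   protonated — hydroxyl and ammonium hydrogen positions are
   rotamer-dependent, and fabricating them would manufacture angle
   evidence. Those donors (Ser/Thr/Tyr OH, Lys NZ, Cys SG) instead fall
   back to distance-only acceptance individually.

### Valence pruning

Each water keeps at most two donated and two accepted bonds. Candidate
bonds are ranked per water by distance (ties broken by the partner's
atom index, for determinism); bonds outside the cap at *either* water
endpoint are dropped. Ranks are computed once on the unpruned list, so
removal cannot cascade. Whether pruning should precede or follow graph
construction is a genuinely open choice; pruning after construction
keeps the candidate set independent of traversal order.

## Chain and Cluster methods

Both operate on the hydrogen-bond graph of one frame, whose vertices
are protein polar heavy atoms (N/O/S) and water oxygens.
Protein–protein hydrogen bonds are recorded but never serve as bridge
edges.

**Chain method** (`chain_method()`): from every protein polar atom,
enumerate all simple paths whose interior vertices are exclusively
waters, up to `maxDepth` waters. Every unordered residue pair connected
by at least one such path becomes one bridge, reported with

* the shortest qualifying water path (among equal-length paths, the
  one with lexicographically smallest water identifiers — a pure
  determinism tie-break),
* `n_waters`, the number of distinct waters appearing in *any*
  qualifying path (so two parallel one-water paths give depth 1,
  multiplicity 2),
* the distance between the two endpoint heavy atoms.

The implementation is exhaustive depth-capped search; with
`maxDepth ≤ 3` and physical water coordination (≤ 4 neighbors) the
branching is small. The test suite checks equality of the resulting
residue-pair set against an independent `igraph` path enumeration on
600 random graphs.

**Cluster method** (`cluster_method()`): connected components of the
subgraph induced by protein–water and water–water edges. Water
membership is truncated at `maxDepth` hops from the nearest
protein-bonded water, mirroring the chain semantics; components with no
protein contact at all are reported as bulk clusters with zero
residues.

## Ensemble statistics

`analyze_ensemble()` runs the chain method on every selected frame and
aggregates per unordered residue pair. A bridge's identity is the
residue pair, *not* the specific water, so water exchange does not
interrupt an interaction — the natural convention when the question is
which residues are persistently coupled.

* **frequency** — fraction of analyzed frames in which the pair is
  bridged (equal to the planted Bernoulli fraction on fixtures, because
  the detector is deterministic given coordinates);
* **mean/SD of the endpoint distance** — over bridged frames only,
  with the *population* SD (divide by n, not n−1): the bridged frames
  are the entire population of interest, not a sample from a larger
  one, and a single bridged frame then cleanly yields SD 0;
* **duration** — the term admits two readings, so both are reported:
  the longest run of consecutive bridged frames and the mean run
  length, each converted to ps when the trajectory carries a timestep;
* **mean water count** — mean multiplicity over bridged frames.

`frequency_matrix()` spreads any of these into a symmetric
residue-by-residue matrix; `color_code_structure()` writes each
residue's maximum bridge frequency into the PDB B-factor column,
clamped to [0, 1], which standard viewers render blue (0) to red (1).

## Hydration sites

`cluster_waters()` clusters water-oxygen positions — one frame's
waters, or positions pooled over all frames — with density-based
(DBSCAN-style) clustering. Density clustering needs no preset site
count and leaves diffuse bulk water as noise, which is exactly the
behavior hydration-site analysis wants. A core point has at least
`min_samples` observations (itself included, the scikit-learn
convention) within `eps`; defaults `eps` = 1.0 Å, `min_samples` = 4
resolve sites a water-diameter apart while ignoring sparse bulk.
Border points reachable from several clusters join the nearest core
point's cluster, Euclidean ties broken by lower cluster index — the
standard algorithm leaves this order-dependent, and the explicit rule
is what makes the partition provably invariant under observation
shuffling. Site occupancy is members divided by frames and may exceed
1 when several waters co-occupy a site; the spread is the RMS
member-to-centroid distance.

## Synthetic fixtures

All tests run on generated inputs with exactly known truth
(`make_bridge_fixture()`, `make_trajectory_fixture()`,
`make_site_fixture()`):

* planted bridges are collinear donor–water–acceptor chains at 2.8 Å
  spacing and 180° angles, one residue pair per 15 Å row; decoy waters
  sit ≥ `distDA` + 1 Å from every polar atom; both properties are
  asserted at generation time;
* trajectories switch each bridge on with probability `occupancy_p`
  per frame (off-frames displace the waters by 3 × `distDA`) and can
  jitter the endpoint distance by a planted, recorded amount —
  defaults (10 frames, p = 0.7, depths 1 and 2) mirror the scales used
  throughout the documentation, and 50-frame runs are used where
  moment recovery is measured;
* site fixtures scatter Gaussian observations (σ = 0.3 Å, 50 per site)
  around centers ≥ 5σ apart, plus optional uniform noise.

Generation is seeded (Mersenne-Twister) and restores the caller's RNG
state; identical specs give byte-identical PDB/DCD files.

What the fixtures deliberately do **not** emulate: physical water
dynamics, rotamer heterogeneity, crystallographic disorder, or
periodic-boundary effects. Passing tests therefore demonstrate
algorithmic correctness — detection, counting, aggregation, clustering
— not force-field-level realism of any particular system.

## Numerical and format choices

* Coordinates are Å throughout; atom indices are 1-based in R
  convention, residue numbering is preserved verbatim from the input.
* Alternate locations reduce to the highest-occupancy conformer (ties:
  altloc letter order). Deuterium counts as hydrogen.
* The candidate search uses a cell list at `distDA` resolution, so
  graph construction is linear in atom count rather than quadratic;
  tests verify exact agreement with an all-pairs scan.
* PDB I/O goes through `bio3d`; coordinates survive a round trip to
  the format's 3-decimal precision. The mmCIF reader covers the
  `atom_site` loop only. DCD files are read in either byte order
  (auto-detected) and written for fixture purposes; the header's delta
  field is interpreted in AKMA units (1 AKMA = 0.04888821 ps). The
  reader is cross-checked against `bio3d::read.dcd` in the tests.
* Trajectories are held in memory as an atoms × 3 × frames array; at
  the problem sizes this package documents (hundreds of frames,
  thousands of atoms) this is simpler and faster than lazy iteration.

## Known limitations

* No periodic-boundary unwrapping: trajectories must be pre-imaged.
* No energetic scoring — the criteria are purely geometric; "advanced"
  customization means the thresholds above, not Lennard-Jones or
  charge terms.
* Protein donors missing hydrogens are handled by the per-atom
  distance-only fallback, which can over-accept at those atoms
  relative to a fully protonated input.
* mmCIF writing, TRR/CRD formats, and coupling to normal-mode or PCA
  analyses are out of scope.

## A worked run

```{r example}
sp <- fixture_spec(planted_depths = c(1, 2), occupancy_p = 0.7,
                   n_frames = 10, seed = 42)
tf <- make_trajectory_fixture(sp)
ens <- analyze_ensemble(tf$trajectory)
ens$stats[, c("res_a", "res_b", "frequency", "mean_distance",
              "max_consecutive")]
```

The recovered frequencies equal the realized planted on-fractions
exactly:

```{r check}
tapply(tf$truth$on, tf$truth$pair, mean)
```
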