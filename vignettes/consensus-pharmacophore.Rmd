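---
title: "Consensus pharmacophores from complex ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pharmacophores from complex ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phore)
```

## The model

A pharmacophore is an abstract 3-D arrangement of interaction features —
hydrogen-bond donors (HBD) and acceptors (HBA), hydrophobes (HYD),
positive and negative ionizable points (POS, NEG) — that a ligand must
present to bind a target. When an ensemble of co-crystal structures of
the same target is available, each complex yields its own set of
receptor-confirmed features; features that recur across many complexes
are better evidence of a binding requirement than features seen once.
`phore` formalizes that as a frequency-thresholded consensus:

1. Every complex is brought into one reference frame (rigid CA-based
   least-squares superposition onto a designated reference complex, with
   an explicit residue pairing).
2. Features are perceived per complex. Perception is *interaction
   filtered*: a candidate read off the ligand's chemistry survives only
   if the receptor confirms it (details below).
3. Features from all $N$ complexes are pooled and clustered (same kind
   only, greedy agglomerative, merge radius 2 Å). Each cluster's
   *statistical frequency* is $\mathrm{round}(100\,c/N)$ percent, where
   $c$ counts the **distinct complexes** among its members — a complex
   contributing two same-kind features to one cluster counts once,
   because frequency measures how many structures exhibit the feature,
   not how many atoms do. Rounding is half-up, so over $N=14$ the counts
   $1,2,5,9,10,11,12$ map to $7,14,36,64,71,79,86$ percent.
4. Clusters with frequency **strictly greater** than the threshold
   (default 60 %) are retained. Strict inequality is deliberate: a
   64 %-frequency cluster (9 of 14) passes a 60 % threshold, while a
   cluster exactly at the threshold would not — "more than 60 %" is taken
   at its word.
5. The retained centroids (with spherical tolerances) plus
   excluded-volume spheres derived from receptor atoms near any ligand
   form the `consensus_pharmacophore`, serialized as a JSON document
   (schema in `inst/extdata/model-schema.json`).

### Perception rules

Commercial packages do not publish their perception definitions, so
`phore` uses explicit Catalyst-style conventions, all collected in one
`perception_rules()` block:

| parameter | default | meaning |
|---|---|---|
| `hbond_max_da` | 3.5 Å | maximum donor–acceptor distance |
| `hbond_min_angle` | 120° | minimum D–H…A angle, only with an explicit H |
| `hyd_contact` | 4.5 Å | hydrophobe centroid → protein apolar carbon |
| `ion_contact` | 5.5 Å | ionizable feature → complementary charged group |
| `tolerance` | 1.6 Å | feature tolerance sphere radius |
| `ev_contact` | 5.0 Å | ligand–protein distance defining EV candidates |
| `ev_radius` | 1.2 Å | excluded-volume sphere radius |
| `ev_merge` | 1.0 Å | EV candidates closer than this merge |
| `cluster_radius` | 2.0 Å | consensus clustering merge distance |

Candidate chemistry: HBD at N/O/S bearing hydrogen (implicit hydrogens
derived from standard valences, so hydrogen-free crystal ligands work);
HBA at N/O with an available lone pair, excluding amide N, ring N–H and
protonatable amines (which are modeled as protonated at pH 7.4); HYD at
centroids of all-carbon rings and of chains of ≥ 3 contiguous non-polar
carbons; POS at formally positive atoms, protonatable amines and
guanidines; NEG at carboxylate/sulfonate/phosphonate groups (feature at
the group centroid) and formally negative atoms. Ionization is a
functional-group lookup, not a pKa calculation. All distance boundaries
are closed (a contact exactly at the cutoff counts); the excluded-volume
clash test is strictly-inside, so an atom on a sphere surface is allowed.

Feature positions are the heavy-atom (or centroid) positions, not
projected points; donor→acceptor directions are stored but do not enter
the fit value. This is the simplest model consistent with spherical
tolerances; directed projected-point features and aromatic ring-normal
features are out of scope.

### Hydrogens

Crystal structures usually lack hydrogens. The hydrogen-bond criterion
therefore degrades gracefully: with an explicit donor hydrogen the
D–H…A angle is enforced; without one, the distance criterion alone
applies. Polar hydrogens are never added.

### Mapping and fit

A conformer maps onto the model through an exhaustive search over
kind-compatible injective assignments of its candidate points to **all**
model features (all-feature matching is mandatory; partial matching is a
possible future flag). Each assignment is rigid-body aligned by Kabsch
onto the feature centers; the assignment is valid if every displacement
$d_f$ stays within its tolerance $t_f$ and no heavy atom enters an
excluded volume. The fit value is the Catalyst-style quadratic falloff
$\sum_f w_f \max(0, 1-(d_f/t_f)^2)$, bounded by $\sum_f w_f$. Exhaustive
search is affordable because retained models carry a handful of features
(six in the default construction; $\le 6!$ assignments before kind
filtering), and the test suite checks it against an independent
brute-force enumeration on random instances. With fewer than three
matched points a rotation is underdetermined; the implementation then
aligns centroids only. Ranking ties (equal fit) break by molecule id;
equal-fit conformers break to the lowest conformer index.

## Design decisions that were genuinely open

- **Alignment.** The multiple-structure alignment used in the original
  setting is replaced by pairwise CA-based Kabsch superposition to an
  explicitly chosen reference with an explicit residue pairing. This is
  deterministic, testable, and avoids re-implementing a
  sequence-structure aligner; the reference complex is a required input
  rather than a guess.
- **Ion stripping.** "Waters and ions" is implemented as HOH/WAT/DOD plus
  a list of common monatomic het codes (NA, K, MG, ZN, CL, CA, MN, FE,
  CU, NI, CO, CD, BR, IOD).
- **Altloc handling.** Highest occupancy wins, ties to first-seen.
- **Cluster labels.** Assigned per kind in descending count order
  (H1 > H2 > …), ties broken by lexicographic centroid order, which makes
  the labeling permutation-invariant.
- **Fit function.** The screening literature names geometric fit values
  without defining them; the weighted quadratic falloff above is the
  de-facto standard for sphere-tolerance pharmacophores and is stated
  explicitly rather than matched bit-for-bit to any closed tool.
- **Hit cutoff.** Whether a screening funnel truncates by rank or by fit
  threshold is supported both ways (`top_k`, `min_fit`).
- **logP.** Open Babel's atom-contribution estimate, an approximation as
  any additive scheme is; donor/acceptor counts for the rule of five use
  the classic conventions (donors = N/O/S–H groups, acceptors = N + O
  count), computed from the bond graph rather than delegated, so the
  counts are exactly reproducible.
- **External docking scores** are never computed — they enter the final
  report only as an optional externally supplied column, because the
  scoring functions in question are proprietary.

## What the synthetic fixtures emulate — and what they do not

`make_complex_ensemble()` plants minimal chemical groups (amine,
carbonyl, three-carbon chain, carboxylate) with matching receptor
partner atoms at 19 well-separated sites, assigning each site to a
seeded random subset of the 14 complexes so that per-site multiplicities
span 1–12 and exactly six sites exceed the 60 % threshold. Per-complex
Gaussian noise (default 0.3 Å) moves each site's ligand group and
receptor partner jointly, so the interaction survives while cluster
members scatter realistically. Sites are laid on a 12 Å lattice with
fixed irregular offsets (≤ 1.5 Å per axis); the irregularity guarantees
that no subset of sites is related to another by a rigid motion, so a
molecule genuinely missing one feature kind cannot map in some rotated
frame. Site spacing is at least three cluster radii by construction
(violations raise an error).

`make_library()` derives actives from a model by planting one group per
feature (placement noise 0.15 Å), and decoys by displacing every group
of one feature kind beyond tolerance (8 Å by default) or deleting it;
the sabotaged kind is chosen so no other planted group can supply a
candidate of that kind. Each molecule receives three conformers: one is
the planted geometry in a random rigid frame (mapping is frame
invariant), the others have their fragments independently scrambled
(4 Å shifts plus random rotations) to emulate wrong conformers.

These fixtures are *not* miniature proteins: receptor residues are
single atoms, ligands are disconnected fragment sets, and there is no
fold, rotamer chemistry, crystallographic disorder, or conformational
strain. Passing tests therefore demonstrate that the geometric and
statistical machinery is correct — perception rules fire exactly where
planted, frequencies and thresholds reproduce known tables, actives
outrank decoys by construction — not that the pipeline's cutoffs are
optimal for real crystal structures. Quantities that depend on real
structures and proprietary perception (absolute feature positions,
excluded-volume counts for a specific target, screening funnels over
commercial catalogues) are outside what desk-scale synthetic data can
certify.

## Numerical choices and degenerate inputs

- Kabsch uses the SVD closed form with the standard reflection guard;
  rotations are validated proper to $10^{-6}$. Fewer than three paired
  points is an error for superposition ("insufficient points").
- Greedy clustering merges the globally closest same-kind pair first;
  exact distance ties (rare off a lattice) break by input order.
  Re-clustering cluster centroids is a fixed point for well-separated
  clusters.
- `frequency()` validates $0 \le c \le N$, $N > 0$ ("bad count").
- An empty retained-cluster set warns ("model has no features") on
  selection and errors ("empty model") on model assembly, so a silent
  featureless model can never be built.
- Serialization writes numbers at full precision; write→read round trips
  are exact to double formatting. SDF output rounds coordinates to
  $10^{-4}$ Å (V2000 fixed width), which perturbs fit values by about
  that order.
- Unreadable library molecules are warned about, skipped and counted,
  never silently dropped.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
scale the statistics call for: 14 complexes × 19 sites (≈ 80 pooled
features), libraries of 10 actives + 90 decoys × 3 conformers, 1000
random rigid transforms for the superposition optimality check, and
25 random instances for the assignment-search oracle. These sizes keep
the exhaustive oracles exact while exercising every code path.

## Known limitations

- No aromaticity perception: rings are detected topologically, so ring
  N–H exclusion and "all-carbon ring" hydrophobes use graph criteria,
  not electronic ones.
- Bond orders from PDB input rely on CONECT multiplicity or distance
  perception (single bonds only); SDF input is authoritative when orders
  matter.
- Feature tolerances are uniform per model; per-feature weights exist in
  the fit function but no weight optimization is provided.
- The superposition is pairwise and rigid; ensembles with domain motion
  would need a binding-site-restricted pairing to align sensibly.
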