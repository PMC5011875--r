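---
title: "Selective 3D pharmacophores for agonist/antagonist discrimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective 3D pharmacophores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmselect)
```

## The problem

Nuclear-receptor ligands split into two pharmacological classes, agonists and
antagonists, that bind the same pocket but stabilise different receptor
conformations. Predicting the class of a ligand from its structure alone is a
long-standing virtual-screening problem. `pharmselect` implements a 3D
pharmacophore strategy for it: build many small geometric models of what
agonist (or antagonist) binding requires, keep only the models that are
*selective* — they retrieve ligands of one class and none of the other — and
combine them into per-receptor, per-class ensembles. A ligand is then
classified by which ensemble retrieves it.

A pharmacophore here is a set of typed feature points — aromatic ring (AR),
hydrophobic area (H), hydrogen-bond acceptor/donor (HBA/HBD), negative and
positive ionizable groups (NI/PI), metal binding (MB) — each with a position
and a spherical tolerance, plus exclusion-volume spheres standing in for
receptor sterics. A conformer is a hit when some rigid placement puts a
type-compatible ligand feature inside every required feature sphere (up to the
*max omitted features* allowance) without any heavy atom entering an exclusion
sphere.

## Model generation

**Structure-based (SB).** From a receptor-ligand complex, ligand features are
perceived, and those satisfying a geometric interaction rule with a receptor
partner become model features: hydrogen bonds at donor-acceptor heavy-atom
distance 2.5-3.8 Å with D-H...A angle ≥ 120°; hydrophobic contacts within
4.5 Å of an apolar receptor carbon; aromatic contacts within 5.5 Å of the ring
centroid; ionic pairs of opposite formal charge within 5.5 Å; metal
coordination within 2.8 Å. The binding site's shape is captured by 1.2 Å
exclusion spheres on every receptor heavy atom within 6 Å of the ligand
(dropping spheres the bound pose itself would violate, so the generating pose
always passes its own screen). These windows are conventional interaction
geometry; the software the original protocol relied on does not publish its
rules, so ours are explicit and configurable (`interaction_rules()`).

**Ligand-based (LB).** A ligand set is first clustered on the pharmacophore
RDF code: a Gaussian-smoothed radial distribution of inter-feature distances,
one block per unordered feature-type pair (28 blocks × 32 bins over 0-16 Å),
L2-normalised as a whole. Distances between codes therefore live on a fixed
0..√2 scale, and the conventional cluster-distance cut of 0.4 (lowered
stepwise to 0.3/0.2 while one cluster still holds more than half of the
ligands) behaves sensibly. The smoothing width is 1.0 Å — commensurate with
the 1.5 Å feature tolerance, so ligands of one chemotype under sub-Ångström
coordinate noise stay within the 0.4 cut; same-type blocks are kept because
hydrophobic-dominated models carry most of their signal in H-H distances.
Complete-linkage clustering is cut at the threshold; singletons are reassigned
to the nearest multi-member cluster by average linkage whenever one exists.

Each cluster is rigidly aligned on its feature-richest member (ties broken by
id) through the same correspondence search used in screening. Features of one
type within a 1.5 Å merge radius across members are merged at their centroid:
features present in *all* members become required; features present in at
least 10 % of members become optional partially-matching features (they are
matched when possible but never cause rejection); rarer features are dropped.
Generation fails if any training member misses more than 4 required merged
features. An exclusion shell is added on probe points 2.0-3.0 Å off the
alignment (kept within 6 Å of the model's features, so the shell limits the
pharmacophore core rather than tracing distal substituents, and never
clashing with a training member); extra spheres can be placed manually to
reject decoys whose inactivity stems from steric clashes.

## The refinement protocol

Every raw model passes through three screenings against its own class
(actives) and the opposite class (decoys — agonists are the decoys for
antagonist models and vice versa):

1. **Screening 1**, max omitted features 0: the model is *validated* only if
   it retrieves at least one active and no decoy. A model that retrieves
   nothing is not validated — it would contribute nothing to an ensemble.
2. **Screening 2**, max omitted features 1: for each enabled feature, the
   extra hits gained when that feature is the omitted one identify
   *non-essential* features — those gaining at least one active and no decoy.
3. **Screening 3**: each non-essential feature is disabled and the model
   re-screened at 0 omitted features; the variant is kept only if it still
   retrieves only actives.

The loop recurses breadth-first on accepted variants (deduplicated by their
enabled-feature set) until three enabled features remain — fewer than three
independent features cannot define a rigid alignment — or no non-essential
feature exists. Validated models are ranked by hit count and pruned greedily
from the smallest: a model is dismissed when its removal leaves the union
recall unchanged. SB and LB survivors are finally gathered into SB, LB and
combined SBLB ensembles (each pruned the same way). Because only validated
models are ever retained, every ensemble retrieves zero decoys at screening
settings, hence FP = 0 and specificity = 1 by construction; recall and MCC
are the quantities that vary.

## The matching engine

Matching a conformer to a model is a search over injective type-compatible
correspondences and rigid transforms. The implementation enumerates
correspondences depth-first with a distance-geometry pruning rule
(`|d_model − d_ligand| ≤ tol_a + tol_b` for every assigned pair — a necessary
condition for any rigid placement) and assesses each complete correspondence
against a deterministic family of candidate transforms: the full
least-squares (Kabsch) superposition, every triplet-seeded superposition,
an iteratively reweighted fit that pushes violated features inside their
tolerance spheres, and finally a Nelder-Mead minimax (Chebyshev) registration
started from the least-squares pose when that start is within 2.5× tolerance.
Acceptance is per-feature (each matched feature inside its own tolerance
sphere), not aggregate RMSD; clash testing rejects any transform placing a
heavy atom strictly inside an exclusion sphere. Among feasible matches the
lowest (omitted count, RMSD) wins, with ties broken by conformer index.

A brute-force twin (`brute_force_match`) enumerates all correspondences
without pruning under the same acceptance contract; the test suite checks
agreement on hundreds of randomized instances. Because feasibility is decided
by a finite transform family, laws such as "disabling a feature never shrinks
the hit set" are not automatic theorems: the reweighted and minimax fallbacks
exist precisely to recover poses that a restricted least-squares fit misses,
and the property suites exercise those laws on randomized cases.

## Feature chemistry

Feature perception is rule-based and configurable; the defaults: HBD on
neutral O-H/N-H (implicit hydrogens inferred from valence); HBA on neutral
oxygens and on nitrogens that are neither amide nor aromatic N-H (hydroxyls
are therefore both donor and acceptor); AR on aromatic rings (all-aromatic
bond orders, or 5/6-rings with ≥ 2 ring double bonds) with the plane normal
stored; H on connected groups of ≥ 3 apolar carbons/halogens, merged within
2 Å; PI on charged nitrogens and neutral amidine/guanidine groups; NI on
carboxylate/sulfonate/phosphate groups and other anionic oxygens; MB on
thiols. These stand in for a commercial tool's unpublished definitions and
are deliberately conventional.

## The synthetic benchmark

Real nuclear-receptor collections are large, proprietary to screen at desk
scale, and carry no ground truth about *why* a ligand binds. The generator
replaces them with a world where the truth is planted: each pseudo-receptor
gets an agonist and an antagonist archetype — 3-6 typed feature points in a
12 Å box, pairwise ≥ 2.5 Å apart, non-collinear, type frequencies matching
the composition observed across nuclear-receptor pharmacophores (H 39.3 %,
HBA 32.5 %, AR 14.0 %, HBD 9.2 %, remainder shared by NI/PI/MB). Ligands are
pseudo-atom realizations of their class archetype: each feature becomes a
minimal probe group that triggers exactly its perception rule (hydroxyl for
HBD, carbonyl for HBA, a three-carbon chain for H, benzene for AR, ammonium
for PI, carboxylate for NI, thiol for MB). Every ligand is jittered by an
isotropic 0.3 Å Gaussian per feature; a quarter of the actives drop one
feature planted as non-essential (so refinement has something real to find);
0-2 distractor features are placed ≥ 17 Å from the archetype body — outside
both the RDF window and any exclusion-shell band — so intact actives remain
recoverable by construction. Each ligand carries a second, rigidly rotated
conformer for alignment-invariance checks. Pseudo-complexes place one
receptor anchor atom per feature at the midpoint of its interaction window
(e.g. an acceptor oxygen 3.15 Å out along the feature's outward direction),
plus apolar shell atoms for exclusion-volume derivation and a designated
clash-site carbon used by steric-clash decoys (a `generate_ligand` option for
targeted exclusion-volume tests; the default benchmark plants none, since a
clash decoy with symmetric features can legally escape its clash sphere
through an alternative correspondence and would then invalidate every model
of the class).

What passing on this benchmark shows — and does not. The synthetic world
exercises the full geometric stack (perception, correspondence search,
alignment, exclusion volumes, the refinement logic, the metrics) against a
decidable oracle, and the two structural guarantees (specificity 1 for every
retained ensemble; full recall when every active is recoverable) reproduce at
the benchmark's scale of 6 receptors × (20 + 10) ligands. It does not emulate
real conformational flexibility, tautomerism, chemotype diversity within a
class, or property-matched decoys; recall on real collections depends on
those and on conformer quality, and is expected to be lower.

## Numerical choices and degenerate inputs

Default feature tolerance 1.5 Å; AR normals are stored but matching does not
constrain them by default (a 30° normal-angle check is available in the data
model). "Independent features" in the three-feature rule is read
geometrically: pairwise-distinct, non-collinear points (within 1e-6 Å), since
rigid alignment needs three non-collinear anchors; optional features do not
count toward the minimum. Clash is strict interiority (distance < radius).
Zero-hit models fail validation; empty datasets are constructor errors;
molecules with no perceivable features yield empty feature sets and never
match. Conformer embedding for SMILES input is a deterministic
distance-geometry build (shortest-path bond-length distances, classical MDS,
restraint refinement) with seeded torsion driving for additional conformers —
chosen over an external 3D builder whose rotor search is not reproducible
across calls. Kendall correlation is tau-b with tie correction and a normal
approximation for the p-value; the composition comparison uses two-sided
Mann-Whitney tests per feature type with a Benjamini-Hochberg column, the
original report of significance not naming its test. MCC follows the printed
formula with the "ND" convention whenever a denominator factor is zero.

## Problem sizes

The bundled analyses and tests run the full pipeline on 6 receptors with
20 agonists and 10 antagonists each (two conformers per ligand), cluster-level
LB generation, and property suites of 100-1000 randomized cases per law —
sizes chosen so the complete study re-runs from scratch in a few minutes on a
single core while still exercising every code path, including multi-cluster
datasets and multi-variant refinement.

## Limitations

Only conformer 1 of each training ligand is used for LB building (all
conformers are used in screening). Water-mediated interactions, halogen
bonds, protein flexibility, tautomer/protomer enumeration and partial-charge
models are out of scope. The matcher's feasibility decision is a deterministic
heuristic over a finite transform family; it agrees with exhaustive
enumeration on the tested distributions but is not a complete decision
procedure for the underlying geometric feasibility problem.
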