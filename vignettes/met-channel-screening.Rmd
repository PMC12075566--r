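---
title: "Pharmacophore screening and hit triage for MET channel modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore screening and hit triage for MET channel modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

## The problem this package addresses

Hair cells of the inner ear transduce sound through mechano-electrical
transduction (MET) channels whose pore is formed by TMC1/TMC2. The same
pore admits ototoxic drugs such as aminoglycosides, so small molecules that
block or modulate it are candidate otoprotectants. A practical route to
such molecules is ligand-based: known MET blockers are chemically diverse
but tend to share a protonatable amine and aromatic rings, suggesting a
common 3D pharmacophore. `metscreen` implements the full desk-side
analysis around that idea:

1. perceive pharmacophore features on 3D small-molecule structures,
2. derive common 3-5-feature hypotheses from a training set of blockers,
3. validate hypotheses against decoys (ROC/AUC and the Güner-Henry family),
4. screen libraries in two passes (geometric RMSD gate, then a screen
   score), aggregate per-compound totals and select compounds above a
   mean-plus-two-standard-deviations threshold,
5. triage hits for structural diversity with Morgan-fingerprint Tanimoto
   clustering and binding-energy ranking,
6. analyze docked pose ensembles for per-residue contact frequencies and
   typed interactions, and
7. profile the channel pore radius along its axis to delimit top, middle
   and bottom binding zones.

Every stage has a seeded synthetic generator that returns its own ground
truth, so the whole pipeline is testable end to end without proprietary
software or large compound libraries.

## Feature perception

Six feature types are used: hydrogen-bond acceptor (A), donor (D),
hydrophobe (H), negative (N), positive (P) and aromatic ring (R). The
perception rules live in an editable CSV table
(`default_feature_rules()`), one row per (type, predicate, placement).
Predicates are named graph rules evaluated on the molecular graph —
elements, bonds, formal charges, ring perception — rather than SMARTS
strings, because no installed R SMARTS engine exposes matched atom
indices, which placement requires. The defaults:

* **R** — planar 5-7-membered rings of C/N/O/S with aromatic or
  alternating bond orders; placed at the ring centroid, direction along
  the ring normal (sign is arbitrary, and all downstream alignment treats
  ring normals as axial).
* **P** — any atom with positive formal charge (protonated amines,
  amidinium, guanidinium); placed at the atom.
* **N** — carboxylates at the midpoint of the two oxygens; other
  negatively charged atoms at the atom.
* **A** — N/O with a free lone pair and non-positive charge; direction
  along the idealized lone-pair vector (opposite the mean bond vector).
* **D** — N/O bearing hydrogens, charged or not; direction along the mean
  X-H vector. A protonated amine therefore carries co-located P and D
  features; whether charged groups should double as donors is genuinely
  open, and keeping both is the permissive default.
* **H** — connected clusters of two or more non-aromatic carbons bonded
  only to C/H/halogen, at the cluster centroid.

Features are computed on structures with explicit hydrogens; all other
geometry in the package (contacts, pore) uses heavy atoms only. Same-type
features within 1 Å merge to their centroid, which stops fused-ring and
tautomer double counting.

## Hypothesis generation and scoring

Common arrangements are found by enumeration, which is exact at
training-set scale (tens of molecules, tens of features): every k-subset
(k = 3..5) of every training molecule's features is a candidate; a
candidate survives if at least the coverage fraction (default 50%) of
training molecules matches it. Candidates are deduplicated by type
signature plus agreement of the sorted inter-feature distances within
tolerance.

Matching is a correspondence search: over all injective same-type
assignments of hypothesis features to molecule features, take the
assignment minimizing RMSD after optimal rigid superposition (Kabsch, via
SVD). A molecule matches when that RMSD is at most the tolerance (default
1.0 Å, the same value as the screening gate — one number, used twice,
deliberately). Partial matching, when enabled, admits subsets covering at
least 75% of the hypothesis.

The hypothesis quality score is defined as

> mean over matched molecules of
> (1 − RMSD/RMSD~max~) × (mean direction-cosine of matched directional
> features), multiplied by coverage, with RMSD~max~ = 2 × tolerance.

It is 1 exactly when every molecule sits on every feature with aligned
feature vectors, 0 when nothing matches, and monotone in geometric and
vector alignment between those extremes. It is *not* numerically
comparable to scores printed by proprietary pharmacophore software; only
its ordering semantics are meaningful. Ranking ties break
lexicographically by hypothesis id, then by feature count (larger first),
so results are deterministic.

A design note on tolerances: a single global tolerance per hypothesis is
used rather than per-feature radii. Per-feature radii add parameters the
training data here cannot constrain; the global default keeps the gate
interpretable.

## Screening, TPS~S~ and the docking threshold

Screening is two-pass. The first pass is purely geometric: compounds whose
best correspondence RMSD exceeds 1 Å against a hypothesis are discarded
for that hypothesis; across hypotheses, `first_pass_filter()` keeps the
top-N lowest-RMSD compounds per model (default 5000) and then demands
agreement of at least two models. The second pass scores survivors:

> screen_score = (matched_fraction + (1 − RMSD/RMSD~max~) +
> vector_alignment) / 3

with configurable weights and scale. Again, the score is an analog with
defined semantics, not a reproduction of any proprietary score.

Per-compound totals (TPS~S~) are the row sums of the compound ×
hypothesis score matrix, with protomers/conformers of one compound
collapsed beforehand by the per-hypothesis maximum. The selection rule is

> D~T~ = mean(TPS~S~) + 2 × sd(TPS~S~), select TPS~S~ ≥ D~T~,

with the sample (n−1) standard deviation and inclusive comparison. The
population-vs-sample choice is undocumented in the method this mirrors;
sample SD is the conservative reading and the difference only matters at
measure-zero ties, as does inclusivity. The rule is affine-equivariant, so
rescaling scores never changes the selected set. With all-equal scores,
D~T~ equals the common value and everything is selected — a documented
edge case, not an error.

## Decoy validation

`roc_auc()` uses the rank (Mann-Whitney) formulation — the probability an
active outscores a decoy, half credit for ties — which equals trapezoidal
ROC integration. `gh_metrics()` computes %Yield, Ya, Se, Sp, EF and the
Güner-Henry score

> GH = [Ha(3A + Ht) / (4·Ht·A)] × [1 − (Ht − Ha)/(D − A)]

from retrieval counts (D screened, A actives, Ht hits, Ha active hits).
GH above 0.7 reads as a good model and above 0.5 as acceptable, with
strict inequalities at the boundaries. Degenerate counts (no hits, no
decoys) raise explicit errors rather than returning NaN.

Decoy sets are inputs: the synthetic generator supplies geometric decoys
(same feature inventory, randomized arrangement, rejection-sampled to lie
at least 2 Å RMSD from the planted truth). This validates the metric code
but is weaker than property-matched decoy generation used in production
screening, which matches physicochemical properties too — a documented
divergence.

## Diversity clustering and hit selection

Fingerprints are Morgan (extended-connectivity) circular fingerprints of
radius 2, computed through OpenBabel (ECFP4) without chirality.
Similarity is the Tanimoto coefficient; clustering is average-linkage
(UPGMA) on 1 − similarity. The cut is *normalized*: the threshold (0.75
for a large diverse library, 0.85 for a small approved-drug library in
the workflow this mirrors) multiplies the maximum merge height of the
dendrogram. That dendrogram-relative reading is adopted because linkage
heights vary per dataset even when distances live in [0, 1], so a relative
cut adapts the absolute height to each library; an absolute-height cut is
available via `normalized = FALSE` for users who prefer it.

Representatives are picked per cluster of at least 3 members, ranked by
binding energy without phospholipids (most negative first, ties by id),
and `consistency_check()` verifies the picks remain thermodynamically
favorable when phospholipid-containing energies are considered, flagging
hits whose binding weakens with lipids present.

## Pose contacts and interaction typing

A residue is contacted by a pose when any ligand heavy atom lies within
5 Å of any residue heavy atom; its frequency is the fraction of poses
contacting it, and frequencies strictly above 0.5 are high-contact. A
frequency of exactly 0.5 is classified low — the boundary is not covered
by the strict-inequality convention, so the conservative side is chosen
and documented. Membrane lipids (e.g. POPC) are ordinary residues under
their PDB residue id, which lets the analysis surface lipid-mediated
binding. Contact profiles are computed over whatever ensemble is
supplied; the pipeline default is one best pose per ligand, and passing
all poses per ligand is simply a different input.

Interaction typing applies distance criteria between heavy atoms: salt
bridge ≤ 4.0 Å (opposite charges), hydrogen bond ≤ 3.5 Å
(donor-acceptor), cation-π ≤ 4.5 Å (cation to aromatic ring centroid),
hydrophobic ≤ 4.5 Å (apolar carbons). These cutoffs are configurable;
they are artifact-defined conventions in the mainstream range for
heavy-atom criteria, not fitted values. Receptor atom roles come from an
editable residue template table; ligand roles from elements and formal
charges. Implicit-solvent docking cannot show water-mediated contacts, so
none are inferred.

## Pore profiling

At each grid position z along the pore axis the profiler reports the
radius of the largest probe sphere that fits: the maximum over probe
centers in the plane normal to the axis of (distance to nearest atom
center − its van der Waals radius). The maximization uses Nelder-Mead
with 8 seeded random restarts per plane, warm-started from the previous
plane's center and bounded to a 15 Å cylinder around the axis. The warm
start makes the probe *track the channel*: a fully global maximizer would
escape any laterally open structure (including real membrane-protein
pores above and below the bilayer and ring-stack test fixtures) to the
unbounded exterior, which is not the quantity of interest. A consequence,
verified in the test suite, is that coarse angular discretization of a
ring fixture does not degrade the profile at ring planes — the ring
center is the in-plane clearance maximum by symmetry — so profile error
on such fixtures is governed by axial spacing.

Van der Waals radii come from a Bondi-style element table shipped as CSV;
reported pore dimensions are table-dependent, so any comparison of a
narrowest-diameter estimate against a published figure (for the TMC1 pore,
roughly 4.5 Å) should be read as approximate and contingent on the radii
set. Planes with no atoms within the search cylinder report a capped
radius (default 15 Å) and are flagged rather than erroring, since open
pore mouths are normal.

Zone boundaries derive from the profile: the middle zone is the
contiguous neighborhood of the global constriction where the radius stays
within 25% of the way from minimum to maximum (at least ±1 Å), and the
expanded flanks become bottom and top. V-shaped profiles collapse the
middle to the configured neighborhood of the minimum; flat profiles fall
back to a single zone with a warning.

## The synthetic generators: what they emulate and what they do not

`gen_planted_set()` emulates a training set of blockers sharing a planted
arrangement — by default a four-point APRR geometry with inter-feature
distances in the 3-7 Å range typical of small-molecule pharmacophores,
chosen once as a realistic arrangement — with per-molecule Gaussian
coordinate noise (default σ = 0.2 Å, the scale of conformer and alignment
jitter rather than of chemical dissimilarity), two distractor features
per molecule, and 40 geometric decoys per active. Study-condition
defaults (6 actives, σ = 0.2 Å, 40 decoys per active, 3-5 features, 50%
coverage, 1 Å gate) are fixed in `default_config()`.

What passing tests on these fixtures shows: the enumeration recovers
planted arrangements through realistic noise; the matcher, metrics,
clustering and profilers agree with independent brute-force oracles; the
selection rule equals its definition. What they do not show: performance
on real conformer ensembles (the generator plants features directly
rather than deriving them from flexible molecules), robustness to
property-matched decoys, or agreement with any proprietary score's
numeric values.

Problem sizes used by the test suite and the acceptance script — 20
replicate seeds for recovery, 6 actives with 240 decoys for screening,
50-residue/36-pose contact systems, 21-ring pore fixtures profiled at
0.5 Å steps — were chosen as the smallest sizes at which every property
under test is comfortably expressed.

## Reproducibility and the pipeline driver

`run_pipeline()` executes the stages in dependency order from a single
configuration (R list or YAML), derives every stage's RNG stream from the
master seed, writes diffable CSV/JSON tables, and records a manifest with
the configuration hash and per-stage row counts. Unknown configuration
keys abort before any stage runs. Re-running an identical configuration
reproduces byte-identical tables; this is asserted in the test suite.

## Known limitations

* Feature perception is rule-table chemistry, not quantum or pKa-aware;
  protonation states must be supplied (pre-enumerated protomer records
  are first-class inputs).
* The hypothesis search is exhaustive by design and scales combinatorially;
  it is intended for training sets of tens of molecules, not libraries.
* Screen and hypothesis scores are analogs with defined semantics; they
  order compounds and models but reproduce no published score values.
* The pore profiler is single-structure; trajectory averaging is plain
  iteration left to the caller.
* Docking and binding free energies are consumed as inputs, never
  computed.
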