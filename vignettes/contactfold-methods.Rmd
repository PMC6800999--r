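---
title: "Contact-driven folding and model ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-driven folding and model ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ContactFold)
```

ContactFold implements two connected pieces of machinery from
contact-driven protein structure prediction: (i) folding a chain from
predicted residue-residue contacts by translating them into distance
restraints and optimising against a restraint energy, and (ii) ranking a
pool of candidate models with a two-level neural-network ensemble fed by
1D, 2D and 3D quality features. A synthetic-data module supplies every
input with controlled ground truth so that both pipelines can be exercised
and benchmarked end to end on a single CPU.

## Contacts and restraints

A *contact* is a residue pair whose C-beta atoms (C-alpha for glycine) lie
within a distance threshold, canonically 8 Angstrom. Predicted contacts
come as CASP RR records `i j d_low d_high probability`; `readRR()` reads
them, normalises pairs to `i < j`, keeps the maximum probability for
duplicates and sorts by decreasing probability.

For folding, the top `x * L` predictions (`selectTopContacts()`, with the
ratio `x` swept from 0.1 to 4 in the full protocol) become distance
restraints between representative atoms with lower bound 3.5 Angstrom,
upper bound 8 Angstrom and width `sd = 0.5` Angstrom, weighted by the
predicted probability.

Two contact energy functions are implemented exactly as published systems
use them:

* `boundedPotential(d, lb = 3.5, ub = 8, sd = 0.5)` — a flat-bottomed
  well: `((d - lb)/sd)^2` below `lb`, zero on `[lb, ub]`,
  `((d - ub)/sd)^2` on `(ub, ub + 0.5 sd]`, then a linear tail with slope
  `1/sd` matched for continuity, `(d - (ub + 0.5 sd))/sd + 0.25`. The
  printed form of the outermost branch in the source literature is
  typographically ambiguous; we adopt the unique continuity-matched linear
  continuation consistent with its visible `1/sd` and `0.5 sd` terms. The
  function is continuous everywhere, zero exactly on `[lb, ub]`, and
  strictly increasing away from the well on both sides.
* `squareWellPotential(d, P, d0 = 8)` — a square well with exponential
  decay: `-P` for `d < d0` and `-P exp(-(d - d0)^2) + P (d - d0)/d`
  beyond, continuous at `d0` and identically zero for `P = 0`. Here too a
  possible missing parenthesisation in the printed second branch exists;
  the adopted reading is the most parsimonious one and the function is
  isolated so an alternative reading is a one-line change.

Predicted secondary structure contributes local restraints
(`ssToRestraints()`): helix runs of at least 4 residues emit per-residue
phi/psi targets of -57/-47 degrees (tolerance 20) and CA(i)-CA(i+4)
distances of 5.4-6.4 Angstrom; strand runs of at least 3 emit phi/psi
-120/+120 (tolerance 30). These numeric targets are canonical textbook
values; the source systems cite them without printing numbers.

## Folding: distance geometry plus simulated annealing

`embedDistanceGeometry()` performs classical metric-matrix embedding. A
full bounds matrix is assembled from the restraints (CB-level bounds are
widened by 1 Angstrom when mapped onto the CA trace), chain bonds
(3.8 Angstrom between consecutive CA), a generic hard-sphere lower bound
of 3.5 Angstrom, and path upper bounds `3.8 |i - j|`; upper bounds are
smoothed by the triangle inequality, and a bound inversion after smoothing
is reported as an infeasibility naming the offending pair. Restrained
pairs enter the distance matrix at their interval midpoint; unrestrained
pairs are drawn uniformly from their smoothed bounds (this seeded
metrization is the only source of randomness and provides decoy
diversity). The top three eigenvectors of the centred Gram matrix give
coordinates. Because a distance matrix cannot distinguish a structure from
its mirror image, chirality is fixed by convention: the mean CA
pseudo-torsion over helix-restrained residues (over the whole chain when
no helix information exists) must be non-negative, matching the
handedness of a right-handed alpha helix.

`annealModel()` refines the embedded trace by Metropolis simulated
annealing over single-residue Cartesian moves. The objective is the
weighted sum of `boundedPotential` terms for all resolvable distance
restraints, a chain-bond term (3.8 +/- 0.1 Angstrom), pseudo-torsion
penalties and a soft-sphere clash term (pairs closer than 3.5 Angstrom).
The model is coarse-grained (CA plus pseudo-CB): C-beta positions are
rebuilt deterministically from the local CA frame, so CB-level restraints
remain meaningful without side chains. Phi/psi restraints are scored as CA
pseudo-torsions (helix target +50 degrees, strand -170 degrees), the
coarse-grained equivalents of the backbone targets. The returned model is
the best-energy snapshot; with `T_start == T_end` the acceptance rule
degenerates to greedy descent. The proposal scale shrinks with
temperature; the schedule is geometric with defaults `T_start = 2`,
`T_end = 0.01`, and `min(20000 L, 2e6)` proposals. Incremental energy
evaluation makes one proposal O(restraints touching the moved residue +
L), which keeps a 60-residue fold in the tens of seconds on one CPU.

`confold2Fold()` runs the two-round protocol. Round 1 folds
`models_per_x` decoys for every ratio in `x_grid`. The pooled round-1
decoys are clustered (`clusterAndSelect()`: greedy TM-score clustering at
threshold 0.6, largest cluster first, representative = best restraint
energy). Round 2 detects beta-strand pairings on the representatives
(`detectBetaPairings()`: pairs of strand runs whose best-register mean
CA-CA distance is below 5.5 Angstrom in at least half of the
representatives), adds pairing restraints (CA-CA 4.5-5.5 Angstrom plus an
N-O hydrogen-bond ladder on alternating rungs), prunes contact restraints
unrealized (outside `[lb, ub]`) in at least half of the representatives,
and repeats embedding and annealing. Both rounds' decoys are returned
with provenance. Since the coarse-grained representation carries no N/O
atoms, the annealer skips the N-O ladder rows and their geometric effect
is carried by the parallel CA-CA ladder; the rows are still emitted so a
full-backbone refinement stage could consume them.

Contact inclusion when *extracting* contacts from a model uses strict
`< threshold`; restraint *satisfaction* uses inclusive `[lb, ub]`. The
boundary convention is not stated by the source systems; the pair of
choices is internally consistent and matches restraint conventions in
CNS-style tools, where a restraint at its boundary is realised.

## Structural metrics

`kabschSuperpose()` computes the least-squares rigid superposition with
proper rotations only (reflections excluded via the determinant
correction). GDT-TS is the mean over cutoffs 1, 2, 4, 8 Angstrom of the
maximal fraction of CA atoms within the cutoff, searched with the
standard seed-extension heuristic: seed fragments of lengths 3, 5 and 7 at
every position, iterative superpose-and-include until the included set is
stable, maximum over seeds. Exact maximisation is combinatorial; for
chains of at most 10 residues the seed set is expanded to every residue
subset of size at least 3, which makes the search exhaustive there (and
verified against independent enumeration). TM-score uses
`d0 = 1.24 (L - 15)^(1/3) - 1.8` and an analogous iterative search; a
TM-score above 0.5 classifies a model as having the correct fold.
`assignSS()` gives a deterministic 3-state assignment from phi/psi windows
when backbone N/C atoms are present, or from CA pseudo-geometry for
coarse-grained models; strand states additionally require a partner
strand within pairing distance. It is intentionally simpler than a full
hydrogen-bond-based assignment: its role here is feature generation, and
an externally computed string can be supplied instead wherever one is
available. `pairwiseConsensusRank()` scores each model by its mean GDT-TS
to the rest of the pool, the classic pairwise-consensus ranking.

## Model ranking: the two-level ensemble

Every model in a pool is described by a feature vector
(`assembleFeatures()`):

* 1D — agreement fractions between the secondary structure and solvent
  accessibility predicted from sequence and those derived from the model
  (`ssMatch`, `saMatch`; exposure uses a sphere-count proxy: a residue is
  exposed if at most 14 other CA lie within 10 Angstrom, an approximate
  25 percent relative-accessibility threshold). Positional identity is
  the simplest reading of "similarity" and is used for both.
* 2D — for each sequence-separation class (short 6-11, medium 12-23, long
  24 and up), the fraction of the top `ceiling(L/5)` predicted contacts in
  that class realised in the model at 8 Angstrom. An empty class scores 0
  and clears the vector's completeness flag (the ceiling convention and
  the flag resolve the behaviour for short lists).
* 3D — external quality-score columns, min-max normalised per target;
  missing values are imputed with the per-target column mean and flag the
  model incomplete.

`trainEnsemble()` reproduces the two-level training procedure. Targets are
split into 10 folds (`targetWiseFolds()`, all models of a target in one
fold). For each fold, every candidate architecture (small fully connected
networks, rectified hidden layers, sigmoid output, mean-squared-error
objective, full-batch Adam, early stopping on the fold's validation MSE
with patience 20) is trained on the other nine folds, and the candidate
with the lowest mean *selection loss* on the held-out fold becomes that
fold's member. Selection loss is the GDT-TS of the best model of a target
minus the GDT-TS of the model the method ranks first. The level-2
combiner is trained on the ten level-1 scores concatenated with the
original features, on a random 9:1 model-level split (the literal protocol
choice; a target-wise level-2 split is the plausible alternative and was
deliberately not chosen), with the architecture selected by validation
MSE. The combiner grid always includes a linear (no-hidden-layer)
candidate: with ten already-calibrated level-1 scores a low-variance
weighting is frequently the best combiner, and the grid search decides
per dataset. All inputs are z-scored with statistics from the respective
training data, stored in the ensemble. `predictDeepRank()` gives the
level-2 output clipped to [0, 1]; `predictDeepRankAvg()` is the simplified
variant that averages the ten level-1 outputs. No single network
architecture is privileged: the *selection procedure* is the fixed part
of the design, and the grid is a configuration knob.

## Pool hygiene and consensus

`filterPool()` drops models covering less than 80 percent of the target
(the notion of "incomplete" is unquantified upstream; 80 percent is this
package's choice) and, scanning each source group in input order, removes
models with GDT-TS above 0.95 to an already retained same-group model.
`consensusCombine()` superposes all pool models with GDT-TS above 0.6 to
the top-ranked model onto it and averages coordinates; if the consensus
stays within GDT-TS 0.88 of the initial top model it is kept, otherwise
the top model is returned flagged for external refinement. The 0.88 check
compares the consensus to the initial top model (the literal reading of
the upstream rule).

## The synthetic-data module

`makeNative()` builds toy natives from an explicit topology string
(e.g. `H:10, C:3, E:7, ...`): helices and strands with ideal backbone
geometry placed rigidly — strands side by side 4.6 Angstrom apart with
in-phase pleats forming a sheet, helices packed on the sheet faces
7.6 Angstrom away, consecutive elements running in alternating directions,
loops laid out along circular arcs with 3.8 Angstrom spacing. Placement is
jittered and retried until self-avoiding. These natives are compact,
contain genuine alpha/beta contact networks (a 60-residue
four-strand/two-helix topology has roughly 140 contacts at 8 Angstrom,
separation 6 and up), and have exactly known secondary structure.

`makeDecoys()` grades quality by hinge rotations (one or two random
pivots, angle scale 2.5 degrees per unit magnitude) plus serially
correlated Gaussian jitter (0.3 Angstrom per unit, AR(1) coefficient
0.85), so decoys keep realistic partially-correct substructure rather
than white-noise blur. Labels are true GDT-TS against the native.

`makeContactPredictions()` mixes true native contacts with sampled
non-contact pairs so each rank is true with probability `precision`;
probabilities decay as `0.95 exp(-r/(coverage L))` so only ordering
matters downstream. Requesting more true contacts than the native has is
an error rather than a silent precision shortfall.

`makeQADataset()` assembles labelled benchmark pools. The design choices
here determine what the QA experiments can show, so they are explicit:

* Pool composition per target: two thirds of the graded decoys cluster in
  the hard-to-rank region (magnitudes 2-4.5, GDT-TS roughly 0.75-0.95 —
  server pools for hard targets rarely contain near-natives), one third
  spread to clearly wrong models, plus a quarter of the pool as
  *topology breakers* — models rotated 25-40 degrees about a single hinge
  in the middle third of the chain, with minimal jitter. Breakers are
  locally clean (individual secondary-structure elements intact) but
  globally wrong; contacts across the hinge are destroyed while 1D
  features barely change. This is the model-pool failure mode that
  motivates contact-based quality features in the first place.
* External 3D score columns emulate single-model quality methods:
  `(1 - b) gdt + b local + noise`, where `local` is the model's
  secondary-structure retention, `b = 0.4` is the local-plausibility bias
  documented for single-model methods (they overrate locally clean,
  topologically wrong models), and the per-column noise SDs default to
  0.15-0.3 — calibrated so that single-feature selection losses fall in
  the 0.04-0.1 range reported for real quality-assessment methods rather
  than the unrealistically easy near-zero regime. One adversarial
  anti-correlated column is always included, and an exact oracle column
  can be requested for recovery experiments.
* Predicted 1D strings are corrupted at realistic error rates (15 percent
  for 3-state secondary structure, 20 percent for 2-state accessibility).

What the generator does *not* emulate: real side-chain packing and its
effect on accessibility, sequence-dependent contact propensities,
template-based model correlations within a server group, multi-domain
architecture, and experimental-structure noise. Passing benchmarks on
these fixtures therefore demonstrates that the machinery is correct and
that the documented mechanisms behave as described — not that the trained
toy ensembles would transfer to real server pools.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale study
conditions chosen to exercise every mechanism on one CPU: 60-residue
natives with 2L perfect contacts and a reduced ratio grid (`x` in {1, 2},
3 models per ratio, 8e5 annealing proposals) for folding recovery;
50-residue natives, 5 seeds and 3e5 proposals for the precision-quality
trend; 12-16 training targets with 14 models each for the ensemble
experiments. Ties in contact selection are broken lexicographically by
(i, j); ranking ties by model id; clustering picks the largest cluster
first and the lowest-energy member as representative. Degenerate inputs
(empty restraint sets, pools that filter to nothing, constant labels)
raise errors or warnings rather than propagating silently.

## Known limitations

* The annealer optimises a CA/pseudo-CB representation; no full-atom
  refinement or side-chain modelling is attempted.
* The secondary-structure assigner is window-based, not hydrogen-bond
  based; near helix/strand boundaries it disagrees with DSSP-style
  assignments more often than in element cores.
* The GDT search is the standard heuristic; it can undershoot the true
  maximum on adversarial instances (it is verified exhaustively only on
  tiny ones).
* Mirror-image ambiguity is resolved by the helix-handedness convention;
  for all-strand topologies with no helix restraints the convention can
  pick the wrong hand, which the TM-score threshold then penalises.
* Ensemble behaviour is demonstrated on synthetic pools whose failure
  modes are designed, not sampled from real predictors.
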