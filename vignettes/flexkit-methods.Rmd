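---
title: "Measuring protein conformational flexibility from redundant structures: methods and design"
author: "flexkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein conformational flexibility from redundant structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexkit)
```

# The measurement problem

A protein deposited many times in a structural archive is, in effect, an
experimental conformational ensemble: each independent deposition samples
the molecule under different conditions (crystal form, ligand, pH,
construct). flexkit treats all depositions of *the same* protein chain as
repeated measurements and asks two separable questions:

* **Global flexibility** — how different are whole conformers from each
  other, and do they fall into discrete states?
* **Local flexibility** — which residues deform, independent of
  rigid-body motion of the domains they sit in?

The package deliberately restricts itself to C-alpha coordinates. All the
quantities it computes (RMSD, distance maps, contacts, morphs) are
well-defined on the Cα trace, and the Cα trace is the part of a deposition
whose errors are smallest and most uniform across depositions.

# Chain ingestion and the disorder model

The unit of analysis is one chain of one deposition. The SEQRES-defined
sequence is the indexing frame: residue *i* always means the *i*-th SEQRES
position, and author residue numbers are kept only as metadata. A residue
present in SEQRES but lacking a Cα coordinate is *disordered* — that
absence is data (order/disorder variation between depositions is itself a
form of flexibility), so unresolved residues are represented explicitly
rather than silently dropped.

When a file's author numbering indexes SEQRES directly (1-based,
increasing, residue types agree) it is trusted; otherwise the ATOM-derived
sequence is placed onto SEQRES by an end-gap-free alignment with penalized
mismatches and cheap gaps, so scattered missing residues open gaps instead
of sliding the register. Mapping by sequence is ambiguous when the residue
type at a disorder boundary repeats; author numbering resolves this in
practice, which is why it is preferred when sane.

Three quality filters with strict boundary semantics remove chains that
cannot support the analysis: more than 25 SEQRES residues required (a
25-residue chain is rejected), no run of more than 20 consecutive unknown
residues, more than 25 resolved Cα atoms required. The length filter is
applied to SEQRES length, with the separate Cα-count filter covering
resolved length, so a long but mostly disordered chain is rejected for the
right reason (`too_few_ca`). Only the first MODEL of a multi-model file is
read — the method targets crystallographic depositions, and NMR ensembles
model a different quantity. For alternate locations the first-listed
conformer is kept, a deterministic choice.

# Sequence clustering and the master frame

Chains are grouped at **95% sequence identity**, loose enough to absorb
construct-boundary differences, expression tags and a few point
mutations, while still meaning "the same protein". Identity is the number
of identical aligned residues divided by the *shorter* sequence length,
with `X` never counting as a match (unknown residues should not inflate
identity), computed from an optimal global alignment with free end gaps
(match +1, mismatch 0, gap open 5 / extend 0.5 subtracted). Free end gaps
and the short-sequence denominator mean a tagged construct and its
untagged twin score identity 1 — exactly the behaviour wanted here.

Clustering is greedy and longest-first: chains sorted by decreasing
length (ties by id) either join the first existing cluster, in creation
order, whose *founding* member they match at threshold, or found a new
cluster. This mirrors the scheme of standard greedy incremental
clusterers; it is order-independent (because of the internal sort) and
deterministic. Every chain instance is a distinct member — two copies of
a chain in one deposition are two conformational samples.

Each cluster's *master* is its longest member, ties broken by resolved
count, then lexicographically. The master–slave alignment (msMSA) aligns
every member to the master and is then *corrected for disorder*: aligned
pairs where either residue is unresolved are removed, because no
coordinate comparison is possible there. The msMSA is the coordinate
frame for every downstream per-residue quantity. Clusters need more than
3 members to be analyzable; flexibility statistics on 2 or 3 conformers
are dominated by chance.

# Superposition

Pairwise Cα RMSD uses the Kabsch algorithm: SVD of the cross-covariance
of the centered aligned coordinates, with the determinant correction that
flips the smallest singular direction when the optimal orthogonal map
would be a reflection. Proper rotations only — a protein and its mirror
image are different molecules. Pairs with fewer than 3 usable aligned
residues are ill-posed and reported as undefined rather than raising an
error; undefined pairs are excluded from cluster averages and from the
most-dissimilar-pair argmax. No outlier trimming is applied: the RMSD is
over all aligned resolved residues, so global and local measures stay
consistent with each other.

# Local flexibility profiles

For each member, every window of 10 consecutive master positions that is
fully aligned and fully resolved in both chains is superposed *by
itself*, and the window RMSD is recorded; a position's track value is the
mean over all complete windows containing it, and the cluster profile is
the mean over members with a defined value.

The per-window local fit is the central interpretive decision in the
package. The alternative — residuals in a single global superposition
frame — conflates rigid-body domain motion with local deformation: after
a 60° hinge bend, every residue of the moved domain has a large global
residual although the domain is internally rigid. The per-window fit
makes the profile measure *local structural change*; on a hinge fixture
the track is ≈0 inside both domains and peaks only in hinge-spanning
windows (this is asserted in the test suite). Both frames remain
available (`frame = "local"` / `"global"`), defaulting to local.

Averaging window RMSDs over all covering windows (rather than assigning
each window to its center) keeps the profile defined at the termini and
smooth, with no extra parameters. The 10-residue default window is short
enough to localize loop motions and long enough that the window
superposition is well-conditioned; it is configurable (`window`, minimum
3).

# Difference distance maps and contact map overlap

The DDM, `values[i,j] = d_A(i,j) − d_B(i,j)` over aligned resolved
positions, is superposition-free because internal distances are rigid
invariants; its block structure reads directly as rigid units
(near-zero blocks) and their rearrangement (signed off-diagonal blocks).
It is exactly antisymmetric under argument swap.

Contact map overlap is the Dice-type symmetric fraction
`2|C_A ∩ C_B| / (|C_A| + |C_B|)` with contacts at Cα–Cα distance ≤ 8 Å
and sequence separation ≥ 3 in master-frame indexing. The 8 Å cutoff is
the common Cα contact convention; separation < 3 pairs are excluded
because they are in contact in any conformation and would inflate the
overlap. When both contact sets are empty the overlap is defined as 1
(two structures with no contacts agree about all of them). All three
knobs are exposed in `contact_config()`.

Clusters are classified from their maximum pairwise RMSD: `rigid` below
0.5 Å, `flexible` above 3 Å, `intermediate` between. The boundaries are
placed at the tails of the empirical distribution of cluster maxima in
large-scale structure collections, where a quarter of clusters fall below
0.5 Å and roughly 15% above 3 Å; both are arguments of
`classify_flexibility()`.

# The conformational landscape

The RMSD matrix is embedded in 2D by classical (Torgerson) scaling —
double-center −D²/2, top two eigenpairs, eigenvector scaling by the root
eigenvalues — delegated to `stats::cmdscale`, which implements exactly
this. Classical scaling was chosen over iterative stress majorization
because it is deterministic and seed-free, which makes the landscape
reproducible byte-for-byte. RMSD matrices need not be Euclidean: negative
eigenvalues are clamped to zero and the information loss is reported as a
normalized stress, `sqrt(Σ(d−d̂)² / Σd²)`. Axis signs are fixed so the
largest-magnitude coordinate on each axis is positive (eigenvectors are
otherwise sign-ambiguous).

Sub-clusters are detected with flat-kernel **mean shift** on the
embedding: each point iterates to the mean of the original points within
`bandwidth` of it until displacement < 1e-6 or 300 iterations; converged
positions within half a bandwidth merge (single linkage, which is
permutation-invariant) into modes; members are labelled by nearest mode
and each mode's representative is the member closest to it (ties to the
smaller id). Mode seeking was chosen precisely because the number of
conformational states is the question, not an input. The default
bandwidth is the 0.30 quantile of the pairwise embedding distances — a
scale-free rule that adapts to tight and diverse clusters alike; any
fixed bandwidth in embedding units (≈ Å) can be supplied instead.
Mean shift runs in embedding space, after the projection, so its result
is consistent with what the 2D landscape shows.

# Distance-geometry morphing

The morph between conformers A and B interpolates their *internal
geometry*, not their coordinates. For each fraction `t` the target
distance matrix `D_t = (1−t) d_A + t d_B` over the aligned resolved
positions becomes a set of harmonic restraints, and the frame is obtained
by minimizing

```
E = w_dm   Σ_{aligned i<j}  (‖x_i − x_j‖ − D_t(i,j))²
  + w_bond Σ_{consecutive}  (‖x_i − x_{i+1}‖ − 3.8)²
  + w_rep  Σ_{|i−j|≥2, ‖x_i−x_j‖<4} (4 − ‖x_i − x_j‖)²
```

starting from the previous frame (warm start, which makes the trajectory
continuous). Frame 0 is the input structure verbatim. Unaligned resolved
residues carry only the bond and repulsion terms, so flanks and
unmatched loops travel with the chain without being pulled to any
target. Because within-rigid-region target distances are identical in
`d_A` and `d_B`, their restraints are constant along the whole path —
rigid regions stay internally rigid by construction, which is the
property that distinguishes this morph from naive Cartesian blending.

Defaults: `w_dm = 1`, `w_bond = 10`, `w_rep = 10` (geometry terms an
order of magnitude stiffer than the restraints, so protein-like geometry
wins local conflicts), bond length 3.8 Å (trans-peptide Cα–Cα), repulsion
onset 4 Å (coarse-grained Cα excluded volume), 11 frames
(`t = 0, 0.1, …, 1`). All are engineering choices exposed in
`morph_config()`. `dm_pair_cutoff` can sparsify the restraints for very
large chains; the default restrains every aligned pair.

The minimizer is gradient descent with Barzilai–Borwein step proposals
and Armijo backtracking. This was authored in-package rather than
delegated to a generic optimizer for two reasons: the energy gradient is
cheap and exact (it is verified against central finite differences at
relative 1e-5 in the tests), and backtracking guarantees a monotone
non-increasing energy trace, a property the test suite asserts directly
and that black-box quasi-Newton wrappers do not expose. Convergence is
declared at RMS gradient < 1e-4 Å per step, capped at 2000 iterations per
frame. A non-finite energy aborts with the iteration index.

**What the residual means.** A convex combination of two distance
matrices is in general not realizable by any 3D point set, so mid-path
frames have an irreducible deviation between their distances and `D_t`,
reported per frame as the maximum absolute restrained-pair deviation. In
a convergence study on the two-domain hinge fixture the halfway residual
grows with hinge amplitude — about 0.11 Å at a 20° hinge, 0.19 Å at 30°,
0.41 Å at 45°, 0.66 Å at 60° — while the *end* frames recover the true
structures to well under 0.5 Å RMSD even for 60° morphs. The residual is
a property of linear DM interpolation, not of the minimizer; tests that
assert near-zero residuals or strict rigid-domain preservation therefore
use moderate amplitudes (≤ 30°) where the interpolated matrices are
near-embeddable, and end-state recovery is asserted at 60°.

# The synthetic ensemble generator

`make_hinge_conformer()` builds the canonical hard case for flexibility
analysis: a two-domain protein with a clean hinge. Each domain is an
ideal helical Cα trace (angular step 100°, radius 2.3 Å, rise chosen so
consecutive Cα distances are *exactly* 3.8 Å), and the second domain is
rigidly rotated about the tangential axis through the hinge residue,
tilting radially outward — a direction chosen so the two arms never sweep
through each other across the full useful angle range (geometrically
impossible angles raise an error rather than returning a clashed
structure). Gaussian coordinate noise emulates experimental variation;
all randomness flows through an explicit seed and the caller's RNG state
is untouched. `make_cluster_fixture()` derives per-member seeds from one
base seed and can mask residue ranges as unresolved to exercise disorder
handling.

What the generator does *not* emulate: realistic protein topology
(β-sheets, irregular loops), sequence diversity within a cluster
(members share one sequence), correlated or anisotropic coordinate
error, crystal-packing artifacts, and partial-occupancy disorder.
Passing tests on these fixtures therefore demonstrate the correctness of
the computations — filters, alignment bookkeeping, superposition
optimality, profile localization, sub-cluster recovery, morph
convergence — under known ground truth; they do not demonstrate
biological insight on real depositions, which is what the `fetch`-based
worked example in the README is for.

The test-suite study conditions use ensembles of six conformers at hinge
angles {0°, 5°, 10°} and {60°, 65°, 70°} with 0.3 Å noise — two states,
three samples each, noise well below the between-state signal —
and planted 2D blobs (50 + 50 points, σ = 0.5, centers 10 apart,
bandwidth 2) for mean-shift recovery. Problem sizes throughout the tests
(domains of 12–30 residues, 3–11 morph frames) are chosen so the full
suite exercises every code path in well under a minute of numerical work
per module.

# Numerical and degenerate-case decisions

* Superposition of < 3 points or a collinear point set errors by name;
  RMSD between chains with < 3 usable aligned pairs is `NA` (undefined),
  not an error, so one fragmentary member cannot abort a cluster.
* Mean shift with a zero automatic bandwidth (all points coincident)
  returns a single sub-cluster.
* MDS of an all-zero matrix returns all-origin coordinates with zero
  stress; `cmdscale`'s dropped zero-eigenvalue columns are padded back.
* Representative and argmax ties break lexicographically by member id;
  mode numbering is by decreasing sub-cluster size. Everything in the
  pipeline is deterministic for fixed inputs, which the manifest test
  (byte-identical reruns) pins down.
* The repulsion term uses distance, not distance squared, inside the
  penalty; its gradient vanishes smoothly at the 4 Å onset, so the
  energy is C¹ everywhere except exact point coincidence, guarded at
  1e-9 Å.

# Known limitations

* Sequence-identity clustering with a single founding representative can
  split a protein family if the founder is an outlier construct; the
  best-matching-cluster alternative was rejected to keep parity with the
  standard greedy tools' auditable behaviour.
* The ATOM→SEQRES placement is sequence-based when author numbering is
  unusable, and sequence-based placement is ambiguous at repeated
  residues flanking a disorder gap.
* CMO and the classification boundaries are convention choices; both are
  config-exposed rather than fitted.
* Morph intermediates are physically plausible (connectivity, excluded
  volume, rigid regions) but are not minimum-free-energy paths; the
  method makes no kinetic claims.
* mmCIF input, all-atom morphing, and ligand annotation are out of
  scope.
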