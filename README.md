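# flexkit

Quantifying conformational flexibility of proteins from redundant
structure depositions.

Most well-studied proteins have been solved by X-ray crystallography many
times — different crystal forms, different ligands, apo and holo states.
The coordinate differences between those independent depositions are not
noise: they trace hinge motions between functional states, mobile loops
near binding sites, and regions that flicker between order and disorder.
flexkit turns a directory of PDB files into a quantitative flexibility
report for each protein it finds, for structural biologists and protein
modelers who need to know *which parts* of a protein move and *between
which states*.

## What it computes

Given a set of chains, flexkit:

1. **Ingests and filters** chains (kept iff >25 SEQRES residues, no run of
   unknown residues longer than 20, >25 resolved Cα atoms), treating the
   SEQRES sequence as the indexing frame so unresolved (disordered)
   residues are first-class data.
2. **Clusters sequences at 95% identity** (greedy, longest-first, against
   each cluster's founding representative), selects the longest, most
   complete member as *master*, and builds a master–slave multiple
   alignment corrected for unresolved residues. Clusters need more than 3
   members to be analyzed.
3. **Global flexibility** — all-vs-all Cα RMSD by Kabsch superposition
   over the aligned resolved residues:

   RMSD = min over rotations R (det R = +1) and translations t of
   sqrt( (1/n) Σᵢ ‖R aᵢ + t − bᵢ‖² )

   The matrix is embedded in 2D by classical multidimensional scaling and
   sub-clusters of conformers (e.g. "open" vs "closed") are detected by
   flat-kernel mean shift, so the number of conformational states emerges
   from the data rather than from a tree-cut threshold.
4. **Local flexibility** — for every 10-residue window fully aligned and
   resolved in master and member, the window alone is superposed and its
   RMSD recorded; per-position averages across windows and members give a
   flexibility profile whose peaks are mobile loops and hinges, cleanly
   separated from rigid-body domain motion.
5. **Comparators** — difference distance maps,
   DDMᵢⱼ = d_A(i,j) − d_B(i,j), superposition-free by construction, and
   contact map overlap, CMO = 2|C_A ∩ C_B| / (|C_A| + |C_B|) with
   contacts at Cα distance ≤ 8 Å and sequence separation ≥ 3. Clusters
   are classified `rigid` (max RMSD < 0.5 Å), `flexible` (> 3 Å) or
   `intermediate`.
6. **Morphing** — physically plausible trajectories between two
   conformers: target distance matrices are linearly interpolated,
   D_t = (1−t) d_A + t d_B, and each frame is reconstructed by minimizing

   E = w_dm Σ(‖xᵢ−xⱼ‖ − D_t(i,j))² + w_bond Σ(‖xᵢ−xᵢ₊₁‖ − 3.8)²
       + w_rep Σ_clash (4 − ‖xᵢ−xⱼ‖)²

   with a monotone backtracking gradient minimizer, so intermediates keep
   protein-like backbone geometry and rigid regions stay internally rigid
   — unlike straight Cartesian interpolation.

A deterministic synthetic-structure generator (`make_hinge_conformer`,
`make_cluster_fixture`) produces two-domain hinge ensembles with known
ground truth, so the entire pipeline is testable offline.

## Worked example

A six-member ensemble of a two-domain protein, three conformers near the
closed state (hinge angles 0°, 5°, 10°) and three near the open state
(60°, 65°, 70°), with 0.3 Å coordinate noise:

```r
library(flexkit)

ensemble <- make_cluster_fixture(angles = c(0, 5, 10, 60, 65, 70),
                                 n_res = 25, noise_sigma = 0.3, seed = 42)
cluster <- build_msmsa(cluster_chains(ensemble)[[1]])

rmsd <- pairwise_rmsd_matrix(cluster)
summarize_cluster(cluster, rmsd)
#> <cluster_summary> 6 members, master hg01A: avg RMSD 3.80 A, max 6.59 A
#>   (hg01A vs hg06A), avg CMO 0.932, min CMO 0.913 -> flexible

subclusters <- mean_shift(embed_mds(rmsd))
subclusters
#> <sub_clustering> 2 sub-cluster(s) (bandwidth 1.09): sizes 3, 3
subclusters$representatives
#> [1] "hg02A" "hg05A"

profile <- average_profile(cluster)
profile
#> <flexibility_profile> master hg01A, 50 positions (50 defined),
#>   mean 0.75 A, peak 1.07 A
which.max(profile$mean_local_rmsd)
#> [1] 26

morph <- generate_morph(cluster$members[["hg01A"]],
                        cluster$members[["hg06A"]])
morph
#> <morph_trajectory> hg01A -> hg06A: 11 frames over 50 residues
#>   (50 restrained); max DM residual 0.901 A
write_morph_pdb(morph, "morph.pdb")   # animation for any molecular viewer
```

Reading the output: the ensemble is one cluster of six chains whose most
dissimilar pair differs by 6.59 Å — `flexible` territory. Mean shift on
the 2D embedding finds exactly the two planted conformational states
(3 + 3). The local flexibility profile peaks at master position 26, next
to the planted hinge (residue 25): local deformation concentrates in the
hinge windows while both domains stay near 0. The morph interpolates
between the most dissimilar conformers; the reported residual is the
worst deviation of any restrained pair distance from its interpolated
target, reflecting that a linearly interpolated distance matrix is not
exactly realizable in 3D mid-path.

The same pipeline runs from the shell via the bundled CLI:

```sh
FK=$(Rscript -e 'cat(system.file("cli", "flexkit.R", package = "flexkit"))')
Rscript $FK fixtures --angles 0,5,10,60,65,70 --n-res 25 --noise 0.3 --out-dir fx
Rscript $FK run fx/*.pdb --out-dir bundle
```

which writes per-cluster `rmsd.csv`, `profile.json`, `ddm.tsv`,
`summary.json`, `landscape.json`, `morph.pdb` and a checksummed
`manifest.json`. With network access, `fetch` downloads real entries
(e.g. the D-galactose-binding periplasmic protein pair
`fetch 2QW1 2HPH`) for the same analysis.

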