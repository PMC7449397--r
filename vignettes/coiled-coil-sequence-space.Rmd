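---
title: "Coiled coil sequence space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coiled coil sequence space: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccspace)
```

## The problem

LINE-1 (L1) retrotransposons replicate through successive families: each
family amplifies to hundreds or thousands of genomic copies, goes extinct,
and is succeeded by the next. The copies are dead on arrival and decay
neutrally, so the genome holds a fossil record of each family's protein
repertoire. The N-terminal coiled coil of ORF1p — fourteen heptads with a
three-residue stammer — is the hypervariable part of that record, and the
question this package addresses is how its *sequence space* is structured:
does each family carry one coiled coil, or several related, coexisting
variants ("clusters"), and how do those variants persist across families?

Two obstacles stand between an alignment of fossil copies and that
question, and they shape the whole pipeline:

1. **Post-insertion CpG decay.** Methylated CG dinucleotides mutate to TG
   (or CA via the complementary strand) at a strongly elevated rate. A
   column of decayed copies therefore shows amino acid "variation" that
   arose after insertion and says nothing about the protein the family
   actually replicated with.
2. **The signal of interest is a column pattern, not a copy pattern.**
   Each copy is an independent noisy draw from its lineage founder; the
   founder is recovered by thresholded consensus, and lineage structure by
   ordination and clustering of the copies.

## CG-null translation and CG restoration

A codon is **CG-affected** when it matches `CGN` or `NCG`, or when it
flanks a cross-codon `C|G` junction (`NNC·GNN`). `cg_null_translate()`
replaces such residues with the null character `"O"`, which every
downstream stage treats as missing data. Two choices here were genuinely
open:

* **Junction masking (both sides).** In an `NNC·GNN` junction the C is
  mutable by C→T and the G by G→A, so either flanking residue can carry
  decay noise. The default masks both (`junction_mask = "both"`); `"left"`
  and `"right"` are available for compatibility with single-sided
  conventions.
* **Column-level masking for family analysis.** An individual decayed copy
  no longer matches any CG pattern at the very position that decay
  corrupted, so per-copy masking leaves the decay products unmasked.
  `cg_null_translate_alignment()` therefore (by default,
  `per = "column"`) locates CG-affected codons in the *CG-restored family
  consensus* and nulls those columns in every record. This removes decay
  noise completely at planted CpG columns — per-record masking
  (`per = "record"`) is retained for single-sequence work.

**CG restoration** rebuilds the ancestral nucleotide consensus:
`nt_consensus()` takes the per-column plurality, then rewrites any adjacent
position pair to CG when the column is populated by the CG form *and* a
decay product (TG or CA), regardless of plurality. All three dinucleotide
frames are considered (codon positions 1–2, 2–3, and the junction),
symmetric with the masking rule.

The CG-presence threshold `min_cg` defaults to **2 observations**. One
observation is not used, for an analytic reason: in an alignment of `n`
neutrally decaying copies, every founder TG site accumulates chance `T→C`
back-mutations at rate `n × p/3` (with `p` the per-site background
substitution probability), so with hundreds of copies a single CG
observation next to abundant TG is more likely to be background noise than
a decayed ancestral CpG, and "restoring" it corrupts the consensus. Two
independent hits at the same site are rare at realistic `n` and `p`,
while genuine CpG columns clear the threshold whenever restoration is
actually needed (if nearly all copies retain CG, plurality already gives
CG without the rule firing). The historical resolution of such rare
ambiguities was manual comparison against sibling-family consensuses; this
package uses the threshold instead and keeps it configurable.

## Threshold consensus

`threshold_consensus()` emits, per column, the most frequent standard
residue if its frequency reaches the threshold (default 0.5; 0.6 mirrors
the stricter consensus used for ancestral resuscitation), else `"X"`.
Conventions, chosen for determinism and consistency with missing-data
semantics:

* the denominator excludes `"-"`, `"O"` and `"X"` (they are missing data);
* a column is emitted as `"-"` or `"O"` only when that character is the
  absolute majority of all rows;
* ties at exactly the threshold pass (`>=`); a tie between two equally
  frequent winners yields `"X"`.

`consensus_pair()` produces the CG-null consensus (`_o` suffix, e.g.
`cL3.5_o`) and the CG-restored consensus (`rt` suffix, e.g. `3.5rt`) in
which each `"O"` is replaced by the translation of the restored
nucleotide-consensus codon.

## Sequence space: one-hot PCA and metric MDS

`one_hot_encode()` maps each residue to a unique 20-bit vector; gap, `"O"`
and `"X"` encode as all-zero blocks, so missing data falls to the block
centroid after centering rather than becoming a 21st state. Two sequences
differing at `d` fully observed positions sit at squared Euclidean distance
`2d`, which ties the PCA geometry to Hamming distance (asserted in the test
suite). `fit_pca()` is a mean-centered SVD with **no column scaling** —
scaling binary indicator columns would inflate rare-residue noise — and a
deterministic sign convention (largest-magnitude loading positive). The
default `k = 3` matches the three-dimensional view used for global
sequence-space figures. `project_into_space()` is affine, so engineered
variants can be mapped into the space of the natural families.

`pairwise_difference()` counts differing columns over pairwise-complete
standard residues (`scale = "count"` by default, matching raw difference
matrices; `"proportion"` for unequal coverage) and records co-observed
column counts so low-overlap pairs (fewer than `min_overlap = 20`
comparable columns) can be flagged. `classical_mds()` double-centers the
squared distances (`B = -J D² J / 2`), eigendecomposes, and keeps the top
positive-eigenvalue axes scaled by the square roots of their eigenvalues;
negative-eigenvalue mass is reported. Supplementary points use Gower's
formula,

```
x_new = 1/2 · Λ⁻¹ · Xᵀ · (diag(B) − d²),
```

which reproduces training coordinates exactly — the package asserts this
to 1e-8.

## Cluster retrieval

`kmeans_cluster()` runs best-of-25 multi-start K-means (`stats::kmeans`)
on the MDS coordinates under a fixed seed; multi-start random
initialization was used in place of k-means++ (not available in
`stats::kmeans`) — the contract, determinism given a seed, is unchanged.
Clusters are renumbered by decreasing size (ties by centroid lexicographic
order) and tagged `cLn.n`, cluster number followed by family number.

No cluster-count rule is inherited from prior work, so `select_k()` makes
the choice explicit: it maximizes the mean silhouette width over
`k_range = 2:8` and retains the whole score table, flagging weak optima
(best silhouette below 0.25). Users can pin `K` per family instead.

`greedy_identity_cluster()` implements dereplication-style greedy centroid
clustering (first-fit in input order, identity over comparable columns) for
probing near-identical sub-clusters at `id = 1.00`. Input order, not
abundance order, is deliberate: the use case is detecting *any* split, and
the test suite verifies order-invariance of the cluster count on separated
data.

## Trees

`nj_tree()` applies neighbor joining (via `ape`) to difference matrices of
CG-null cluster consensuses, so CG-affected positions count as missing
data rather than divergence. Maximum-likelihood inference and bootstrap
support are deliberately out of scope; `write_phylip()` /
`write_alignment()` export the consensus alignment for external ML tools.
NJ recovers additive matrices exactly (tested on random 6–10-leaf trees),
which is sufficient for the simulation-scale questions here, e.g. whether
consensuses sharing a persistent founder lineage are placed as neighbors.

## The simulator

`simulate_family_series()` is the ground-truth generator for every stage.
Its defaults are the package's statement of the study conditions, chosen
once:

| parameter | default | rationale |
|---|---|---|
| `protein_length` | 101 codons | a 14-heptad coiled coil with stammer |
| `lineages_per_family` | 3 | families carry 2–5 coexisting clusters |
| `copies_per_lineage` | 50 | hundreds of copies per family (n = 150) |
| `lineage_divergence` | 14 | founders ~86% identical, clusters distinct but related |
| `master_sub_rate` | 0.02/codon/step | detectable family-to-family drift |
| `neutral_rate` | 0.008/site/age | copies a few % diverged from their founder |
| `cpg_rate_multiplier` | 10 | strongly elevated CpG decay |
| `decay_time_scale` | 1 | older families decay longer (age = rank) |
| `lineage_persistence` | 0 | persistence is enabled per experiment |

Copies decay neutrally: planted CpG dinucleotides mutate only through the
deamination channel at `cpg_rate_multiplier × neutral_rate`, to TG or CA
with equal probability, so a CpG survives as CG with probability
`exp(-neutral_rate · multiplier · age)` — an analytic expectation the
tests check against binomial confidence intervals. Background sites mutate
uniformly. The master and founders pass a weak purifying filter (no
stops); dead copies do not, and internal stops translate to `"X"` with a
warning rather than aborting.

What the simulator does *not* emulate: indels and alignment error (copies
are aligned by construction; an alignment is an input contract, not a
product, of this package), 5′ truncation and target-site duplications,
selection on dead copies, strand-asymmetric background mutation, and
context effects beyond CpG. Passing tests therefore demonstrate that the
machinery is correct under clean alignments with CpG-dominated decay; they
do not certify robustness to alignment artifacts in genome-derived data.

## The synthetic ORF1p reference system

The difference-accounting operations are exercised against a packaged
**synthetic** modern/ancestral ORF1p parent pair
(`inst/extdata/synthetic_orf1_*`), constructed — not taken from any genome
— to carry the documented difference structure of the modern-vs-ancestral
mosaic study design: 42 differences in 338 residues, 30 inside the coiled
coil, a 21/9 split across the mosaic region boundary, the negatively
epistatic quartet at 105/107/108/111, the epistatic I77L site, 4
N-terminal-domain and 8 C-terminal differences. Since no full-protein
coordinate for the coil is printed anywhere in the source material, the
fixture places it at residues 46–146; this is the unique-up-to-small-shifts
choice under which the quartet falls in heptads 8–9 while the 21
restitution sites and residue 77 fall in heptads 1–8, and position 134 lies
inside the coil. Tests assert those memberships rather than the raw
coordinates. Variant activities follow the assay classification: ≥80% of
the modern reference is *active*, <5% *inactive*, and the open interval
in between is reported as *intermediate* rather than forced into either
class.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; `run_pipeline()` echoes its
config and seed into an immutable run directory, and reruns are
byte-identical. The shipped test and acceptance workloads use desk-scale
problem sizes chosen as the package's own defaults: 20 simulation
replicates of one 150-copy family for cluster recovery, 150–200 copies for
CpG calibration checks, 50 random 6–10-leaf trees for NJ, and exactness
tolerances of 1e-8 for MDS reconstruction and supplementary projection.

## Known limitations

* CG restoration with the permissive "CG plus one decay product" rule can
  still, rarely, reinstate a spurious CG at deep coverage; `min_cg` should
  be raised for families with thousands of copies.
* Greedy identity clustering is order-dependent for overlapping clusters
  (by design, mirroring first-fit dereplication); only its cluster count
  on separated data is order-invariant.
* `classical_mds()` drops negative-eigenvalue mass; for strongly
  non-Euclidean matrices (heavy missing-data patterns) the reported mass
  fraction should be checked before interpreting distances.
* Heptad annotation is an input contract; no coiled coil prediction is
  performed.
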