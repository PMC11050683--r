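---
title: "Essential dynamics of the FGFR2 kinase domain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential dynamics of the FGFR2 kinase domain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfr2dyn)
```

## The problem

The tyrosine kinase domain of FGFR2 (FGFR2-TKD) switches between an
inactive, unphosphorylated conformation and an active, phosphorylated one;
the activation loop (residues 643--664) is the main moving part, and an
autoinhibitory "molecular brake" around the kinase hinge (N549, E565,
K641) holds the inactive state in place. Most disease-associated FGFR2
mutations are missense changes that relieve this brake and shift the
population balance toward active conformations — the conformational
selection view: mutations re-weight pre-existing conformations rather than
inventing new ones.

Because many crystal structures of FGFR2-TKD exist — wildtype and mutant,
active and inactive — the deposited ensemble itself samples the domain's
conformational space. This package treats that ensemble as data: it
extracts the collective motions that distinguish the structures, maps them
onto functional regions, embeds the structures in two dimensions for
annotation with activation state and disease class, and places modeled
variant structures into the same space.

## From PDB files to an ensemble matrix

Each chain is reduced to its C-alpha trace (one 3-vector per residue, in
author numbering, assumed to match UniProt P21802 positions). Chains
missing any residue of the curated functional regions — nucleotide-binding
loop 480--490, alpha-C helix 525--539, gatekeeper 564, hinge and vicinity
549/565/566--571, kinase insert 579--599, catalytic pocket 620--630,
alpha-C tether 650, activation loop 643--649/651--664 — are removed
(`curate_chains()`); a chain with a disordered activation loop cannot
inform activation-loop dynamics. The retained traces are restricted to the
residues common to *all* of them (set intersection, ascending) and
flattened into an $n \times 3R$ matrix, one structure per row
(`build_ensemble()`).

Choices worth stating:

* **Intersection, not a fixed range.** How the common residue set should
  be formed is a genuinely open choice; intersection is the only option
  that guarantees every retained chain contributes every column, and the
  curation step already ensures the functionally important residues
  survive it.
* **Altloc and model handling.** Alternate conformers resolve to the
  highest-occupancy copy (ties to the lexicographically first altloc id);
  multi-model files contribute model 1 only; modified residues with a CA
  are kept. Residue identity includes the insertion code.
* **Equal weights.** All chains of a multi-chain entry enter the analysis
  with equal weight; nothing in the data supports a per-entry reweighting.

## Superposition

Crystallographic poses are arbitrary, so every row is superposed onto a
reference trace by the Kabsch algorithm (`kabsch()`,
`align_ensemble()`): the SVD-based proper rotation plus translation that
minimizes RMSD, with reflections corrected through the sign attached to
the smallest singular value. The default reference is chain A of 1GJO,
the best-resolved genuinely autoinhibited wildtype structure (the entry
fixes the conformational state; the chain choice within it is ours, as
deposition order). Alignment is a single pass onto the reference — no
iterative mean-structure refinement — because one fixed, interpretable
frame is wanted for projection of new structures later. Degenerate point
sets (coincident or collinear) make the rotation underdetermined and are
an explicit error.

`rmsd_direct()` deliberately does *not* re-superpose: reconstruction
errors (below) are measured in the common aligned frame, where
re-superposition would conflate alignment quality with reconstruction
fidelity.

## Essential dynamics (PCA)

`essential_dynamics()` centers the aligned matrix on the average trace
and takes its SVD, $X = U \Sigma V^{T}$. The rows of $V^{T}$ are the
principal components — collective displacement fields over the structure —
and component $i$ captures the fraction $\sigma_i^2 / \sum_j \sigma_j^2$
of the total structural variance. A trace $S$ projects as
$P = (S - \bar S)\,V$ and reconstructs as $S = P\,V^{T} + \bar S$; both
operations apply out-of-sample, which is how modeled variant structures
are placed into the fitted space (`place_variant()`) without refitting.

Numerical conventions:

* **Sign convention.** SVD signs are arbitrary; each component is flipped
  so its largest-magnitude loading is positive (ties to the lowest
  index), and the classical-MDS axes follow the same rule, so regression
  tests and cross-method comparisons are deterministic.
* **Rank.** At most $\min(n-1, 3R)$ components are kept (a centered
  matrix has rank at most $n-1$). A zero-variance ensemble yields a zero
  spectrum with a warning, not an error.
* **Variance fractions** are computed from squared singular values and
  are scale-free; no $1/(n-1)$ convention enters.
* **Displacement profiles** (`displacement_profile()`) report, per
  residue, the norm of the residue's $(x,y,z)$ loading triplet within the
  unit-norm component: the *shape* of the mode. An optional flag scales
  by the singular value for amplitude-weighted profiles; shapes are the
  default because region attribution should not depend on overall mode
  amplitude.
* **Degenerate eigenvalue ties** leave the spanning subspace well defined
  but the individual axes rotation-ambiguous; direction-recovery tests
  therefore use well-separated planted spectra.

Reconstruction-error curves (`reconstruction_error()`) report, per trace
and per $m$, the RMSD between the original trace and its reconstruction
from the leading $m$ projection coordinates; nested subspaces make each
curve non-increasing, and full rank reconstructs exactly.

## Isomap

`isomap()` composes a union-symmetrized $k$-nearest-neighbor graph on
Euclidean distances (default $k = 8$, standard Isomap practice at this
ensemble size), all-pairs shortest paths (Dijkstra), and classical MDS
(double-centering $-\tfrac12 J D^2 J$, eigendecomposition, coordinates
$v\sqrt{\lambda}$). Three deliberate decisions:

* **Disconnection is an error**, never a silent largest-component
  fallback: every trace must keep its place in the labeled embeddings,
  and a disconnected graph means $k$ is too small for the data.
* **No out-of-sample extension.** A new structure cannot be placed into
  a geodesic embedding without rebuilding the graph; variant placement is
  therefore PCA-only.
* **Graph geodesics overestimate.** For non-adjacent pairs the
  shortest-path length strictly exceeds the straight-line distance unless
  the straight line is itself a graph path; even perfectly flat
  (plane-sampled) data is reproduced exactly only when the graph contains
  those straight paths (complete graph, or ordered sampling along a
  curve). The tests exercise exactness where it genuinely holds and treat
  sparse-graph embeddings as approximations, judged by residual variance
  (`residual_variance()`).

## Annotation

The bundled tables (`fgfr2_regions()`, `fgfr2_structures()`,
`fgfr2_diseases()`, `fgfr2_pathogenicity()`) are verbatim transcriptions
of the curated study data: functional regions, the 29-entry structure set
with activation states, mutations and removal notes, variant-to-disease
records, and 16 pathogenicity calls. Two source conflicts are preserved
rather than resolved: the region table's hinge row (which includes 549
and 565) is authoritative for `assign_region()`, while the structure
table's literature region strings (e.g. "Kinase Insert" for N549
mutants) are stored verbatim as display labels; and 3B2T is recorded
"Active" although the A628T mutation is described in the literature as
reducing catalytic activity. `pathogenicity_hits()` counts a record as a
hit when it is called likely pathogenic *and* a disease association is
documented — 14 of the 16 bundled records, i.e. 87.5%.

## The synthetic generator

`generate_ensemble()` builds ensembles with known ground truth:
`trace`$_i$ = base + $\sum_k c_{ik}\,$mode$_k$ + noise, optionally posed
by random rigid motions. It emulates exactly the statistical structure the
essential-dynamics model assumes — a mean structure, a few orthonormal
collective modes with Gaussian coefficients, isotropic Gaussian
coordinate noise, arbitrary poses — which is what makes every recovery
test sharp: planted spectra, mode directions, localized-mode windows and
pose invariance all have analytic expectations.

Defaults are fixed at study scale and not revisited: 52 traces of 263
residues (the curated ensemble's dimensions), three modes with
amplitudes 3, 1.2 and 0.8 Å (a dominant activation-loop-like motion plus
two weaker modes, comparable to the spread seen across kinase crystal
forms), coordinate noise 0.1 Å (crystallographic-precision scale), pose
jitter on. The base trace is a helix-like parametric curve with 3.8 Å
consecutive-CA spacing — geometrically realistic for viewers, though the
math nowhere requires it. All randomness flows through R's
Mersenne-Twister from a caller-supplied seed, with the caller's RNG state
restored.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: real ensembles violate Gaussianity (discrete
conformational clusters, not one ellipsoid), have position-dependent
noise (flexible loops are less well determined), and carry batch effects
between laboratories and space groups. Synthetic recovery demonstrates
the estimator is correct, not that three modes suffice for FGFR2.

## Problem sizes and budgets

The test suite runs on generated ensembles of 6--40 traces and 8--100
residues (200 traces for the spectrum-recovery repetitions, 500 for the
flat-spectrum bound), sizes at which the independent oracles — quaternion
superposition, covariance eigendecomposition, Floyd–Warshall, Procrustes
— are exact and fast. The acceptance script re-runs the full pipeline at
the study scale of 52 × 263. The real-data reproduction additionally
requires the 29 PDB entries on disk (see the README); the package never
downloads them itself.

## Known limitations

* Author residue numbering is assumed to match UniProt positions; a
  per-entry offset override is the escape hatch when it does not.
* The analysis is blind to side chains, by construction; mutations whose
  effect is purely side-chain-local are invisible to CA-trace dynamics.
* With $n = 52$ structures in ~800 dimensions, variance fractions carry
  substantial sampling spread; printed percentages are reported to two
  decimals to match convention, not as a claim of that precision.
* Isomap embeddings depend on $k$; the package treats disconnection as
  the user's signal to raise it, and makes no attempt to select $k$
  automatically.
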