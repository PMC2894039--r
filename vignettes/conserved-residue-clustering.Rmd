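---
title: "Measuring the spatial clustering of conserved residues in protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the spatial clustering of conserved residues in protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiclust)
```

## The question and the statistic

Residues that matter for a protein-protein interaction tend to be conserved
by evolution, and functionally coupled residues tend to sit close together
in space. `ppiclust` asks a quantitative version of that observation: given
an interface and a multiple sequence alignment of homologues, are the
conserved interface residues *spatially clustered* within the interface, or
scattered across it? And can the degree of clustering, measured for every
candidate surface patch, pick out the true binding site?

The clustering of a residue set with $N_s \ge 2$ members is summarised by
the mean inverse distance over all residue pairs,

$$M_s = \frac{1}{N_{pairs}} \sum_{i<j} \frac{1}{r_{ij}}, \qquad
  N_{pairs} = \frac{N_s (N_s - 1)}{2},$$

with $r_{ij}$ the distance between residue centres of mass (heavy atoms,
mass-weighted). Because distant pairs contribute little, a few outlying
members cannot dominate the score; removing an outlier whose mean inverse
distance to the rest is below the set's $M_s$ can only raise it. $M_s$
scales as $1/c$ under uniform scaling by $c$ and is invariant under rigid
motion and permutation.

The conserved subset's clustering *relative to its context* (the whole
interface, or the whole patch) is the ratio

$$\rho = \frac{M_{s,\mathrm{cons}}}{M_{s,\mathrm{int}}},$$

which is dimensionless and scale-invariant. $\rho > 1$ means the conserved
residues are more tightly packed than the set they were drawn from.
Significance is assessed empirically: 1000 random same-size subsets of the
interface are drawn, their $M_s$ values form the null distribution, and the
reported p-value is $(1 + k)/(N + 1)$ with $k$ the number of random subsets
scoring at least the observed value. The estimator never returns 0, and for
an observed subset drawn by the same mechanism it is uniform up to
discreteness (verified by a calibration test in the suite).

## Conservation scoring

Each alignment column is scored by the Shannon entropy of amino-acid
*class* frequencies,

$$s(i) = -\sum_k p_i(k) \ln p_i(k),$$

over seven classes — (1) A,V,L,I,M,C; (2) G,S,T; (3) D,E; (4) N,Q;
(5) R,K; (6) P,F,Y,W; (7) H — so substitutions within a class carry no
penalty. Natural logarithms are used throughout; the selection criteria
below compare a column's entropy to the mean over the same set, so the base
cancels anyway. An optional relative-entropy variant scores
$\sum_k p(k)\ln(p(k)/p_{back}(k))$ against background class frequencies
(only classes observed in the column enter the sum; the background is not
renormalised over them, and larger values mean stronger constraint).
Background frequencies can be supplied as a file, or derived from a pool of
interface sequences with one pseudo-count per class so the score is always
defined.

Conserved residues are selected over a stated residue set (an interface or
a patch), with the mean $\langle s \rangle$ and standard deviation
$\sigma$ computed on that set itself:

* `mean` — $s(i) < \langle s \rangle$ (strict, per the criterion's wording);
* `mean-sd` — $s(i) < \langle s \rangle - \sigma$;
* `zero` — $s(i) = 0$ within $10^{-12}$, the fully conserved positions.

Gaps and unknown letters (`X`) are excluded from column counts; columns
with fewer than 2 usable rows (configurable) are marked undefined and never
enter conserved-set selection, which avoids spurious zero entropies from
near-empty columns. The alignment's query row is mapped onto the chain by
global sequence alignment; identity mismatches are tolerated up to 5%
(configurable) to accommodate real PDB/MSA pairs, and columns whose
residues are missing from the coordinates are dropped with a warning.

## Interface and surface definitions

A residue belongs to the interface if it loses more than 0.1 Å² of
solvent-accessible surface area when the complex forms, comparing each
chain group in isolation with the complex. The threshold is applied to the
residue-level sum of atomic differences (the residue-level choice is what
every downstream residue-set operation needs). SASA is computed by a
Shrake-Rupley scheme: each atom's solvent sphere (van der Waals radius +
1.4 Å probe) is sampled at 960 deterministic golden-spiral points, a point
being accessible when outside every other atom's solvent sphere. The point
set is fixed, so results are exactly reproducible and invariant (to within
sampling error, about 1%) under rigid motion. Hydrogens are excluded;
alternate locations keep the highest-occupancy conformer.

Surface residues are those with relative accessibility of at least 5%,
where relative accessibility divides the residue's SASA by a reference
maximal value for its type (extended Gly-X-Gly tripeptide reference,
Tien et al. 2013 theoretical values, replaceable via the
`reference` argument).

## Sub-clusters and the distance threshold

Conserved residues are partitioned into sub-clusters by agglomerative
average-linkage clustering on centre-of-mass distances, merging while the
minimum average inter-cluster distance is $\le$ the threshold (the choice
of `<=` over `<` is immaterial for continuous coordinates).
Singletons are legitimate clusters. The conventional thresholds are 21 Å
for homodimer interfaces and 15 Å for heterocomplexes; the rule behind
them — half the mean over interfaces of the maximum distance between any
two atoms of conserved residues — is exposed as
`derive_linkage_threshold()`, and note that it deliberately uses *atoms*
while the clustering itself uses residue centres.

## Surface patches and binding-site ranking

One patch is generated per surface residue, by three schemes:

1. **Fixed radius** — all surface residues whose centres lie within a fixed
   radius of the centre residue (15 Å for complexes, 22 Å for homodimers,
   half the typical maximal interface atom-pair distance of each dataset).
2. **Adaptive radius** — the radius is half the maximum atom-pair distance
   of *this* protein's interface, so patch size tracks interface size.
3. **Adaptive radius + solvent vectors** — each surface residue gets a unit
   "solvent vector": the inverse of the vector from its centre to the
   centroid of its ten nearest surface neighbours, pointing into solvent. A
   residue joins a patch only if its solvent vector is within 110° of the
   centre's, which stops patches from wrapping to the opposite face of a
   thin molecule.

Each patch is scored exactly like an interface: conserved members selected
against the patch's own entropy mean, then $\rho$. Patches with fewer than
two scored or two conserved residues receive a marker instead of a number;
they stay in the denominator of the ranking but below every numeric
$\rho$ — a patch without clustered conservation is evidence against binding
there. The true interface is scored as its own residue set, ranked by
1 + the number of patches with strictly greater $\rho$ (optimistic
tie-break, documented because the convention is not forced), binned into
deciles over all patches plus the interface, and given a z-score
$Z = (\rho_{int} - \langle\rho\rangle)/\sigma$ over the numeric patch
values, with $Z > 1.64$ the usual 95th-percentile significance line. The
best patch-versus-interface overlap
($100 \cdot |patch \cap interface| / |interface|$) is reported alongside.

## What the synthetic fixtures emulate — and what they do not

All validation runs on generated data with recorded ground truth:

* **Two-slab complexes** — two planar grids of two-bead residues (6 Å
  spacing; backbone and side-chain carbon beads). Over a designed contact
  block the chains approach to van der Waals contact (4.2 Å between facing
  beads); elsewhere they stay 25 Å apart. The geometry guarantees that
  exactly the designed residues cross the 0.1 Å² burial threshold, with a
  wide margin, so interface recovery is exact by construction.
* **Sphere-shell chains** — residues on a sphere (side chains pointing
  inward), every residue surface-exposed; a polar cap is the designated
  interface. For patch-ranking fixtures, a tight conserved blob is planted
  in the cap and background conservation is scattered at the same density
  over the rest of the surface. The scatter matters: real surfaces have
  conserved residues everywhere, and without them any patch catching a
  corner of the blob gets a tiny, ultra-tight conserved set and an inflated
  $\rho$.
* **Alignments** — the query row is the chain sequence; planted conserved
  columns are drawn within one class (entropy exactly 0); all other columns
  mix the query's class with randomly chosen other classes at proportions
  targeting a chosen entropy (default $\ln 2$), with homologue rows sampled
  stochastically so column entropies vary realistically (about ±0.1 nat at
  depth 100).
* **Hot-spot annotations** — an exact planted fraction of high-ΔΔG
  (≥ 2 kcal/mol) residues inside the conserved set, the rest of the
  interface below 1 kcal/mol.

Defaults — 100 residues per chain, 24 interface residues, conserved
fraction 0.5, alignment depth 100 — mirror the per-chain scale reported for
heterocomplex datasets (roughly 29 ± 13 interface residues, about half of
them conserved). The fixtures deliberately do *not* emulate realistic
protein geometry, rotamers, secondary structure, phylogenetic correlation
between alignment rows, or alignment errors. Passing tests therefore
demonstrate that the statistics, selection rules and rankings behave as
designed under controlled signal and null conditions — not that any given
real complex will rank its interface first.

## Numerical choices and degenerate inputs

* Coincident residue centres would make $1/r_{ij}$ infinite and are an
  error, not a warning.
* Subsets with fewer than two members yield a distinct "too few" marker
  wherever a policy decision belongs to the caller (patch ranking keeps
  such patches ranked last; `clustering_ratio` reports `NA`).
* The golden-spiral SASA point set, fixture generators and the
  random-subset test are all deterministic given their seed arguments;
  generators save and restore the caller's RNG state. JSON reports carry a
  configuration hash and no timestamps, so identical runs are
  byte-identical.
* A geometric caveat found while validating the solvent vectors: on a
  uniform-radius shell the neighbour-centroid sits only slightly inside the
  surface, and the pull shrinks as the shell grows while the lattice
  asymmetry of neighbour placement stays constant. The "points radially
  outward" check is therefore performed on a small shell whose ten
  neighbours span a wide solid angle; on large single-radius shells only
  the unit-norm contract is asserted. Real protein surfaces, with residues
  at varying depths, are less pathological than a mathematically perfect
  shell.

## Problem sizes used in validation

The shipped suite and the acceptance script use: 100 randomised instances
per oracle-equivalence check; 200 planted + 200 scattered interface
fixtures (1000 random subsets each) for detection and calibration; 100
seeds per planted blob count (1-3) for sub-cluster recovery; 50 seeded
sphere fixtures × 3 patch methods for ranking recovery, plus a 200-replicate
null for decile uniformity; 20 fixtures for hot-spot closure. These sizes
give binomial standard errors of a few percent on every reported rate
while keeping a full run in the order of a minute or two.

## Limitations

* HSSP retrieval and MSA construction are out of scope; users supply an
  aligned FASTA whose query row matches the analysed chain.
* Antibody-antigen-like systems, where interface positions are
  hypervariable, violate the premise that binding sites are conserved; the
  method is expected to be uninformative there.
* The patch ranking uses conservation clustering alone; combining it with
  physicochemical patch descriptors is deliberately not implemented.
* Biological-assembly reconstruction from symmetry records is not
  performed; analyse the chains present in the coordinate file.

## A minimal session

```{r example, eval = FALSE}
spec <- fixture_spec(seed = 7)
fx <- make_complex(spec)
aln <- make_alignment(spec, fx$truth, fx$structure, "A")
res <- analyze_interface(fx$structure, aln, "A", "B")
print(res)

pf <- make_chain_sphere(fixture_spec(seed = 3, placement = "clustered"))
paln <- make_alignment(fixture_spec(seed = 3, placement = "clustered"),
                       pf$truth, pf$structure, "A")
pred <- predict_binding_site(pf$structure, paln, "A", method = 3,
                             true_interface = pf$truth$interface)
print(pred)
```
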