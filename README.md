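# ppiclust

Quantify how tightly evolutionarily conserved residues cluster in three
dimensions within a protein-protein interface, and use that clustering to
rank candidate binding sites on a protein surface.

## The problem and the method

Functionally important interface residues are both conserved and spatially
coupled. Given (a) the atomic coordinates of a complex (PDB), and (b) a
multiple sequence alignment of homologues of the analysed chain (aligned
FASTA, query row = the chain), `ppiclust`:

1. **Finds interface residues** — those losing more than 0.1 Å² of
   solvent-accessible surface area on complexation (Shrake–Rupley SASA,
   1.4 Å probe).
2. **Scores conservation** per alignment column as the Shannon entropy of
   seven amino-acid classes, s(i) = −Σₖ p(k) ln p(k) (within-class
   substitutions are free; a relative-entropy variant against background
   class frequencies is available), and selects the conserved subset as the
   residues with entropy below the interface mean (stricter criteria:
   mean − σ, or exactly 0).
3. **Measures spatial clustering** of a residue set as the mean inverse
   distance over residue-pair centres of mass,
   M_s = (1/N_pairs) Σ_{i<j} 1/r_ij, and summarises the conserved subset's
   clustering by ρ = M_s,cons / M_s,int. ρ > 1 means the conserved residues
   are clustered within the interface; significance comes from 1000 random
   same-size interface subsets (empirical p = (1+k)/(N+1)).
4. **Partitions** conserved residues into sub-clusters by average-linkage
   clustering (thresholds 21 Å / 15 Å for homodimers / complexes, from the
   half-mean-maximal-atom-distance rule), computes per-amino-acid
   enrichment E_X in the conserved subset, and localises experimental
   alanine-scanning hot spots (ΔΔG ≥ 1 / 1.5 / 2 kcal/mol) within the
   clusters.
5. **Predicts binding sites** by generating one surface patch per surface
   residue (fixed radius; interface-adapted radius; or adapted radius plus
   a 110° solvent-vector constraint that keeps patches on one face),
   scoring ρ within every patch, and ranking the true interface among all
   patches (rank, decile, Z = (ρ_int − ⟨ρ⟩)/σ, best patch overlap).

Synthetic fixture generators (toy complexes, controlled alignments,
planted hot spots — all with recorded ground truth) make the whole pipeline
testable offline; see the methods vignette
(`vignettes/conserved-residue-clustering.Rmd`) for the model, assumptions,
and design choices.

## Worked example

```r
library(ppiclust)

## a toy complex with a conserved cluster planted in its interface,
## and a matched alignment (depth 100, noise entropy ln 2)
spec <- fixture_spec(seed = 7)
fx   <- make_complex(spec)
aln  <- make_alignment(spec, fx$truth, fx$structure, "A")

res <- analyze_interface(fx$structure, aln, "A", "B")
print(res)
#> Conserved-residue clustering analysis (complex)
#>   chain A vs [B]: 24 interface residues, 12 conserved (criterion mean)
#>   <s>_int = 0.3446 nats (sd 0.3520)
#>   M_s,cons = 0.1026, M_s,int = 0.0798 (1/A), rho = 1.2864
#>   <M_s,random> = 0.0797 (sd 0.0052), empirical p = 0.000999
#>   sub-clusters at 15 A: 1 (sizes 12 )
```

The 24 interface residues of chain A contain 12 below-mean-entropy
(conserved) residues; their mean inverse pair distance (0.1026 /Å) exceeds
that of the whole interface (0.0798 /Å), giving ρ = 1.29 — the conserved
residues are clustered — and none of 1000 random 12-residue subsets matched
it (p ≈ 0.001). They form a single sub-cluster at the 15 Å threshold.

Binding-site prediction on a single chain with a planted interface:

```r
spec2 <- fixture_spec(seed = 3, placement = "clustered")
pf    <- make_chain_sphere(spec2)
paln  <- make_alignment(spec2, pf$truth, pf$structure, "A")
pred  <- predict_binding_site(pf$structure, paln, "A", method = 3,
                              true_interface = pf$truth$interface)
print(pred)
#> binding_site_prediction: chain A, method 3, radius 13.8 A, 100 patches
#>   top patch centres by rho:
#>     A:99  size 19, conserved 8, rho 1.257
#>     ...
#> patch_ranking: 100 surface patches
#>   interface rho = 1.2697, rank 1 / 101 (decile 1), Z = 3.44
#>   Z > 1.64 marks clustering significant at the 95th percentile: significant
#>   best patch overlap with the true interface: 79.2%
```

The true interface outranks all 100 generated surface patches (decile 1)
and its clustering is significant at the 95th percentile (Z = 3.44).

A thin CLI over the same functions lives at `inst/cli/ppiclust.R`
(subcommands `interface`, `predict`, `simulate`).

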