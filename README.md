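# coevotopo

Infers the three-dimensional arrangement of subunit centers — the
*quaternary topology* — of a multi-subunit protein complex from
correlations in the evolutionary rates of its subunits, and validates the
inferred configuration against a reference crystal structure.

## Who this is for

Researchers with one phylogenetic tree per subunit family of a complex
(typical case: respiratory complex I, with its L-shaped matrix and
membrane arms, dozens of subunits and transiently bound assembly factors)
who want to know how much of the complex's spatial organization is
recoverable from sequence evolution alone — and where subunits of unknown
position, or assembly factors absent from crystal structures, are likely
to sit.

## The method

1. **Patristic distance vectors.** Each family tree becomes a vector *v*
   of patristic distances over species pairs, on a shared canonical pair
   index, with coverage filters (species in ≥ 8 families, pairs in ≥ 5
   vectors, warning below 15 shared species per family pair).
2. **Phylogeny correction (mirror-tree).** The shared species-phylogeny
   signal is removed by orthogonal projection on the averaged reference
   vector *p*:

   *v*\* = *v* − (*p*ᵀ*v* / *p*ᵀ*p*) *p*

   Corrected vectors are compared by Spearman rank correlation, giving
   the co-evolution matrix *r*.
3. **Embedding.** *d′* = 1 − *r*, *d* = *d′*/max *d′*; classical MDS
   eigendecomposes B = −½ J D⁽²⁾ J and retains k = 3 dimensions; the
   goodness-of-fit P₍k₎ = Σᵢ≤k g(λᵢ) / Σᵢ≤n−1 g(λᵢ) (default
   g = |λ|) says how much eigenvalue mass the 3D model captures, and a
   permutation null (upper-triangle shuffles) calibrates it.
4. **Validation.** Subunit centers from a PDB structure (mean Cβ, Cα for
   glycine) give physical distances; similarity Procrustes (translation,
   rotation, optional reflection, isometric scale) gives
   rmsd = √(Σᵢ |tᵢ − cᵢ|² / n), per-axis r² after principal-axis
   reorientation, and distance-versus-distance regressions.

A synthetic generator (`makeConfiguration`, `noisyDissimilarities`,
`simulateRateCorrelatedTrees`) produces ground-truth L-shaped
configurations and species trees whose branch-rate multipliers correlate
with physical distance, so the whole pipeline is testable without any
downloads.

## Worked example

Simulate a 12-unit two-armed complex, recover its topology, and compare
with the ground truth:

```r
library(coevotopo)
truth <- makeConfiguration(7, 5, jitter = 0, seed = 1)
trees <- simulateRateCorrelatedTrees(truth, n_species = 60,
                                     sigma_rate = 0.5, seed = 2)
set <- assembleVectorSet(lapply(trees, patristicVector))
cm  <- coevolutionMatrix(set)
D   <- toDissimilarity(cm)
emb <- classicalMDS(D, k = 3)
emb
#> EmbeddingResult: 12 units in 3D, P_3 = 0.7618 (eigenvalue policy: absolute)
permutationNull(D, n_perm = 1000, seed = 9)
#> PermutationNull: observed P_3 = 0.7618, null 0.5899 +/- 0.033 (1000 permutations, seed 9)
#>   empirical p = 0.000999
procrustesFit(emb, truth$xyz)
#> SuperpositionResult: 12 units, rmsd = 1.8155 (denominator n), scale = 5.0359
distanceAgreement(D, physicalDistances(truth$xyz))
#>                 axis r_squared      p_value  n
#> 1 pairwise-distances 0.3905204 2.043083e-08 66
```

Reading: the 3D model captures 76% of the eigenvalue mass — far more than
any permuted arrangement of the same dissimilarities (p ≈ 0.001), so the
matrix is genuinely 3D-embeddable; the fitted configuration sits 1.8
distance units from the truth (arm spacing is 1.0); and 39% of the
variation in co-evolutionary dissimilarity is explained by true physical
distance. With real complex I trees the same calls take a tree manifest,
a PDB reference and a chain→unit table (an example for the bacterial
structure ships in `inst/extdata/chain_map_3m9s.tsv`), via
`runPipeline()` or the CLI in `inst/cli/coevotopo.R`
(`simulate` / `distances` / `correlate` / `embed` / `superpose` / `run`).

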