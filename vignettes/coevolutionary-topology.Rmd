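---
title: "Inferring quaternary topology from evolutionary rate correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring quaternary topology from evolutionary rate correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotopo)
```

## The problem and the model

Subunits of a stable protein complex evolve under a shared constraint: a
mutation that perturbs an interface must be compensated in the partner
subunit at a comparable rate, so physically close subunits tend to show
correlated evolutionary rates. `coevotopo` turns that observation into a
geometric inference: given one phylogenetic tree per subunit family, it
estimates a three-dimensional arrangement of subunit centers — the
*quaternary topology* — and quantifies how well that arrangement explains
the co-evolutionary signal.

The procedure has four stages.

**1. Patristic distance vectors.** Each family tree is reduced to a vector
$v$ of patristic distances (sum of branch lengths, substitutions/site) over
all unordered species pairs. All vectors are aligned on a common canonical
pair index. Coverage filters then mirror standard mirror-tree practice:
species present in fewer than `min_units_per_species` (default 8) families
are dropped, then species pairs present in fewer than `min_vector_count`
(default 5) vectors; family pairs sharing fewer than `min_shared_species`
(default 15) species are flagged with a warning because their correlations
rest on few observations.

**2. Phylogeny correction and correlation.** All trees reflect the same
underlying species phylogeny, so raw distance vectors correlate strongly no
matter what. The shared signal is removed by orthogonal projection on a
reference vector $p$, the per-pair mean of the family vectors:
$$v^{*} = v - \frac{p^{\mathsf T} v}{p^{\mathsf T} p}\,p .$$
Using the within-complex average as reference also removes rate covariation
common to the whole complex, focusing the residuals on between-subunit
differences. Corrected vectors are compared by Spearman rank correlation
(average ranks on ties) over their jointly present pairs, giving the
co-evolution matrix $r$ with, per cell, the number of species pairs that
supported it.

**3. Embedding.** Correlations become dissimilarities by $d' = 1 - r$
(negative rate correlation counts as evidence of distance) and
$d = d'/\max d'$, so $d \in [0,1]$. Classical (Torgerson) MDS
eigendecomposes the double-centered squared dissimilarities
$B = -\tfrac12 J D^{(2)} J$ and takes coordinates
$X = Q_{+}\Lambda_{+}^{1/2}$ from the top $k = 3$ eigenvalues. The
goodness-of-fit
$$P_k = \frac{\sum_{i\le k} g(\lambda_i)}{\sum_{i\le n-1} g(\lambda_i)}$$
measures the eigenvalue mass captured by the retained dimensions.

**4. Validation.** The embedded configuration is compared to a reference
structure: per-subunit centers are approximated by the mean of C$\beta$
coordinates (C$\alpha$ for glycine), and the configuration is fitted by
similarity Procrustes (translation, rotation, optional reflection,
isometric scale), summarized by
$\mathrm{rmsd} = \sqrt{\sum_i |t_i - c_i|^2 / n}$, by per-axis squared
correlations after rotating both configurations into the embedding's
principal-axis frame, and by regressions of co-evolutionary on physical
pairwise distances.

## Numerical choices

**Negative eigenvalues and the $P_k$ denominator.** Co-evolutionary
dissimilarities are not Euclidean, so $B$ has negative eigenvalues and the
eigenvalue-mass denominator needs a policy $g$. The default is
$g(\lambda)=|\lambda|$, the criterion used by `stats::cmdscale`; this is
also the policy under which the permutation-null level for 45-unit matrices
comes out at the published $\approx 0.17$, whereas the positive-part policy
$g(\lambda)=\max(\lambda,0)$ yields $\approx 0.23$ and the raw sum is
unstable (the three options are all selectable, and every result records
which was used). The policy is applied to numerator and denominator alike,
which makes $P_k$ monotone in $k$; for the usual case where the top $k$
eigenvalues are positive the numerator is their plain sum under every
policy.

**Permutation null.** "Random symmetric matrix" is made precise as:
permute the $n(n-1)/2$ upper-triangle values uniformly and mirror. This
preserves the value multiset exactly and destroys all geometry, so the null
isolates *arrangement* rather than the marginal distribution of distances.
The empirical p-value counts the observed value among the samples,
$p = (1 + \#\{P_k^{\mathrm{null}} \ge P_k\})/(1 + n_{\mathrm{perm}})$, so it
is never zero.

**Projection with ragged coverage.** Families cover different species
subsets, so $p^{\mathsf T}v$ and $p^{\mathsf T}p$ are computed over the
pairs present in $v$ only. This keeps the orthogonality contract
$\langle v^{*}, p\rangle = 0$ exactly testable per vector; an alternative
(projecting on the full index) would leave residual shared signal in
sparse vectors. Zero-variance residuals yield an *undefined* correlation
(`NA`), never 0: a 0 would fabricate evidence of independence.

**Procrustes details.** The optimal rotation comes from the SVD of the
cross-covariance; reflections are allowed by default because cMDS output
chirality is arbitrary — forbidding them forces a proper rotation by
flipping the smallest singular direction, and the choice is recorded in
`reflection_used`. The rmsd denominator is $n$ by default; a literal
$n^2$ variant is provided as a sensitivity flag (it rescales rmsd by
$1/\sqrt n$, nothing else). Eigenvalues closer than rounding error are a
degenerate block whose within-block rotation is arbitrary; tests therefore
compare only rotation-invariant quantities (distances, rmsd,
eigenvalues).

**Degenerate inputs.** Branch lengths of exactly 0 are accepted; tiny
negative branch lengths (an artifact of some tree programs) are clamped to
0 with a warning. Two leaves mapping to one species is an error, because a
single ortholog per species is an upstream requirement. A reference vector
with $p^{\mathsf T}p = 0$ is an error. Eigenvalues within
$10^{-8}\,\max|\lambda|$ of zero define no coordinates; if fewer than $k$
eigenvalues remain, trailing coordinate columns are zero with a warning.

## What the synthetic generator emulates — and what it does not

`makeConfiguration()` builds an L-shaped, two-armed arrangement of unit
centers (defaults 7 + 5 units, spacing 1), the characteristic geometry of a
two-arm complex such as respiratory complex I.
`simulateRateCorrelatedTrees()` generates the mirror-tree signal from first
principles: one pure-birth species tree (default 60 species, as a round
figure of the same order as the real alignments, which mostly have 44–100+
sequences), then per unit a copy whose branch $e$ is scaled by
$\exp(z_u(e))$ with
$\mathrm{Cov}(z_u, z_v) = \sigma^2 e^{-\|x_u - x_v\|/L}$. The lognormal
multiplier with exponentially decaying covariance is the simplest model in
which rate correlation decays smoothly with physical distance — which is
precisely the phenomenon the method detects; $\sigma = 0.5$ gives
realistic rate dispersion (roughly 1.6-fold standard deviation around the
species-tree rate), and $L$ defaults to one third of the configuration
extent so that within-arm correlations clearly exceed between-arm ones.
`noisyDissimilarities()` shortcuts the tree stage with a noisy affine map
of true distance, emulating the observed linear distance/co-evolution
relation directly.

Real data differ in ways the generator deliberately ignores: rates are not
lognormal, selective constraints vary along sequences, expression level
and general functional relatedness correlate rates independently of
distance, mitochondria- and nucleus-encoded subunits experience different
mutation pressures, and species coverage is biased rather than
missing-at-random (`dropout` thins uniformly). Passing the benchmark
therefore shows the *machinery* recovers geometry from
distance-structured rate correlation; it does not show that any real
complex's rates are so structured — that is the empirical question the
pipeline is built to ask.

## Benchmark design

The end-to-end benchmark runs 20 replicates of the default generator
(7 + 5 units, 60 species, $\sigma = 0.5$, $L$ = extent/3) and requires the
embedding to separate the two arms (between-arm mean distance above
within-arm mean) in at least 18. The same problem sizes are used by the
acceptance script; they keep a full run to seconds while leaving each
Spearman cell with ~1700 species pairs, ample for stable rank
correlations. The permutation-null check uses a 45-unit synthetic matrix
built from the affine-noise model — a synthetic stand-in, since the null
level depends only weakly on the entry distribution (it is a property of
permuted symmetric matrices of that size), which is what makes the
published level reproducible without the original matrix.

## Reference structures

`subunitCenters()` reads PDB files (first model, highest-occupancy
alternate location, hetero residues skipped) and averages one anchor atom
per residue: C$\beta$, C$\alpha$ for glycine, C$\alpha$ as fallback where
C$\beta$ is missing (counted and reported). Merged units — for complex I,
the three membrane subunits that cannot be placed individually are treated
as the single unit NADH34L6 — pool the residues of all member chains
before averaging, i.e. the merged center is residue-count weighted; this
is closest to a mass-center approximation (the alternative, a mean of
chain centers, is easily computed from the per-chain output for
comparison). The chain-to-unit table shipped in
`inst/extdata/chain_map_3m9s.tsv` documents a usable mapping for the
bacterial complex I reference, including the *assumption* of which chains
feed the merged unit; it is configuration, not code, and should be checked
against the chain table of the actual structure file.

## Known limitations

- Correlations measure co-evolution only indirectly; expression and
  function confound them, and indirect (transitive) correlations are not
  deconvolved — no partial-correlation correction is attempted.
- The averaged reference vector is itself estimated from the same data it
  corrects, which slightly deflates all residual correlations; with ≥ 40
  families the effect is negligible but with few families it is not.
- Whether dissimilarities are rescaled before or after subsetting changes
  raw embedded distances (not $P_k$, which is scale-invariant); both
  orders are available via `toDissimilarity(rescale=)` and subsetting, and
  results record which was used.
- Regression p-values over distance pairs ignore their non-independence;
  a Mantel permutation p is available (`distanceAgreement(mantel=)`) and
  is the defensible choice when the pair count is small.

## A small worked run

```{r, eval = FALSE}
truth <- makeConfiguration(7, 5, jitter = 0, seed = 1)
trees <- simulateRateCorrelatedTrees(truth, n_species = 60,
                                     sigma_rate = 0.5, seed = 2)
set <- assembleVectorSet(lapply(trees, patristicVector))
cm <- coevolutionMatrix(set)
emb <- classicalMDS(toDissimilarity(cm), k = 3)
emb$Pk                                  # goodness-of-fit of the 3D model
procrustesFit(emb, truth$xyz)$rmsd      # agreement with the ground truth
```
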