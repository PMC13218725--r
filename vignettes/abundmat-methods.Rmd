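---
title: "Methods: structure-conditioned substitution matrices from variant abundance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-conditioned substitution matrices from variant abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abundmat)
```

This vignette documents the models and procedures implemented in
`abundmat`, the assumptions behind them, the tunable parameters and their
defaults, the design choices made where several reasonable options existed,
and what the synthetic benchmark does and does not demonstrate.

## Data model and normalisation

A variant abundance score is a unitless number normalised per experiment so
that 0 corresponds to nonsense-variant-like abundance and 1 to
wild-type-like abundance; values outside [0, 1] are legitimate and are
never clipped anywhere in the package. `normaliseFromBinWeights()`
implements the min-max normalisation
`(W_var - W_nonsense) / (W_wt - W_nonsense)` for users ingesting raw
bin-weighted averages, but published tables arrive normalised and bypass
it. Pooling (`combineDatasets()`) is deliberate concatenation without any
cross-dataset rescaling: the working assumption is that datasets produced
by the same assay type are comparable enough for averaged analyses, and
that assay-specific distortions show up as noise rather than bias. This
assumption is a known limitation — absolute score values depend on each
experiment's variant library composition — and nothing in the package
attempts to correct for it.

Filtering (`filterSubstitutions()`) keeps single missense substitutions
only: synonymous and nonsense rows and user-declared excluded position
ranges (e.g. a transmembrane segment scored by the assay but outside the
soluble domain being analysed) are removed, with per-category counts
retained in the dataset metadata.

### Noise ceilings

`noiseResample()` draws every score independently from
`Normal(score, sd)` (per-variant reported standard deviations, independence
across variants) and reports the mean Pearson and Spearman correlation
between original and resampled vectors over `nResamples = 100` draws. This
estimates the correlation a *perfect* predictor could achieve against the
noisy measurements; it is an upper bound for the LOPO results below. The
attenuation closed form `E[r] ≈ sd(truth) / sqrt(sd(truth)^2 + sigma^2)`
for homoscedastic noise is used as an independent oracle in the tests.

## Structural descriptors

* **rASA** — numerical rolling-probe (Shrake–Rupley-style) solvent
  accessible surface area on heavy atoms, probe 1.4 Å, 192 Fibonacci
  sphere points per atom (per-residue rASA changes by < 0.02 when the
  resolution is doubled), normalised by a per-residue-type theoretical
  maximum (`maxAsaTable()`, the Tien et al. 2013 theoretical scale).
  Burial is always evaluated in the context of *all* chains present in the
  input assembly, so the same chain gives monomer- or dimer-context
  features depending on which file is supplied. No installed R package
  provides SASA, so the implementation is in-package; its oracles are
  closed-form single- and two-sphere areas and total-occlusion fixtures,
  not another program — the realistic contract for reproducing published
  burial classes is class-level, not area-level, agreement.
* **WCN** — `WCN_i = Σ_{j≠i} s(r_ij)` with
  `s(r) = (1-(r/r0)^6)/(1-(r/r0)^12)`, `r0 = 7 Å`, evaluated through the
  algebraically identical `1/(1+(r/r0)^6)` to avoid the removable
  singularity at `r = r0` (where the limit is 1/2). `r_ij` is the shortest
  heavy-atom distance between side chains; glycine (or any residue without
  side-chain atoms) falls back to all-atom shortest distance.
* **Secondary structure** — read from DSSP files and mapped H/G/I → helix,
  E/B → strand, everything else → loop. An `alphaOnly` mode restricts
  helix to `H` for the helix-propensity analysis only. The hydrogen-bond
  assignment algorithm itself is out of scope; `ss3FromDihedrals()` is a
  coarse Ramachandran-window fallback used exclusively to label synthetic
  fixtures and is documented as such.
* **Dihedrals** — standard phi/psi via an atan2 formulation, cross-checked
  in the tests against both forward-kinematics fixtures (backbones built
  from prescribed angles with ideal geometry) and `bio3d::torsion.pdb`.

Structure cleaning removes HETATM records (waters, ligands, co-factors,
ions) and hydrogens and resolves alternate locations to highest occupancy
then first encountered. Descriptors therefore ignore bound co-factors by
construction.

## Residue classification and substitution matrices

The two-descriptor burial rule classifies a residue buried iff
`rASA <= c_rasa` **and** `WCN >= c_wcn`; with the default `c_wcn = 0` this
reduces exactly to the rASA-only rule, and `c_rasa = 0.1` is the default
cutoff. `gridSearchCutoffs()` re-derives this choice: it scans
`c_rasa ∈ {0, 0.05, …, 0.5} × c_wcn ∈ {0, 1, …, 20}` (step sizes are a
package choice), rebuilding exposure matrices and evaluating them by LOPO
prediction at every grid point, and reports the argmax of mean r and
argmin of mean MAE (first grid point on exact ties).

A `SubstitutionMatrix` stores the 20×20 arithmetic cell means, the
parallel count matrix and per-cell standard deviations. Diagonal
(synonymous) cells are structurally missing and are only set to 1 at the
entry point of clustering/PCA. No minimum per-cell count is imposed —
counts are exposed so users can filter downstream. Conditioning schemes are
`global` (1 matrix), `exposure` (2), `secondary` (3) and `combined` (6);
each scheme's labels partition the residues, so every record contributes
to exactly one matrix per scheme.

## Prediction

`predictLopo()` always rebuilds matrices without the target protein;
predictions are cell lookups keyed by the wild-type residue's environment.
When an environment-specific cell is empty the fallback chain is
environment cell → global cell (also LOPO) → missing, and every prediction
carries a provenance string naming its source. The fallback hierarchy is a
package choice (the alternatives — no fallback, or neighbour-cell
imputation — either discard data or blur the environment signal).
Evaluation reports Pearson r, Spearman r_s (average ranks), and MAE over
pairwise-complete pairs, with missing-prediction counts. Confidence
intervals on means across proteins use percentile bootstrap with 10,000
draws (`bootstrapMeanCI()`).

External baselines: `baselineMatrixPredict()` scores substitutions with
any user-supplied 20×20 matrix (e.g. a BLOSUM-style matrix from CSV), and
`ddgPrepare()` standardises stability-change tables to kcal/mol per
subunit (Rosetta energy units divided by 2.9; dimer values halved because
the substitution is applied in both chains).

## Residue profile classification

`classifyBurialLike()` resamples a residue's profile 10,000 times from
variant-specific Gaussians (independent errors across variants of a
residue), computes for each resample the RMSD to the buried and exposed
average profiles of its amino-acid type, and calls the residue buried-like
when the buried RMSD is smaller in more than 95% of resamples
(exposed-like below 5%, inconclusive otherwise). Only residues with at
least five scores are evaluated. For interface work the reference matrices
are rebuilt excluding the target protein and using monomer-context
classifications, so that dimer-contact residues are judged against
genuinely exposed averages. When a reference row has missing cells, the
RMSD uses the defined overlap and reports its size.

Exact resample ties are split evenly (each side gets weight 1/2). A tie is
a probability-zero event under continuous noise but occurs when the two
reference rows coincide or all standard deviations are zero; the even
split makes a perfectly symmetric comparison come out at frac = 0.5
(inconclusive) instead of forcing a definite call, keeps
`frac ∈ {0, 1}` in noise-free non-tied cases, and makes swapping the two
reference matrices map frac to exactly `1 - frac`.

`classifyFavoured()` applies the same machinery to rank correlations: a
residue is evaluated only if its observed `-r_s(ΔΔG)` and `r_s(matrix)`
are both positive and at least five variants carry a score, a matrix
prediction and a ΔΔG value; it is called ΔΔG-favoured when
`-r_s(ΔΔG) > r_s(matrix)` in at least 95% of resamples and
matrix-favoured at 5% or below. No multiple-testing correction is applied
across residues, deliberately.

## Matrix-level analyses

* **Asymmetry** `mean - t(mean)` and elementwise matrix differences
  propagate missingness.
* **Clustering** is average-linkage agglomerative clustering with
  Euclidean distances, run separately on rows (mutation *from*) and
  columns (mutation *to*) after setting the diagonal to 1 and imputing
  missing off-diagonal cells with the row mean of defined off-diagonal
  cells (counts accompany outputs so users can judge the imputation).
* **PCA** operates on 20 concatenated 40-vectors (row profile then column
  profile, synonymous slots = 1), centred but not scaled. PCA signs are
  arbitrary; each component is oriented so its largest-magnitude loading
  is positive, making outputs deterministic.
* **Helix propensity** builds `P_ij = ddg_i - ddg_j` from a propensity
  scale (default: the Pace & Scholtz consensus scale, kcal/mol relative to
  alanine) and correlates defined off-diagonal cells against an
  alpha-helix-only abundance matrix.
* **Left-handed loops** selects crystal-resolved loop residues with
  `0° < phi < 180°` and `-90° < psi < 90°` (open intervals, matching the
  strict inequalities of the window definition), builds their matrix and
  summarises mean scores per variant type with standard deviations over
  all contributing scores.

## The synthetic benchmark

`syntheticBenchmark()` is first-class, tested code, not a fixture. Its
defaults define the package's reference conditions: 6 proteins × 150
residues, per-variant Gaussian noise with sd 0.05, 90% mutational
completeness (within the 57–99% range typical of published datasets), two
homodimer proteins, two degron-like surface sites and six
left-handed-loop sites per protein, uniform amino-acid composition (a
simplification that guarantees cell coverage at this problem size).

Structures are compact pseudo-proteins: a self-avoiding boustrophedon path
through a near-cubic lattice with 3.8 Å spacing between consecutive CA
atoms, small positional jitter, and one pseudo side-chain atom 2.4 Å from
each CA pointing away from the centroid. Every residue type carries the
pseudo atom, and rASA on generator output is normalised by the model's own
closed-form maximum area (`syntheticMaxAsa()`) rather than the all-atom
Tien scale: with an all-atom normalisation, identical pseudo-residue
geometry would map to a 2.6-fold spread of rASA across types and
concentrate misclassification in specific matrix rows. Core sites (all 26
lattice neighbours occupied) are the ground-truth buried class; computed
rASA reproduces the labels for ≥ 95% of residues. Dimer files mirror the
chain across the contact face at a 4.4 Å gap; the planted interface is the
*whole* contact face (25 sites for the 6×5×5 box), because every
contact-face residue is occluded by the partner chain.

Scores are drawn from generating mean matrices (`defaultTrueMatrices()`):
buried means decrease with a hydropathy-plus-volume substitution distance
(0.95 down to ~0.05), exposed means sit near 0.95, and substitutions to
proline score poorly in both environments, so the generating model
reproduces the qualitative patterns the analysis is designed to detect
(buried harsher than exposed, aggregate bimodality near 0 and 1,
conservative substitutions tolerated). Special sites override their
environment: interface and degron-like sites draw from the buried matrix
regardless of monomer exposure, and left-handed sites use a planted
profile (substitution to G well tolerated; to P/I/V/W poorly).

What passing the benchmark shows: the pipeline recovers planted means,
cutoffs, interfaces and orderings from data whose generative process
matches the analysis assumptions exactly. What it does not show: anything
about assay-specific score distortions, heteroscedastic noise, correlated
errors within positions, non-bimodal score distributions, or real
all-atom structure — conclusions about real data rest on the published
analyses, not on these tests.

### Recovery tolerances

Matrix recovery on the benchmark is asserted cell-wise within 3 empirical
standard errors of the cell mean for cells with at least 20 scores. Two
statistical realities shape the test: (i) 3 SEM covers 99.73% per cell, so
over ~330 qualifying cells about one failure is *expected*; the assertion
is therefore that ≥ 98% of qualifying cells agree (buggy intermediate
implementations measured during development sat at 70–86%). (ii) At the
benchmark's depth, buried cells hold ~10 scores and never reach the
count-20 gate, so the buried matrix is asserted in aggregate instead:
signed mean cell error within ±0.02 and recovered-vs-true correlation
above 0.98. Degron-like and left-handed sites are excluded from this
comparison because the generator deliberately draws them from other
distributions; interface sites are retained (buried-generated and
buried-classified in the dimer context).

Profile-classification recovery asserts ≥ 90% of planted interface and
degron sites called buried-like and ≥ 90% of ordinary surface residues not
called buried-like at 10,000 resamples (observed: 100% on the reference
seed).

## Problem sizes and determinism

Default analysis sizes — 100 noise resamples, 10,000 profile resamples,
the 11×21 cutoff grid, the full 2^(n-1)-1 dataset-combination enumeration
at n = 6 — run in seconds to a few minutes on one CPU at benchmark scale.
Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state; identical seeds give bit-identical results,
including byte-identical generated PDB files.

## Known limitations

* Pooling assumes cross-dataset comparability of normalised scores; no
  harmonisation is attempted, and noise ceilings do not always match
  replicate-to-replicate correlations of the source experiments.
* The SASA implementation targets class-level agreement with standard
  programs, not bit-level area agreement (radii sets and hydrogen handling
  differ between programs).
* Matrix cells with few observations are reported with their counts but
  not smoothed; users should gate on counts for downstream use.
* The favoured/ΔΔG comparison consumes precomputed ΔΔG tables; running
  stability predictors is out of scope.
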