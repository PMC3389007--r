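---
title: "Delimiting evolutionary genetic species with K/theta and GMYC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting evolutionary genetic species with K/theta and GMYC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egdelim)
```

## Scope

`egdelim` tests whether clades in a single-locus alignment of asexual
organisms are *evolutionary genetic (EG) species*: populations that have
evolved independently long enough that the gap separating them cannot be a
product of drift within one population. Two criteria with different
rationales are implemented — the K/θ (4×) rule and the generalized mixed
Yule-coalescent (GMYC) model — together with the tree-building and
distance machinery they need and a coalescent simulator that generates
data sets with known species boundaries.

## The K/θ rule

The procedure has four steps.

1. A neighbor-joining tree is built on maximum-likelihood pairwise
   distances under the locus's GTR-family model, midpoint-rooted (or
   rooted on a user outgroup, which is then removed), and clades with
   bootstrap support at or above `support_threshold` (default 0.90,
   `ktheta_config()`) are retained. Each maximal retained clade is paired
   with its sister when the sister is itself retained or a single tip,
   otherwise with the non-nested retained clade minimizing K.
2. Within each clade, the mean pairwise uncorrected difference `d` (with
   pairwise deletion of gaps and N) gives the nucleotide diversity
   `pi = d n/(n-1)` and the corrected diversity
   `theta = pi/(1 - 4 pi/3)`, an approximation to 2 Ne mu. When all n
   sequences are identical, `d = 2/(L n)` — as if one sequence differed
   from each of the others at one site. For a singleton clade the
   quantities are undefined and the partner clade's theta is used.
3. Between the clades, `K` is the mean maximum-likelihood pairwise
   distance under the model (GTR+I+G for a COI-like locus, GTR+G for an
   ITS2-like locus; presets `coi_paper`, `its2_paper`).
4. The ratio K/θ and the clade sizes (n1, n2) give the decision. Under
   neutral drift the expected gap depth within one species is 2 Ne
   generations, with 95% of gaps within 4 Ne; at that point K ≈ 8 Ne mu
   against θ ≈ 2 Ne mu, hence the threshold K/θ ≥ 4. The second
   requirement is that samples of sizes n1 and n2 from populations
   separated τ·Ne generations would be reciprocally monophyletic with
   probability ≥ `p_threshold` (default 0.95).

**The τ convention.** The lookup table used in the original analyses for
the monophyly probability is unpublished, so the package defines its own
convention and documents it in every report: τ = K/θ, time in units of Ne
generations, which follows from K = 2 μ t and θ = 2 Ne μ. The probability
itself comes from a two-population coalescent (pairwise coalescence rate
1/Ne within each population, standard Kingman in the ancestor): closed
forms for samples of at most two per side — for example
P(RM | n1=2, n2=1, τ) = 1 − (2/3)e^(−τ) — and seeded Monte Carlo
(default `mc_reps = 1e5`, standard error below 0.002 near p = 0.95)
otherwise. The published probability for the ratio-4.04, (2,1) pair is
0.94, lower than this convention's 0.988, so the convention is mildly
liberal; it is not claimed to reproduce the original table.

**θ selection.** By default the larger of the two clades' θ is used
(conservative: it can only lower the ratio). The rule
`theta_rule = "smaller_on_n2"` reproduces the published exception for a
clade of n = 2, where π = 2d is judged an over-correction.

**Decisions.** `species` requires both criteria; a pair whose ratio
passes but whose probability falls short of the threshold by less than
5% is reported `flagged` rather than rejected — mirroring the published
treatment of a 0.94 case — while a ratio below 4 is always
`not-species`: the 4× gap is the species definition itself, so it is not
softened. Ratios are stored at full precision and rounded to two
decimals only in printed reports.

## The GMYC model

On a rooted ultrametric tree with N tips, branching events are ordered
from the root; interval i (duration x_i, n_i = i+1 lineages, the last
interval running to the present, so Σ x_i equals the tree height) carries
the hazard

    b_i = lambda_spec * k_i^p_spec + lambda_coal * sum_j [m_ij (m_ij - 1)]^p_coal

where k_i counts species-level lineages — lineages whose most recent
crossing of the applicable threshold lies above them, including
singletons — and m_ij the lineages of within-species cluster j. The
log-likelihood is Σ_i (ln b_i − b_i x_i). The null model classifies every
event as one process, b_i = λ [n_i(n_i−1)]^p. These functional forms and
the likelihood-ratio degrees of freedom (df = 3 against the null: extra
rate, extra exponent, threshold) are fixed here so the package is
self-contained; they are printed in the report header.

Numerical choices:

* The single-threshold likelihood is piecewise constant in the threshold
  age between node ages, so candidates sit at midpoints between
  consecutive distinct ages, plus *just above the root* and *just above
  the tips*. The above-root candidate classifies every event as
  coalescent and reproduces the null model exactly, which makes
  `ll_gmyc >= ll_null` hold by construction.
* Rates are log-transformed and the exponents mapped smoothly into
  [0.01, 10]; each candidate is maximized by Nelder-Mead (relative
  tolerance 1e-8) from three deterministic starts, with exact 1-d
  profile fits for single-process classifications. Ties across
  candidates break toward fewer species.
* The species count is the number of lineages crossing the threshold
  (clusters plus singletons); the confidence set collects the counts of
  all candidates within 2 log-likelihood units of the optimum.
* Internal-node ages of exactly zero (duplicate haplotypes) are jittered
  to 1e-9 of the tree height; the haplotype-pruned re-analysis, reported
  alongside the complete one by `gmyc_grid()`, is the structural remedy.
* The multiple-threshold fit refines the single optimum greedily, moving
  the diversification/coalescent boundary one node rootward or tipward
  on one lineage at a time and re-optimizing, accepting the best move
  until none improves by more than 1e-6. It therefore nests the single
  fit by construction but searches locally, not exhaustively; an
  exhaustive oracle is retained in the test suite for trees of up to 7
  tips. Its `df` against the single fit is the number of distinct
  transition ages minus one.

Trees come from `upgma()` on model distances when only an alignment is
available (the clock-ML tree searches used in the original analyses are
out of scope), or from any user-supplied ultrametric Newick
(ultrametricity tolerance: 1e-6 of tree height, absorbing decimal
rounding).

## The simulator

`simulate_genealogy()` draws a multispecies Kingman coalescent: pairwise
coalescence rate 1/Ne per generation within each population (so
E[T2] = Ne and θ = 2 Ne μ exactly, the haploid-style convention
appropriate for mitochondrial-like loci of asexuals), with surviving
lineages pooled into ancestral populations at the species-tree divergence
times. `simulate_sequences()` evolves sites along the genealogy under the
same GTR(+I+G) machinery used for distances: root drawn from the
stationary frequencies, per-site invariant/gamma categories, transition
matrices P(μ·branch·rate). There is no recombination, migration,
selection, demographic change or indel process — exactly the drift-only
null that the K/θ gap argument assumes. Passing tests therefore show
correct behavior under that null, not robustness to gene flow, selection
or alignment error in real data.

The `coi_like` fixture (58 specimens, 29 distinct haplotypes, 16 species
inside 5 morphospecies, 385 bp, GTR+I+G with p_inv = 0.58 and shape 1.57)
and the `its2_like` fixture (22 specimens, 14 haplotypes, 5 species,
GTR+G with shape 0.45) mirror the sizes of the study design they emulate;
within-species θ spans 0.002-0.02 and between-species divergences fall in
the 0.02-0.14 substitutions/site range. Specimen and haplotype counts are
engineered to those exact values by duplicating sampled haplotypes and,
where needed, collapsing the closest within-species haplotype pair or
adding a single substitution — so the complete/pruned analysis pair is
always exercised reproducibly.

## Problem sizes in the checks

The simulation studies in the test suite and `scripts/acceptance.R` use:
5 species × 6 tips with divergences staggered at 20-35 Ne for GMYC
species-count recovery; 20-tip single-population trees for the GMYC
likelihood-ratio null calibration; two populations of 10 samples at
t = 10 Ne (θ = 0.01, L = 385, 100 bootstrap replicates on p-distances,
2000 Monte Carlo replicates for the monophyly probability) for K/θ power
and a 20-tip single population for its false-positive rate; and n = 10,
L = 385 for θ recovery at θ ∈ {0.002, 0.01}. These sizes were chosen as
representative of single-locus data sets in this field.

## Known limitations

* A single locus carries large genealogical variance: θ estimates have
  heavy right tails (and a structural n/(n−1) inflation at small n), so
  the conservative larger-θ rule can push K/θ below 4 even for cleanly
  separated populations, and drift gaps of ~4-6 Ne inside one population
  can push it above 4. The acceptance script measures both operating
  characteristics; they are properties of the method, not of the
  implementation.
* GMYC likelihood surfaces are often nearly flat across neighboring
  threshold candidates, producing ±1-2 species near-ties and a tendency
  to split deep coalescent clusters; the confidence set, the LR test and
  the haplotype-pruned re-analysis should always be read together with
  the point estimate.
* τ = K/θ for the monophyly probability is a documented convention, not
  a reproduction of the unpublished lookup table used in the original
  analyses.
* `theta = pi/(1 - 4 pi/3)` has a pole at π = 0.75; diversities that
  high (biologically implausible within a clade) raise an error rather
  than a nonsensical value.
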