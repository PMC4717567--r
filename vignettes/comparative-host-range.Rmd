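---
title: "Methods: phylogeny, ovipositor morphology and host range in parasitoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny, ovipositor morphology and host range in parasitoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostrangr)
```

`hostrangr` asks a classical comparative question about parasitoid wasps:
are host range and ovipositor morphology constrained by phylogenetic
history, or are they evolutionarily labile? This vignette is the package's
own account of the statistical machinery, its assumptions, and the design
choices that were genuinely open.

## The data model

Three inputs define an analysis:

* a rooted phylogeny with branch lengths (newick). Tips may be individual
  specimens; `prune_to_species()` collapses them to one exemplar per
  species. Basal or internal multifurcations (e.g. collapsed poorly
  supported nodes) are accepted;
* individual morphometric measurements: per specimen, the length of the
  visible ovipositor sheath and of the metatibia, both in micrometres.
  These summarize to AOS (species median sheath length) and ROS (species
  median of the per-individual sheath/metatibia ratio, a size-corrected
  measure less sensitive to host-induced plasticity);
* host-rearing records: parasitoid species x host insect species, with the
  host's family and order and the host plant's family (possibly missing).

The analysis universe is derived from data availability, not hard-coded:
morphological tests run on tree ∩ measurements, ecological tests on that
set ∩ host records. With default synthetic data that is 19 and 13 species,
mirroring the dimensions the defaults emulate.

## Distance matrices

All tests operate on labelled, symmetric, zero-diagonal matrices
(`dist_matrix`), validated at construction (symmetry tolerance 1e-12) and
stored in C-locale lexicographic label order; every consumer aligns by
label, never by index, so input ordering cannot leak into results.

* **Phylogenetic**: patristic distances on the supplied phylogram. An
  alignment-based genetic distance is deliberately *not* computed — the
  package consumes a finished tree whose branch lengths are already in
  substitutions per site, and no sequence handling is in scope. With
  multiple individuals per species, either an exemplar is chosen
  (default: first in tip order; alternatively the tip with minimal mean
  patristic distance to its conspecifics) or the median over all
  between-species tip pairs is taken (`mode = "between_species_median"`);
  the mode used is recorded in the matrix metadata.
* **Morphological**: relative difference of species medians,
  $|d_i-d_j|/\big((d_i+d_j)/2\big)$, bounded by 2 (reached when one median
  is 0). The 0/0 case is defined as 0: two species with identical values
  are maximally similar.
* **Ecological**: binary Bray–Curtis, $(b+c)/(2a+b+c)$ — the complement of
  Sørensen similarity — on incidence ("at least one record vs none") at
  host species, family, order, or plant-family level. The closed binary
  form is used rather than the abundance form because rearing effort is
  uneven across species, making abundances uninterpretable. Records with
  missing plant family are dropped (and counted) only at the plant level;
  a parasitoid left without any positive entry is excluded with a warning,
  since Bray–Curtis is undefined for an empty row.

## Mantel tests

The Mantel statistic is the Pearson correlation of the strict lower
triangles. The permutation null jointly permutes rows and columns of the
second matrix; the partial test computes
$r_{AB\cdot C}=(r_{AB}-r_{AC}r_{BC})/\sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}$ and
permutes the labels of $A$ while holding $B$ and $C$ fixed. Which matrix
was permuted is recorded in every result.

Conventions that were open and are now fixed (and stamped into results):

* default tail is two-sided (the source analyses report non-significance
  without stating a tail);
* default 9999 Monte-Carlo permutations, with the +1 correction in
  numerator and denominator so p is never 0 and never below
  $1/(n_{perm}+1)$;
* when $n! \le 40320$ (n ≤ 8 by default) the test switches to exhaustive
  enumeration of all relabelings and reports the exact proportion at least
  as extreme, identity included;
* ties in the permutation distribution are counted as extreme using a
  1e-12 comparison tolerance, so `A` vs `A` gives the minimal attainable p
  rather than an artifact of floating-point noise.

Degenerate inputs error rather than guess: label mismatches report the
symmetric difference, a zero-variance triangle is an undefined
correlation, and $|r_{AC}|$ or $|r_{BC}|$ at 1 is degenerate conditioning.

## The D statistic

Binary traits are tested for phylogenetic signal by the scaled sum of
state changes. Internal nodes get contrasts-style nodal estimates: each
node is the average of its two daughters weighted by the inverse of their
adjusted branch lengths, and the node's parent-facing branch is extended
by the product-over-sum of the daughter lengths — the standard pruning
recursion. The observed $d$ is the sum over all edges of
$|v_{child}-v_{parent}|$. Two nulls, both preserving the observed
prevalence exactly so the $d$ distributions are comparable:

* *phylogenetic randomness*: shuffle the tip states;
* *Brownian threshold*: simulate Brownian motion from root value 0 along
  the branch lengths and assign state 1 to the tips with the largest
  values. Because thresholding is rank-based, D is invariant to the
  Brownian rate; `sigma2 = 1` is the default and a property test asserts
  the invariance.

$D=(d_{obs}-\bar d_B)/(\bar d_R-\bar d_B)$, with p-values oriented the way
each null is informative: `p_random` is the fraction of shuffles at least
as *conserved* ($d \le d_{obs}$), `p_brownian` the fraction of Brownian
draws at least as *overdispersed* ($d \ge d_{obs}$), both with the +1
correction. Default 1000 simulations per null (minimum 100).

Numerical choices: polytomies are resolved deterministically
(left-to-right, zero-length edges) because the recursion assumes
bifurcation — path lengths are preserved; branch lengths below 1e-9 are
floored to 1e-9 *only* inside weight computations that divide by length,
never in stored trees; a monomorphic trait is an error ("signal
undefined"), as is a degenerate scaling where the two null means coincide.

Internally the tree traversal is prepared once and simulated state vectors
are scored in vectorized batches, which is what makes the calibration
experiments below cheap.

## Bayes factors for partitioning schemes

$BF = 2(\ln M_1-\ln M_0)+(P_1-P_0)\ln(0.01)$ from harmonic-mean log
marginal likelihoods and free-parameter counts, with $\ln(0.01)$ in double
precision (not the rounded −4.6052). Evidence bands: (2, 6] positive,
(6, 10] strong, > 10 very strong, with right-closed boundaries (the band
endpoints are ambiguous in the usual verbal statement; a choice had to be
made) and everything ≤ 2 labelled `negative_or_weak`. `rank_schemes()`
orients each pair as later-listed vs earlier-listed model — the layout of
published partition-selection tables, simplest scheme first — and calls
"best" the model never disfavoured. Estimating marginal likelihoods from
MCMC traces is out of scope; the module consumes the summary table.

## Binarization at the third quartile

"Long-ovipositor" species are those whose AOS (or ROS) *strictly* exceeds
the third quartile of the species values. The quartile estimator is linear
interpolation at position $1+0.75(n-1)$ (`stats::quantile` type 7, the
common default of mainstream numeric stacks); ties at exactly Q3 are
"short" ("exceeding" read strictly). Neither the estimator nor the tie
rule is forced by the verbal definition, so both are recorded in the trait
attributes and report metadata. With 19 distinct values this yields
exactly 5 "long" species, or 4 when a tie straddles the interpolation
interval — the split the source analysis reports. For distinct values the
count of "long" species is $n-\lceil h\rceil+1$ for non-integer
$h = 1+0.75(n-1)$ and $n-h$ for integer $h$; the property tests assert
this closed form.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: 19 parasitoid species on a Yule tree (birth rate 1);
~121 measured individuals (2–12 per species, mean 7, two singleton
species); species-true AOS drawn uniformly in 398–1179 μm and ROS in
0.58–1.16; host ranges for 13 of the species, drawn from 95 host species
in 22 families and 6 orders on 18 plant families; strict specialists with
probability 3/13 and generalist host counts uniform in 2–21. Measurement
noise is multiplicative lognormal with a 5% coefficient of variation —
lengths are positive and ratios should be scale-free, and no error model
is dictated by the data, so a modest lognormal is the natural choice.
Taxonomy sizes are exact by construction (the first members of each level
seed the level above).

Host assignment has two regimes. In the default no-signal regime every
quantity is drawn independently of the tree, which makes the generator a
null machine for calibration. In the signal regime a Brownian latent
affinity per host order is simulated on the tree and hosts are drawn with
probability proportional to the parasitoid's affinity for their order —
reusing the package's own Brownian machinery rather than inventing a new
clustering process — so related parasitoids share host orders and the
D-statistic's power can be exercised.

What the synthetic data do *not* emulate: real measurement error structure
(allometry, observer effects), uneven rearing effort (every recorded host
is equally detectable), non-Yule tree shape, and any correlation between
ovipositor length and host use. Passing calibration on these data shows
the machinery is unbiased and correctly sized under its own assumptions —
it does not validate the biological conclusions one would draw from real
data.

## Calibration experiments and problem sizes

The test suite runs the calibration at sizes chosen to keep the full suite
in the few-minute range while leaving Monte-Carlo error well inside the
asserted bands:

* *D recovery*: 200 Yule trees of 19 tips, prevalence 5, 1000 simulations
  per null; mean D within [0.8, 1.2] under shuffled traits and
  [−0.2, 0.2] under Brownian-threshold traits;
* *Mantel calibration*: 1000 independent 13×13 matrix pairs at 999
  permutations, two-sided rejection at α = 0.05 within [0.03, 0.07]; 500
  independent triples for the partial test, p-values uniform by a KS
  check;
* *global null calibration*: 100 complete no-signal studies through the
  whole pipeline (499 permutations, 250 simulations), pooling every Mantel
  p-value and every D-test `p_random` — each test compared against the
  null its data were generated under; the significant fraction stays within
  0.05 ± 0.03. (`p_brownian` is *excluded* from this pooling: traits that
  are random with respect to the tree are genuinely overdispersed relative
  to a Brownian null, so rejecting it is correct behaviour, not a false
  positive.)

Reports are deterministic: a master seed scopes the whole pipeline run,
every result records the parameters that produced it, and serializing the
same configuration twice yields byte-identical JSON. Raw p-values are
reported with no multiple-testing correction, and the report says so
explicitly.

## Known limitations

* The D statistic's printed values for any particular empirical dataset
  depend on that dataset and on simulation counts; with the synthetic
  generator the package demonstrates distributional correctness, not
  numerical replication of any published D value.
* Partial Mantel tests have well-known inferential caveats under spatial
  or phylogenetic autocorrelation of the conditioning matrix; the package
  implements the standard procedure and leaves interpretation to the
  analyst.
* The harmonic-mean marginal-likelihood estimator is known to be unstable;
  the Bayes-factor module deliberately treats it as given input rather
  than estimating it.
* Host-range incidence treats detection as perfect; unequal sampling
  effort across parasitoid species is the main caveat for real rearing
  data (the source analyses address it with a robustness variant recoding
  rarely collected species as specialists, which the pipeline exposes via
  `rare_species`).
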