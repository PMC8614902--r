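---
title: "Dominant-marker genetic diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker genetic diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdiv)
```

## The problem

Dominant marker systems — RAPD, ISSR and REMAP — fingerprint a genome as an
anonymous panel of PCR fragments scored only as present (1) or absent (0)
per individual. Because a heterozygote is indistinguishable from a dominant
homozygote, the data carry no allele frequencies, only band-sharing
information. They remain a fast and inexpensive way to compare the genetic
diversity of plant populations, in particular to ask whether invasive
populations have lost diversity relative to native or source material
(bottlenecks and founder effects) or rebuilt it (multiple introductions,
admixture, cross-pollination).

`markerdiv` implements the complete analysis chain for such data: binary
band matrices, Nei–Li band-sharing diversity within and between
populations, population consensus profiles, summary tables with ratios and
differences, and UPGMA dendrograms with bootstrap support. A simulator with
known truth makes every stage testable even when the original
per-individual matrices are unavailable.

## The diversity statistic

For two binary profiles $x$ and $y$ the Nei–Li genetic diversity is

$$Gd(x,y) \;=\; 1 - \frac{2\,N_{xy}}{N_x + N_y},$$

where $N_x$ and $N_y$ are the numbers of bands present in each profile and
$N_{xy}$ the number present in both. It is the complement of the Dice/
Sørensen band-sharing similarity: 0 exactly when the two presence sets
coincide, 1 when they are disjoint. It is symmetric and bounded but is not
a metric (the triangle inequality can fail), which is no obstacle to
average-linkage clustering. We deliberately read $N_x$ and $N_y$ as *total*
band counts: the alternative reading — bands present in one profile but
absent in the other — makes the expression ill-defined for identical
profiles (0/0) and unbounded above 1, and cannot reproduce the value ranges
that band-sharing studies report. The degenerate pair of two all-empty
profiles is scored 0 (their presence sets are identical and empty), with a
warning, so that sparse bootstrap replicates cannot crash a run.

* Within a population (or pooled unit) of $k$ samples, diversity is
  summarized by the min / mean / max over all $k(k-1)/2$ pairs; units with
  a single sample are rejected for within-unit analysis but still usable
  between units.
* Between units, each unit is first reduced to a **consensus profile**:
  band $j$ is present when more than half of the unit's samples carry it.
  A band carried by exactly half of an even-sized unit is a tie; the
  default scores it absent — the conservative choice, consistent with
  scoring only consistently detected bands — and `tie = "present"` flips
  the rule. The tie rule is a genuine unknown of consensus scoring, which
  is why it is a visible, logged option rather than a constant.

Reported precision follows the field's table conventions: three decimals
for Gd, one decimal for ratios, with half-up rounding (`round_half_up()`),
not banker's rounding.

### Combining marker systems

Two defensible definitions exist for "RAPD + ISSR + REMAP combined"
diversity, and published tables rarely say which was used. The default here
is **column concatenation**: the per-system matrices are joined into one
matrix before any distance is computed, which weights each system by its
fragment count. The alternative, `combination = "average"`, averages the
per-system distance matrices, weighting systems equally. Concatenation is
the default because a combined mean diversity computed from concatenated
columns is generally *not* the average of the per-system means — the
discrepancy observable between reported combined values and per-system
averages points to concatenation — and because it keeps the combined matrix
available for character bootstrap.

## Dendrograms

`upgma()` implements Unweighted Pair Group Method with Arithmetic Mean:
the closest pair of clusters merges at a node of height $d/2$, and
cluster-to-cluster distance is the arithmetic mean over all cross pairs
(size-weighted update). Heights in $d/2$ units make branch lengths read
directly in Gd, and every root-to-leaf path has equal length (ultrametric
to $10^{-9}$, enforced by tests). Average-linkage merge heights are
non-decreasing, so the dendrogram is monotone by construction.

Exact ties between candidate merges are broken deterministically: the pair
whose smallest member labels sort lexicographically first merges, and
children of every node are laid out in the same order. Ties have measure
zero for real-valued data; the rule exists so that tests, logs and repeated
runs are byte-identical. The implementation is intentionally the plain
$O(n^3)$ algorithm — population trees here have tens of leaves at most —
and is cross-checked in the test suite against `stats::hclust(method =
"average")`, an independent implementation, on hundreds of random matrices.

Trees are `ape::phylo` objects; `to_newick()` writes standard Newick with
branch lengths and integer internal-node support labels.

### Bootstrap support

`bootstrap_support()` resamples **band columns** with replacement (the
characters), not samples: the tree's leaves are populations and resampling
individuals would change the consensus profiles' meaning, whereas character
resampling is the standard nonparametric bootstrap for marker trees. When
the matrix combines several systems, resampling is stratified by system so
every replicate keeps the observed RAPD/ISSR/REMAP composition. Each
replicate reruns the entire chain (consensus → Gd → UPGMA), and each
internal node of the observed tree is annotated with the percentage of
replicates whose tree contains the same leaf bipartition (canonicalized as
the side not containing the alphabetically first leaf). Support is attached
to the observed topology, not to a majority-rule consensus tree, matching
how classical dendrogram figures are annotated. The root's bipartition is
trivial and left unannotated. One seeded generator drives a run
(default seed 20211025); the same seed reproduces the annotated tree
exactly, and the seed is written to the run log.

## The simulator

`simulate_markers()` generates data with the structure this analysis
assumes, plus known truth for recovery tests. Three band classes mirror
what dominant-marker studies of structured plant populations report:

* **species-monomorphic** bands fixed present in every sample
  (`monomorphic_fraction`, default 0.10);
* **population-diagnostic** bands private and fixed in one population
  (`diagnostic_fraction`, default 0.05, assigned round-robin);
* **ordinary** bands: ancestral frequency $\pi_j \sim
  \mathrm{Beta}(a, b)$ (default $\mathrm{Beta}(1,1)$), population frequency
  from the Balding–Nichols distribution
  $f_{pj} \sim \mathrm{Beta}\!\big(\pi_j \tfrac{1-\theta}{\theta},\,
  (1-\pi_j)\tfrac{1-\theta}{\theta}\big)$, presence
  $\sim \mathrm{Bernoulli}(f_{pj})$ independently per sample.

Balding–Nichols was chosen because it provides a single interpretable
differentiation knob $\theta \in [0,1)$ while keeping frequencies in
$[0,1]$; $\theta = 0$ means panmixia ($f_{pj} = \pi_j$). Bands are
independent given frequencies (dominant fingerprinting loci are scored as
anonymous independent characters), and dominance is modelled directly at
the band level — presence probability equals band frequency — because only
band presence is ever analyzed. Scoring error is deliberately not
simulated; the matrices emulate idealized, consistently scored bands. The
defaults (4 populations × 10 samples, 60/40/25 RAPD/ISSR/REMAP bands,
$\theta = 0.15$) give within-population diversities in the 0.2–0.4 range
typical of such studies; raising $\theta$ and seed-stock heterogeneity
moves the data from the within &gt; between regime to the between &gt;
within regime, so both patterns seen in real invasions are reachable.

What passing simulation tests does **not** show: robustness to band-calling
error, size-homology mistakes across gels, linkage between fragments, or
non-equilibrium demography. Conclusions about real datasets inherit those
caveats.

### Closed-form expectation

For a population with independent band frequencies $f_j$,
$E[N_{xy}] = \sum_j f_j^2$ and $E[(N_x+N_y)/2] = \sum_j f_j$ for two random
members, so

$$E[Gd] \;\approx\; 1 - \frac{\sum_j f_j^2}{\sum_j f_j},$$

a ratio-of-expectations approximation (`expected_within_gd()`), accurate
when many bands contribute to the denominator. `recovery_experiment()`
simulates, runs the observed pipeline, and reports the absolute error
against this expectation; at 2 populations × 30 samples × 300 bands and
$\theta = 0.05$ the maximum error is well inside 0.02, and the test suite
also verifies the formula against a Monte-Carlo oracle within three
standard errors.

## Numerical and design choices

* **Band identity** is the exact (system, primer, fragment size) triple:
  scoring "the same size" bands is assumed done upstream on the gels, so no
  size-tolerance binning is attempted here. This is a convention, not a
  biological claim; homologizing near-identical sizes across gels is an
  open problem of the data type.
* **Strict diagnostics by default**: `find_diagnostic_bands()` uses 100%
  presence/absence (an optional frequency threshold relaxes it), because
  diagnostic fragments are described categorically in practice.
* **Degenerate inputs**: matrices must be strictly binary (anything else is
  an error with coordinates), single-sample units are rejected for
  within-unit diversity, empty band sets are refused on write, and
  distance matrices are validated for symmetry, zero diagonal and the
  $[0,1]$ range before clustering.
* **Determinism**: every stochastic routine takes a seed, restores the
  caller's RNG state on exit, and the pipeline derives per-tree seeds from
  the run seed by sorted system name, so outputs are invariant to the
  order in which matrices are listed.
* **Problem sizes in the tests**: the property suites use matrices up to
  50 samples and 12-leaf trees (200 random instances against the
  independent average-linkage oracle), the recovery experiment uses
  2 × 30 × 300 with $\theta = 0.05$, and drift monotonicity averages 20
  seeds at 2 × 8 × 120 — sizes chosen to make sampling error negligible
  relative to the tolerances while keeping the whole suite fast.

## Worked example

```{r example}
lup <- markerdiv_example("lupin_between_gd")
unlist(gd_range(lup))

tree <- upgma(lup)
to_newick(tree)
```

The matrix minimum (0.196, Moscow–Kaluga) becomes the first merge at
height 0.098, and the variety splits off at the root — varieties are bred
from narrow stocks and sit apart from naturalized material.

```{r simulate}
cfg <- sim_config(n_populations = 2, samples_per_population = 10,
                  bands_per_system = c(RAPD = 60, ISSR = 40, REMAP = 25),
                  differentiation = 0.3, seed = 42)
rec <- recovery_experiment(cfg)
rec$per_population
```

## Known limitations

* Nei–Li Gd from dominant bands is a band-sharing dissimilarity, not an
  estimate of expected heterozygosity; no dominant-marker allele-frequency
  corrections (e.g. Lynch–Milligan), AMOVA or F-statistics are provided.
* Neighbor-joining, likelihood and parsimony trees, and majority-rule
  consensus trees are out of scope; UPGMA assumes rate constancy across
  lineages, which band-sharing data cannot test.
* The consensus-profile reduction discards within-unit frequency
  information; two units can have identical consensus profiles (Gd 0)
  while differing in band frequencies.
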