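---
title: "Methods: autotetraploid linkage mapping, map integration and map-based scaffolding"
author: "tetramap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autotetraploid linkage mapping, map integration and map-based scaffolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tetramap` implements the computational core of a genetic-map-driven genome
project in an outcrossing autotetraploid (2n = 4x, eight chromosomes in the
motivating crop): simulation of F1 crosses under polysomic inheritance,
two-point linkage estimation from SNP dosage data, linkage-group and
homologue assignment, marker ordering, LOD^2-weighted integration of two
population maps, marker-based anchoring of contigs into AGP/FASTA
pseudomolecules, Marey-map recombination-landscape statistics, and
BUSCO-driven assembly purging with standard assembly metrics. Everything
runs on desk-scale synthetic data; no external sequencing data is needed.

# The inheritance model

All estimation assumes **bivalent polysomic inheritance**: at meiosis the
four homologues of a chromosome form two bivalents, the three possible
pairings being equally likely, and the gamete receives one recombinant
chromatid per bivalent. For a marker pair with parental dosages and a phase
(the number of homologues carrying both alleles — coupling is the maximal
overlap, repulsion the minimal), the two-locus gamete distribution follows
by exhaustive enumeration of pairing, chromatid choice and a recombination
indicator with probability $r$ per chromatid. These probabilities are exact
quadratics in $r$; offspring joint-dosage class probabilities (the
convolution over the two parents) are exact quartics, which the estimators
exploit by caching polynomial coefficients per segregation-type/phase
combination.

The two-point estimate maximises the multinomial likelihood of the 5x5
offspring joint dosage table over $r \in [0, 0.5]$ for every candidate
phase (bounded search, tolerance $10^{-6}$; boundary points checked
exactly), picks the phase with the highest maximised likelihood (ties
toward coupling, whose linkage signal drives homologue assignment), and
reports $\mathrm{LOD} = \log_{10} L(\hat r) - \log_{10} L(0.5)$. At
$r = 0.5$ the class distribution is phase-free, so the LOD base line does
not depend on the chosen phase. A batch path groups pairs by
segregation-type combination and replaces `stats::optimize` with a coarse
grid plus vectorised golden-section refinement; unit tests pin the two
paths together at $10^{-5}$.

Repulsion-phase pairs carry intrinsically less information than coupling
pairs in a tetraploid (their class probabilities respond weakly to $r$),
which is why accuracy statements about $\hat r$ (e.g. mean absolute error
$\le 0.02$ at $n = 500$, $r \le 0.2$) are made for coupling-phase pairs;
the pooled error across all phases is a few-fold larger for the same data.

# The simulator and its stated world

`sim_config()` defaults describe the motivating design: 8 chromosomes, 200
markers per chromosome, F1 sizes 187 (population 1) and 248 (population 2),
`co_rate` $\lambda = 2.8$ crossovers per bivalent (one obligate plus
Poisson extras; a transmitted chromatid participates in each crossover with
probability 1/2, giving $50\lambda = 140$ cM chromosomes, matching the
published map lengths), 1% dosage-call error, 3% missingness, a 20%
quadrivalent rate and a 4.5% marginal double-reduction (DR) rate — the
level observed at the telomeres of all chromosomes in the study that
motivated this package.

Choices worth spelling out:

* **Crossover thinning.** A crossover involves two of the four chromatids
  of a bivalent. The transmitted chromatid therefore switches homologue at
  each crossover with probability 1/2, not deterministically; omitting this
  doubles all map lengths.
* **Quadrivalents** are simplified to a pairing-partner exchange at the
  centromere: left-arm and right-arm bivalent pairings are drawn
  independently and the transmitted chromatid continues across the
  centromere into the right-arm pairing. Full multivalent chromatid
  bookkeeping is not attempted; the simplification suffices to generate the
  telomeric DR signal the estimators target.
* **Double reduction.** `double_reduction_rate` is the *marginal*
  per-gamete probability of a DR gamete (two sister-derived copies of one
  homologue); mechanistically DR only arises in quadrivalents, so the
  conditional rate is $\alpha / q$ and $\alpha \le q$ is enforced. A DR
  gamete carries two copies of a uniformly chosen homologue for the whole
  chromosome (recorded exchange point at the centromere). Arm-resolved
  sister bookkeeping would halve the per-telomere DR signal without any
  mechanistic guidance from the source study; the chosen model makes the
  DR estimator's expectation exact: the dosage-2 frequency at a simplex x
  nulliplex marker is $\alpha/4$, hence $\hat\alpha = 4 n_2 / n$.
* **Crossover density** defaults to `uniform`, although the motivating
  species recombines pericentromerically. Marker order inside a
  recombination desert is genetically unidentifiable, so ordering-accuracy
  tests presuppose an identifiable (uniform) landscape; the
  pericentromeric and distal densities (Beta-type, one concentration
  parameter) are exercised by the Marey-map tests, where they are the
  object of study.
* **Segregation mix.** Defaults allocate 35% / 35% to maternal/paternal
  simplex x nulliplex (the workhorse marker class), 15% to simplex x
  simplex (the only cross-parent bridge) and 15% to duplex types. The mix
  is configurable; forced mixes (e.g. all `1x0`) are used throughout the
  tests.

What a green test does **not** establish: the generator produces no
array-intensity artefacts, no segregation distortion, no null alleles, no
linkage between chromosomes, and errors are independent across calls —
real Axiom data violate all of these to some degree.

# Map construction

The pipeline mirrors standard polyploid-mapping practice: missingness
filters (defaults 10% per marker and individual — the source study states
no thresholds, so they are exposed as configuration), merging of duplicate
individuals (identity $\ge 0.98$ over shared calls; conflicts become
missing), masking of dosage calls impossible under a marker's segregation
type (miscall artefacts that would otherwise zero out likelihoods),
binning of markers with identical dosage vectors, LOD-ladder clustering
(default ladder 3, 4, 5, 6, 7, 10) of simplex markers into the expected
number of linkage groups, coupling-graph homologue assignment with
1x1-marker bridging, and marker ordering.

Ordering minimises the weighted 1-D stress
$\sum_{ij} w_{ij} (|x_i - x_j| - d_{ij})^2$ with Haldane distances
$d = -50\ln(1-2r)$ and weights $w = \mathrm{LOD}^2$. The solver combines
spectral seriation starts (Fiedler vectors of the plain and the normalised
weighted Laplacian — the plain one can collapse onto a weakly connected
marker, the normalised one is robust to degree spread), a 1-D weighted
SMACOF majorisation, single-marker repositioning over the piecewise-
quadratic breakpoints, block reversals (2-opt) to unfold mirrored
segments, and adjacent swaps; the best final stress across starts wins.
Restarts use fixed internal seeds, so ordering is deterministic given the
pairwise data. Ill-fitting markers are removed one at a time while the
worst nearest-neighbour stress exceeds 3x the group median *and* the
marker's rms residual exceeds an absolute floor (default 5 cM, several
times the adjacent-distance noise at these sample sizes; without the
floor the relative rule never self-terminates on clean data, whose median
stress is near zero), capped at 20% of the group; binned duplicates
re-enter at their representative's position. Homologue assignment accepts
the first LOD threshold yielding at most four non-trivial coupling
clusters per parent and attaches weakly linked leftovers by their best
summed coupling LOD. The Haldane function is used throughout (the source study names
no map function); it is the no-interference default consistent with
two-point data.

# Map integration

Pairwise linkage data from the two populations are merged by the published
rule: for shared pairs both $r$ and LOD are averaged with weights equal to
the squared LOD scores; one-sided pairs are copied unchanged; ordering and
fine-tuning are rerun on the merged data. A chromosome represented in only
one population is carried over unchanged (the study's chromosome-6 rule).
Phases are population-specific and are not re-estimated after merging (the
source is silent; only $r$/LOD are combined). The consensus re-ordering
warm-starts from the input maps' positions (population 2 aligned to
population 1 through shared markers): where the merged data cannot
distinguish two orders, the consensus stays with the populations' maps
instead of wandering between statistically equivalent local optima. One
consequence is that integrating a population with itself reproduces the
input map up to the data's own resolution — re-applied fine-tuning may
still flip near-coincident neighbours — rather than byte-identically.

# Anchoring and landscape

Marker-contig alignments pass the published filters (coverage $\ge 0.98$,
identity $\ge 0.95$, unique mapping position, at most 4 genome-wide hits,
at most 350 probes per contig, the cap keeping the highest-identity
probes). Contigs take the majority linkage group of their markers (ties
are unresolved conflicts and are dropped), are ordered by weighted mean cM
and oriented by the sign of the Spearman correlation between within-contig
bp and cM when two markers with distinct cM support it. Pseudomolecules
concatenate contigs with 100 N per junction — the published gap total
(30,800 N for 316 contigs in 8 chromosomes, i.e. 308 junctions) forces
exactly 100 — and the AGP v2.1 table is emitted alongside and checked
against the FASTA.

Marey maps plot genetic against physical position. After orienting the
genetic axis so the Spearman $\rho \ge 0$, an isotonic fit gives a
monotone Marey curve, from which the **central-tertile fraction**
$C = (g(2L/3) - g(L/3)) / g(L)$ is read. $C$ and its thresholds are
package-defined to make the qualitative proximal/distal dichotomy
testable: uniform recombination gives $C = 1/3$; $C > 0.5$ is classified
`proximal` (the pericentromeric landscape the motivating study reports),
$C < 0.25$ `distal`, otherwise `mixed`. Synteny comparison sorts shared
markers by position on assembly A and reports maximal runs of
monotone-decreasing B positions of length $\ge 5$ as candidate inversions
and off-chromosome markers as translocation candidates.

# Assembly statistics and BUSCO purge

N50/L50 use the sorted cumulative half-total rule; GC is computed over
non-N bases; percentages round half away from zero to one decimal
(matching the published 38.3 / 94.3 / 97.2-style figures). The purge
selects a minimal contig set optimising single-copy BUSCO content by
greedy maximum coverage — repeatedly add the contig completing the most
not-yet-covered orthologs, ties broken by fewer added duplicate hits, then
larger contig, then name — stopping when nothing new is covered. The
original study describes its purge only as pseudocode in supplementary
material not available to this package, so the greedy rule is adopted
explicitly and validated against exhaustive subset search on small
instances rather than guessed control flow. Because greedy max-coverage
can overshoot the minimum cover by one contig on adversarial instances,
selections over at most 15 hit-bearing contigs are certified by
exhaustive search and replaced when a strictly smaller cover exists; at
genome scale the greedy solution stands.

The genome-size estimate is the coverage-peak rule: total sequencing yield
divided by the first k-mer-spectrum peak gives the full (4n) complement;
dividing by the ploidy gives the per-copy size.

# Numerical choices and degenerate inputs

* Likelihood evaluation floors probabilities at $10^{-300}$; classes with
  observed counts that are impossible under *every* candidate phase raise
  a data-consistency error (single-pair path) — the batch path is fed by
  the filter that masks such calls first.
* $r$ is capped at 0.49 before the Haldane transform in ordering
  ($d \approx 195$ cM), keeping weights finite; such pairs carry ~zero
  weight anyway.
* Maps are shifted so the minimum position is 0; group lengths are the
  maximum position.
* `order_markers` refuses a disconnected pairwise graph (listing component
  sizes) and two-marker groups are placed analytically.
* Marey statistics require $\ge 5$ markers and $\ge 2$ distinct physical
  positions per chromosome; isotonic fits use `stats::isoreg` with mean
  tie-handling.

# Known limitations

* The two-point engine models bivalent pairing only; quadrivalent-induced
  dosage classes are treated as noise (masked when impossible), matching
  the source study's practice of mapping with bivalent tools and reporting
  DR separately.
* Homologue assignment reports at most four coupling clusters per parent
  and leaves cross-parent matching undetermined without 1x1 markers.
* The consensus integrates exactly two populations.
* Orientation of single-marker contigs is undetermined by construction;
  they are placed unoriented, as in the source study's scaffolding.
* The greedy purge is validated to the exhaustive optimum only at small
  instance sizes; at genome scale it is a heuristic with the usual greedy
  max-coverage guarantee.
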