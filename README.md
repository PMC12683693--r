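# tetramap

Linkage mapping, map integration and map-based scaffolding for
**autotetraploid F1 populations** genotyped with SNP-array dosage calls.

Genetic maps in outcrossing autotetraploids (2n = 4x; leek is the
motivating crop: 8 chromosomes, two F1 populations of 187 and 248 plants)
cannot be built with diploid tools: every marker has a parental dosage in
0..4, four homologues pair at random into bivalents (polysomic
inheritance), quadrivalents produce double-reduction gametes, and phase
(coupling/repulsion) must be estimated together with the recombination
fraction. `tetramap` provides the full computational chain:

* **simdata** — simulate parental genomes and F1 dosage matrices under
  polysomic meiosis with configurable crossover rate/density (uniform,
  pericentromeric, distal), quadrivalent rate `q`, marginal
  double-reduction rate `alpha`, dosage-error rate and missingness, with a
  complete ground-truth record for parameter-recovery testing.
* **tetrapoint** — exact two-locus gamete probabilities under the bivalent
  model (enumeration of the 3 equiprobable pairings), maximum-likelihood
  two-point estimation of `r` and `LOD = log10 L(r̂) − log10 L(0.5)` with
  phase selection, a vectorised batch path for genome-scale pair lists,
  the double-reduction estimator `α̂ = 4 · freq(dosage 2)` at simplex ×
  nulliplex markers, and a preferential-pairing chi-squared test.
* **mapbuild** — missingness filtering, duplicate-individual merging,
  duplicate-marker binning, LOD-ladder clustering into linkage groups,
  coupling-graph homologue assignment bridged by 1x1 markers, and marker
  ordering by weighted 1-D least squares on Haldane distances
  (`d = −50 ln(1 − 2r)`, weights `LOD²`) with spectral-seriation starts,
  SMACOF majorisation, block reversals and ill-fit pruning.
* **mapmerge** — integration of two populations' pairwise linkage data by
  the published rule (`r` and `LOD` averaged with weights `LOD²`),
  re-ordering on the merged data, single-population carry-over for
  chromosomes absent from one population.
* **anchor** — marker–contig alignment filtering (coverage ≥ 0.98,
  identity ≥ 0.95, unique position, ≤ 4 hits, ≤ 350 probes/contig),
  majority-vote contig placement, weighted-mean-cM ordering,
  rank-correlation orientation, pseudomolecule FASTA + AGP v2.1 emission
  (100 N per junction), Marey-map statistics (Spearman ρ, central-tertile
  fraction `C`, proximal/distal classification) and marker-based synteny
  comparison (inversion/translocation candidates).
* **asmstats** — N50/L50/GC assembly reports, BUSCO full-table parsing and
  summaries, the BUSCO-optimising contig purge (greedy minimal covering
  set, exhaustively certified on small instances), and the coverage-peak
  genome-size estimate.
* **io_cli** — TSV/JSON/FASTA/AGP readers and writers, a validated JSON
  pipeline configuration, `run_pipeline()`, and a subcommand CLI at
  `inst/cli/tetramap.R`.

## Worked example

```r
library(tetramap)

cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 80,
                  n_offspring = 187, quadrivalent_rate = 0,
                  double_reduction_rate = 0, dosage_error_rate = 0,
                  missing_rate = 0, seed = 3)
parents <- simulate_parents(cfg)
sim <- simulate_f1(parents, cfg)
sim$dosage
#> <dosage_matrix> 160 markers x 187 individuals (0.0% missing)

bm <- build_map(sim$dosage, n_groups = 2)
bm
#> <genetic_map_build>
#>  linkage_group markers length_cM
#>              1      64   126.464
#>              2      64   123.189
```

Two linkage groups of ~125 cM emerge from 187 offspring — the expected
`50 × co_rate = 140` cM chromosome length, shortened slightly by edge
markers pruned as ill-fitting. The textbook two-point table — 48 offspring
in each parental class, 2 in each recombinant class — where the closed
form `(n10 + n01)/n = 0.04` must equal the MLE:

```r
cc <- matrix(0, 5, 5)
cc[1, 1] <- 48; cc[2, 2] <- 48; cc[2, 1] <- 2; cc[1, 2] <- 2
estimate_two_point(cc, classify_segregation(1, 0), classify_segregation(1, 0))
#> <two_point> r = 0.0400, LOD = 22.81, phase = coupling/none, n = 100
```

The genome-size worked example:

```r
genome_size_estimate(883e9, 14, ploidy = 4)$full_complement / 1e9
#> [1] 63.07143   # ~63 Gbp 4n complement, 15.75 Gbp per copy
```

## CLI

```sh
Rscript inst/cli/tetramap.R pipeline --seed 1 --out out/
Rscript inst/cli/tetramap.R twopoint --dosage dosage.tsv --out out/
Rscript inst/cli/tetramap.R stats --fasta contigs.fasta
```

See `vignettes/tetramap-methods.Rmd` for the model, its assumptions, the
simulator's stated world, numerical choices and known limitations.
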