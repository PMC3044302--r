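# clustersim

Simulation of gene-cluster evolution — segmental duplications, deletions
and interlocus **gene conversions** interleaved with HKY85 nucleotide
substitutions on a three-species primate-like tree — with exact tracking
of every true orthologous and paralogous alignment, and scoring of
conversion-detection predictions against the known truth.

## Who this is for

Gene conversion copies part of one paralogous segment onto the
homologous stretch of another, making the converted tract locally
identical and turning each copy into a mosaic of regions with different
divergences.  Tools that claim to detect such events (GENECONV, RDP,
phylogenetic HMMs, similarity scanners, ...) can only be benchmarked
where the true history is known.  `clustersim` generates such ground
truth: realistic cluster histories, the true alignments at basepair
resolution, detector-ready input alignments, and sensitivity/FDR scoring
of any detector's output.

## The model in brief

* **Tree**: New World monkey (NWM), Old World monkey (OWM), human.
  Branch lengths are calibrated so the ungapped identities hit their
  targets (defaults: NWM–human 89%, OWM–human 93%) by solving
  `Σ_i π_i P_ii(T) = target` for the total separation time `T`, where
  `P(t) = exp(Qt)` is the HKY85 transition matrix (κ = 4 by default,
  rate matrix normalised to 1 expected substitution/site/unit time) and
  a molecular clock splits `T` equally.
* **Events**: per epoch, `d` duplication-category events per lineage
  (becoming deletions with probability 0.2) and, after the first split,
  `c` conversions per lineage — so each terminal species experiences
  `3d` duplication-category and `2c` conversion events, at uniform
  times.  Conversion partners are drawn uniformly from the full
  transitive paralogy closure (if A→B and B→C were duplications, (A,C)
  is eligible too).
* **Selection** (optional): conserved elements covering 5% of the
  ancestor, geometric lengths of mean 110 bp, evolving 30% slower than
  neutral sites (`rate_factor = 0.7`).
* **Truth**: every alignment is a gapless interval pair maintained in
  current coordinates through every edit — split by insertions,
  trimmed/removed by deletions, with conversion tracts tracked the same
  way — so the final orthologs, paralogs and converted basepairs are
  known exactly.
* **Metrics**: per-basepair and pair-level ("existence") sensitivity
  and false discovery rate, per replicate and averaged per `(d, c)`
  setting.

## Worked example

```r
library(clustersim)

cfg <- simulation_config(d = 3, c_conv = 2)      # lightest study setting
rep <- run_replicate(cfg, seed = 1)
rep
#> <cs_replicate seed=1: d=3 c=2, 28 events, 45 paralogous pairs, 12 conversion tracts>

head(rep$events[, c("event_id","lineage","epoch","kind","src_start","src_end")], 3)
#>   event_id lineage epoch        kind src_start src_end
#> 1       e1    stem     1 duplication     30916   33607
#> 2       e2    stem     1 duplication    130052  137119
#> 3       e3    stem     1 duplication    129185  134815
```

The replicate holds three terminal sequences (here 249,228 bp for NWM,
252,014 bp for OWM and 225,616 bp for human, grown/shrunk from the
200 kb ancestor by duplications and deletions), the truth store, the
event log, the final paralogous-pair catalog and the conversion truth.
`write_outputs(rep, "out/rep1")` emits per-species FASTA, the true
alignments as MAF, per-homolog-set aligned FASTA and PHYLIP (what you
feed a detector), conserved-element BED, and TSV tables of events,
conversion tracts, pairs and per-pair converted basepairs.

Scoring a detector's predictions (TSV: `pair_id seq_id start end`;
coordinates 0-based half-open) against a written replicate:

```r
report <- evaluate_outputs("out/rep1", "my_detector_calls.tsv")
```

Feeding the truth back in as a prediction demonstrates the metric
identities:

```r
evaluate_replicate(rep, truth_as_predictions(rep$truth))
#>   bp_sensitivity bp_fdr existence_sensitivity existence_fdr true_bp true_pairs
#> 1              1      0                     1             0   14308          8
```

Here 14,308 basepairs across 8 paralogous pairs are truly converted; a
perfect detector recovers all of them with no false calls, so both
sensitivities are 1 and both FDRs 0.  A real detector's numbers fall in
between; `aggregate_replicates()` averages them over replicates per
`(d, c)` setting.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/clustersim.R simulate --config config.yaml --out DIR --seed 5
Rscript inst/cli/clustersim.R evaluate --truth DIR/rep1 --pred calls.tsv --out report.tsv
```

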