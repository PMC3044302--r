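---
title: "Simulating gene-cluster evolution with gene conversion: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene-cluster evolution with gene conversion: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustersim)
```

# Why simulate gene clusters

Gene clusters — genomic regions holding multiple similar copies produced
by segmental duplication — are notoriously hard to analyse because
interlocus gene conversion overwrites parts of one paralog with the
homologous stretch of another, leaving each copy a mosaic of segments
with different divergences.  Methods that claim to detect conversion can
only be benchmarked where the true history is known, and the only place
it can be known exactly is a simulation that (i) generates realistic
duplication/deletion/conversion histories and (ii) tracks every true
homology relation through every event.  `clustersim` provides that
simulator, the truth bookkeeping, true multiple alignments for feeding
external detectors, and the scoring of their predictions.

# The evolutionary model

## Species tree and divergence calibration

Three terminal species mimic New World monkeys (NWM), Old World monkeys
(OWM) and human.  NWM splits first, then OWM.  Branch lengths are not set
directly: the user supplies two target ungapped identities — NWM–human
(default 0.89) and OWM–human (default 0.93), typical of primate
orthologous DNA — and the model solves

$$\sum_i \pi_i P_{ii}(T) = \text{target identity}$$

for the total separation time $T$ by bisection (tolerance $10^{-10}$),
where $P(t) = e^{Qt}$ is the HKY85 transition matrix.  A molecular clock
splits $T$ equally between the two descendant lineages, which fixes the
three epoch durations: the inter-split segment lasts
$(T_{\mathrm{NWM}}-T_{\mathrm{OWM}})/2$ and the post-OWM-split segment
$T_{\mathrm{OWM}}/2$ on every lineage alive.  The stem above the first
split carries events but, by default, no substitution time
(`stem_time = 0`): a shared stem shifts all sequences identically and
leaves every pairwise divergence unchanged, so the ancestor is simply
taken to be the sequence at the first split.

## Substitutions

Small-scale mutation is substitution-only under HKY85
($\kappa$ default 4, equilibrium frequencies estimated from the
ancestral sequence), with the rate matrix normalised to one expected
substitution per site per unit time; all times in the package are
branch lengths in expected substitutions per neutral site.  Over each
inter-event gap of length $t$ every site draws its new base from the row
of $P(t)$ for its current base.  Applying the closed-form matrix over a
whole interval is distributionally identical to simulating individual
mutation events and much cheaper; $P(t)$ is computed from the spectral
decomposition of the reversible rate matrix (symmetrised with
$\sqrt{\pi}$), so no numerical matrix exponential is needed at run
time — a numerical `expm` serves as an independent oracle in the tests
instead.

## Purifying selection

In `"neutral+purifying"` mode, conserved elements are placed on the
ancestor with geometric lengths (mean `conserved_mean_len = 110` bp,
matching the 100–120 bp averages reported for mammalian conserved
elements) and uniform non-overlapping positions until they cover
`conserved_coverage = 0.05` of the sequence; overshoot is bounded by one
element length.  Conserved sites evolve with their elapsed time scaled by
`rate_factor = 0.7`, i.e. 30% slower than neutral sites.  Conserved
status is a property of *positions*: duplications copy the mask with the
segment, deletions excise it, and conversions leave it untouched (a
conversion replaces bases, not the selective regime of the locus).  Since
the ancestral placement happens before any event, all three species share
the mask in a substitutions-only run — which is exactly what makes the
rate-factor recovery measurable.

## Large-scale events

Each epoch carries `d` duplication-category events per lineage
(relabelled deletion with probability `p_del = 0.2`, since duplications
and deletions form one empirical category whose mix is not separately
known) and, from the second epoch on, `c` conversions per lineage; event
times are i.i.d. uniform within the epoch.  Every terminal species thus
experiences `3d` duplication-category and `2c` conversion events.

Event properties are drawn from configurable distributions
(`event_distributions()`).  Published empirical event-size tables for
gene clusters are not available in machine-readable form, so the package
ships parametric stand-ins on the scales typical of primate clusters —
log-normal lengths (duplication/deletion median 5 kb, conversion tract
median 1 kb), geometric source-to-copy spacing (mean 10 kb), 20%
inverted copies, symmetric conversion direction — and documents the
config schema so any empirical table can be substituted.

A duplication's source may span *any* current region, including parts of
earlier copies, so tandem stacks re-duplicate together naturally.  A
conversion chooses its pair uniformly from the lineage's full paralogy
closure (see below), draws a tract length (truncated to the pair
length), places the tract uniformly within the pair, samples a
direction, and overwrites the target with the homologous source text
(reverse-complemented across inverted pairs).  At the instant of
application the tract's pairwise identity is exactly 1 — the similarity
signal detectors exploit — and it decays again under subsequent
substitution.

If a conversion is scheduled before any paralogy exists, it is deferred
past the next event rather than dropped, so each lineage reaches its
quota whenever a pair ever forms; with `d = 0` and `c > 0` no pair can
ever form and the leftover conversions are dropped with a warning and
counted in the replicate.

# Truth tracking

All coordinates are 0-based half-open.  Because mutation is
substitution-only, every true alignment is *gapless* and is represented
as a `pairwise_map`: two equal-length intervals plus an orientation.
Ortholog maps start as the single full-length alignment created at each
species split; self maps are created by duplications.  Every insertion
or deletion remaps every affected map: shifted, truncated, or split when
the edit falls strictly inside (one duplication splits alignment *a*
into *a1*, *a2* and generates the copy's alignment *b*).  Partner sides
are trimmed at homologous offsets, mirrored across inverted maps.  Maps
shorter than `min_map_length` (default 50 bp) are dropped — composition
and truncation can shred alignments into fragments too short to
constitute meaningful paralogy, a regime the underlying model never
discusses.

Transitive paralogy is computed by map composition: if A was duplicated
to B and B to C, composing (A,B) with (B,C) yields (A,C), an eligible
conversion partner.  `paralog_closure()` iterates composition to a fixed
point but keeps only *maximal* homologies: a composed map whose
correspondence is already contained in a retained map adds no new
paralogy and is discarded.  This keeps the closure finite (fragments of
fragments would otherwise proliferate) and is what bounds the pair
catalog at a few hundred pairs in the heaviest setting.

Conversion tracts are themselves stored as pairwise maps (tract-on-A
versus tract-on-B), so subsequent edits split and shift them with the
same machinery and the truly converted basepairs are known exactly in
final coordinates.  At the end of a run each surviving tract piece is
attributed to every catalog pair that carries the *same* homologous
correspondence (an exact positional sub-map test, not mere interval
overlap), which prevents a conversion between (A,B) from being credited
to an unrelated pair that happens to overlap A.

The label-replay oracle used throughout the test suite gives every
ancestral basepair a unique label, replays all events on the label
vectors, and checks that every tracked map pairs equal labels — an
independent per-position re-derivation of the entire coordinate
bookkeeping.

# Detector inputs and scoring

For each catalog pair, the homologous set consists of the two paralogous
segments plus every orthologous segment in the other species, found by
composing the pair's sides with the ortholog maps.  Rows are literal
final-sequence substrings (no gap characters).  Members fragmented by
lineage-specific events are emitted block-wise: the pair's range is cut
at every member boundary and each block carries the members that fully
cover it, so each block is rectangular.  When several orthologs exist,
all of them are included.  Inverted members are reverse-complemented
into alignment orientation and flagged (`-` strand) in headers.

Predictions are tab-separated intervals per pair.  Four metrics are
computed: per-basepair sensitivity (detected converted bp / true
converted bp) and FDR (called bp not truly converted / called bp), and
their pair-level "existence" analogues, where one predicted basepair
anywhere on a truly converted pair counts as detection.  Both sides of a
converted tract count as truly converted by default; the
`direction_aware` flag restricts truth to the overwritten side.  The
basepair universe is the positions inside cataloged pairs — calls
outside any pair are rejected at parse time with a line number.  A pair
is counted once however many conversions hit it.  With no calls at all
the FDR is reported as 0 with an `empty_calls` flag.  Replicate reports
are averaged unweighted within each `(d, c)` setting, with per-metric
counts when a metric is missing for some replicates.

# Numerical and design choices

* **Coordinates** are 0-based half-open everywhere, including all output
  files (BED/MAF convention).
* **Insertion inside its own source** is disallowed at sampling time, so
  "copy the source, then insert" is unambiguous; the sampler places the
  copy a sampled spacing left or right of the source, clipped to the
  sequence bounds.
* **Deletions** never shrink a lineage below `min_seq_len` (default
  10 kb) so the cluster cannot delete itself away.
* **Inverted self maps** are eligible conversion partners by default
  (`allow_inverted_conversion`), since inverted duplications create true
  paralogy; the flag exists because detector conventions differ.
* **Conversion location vs. pair location** are parameterised
  independently: which pair converts is uniform over the closure, and
  where the tract falls inside the pair is a separate (uniform)
  distribution.
* **Determinism**: all randomness derives from one integer seed via
  per-(epoch, lineage) substreams, so identical configuration and seed
  reproduce byte-identical output files, and lineage processing order
  cannot leak randomness across lineages.
* **Calibration domain**: target identities must exceed the equilibrium
  identity $\sum_i \pi_i^2$ (the identity of unrelated sequences);
  anything lower is rejected rather than silently saturated.

# What the generator does and does not emulate

The generator reproduces the *structure* of gene-cluster evolution —
repeated, possibly nested and inverted segmental duplications, deletions,
conversions between any transitively paralogous pair, two-class
purifying selection, primate-calibrated divergences — under an i.i.d.
random ancestor (a user FASTA can substitute a real duplication-free
region; this changes base composition only).  It does not model small
indels, inversions, interspersed-repeat insertion, codon structure,
positive selection, rate heterogeneity beyond the two-class model,
population-genetic processes (allelic conversion, crossover), or more
than three species.  Benchmarks on these data therefore measure a
detector's ability to recover conversion tracts from substitution
patterns in structurally realistic paralogy, not its robustness to
alignment error (truth alignments are exact) or to indel noise.

# Problem sizes and verification

The test suite verifies the divergence calibration and the
purifying-selection recovery on 200 kb sequences (binomial /
delta-method error bounds at three standard errors), the coordinate
bookkeeping against the label-replay oracle on randomized histories,
the worked two-duplication scenario (three, then six ortholog
alignments), event quotas for all four `(d, c)` study settings, metric
identities (truth fed back as predictions scores sensitivity 1 and
FDR 0 at both levels), and byte-level determinism.  The acceptance
script re-runs the substitutions-only calibration, the conserved-element
placement, and a long (0.5 substitutions/site) purifying-selection
simulation chosen to make the rate-factor inversion well-conditioned,
and reports the resulting percentages.
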