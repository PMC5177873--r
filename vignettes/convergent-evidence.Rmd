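---
title: "Convergent-evidence prioritization: model, weights and benchmark"
author: "ceRank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent-evidence prioritization: model, weights and benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRank)
```

## The problem

For amorphous, heterogeneous phenotypes — musical traits being the motivating
case — molecular evidence is scattered over study designs that cannot be
meta-analysed on a common effect-size scale: genome-wide association and
linkage scans, candidate-gene tests, expression experiments in model
organisms (songbirds especially), and hormone or protein measurements. What
these studies do share is a reportable *detection*: a gene or biomarker was,
or was not, implicated. `ceRank` aggregates those detections by weighted vote
counting and ranks molecules by how convergently independent study types
report them.

## The model

Every study contributes one or more *evidence layers* — a gene-mapping study
reporting both association and linkage results contributes two, and a study
re-analysing several independent datasets contributes one per dataset. Layer
$i$ casts a vote of weight $w_i$ for each molecule in its detected set. For
molecule $g$ with binary detection indicator $e_{gi}$, the
convergent-evidence score is the weighted arithmetic mean

$$ CE_g = \frac{\sum_i w_i\, e_{gi}}{\sum_i w_i} \in [0, 1]. $$

The score is scale-invariant in the weights, reduces to the detection
fraction under uniform weights, and equals 1 only for a molecule detected by
every analyzed layer. No p-values or effect sizes enter: this is deliberate,
since most layers cannot supply them comparably, but it also means every
detection within a layer counts equally regardless of its within-study
strength.

### Layer weights

$w_i$ is a product of three self-importance factors, each on $[0.8, 1]$,
times a pairing penalty:

* **phenotype precision** — 1.0 when the study measured precisely the trait
  of interest, 0.8 for related phenotypes;
* **homology conversion** — 1.0 for human studies, 0.8 otherwise, reflecting
  the risk that cross-species homolog translation is wrong or incomplete;
* **sample size** — linear rescaling of the study's N onto $[0.8, 1]$
  *within* one of two pools (gene-mapping studies vs everything else), the
  pool's smallest study scoring 0.8 and its largest 1.0;
* **linkage pairing** — a linkage layer is multiplied by 0.9 when the same
  study also contributed an association layer, discounting the coarser of
  two non-independent vote sources. The association layer is never
  penalized.

Without the pairing penalty, weights span exactly $[0.8^3, 1] = [0.512, 1]$;
with it the floor is $0.8^3 \times 0.9 = 0.4608$.

Two edge cases are not dictated by the weighting scheme itself and were
decided here once: a pool in which all sample sizes are equal (including a
single-study pool) carries no size information and scores 1.0 rather than
penalizing the only study available; a *missing* sample size scores the floor
0.8 with a warning, the conservative reading. The rescaling uses raw N, not a
transformed scale. The factors are exact decimals multiplied in double
precision; scores are rounded (3 decimals) only when written to disk.

### Ranking, selection, stratification

Ties in $CE_g$ are real (many molecules share a single supporting layer), so
the ranking is made deterministic: score descending, then raw detection
count descending, then identifier ascending. The "top $q$ quantile" rule is
operationalized as the first $\lceil (1-q) N \rceil$ molecules of that
ranking rather than a threshold on an interpolated quantile value, which
would be tie-sensitive: at $q = 0.995$ a 7895-molecule universe yields
exactly 40 molecules. Subphenotype strata (listening, ability, practice)
restrict the layer set to studies carrying the class — a study may carry
several — and recompute the denominator $\sum_i w_i$ over the subset only.
Stratum scores are therefore comparable within, not across, strata, and a
molecule undetected within a stratum simply does not appear in it.

## Region-to-gene mapping

Association markers become candidate regions of ±500 kb (the default
`flank`) clamped to the chromosome; linkage results reported only in genetic
map units are converted at exactly 1 cM = 1 Mb around the peak. The
half-width applied to cM peaks is a visible configuration parameter
(`cm_half_width`, default 10 cM) because source studies differ in what they
report; reported physical bounds are always preferred when present.
Coordinates are 1-based inclusive (GFF3 convention; BED input is shifted on
read), membership is any 1-bp overlap, and strand is ignored. A marker whose
region contains no annotated gene is dropped with a log message, not an
error. The interval queries go through `GenomicRanges::findOverlaps`; the
test suite checks them against an exhaustive linear scan.

## Homolog translation

Cross-species translation is a user-supplied table, not a live database
query, for reproducibility: each non-human identifier expands to *all* its
human homologs, unmapped identifiers are dropped and counted per layer, and
biomarkers (cortisol, dopamine, …, see `defaultBiomarkers()`) pass through
untranslated in every species. Expansion happens before within-layer
deduplication, so two source genes sharing a homolog still yield a single
detection for that layer.

## Enrichment and networks

Over-representation of a gene set in the top set is the one-sided
hypergeometric tail (Fisher's exact test), with the *database universe* —
every molecule detected at least once — as the default background rather
than the genome, matching the vote-counting frame. Raw p-values are the
primary output; Benjamini–Hochberg adjustment is an optional column, off by
default, because the reference workflow reports raw thresholds.

The interaction-network builder reimplements a proprietary procedure from
its published description, so only its seeding rule is verbatim: the seed is
the focus molecule contained in the most connective triangles (ties: degree,
then name). Growth is a documented choice, not a claim of equivalence: at
each step the neighbour with the most edges into the current network joins,
focus molecules preferred over connectors at equal connectivity, until
`max_size` (default 35) nodes or no candidate connects. Consumed nodes are
excluded from later networks, so networks are node-disjoint.

## The synthetic benchmark

`generateStudyDatabase()` emulates the statistical structure the analysis
assumes: a 35/55/15 human/songbird/other-animal study composition by
default, human gene-mapping studies contributing paired association and
linkage layers, a molecule universe of several thousand symbols, and
independent Bernoulli detection — planted signal molecules at `pSignal` per
layer, background at `pNoise`. Independence across layers is exactly the
null the vote count assumes; the generator deliberately does not simulate
linkage disequilibrium, co-expression correlation, or literature bias, so a
passing benchmark shows the pipeline machinery recovers a planted signal
under the model's own assumptions, not that real literature corpora behave
this way. Non-human layers emit species-native identifiers resolvable
through a generated many-to-many homolog table; a configurable fraction of
*background* genes is left unmappable (planted genes stay mappable so that
recovery measures ranking, not table quality). A layer that would come out
empty receives one forced background detection, because empty layers are
load-time errors. All randomness flows from a single seed.

`recoveryExperiment()` runs generate → weight → score → rank per replicate
and reports the fraction of planted molecules inside the top-$K$ set
($K$ = number planted). The shipped acceptance harness runs 50 replicates at
110 layers, 8000 molecules, 40 planted, `pSignal` 0.3, `pNoise` 0.01 —
problem sizes chosen to mirror the scale of the motivating curated database
(111 layers, 7895 molecules, top 40) while keeping a full run in the
low minutes on one CPU; the monotonicity-in-`pSignal` check uses a reduced
2000-molecule universe with 10 replicates per grid point and a
Monte-Carlo-error tolerance.

## Degenerate inputs and numerical notes

* Zero total layer weight, an empty universe, an empty top set, and a
  quantile outside (0, 1) are hard errors.
* $\lceil (1-q) N \rceil$ is computed with a small epsilon guard because
  $1 - q$ is not exact in binary floating point.
* Equal CE scores *and* equal detection counts fall back to lexicographic
  order; this is stated in the output docs so downstream consumers do not
  read meaning into it.
* The detection matrix is stored sparse; scoring is a single
  matrix–vector product checked against a per-molecule loop to $10^{-12}$.

## Known limitations

Votes within a study's layer are exchangeable: a genome-wide-significant hit
and a suggestive one carry the same indicator. Strata share layer weights
with the global analysis (only the denominator changes). The network growth
rule approximates an under-specified published procedure. And the linkage
half-width default cannot reproduce per-study region widths that varied with
what each source article reported.
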