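---
title: "Models and methods behind midsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind midsat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midsat)
```

midsat discovers medium-sized tandem repeats (satellite monomers of roughly
40–500 bp) in genome assemblies by combining in silico restriction
digestion, direct tandem-array scanning, and consensus/cluster analysis.
This vignette explains the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## Degenerate-site semantics

Recognition sequences and consensus monomers both use IUPAC ambiguity codes
(`S` = G/C, `W` = A/T, `M` = A/C, `N` = any, ...). Two matching conventions
are used, deliberately different:

* **Genome scanning** (`find_sites()`): a pattern character matches a
  genome base iff the base is in its expansion set, and a genome `N`
  matches *nothing*, including pattern `N`. Draft assemblies contain long
  `N` gaps; under the permissive convention a single `GGNCC` enzyme would
  "cut" every position of an N-run and fabricate thousands of fragments.
* **Consensus mapping** (`map_sites()`): both sides may be degenerate, and
  a position matches when the two expansion sets intersect. A consensus `S`
  column *can* host a `CATG` site in some fraction of the real units, so
  intersection reports it as a potential site. Consequently a degenerate
  monomer may show more potential sites than any one concrete unit carries;
  the site map is an upper envelope, which is the informative object when
  predicting which digestion fragments can occur.

Sequences are encoded as 4-bit masks (A=1, C=2, G=4, T=8; codes are unions;
genome `N` = 0), so a site test is a vectorised bitwise AND over all start
positions at once. The test suite checks this scanner against an
independent PCRE regex oracle (lookahead character classes) on a thousand
random sequences per enzyme.

## Digestion model and distribution diagrams

Each scaffold is a linear molecule: cuts at `site_start + cut_offset`
(0-based, between-base), fragments are successive differences including
the two terminal fragments, and zero-length fragments are dropped. Terminal
fragments are kept so that combined mass is conserved exactly —
`sum(length * count) == genome length` — an invariant asserted for every
digestion in the tests. Coincident cuts from overlapping site occurrences
collapse to one cut.

Distribution diagrams record fragment counts and combined mass
(`length * count`) per 1 bp bin; plots default to the 1–2000 bp range where
monomer peaks live, but the full map is retained. Both counts and mass are
emitted because a gel responds to mass while the count diagram is the
sharper statistic for peak calling.

**Peak calling.** A length `L` is a peak when its count reaches
`min_count`, exceeds every other count in `[L - window, L + window]` (ties
toward the smaller length), and is at least `min_prominence` times the
median count over that window (absent lengths count as zero; the window is
zero-padded at the axis ends). Defaults `window = 5`, `min_prominence = 5`,
`min_count = 100` suit megabase-scale genomes; `min_count` should be scaled
down roughly with genome size for small inputs. There is no field-standard
definition of a "distinct peak" in a digestion diagram; these defaults were
fixed before any acceptance measurement and are deliberately conservative.

**Gel-band visibility.** A fragment length is predicted visible when its
combined mass reaches `mass_fraction_threshold` (default 0.05%) of total
genome mass. This reproduces the familiar observation that very short
(sub-100 bp) fragments, however numerous, stay below detection level.
The default is an invented operational threshold, not a calibrated
photometric model.

**Cross-enzyme candidates.** Peak lengths from two or more enzymes are
clustered by single linkage within `tolerance_bp` (default 5); clusters
supported by at least two distinct enzymes are reported with the median
member length. Same-size fragments from different enzymes are the classic
indication of a tandemly repeated unit carrying one site per enzyme.

## Tandem-array scanner

The scanner is a purpose-built detector, not a reimplementation of Tandem
Repeats Finder's probabilistic model. Published unit/cluster counts
obtained with TRF depend on alignment weights and score thresholds that are
rarely stated, so the package's accuracy claims rest on planted-truth
recovery instead (below).

Stages:

1. **Seeding.** All exact k-mer (default `k = 12`) recurrences at a
   distance `d` within `[min_period, max_period]` vote for "period `d` at
   this position". Votes are grouped by position adjacency, single-linkage
   clustered on `d` (5% tolerance), and split at position gaps larger than
   one period; a run must span at least `0.8 * min_copies * period`.
2. **Segmentation.** Within a candidate region the first unit is the
   reference; each subsequent unit boundary is re-anchored at the offset
   (±15% of the period) minimising ungapped mismatches against the
   reference. Re-anchoring at every unit stops indel drift from
   accumulating across the array.
3. **Verification.** Adjacent-unit identity is measured by global alignment
   (match +1, mismatch −1, gap −2; identity = matching columns / alignment
   columns) on up to 10 evenly spaced adjacent pairs. For equal-length
   pairs the ungapped identity — a lower bound on the alignment identity —
   stands in when it already clears the threshold by 5 points. Arrays need
   `min_copies` (default 3) copies and `min_identity` (default 75%) mean
   adjacent identity. Overlapping candidates are resolved toward the higher
   `copy_number * identity`, ties to the leftmost.

The period is reported as the median unit length (hence ranges like
153–154 in census tables), `copy_number` as array span / period. The
40–500 bp default range reflects the niche between minisatellites and
large satellites; both bounds are parameters.

At 12 exact matching positions, seeding tolerates substantial divergence: at
9% per-base substitution plus 1% indels an adjacent copy pair still shares
~8% of its k-mer positions, ample for several votes per junction. Random
50 kb sequence yields no arrays at the defaults (checked over ten seeds).

**Census and family consensus.** `census()` pools rounded copy numbers and
array counts per period bin; unit totals conserve the rounded copy numbers
exactly. `pool_consensus()` rotationally aligns per-array consensi (best
circular offset by maximal IUPAC-aware identity), projects them onto a
reference — chosen as the consensus of median length so per-array indel
noise cannot inflate the pooled monomer — and calls the column-wise IUPAC
consensus.

## IUPAC consensus construction

Per alignment column, bases with frequency at least the inclusion threshold
(default 0.25) form the ambiguity set; a single base above the majority
threshold (default 0.75) is written as that base; columns that are more
than half gaps are dropped. A 50/50 G/C column therefore becomes `S`.
These thresholds are an operational choice — published satellite consensi
rarely state how their codes were assigned — and both are parameters of
`build_consensus()`. Input letters may themselves be degenerate; each
contributes its expansion set with the weight split evenly, which is what
lets per-array consensi be pooled into a family consensus.

Restriction sites are mapped on the **circularised** monomer (the sequence
plus its first `site length − 1` bases): interior units of a head-to-tail
array are effectively circular, so predicted fragments are the circular
gaps between cut positions and always sum to the monomer length. The test
suite verifies that these predictions equal, exactly, the interior fragment
lengths of digesting a 50-copy exact array, and that mutating one site in
one copy fuses the two flanking fragments into their sum.

## Cluster tiling and classification

`tile_cluster()` decomposes a repeat-cluster locus by greedy,
score-descending local alignment of the consensus against the
not-yet-annotated sequence, masking each accepted match and repeating;
unmatched stretches become spacers, and the segments always partition the
region. Matches below `min_identity` (default 80%) or `min_match` (default
20 bp), or indistinguishable from chance (a log-likelihood significance
filter: a matching column is ~4× likelier under copy than junk, a
mismatching one ~25× less; acceptance requires +15 nats), are masked as
spacer and the search continues elsewhere.

Classes: **full** (exact consensus-length match spanning the whole
consensus), **full_variant** (within `length_tolerance = 3` bp, covering
the odd 170/173/175 bp near-full units of real clusters, and any other
internal partial match), **truncated5p** (alignment starts at least
`trunc5_min = 8` bases into the consensus and reaches within 4 bp of its 3'
end — the 5'-deleted copies, which in the motivating cluster lack 11 bp),
**short_fragment** (at most `short_max = 35` bp, covering 28–29 bp
fragments), and **spacer**. The terminal 6-mer downstream of each short
fragment is reported but never used for classification.

The delicate part is the 5' boundary at piece junctions. Local alignment
trims mismatching terminal bases from a full copy with a diverged edge, and
conversely accretes chance-matched columns from the neighbouring piece onto
a truncated copy; both distort the class. The boundary is therefore
re-derived by a maximum-likelihood changepoint anchored at the reliable 3'
end of the match: columns before the boundary are modelled as chance
sequence (P(match) = 0.25), columns after it as copy sequence (P(match) =
0.97). Relative to "keep everything", skipping a mismatching column gains
log(.75/.03) ≈ 3.2 nats and skipping a matching one loses log(.97/.25) ≈
1.4 nats; a fixed 8-nat prior keeps one or two mutated edge bases attached
to their copy, and near-tied changepoints resolve toward the cleanest
downstream 16-column window (which steps over short runs of chance-matched
junk). An 11-column junk prefix gains ~22 nats and is cleanly skipped,
while a genuine full copy with an early mutation stays intact. Lowering
`min_identity` never decreases the number of non-spacer segments (the
greedy sequence is unchanged; the stop comes later), a monotonicity
property asserted in the tests.

## Synthetic genomes and what passing tests mean

`synth_generate()` draws i.i.d. background at a configurable GC content,
builds each array as head-to-tail copies of its unit — per copy: IUPAC
positions resolved uniformly over their expansion sets, then substitutions
uniform over the three alternative bases, then single-base indels with
equal insert/delete probability — and inserts features at random
non-overlapping points, so output length = background + planted lengths
exactly. Identical specs are byte-identical; every feature is recorded in a
truth table. Rates are capped at 0.25 per base.

`make_multifamily_genome()` is the bundled study condition: three scaffolds,
~1.8 Mb, with (i) a 225 bp family (one CCGG, one GTAC, two CATG per unit)
at 1% substitution, (ii) a 154 bp family (two GATC splitting the circle
36 + 118, one AGCT) at 1% substitution, (iii) the degenerate 172 bp monomer
`SAT172_CONSENSUS` at 9% substitution + 1% indels, and interspersed
5'-truncated remnants of the 154 bp unit. The 1% rate matches the 96–99%
unit-to-consensus identity typical of young satellite families; the
172-family rates encode a diverged family: substitutions alone only delete
sites (surviving site pairs still yield exact-length fragments), so indels
are what smear the fragment-length distribution and erase the digestion
peak while the census peak persists. Unit site layouts are enforced on the
circular unit, so copy junctions cannot carry stray sites.

What the generator does **not** emulate: higher-order repeat structure,
GC/mutation heterogeneity along the genome, large-scale duplications, and
sequencing/assembly artefacts other than `N` handling. Passing
planted-truth tests therefore demonstrates correctness of the algorithms
under a clean insertion model, not end-to-end performance on a real draft
assembly.

## Problem sizes and numerical choices

The test-suite and acceptance-script workloads are sized for a laptop-class
single core: the multi-family fixture is ~1.8 Mb (pipeline ≈ 10 s); scanner
recovery uses 20 genomes of ~60 kb with two planted arrays each (periods
from {60, 154, 172, 225, 400}, 5–50 copies, 0–3% substitution); cluster
recovery uses 20 clusters of 2–6 full, 0–3 truncated and 1–3 short copies
at 0–3% substitution. Alignment scores are integers (match +1, mismatch −1,
linear gap −2) throughout; ties in peak calling break toward shorter
lengths, in overlap resolution toward the leftmost array, and in the
changepoint toward the smaller offset — all deterministic. The only
randomness anywhere is the user-supplied generator seed.

## Known limitations

* The scanner reports a double-period array (e.g. 344 for a 172 bp family)
  where high divergence breaks every adjacent junction in a stretch but
  alternate junctions survive; such arrays are rare, carry few units, and
  are filtered from family tables by the `min_family_units` threshold.
* Very short periods (< k = 12) are out of range by construction;
  minisatellites need a different tool.
* `percent_identity()` is quadratic in sequence length and intended for
  monomer-scale comparisons, not chromosome alignments.
* Cluster tiling classes are tuned to 5'-truncation; 3'-truncated copies
  are reported as `full_variant` rather than a dedicated class.
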