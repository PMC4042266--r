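---
title: "Weighted n-gram profiling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted n-gram profiling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The method

`ngramid` profiles shotgun metagenomic read sets against a reference panel
of bacterial genomes without alignment. Three ideas carry the whole method.

**1. A weighted n-gram index.** Every genome is decomposed into its
overlapping substrings of length *n* (n-grams, equivalently k-mers; a
sequence of length *k* yields *k − n + 1* of them). Across a panel of *C*
genomes each distinct n-gram *x* is assigned the dampening weight

$$ w(x) \;=\; \frac{\log\!\big(C/m_x\big)}{\log C}, $$

where $m_x$ is the number of panel genomes containing *x*. An n-gram unique
to one genome gets weight 1, an n-gram present in every genome gets weight
0, and the weight decreases strictly in $m_x$ in between. This is an
inverse-document-frequency weighting with genomes as documents: ubiquitous
n-grams carry no taxonomic signal and are silenced, rare ones dominate. The
ratio of logarithms makes the weight independent of the logarithm base,
which the test suite checks to machine precision.

**2. Column-sum classification.** A query is a *set* of n-grams — harvested
from a whole read set, or sampled from a genome in validation experiments.
Conceptually a (query n-grams × genomes) matrix is filled with $w(x)$ where
genome *f* contains *x* and 0 elsewhere; each genome's score is its column
sum, and the whole query set is assigned to the genome with the largest
score. The implementation computes the same numbers sparsely, by a keyed
join of the query against the membership table followed by a grouped sum; a
brute-force dense-matrix implementation is kept in the test suite as an
independent oracle and the two agree exactly on randomized toy panels.
Classification operates on read *sets*, not single reads: a single 100 bp
read carries at most 89 n-grams, often too few to discriminate strains,
while a set pools thousands. Ties (equal top scores, e.g. for duplicate
genomes under different tags) are broken lexicographically for determinism
and flagged, and callers should treat flagged ties as mispredictions.

**3. Repeat-ratio-corrected abundance.** For each genome the repeat ratio
is the percentage of its n-gram occurrences that are repeats,
$RR = 100\,(\text{total} - \text{distinct})/\text{total}$. Abundance
estimation starts from per-genome intersection counts between read n-grams
and the genome's indexed n-grams; observed abundance scales these to mean 1
over the *k* community members,
$\mathrm{obs}_i = k\, c_i / \sum_j c_j$. Because genomes with extreme
repeat ratios are systematically mis-estimated, a correction
$\mathrm{corr}_i = \mathrm{obs}_i - \log_{10}(RR_i)/D$ is applied, with
$D = \mu$ of the panel's repeat ratios when $15 < RR < 50$, $\mu - \sigma$
when $RR > 50$, and $\mu + \sigma$ when $RR < 15$ (boundary values use
$\mu$; the strict inequalities in the source formulation leave the boundary
open, and the central branch is the conservative assignment). Corrected
values are clamped at 0 and renormalized so the estimates sum to 100% (or
to the number of species). $\mu$ and $\sigma$ are always recomputed from
the current panel — they change whenever genomes are added or removed — and
$\sigma$ defaults to the population standard deviation (the panel is the
entire reference universe, not a sample from one; `sigma_type = "sample"`
is available).

# Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `n` | 12 | n-gram length. Short enough that 100 bp reads yield 89 n-grams, long enough that random 12-mer collisions are rare below ~1 Mb of sequence (4^12 ≈ 1.7e7). |
| `alpha` | 1 | fraction of each genome's distinct n-grams indexed; `alpha < 1` emulates partially sequenced references (sampling is per genome, proportional to its distinct-set size, seeded). |
| `both_strands` | `TRUE` (classification) | look up each query n-gram also as its reverse complement and keep the better-weighted orientation per genome. The index stores forward-strand genome n-grams only; real reads come from both strands. `FALSE` reproduces the literal forward-only scheme, and the oracle-equivalence tests run in that mode. Ambiguity codes are looked up literally (no complement). |
| `sigma_type` | `"population"` | convention for σ of the repeat ratios. |
| `per_read` (abundance) | `TRUE` | count each read's distinct n-gram matches and sum over reads, rather than intersecting the pooled read n-gram set with the genome. The pooled set intersection stops growing once coverage approaches 1× (the fraction of genome n-grams seen is ≈ 1 − e^(−coverage)), so it cannot track abundance across a staggered community where abundant members are sequenced to several-fold coverage; the per-read count stays linear in read number. The pooled mode is retained for comparison. |
| test sampling fraction | any of (0, 1] | the validation protocol samples `round(fraction · |set|)` distinct n-grams per genome; 1%, 3%, 5%, 7% are the conventional grid. |

# The synthetic panel and read simulator

The package generates its own study systems; nothing is downloaded.

`generate_panel()` emulates the features of a real reference panel that the
method is sensitive to, at a controllable scale: (i) *strain structure* —
strain groups share a species backbone, and each further strain differs by
independent point substitutions at `mutation_rate` (0.001 ≈ typical
intra-species strain divergence of 0.1%); (ii) *repeat content* — a chosen
fraction of each genome is built from tandem and dispersed copies of
internal 0.5–2 kb segments, steering the repeat ratio anywhere in the range
observed for real bacteria (below 1% up to ~70%); (iii) *hierarchical tags*
— `GGG_SSS_strain` with consecutive species sharing a genus, so genus-,
species- and strain-level evaluation all have structure to resolve. The
default `repeat_fraction = 0.25` puts the panel's mean repeat ratio near
25%, matching the mid-20s mean of real bacterial panels at n = 12.

`simulate_reads()` replaces an external read simulator. Per-genome read
counts are multinomial with weights abundance × genome length (a genome at
abundance *a* contributes cells, each cell contributes DNA proportional to
genome size; `weight_by_length = FALSE` gives abundance-only weighting).
Start positions are uniform, strands uniform. The error model is
parametric, Illumina-like, and fully configurable: per-base substitution
probability ramping linearly from 0.1% at the first position to 1% at the
last, plus flat 0.01% insertion and deletion rates. These defaults are the
package's own surrogate for an empirical error profile — they reproduce the
qualitative behaviour (errors concentrated at read ends, indels an order of
magnitude rarer than substitutions) rather than any particular instrument.
`staggered_abundances()` draws log-uniform values on [0.1%, 10%] and
rescales them to sum to 100% (clipping at the floor): log-uniform is the
standard "staggered" mock profile, spanning the range evenly on the scale
on which abundances vary.

What the simulator deliberately does *not* emulate: quality-score
distributions (the method never reads them), GC bias, chimeric fragments,
contamination, and inter-species homology other than what random sequence
and shared backbones produce. Passing tests on these communities therefore
demonstrate the *mechanics* of the method — weighting, scoring, correction,
normalization — under controlled truth, not its accuracy on real gut
metagenomes, where conserved regions across distantly related taxa are far
more common than between random synthetic genomes.

# Reference experiment and problem sizes

`run_staggered_benchmark()` is the package's end-to-end experiment and what
`scripts/acceptance.R` runs: 50 genomes of 100 kb (10 strain pairs at 0.1%
divergence plus 30 singletons, repeat fraction 0.25), the full index at
n = 12, and 100,000 reads of 100 bp at staggered abundances. These sizes
are the package's chosen desk-scale study conditions: they keep the
complete run around two minutes on one core while preserving every
structural feature of the full-scale setting (strain pairs closer than 1
part in 1000, members sequenced anywhere from ~0.1× to ~10× coverage).
Cross-validation is implemented as repeated seeded sub-sampling of query
n-grams per genome — folding *genomes* into held-out sets would leave test
genomes without a class in a closed-world classifier — which matches the
1/3/5/7% sampling protocol; each fold is an independent draw.

On this benchmark every one of the 50 read sets is assigned to the correct
strain (the test suite asserts 100%), and estimated abundances track truth
within a few percent relative for members above 1% truth abundance.

# Numerical choices and degenerate inputs

* Sequences shorter than `n` yield an empty n-gram set (flagged by a zero
  total), never an error: short reads near contig ends must not abort runs.
* A query with no n-gram in the index returns an explicit `unclassifiable`
  result with an empty ranking, not an exception.
* Genomes are linear strings; no wrap-around n-grams are formed at the
  origin of circular chromosomes (consistent with the k − n + 1 count).
* Weights are serialized with 17 significant digits so a written model
  reloads bit-identically; a row-count footer in the header detects
  truncated files.
* A repeat ratio of exactly 0 (tiny toy genomes only) takes zero
  correction; the correction function itself requires RR > 0, and a panel
  with μ − σ ≤ 0 combined with RR > 50 is rejected as degenerate.
* All randomness flows through explicit seeds; child seeds for per-genome
  sampling and per-fold draws are derived arithmetically (mod 2^31-ish
  prime) so runs are reproducible end to end and independent sub-draws do
  not reuse a stream.

# Known limitations

**The correction term distorts rare members.** The repeat correction
subtracts an *absolute* offset $\log_{10}(RR)/D$ — about 0.05 for a panel
with mean repeat ratio in the twenties — from an observed value whose size
is proportional to the member's abundance. For a community of 50 members,
truth abundance 0.1% corresponds to an observed value of 0.05, the same
order as the offset itself, so estimates for members below roughly 0.4%
truth are driven to zero (the clamp) or distorted by more than the offset's
share of larger members. This is a structural property of the published
correction, not an implementation artifact: the offset is zero only at
RR = 1% exactly, and no repeat structure of the panel avoids it. The
package reports corrected and uncorrected (observed) columns side by side
so users can judge the low-abundance tail; the acceptance suite states the
recovery bands for both regimes and the sub-1% band is knowingly not met at
the 0.1% floor.

**Closed-world classification.** Every query is assigned to some panel
genome (or declared unclassifiable); reads from organisms outside the panel
are not modelled. The faithful operating mode assumes reads arrive grouped
into per-genome sets (as simulation truth provides); how to partition a
real mixed metagenome into such sets is outside the method, and per-read
classification is offered only as an explicit extension
(`classify_reads()`).

**Memory scale.** The index is an in-memory long table of (n-gram, genome)
pairs; a 50 × 100 kb panel is ~5 × 10^6 rows. Full bacterial panels (Mb
genomes, thousands of references) are supported by the same code path but
need memory in proportion.
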