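# ngramid

Alignment-free, strain-resolved identification and relative-abundance
estimation for shotgun metagenomic read sets, for microbiome researchers
who need to ask "*which* reference strains are in this sample, and in what
proportions?" without running an aligner.

## The method

A reference panel of `C` genomes is decomposed into overlapping n-grams
(k-mers, default `n = 12`). Each distinct n-gram `x`, present in `m_x`
genomes, is weighted with an inverse-document-frequency style dampening
factor

    w(x) = log(C / m_x) / log(C)

so that genome-unique n-grams score 1, ubiquitous ones score 0, and the
weight falls strictly as an n-gram becomes more widespread. A query — the
pooled n-gram set of a whole read set — is scored against every genome by
the column sum `score(f) = Σ_x w(x) · [x ∈ genome f]`, and assigned to the
top-scoring genome. Because unique n-grams dominate the sums, strains
differing by as little as 1 substitution per 1000 bp separate cleanly.

Relative abundance starts from per-genome counts of read n-grams found in
the reference (`c_i`), scaled to `obs_i = k · c_i / Σ_j c_j` over the `k`
community members, then corrected for each genome's repeat ratio `RR_i`
(the percentage of its n-gram occurrences that are repeats):

    corr_i = obs_i − log10(RR_i) / D,   D = μ (15 < RR < 50),
                                        D = μ − σ (RR > 50),
                                        D = μ + σ (RR < 15)

with `μ, σ` the mean/sd of repeat ratios over the current panel; corrected
values are clamped at 0 and renormalized to 100% (or to the number of
species). The package also ships a synthetic genome-panel generator
(controlled strain divergence and repeat content), a mock-community read
simulator with an Illumina-like error model, and an evaluation harness
(per-level accuracy, balanced accuracy, cross-validation, partial-model
experiments). See the methods vignette (`vignettes/methods.Rmd`) for the
model details and design rationale.

## Worked example

Six synthetic 20 kb genomes — one pair of sibling strains at 0.1%
divergence plus four unrelated species — profiled from 20,000 simulated
100 bp reads at staggered abundances:

```r
library(ngramid)

panel <- generate_panel(num_genomes = 6, genome_length = 20000,
                        strain_groups = c(2, 1, 1, 1, 1),
                        mutation_rate = 0.001, repeat_fraction = 0.25,
                        seed = 42)
model <- build_model(panel, n = 12)
model
#> ngram_model: n=12, C=6 genomes, alpha=1
#>   75,291 indexed n-grams: 60,400 unique (weight 1), 14,891 common
#>   panel repeat ratio: mu=24.76%, sigma=0.10% (population sd)

spec  <- community_spec(data.frame(tag = panel$tag,
                                   abundance = c(30, 25, 20, 15, 7, 3)),
                        total_reads = 20000, seed = 43)
reads <- simulate_reads(panel, spec)
sets  <- split(reads$sequence, reads$tag)[panel$tag]

classify_read_sets(sets, model)
#>           set  predicted    score     margin    tie unclassifiable
#> 1: AAA_AAA_S1 AAA_AAA_S1 18522.95   379.0000  FALSE          FALSE
#> 2: AAA_AAA_S2 AAA_AAA_S2 18619.94   502.4526  FALSE          FALSE
#> 3: AAA_AAB_S1 AAA_AAB_S1 29931.39 29856.6789  FALSE          FALSE
#> 4: AAB_AAC_S1 AAB_AAC_S1 29941.30 29852.3578  FALSE          FALSE
#> 5: AAB_AAD_S1 AAB_AAD_S1 28794.01 28730.0657  FALSE          FALSE
#> 6: AAC_AAE_S1 AAC_AAE_S1 23206.49 23171.2920  FALSE          FALSE

abundance_table(sets, model)
#>           tag intersection_count repeat_ratio  observed corrected estimated
#> 1: AAA_AAA_S1             495762     24.82866 1.7870213 1.7306792 30.565244
#> 2: AAA_AAA_S2             410767     24.52849 1.4806487 1.4245200 25.158216
#> 3: AAA_AAB_S1             336322     24.79364 1.2123046 1.1559873 20.415704
#> 4: AAB_AAC_S1             250095     24.79364 0.9014912 0.8451739 14.926478
#> 5: AAB_AAD_S1             122257     24.79864 0.4406870 0.3843661  6.788227
#> 6: AAC_AAE_S1              49339     24.80864 0.1778471 0.1215191  2.146130
```

Every read set is assigned to its true strain — note the two sibling
strains `AAA_AAA_S1`/`S2` separated by margins of a few hundred weight
units, versus five-figure margins for unrelated genomes (their shared
backbone n-grams score for both siblings; only the ~20 strain-private
n-gram neighborhoods differ). The `estimated` column tracks the simulated
truth (30/25/20/15/7/3%) within a few percent relative; `observed` vs
`corrected` shows the repeat-ratio offset at work.

A command-line wrapper with `build`, `classify`, `abundance`, `simulate`,
`evaluate` and `xval` subcommands is installed at
`inst/scripts/ngramid` (see `?ngramid_main`).

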