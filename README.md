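# cnelink

Conserved noncoding elements (CNEs) and the evolutionary linkage score
that assigns them to target genes.

Enhancers act on genes across hundreds of kilobases, and selection
against rearrangements that would separate an enhancer from its target
keeps functional pairs physically linked across vertebrate evolution.
`cnelink` turns that signature into a prediction pipeline:

1. **Scan** multi-species alignment blocks (MAF) for CNEs: exon- and
   repeat-masked columns, conservation per column (≥ 7 species beyond
   the reference, substitutions under a 12% threshold), 10-bp core
   windows with ≥ 90% conserved columns, extension across non-conserved
   runs of ≤ 3 columns, fusion of same-pattern elements < 100 bp apart,
   and a conservation score summing the per-phylogenetic-group maximum
   percent identities (e.g. 97 + 68 + 62 + 54 + 49 = 330).
2. **Score linkage**: for every CNE and every gene family within 1 Mb,
   classify the ortholog in each aligned species — linked within the
   size-scaled radius *d_e* (S1), same chromosome beyond it (S2),
   different chromosome (S3), unannotated (S0) — and accumulate
   weighted evidence `+s1(1−R_e)` / `s2·C_e` / `s3·C_e` / `s0·C_e`,
   where `R_e` is the conserved-synteny level (fraction of adjacent
   reference gene pairs still adjacent in species *e*) and `C_e`
   discounts absence evidence from low-coverage assemblies. A sigmoid
   maps raw scores to `S_A ∈ (0,1)`; the best-scoring families (ties
   kept) are the predicted targets, and co-targeting CNEs < 100 bp
   apart fuse into regulatory elements.
3. **Annotate**: coverage-weighted overlap with functional signal
   tracks (a 100-bp element overlapped over 40 bp by a value-12 peak
   scores 12 × 40/100 = 4.8) and `S_A`-binned enrichment curves.
4. **Check against chromatin interactions**: the fraction of elements
   whose predicted targets match promoter-interaction (ChIA-PET-style)
   genes, with a permutation null that re-draws each element's targets
   from the genes in a 2-Mb window (`p = (r+1)/(n+1)`, reported as
   `p < 1/n` at the floor).
5. **Simulate**: a synthetic-genome generator plants enhancer–target
   pairs in an ancestral chromosome, rearranges descendant genomes
   while protecting true pairs, and emits MAF/TSV/BED/bedGraph/BEDPE
   bundles with full ground truth, so the whole pipeline is testable
   offline.

## Worked example

```r
library(cnelink)

bundle <- simulate_bundle(sim_config(seed = 1))   # 20 species, 6 Mb, 100 CNEs
res    <- run_pipeline(bundle)                    # scan -> score -> fuse

nrow(res$cnes)                                    # 100 called CNEs
res$link$selections[1:3, c("cne_id", "start", "end", "max_SA", "relative")]
#>     cne_id start   end max_SA relative
#> 1 CNE00001 53361 53463      1  0.09608
#> 2 CNE00002 94751 94825      1  0.06056
#> 3 CNE00003 95702 95762      1  0.00196
```

Each selection row is one element with its best `S_A` and the contrast
to the runner-up gene. Against the generator's ground truth, the
planted true target is among the predicted targets for 96% of planted
enhancers at this seed:

```r
m   <- match_planted(res$link$selections, bundle$truth$cnes)
enh <- which(!is.na(m$enhancer) & m$enhancer)
hit <- vapply(enh, function(i) m$true_target[i] %in% m$targets[[i]],
              logical(1))
mean(vapply(split(hit, m$planted_id[enh]), any, logical(1)))
#> [1] 0.96
```

Functional enrichment along the score, and consistency with the
simulated interaction pairs:

```r
sc    <- functional_scores(res$cnes, bundle$peaks)
el    <- element_score_from_cnes(res$reg_elements, sc)
curve <- enrichment_by_score(res$reg_elements$max_SA, el$overlaps, bins = 5)
fold_change(curve)
#> [1] 5.5

permutation_test(res$reg_elements, bundle$interactions, bundle$ref_genes,
                 n_resamples = 10000, seed = 1)
#> consistency: 27 of 31 overlapping elements (87.1%)
#> no resample reached the observed count: p < 0.0001 (10000 resamplings)
```

The proportion of elements carrying a planted peak climbs from 0.10 in
the lowest `S_A` bin to 0.80 near the top (fold change 5.5), and the
observed target/interaction agreement is never reached by any of the
10,000 window resamplings.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/cnelink.R` with subcommands `simulate`, `scan`, `score`,
`annotate` and `chiapet`.

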