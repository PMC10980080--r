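# era3d — gene evolutionary age and the 3D genome

Human protein-coding genes differ enormously in evolutionary age: most are
ancient (detectable down to bacteria), while others are restricted to
narrow lineages — down to primate- or human-specific genes. `era3d` is an R
package for asking how genes of different ages sit within features of 3D
genome organization (topologically associating domains, chromatin-loop
anchors, domain boundaries) and how their expression scales with age. It is
aimed at regulatory-genomics and molecular-evolution researchers who have
interval annotations, homology hit tables and count matrices, and want the
full pipeline — age assignment, track pooling, binned-density correlation,
control construction, expression statistics — as tested, seeded, reusable
components.

## What it computes

* **Phylostratigraphic age assignment.** Each isoform's minimal age is the
  minimum phylostratum (PS 1 = cellular organisms … PS 31 = query-species
  restricted) among homology hits with e-value `< 1e-3`, ignoring
  self-species hits; genes are represented by the longest of their oldest
  isoforms, and phylostrata group into eras (Ancient PS 1–3, Metazoan 4–7,
  Chordate 8–17, Mammal 18–22, Primate 23–31). Two age-estimation methods
  can be compared at era rank (`compare_age_methods()`).
* **Interval algebra.** BED-style tracks validated against a genome model;
  pooling across datasets with overlap collapsing; coverage statistics
  (region count, median size, bp, % genome); unique-overlap subsetting.
* **Binned density correlation.** The genome is split into fixed bins
  (20/50/100 kb); per bin the covered fraction of each feature is computed,
  and feature pairs are related by Spearman's rank correlation
  ρ over all genome-wide bins, with a two-sided t-approximation p value.
* **Intergenic controls.** Igen ORFs (ATG + ≥40 non-stop codons + stop,
  six-frame scan, outside genes/repeats) and length-matched Igen Non-ORF
  intervals that cannot be mistaken for coding sequence.
* **Expression statistics.** Median-of-ratios size factors, tissue-category
  aggregation (with overlapping categories where configured), two-sided
  Mann–Whitney U comparisons with Benjamini–Hochberg correction,
  gene-length decile stratification, and a zero-safe log10 display
  transform.
* **Synthetic data.** A seeded generator plants era labels, track
  enrichments, hit tables and expression gradients so every downstream
  claim is checked by parameter recovery and null calibration.

## Worked example

Generate a toy study system with a track enriched around ancient genes,
then recover the planted structure:

```r
library(era3d)

spec <- synthetic_spec(
  genes_per_era = c(Ancient = 200, Metazoan = 200, Chordate = 200,
                    Mammal = 200, Primate = 200),
  enrichment = c(Ancient = 5, Metazoan = 1, Chordate = 1,
                 Mammal = 1, Primate = 1),
  chrom_lengths = c(chr1 = 5e6, chr2 = 5e6), seed = 42)
g   <- gen_genome(spec, sequence = FALSE)
trk <- gen_feature_track(g$genes, g$genome, spec$enrichment,
                         seed = 43, name = "domains")
coverage_stats(trk)
#>      name n_regions median_size coverage_bp pct_genome
#> 1 domains      1663        1000     2138000      21.38

grid <- make_bins(g$genome, 50000)
tbl <- bin_density_table(grid, list(
  ancient_genes = genes_as_track(g$genes, g$genome, era = "Ancient"),
  primate_genes = genes_as_track(g$genes, g$genome, era = "Primate"),
  domains = trk))
correlation_matrix(tbl)$results[, c("track_a", "track_b", "rho", "p", "significant")]
#>         track_a       track_b          rho           p significant
#> 1 ancient_genes primate_genes -0.009871011 0.889667030       FALSE
#> 2 ancient_genes       domains  0.228782912 0.001119926        TRUE
#> 3 primate_genes       domains  0.021262805 0.765054152       FALSE
```

Only the track with planted enrichment correlates with ancient-gene
density (ρ = 0.23 across 200 bins, p ≈ 0.001); the null pairs are flat.
Ages round-trip from the generated homology hits, and the planted
expression gradient is recovered:

```r
tax  <- example_taxonomy()
ages <- assign_gene_ages(gen_hit_table(g$genes, tax, seed = 44),
                         g$genes, tax)
table(ages$era_five)
#>  Ancient Metazoan Chordate   Mammal  Primate
#>      200      200      200      200      200

ex <- gen_expression(g$genes, spec)
cm <- aggregate_by_category(normalize_counts(ex$counts),
                            ex$sample_tissue, ex$tissue_category)
cc <- compare_groups(cm, g$genes$era,
                     comparisons = rbind(c("Ancient", "Primate")))
cc[cc$category == "ectoderm",
   c("group_a", "group_b", "U", "p_adj", "median_a", "median_b")]
#>   group_a group_b     U     p_adj median_a median_b
#> 1 Ancient Primate 40000 5.797e-67     2073    92.55
```

Ancient genes are expressed ~20-fold above primate genes in the planted
conditions (median 2,073 vs 93 normalized counts in ectoderm), with a
BH-adjusted Mann–Whitney p of ~6e-67.

An end-to-end run from one config — age assignment, track statistics,
correlations at several bin sizes, controls, expression comparisons, plus a
manifest with seed and output checksums — is `run_pipeline(config)`; a thin
command-line wrapper lives at `inst/scripts/era3d.R`.

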