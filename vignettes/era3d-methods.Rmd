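---
title: "Methods: gene evolutionary age and the 3D genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene evolutionary age and the 3D genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

era3d analyses how human protein-coding genes of different evolutionary ages
sit within features of 3D genome organization — topologically associating
domains, chromatin-loop anchors, and the boundaries that insulate domains —
and how expression scales with gene age. This vignette documents the models
and procedures behind each stage, the tunable parameters, the numerical
conventions that were genuinely open choices, and what the synthetic data do
and do not establish.

## Gene age by phylostratigraphy

The minimal evolutionary age of a gene is estimated from protein sequence
similarity: the most taxonomically distant species containing a sufficiently
similar protein places a lower bound on the gene's age, because the gene must
be at least as old as the last common ancestor of that species and the query.
Operationally, the lineage of the query species is divided into 31
*phylostrata* (PS), PS 1 being cellular organisms and PS 31 the query species
alone. Each isoform is assigned the minimum phylostratum among its homology
hits with e-value strictly below a cutoff (`evalue_cutoff`, default `1e-3`,
dimensionless); hits in the query species itself are ignored since they carry
no lineage information, and an isoform with no passing non-self hit is
query-restricted (PS 31). Isoforms shorter than 40 amino acids are removed
before assignment — short sequences can arise repeatedly by chance, so their
lineage restriction is unreliable — as are those of 4,000 AA or more
(retained iff `40 <= length < 4000`). One isoform then represents each gene:
the longest of the oldest, with equal lengths broken by the lexicographically
smallest isoform id so results are reproducible.

Phylostrata are grouped into *eras*. The five-era scheme is Ancient (PS
1–3), Metazoan (PS 4–7), Chordate (PS 8–17), Mammal (PS 18–22), Primate (PS
23–31). The four-era scheme — Early (PS 1–13), Vertebrate (PS 14–17),
Mammal, Primate — exists because synteny-based age databases resolve only a
subset of nodes, the oldest of which spans PS 1–13; comparisons between a
similarity-based and a synteny-based assignment (`compare_age_methods()`)
are therefore done at era rank, classifying each shared gene as same age,
younger by one method, or younger by the other. A phylostratum-level
comparison would suggest resolution the coarser method does not have, so the
era-rank comparison is the default and the gene universe is the intersection
of the two inputs.

The taxonomy itself (species → phylostratum) is an explicit input rather
than a hard-coded lineage, so the machinery applies to any query species
with an ordered divergence series.

## Interval algebra for feature tracks

Feature tracks (domains, loop anchors, boundaries, conserved-element sets)
are sets of genomic intervals in 0-based half-open BED convention, validated
against a genome model (`0 <= start < end <= chromosome length`). Datasets
from different studies and cell types are pooled by concatenation followed
by collapsing of overlapping intervals, so any given region is counted only
once. Two conventions were open and are pinned by tests:

* **Bookended intervals merge.** An interval ending exactly where the next
  begins covers contiguous sequence; merging them matches the default of the
  common merge tools. This affects region counts (not coverage), so it is
  documented and test-pinned.
* **Overlap subsetting does not pre-merge.** `intersect_unique(a, b)`
  returns the records of `a` having at least 1 bp of overlap with `b`, each
  written once regardless of how many `b` regions it touches, and without
  merging `a`'s records with each other — the records are reported as given,
  which is what downstream region-based enrichment tools expect.

Coverage statistics per track are the number of regions, the median region
size (average-of-middle-two for even counts; undefined and reported as `NA`
for an empty track), total covered base pairs, and percent of the genome
covered. Internally the algebra stands on `IRanges`/`GenomicRanges`
(`reduce`, `findOverlaps`); the test suite validates every operation against
an independent per-base boolean-mask oracle on small genomes.

## Binned densities and Spearman correlation

The central statistic couples a track to a gene-age class through genome
binning: the genome is partitioned into consecutive bins of fixed size
(`bin_size`, bp; 20 kb, 50 kb and 100 kb are the conventional choices), and
in each bin the fraction of sequence covered by each feature is computed.
Pairwise association between two features is the Spearman rank correlation
of their per-bin fractions over all genome-wide bins pooled across
chromosomes.

Numerical choices, each of which was open:

* **All bins enter**, including zero-density bins — global binning implies
  the full genome is the sampling frame. A gap mask can be supplied as an
  exclusion at track-construction time if unassembled regions should not
  count.
* **The terminal bin of each chromosome is truncated** at the chromosome end
  and enters with its true length as the denominator, so the union of bins
  is exactly the genome and the conservation law
  `sum(fraction × bin length) = track coverage` holds identically (tested
  exactly on toys).
* **Ties get average ranks.** Density vectors contain many identical values
  (especially zeros), so the tie-corrected rho — Pearson correlation of
  average-ranked values — is required.
* **P values use the two-sided t approximation** with `n − 2` degrees of
  freedom. With thousands of bins this is accurate; it is also what the
  standard non-exact Spearman test computes, which the suite verifies.
  Reported p values are floored at `2.225e-308` so they remain in `(0, 1]`.
* **A constant input is an error**, not a silent zero: a track with no
  variation across bins has no defined rank correlation. In a correlation
  matrix the offending pairs are reported as `NA` with a note so one
  degenerate track does not abort the rest.
* **Raw p values by default.** The matrix reports per-pair p values without
  multiple-testing correction, with an optional Benjamini–Hochberg mode
  (off by default).

## Intergenic ORF controls

Protein-coding genes need a non-genic yardstick. Two control sets are
constructed from the genome sequence:

* **Igen ORFs** — potential open reading frames in the non-genic,
  non-repetitive part of the genome: an ATG, at least `min_codons` non-stop
  codons, then a stop (TAA/TAG/TGA). Two readings were open and are pinned:
  the Met codon *counts* toward the `min_codons = 40` threshold, making the
  minimal span `3 × (40 + 1) = 123` bp including the stop; and the scan
  reports *maximal* ORFs — within an inter-stop segment only the ORF from
  the first ATG is reported, so no reported ORF is nested in another in the
  same frame and no region is counted twice. All six frames (three per
  strand) are scanned. "Non-repetitive" is encoded as soft-masking: ORFs
  touching lowercase sequence, an N, or any excluded interval (genes,
  previously reported controls) are dropped.
* **Igen Non-ORFs** — length-matched controls with no coding constraint:
  for each ORF length, an interval of exactly that length is
  rejection-sampled from unmasked, N-free intergenic sequence, rejecting
  candidates that start with ATG (applied on the plus strand only; the
  orientation of a non-coding control is arbitrary, so one strand suffices
  and keeps the constraint symmetric across draws) or overlap exclusions,
  ORFs, or previously drawn controls. Exact length matching makes the
  produced length distribution identical to the requested one by
  construction.

## Expression statistics

Count matrices (gene × sample) are normalized with median-of-ratios size
factors: per gene with non-zero counts in every sample, the geometric mean
across samples; per sample, the median of `count / geometric mean` over
those genes, the median being taken on the log scale so that an even-count
median averages geometrically — this matches the reference implementation of
this normalization exactly (verified against it in the suite). Size factors
are relative quantities, defined up to a common scale.

Samples aggregate to tissues (mean over replicates) and tissues to
categories (mean over member tissues). The default category map groups
tissues into the three germ layers, the germ line (ovary, testis) and brain;
cortex and cerebellum belong to both ectoderm and brain, and a tissue listed
in several categories contributes to each — the overlap rule is explicit in
the map rather than hidden in code.

Group comparisons (between eras, or era vs control class) use the two-sided
Mann–Whitney U test with the normal approximation, tie-corrected and
continuity-corrected (sidedness was an open choice; two-sided is the
conservative default), with Benjamini–Hochberg correction applied over all
comparisons requested in a single invocation — the BH family is exactly what
one run produces, no more and no less. Group summaries (mean, standard error
of the mean, median, n) are computed on untransformed normalized counts. For
display, `log10_display()` applies `log10(value + m)` where `m` is the
smallest non-zero value, added to every argument; the transform is
display-only and strictly monotone. P values are floored at `2.225e-308`
(the smallest normal double), and a gene-length stratification
(`length_decile_stratify()`) checks that expression gradients across eras
persist within each length decile, since expression also rises with gene
length.

## What the synthetic generator emulates

Every stage is testable without external data through a seeded generator
whose defaults are the package's standard simulated conditions:

* **Genome and genes**: 500 genes per era (2,500 total) placed without
  overlap, with uniform random gaps, on a 20 Mb two-chromosome genome; gene
  lengths normal with mean 1,000 bp, sd 300 bp, floored at 90 bp. These
  sizes keep a full parameter-recovery run in seconds while leaving ~2,000
  bins at 10 kb — enough for the correlation machinery to behave
  asymptotically.
* **Feature tracks**: candidate windows (1 kb) are included by Bernoulli
  draws at baseline probability 0.2; a window overlapping genes of era *e*
  has its inclusion odds multiplied by that era's multiplier. With all
  multipliers at 1, inclusion is independent of gene positions, giving an
  exact null; multipliers above/below 1 plant positive/negative
  associations with controllable marginal coverage.
* **Hit tables**: each gene draws a target phylostratum inside its planted
  era, a sub-cutoff hit in a species of that stratum, closer sub-cutoff
  hits, and supra-cutoff decoy hits in more distant species. Age assignment
  must recover every planted era and ignore the decoys.
* **Expression**: negative-binomial counts with per-era means falling from
  2,700 (ancient) to 120 (primate) and dispersion 1 (variance
  `mu + mu^2`). The end points match the order of magnitude of published
  mean-count summaries for the oldest and youngest era in ectoderm; the
  intermediate means interpolate the gradient roughly geometrically, and
  dispersion 1 is a deliberately heavy-tailed choice typical of bulk RNA
  counts.
* **ORF test sequence**: a 1 Mb chromosome of stop-rich background (no
  frame on either strand runs more than ~80 bp without a stop, so no chance
  ORF can reach threshold) with 50 compliant ORFs and 50 decoys exactly one
  codon short embedded at known positions on both strands; the scanner must
  report exactly the 50 compliant ORFs with exact coordinates.

What the synthetic data do **not** establish: real genomes have
non-uniform gene density, GC and repeat structure, spatially autocorrelated
feature tracks, and library-size and composition effects far richer than a
single scaling — so passing parameter-recovery and calibration tests shows
the machinery is correct and calibrated under its model, not that effect
sizes on real data will match. The published cell-type-specific correlation
values require the original Hi-C and expression accessions and are out of
scope; what the package reproduces exactly is the published bookkeeping
arithmetic (era census; method-comparison fractions over 18,098 genes),
recomputed from the tallies at run time.

## Degenerate inputs and determinism

Empty interval sets merge and pool to empty sets with zero coverage and
undefined (NA) median size; empty gene sets yield empty expression matrices;
all-zero value vectors make the log10 display transform an error, as does a
count matrix with no gene expressed in every sample. All generators are
seed-deterministic — identical spec and seed give byte-identical outputs —
and `run_pipeline()` writes a manifest with the seed, parameter echo, and
md5 checksums of every output so a run can be reproduced and verified. Gene
placement and sequence generation consume independent seed streams, so
coordinates are identical whether or not sequence is requested.

## Known limitations

* Assembly liftover is out of scope; all inputs must share one assembly.
* Domain/boundary/loop calling from Hi-C contact maps is out of scope; the
  package consumes published interval annotations.
* The ontology-enrichment analysis itself is out of scope; the package
  prepares its inputs (unique-overlap subsetting) only.
* TPM-style length-corrected expression is accepted only as a precomputed
  matrix; the package does not recompute it from read-level data.
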