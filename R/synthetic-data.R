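#' Specification for the synthetic-data generator
#'
#' Bundles the parameters of the toy study system: era-labelled genes placed
#' on a small genome, feature tracks with tunable per-era enrichment, and
#' overdispersed expression counts with era-dependent means. Defaults define
#' the standard simulated conditions used throughout the package's tests:
#' 500 genes per era on a 20 Mb two-chromosome genome, mean expression
#' falling from 2700 counts (ancient) to 120 (primate), negative-binomial
#' dispersion 1.
#'
#' @param genes_per_era Named non-negative integer vector; names are the
#'   five-era labels.
#' @param gene_length_mean,gene_length_sd Gene length distribution in bp
#'   (normal, rounded, floored at 90 bp); `sd = 0` gives fixed lengths.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param enrichment Named per-era odds multipliers (> 0) used by
#'   [gen_feature_track()]; 1 means no planted association.
#' @param expr_means Named per-era mean counts used by [gen_expression()].
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param mask_fraction Fraction of intergenic sequence soft-masked
#'   (lowercase), emulating repeats.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(genes_per_era = c(Ancient = 500, Metazoan = 500,
                                             Chordate = 500, Mammal = 500,
                                             Primate = 500),
                           gene_length_mean = 1000, gene_length_sd = 300,
                           chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                           enrichment = c(Ancient = 1, Metazoan = 1,
                                          Chordate = 1, Mammal = 1,
                                          Primate = 1),
                           expr_means = c(Ancient = 2700, Metazoan = 900,
                                          Chordate = 400, Mammal = 200,
                                          Primate = 120),
                           dispersion = 1, mask_fraction = 0.1, seed = 1L) {
  if (any(genes_per_era < 0) || any(genes_per_era != floor(genes_per_era))) {
    stop("`genes_per_era` must be non-negative integers", call. = FALSE)
  }
  if (any(enrichment <= 0)) stop("odds multipliers must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (any(expr_means < 0)) stop("`expr_means` must be >= 0", call. = FALSE)
  if (mask_fraction < 0 || mask_fraction >= 1) {
    stop("`mask_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(genes_per_era = genes_per_era,
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd,
                 chrom_lengths = chrom_lengths,
                 enrichment = enrichment,
                 expr_means = expr_means,
                 dispersion = dispersion,
                 mask_fraction = mask_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# uniform random partition of `free` bp into k+1 gaps, each >= min_gap
.random_gaps <- function(k, free, min_gap) {
  extra <- free - (k + 1) * min_gap
  cuts <- sort(stats::runif(k, 0, extra))
  diff(c(0, cuts, extra)) + min_gap
}

#' Generate a toy genome with era-labelled genes
#'
#' Places non-overlapping genes (uniform random gaps) on the chromosomes of
#' the specification object, each carrying a planted era label, and optionally generates the
#' underlying DNA sequence with intergenic repeat-like stretches soft-masked
#' as lowercase. Placement and sequence are independently seeded from
#' `spec$seed`, so gene coordinates are identical whether or not sequence is
#' requested.
#'
#' @param spec A [synthetic_spec()].
#' @param sequence Generate DNA sequence? (Sequence for a 20 Mb genome takes
#'   a few seconds; turn off when only coordinates are needed.)
#' @return A list: `genome` ([genome_model()]), `genes` (data frame
#'   `gene_id`, `isoform_id`, `chrom`, `start`, `end`, `era`,
#'   `protein_length`), and `sequence` (named list of chromosome strings,
#'   lowercase = masked; `NULL` if not requested).
#' @export
gen_genome <- function(spec, sequence = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  eras <- names(spec$genes_per_era)
  n <- sum(spec$genes_per_era)
  genome <- genome_model(names(spec$chrom_lengths), spec$chrom_lengths)
  min_gap <- 200L

  if (n == 0) {
    genes <- data.frame(gene_id = character(0), isoform_id = character(0),
                        chrom = character(0), start = numeric(0),
                        end = numeric(0), era = character(0),
                        protein_length = numeric(0), stringsAsFactors = FALSE)
  } else {
    len <- round(stats::rnorm(n, spec$gene_length_mean, spec$gene_length_sd))
    len <- pmax(len, 90)
    era <- sample(rep(eras, spec$genes_per_era))
    # spread genes over chromosomes proportionally to chromosome length
    chrom_of <- sample(genome$chrom, n, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    placed <- lapply(genome$chrom, function(ch) {
      i <- which(chrom_of == ch)
      if (length(i) == 0) return(NULL)
      L <- genome$length[genome$chrom == ch]
      k <- length(i)
      free <- L - sum(len[i])
      if (free < (k + 1) * min_gap) {
        stop("genome too small to place requested genes on ", ch,
             call. = FALSE)
      }
      gaps <- .random_gaps(k, free, min_gap)
      starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, len[i][-k]))
      data.frame(idx = i, chrom = ch, start = starts,
                 end = starts + len[i], stringsAsFactors = FALSE)
    })
    placed <- do.call(rbind, placed)
    placed <- placed[order(placed$idx), ]
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n)),
      isoform_id = sprintf("gene%04d.1", seq_len(n)),
      chrom = placed$chrom, start = placed$start, end = placed$end,
      era = era,
      protein_length = pmax(floor((placed$end - placed$start) / 3) - 1, 40),
      stringsAsFactors = FALSE
    )
    genes <- genes[order(genes$chrom, genes$start), ]
    rownames(genes) <- NULL
  }

  seqs <- NULL
  if (sequence) {
    set.seed(spec$seed + 777L)
    seqs <- lapply(seq_len(nrow(genome)), function(ci) {
      L <- genome$length[ci]
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      g <- genes[genes$chrom == genome$chrom[ci], , drop = FALSE]
      genic <- rep(FALSE, L)
      for (k in seq_len(nrow(g))) genic[(g$start[k] + 1):g$end[k]] <- TRUE
      # soft-mask repeat-like blocks in intergenic sequence
      target <- spec$mask_fraction * sum(!genic)
      masked <- rep(FALSE, L)
      tries <- 0
      while (sum(masked) < target && tries < 10000) {
        w <- sample(200:800, 1)
        st <- sample.int(L - w, 1)
        block <- st:(st + w - 1)
        if (!any(genic[block])) masked[block] <- TRUE
        tries <- tries + 1
      }
      s[masked] <- tolower(s[masked])
      paste(s, collapse = "")
    })
    names(seqs) <- genome$chrom
  }

  list(genome = genome, genes = genes, sequence = seqs)
}

# interval_set view of a gene table (optionally one era)
#' Gene intervals as a track
#'
#' @param genes Gene table from [gen_genome()] (or any data frame with
#'   `chrom`, `start`, `end` and optionally `era`).
#' @param genome A [genome_model()].
#' @param era Optional era label to subset on.
#' @param merged Collapse overlaps? (default TRUE, ready for [bin_density()]).
#' @return An `interval_set`.
#' @export
genes_as_track <- function(genes, genome, era = NULL, merged = TRUE) {
  if (!is.null(era)) genes <- genes[genes$era == era, , drop = FALSE]
  name <- if (is.null(era)) "genes" else paste0(tolower(era), "_genes")
  s <- interval_set(genes[, c("chrom", "start", "end")], genome, name = name)
  if (merged) merge_intervals(s) else s
}

#' Generate a feature track with planted per-era enrichment
#'
#' Tiles the genome with candidate windows and includes each window as a
#' Bernoulli draw. A window overlapping genes multiplies the baseline odds by
#' the odds multiplier of every era present in it, so the probability that a
#' gene of era e is covered scales with its multiplier. With all multipliers
#' equal to 1 window inclusion is independent of gene positions (no planted
#' association). Selected windows are collapsed into a merged track.
#'
#' @param genes Gene table (columns `chrom`, `start`, `end`, `era`).
#' @param genome A [genome_model()].
#' @param enrichment Named per-era odds multipliers (> 0).
#' @param seed Integer seed.
#' @param base_prob Baseline inclusion probability of a window.
#' @param window Candidate window width in bp.
#' @param name Track name.
#' @return A merged `interval_set` with attribute `coverage_fraction`.
#' @export
gen_feature_track <- function(genes, genome, enrichment, seed,
                              base_prob = 0.2, window = 1000,
                              name = "feature_track") {
  if (any(enrichment <= 0)) stop("odds multipliers must be > 0", call. = FALSE)
  set.seed(seed)
  grid <- make_bins(genome, window)
  p <- rep(base_prob, nrow(grid))
  if (nrow(genes) > 0) {
    win_gr <- GenomicRanges::GRanges(
      grid$chrom, IRanges::IRanges(grid$start + 1L, grid$end))
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    ov <- GenomicRanges::findOverlaps(win_gr, gene_gr)
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov)
      mult_hit <- enrichment[genes$era[S4Vectors::subjectHits(ov)]]
      # one multiplier per era present in the window
      key <- paste(q, genes$era[S4Vectors::subjectHits(ov)])
      first <- !duplicated(key)
      log_mult <- tapply(log(mult_hit[first]), q[first], sum)
      idx <- as.integer(names(log_mult))
      odds <- (base_prob / (1 - base_prob)) * exp(as.numeric(log_mult))
      p[idx] <- odds / (1 + odds)
    }
  }
  keep <- stats::runif(nrow(grid)) < p
  kept <- as.data.frame(grid)[keep, , drop = FALSE]
  out <- if (nrow(kept) == 0) {
    s <- interval_set(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0)), genome, name = name)
    attr(s, "merged") <- TRUE
    s
  } else {
    merge_intervals(interval_set(kept, genome, name = name))
  }
  attr(out, "coverage_fraction") <- sum(out$end - out$start) / genome_length(genome)
  out
}

#' A toy taxonomy of the human lineage
#'
#' Thirty-one phylostrata with two placeholder species each, plus named
#' anchor species at the era-defining strata: *Escherichia coli* (PS 1),
#' *Amphimedon queenslandica* (PS 4), *Branchiostoma floridae* (PS 8),
#' *Ornithorhynchus anatinus* (PS 18), lemur (PS 23), and *Homo sapiens* as
#' the query species at PS 31.
#'
#' @return A [taxonomy()].
#' @export
example_taxonomy <- function() {
  ps <- rep(1:31, each = 2)
  species <- sprintf("clade%02d_sp%d", ps, rep(1:2, 31))
  anchors <- c("1" = "Escherichia coli",
               "4" = "Amphimedon queenslandica",
               "8" = "Branchiostoma floridae",
               "18" = "Ornithorhynchus anatinus",
               "23" = "Lemur catta",
               "31" = "Homo sapiens")
  for (k in names(anchors)) {
    species[match(as.integer(k), ps)] <- anchors[[k]]
  }
  # PS 31 is query-restricted: drop its placeholder second species
  keep <- !(ps == 31 & species != "Homo sapiens")
  taxonomy(species[keep], ps[keep], query_species = "Homo sapiens")
}

#' Generate a homology hit table consistent with planted eras
#'
#' For each gene, draws a target phylostratum inside the planted era and
#' emits a hit with sub-cutoff e-value in a species of that phylostratum (the
#' "most distant" hit), plus closer sub-cutoff hits and supra-cutoff decoy
#' hits in more distant species. Age assignment on the result recovers every
#' planted era, and is invariant to the decoys. Genes planted in the era
#' containing the query-restricted phylostratum may draw PS 31, in which case
#' only self-species hits are emitted.
#'
#' @param genes Gene table with columns `gene_id`, `isoform_id`, `era`
#'   (five-era labels).
#' @param taxonomy A [taxonomy()], e.g. [example_taxonomy()].
#' @param seed Integer seed.
#' @param evalue_cutoff The cutoff the downstream assignment will use.
#' @param n_decoys Decoy (supra-cutoff) hits per gene.
#' @return A hit table (`gene_id`, `isoform_id`, `species`, `evalue`).
#' @export
gen_hit_table <- function(genes, taxonomy, seed, evalue_cutoff = 1e-3,
                          n_decoys = 2) {
  set.seed(seed)
  scheme <- era_scheme("five_era")
  ranges <- lapply(split(scheme$phylostratum, scheme$era), range)
  query <- attr(taxonomy, "query_species")
  species_of_ps <- split(taxonomy$species, taxonomy$phylostratum)
  pick_species <- function(ps) {
    pool <- species_of_ps[[as.character(ps)]]
    pool[sample.int(length(pool), 1)]
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    era <- as.character(genes$era[i])
    rng <- ranges[[era]]
    target_ps <- sample(seq(rng[1], rng[2]), 1)
    out <- list()
    if (target_ps == 31) {
      # query-restricted: only a self hit
      out$self <- data.frame(species = query, evalue = 10^stats::runif(1, -80, -20))
    } else {
      out$distant <- data.frame(species = pick_species(target_ps),
                                evalue = 10^stats::runif(1, -50, -5))
      # a couple of closer (younger) sub-cutoff hits
      closer_pool <- seq(target_ps, 30)
      closer_ps <- closer_pool[sample.int(length(closer_pool),
                                          min(2, 31 - target_ps),
                                          replace = TRUE)]
      out$closer <- data.frame(species = vapply(closer_ps, pick_species, ""),
                               evalue = 10^stats::runif(length(closer_ps), -50, -5))
      out$self <- data.frame(species = query, evalue = 10^stats::runif(1, -80, -20))
    }
    if (n_decoys > 0 && target_ps > 1) {
      # decoys: more distant species but e-value above the cutoff
      decoy_ps <- sample(seq_len(target_ps - 1), n_decoys, replace = TRUE)
      out$decoy <- data.frame(
        species = vapply(decoy_ps, pick_species, ""),
        evalue = 10^stats::runif(n_decoys, log10(evalue_cutoff) + 0.1, 0))
    }
    hits <- do.call(rbind, out)
    hits$gene_id <- genes$gene_id[i]
    hits$isoform_id <- genes$isoform_id[i]
    hits
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[, c("gene_id", "isoform_id", "species", "evalue")]
}

#' Default tissue-to-category map of the synthetic expression data
#'
#' Nine tissues in six categories modelled on germ-layer groupings: ectoderm
#' (cortex, cerebellum), brain (cortex, cerebellum, amygdala), mesoderm
#' (heart, muscle), endoderm (liver, pancreas), ovary and testis. Cortex and
#' cerebellum deliberately belong to both ectoderm and brain, exercising the
#' overlapping-category rule.
#'
#' @return A data frame with columns `tissue`, `category`.
#' @export
default_tissue_categories <- function() {
  data.frame(
    tissue = c("cortex", "cerebellum", "cortex", "cerebellum", "amygdala",
               "heart", "muscle", "liver", "pancreas", "ovary", "testis"),
    category = c("ectoderm", "ectoderm", "brain", "brain", "brain",
                 "mesoderm", "mesoderm", "endoderm", "endoderm",
                 "ovary", "testis"),
    stringsAsFactors = FALSE
  )
}

#' Generate an expression count matrix with era-dependent means
#'
#' Counts are negative-binomial with mean `expr_means[era]` per gene per
#' sample and variance `mu + dispersion * mu^2`, the standard overdispersed
#' model for RNA counts. A tissue layout with replicate samples and the
#' default tissue-to-category map are attached.
#'
#' @param genes Gene table with columns `gene_id`, `era`.
#' @param spec A [synthetic_spec()] (uses `expr_means`, `dispersion`,
#'   `seed`).
#' @param samples_per_tissue Replicate samples per tissue.
#' @param categories Tissue-to-category map
#'   (default [default_tissue_categories()]).
#' @return A list: `counts` (gene x sample matrix), `sample_tissue` (named
#'   character, sample -> tissue), `tissue_category` (data frame), `genes`.
#' @export
gen_expression <- function(genes, spec, samples_per_tissue = 3,
                           categories = default_tissue_categories()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 333L)
  tissues <- unique(categories$tissue)
  samples <- paste(rep(tissues, each = samples_per_tissue),
                   seq_len(samples_per_tissue), sep = "_")
  sample_tissue <- stats::setNames(rep(tissues, each = samples_per_tissue),
                                   samples)
  n_genes <- nrow(genes)
  counts <- matrix(0, nrow = n_genes, ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  if (n_genes > 0) {
    mu <- spec$expr_means[as.character(genes$era)]
    size <- 1 / spec$dispersion
    counts[] <- stats::rnbinom(n_genes * length(samples),
                               mu = rep(mu, times = length(samples)),
                               size = size)
  }
  list(counts = counts, sample_tissue = sample_tissue,
       tissue_category = categories, genes = genes)
}

# ---- ORF test-sequence construction -----------------------------------------

.STOPS <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, .STOPS)
}

# 24-mer with stop codons in all six frames:
# TAA at offsets 0/4/8 (+ frames), TTA (reverse-strand TAA) at 12/16/20
.STOP_MOTIF <- "TAAATAAATAAATTATTTATTTAT"

# 4-codon sense block placing stops in every frame except the reading frame,
# used inside planted ORF bodies so no off-frame ORF can reach the length
# threshold
.GUARD_BLOCK <- c("CTA", "ACT", "AAT", "TAT")

# stop-rich random background: no reading frame on either strand goes more
# than ~80 bp without a stop, so no chance ORF can reach `min_codons`
.stop_rich_background <- function(n) {
  pieces <- character(0)
  total <- 0
  while (total < n) {
    chunk <- paste(sample(c("A", "C", "G", "T"), sample(40:70, 1),
                          replace = TRUE), collapse = "")
    pieces <- c(pieces, chunk, .STOP_MOTIF)
    total <- total + nchar(chunk) + nchar(.STOP_MOTIF)
  }
  # keep the suffix so the piece always ends with the stop motif: adjacent
  # pieces then never concatenate into a long stop-free run
  s <- paste(pieces, collapse = "")
  substr(s, nchar(s) - n + 1, nchar(s))
}

# one planted ORF body: ATG + (n_codons - 1) sense codons + stop, with guard
# blocks every 7 codons so off-frame runs stay short
.planted_orf <- function(n_codons) {
  sense <- .sense_codons()
  body <- character(0)
  remaining <- n_codons - 1
  while (remaining > 0) {
    take <- min(7, remaining)
    body <- c(body, sample(sense, take, replace = TRUE))
    remaining <- remaining - take
    if (remaining >= 4) {
      body <- c(body, .GUARD_BLOCK)
      remaining <- remaining - 4
    }
  }
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Generate a test sequence with embedded ORFs and boundary decoys
#'
#' Builds one chromosome of stop-rich background sequence (no reading frame
#' on either strand runs more than ~80 bp without a stop codon, so no chance
#' ORF can reach the reporting threshold) and embeds `n_orfs` compliant open
#' reading frames (`min_codons` non-stop codons including the Met start,
#' followed by a stop) and `n_decoys` boundary-failing decoys with
#' `min_codons - 1` codons. Half of the embedded constructs are placed on the
#' minus strand. The flanks of every insert carry stop codons in all six
#' frames, so reported ORF coordinates coincide exactly with the planted
#' ones.
#'
#' @param n_orfs Number of compliant ORFs.
#' @param n_decoys Number of decoys one codon short of the threshold.
#' @param chrom_length Chromosome length in bp.
#' @param seed Integer seed.
#' @param min_codons Reporting threshold used downstream.
#' @return A list: `sequence` (named list with one chromosome string),
#'   `genome`, `truth` (data frame `chrom`, `start`, `end`, `strand`,
#'   `type` in {"orf", "decoy"}).
#' @export
gen_orf_sequence <- function(n_orfs = 50, n_decoys = 50, chrom_length = 1e6,
                             seed = 1L, min_codons = 40) {
  set.seed(seed)
  n_ins <- n_orfs + n_decoys
  type <- sample(c(rep("orf", n_orfs), rep("decoy", n_decoys)))
  strand <- sample(rep(c("+", "-"), length.out = n_ins))
  inserts <- vapply(seq_len(n_ins), function(i) {
    nc <- if (type[i] == "orf") min_codons else min_codons - 1
    s <- .planted_orf(nc)
    if (strand[i] == "-") s <- revcomp_dna(s)
    paste0(.STOP_MOTIF, s, .STOP_MOTIF)
  }, "")
  slot <- floor(chrom_length / n_ins)
  ins_len <- nchar(inserts)
  if (any(ins_len + 100 > slot)) {
    stop("chromosome too short for the requested inserts", call. = FALSE)
  }
  offs <- vapply(seq_len(n_ins), function(i) {
    sample.int(slot - ins_len[i] - 50, 1) + 25
  }, numeric(1))
  pieces <- character(0)
  truth <- vector("list", n_ins)
  pos <- 0
  for (i in seq_len(n_ins)) {
    gap1 <- offs[i]
    pieces <- c(pieces, .stop_rich_background(gap1), inserts[i],
                .stop_rich_background(slot - gap1 - ins_len[i]))
    motif_w <- nchar(.STOP_MOTIF)
    start0 <- pos + gap1 + motif_w
    truth[[i]] <- data.frame(chrom = "chrS", start = start0,
                             end = start0 + ins_len[i] - 2 * motif_w,
                             strand = strand[i], type = type[i],
                             stringsAsFactors = FALSE)
    pos <- pos + slot
  }
  tail_n <- chrom_length - pos
  if (tail_n > 0) pieces <- c(pieces, .stop_rich_background(tail_n))
  list(sequence = list(chrS = paste(pieces, collapse = "")),
       genome = genome_model("chrS", chrom_length),
       truth = do.call(rbind, truth))
}
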