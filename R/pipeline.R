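#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run from a single configuration: gene age
#' assignment from a hit table, feature-track pooling and coverage
#' statistics, binned density correlations at every configured bin size,
#' intergenic control construction (when sequence is available), and
#' expression group comparisons. All tables are written to the output
#' directory together with a run manifest (package version, seed, parameter
#' echo, output checksums). Any stage failure aborts with a stage-tagged
#' message.
#'
#' The configuration is a named list (or a YAML/JSON file path) with fields:
#' \describe{
#'   \item{seed}{integer seed used for every random step}
#'   \item{outdir}{output directory (created if needed)}
#'   \item{bin_sizes}{bin sizes in bp (default 20000, 50000, 100000)}
#'   \item{evalue_cutoff, min_aa, max_aa, min_codons}{age/ORF cutoffs
#'     (defaults 1e-3, 40, 4000, 40)}
#'   \item{synthetic}{optional list of [synthetic_spec()] arguments; when
#'     present all inputs are generated}
#'   \item{inputs}{otherwise, paths: `chrom_sizes`, `genes_bed` (6-column
#'     with era labels in the name field), `hits_tsv`, `taxonomy_tsv`,
#'     `query_species`, `tracks` (BED paths), `fasta` (optional), `counts_tsv`
#'     + `sample_map_tsv` + `category_map_tsv` (optional)}
#' }
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with the main result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- as.integer(cfg$seed %||% 1L)
  outdir <- cfg$outdir %||% stop("[config] `outdir` is required", call. = FALSE)
  bin_sizes <- cfg$bin_sizes %||% c(20000, 50000, 100000)
  evalue_cutoff <- cfg$evalue_cutoff %||% 1e-3
  min_aa <- cfg$min_aa %||% 40
  max_aa <- cfg$max_aa %||% 4000
  min_codons <- cfg$min_codons %||% 40
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ---------------------------------------------------------------
  synthetic <- !is.null(cfg$synthetic)
  if (synthetic) {
    world <- stage("synth", {
      spec_args <- cfg$synthetic
      with_seq <- isTRUE(spec_args$sequence %||% TRUE)
      spec_args$sequence <- NULL
      spec_args$seed <- seed
      # config files deliver named lists; spec fields are atomic vectors
      spec_args <- lapply(spec_args, function(x) if (is.list(x)) unlist(x) else x)
      spec <- do.call(synthetic_spec, spec_args)
      g <- gen_genome(spec, sequence = with_seq)
      list(spec = spec, genome = g$genome, genes = g$genes,
           sequence = g$sequence,
           taxonomy = example_taxonomy(),
           hits = gen_hit_table(g$genes, example_taxonomy(), seed = seed + 1L,
                                evalue_cutoff = evalue_cutoff))
    })
    tracks <- stage("tracks", {
      trk <- gen_feature_track(world$genes, world$genome,
                               enrichment = world$spec$enrichment,
                               seed = seed + 2L, name = "feature_track")
      list(feature_track = trk)
    })
    expr_data <- stage("expr-input",
                       gen_expression(world$genes, world$spec))
  } else {
    inp <- cfg$inputs %||% stop("[config] need `synthetic` or `inputs`",
                                call. = FALSE)
    paths <- unlist(inp[c("chrom_sizes", "genes_bed", "hits_tsv",
                          "taxonomy_tsv", "fasta", "counts_tsv",
                          "sample_map_tsv", "category_map_tsv")],
                    use.names = TRUE)
    paths <- c(paths, unlist(inp$tracks))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("[inputs] missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    world <- stage("inputs", {
      genome <- read_chrom_sizes(inp$chrom_sizes)
      gb <- utils::read.table(inp$genes_bed, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
      genes <- data.frame(gene_id = gb$V4, isoform_id = paste0(gb$V4, ".1"),
                          chrom = gb$V1, start = gb$V2, end = gb$V3,
                          era = gb$V5,
                          protein_length = floor((gb$V3 - gb$V2) / 3) - 1,
                          stringsAsFactors = FALSE)
      tax <- read_taxonomy(inp$taxonomy_tsv, inp$query_species)
      list(genome = genome, genes = genes, taxonomy = tax,
           hits = read_hit_table(inp$hits_tsv, tax),
           sequence = if (!is.null(inp$fasta)) read_fasta(inp$fasta))
    })
    tracks <- stage("tracks", {
      trk <- lapply(inp$tracks, function(p)
        merge_intervals(read_bed(p, world$genome)))
      names(trk) <- vapply(trk, track_name, "")
      trk
    })
    expr_data <- if (!is.null(inp$counts_tsv)) stage("expr-input", {
      counts <- as.matrix(utils::read.table(inp$counts_tsv, sep = "\t",
                                            header = TRUE, row.names = 1,
                                            check.names = FALSE))
      smap <- utils::read.table(inp$sample_map_tsv, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
      cmap <- utils::read.table(inp$category_map_tsv, sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
      list(counts = counts,
           sample_tissue = stats::setNames(smap$tissue, smap$sample),
           tissue_category = cmap, genes = world$genes)
    })
  }

  tsv <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  outputs <- character(0)

  # ---- age assignment -------------------------------------------------------
  ages <- stage("age", {
    iso <- filter_proteins(world$genes, min_aa, max_aa)
    assign_gene_ages(world$hits, iso, world$taxonomy, evalue_cutoff)
  })
  outputs <- c(outputs, tsv(ages, "gene_ages.tsv"))

  # ---- interval pooling and stats ------------------------------------------
  era_tracks <- stage("intervals", {
    lv <- levels(ages$era_five)
    out <- lapply(lv, function(e) {
      genes_as_track(transform(ages, era = era_five), world$genome, era = e)
    })
    names(out) <- paste0(tolower(lv), "_genes")
    out
  })
  all_tracks <- c(era_tracks, tracks)
  stats_tbl <- stage("intervals",
                     do.call(rbind, lapply(all_tracks, coverage_stats)))
  outputs <- c(outputs, tsv(stats_tbl, "track_stats.tsv"))

  # ---- binned density correlations -----------------------------------------
  corr_long <- stage("corr", {
    do.call(rbind, lapply(bin_sizes, function(bs) {
      grid <- make_bins(world$genome, bs)
      tbl <- bin_density_table(grid, all_tracks)
      cm <- correlation_matrix(tbl)
      cbind(bin_size = bs, cm$results)
    }))
  })
  outputs <- c(outputs, tsv(corr_long, "correlations.tsv"))

  # ---- intergenic controls --------------------------------------------------
  controls <- NULL
  if (!is.null(world$sequence)) {
    controls <- stage("controls", {
      gene_excl <- merge_intervals(genes_as_track(world$genes, world$genome,
                                                  merged = FALSE))
      orfs <- find_intergenic_orfs(world$sequence, world$genome,
                                   exclusions = gene_excl,
                                   min_codons = min_codons)
      non_orfs <- if (nrow(orfs) > 0) {
        orf_excl <- pool_datasets(list(
          gene_excl,
          interval_set(orfs[, c("chrom", "start", "end")], world$genome,
                       name = "orfs")), name = "exclusions")
        sample_non_orfs(world$sequence, orfs$length, world$genome,
                        exclusions = orf_excl, seed = seed + 3L)
      } else {
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), length = numeric(0))
      }
      list(orfs = orfs, non_orfs = non_orfs)
    })
    p1 <- file.path(outdir, "igen_orfs.bed")
    write_bed(controls$orfs, p1, strand = controls$orfs$strand)
    p2 <- file.path(outdir, "igen_non_orfs.bed")
    write_bed(controls$non_orfs, p2)
    outputs <- c(outputs, p1, p2)
  }

  # ---- expression comparisons ----------------------------------------------
  expr_cmp <- NULL
  if (!is.null(expr_data)) {
    expr_cmp <- stage("expr", {
      sf <- size_factors(expr_data$counts)
      norm <- normalize_counts(expr_data$counts, sf)
      cat_means <- aggregate_by_category(norm, expr_data$sample_tissue,
                                         expr_data$tissue_category)
      grouping <- expr_data$genes$era[match(rownames(cat_means),
                                            expr_data$genes$gene_id)]
      compare_groups(cat_means, grouping)
    })
    outputs <- c(outputs, tsv(expr_cmp, "expression_comparisons.tsv"))
  }

  # ---- manifest -------------------------------------------------------------
  manifest <- list(
    package = "era3d",
    version = as.character(utils::packageVersion("era3d")),
    seed = seed,
    parameters = list(bin_sizes = bin_sizes, evalue_cutoff = evalue_cutoff,
                      min_aa = min_aa, max_aa = max_aa,
                      min_codons = min_codons,
                      synthetic = if (synthetic) cfg$synthetic),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ages = ages, track_stats = stats_tbl,
                 correlations = corr_long, controls = controls,
                 expression = expr_cmp, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
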