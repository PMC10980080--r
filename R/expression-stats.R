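#' Median-of-ratios size factors
#'
#' The normalization used for sequencing-depth and RNA-composition
#' differences between samples: for each gene with non-zero counts in every
#' sample, compute its geometric mean across samples; a sample's size factor
#' is the median over those genes of `count / geometric mean`. Normalized
#' counts are `counts / factor` (column-wise).
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @return Named numeric vector of per-sample size factors.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors(m)  # ratio 2
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  ref_genes <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref_genes)) {
    stop("no gene has non-zero counts in every sample; cannot compute ",
         "median-of-ratios size factors", call. = FALSE)
  }
  log_geo <- rowMeans(log(counts[ref_genes, , drop = FALSE]))
  # median taken on the log-ratio scale (so an even-count median averages
  # geometrically), matching the reference median-of-ratios implementation
  sf <- apply(counts[ref_genes, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @return The normalized matrix.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Aggregate normalized counts into tissue-category means
#'
#' Per gene: first the mean over the replicate samples of each tissue, then
#' the mean over the tissues belonging to each category. A tissue listed in
#' several categories contributes to each of them (e.g. cortex and
#' cerebellum in both ectoderm and brain).
#'
#' @param normalized Gene x sample matrix (typically [normalize_counts()]
#'   output).
#' @param sample_tissue Named character vector: sample -> tissue. Every
#'   column of `normalized` must be mapped.
#' @param tissue_category Data frame with columns `tissue`, `category`.
#' @return Gene x category matrix of mean counts.
#' @export
aggregate_by_category <- function(normalized, sample_tissue,
                                  tissue_category) {
  normalized <- as.matrix(normalized)
  if (!all(colnames(normalized) %in% names(sample_tissue))) {
    stop("every sample must map to exactly one tissue", call. = FALSE)
  }
  tiss <- sample_tissue[colnames(normalized)]
  tissues <- unique(tiss)
  tissue_means <- vapply(tissues, function(t) {
    rowMeans(normalized[, tiss == t, drop = FALSE])
  }, numeric(nrow(normalized)))
  if (nrow(normalized) == 1) tissue_means <- matrix(tissue_means, nrow = 1,
                                                    dimnames = list(rownames(normalized), tissues))
  cats <- unique(tissue_category$category)
  out <- vapply(cats, function(cc) {
    members <- tissue_category$tissue[tissue_category$category == cc]
    members <- intersect(members, colnames(tissue_means))
    if (length(members) == 0) {
      stop("category '", cc, "' has no tissues in the matrix", call. = FALSE)
    }
    rowMeans(tissue_means[, members, drop = FALSE])
  }, numeric(nrow(normalized)))
  if (nrow(normalized) == 1) out <- matrix(out, nrow = 1,
                                           dimnames = list(rownames(normalized), cats))
  rownames(out) <- rownames(normalized)
  out
}

.group_summary <- function(v) {
  c(mean = mean(v),
    sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
    median = stats::median(v),
    n = length(v))
}

#' Rank-based comparisons between gene groups
#'
#' For each requested pair of groups (in each value column), a two-sided
#' Mann-Whitney U test with the normal approximation (tie- and
#' continuity-corrected), Benjamini-Hochberg adjustment over all comparisons
#' produced in this invocation, and per-group summaries (mean, standard error
#' of the mean, median, n) on the untransformed values. Reported p values are
#' floored at `2.225e-308`. Comparisons involving an empty group are skipped
#' with a warning.
#'
#' @param values Numeric vector or gene x category matrix of per-gene values
#'   (e.g. [aggregate_by_category()] output).
#' @param grouping Factor or character vector, one group label per gene.
#' @param comparisons Two-column matrix/data frame of group label pairs;
#'   default: all unordered pairs of observed groups.
#' @return Data frame with columns `category`, `group_a`, `group_b`, `U`,
#'   `p`, `p_adj`, and per-group `mean/sem/median/n`.
#' @export
compare_groups <- function(values, grouping, comparisons = NULL) {
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "all"))
  }
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(values))
  groups <- unique(grouping)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(groups, 2))
  }
  comparisons <- as.matrix(comparisons)
  rows <- list()
  for (cat_name in colnames(values)) {
    v <- values[, cat_name]
    for (k in seq_len(nrow(comparisons))) {
      ga <- comparisons[k, 1]; gb <- comparisons[k, 2]
      va <- v[grouping == ga]; vb <- v[grouping == gb]
      if (length(va) == 0 || length(vb) == 0) {
        warning("skipping comparison ", ga, " vs ", gb,
                ": empty group", call. = FALSE)
        next
      }
      wt <- suppressWarnings(
        stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE))
      sa <- .group_summary(va); sb <- .group_summary(vb)
      rows[[length(rows) + 1]] <- data.frame(
        category = cat_name, group_a = ga, group_b = gb,
        U = unname(wt$statistic),
        p = max(wt$p.value, 2.225e-308),
        mean_a = sa["mean"], sem_a = sa["sem"], median_a = sa["median"],
        n_a = sa["n"],
        mean_b = sb["mean"], sem_b = sb["sem"], median_b = sb["median"],
        n_b = sb["n"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(rows) == 0) {
    stop("no comparison could be performed", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmax(stats::p.adjust(out$p, method = "BH"), out$p)
  out
}

#' Per-decile, per-group expression summaries stratified by gene length
#'
#' Assigns genes to deciles of coding length over the pooled gene set (ties
#' broken by rank order, so deciles are always as equal as possible) and
#' summarizes values per group within each decile. Useful for checking that
#' an expression gradient across groups is maintained at every gene length.
#'
#' @param lengths Numeric vector of gene lengths.
#' @param values Numeric vector of per-gene values (same order).
#' @param grouping Factor/character of group labels per gene.
#' @param n_bins Number of strata (default 10).
#' @return Data frame `decile`, `group`, `n`, `mean`, `sem`, `median`; the
#'   attribute `degenerate` is TRUE when all lengths are identical, in which
#'   case the stratification is arbitrary.
#' @export
length_decile_stratify <- function(lengths, values, grouping, n_bins = 10) {
  n <- length(lengths)
  stopifnot(length(values) == n, length(grouping) == n)
  if (n < n_bins) stop("need at least ", n_bins, " genes", call. = FALSE)
  r <- rank(lengths, ties.method = "first")
  decile <- ceiling(r / n * n_bins)
  grouping <- as.character(grouping)
  rows <- list()
  for (d in sort(unique(decile))) {
    sel <- decile == d
    for (g in unique(grouping[sel])) {
      s <- .group_summary(values[sel & grouping == g])
      rows[[length(rows) + 1]] <- data.frame(
        decile = d, group = g, n = unname(s["n"]), mean = unname(s["mean"]),
        sem = unname(s["sem"]), median = unname(s["median"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- length(unique(lengths)) == 1
  out
}

#' Display transform: log10 with smallest-nonzero offset
#'
#' Handles zeros by adding the smallest non-zero value to every log10
#' argument: with `m = min(values[values > 0])`, returns
#' `log10(values + m)`. Strictly increasing in the input. For display only;
#' summaries elsewhere are computed on untransformed values.
#'
#' @param values Non-negative numeric vector with at least one non-zero
#'   entry.
#' @return Transformed vector.
#' @examples
#' log10_display(c(0, 1, 99))  # log10(1, 2, 100)
#' @export
log10_display <- function(values) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  nz <- values[values > 0]
  if (length(nz) == 0) {
    stop("all values are zero; transform undefined", call. = FALSE)
  }
  log10(values + min(nz))
}
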