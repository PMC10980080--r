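#' Partition a genome into fixed-size bins
#'
#' Each chromosome of length L contributes `ceiling(L / bin_size)` consecutive
#' non-overlapping bins; the final bin is truncated at the chromosome end and
#' enters downstream densities with its true length as denominator. The union
#' of bins is exactly the genome.
#'
#' @param genome A [genome_model()].
#' @param bin_size Bin size in bp (> 0). Typical values: 20000, 50000, 100000.
#' @return A `bin_grid`: data frame with `chrom`, `start`, `end` plus
#'   attributes `genome` and `bin_size`.
#' @examples
#' make_bins(genome_model("chr1", 120), 50)
#' @export
make_bins <- function(genome, bin_size) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    starts <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, L), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, pieces),
            genome = genome, bin_size = bin_size,
            class = c("bin_grid", "data.frame"))
}

#' Per-bin covered fraction of a track
#'
#' For each bin, the fraction of its base pairs covered by the track:
#' `overlap bp / bin length`, in `[0, 1]`. The track must be merged so that
#' overlapping regions do not double count. Conservation law:
#' `sum(fraction * bin length)` equals the track's total coverage.
#'
#' @param grid A `bin_grid` from [make_bins()].
#' @param track A merged `interval_set` on the same genome model.
#' @return Numeric vector of covered fractions, one per bin (grid row order).
#' @export
bin_density <- function(grid, track) {
  stopifnot(inherits(grid, "bin_grid"), inherits(track, "interval_set"))
  if (!.same_genome(attr(grid, "genome"), attr(track, "genome"))) {
    stop("bin grid and track use different genome models", call. = FALSE)
  }
  if (!is_merged(track)) {
    stop("`track` must be merged (see merge_intervals())", call. = FALSE)
  }
  bins_gr <- GenomicRanges::GRanges(
    grid$chrom, IRanges::IRanges(grid$start + 1L, grid$end))
  track_gr <- .as_granges(track)
  ov <- GenomicRanges::findOverlaps(bins_gr, track_gr)
  covered <- numeric(nrow(grid))
  if (length(ov) > 0) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(bins_gr)[q], IRanges::ranges(track_gr)[s]))
    agg <- tapply(w, q, sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / (grid$end - grid$start)
}

#' Per-bin density table for several tracks
#'
#' @param grid A `bin_grid`.
#' @param tracks A named list of merged `interval_set` objects; names default
#'   to each track's own name.
#' @return A data frame: bin coordinates (`chrom`, `start`, `end`) followed by
#'   one covered-fraction column per track.
#' @export
bin_density_table <- function(grid, tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- vapply(tracks, track_name, "")
  }
  dens <- lapply(tracks, function(tr) bin_density(grid, tr))
  out <- cbind(as.data.frame(grid), as.data.frame(dens, optional = TRUE))
  attr(out, "bin_size") <- attr(grid, "bin_size")
  attr(out, "track_names") <- names(tracks)
  out
}

#' Spearman rank correlation with a t-approximation p value
#'
#' Rho is the Pearson correlation of average-ranked values (tie-corrected).
#' The two-sided p value uses the t approximation with `n - 2` degrees of
#' freedom, appropriate for the thousands of genome-wide bins this statistic
#' is designed for; it is floored at `2.225e-308` so that reported p values
#' stay in `(0, 1]`. Constant input is an error (`era3d_constant_input`), not
#' a silent zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` (per-bin fractions or
#'   any paired observations).
#' @return A list with `rho`, `p`, `n`, class `spearman_cor`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop(structure(class = c("era3d_constant_input", "error", "condition"),
                   list(message = "constant input: Spearman correlation undefined",
                        call = sys.call(-1))))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 2.225e-308
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(max(p, 2.225e-308), 1)
  }
  structure(list(rho = rho, p = p, n = n), class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g, n = %d\n", x$rho, x$p, x$n))
  invisible(x)
}

#' All pairwise Spearman correlations between track densities
#'
#' Computes [spearman_cor()] for every unordered pair of track columns of a
#' density table (all genome-wide bins pooled across chromosomes). Pairs
#' where one track is constant are reported with `NA` rho/p and a note rather
#' than aborting the whole matrix. P values are reported raw by default;
#' `p_adjust = "BH"` applies Benjamini-Hochberg across the pairs.
#'
#' @param table A density table from [bin_density_table()], or a plain
#'   data frame / matrix whose columns are track densities.
#' @param tracks Character vector of track column names to use; defaults to
#'   the table's track columns.
#' @param alpha Significance level for the `significant` flag.
#' @param p_adjust Either "none" (default) or "BH".
#' @return A list with `results` (long-format data frame: `track_a`,
#'   `track_b`, `rho`, `p`, `n`, `significant`, `note`), `rho` and `p`
#'   (symmetric matrices, unit diagonal / NA), `bin_size`.
#' @export
correlation_matrix <- function(table, tracks = NULL, alpha = 0.05,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(tracks)) {
    tracks <- attr(table, "track_names")
    if (is.null(tracks)) {
      tracks <- setdiff(colnames(table), c("chrom", "start", "end"))
    }
  }
  if (length(tracks) < 2) stop("need at least 2 tracks", call. = FALSE)
  pairs <- utils::combn(tracks, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- tryCatch(spearman_cor(table[[a]], table[[b]]),
                  era3d_constant_input = function(e) e)
    if (inherits(r, "error")) {
      data.frame(track_a = a, track_b = b, rho = NA_real_, p = NA_real_,
                 n = length(table[[a]]), note = conditionMessage(r),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(track_a = a, track_b = b, rho = r$rho, p = r$p, n = r$n,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  if (p_adjust == "BH") res$p <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p) & res$p < alpha
  rho_m <- matrix(NA_real_, length(tracks), length(tracks),
                  dimnames = list(tracks, tracks))
  p_m <- rho_m
  diag(rho_m) <- 1
  for (k in seq_len(nrow(res))) {
    a <- res$track_a[k]; b <- res$track_b[k]
    rho_m[a, b] <- rho_m[b, a] <- res$rho[k]
    p_m[a, b] <- p_m[b, a] <- res$p[k]
  }
  list(results = res, rho = rho_m, p = p_m,
       bin_size = attr(table, "bin_size"))
}
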