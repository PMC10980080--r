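#' Create a set of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention) and validated against a
#' [genome_model()]: `0 <= start < end <= chromosome length`. A fresh set is
#' not assumed merged; see [merge_intervals()].
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param genome A [genome_model()].
#' @param name Track name (used in density tables and stats output).
#' @return An `interval_set`: a data frame with attributes `genome`, `name`
#'   and `merged`.
#' @examples
#' gm <- genome_model("chr1", 100)
#' s <- interval_set(data.frame(chrom = "chr1", start = 0, end = 10), gm)
#' @export
interval_set <- function(intervals, genome, name = "intervals") {
  stopifnot(inherits(genome, "genome_model"))
  intervals <- as.data.frame(intervals)[, c("chrom", "start", "end")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  lens <- .chrom_lengths(genome)
  bad_chrom <- !(intervals$chrom %in% names(lens))
  if (any(bad_chrom)) {
    stop("interval(s) on chromosome(s) absent from the genome model: ",
         paste(unique(intervals$chrom[bad_chrom]), collapse = ", "),
         call. = FALSE)
  }
  bad <- intervals$start < 0 | intervals$start >= intervals$end |
    intervals$end > lens[intervals$chrom]
  if (any(bad)) {
    stop(sum(bad), " interval(s) violate 0 <= start < end <= chrom length",
         call. = FALSE)
  }
  structure(intervals,
            genome = genome, name = name, merged = FALSE,
            class = c("interval_set", "data.frame"))
}

is_merged <- function(x) isTRUE(attr(x, "merged"))

track_name <- function(x) attr(x, "name")

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set '%s'> %d interval(s), %s bp%s\n",
              attr(x, "name"), nrow(x),
              format(sum(x$end - x$start), big.mark = ","),
              if (is_merged(x)) ", merged" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# GRanges view of an interval set (1-based closed internally)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# back from GRanges to a plain 0-based half-open data frame
.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file into an interval set
#'
#' Reads a 3+ column tab-separated BED file (0-based, half-open). Lines
#' starting with `track`, `browser` or `#` and blank lines are skipped.
#' A line with fewer than three fields or non-numeric coordinates is a parse
#' error reported with its line number. Structurally valid records whose
#' coordinates violate the genome model (start >= end, negative start, end
#' beyond the chromosome, unknown chromosome) are dropped; the number of
#' dropped records is reported via `message()`.
#'
#' @param path Path to the BED file.
#' @param genome A [genome_model()].
#' @param name Track name; defaults to the file name without extension.
#' @return An `interval_set` (unmerged, in file order).
#' @export
read_bed <- function(path, genome, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", idx[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad_num <- is.na(start) | is.na(end)
  if (any(bad_num)) {
    stop("malformed BED line ", idx[which(bad_num)[1]], " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  lens <- .chrom_lengths(genome)
  invalid <- !(chrom %in% names(lens)) | start < 0 | start >= end
  known <- chrom %in% names(lens)
  invalid[known] <- invalid[known] | end[known] > lens[chrom[known]]
  if (any(invalid)) {
    message(sum(invalid), " record(s) rejected while reading ", path,
            " (out of bounds or start >= end)")
  }
  interval_set(
    data.frame(chrom = chrom[!invalid], start = start[!invalid],
               end = end[!invalid], stringsAsFactors = FALSE),
    genome, name = name
  )
}

#' Write an interval set to a BED file
#'
#' Three columns, tab-separated, 0-based half-open. With `strand` supplied a
#' 6-column BED is written (name ".", score 0).
#'
#' @param x An `interval_set` or a data frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @param strand Optional character vector of strands recycled to `nrow(x)`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, strand = NULL) {
  df <- as.data.frame(x)[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (!is.null(strand)) {
    df$name <- "."
    df$score <- 0
    df$strand <- rep_len(strand, nrow(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse overlapping and bookended intervals
#'
#' Returns the minimal sorted set of intervals covering exactly the same base
#' pairs as the input. Touching intervals (one's end equals the next one's
#' start) are merged, matching the default of common merge tools; this choice
#' affects region counts and is pinned by tests.
#'
#' @param x An `interval_set`.
#' @return A merged `interval_set` with the same name and genome.
#' @examples
#' gm <- genome_model("chr1", 100)
#' s <- interval_set(data.frame(chrom = "chr1", start = c(0, 5, 20),
#'                              end = c(10, 15, 30)), gm)
#' merge_intervals(s)
#' @export
merge_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  merged <- .from_granges(GenomicRanges::reduce(.as_granges(x)))
  out <- interval_set(merged, attr(x, "genome"), name = attr(x, "name"))
  attr(out, "merged") <- TRUE
  out
}

#' Pool several interval sets into one collapsed dataset
#'
#' Concatenates the inputs and collapses overlaps, so that any given region is
#' counted only once — the construction used for "pooled domains", "pooled
#' loop anchors" and "pooled boundaries" style tracks. All inputs must share
#' one genome model.
#'
#' @param sets A list of `interval_set` objects.
#' @param name Name for the pooled track.
#' @return A merged `interval_set`.
#' @export
pool_datasets <- function(sets, name = "pooled") {
  stopifnot(is.list(sets), length(sets) >= 1)
  genome <- attr(sets[[1]], "genome")
  for (s in sets) {
    if (!inherits(s, "interval_set")) {
      stop("all elements must be interval_set objects", call. = FALSE)
    }
    if (!.same_genome(attr(s, "genome"), genome)) {
      stop("interval sets come from different genome models", call. = FALSE)
    }
  }
  all_df <- do.call(rbind, lapply(sets, function(s) {
    as.data.frame(s)[, c("chrom", "start", "end")]
  }))
  merge_intervals(interval_set(all_df, genome, name = name))
}

#' Coverage statistics of an interval set
#'
#' Number of regions, median region size (average-of-middle-two for even
#' counts), total coverage in bp, and proportion of the genome covered in
#' percent. The input should be merged so regions are counted once.
#'
#' @param x An `interval_set`.
#' @param genome A [genome_model()]; defaults to the set's own genome.
#' @return A one-row data frame with columns `name`, `n_regions`,
#'   `median_size`, `coverage_bp`, `pct_genome`. `median_size` is `NA` for an
#'   empty set.
#' @examples
#' gm <- genome_model("chr1", 100)
#' s <- merge_intervals(interval_set(
#'   data.frame(chrom = "chr1", start = c(0, 20), end = c(15, 30)), gm))
#' coverage_stats(s)
#' @export
coverage_stats <- function(x, genome = attr(x, "genome")) {
  stopifnot(inherits(x, "interval_set"))
  w <- x$end - x$start
  data.frame(
    name = attr(x, "name"),
    n_regions = nrow(x),
    median_size = if (nrow(x) == 0) NA_real_ else stats::median(w),
    coverage_bp = sum(w),
    pct_genome = 100 * sum(w) / genome_length(genome),
    stringsAsFactors = FALSE
  )
}

#' Subset regions of one set that overlap another, each written once
#'
#' Returns the regions of `a` that have at least 1 bp of overlap with any
#' region of `b`. Each region of `a` appears at most once regardless of how
#' many regions of `b` it overlaps, and the regions of `a` are reported as
#' given — they are not merged with each other.
#'
#' @param a,b `interval_set` objects on the same genome model.
#' @return An `interval_set` containing the overlapping records of `a`.
#' @export
intersect_unique <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (!.same_genome(attr(a, "genome"), attr(b, "genome"))) {
    stop("interval sets come from different genome models", call. = FALSE)
  }
  hit <- IRanges::overlapsAny(.as_granges(a), .as_granges(b))
  out <- interval_set(as.data.frame(a)[hit, , drop = FALSE],
                      attr(a, "genome"), name = attr(a, "name"))
  attr(out, "merged") <- is_merged(a)
  out
}
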