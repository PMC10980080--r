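#' Define a genome model
#'
#' A genome model is the coordinate system every interval container in this
#' package is validated against: a set of uniquely named chromosomes with
#' positive integer lengths in base pairs. It plays the role of a
#' chromosome-sizes file ("chrom.sizes").
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer-valued vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_model`: a data frame with columns
#'   `chrom` and `length`.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e5, 5e4))
#' genome_length(gm)
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp. No header.
#'
#' @param path Path to the TSV file.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_model(df$chrom, df$length)
}

#' Write a chromosome-sizes table
#'
#' @param genome A [genome_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(as.data.frame(genome), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total genome length
#'
#' @param genome A [genome_model()].
#' @return Total length in bp.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$length)
}

# named vector chrom -> length
.chrom_lengths <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

.same_genome <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
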