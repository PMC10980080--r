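#' Reverse complement of a DNA string
#'
#' Case-preserving (soft-masked lowercase stays lowercase) and N-aware.
#'
#' @param x A single DNA string.
#' @return The reverse complement string.
#' @export
revcomp_dna <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Read sequences from a FASTA file, preserving soft-mask case
#'
#' @param path Path to a FASTA file.
#' @return A named list of sequence strings (lowercase = masked).
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  lapply(seqs, function(s) as.character(s)[1])
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named list of sequence strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

# scan one strand of an uppercase chromosome string; returns 0-based
# half-open intervals in the scanned string's own coordinates, including the
# stop codon. Reports, per inter-stop segment, the ORF from the first ATG
# (nested ATGs are not reported separately). ORFs must terminate at an actual
# stop codon.
.scan_frames <- function(seq_uc, min_codons) {
  L <- nchar(seq_uc)
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3
    if (n_cod < min_codons + 1) next
    starts <- seq.int(f + 1, by = 3, length.out = n_cod)
    codons <- substring(seq_uc, starts, starts + 2)
    stop_idx <- which(codons %in% .STOPS)
    if (length(stop_idx) == 0) next
    atg_idx <- which(codons == "ATG")
    if (length(atg_idx) == 0) next
    # next stop at or after each ATG
    pos <- findInterval(atg_idx - 1L, stop_idx) + 1L
    has_stop <- pos <= length(stop_idx)
    atg_idx <- atg_idx[has_stop]
    nxt <- stop_idx[pos[has_stop]]
    # first ATG per segment (segment keyed by its terminating stop)
    keep <- !duplicated(nxt)
    atg_idx <- atg_idx[keep]
    nxt <- nxt[keep]
    n_codons <- nxt - atg_idx
    ok <- n_codons >= min_codons
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      start = f + (atg_idx[ok] - 1L) * 3L,
      end = f + nxt[ok] * 3L,
      codons = n_codons[ok]
    )
  }
  if (length(out) == 0) {
    data.frame(start = integer(0), end = integer(0), codons = integer(0))
  } else {
    do.call(rbind, out)
  }
}

# 1-based positions of masked (lowercase) bases
.masked_positions <- function(seq) {
  gregexpr("[acgtn]", seq)[[1]]
}

#' Find intergenic open reading frames
#'
#' Scans both strands and all three frames per strand for maximal open
#' reading frames: an ATG start followed by at least `min_codons` non-stop
#' codons (the Met counts as one of them), terminated by a stop codon
#' (TAA/TAG/TGA), i.e. a minimum span of `3 * (min_codons + 1)` bp including
#' the stop. Within an inter-stop segment only the ORF from the first ATG is
#' reported, so no reported ORF is nested in another on the same frame.
#' ORFs overlapping excluded intervals, soft-masked (lowercase) sequence, or
#' any N are dropped. Characters other than ACGTN (either case) are a parse
#' error.
#'
#' @param sequence Named list of chromosome strings (lowercase = masked), or
#'   a FASTA path.
#' @param genome A [genome_model()]; inferred from sequence lengths if NULL.
#' @param exclusions Optional `interval_set` of regions to avoid (genes,
#'   previously reported controls, ...).
#' @param min_codons Minimum number of non-stop codons including the Met
#'   start (default 40).
#' @return A data frame (`chrom`, `start`, `end`, `strand`, `length`,
#'   `codons`) of ORFs in 0-based half-open coordinates, stop included.
#' @export
find_intergenic_orfs <- function(sequence, genome = NULL, exclusions = NULL,
                                 min_codons = 40) {
  if (is.character(sequence) && length(sequence) == 1) {
    sequence <- read_fasta(sequence)
  }
  if (is.null(genome)) {
    genome <- genome_model(names(sequence),
                           vapply(sequence, nchar, numeric(1)))
  }
  res <- lapply(names(sequence), function(ch) {
    s <- sequence[[ch]]
    if (grepl("[^ACGTNacgtn]", s)) {
      stop("non-DNA characters in sequence of ", ch, call. = FALSE)
    }
    L <- nchar(s)
    up <- toupper(s)
    fwd <- .scan_frames(up, min_codons)
    fwd$strand <- rep("+", nrow(fwd))
    rev <- .scan_frames(toupper(revcomp_dna(s)), min_codons)
    if (nrow(rev) > 0) {
      tmp <- data.frame(start = L - rev$end, end = L - rev$start,
                        codons = rev$codons, strand = "-")
      rev <- tmp
    } else {
      rev$strand <- character(0)
    }
    orfs <- rbind(fwd, rev)
    if (nrow(orfs) == 0) return(NULL)
    orfs$chrom <- ch
    # drop ORFs touching masked bases or N
    bad_pos <- c(.masked_positions(s), as.integer(gregexpr("N", up)[[1]]))
    bad_pos <- bad_pos[bad_pos > 0]
    if (length(bad_pos) > 0) {
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(orfs$start + 1L, orfs$end),
        IRanges::IRanges(bad_pos, bad_pos))
      orfs <- orfs[!hit, , drop = FALSE]
    }
    orfs
  })
  orfs <- do.call(rbind, res)
  if (is.null(orfs) || nrow(orfs) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), codons = integer(0)))
  }
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    orf_set <- interval_set(orfs[, c("chrom", "start", "end")], genome,
                            name = "orfs")
    hit <- IRanges::overlapsAny(.as_granges(orf_set), .as_granges(exclusions))
    orfs <- orfs[!hit, , drop = FALSE]
  }
  orfs$length <- orfs$end - orfs$start
  orfs <- orfs[order(orfs$chrom, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs[, c("chrom", "start", "end", "strand", "length", "codons")]
}

#' Sample length-matched intergenic non-ORF controls
#'
#' Draws one interval per requested length by seeded rejection sampling,
#' subject to: exact length; entirely unmasked, N-free sequence; no overlap
#' with the exclusion set, with previously drawn controls, or with supplied
#' ORFs; and not beginning with an ATG codon on the plus strand. Because
#' lengths are matched exactly, the produced length distribution equals the
#' requested one.
#'
#' @param sequence Named list of chromosome strings (lowercase = masked), or
#'   a FASTA path.
#' @param lengths Numeric vector of interval lengths in bp (typically the
#'   lengths of a set of intergenic ORFs).
#' @param genome A [genome_model()]; inferred from sequence if NULL.
#' @param exclusions Optional `interval_set` to avoid (genes and ORFs).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per length before failing.
#' @return A data frame (`chrom`, `start`, `end`, `length`), 0-based
#'   half-open.
#' @export
sample_non_orfs <- function(sequence, lengths, genome = NULL,
                            exclusions = NULL, seed = 1L, max_tries = 10000) {
  if (is.character(sequence) && length(sequence) == 1) {
    sequence <- read_fasta(sequence)
  }
  if (is.null(genome)) {
    genome <- genome_model(names(sequence),
                           vapply(sequence, nchar, numeric(1)))
  }
  set.seed(seed)
  chroms <- names(sequence)
  chrom_len <- vapply(sequence, nchar, numeric(1))
  excl <- if (is.null(exclusions) || nrow(exclusions) == 0) NULL else
    as.data.frame(exclusions)[, c("chrom", "start", "end")]
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  overlaps_any <- function(df, ch, st, en) {
    if (is.null(df) || nrow(df) == 0) return(FALSE)
    any(df$chrom == ch & df$start < en & st < df$end)
  }
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    w <- lengths[i]
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- chroms[sample.int(length(chroms), 1,
                              prob = chrom_len / sum(chrom_len))]
      if (chrom_len[ch] < w) next
      st <- sample.int(chrom_len[ch] - w + 1, 1) - 1
      frag <- substr(sequence[[ch]], st + 1, st + w)
      if (grepl("[acgtn]|N", frag)) next
      if (toupper(substr(frag, 1, 3)) == "ATG") next
      if (overlaps_any(excl, ch, st, st + w)) next
      if (overlaps_any(placed, ch, st, st + w)) next
      rec <- data.frame(chrom = ch, start = st, end = st + w,
                        stringsAsFactors = FALSE)
      placed <- rbind(placed, rec)
      out[[i]] <- rec
      done <- TRUE
      break
    }
    if (!done) {
      stop("could not place a non-ORF control of length ", w,
           " after ", max_tries, " tries", call. = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  }
  rownames(res) <- NULL
  res$length <- res$end - res$start
  res
}
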