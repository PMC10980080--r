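# Independent oracles used to validate the package's primitives.
# Each oracle takes a deliberately different route from the implementation
# it checks (per-base masks, explicit rank-Pearson, exhaustive enumeration).

# per-base boolean mask of a set of 0-based half-open intervals on one
# chromosome of length L
mask_cover <- function(starts, ends, L) {
  m <- rep(FALSE, L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) m[(starts[i] + 1):ends[i]] <- TRUE
  }
  m
}

# minimal merged intervals from a boolean mask (0-based half-open)
mask_to_intervals <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# random interval data frame on one chromosome
random_intervals <- function(n, L) {
  s <- sample.int(L - 1, n, replace = TRUE) - 1
  w <- sample.int(max(2, L %/% 5), n, replace = TRUE)
  data.frame(chrom = "chr1", start = s, end = pmin(s + w, L))
}

# Spearman rho by explicit average-ranking then textbook Pearson
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact Mann-Whitney by enumerating all assignments of the pooled values to
# the two groups; returns U of the first sample and the exact two-sided p
# (probability of a U at least as far from the null mean)
mwu_exact <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  mid <- n1 * length(y) / 2
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p <- mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
  list(U = u_obs, p = p)
}

# Benjamini-Hochberg by the step-up formula
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force ORF scan of one strand by walking every start position
orf_scan_bruteforce <- function(seq_uc, min_codons) {
  L <- nchar(seq_uc)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  claimed_stops <- character(0)
  for (p in seq_len(L - 2)) {
    if (substr(seq_uc, p, p + 2) != "ATG") next
    q <- p
    n_cod <- 0
    repeat {
      if (q + 2 > L) { q <- NA; break }
      cod <- substr(seq_uc, q, q + 2)
      if (cod %in% stops) break
      n_cod <- n_cod + 1
      q <- q + 3
    }
    if (is.na(q) || n_cod < min_codons) next
    key <- paste(q, (p - 1) %% 3)   # one ORF per (stop, frame)
    if (key %in% claimed_stops) next
    claimed_stops <- c(claimed_stops, key)
    found[[length(found) + 1]] <- data.frame(start = p - 1, end = q + 2,
                                             codons = n_cod)
  }
  if (length(found) == 0) {
    data.frame(start = integer(0), end = integer(0), codons = integer(0))
  } else {
    do.call(rbind, found)
  }
}
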