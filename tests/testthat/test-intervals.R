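gm100 <- genome_model("chr1", 100)

iset <- function(starts, ends, gm = gm100) {
  interval_set(data.frame(chrom = rep("chr1", length(starts)),
                          start = starts, end = ends), gm)
}

test_that("interval sets are validated against the genome model", {
  expect_error(iset(50, 40), "start < end")
  expect_error(iset(-1, 10), "start < end|violate")
  expect_error(iset(90, 110), "violate")
  expect_error(interval_set(data.frame(chrom = "chrX", start = 0, end = 5),
                            gm100), "absent")
  expect_equal(nrow(iset(numeric(0), numeric(0))), 0)
})

test_that("merge collapses overlapping and touching intervals", {
  m <- merge_intervals(iset(c(0, 5, 20), c(10, 15, 30)))
  expect_equal(as.data.frame(m)$start, c(0, 20))
  expect_equal(as.data.frame(m)$end, c(15, 30))
  # bookended intervals merge
  m2 <- merge_intervals(iset(c(0, 10), c(10, 20)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$end, 20)
  # empty set
  expect_equal(nrow(merge_intervals(iset(numeric(0), numeric(0)))), 0)
  # idempotent
  expect_equal(as.data.frame(merge_intervals(m)), as.data.frame(m))
})

test_that("merge and pool agree with the per-base mask oracle", {
  set.seed(11)
  for (rep in 1:50) {
    L <- sample(50:500, 1)
    gm <- genome_model("chr1", L)
    df <- random_intervals(sample(1:12, 1), L)
    s <- interval_set(df, gm)
    m <- merge_intervals(s)
    oracle <- mask_to_intervals(mask_cover(df$start, df$end, L))
    expect_equal(as.data.frame(m)[, c("start", "end")], oracle,
                 ignore_attr = TRUE)
    # coverage preserved
    expect_equal(sum(m$end - m$start), sum(mask_cover(df$start, df$end, L)))
    # pooling two random sets == mask union
    df2 <- random_intervals(sample(1:12, 1), L)
    pooled <- pool_datasets(list(s, interval_set(df2, gm)))
    oracle2 <- mask_to_intervals(mask_cover(c(df$start, df2$start),
                                            c(df$end, df2$end), L))
    expect_equal(as.data.frame(pooled)[, c("start", "end")], oracle2,
                 ignore_attr = TRUE)
  }
})

test_that("pooling is idempotent, commutative, and rejects mixed genomes", {
  a <- iset(c(0, 30), c(10, 40))
  b <- iset(c(5, 60), c(20, 70))
  expect_equal(as.data.frame(pool_datasets(list(a))),
               as.data.frame(merge_intervals(a)), ignore_attr = TRUE)
  expect_equal(as.data.frame(pool_datasets(list(a, a))),
               as.data.frame(merge_intervals(a)), ignore_attr = TRUE)
  expect_equal(as.data.frame(pool_datasets(list(a, b))),
               as.data.frame(pool_datasets(list(b, a))), ignore_attr = TRUE)
  # disjoint sets: coverage adds
  d1 <- iset(0, 10); d2 <- iset(50, 60)
  expect_equal(sum(with(pool_datasets(list(d1, d2)), end - start)), 20)
  gm2 <- genome_model("chr1", 200)
  expect_error(pool_datasets(list(a, iset(0, 10, gm2))), "different genome")
})

test_that("coverage statistics follow the stated definitions", {
  s <- merge_intervals(iset(c(0, 20), c(15, 30)))
  st <- coverage_stats(s)
  expect_equal(st$n_regions, 2)
  expect_equal(st$median_size, 12.5)
  expect_equal(st$coverage_bp, 25)
  expect_equal(st$pct_genome, 25)
  # odd count median
  s3 <- merge_intervals(iset(c(0, 20, 50), c(10, 40, 140),
                             genome_model("chr1", 1000)))
  expect_equal(coverage_stats(s3)$median_size, 20)
  # empty set
  st0 <- coverage_stats(merge_intervals(iset(numeric(0), numeric(0))))
  expect_equal(st0$n_regions, 0)
  expect_equal(st0$coverage_bp, 0)
  expect_true(is.na(st0$median_size))
})

test_that("intersect_unique reports each overlapping record of a once", {
  a <- iset(c(0, 50), c(10, 60))
  b <- iset(c(5, 6), c(8, 9))
  r <- intersect_unique(a, b)
  expect_equal(as.data.frame(r)[, c("start", "end")],
               data.frame(start = 0, end = 10), ignore_attr = TRUE)
  # empty b
  expect_equal(nrow(intersect_unique(a, iset(numeric(0), numeric(0)))), 0)
  # a fully covered: unchanged, unmerged records preserved
  cover <- iset(0, 100)
  aa <- iset(c(0, 5, 50), c(10, 15, 60))
  expect_equal(as.data.frame(intersect_unique(aa, cover)),
               as.data.frame(aa))
})

test_that("intersect_unique matches pairwise brute force on random sets", {
  set.seed(21)
  for (rep in 1:30) {
    L <- 300
    gm <- genome_model("chr1", L)
    a_df <- random_intervals(sample(1:10, 1), L)
    b_df <- random_intervals(sample(1:10, 1), L)
    got <- as.data.frame(intersect_unique(interval_set(a_df, gm),
                                          interval_set(b_df, gm)))
    keep <- vapply(seq_len(nrow(a_df)), function(i) {
      any(a_df$start[i] < b_df$end & b_df$start < a_df$end[i])
    }, logical(1))
    expect_equal(got[, c("start", "end")],
                 a_df[keep, c("start", "end")], ignore_attr = TRUE)
  }
})

test_that("BED round trip preserves intervals and validates input", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t0\t10", "chr1\t50\t60"), path)
  s <- read_bed(path, gm100)
  expect_equal(as.data.frame(s)$start, c(0, 50))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, out)
  expect_equal(as.data.frame(read_bed(out, gm100))[, c("start", "end")],
               as.data.frame(s)[, c("start", "end")])
  # start >= end and out-of-bounds records dropped with a message
  writeLines(c("chr1\t50\t40", "chr1\t0\t10", "chr1\t90\t200"), path)
  expect_message(s2 <- read_bed(path, gm100), "2 record")
  expect_equal(nrow(s2), 1)
  # malformed lines are parse errors with line numbers
  writeLines(c("chr1\t0\t10", "chr1\t5"), path)
  expect_error(read_bed(path, gm100), "line 2")
  writeLines(c("chr1\tzero\tten"), path)
  expect_error(read_bed(path, gm100), "non-numeric")
})
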