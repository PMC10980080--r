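test_that("size factors follow the median-of-ratios closed form", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(m)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  # identical samples get equal factors; single sample gets factor 1
  m2 <- cbind(a = c(5, 7), b = c(5, 7))
  expect_equal(unname(size_factors(m2)[1]), unname(size_factors(m2)[2]))
  expect_equal(unname(size_factors(matrix(c(3, 9), ncol = 1))), 1)
  # no all-nonzero gene -> error
  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "non-zero")
})

test_that("size factors match DESeq2 and are scale-equivariant", {
  skip_if_not_installed("DESeq2")
  set.seed(71)
  m <- matrix(rnbinom(400, mu = 50, size = 2) + 1, nrow = 80,
              dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(size_factors(m),
               DESeq2::estimateSizeFactorsForMatrix(m), tolerance = 1e-12)
  # size factors are defined up to a common scale, so scaling one sample by
  # c multiplies its factor by c relative to the others...
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  sf <- size_factors(m)
  sf2 <- size_factors(m2)
  expect_equal(unname((sf2[3] / sf2[-3]) / (sf[3] / sf[-3])), rep(4, 4),
               tolerance = 1e-12)
  # ...and leaves normalized counts invariant up to that common scale
  n1 <- normalize_counts(m, sf)
  n2 <- normalize_counts(m2, sf2)
  expect_equal(n2 * (n1[1, 1] / n2[1, 1]), n1, tolerance = 1e-12)
})

test_that("category aggregation averages tissues, sharing where configured", {
  counts <- matrix(c(10, 0, 20, 0, 30, 60), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:6)))
  smap <- setNames(c("cortex", "cortex", "cerebellum", "cerebellum",
                     "liver", "liver"), paste0("s", 1:6))
  cmap <- data.frame(
    tissue = c("cortex", "cerebellum", "cortex", "cerebellum", "liver"),
    category = c("ectoderm", "ectoderm", "brain", "brain", "endoderm"))
  out <- aggregate_by_category(counts, smap, cmap)
  # cortex mean 5, cerebellum mean 10, liver mean 45
  expect_equal(out["g1", "ectoderm"], 7.5)
  expect_equal(out["g1", "brain"], 7.5)     # shared tissues count in both
  expect_equal(out["g1", "endoderm"], 45)
  # one tissue per category: category mean equals tissue mean
  cm1 <- data.frame(tissue = "liver", category = "endoderm")
  expect_equal(aggregate_by_category(counts, smap, cm1)[1, 1], 45)
  # all-zero gene stays zero
  z <- matrix(0, 1, 6, dimnames = list("z", paste0("s", 1:6)))
  expect_equal(unname(aggregate_by_category(z, smap, cmap)[1, ]), c(0, 0, 0))
  expect_error(aggregate_by_category(
    counts, smap, data.frame(tissue = "kidney", category = "mesoderm")),
    "no tissues")
})

test_that("group comparison U, p and BH behave on pinned cases", {
  # identical groups: U = n1*n2/2 and p ~ 1
  r <- compare_groups(c(1, 2, 3, 1, 2, 3),
                      c("a", "a", "a", "b", "b", "b"))
  expect_equal(r$U, 4.5)
  expect_gt(r$p, 0.9)
  # complete separation: U = 0, small p
  r2 <- compare_groups(c(1, 2, 3, 10, 20, 30),
                       c("a", "a", "a", "b", "b", "b"))
  expect_equal(r2$U, 0)
  expect_lt(r2$p, 0.1)
  # empty group comparisons are skipped with a warning
  expect_warning(
    compare_groups(1:4, c("a", "a", "b", "b"),
                   comparisons = rbind(c("a", "b"), c("a", "c"))),
    "empty group")
})

test_that("U and p agree with exhaustive enumeration for small groups", {
  set.seed(81)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(1:8, n1, replace = TRUE)
    y <- sample(1:8, n2, replace = TRUE)
    r <- compare_groups(c(x, y), rep(c("x", "y"), c(n1, n2)),
                        comparisons = rbind(c("x", "y")))
    ex <- mwu_exact(x, y)
    expect_equal(r$U, ex$U)
    # normal approximation tracks the exact p away from the extreme tails
    if (ex$p > 0.2 && ex$p < 1) {
      expect_lt(abs(r$p - ex$p) / ex$p, 0.35)
    }
  }
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  r <- compare_groups(rep(1:10, 5), rep(letters[1:5], each = 10))
  expect_true(all(r$p_adj >= r$p))
  expect_true(all(r$p_adj <= 1))
  set.seed(91)
  for (rep in 1:20) {
    pv <- runif(sample(2:12, 1))
    expect_equal(p.adjust(pv, "BH"), bh_stepup(pv), tolerance = 1e-15)
  }
  expect_equal(bh_stepup(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
})

test_that("length-decile stratification preserves a planted gradient", {
  set.seed(101)
  n <- 100
  lengths <- sample(200:5000, n)
  grp <- rep(c("old", "young"), each = n / 2)
  values <- ifelse(grp == "old", 100, 10) + rnorm(n)
  out <- length_decile_stratify(lengths, values, grp)
  expect_equal(sum(out$n), n)
  expect_false(attr(out, "degenerate"))
  for (d in unique(out$decile)) {
    sub <- out[out$decile == d, ]
    if (all(c("old", "young") %in% sub$group)) {
      expect_gt(sub$median[sub$group == "old"],
                sub$median[sub$group == "young"])
    }
  }
  # distinct lengths, 100 genes -> deciles of 10
  expect_equal(unname(table(rep(out$decile, out$n))), rep(10, 10),
               ignore_attr = TRUE)
  # identical lengths flagged degenerate
  deg <- length_decile_stratify(rep(5, 20), rnorm(20), rep("g", 20))
  expect_true(attr(deg, "degenerate"))
  expect_error(length_decile_stratify(1:5, 1:5, rep("g", 5)), "at least")
})

test_that("log10 display transform offsets by the smallest non-zero value", {
  expect_equal(log10_display(c(0, 1, 99)), c(0, log10(2), 2))
  expect_equal(log10_display(5), 1)
  v <- c(0, 0.5, 2, 7)
  expect_true(all(diff(log10_display(v)) > 0))
  expect_error(log10_display(c(0, 0)), "all values are zero")
  expect_error(log10_display(c(-1, 2)), ">= 0")
})
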