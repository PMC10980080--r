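tax <- example_taxonomy()

test_that("protein length filtering keeps [40, 4000) and reports rejects", {
  iso <- data.frame(gene_id = "g", isoform_id = letters[1:5],
                    protein_length = c(39, 40, 3999, 4000, NA))
  expect_warning(
    expect_message(out <- filter_proteins(iso), "removed"),
    "missing")
  expect_equal(out$protein_length, c(40, 3999))
  expect_equal(nrow(filter_proteins(iso[0, ])), 0)
})

test_that("phylostratum assignment takes the most distant sub-cutoff hit", {
  expect_equal(assign_phylostratum(
    data.frame(species = "Escherichia coli", evalue = 1e-50), tax), 1L)
  expect_equal(assign_phylostratum(
    data.frame(species = c("Ornithorhynchus anatinus", "Lemur catta"),
               evalue = c(1e-5, 1e-20)), tax), 18L)
  # the cutoff is strict: an e-value of 0.01 does not count
  expect_equal(assign_phylostratum(
    data.frame(species = c("Escherichia coli", "Lemur catta"),
               evalue = c(0.01, 1e-9)), tax), 23L)
  # e-value exactly at the cutoff is excluded
  expect_equal(assign_phylostratum(
    data.frame(species = c("Escherichia coli", "Lemur catta"),
               evalue = c(1e-3, 1e-9)), tax), 23L)
  # no non-self hits -> query-restricted
  expect_equal(assign_phylostratum(
    data.frame(species = "Homo sapiens", evalue = 1e-80), tax), 31L)
  expect_equal(assign_phylostratum(NULL, tax), 31L)
})

test_that("adding a more distant sub-cutoff hit never increases the stratum", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    hits <- data.frame(
      species = sprintf("clade%02d_sp2", sample(1:30, n, replace = TRUE)),
      evalue = 10^runif(n, -50, 0))
    ps0 <- assign_phylostratum(hits, tax)
    extra_ps <- sample(1:30, 1)
    hits2 <- rbind(hits, data.frame(
      species = sprintf("clade%02d_sp2", extra_ps), evalue = 1e-10))
    ps1 <- assign_phylostratum(hits2, tax)
    expect_lte(ps1, ps0)
    expect_lte(ps1, extra_ps)
  }
})

test_that("representative isoform is the longest of the oldest", {
  iso <- data.frame(gene_id = "g", isoform_id = c("i1", "i2", "i3"),
                    phylostratum = c(3, 1, 1),
                    protein_length = c(100, 50, 80))
  r <- select_representative(iso)
  expect_equal(r$phylostratum, 1)
  expect_equal(r$protein_length, 80)
  expect_equal(select_representative(iso[1, ])$isoform_id, "i1")
  # equal-length tie broken by smallest isoform id
  tie <- data.frame(gene_id = "g", isoform_id = c("b", "a"),
                    phylostratum = 1, protein_length = 80)
  expect_equal(select_representative(tie)$isoform_id, "a")
})

test_that("era maps cover all 31 strata and agree on the recent eras", {
  five <- era_scheme("five_era")
  four <- era_scheme("four_era")
  expect_equal(nrow(five), 31)
  expect_false(anyNA(five$era))
  expect_false(anyNA(four$era))
  expect_equal(as.character(map_to_era(5, five)), "Metazoan")
  expect_equal(as.character(map_to_era(13, four)), "Early")
  expect_equal(as.character(map_to_era(31, five)), "Primate")
  expect_equal(as.character(map_to_era(31, four)), "Primate")
  # five- and four-era schemes classify PS 18-31 identically
  recent <- 18:31
  expect_equal(as.character(map_to_era(recent, five)),
               as.character(map_to_era(recent, four)))
  expect_error(map_to_era(0, five), "1..31")
  expect_error(map_to_era(32, five), "1..31")
})

test_that("full age assignment picks per-gene representatives", {
  iso <- data.frame(gene_id = c("g1", "g1", "g2"),
                    isoform_id = c("g1.1", "g1.2", "g2.1"),
                    protein_length = c(100, 200, 60))
  hits <- rbind(
    data.frame(gene_id = "g1", isoform_id = "g1.1",
               species = "Escherichia coli", evalue = 1e-40),
    data.frame(gene_id = "g1", isoform_id = "g1.2",
               species = "Lemur catta", evalue = 1e-40),
    data.frame(gene_id = "g2", isoform_id = "g2.1",
               species = "Branchiostoma floridae", evalue = 1e-10))
  ages <- assign_gene_ages(hits, iso, tax)
  expect_equal(ages$phylostratum, c(1L, 8L))
  # g1's oldest isoform (PS 1) wins though the PS-23 one is longer
  expect_equal(ages$isoform_id[ages$gene_id == "g1"], "g1.1")
  expect_equal(as.character(ages$era_five), c("Ancient", "Chordate"))
  expect_equal(as.character(ages$era_four), c("Early", "Early"))
})

test_that("method comparison classifies by era rank and reports fractions", {
  eras <- c("Early", "Vertebrate", "Mammal", "Primate")
  f <- function(x) factor(x, levels = eras, ordered = TRUE)
  a <- setNames(f(c("Early", "Mammal", "Primate")), c("g1", "g2", "g3"))
  b <- setNames(f(c("Early", "Early", "Mammal")), c("g1", "g2", "g3"))
  r <- compare_age_methods(a, b)
  expect_equal(unname(r$summary["same"]), 1 / 3)
  expect_equal(unname(r$summary["younger_by_a"]), 2 / 3)
  expect_equal(sum(r$summary[c("same", "younger_by_a", "younger_by_b")]), 1)
  # identical inputs -> all same
  expect_equal(unname(compare_age_methods(a, a)$summary["same"]), 1)
  # a younger than b everywhere
  a2 <- setNames(f(c("Mammal", "Primate", "Vertebrate")), c("g1", "g2", "g3"))
  b2 <- setNames(f(c("Early", "Mammal", "Early")), c("g1", "g2", "g3"))
  expect_equal(unname(compare_age_methods(b2, a2)$summary["younger_by_b"]), 1)
  # intersection of gene universes is used
  a3 <- setNames(f(c("Early", "Early")), c("g1", "gX"))
  expect_equal(compare_age_methods(a3, b)$n, 1)
  expect_error(compare_age_methods(
    setNames(f("Early"), "only_a"), setNames(f("Early"), "only_b")),
    "no genes")
})

test_that("comparison labels rebuilt from tallies reproduce the tallies", {
  lab <- build_comparison_labels(
    n_total = 1000, n_same = 600, n_younger_a = 350, n_younger_b = 50,
    n_oldest_a = 550, n_oldest_b = 850)
  expect_equal(nrow(lab), 1000)
  r <- compare_age_methods(setNames(lab$era_a, lab$gene_id),
                           setNames(lab$era_b, lab$gene_id))
  expect_equal(unname(r$summary["same"]), 0.6)
  expect_equal(unname(r$summary["younger_by_a"]), 0.35)
  expect_equal(unname(r$summary["younger_by_b"]), 0.05)
  expect_equal(unname(r$summary["oldest_a"]), 0.55)
  expect_equal(unname(r$summary["oldest_b"]), 0.85)
  expect_error(build_comparison_labels(10, 5, 4, 2, 5, 5), "sum")
})
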