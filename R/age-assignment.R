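#' Build a taxonomy of phylostrata
#'
#' A phylostratum (PS) is the interval between successive divergence nodes on
#' the query species' lineage: PS 1 is the most ancient (cellular organisms),
#' PS 31 is restricted to the query species. Every species maps to exactly one
#' phylostratum; the query species maps to the youngest one.
#'
#' @param species Character vector of species names (unique).
#' @param phylostratum Integer vector in `1..n_strata`, one per species.
#' @param query_species Name of the query species; must map to `n_strata`.
#' @param age_mya Optional numeric vector of node ages in million years.
#' @param n_strata Number of phylostrata (default 31, the human lineage).
#' @return A `taxonomy` data frame with attributes `query_species`,
#'   `n_strata`.
#' @export
taxonomy <- function(species, phylostratum, query_species,
                     age_mya = NULL, n_strata = 31L) {
  species <- as.character(species)
  phylostratum <- as.integer(phylostratum)
  if (anyDuplicated(species)) {
    stop("each species must map to exactly one phylostratum", call. = FALSE)
  }
  if (any(phylostratum < 1 | phylostratum > n_strata)) {
    stop("phylostrata must lie in 1..", n_strata, call. = FALSE)
  }
  if (!query_species %in% species ||
      phylostratum[match(query_species, species)] != n_strata) {
    stop("`query_species` must be present and map to phylostratum ",
         n_strata, call. = FALSE)
  }
  df <- data.frame(species = species, phylostratum = phylostratum,
                   stringsAsFactors = FALSE)
  if (!is.null(age_mya)) df$age_mya <- as.numeric(age_mya)
  structure(df, query_species = query_species, n_strata = as.integer(n_strata),
            class = c("taxonomy", "data.frame"))
}

#' Read a taxonomy table
#'
#' Tab-separated with header columns `species`, `phylostratum` and optionally
#' `age_mya`.
#'
#' @param path Path to the TSV.
#' @param query_species Query species name.
#' @param n_strata Number of phylostrata.
#' @return A [taxonomy()].
#' @export
read_taxonomy <- function(path, query_species, n_strata = 31L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  taxonomy(df$species, df$phylostratum, query_species,
           age_mya = df$age_mya, n_strata = n_strata)
}

#' Era schemes: grouping phylostrata into large-scale evolutionary eras
#'
#' Two schemes are provided. `five_era`: Ancient (PS 1-3), Metazoan (PS 4-7),
#' Chordate (PS 8-17), Mammal (PS 18-22), Primate (PS 23-31). `four_era`
#' (used when comparing against synteny-based ages whose oldest branch spans
#' PS 1-13): Early (PS 1-13), Vertebrate (PS 14-17), Mammal (PS 18-22),
#' Primate (PS 23-31). Both maps are total over PS 1-31 and agree on
#' Mammal/Primate.
#'
#' @param name `"five_era"` or `"four_era"`.
#' @return An `era_scheme` data frame with columns `phylostratum` and `era`
#'   (ordered factor, oldest first).
#' @examples
#' era_scheme("five_era")
#' @export
era_scheme <- function(name = c("five_era", "four_era")) {
  name <- match.arg(name)
  if (name == "five_era") {
    labels <- c("Ancient", "Metazoan", "Chordate", "Mammal", "Primate")
    breaks <- c(3, 7, 17, 22, 31)
  } else {
    labels <- c("Early", "Vertebrate", "Mammal", "Primate")
    breaks <- c(13, 17, 22, 31)
  }
  era <- labels[findInterval(1:31, c(0, breaks[-length(breaks)]) + 1)]
  structure(
    data.frame(phylostratum = 1:31,
               era = factor(era, levels = labels, ordered = TRUE)),
    scheme_name = name,
    class = c("era_scheme", "data.frame")
  )
}

#' Map phylostrata to era labels
#'
#' @param ps Integer vector of phylostrata in 1..31.
#' @param scheme An [era_scheme()].
#' @return Ordered factor of era labels (oldest level first).
#' @examples
#' map_to_era(c(1, 5, 13, 31), era_scheme("five_era"))
#' @export
map_to_era <- function(ps, scheme = era_scheme("five_era")) {
  stopifnot(inherits(scheme, "era_scheme"))
  ps <- as.integer(ps)
  if (any(is.na(ps)) || any(ps < 1 | ps > nrow(scheme))) {
    stop("phylostrata must lie in 1..", nrow(scheme), call. = FALSE)
  }
  scheme$era[match(ps, scheme$phylostratum)]
}

#' Filter isoforms by protein length
#'
#' Short proteins (< `min_aa`) cannot be assigned a lineage restriction level
#' reliably; extremely long ones (>= `max_aa`) are removed as well. A record
#' is retained iff `min_aa <= length < max_aa`. Records with missing length
#' are rejected with a warning.
#'
#' @param isoforms Data frame with a `protein_length` column (amino acids).
#' @param min_aa,max_aa Length bounds (defaults 40 and 4000).
#' @return The retained rows; counts of removed records are reported via
#'   `message()`.
#' @export
filter_proteins <- function(isoforms, min_aa = 40, max_aa = 4000) {
  len <- isoforms$protein_length
  missing_len <- is.na(len)
  if (any(missing_len)) {
    warning(sum(missing_len), " record(s) with missing protein length rejected",
            call. = FALSE)
  }
  keep <- !missing_len & len >= min_aa & len < max_aa
  n_short <- sum(!missing_len & len < min_aa)
  n_long <- sum(!missing_len & len >= max_aa)
  if (n_short + n_long > 0) {
    message("removed ", n_short, " protein(s) < ", min_aa, " AA and ",
            n_long, " >= ", max_aa, " AA")
  }
  isoforms[keep, , drop = FALSE]
}

#' Assign a phylostratum to one isoform from its homology hits
#'
#' The minimal evolutionary age of a gene is set by the most taxonomically
#' distant species containing a sufficiently similar protein: among hits with
#' e-value strictly below the cutoff, the minimum phylostratum number is
#' returned ("most distant" = most ancient). Hits in the query species itself
#' carry no lineage information and are ignored. If no non-self hit passes
#' the cutoff the youngest phylostratum is returned — the gene is restricted
#' to the query species.
#'
#' @param hits Data frame of hits for one isoform with columns `species` and
#'   `evalue`.
#' @param taxonomy A [taxonomy()].
#' @param evalue_cutoff Strict upper bound on e-values (default `1e-3`).
#' @return A single integer phylostratum.
#' @examples
#' tax <- example_taxonomy()
#' assign_phylostratum(
#'   data.frame(species = "Escherichia coli", evalue = 1e-50), tax)
#' @export
assign_phylostratum <- function(hits, taxonomy, evalue_cutoff = 1e-3) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  if (nrow(taxonomy) == 0) stop("empty taxonomy", call. = FALSE)
  stopifnot(evalue_cutoff > 0)
  n_strata <- attr(taxonomy, "n_strata")
  if (is.null(hits) || nrow(hits) == 0) return(as.integer(n_strata))
  ps <- taxonomy$phylostratum[match(hits$species, taxonomy$species)]
  if (anyNA(ps)) {
    stop("hit species not in taxonomy: ",
         paste(unique(hits$species[is.na(ps)]), collapse = ", "),
         call. = FALSE)
  }
  pass <- hits$evalue < evalue_cutoff &
    hits$species != attr(taxonomy, "query_species")
  if (!any(pass)) return(as.integer(n_strata))
  as.integer(min(ps[pass]))
}

#' Select the representative isoform of a gene
#'
#' To avoid double counting, one isoform represents each gene: the longest of
#' the oldest isoforms. Among isoforms with the minimal phylostratum number,
#' the one with maximal protein length is chosen; equal lengths are broken
#' deterministically by the lexicographically smallest isoform id.
#'
#' @param isoforms Data frame of one gene's isoforms with columns
#'   `phylostratum`, `protein_length`, `isoform_id`.
#' @return The selected row.
#' @export
select_representative <- function(isoforms) {
  stopifnot(nrow(isoforms) >= 1)
  cand <- isoforms[isoforms$phylostratum == min(isoforms$phylostratum), ,
                   drop = FALSE]
  cand <- cand[cand$protein_length == max(cand$protein_length), ,
               drop = FALSE]
  cand[order(cand$isoform_id)[1], , drop = FALSE]
}

#' Read a homology hit table
#'
#' Tab-separated with header columns `gene_id`, `isoform_id`, `species`,
#' `evalue`. Species that cannot be resolved in the taxonomy are rejected at
#' load time.
#'
#' @param path Path to the TSV.
#' @param taxonomy A [taxonomy()] used to validate species names.
#' @return A data frame of hits.
#' @export
read_hit_table <- function(path, taxonomy) {
  hits <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  req <- c("gene_id", "isoform_id", "species", "evalue")
  if (!all(req %in% colnames(hits))) {
    stop("hit table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(hits$evalue < 0)) stop("e-values must be >= 0", call. = FALSE)
  unknown <- !(hits$species %in% taxonomy$species)
  if (any(unknown)) {
    stop("hit table contains species absent from the taxonomy: ",
         paste(unique(hits$species[unknown]), collapse = ", "), call. = FALSE)
  }
  hits
}

#' Assign gene ages from a hit table
#'
#' Runs the full per-gene age assignment: each isoform gets the phylostratum
#' of its most distant sub-cutoff hit ([assign_phylostratum()]); isoforms with
#' no hits are query-restricted; then the longest of the oldest isoforms
#' represents the gene ([select_representative()]). Era labels under both the
#' five-era and four-era schemes are attached.
#'
#' @param hits Hit table (columns `gene_id`, `isoform_id`, `species`,
#'   `evalue`), e.g. from [read_hit_table()].
#' @param isoforms Data frame of isoforms with columns `gene_id`,
#'   `isoform_id`, `protein_length` (plus any coordinate columns, carried
#'   through).
#' @param taxonomy A [taxonomy()].
#' @param evalue_cutoff Strict e-value cutoff (default `1e-3`).
#' @return One row per gene: the representative isoform's columns plus
#'   `phylostratum`, `era_five`, `era_four`.
#' @export
assign_gene_ages <- function(hits, isoforms, taxonomy, evalue_cutoff = 1e-3) {
  stopifnot(all(c("gene_id", "isoform_id", "protein_length") %in%
                  colnames(isoforms)))
  hit_split <- split(hits[, c("species", "evalue")], hits$isoform_id)
  iso <- isoforms
  iso$phylostratum <- vapply(iso$isoform_id, function(id) {
    assign_phylostratum(hit_split[[id]], taxonomy, evalue_cutoff)
  }, integer(1))
  reps <- do.call(rbind, lapply(split(iso, iso$gene_id), select_representative))
  rownames(reps) <- NULL
  reps$era_five <- map_to_era(reps$phylostratum, era_scheme("five_era"))
  reps$era_four <- map_to_era(reps$phylostratum, era_scheme("four_era"))
  reps[order(reps$gene_id), , drop = FALSE]
}

#' Compare era assignments from two age-estimation methods
#'
#' For every gene present in both inputs, compares era ranks (later era =
#' younger) and classifies the gene as `same`, `younger_by_a` (method A
#' assigns a younger era) or `younger_by_b`. Also reports, per method, the
#' fraction of genes assigned the oldest era. The gene universe is the
#' intersection of the two inputs; its size is returned.
#'
#' @param ages_a,ages_b Named factors (gene id -> era), both using the same
#'   ordered era levels (oldest first).
#' @return A list: `per_gene` (data frame `gene_id`, `era_a`, `era_b`,
#'   `class`), `summary` (named fractions `same`, `younger_by_a`,
#'   `younger_by_b`, `oldest_a`, `oldest_b`), `n` (genes compared).
#' @export
compare_age_methods <- function(ages_a, ages_b) {
  common <- intersect(names(ages_a), names(ages_b))
  if (length(common) == 0) {
    stop("the two age sets share no genes", call. = FALSE)
  }
  a <- ages_a[common]
  b <- ages_b[common]
  if (!identical(levels(a), levels(b))) {
    stop("the two age sets must use the same era levels", call. = FALSE)
  }
  ra <- as.integer(a)
  rb <- as.integer(b)
  cls <- ifelse(ra == rb, "same",
                ifelse(ra > rb, "younger_by_a", "younger_by_b"))
  n <- length(common)
  frac <- function(x) sum(x) / n
  list(
    per_gene = data.frame(gene_id = common, era_a = a, era_b = b,
                          class = cls, stringsAsFactors = FALSE,
                          row.names = NULL),
    summary = c(same = frac(cls == "same"),
                younger_by_a = frac(cls == "younger_by_a"),
                younger_by_b = frac(cls == "younger_by_b"),
                oldest_a = frac(ra == 1L),
                oldest_b = frac(rb == 1L)),
    n = n
  )
}

#' Reconstruct per-gene two-method era labels from summary tallies
#'
#' Given the total number of genes, the per-class tallies of an age-method
#' comparison (same age, younger by method A, younger by method B) and the
#' number of genes each method assigns to the oldest era, builds one concrete
#' per-gene label assignment consistent with all tallies, using the four-era
#' scheme. Useful for recomputing comparison fractions from published count
#' summaries.
#'
#' @param n_total Total genes.
#' @param n_same,n_younger_a,n_younger_b Class tallies (must sum to
#'   `n_total`).
#' @param n_oldest_a,n_oldest_b Genes assigned the oldest era by each method.
#' @param eras Ordered era labels, oldest first.
#' @return A data frame `gene_id`, `era_a`, `era_b` (factors) with one row
#'   per gene, suitable for [compare_age_methods()].
#' @export
build_comparison_labels <- function(n_total, n_same, n_younger_a, n_younger_b,
                                    n_oldest_a, n_oldest_b,
                                    eras = c("Early", "Vertebrate",
                                             "Mammal", "Primate")) {
  if (n_same + n_younger_a + n_younger_b != n_total) {
    stop("class tallies must sum to `n_total`", call. = FALSE)
  }
  # x genes are oldest-era by both methods; the cross cells
  # (oldest by one method only) force the feasible range of x.
  x <- max(n_oldest_a - n_younger_b, n_oldest_b - n_younger_a,
           n_oldest_a + n_oldest_b - n_total, 0)
  cross_b <- n_oldest_a - x   # a oldest, b younger -> class younger_by_b
  cross_a <- n_oldest_b - x   # b oldest, a younger -> class younger_by_a
  rest_same <- n_same - x
  rest_a <- n_younger_a - cross_a
  rest_b <- n_younger_b - cross_b
  if (min(cross_a, cross_b, rest_same, rest_a, rest_b) < 0 || x > min(n_oldest_a, n_oldest_b)) {
    stop("tallies are mutually inconsistent", call. = FALSE)
  }
  e <- function(i) eras[i]
  blocks <- list(
    data.frame(era_a = e(1), era_b = e(1))[rep(1, x), , drop = FALSE],
    data.frame(era_a = e(2), era_b = e(1))[rep(1, cross_a), , drop = FALSE],
    data.frame(era_a = e(1), era_b = e(2))[rep(1, cross_b), , drop = FALSE],
    data.frame(era_a = e(2), era_b = e(2))[rep(1, rest_same), , drop = FALSE],
    data.frame(era_a = e(3), era_b = e(2))[rep(1, rest_a), , drop = FALSE],
    data.frame(era_a = e(2), era_b = e(3))[rep(1, rest_b), , drop = FALSE]
  )
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out <- data.frame(
    gene_id = sprintf("g%06d", seq_len(nrow(out))),
    era_a = factor(out$era_a, levels = eras, ordered = TRUE),
    era_b = factor(out$era_b, levels = eras, ordered = TRUE),
    stringsAsFactors = FALSE
  )
  out
}
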