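# U/T ratio, Shannon partitions, unknown-diversity accounting, taxon
# frequency tables.

test_that("U/T ratio hits its degenerate extremes", {
  shared <- as_detection_matrix(tidyr::expand_grid(
    sample_id = c("s1", "s2", "s3"), species = c("A a", "B b")
  ) |> dplyr::mutate(group = "case"), "culturomics")
  res <- ut_ratio(shared, "case")
  expect_equal(res$unique_count, 0L)
  expect_equal(res$ratio, 0)

  solo <- as_detection_matrix(tibble::tibble(
    sample_id = c("s1", "s2"), group = "case", species = c("A a", "B b")
  ), "culturomics")
  expect_equal(ut_ratio(solo, "case")$ratio, 1)
})

test_that("U/T equals a brute-force column-sum recount on random matrices", {
  for (seed in c(2, 9, 21)) {
    det <- random_detection(5, 20, seed = seed)
    for (g in unique(det$group)) {
      res <- ut_ratio(det, g)
      sub <- unique(det[det$group == g, c("sample_id", "species")])
      counts <- table(sub$species)
      expect_equal(res$unique_count, sum(counts == 1))
      expect_equal(res$total_count, length(counts))
      expect_equal(res$ratio, sum(counts == 1) / length(counts))
    }
  }
})

test_that("U/T formatting renders count fractions like published tables", {
  expect_equal(fraction_label(151, 335), "151/335 (45%)")
  expect_equal(fraction_label(185, 281), "185/281 (66%)")
  expect_equal(fraction_label(3, 335), "3/335 (0.9%)")
  expect_equal(fraction_label(0, 281), "0/281 (0%)")
})

test_that("U/T is invariant under row and species reordering", {
  det <- random_detection(6, 15, seed = 4)
  shuffled <- det[sample(nrow(det)), ]
  expect_equal(ut_ratio(det, "case"), ut_ratio(shuffled, "case"))
})

test_that("duplicating a sample cannot increase the unique count", {
  det <- random_detection(4, 15, seed = 8)
  dup <- det[det$sample_id == "s01", ]
  dup$sample_id <- "s99"
  more <- dplyr::bind_rows(det, dup)
  expect_lte(ut_ratio(more, "case")$unique_count,
             ut_ratio(det, "case")$unique_count)
})

test_that("the U/T ratio errors when a group has no detections", {
  det <- toy_detection()
  none <- dplyr::filter(det, group == "case")
  expect_error(ut_ratio(none, "control"), "undefined|no detections")
})

test_that("Shannon index matches closed forms and the summation oracle", {
  expect_equal(shannon_index(c(a = 5))$shannon_bits, 0)
  expect_equal(shannon_index(rep(1, 4))$shannon_bits, 2.0)
  withr::with_seed(31, {
    x <- runif(10, 0.1, 10)
  })
  expect_equal(shannon_index(x)$shannon_bits, oracle_shannon_bits(x),
               tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "positive")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("merging two species never increases Shannon diversity", {
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- runif(6, 0.01, 5)
      merged <- c(x[1] + x[2], x[-(1:2)])
      expect_lte(shannon_index(merged)$shannon_bits,
                 shannon_index(x)$shannon_bits + 1e-12)
      expect_equal(shannon_index(sample(x))$shannon_bits,
                   shannon_index(x)$shannon_bits)
    }
  })
})

test_that("trait-partitioned Shannon renormalises within the partition", {
  cat <- toy_catalog()
  x <- c("Bacteroides fragilis" = 10, "Escherichia coli" = 30,
         "Clostridium butyricum" = 10, "Novellum gutense" = 20)
  anae <- shannon_index(x, cat, scope = "anaerobic")
  # anaerobes are B. fragilis, C. butyricum, N. gutense: props 1/4, 1/4, 1/2
  expect_equal(anae$n_species, 3L)
  expect_equal(anae$shannon_bits, 1.5)
  aero <- shannon_index(x, cat, scope = "aerotolerant")
  expect_equal(aero$n_species, 1L)
  expect_equal(aero$shannon_bits, 0)
  # global-proportion variant sums only in-scope terms without renormalising
  unnorm <- shannon_index(x, cat, scope = "anaerobic", renormalize = FALSE)
  p <- c(10, 10, 20) / 70
  expect_equal(unnorm$shannon_bits, -sum(p * log2(p)))
})

test_that("unknown diversity counts novelty classes from the catalog", {
  taxa <- new_taxa_catalog()
  cat <- as_species_catalog(taxa[c("species", "family", "obligate_anaerobe",
                                   "novelty")])
  ctrl <- unknown_diversity(taxa$species[taxa$origin == "control"], cat,
                            "culturomics")
  expect_equal(ctrl$n_new_species, 26L)
  case <- unknown_diversity(taxa$species[taxa$origin == "case"], cat,
                            "culturomics")
  expect_equal(case$n_new_species, 18L)

  empty <- unknown_diversity(character(), cat, "culturomics")
  expect_equal(empty$unknown_diversity, 0L)
})

test_that("unknown diversity enforces the modality contract", {
  cat <- toy_catalog()
  expect_error(unknown_diversity(cat$species, cat, "metagenomics"),
               "n_unidentified_otus")
  expect_error(
    unknown_diversity(cat$species, cat, "culturomics",
                      n_unidentified_otus = 5),
    "metagenomics"
  )
  meta <- unknown_diversity(modality = "metagenomics",
                            n_unidentified_otus = 12)
  expect_equal(meta$unknown_diversity, 12L)
})

test_that("unresolvable species error or warn as configured", {
  cat <- toy_catalog()
  expect_error(unknown_diversity(c("Missing species"), cat, "culturomics"),
               "not found")
  expect_warning(
    res <- unknown_diversity(c("Missing species"), cat, "culturomics",
                             unresolved = "warn"),
    "not found"
  )
  expect_equal(res$unknown_diversity, 0L)
})

test_that("taxon frequencies count k out of N and sum to one", {
  cat <- toy_catalog()
  tab <- taxon_frequency_table(cat$species, cat, "phylum")
  expect_equal(sum(tab$k), nrow(cat))
  expect_equal(sum(tab$proportion), 1)
  expect_equal(tab$k[tab$taxon == "Firmicutes"], 3L)
  expect_equal(tab$label[tab$taxon == "Firmicutes"], "3/5 (60%)")

  single <- taxon_frequency_table("Escherichia coli", cat, "phylum")
  expect_equal(single$label, "1/1 (100%)")
})

test_that("taxon frequencies match a group-by recount on random subsets", {
  cat <- toy_catalog()
  withr::with_seed(6, {
    for (i in 1:10) {
      sub <- sample(cat$species, sample(2:5, 1))
      tab <- taxon_frequency_table(sub, cat, "genus")
      manual <- table(cat$genus[match(sub, cat$species)])
      expect_equal(sort(setNames(tab$k, tab$taxon)),
                   sort(setNames(as.integer(manual), names(manual))))
    }
  })
})

test_that("per-sample Shannon handles empty scopes gracefully", {
  abund <- tibble::tibble(
    sample_id = "s1", species = "Escherichia coli", reads = 100
  )
  res <- shannon_by_sample(abund, toy_catalog())
  expect_true(is.na(res$shannon_bits[res$scope == "anaerobic"]))
  expect_equal(res$shannon_bits[res$scope == "all"], 0)
})
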