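# Synthetic community generator: determinism, structural invariants, ground
# truth, and effect monotonicity.

small_cfg <- function(...) {
  synth_config(n_case = 4, n_control = 3, species_pool = 80,
               reads_per_sample = 3000, ...)
}

test_that("generation is deterministic given the seed", {
  a <- synth_generate(small_cfg(seed = 77))
  b <- synth_generate(small_cfg(seed = 77))
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$detection, b$detection)
  expect_identical(a$otus, b$otus)
  c <- synth_generate(small_cfg(seed = 78))
  expect_false(identical(a$otus, c$otus))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(phylum_mixture = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(synth_config(n_case = 0), "at least one")
  expect_error(synth_config(detect_prob_culturomics = 1.5), "probabilities")
  expect_error(synth_config(anaerobe_depletion_delta = 0), "positive")
})

test_that("generated OTU tables satisfy the schema and depth bound", {
  ds <- synth_generate(small_cfg(seed = 3))
  expect_silent(as_otu_table(ds$otus)) # validates counts, identities, ids
  depth <- dplyr::count(ds$otus, sample_id, wt = read_count)
  expect_true(all(depth$n <= 3000))
  expect_true(all(depth$n >= 3000 * 0.99)) # only zero-read drops allowed
  ident <- ds$otus$best_hit_identity
  expect_true(all(is.na(ident) | (ident >= 0.9 & ident <= 1)))
})

test_that("ground truth echoes the configured effects", {
  null_ds <- synth_generate(small_cfg(seed = 5, anaerobe_depletion_delta = 1,
                                      proteobacteria_enrichment = 1))
  gt <- synth_ground_truth(null_ds)
  expect_equal(gt$anaerobe_depletion_delta, 1)
  expect_equal(gt$proteobacteria_enrichment, 1)
  expect_length(gt$forced_control_only, 0)
})

test_that("engineered control-only species are recovered as ground truth", {
  ds <- synth_generate(small_cfg(seed = 11, force_control_only = 4))
  gt <- synth_ground_truth(ds)
  expect_length(gt$forced_control_only, 4)
  expect_true(all(gt$forced_control_only %in% gt$control_only_species))
})

test_that("the realised control-only set matches the repertoire module", {
  for (seed in c(2, 12)) {
    ds <- synth_generate(small_cfg(seed = seed, force_control_only = 2))
    cult <- dplyr::filter(ds$detection, modality == "culturomics")
    meta <- dplyr::filter(ds$detection, modality == "metagenomics")
    expect_setequal(missing_repertoire(cult, meta),
                    synth_ground_truth(ds)$control_only_species)
  }
})

test_that("weakening the anaerobe depletion shrinks the richness gap", {
  gap <- function(delta) {
    gaps <- vapply(1:15, function(seed) {
      ds <- synth_generate(small_cfg(seed = seed,
                                     anaerobe_depletion_delta = delta))
      cult <- dplyr::filter(ds$detection, modality == "culturomics")
      anaer <- ds$catalog$species[ds$catalog$obligate_anaerobe]
      per_sample <- cult |>
        dplyr::filter(species %in% anaer) |>
        dplyr::count(sample_id, group)
      mean(per_sample$n[per_sample$group == "control"]) -
        mean(per_sample$n[per_sample$group == "case"])
    }, numeric(1))
    mean(gaps)
  }
  g_strong <- gap(0.3)
  g_weak <- gap(0.7)
  g_null <- gap(1.0)
  expect_gt(g_strong, g_weak)
  expect_gt(g_weak, g_null)
  expect_lt(abs(g_null), 4) # null gap hovers near zero
})

test_that("with no group effects the anaerobe U/T test is calibrated", {
  # equal-sized exchangeable groups, all effect multipliers at 1: the
  # chi-square on the anaerobe U/T 2x2 should reject near the nominal level
  # (slightly conservatively, since per-species detectability varies)
  rej <- vapply(1:500, function(seed) {
    ds <- synth_generate(synth_config(
      n_case = 6, n_control = 6, species_pool = 120, reads_per_sample = 300,
      anaerobe_depletion_delta = 1, proteobacteria_enrichment = 1,
      unknown_fraction_case = 0.15, unknown_fraction_control = 0.15,
      seed = seed
    ))
    cult <- dplyr::filter(ds$detection, modality == "culturomics")
    anaer <- ds$catalog$species[ds$catalog$obligate_anaerobe]
    ut <- ut_ratio(cult, species = anaer)
    m <- c(ut$unique_count[1], ut$total_count[1] - ut$unique_count[1],
           ut$unique_count[2], ut$total_count[2] - ut$unique_count[2])
    chisq_uncorrected(m)$p_value <= 0.05
  }, logical(1))
  mc_sd <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc_sd)
})

test_that("synthetic datasets round-trip through the TSV writers", {
  ds <- synth_generate(small_cfg(seed = 21))
  dir <- withr::local_tempdir()
  write_synth_dataset(ds, dir)
  expect_setequal(
    dir(dir),
    c("catalog.tsv", "samples.tsv", "culturomics_detection.tsv", "otus.tsv")
  )
  cat2 <- suppressWarnings(read_species_catalog(file.path(dir, "catalog.tsv")))
  expect_equal(cat2$species, ds$catalog$species)
  otus2 <- read_otu_table(file.path(dir, "otus.tsv"))
  expect_equal(otus2$read_count, ds$otus$read_count)
  cult2 <- read_detection_matrix(file.path(dir, "culturomics_detection.tsv"),
                                 "culturomics")
  expect_equal(
    dplyr::arrange(cult2, sample_id, species),
    dplyr::arrange(dplyr::filter(ds$detection, modality == "culturomics"),
                   sample_id, species)
  )
})
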