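# End-to-end orchestration: load inputs -> amplicon post-processing ->
# diversity statistics -> test battery -> missing repertoire -> report
# bundle. Every reported p-value is traceable to its test and inputs through
# the bundle's tests log.

#' Default pipeline options
#'
#' @return Named list of thresholds and policy switches with their defaults:
#'   `min_reads` (20), `identity_threshold` (0.97), `novelty_thresholds`
#'   (0.9865 / 0.95), `quantitative_test` ("t_test" or "mann_whitney"),
#'   `barnard_max_n` (10), `fisher_min_expected` (5), `min_control_samples`
#'   (1), `group_aliases` (none), `seed` (1).
#' @export
pipeline_defaults <- function() {
  list(
    min_reads = 20,
    identity_threshold = 0.97,
    novelty_thresholds = c(new_species = 0.9865, new_genus = 0.95),
    quantitative_test = "t_test",
    barnard_max_n = 10,
    fisher_min_expected = 5,
    min_control_samples = 1,
    species_tests = TRUE,
    group_aliases = NULL,
    out_dir = NULL,
    seed = 1
  )
}

#' Read a pipeline run configuration from a YAML file
#'
#' Recognised keys: `catalog`, `culturomics`, `otus`, `samples` (input file
#' paths, resolved relative to the YAML file) plus any option listed in
#' [pipeline_defaults()].
#'
#' @param path Path to a YAML file.
#' @return A named list usable as `config` in [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("catalog", "culturomics", "otus", "samples")) {
    if (!is.null(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  cfg
}

load_pipeline_inputs <- function(config) {
  for (key in c("catalog", "culturomics", "otus", "samples")) {
    p <- config[[key]]
    if (is.null(p)) abort(sprintf("config is missing input path %s", dQuote(key)))
    if (!file.exists(p)) {
      abort(sprintf("input %s not found at %s", dQuote(key), p))
    }
  }
  catalog <- suppressWarnings(read_species_catalog(config$catalog))
  samples <- readr::read_tsv(config$samples,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  list(
    catalog = catalog,
    samples = samples,
    culturomics = read_detection_matrix(config$culturomics, "culturomics",
                                        config$group_aliases, catalog),
    otus = read_otu_table(config$otus)
  )
}

#' Run the full comparison pipeline
#'
#' Orchestrates the analysis end to end on either a synthetic dataset (from
#' [synth_generate()]) or files referenced by a config list / YAML path:
#' OTU filtering and assignment, per-sample amplicon summaries, U/T
#' beta-diversity with its 2x2 tests (overall and partitioned by oxygen
#' tolerance), per-sample Shannon indices with group comparison,
#' hitherto-unknown-diversity accounting, per-phylum frequency comparisons,
#' per-species presence tests, and the missing-repertoire / candidate screen.
#'
#' @param dataset Optional `synth_dataset` (takes precedence over file
#'   inputs in `config`).
#' @param config Named list (see [pipeline_defaults()] for options and
#'   [read_run_config()] for file inputs) or path to a YAML file.
#' @return An `mm_report` list with elements `amplicon`, `ut`, `shannon`,
#'   `shannon_tests`, `unknown`, `unknown_tests`, `taxon_freq`,
#'   `species_tests`, `repertoire`, `tests` (the consolidated log of every
#'   test run, with its input table) and `options`. Written to
#'   `config$out_dir` as TSV/JSON when that option is set.
#' @export
run_pipeline <- function(dataset = NULL, config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  opts <- modifyList(pipeline_defaults(), config)
  if (!opts$quantitative_test %in% c("t_test", "mann_whitney")) {
    abort("quantitative_test must be 't_test' or 'mann_whitney'")
  }

  if (!is.null(dataset)) {
    if (!inherits(dataset, "synth_dataset")) {
      abort("dataset must come from synth_generate()")
    }
    catalog <- dataset$catalog
    samples <- dataset$samples
    cult <- filter(dataset$detection, .data$modality == "culturomics")
    otus <- dataset$otus
  } else {
    inputs <- load_pipeline_inputs(opts)
    catalog <- inputs$catalog
    samples <- inputs$samples
    cult <- inputs$culturomics
    otus <- inputs$otus
  }
  samples$group <- map_groups(samples$group, opts$group_aliases)

  # --- amplicon stage -------------------------------------------------------
  kept <- filter_low_count_otus(otus, opts$min_reads)
  assignment <- assign_otus(kept, opts$identity_threshold)
  amplicon <- summarize_amplicon(kept, assignment) |>
    left_join(samples, by = "sample_id") |>
    relocate("group", .after = "sample_id")
  meta <- amplicon_detection(amplicon, samples, catalog = catalog)
  abund <- species_read_counts(kept, assignment)

  tests_log <- list()
  log_test <- function(comparison, modality, res) {
    tests_log[[length(tests_log) + 1L]] <<- mutate(
      tidy(res),
      comparison = comparison, modality = modality,
      inputs = paste(deparse(res$inputs[[1]], width.cutoff = 500), collapse = ""),
      .before = 1
    )
    res
  }

  # --- U/T beta-diversity ---------------------------------------------------
  anaerobes <- catalog$species[catalog$obligate_anaerobe %+na% FALSE]
  aerotol <- catalog$species[!(catalog$obligate_anaerobe %+na% TRUE)]
  ut_scope <- function(det, mod) {
    scopes <- list(all = NULL, anaerobic = anaerobes, aerotolerant = aerotol)
    imap(scopes, function(sp, nm) {
      res <- tryCatch(ut_ratio(det, species = sp), error = function(e) NULL)
      if (is.null(res) || nrow(res) < 2) return(NULL)
      wide <- tidyr::pivot_wider(
        res, names_from = "group",
        values_from = c("n_samples", "unique_count", "total_count",
                        "ratio", "label")
      )
      m <- c(res$unique_count[res$group == "case"],
             res$total_count[res$group == "case"] -
               res$unique_count[res$group == "case"],
             res$unique_count[res$group == "control"],
             res$total_count[res$group == "control"] -
               res$unique_count[res$group == "control"])
      test <- log_test(paste0("U/T ratio, ", nm, " species"), mod,
                       chisq_uncorrected(m))
      mutate(wide, modality = mod, scope = nm,
             delta_ratio = .data$ratio_control - .data$ratio_case,
             p_value = test$p_value, .before = 1)
    }) |>
      list_rbind()
  }
  ut <- bind_rows(ut_scope(cult, "culturomics"), ut_scope(meta, "metagenomics"))

  # --- Shannon diversity (sequencing side) ----------------------------------
  shannon <- shannon_by_sample(abund, catalog) |>
    left_join(samples, by = "sample_id") |>
    relocate("group", .after = "sample_id")
  quant_test <- function(x, y) {
    if (opts$quantitative_test == "t_test") pooled_t_test(x = x, y = y)
    else mann_whitney_test(x, y)
  }
  shannon_tests <- map(unique(shannon$scope), function(sc) {
    sub <- filter(shannon, .data$scope == sc, !is.na(.data$shannon_bits))
    x <- sub$shannon_bits[sub$group == "case"]
    y <- sub$shannon_bits[sub$group == "control"]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    res <- log_test(paste0("Shannon, ", sc, " scope"), "metagenomics",
                    quant_test(x, y))
    mutate(tidy(res), scope = sc,
           mean_case = mean(x), sd_case = stats::sd(x),
           mean_control = mean(y), sd_control = stats::sd(y), .before = 1)
  }) |>
    list_rbind()

  # --- hitherto-unknown diversity -------------------------------------------
  cult_unknown <- cult |>
    distinct(.data$sample_id, .data$group, .data$species) |>
    group_by(.data$sample_id, .data$group) |>
    group_modify(~ unknown_diversity(.x$species, catalog, "culturomics",
                                     unresolved = "warn")) |>
    ungroup()
  meta_unknown <- amplicon |>
    transmute(.data$sample_id, .data$group, modality = "metagenomics",
              n_new_species = NA_integer_, n_not_known_human = NA_integer_,
              n_known_human_not_gut = NA_integer_,
              .data$n_unidentified_otus,
              unknown_diversity = .data$n_unidentified_otus)
  unknown <- bind_rows(cult_unknown, meta_unknown)
  unknown_tests <- unknown |>
    group_by(.data$modality) |>
    group_modify(function(d, key) {
      x <- d$unknown_diversity[d$group == "case"]
      y <- d$unknown_diversity[d$group == "control"]
      if (length(x) < 2 || length(y) < 2) return(tibble())
      res <- log_test("unknown diversity per sample", key$modality,
                      quant_test(x, y))
      mutate(tidy(res), mean_case = mean(x), mean_control = mean(y),
             .before = 1)
    }) |>
    ungroup()

  # --- per-phylum frequency comparison --------------------------------------
  taxon_freq <- map(list(cult = cult, meta = meta), function(det) {
    mod <- det$modality[1]
    sets <- list(case = group_species_set(det, "case"),
                 control = group_species_set(det, "control"))
    tabs <- imap(sets, function(sp, g) {
      taxon_frequency_table(sp, catalog, "phylum", unresolved = "warn") |>
        mutate(group = g)
    })
    all_taxa <- union(tabs$case$taxon, tabs$control$taxon)
    n_case <- length(sets$case); n_control <- length(sets$control)
    map(all_taxa, function(tx) {
      k1 <- tabs$case$k[match(tx, tabs$case$taxon)] %+na% 0L
      k2 <- tabs$control$k[match(tx, tabs$control$taxon)] %+na% 0L
      m <- c(k1, n_case - k1, k2, n_control - k2)
      choice <- select_2x2_test(m, per_sample = FALSE,
                                fisher_min_expected = opts$fisher_min_expected)
      res <- log_test(paste0("phylum frequency: ", tx %+na% "unresolved"),
                      mod, run_2x2_test(m, choice))
      tibble(
        modality = mod, taxon = tx,
        case = fraction_label(k1, n_case),
        control = fraction_label(k2, n_control),
        test = res$test, p_value = res$p_value
      )
    }) |>
      list_rbind()
  }) |>
    list_rbind()

  # --- per-species presence tests (small-cohort Barnard) --------------------
  species_tests <- NULL
  if (isTRUE(opts$species_tests)) {
    n1 <- sum(samples$group == "case"); n2 <- sum(samples$group == "control")
    species_tests <- meta |>
      distinct(.data$sample_id, .data$group, .data$species) |>
      count(.data$species, .data$group) |>
      pivot_wider(names_from = "group", values_from = "n", values_fill = 0L)
    if (!"case" %in% names(species_tests)) species_tests$case <- 0L
    if (!"control" %in% names(species_tests)) species_tests$control <- 0L
    species_tests <- map(seq_len(nrow(species_tests)), function(i) {
      row <- species_tests[i, ]
      m <- c(row$case, n1 - row$case, row$control, n2 - row$control)
      choice <- select_2x2_test(m, per_sample = TRUE,
                                barnard_max_n = opts$barnard_max_n,
                                fisher_min_expected = opts$fisher_min_expected)
      res <- log_test(paste0("species presence: ", row$species),
                      "metagenomics", run_2x2_test(m, choice))
      tibble(
        species = row$species,
        case = fraction_label(row$case, n1),
        control = fraction_label(row$control, n2),
        test = res$test, p_value = res$p_value
      )
    }) |>
      list_rbind() |>
      arrange(.data$p_value)
  }

  # --- missing repertoire ----------------------------------------------------
  missing <- missing_repertoire(cult, meta, catalog,
                                opts$min_control_samples)
  repertoire <- suppressWarnings(annotate_candidates(missing, catalog))

  bundle <- structure(
    list(
      amplicon = amplicon, ut = ut, shannon = shannon,
      shannon_tests = shannon_tests, unknown = unknown,
      unknown_tests = unknown_tests, taxon_freq = taxon_freq,
      species_tests = species_tests, repertoire = repertoire,
      tests = list_rbind(tests_log), options = opts
    ),
    class = "mm_report"
  )
  if (!is.null(opts$out_dir)) write_report(bundle, opts$out_dir)
  bundle
}

#' @export
print.mm_report <- function(x, ...) {
  cat("Two-group dual-modality microbiota comparison\n")
  cat(sprintf("  samples: %d case / %d control\n",
              sum(x$amplicon$group == "case"),
              sum(x$amplicon$group == "control")))
  cat(sprintf("  tests run: %d\n", nrow(x$tests)))
  print(x$repertoire)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits one TSV per result table plus a `summary.json` with the repertoire
#' summary and every test's name, inputs and p-value.
#'
#' @param bundle An `mm_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- function(df) {
    df[vapply(df, is.list, logical(1))] <- NULL
    df
  }
  tables <- list(
    amplicon_summary = flat(bundle$amplicon),
    ut_diversity = bundle$ut,
    shannon_per_sample = bundle$shannon,
    shannon_tests = bundle$shannon_tests,
    unknown_diversity = bundle$unknown,
    unknown_tests = bundle$unknown_tests,
    taxon_frequency = bundle$taxon_freq,
    species_tests = bundle$species_tests,
    repertoire_species = bundle$repertoire$species,
    tests_log = bundle$tests
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && nrow(tables[[nm]])) {
      readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  summary <- list(
    repertoire = as.list(glance(bundle$repertoire)),
    candidates_by_phylum = bundle$repertoire$summary$candidates_by_phylum[[1]],
    n_tests = nrow(bundle$tests)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
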