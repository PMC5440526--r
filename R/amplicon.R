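# Post-processing of precomputed OTU tables: low-count filtering, species
# assignment by best-hit identity, and per-sample accounting of identified
# species, unidentified OTUs and the assigned-read fraction.

#' Read an OTU table from a tab-separated file
#'
#' Expected columns: `sample_id`, `otu_id`, `read_count`, `best_hit_species`,
#' `best_hit_identity` (identity as a fraction in `[0, 1]`; empty cells mean
#' no usable best hit).
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated OTU tibble.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("OTU file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = "c", otu_id = "c", read_count = "d",
      best_hit_species = "c", best_hit_identity = "d"
    ),
    progress = FALSE
  )
  as_otu_table(raw)
}

#' Validate and coerce a data frame to the OTU-table schema
#'
#' @param df Data frame with columns `sample_id`, `otu_id`, `read_count` and,
#'   optionally, `best_hit_species` and `best_hit_identity`.
#' @return A validated OTU tibble.
#' @export
as_otu_table <- function(df) {
  df <- as_tibble(df)
  need <- setdiff(c("sample_id", "otu_id", "read_count"), names(df))
  if (length(need)) {
    abort(sprintf("OTU table is missing column(s): %s",
                  paste(need, collapse = ", ")))
  }
  if (!"best_hit_species" %in% names(df)) df$best_hit_species <- NA_character_
  if (!"best_hit_identity" %in% names(df)) df$best_hit_identity <- NA_real_
  if (any(is.na(df$read_count) | df$read_count < 0 |
            df$read_count != round(df$read_count))) {
    abort("read_count must be a non-negative integer")
  }
  ident <- df$best_hit_identity
  if (any(!is.na(ident) & (ident < 0 | ident > 1))) {
    abort("best_hit_identity must lie in [0, 1] when present")
  }
  if (anyDuplicated(df[c("sample_id", "otu_id")])) {
    abort("otu_id must be unique within each sample")
  }
  select(df, "sample_id", "otu_id", "read_count",
         "best_hit_species", "best_hit_identity")
}

#' Remove low-count OTUs
#'
#' Drops every OTU with fewer than `min_reads` reads (strictly below the
#' threshold: an OTU with exactly `min_reads` reads is kept). Row order is
#' preserved. Filtering acts row-wise on the table as given, i.e. per sample
#' when the table holds one sample per `sample_id`.
#'
#' @param otus An OTU tibble.
#' @param min_reads Minimum read count an OTU must reach to be kept
#'   (default 20).
#' @return The filtered OTU tibble.
#' @export
filter_low_count_otus <- function(otus, min_reads = 20) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L || min_reads < 0) {
    abort("min_reads must be a single non-negative number")
  }
  otus <- as_otu_table(otus)
  filter(otus, .data$read_count >= min_reads)
}

#' Assign OTUs to species by best-hit identity
#'
#' An OTU is assigned to its best-hit species when the hit identity is at
#' least `identity_threshold` (a hit exactly at the threshold is assigned);
#' OTUs with a weaker hit, or with no best hit at all, are unidentified
#' (`species` is `NA`).
#'
#' @param otus An OTU tibble, normally already filtered with
#'   [filter_low_count_otus()].
#' @param identity_threshold Minimum best-hit identity for assignment
#'   (default 0.97).
#' @return A tibble with columns `sample_id`, `otu_id`, `species` (`NA` for
#'   unidentified OTUs).
#' @export
assign_otus <- function(otus, identity_threshold = 0.97) {
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
        identity_threshold < 0 || identity_threshold > 1) {
    abort("identity_threshold must be a single fraction in [0, 1]")
  }
  otus <- as_otu_table(otus)
  otus |>
    transmute(
      .data$sample_id, .data$otu_id,
      species = ifelse(
        !is.na(.data$best_hit_species) &
          !is.na(.data$best_hit_identity) &
          .data$best_hit_identity >= identity_threshold,
        .data$best_hit_species, NA_character_
      )
    )
}

#' Per-sample summary of an assigned OTU table
#'
#' Counts, for every sample, the distinct species detected, the number of
#' unidentified OTUs, the total number of OTUs surviving the filter, and the
#' fraction of reads carried by assigned OTUs. Because several OTUs can map
#' to one species, `n_species + n_unidentified_otus <= n_otus`.
#'
#' @param otus A filtered OTU tibble.
#' @param assignment The matching assignment from [assign_otus()]; every OTU
#'   in `otus` must be covered.
#' @return A tibble with one row per sample: `sample_id`, `n_species`,
#'   `n_unidentified_otus`, `n_otus`, `assigned_read_fraction` and a
#'   `species_detected` list-column.
#' @export
summarize_amplicon <- function(otus, assignment = assign_otus(otus)) {
  otus <- as_otu_table(otus)
  joined <- left_join(otus, assignment, by = c("sample_id", "otu_id"))
  if (!"species" %in% names(joined)) {
    abort("assignment must have columns sample_id, otu_id, species")
  }
  covered <- semi_join(otus, assignment, by = c("sample_id", "otu_id"))
  if (nrow(covered) < nrow(otus)) {
    miss <- anti_join(otus, assignment, by = c("sample_id", "otu_id"))
    abort(sprintf("assignment is missing %d OTU(s), e.g. %s in sample %s",
                  nrow(miss), miss$otu_id[1], miss$sample_id[1]))
  }
  joined |>
    group_by(.data$sample_id) |>
    summarise(
      n_species = n_distinct(.data$species[!is.na(.data$species)]),
      n_unidentified_otus = sum(is.na(.data$species)),
      n_otus = n(),
      assigned_read_fraction =
        sum(.data$read_count[!is.na(.data$species)]) / sum(.data$read_count),
      species_detected = list(sort(unique(
        .data$species[!is.na(.data$species)]
      ))),
      .groups = "drop"
    )
}

#' Run the full OTU post-processing for one table
#'
#' Convenience wrapper: filter low-count OTUs, assign the survivors, and
#' summarise per sample.
#'
#' @inheritParams filter_low_count_otus
#' @inheritParams assign_otus
#' @return See [summarize_amplicon()].
#' @export
process_otu_table <- function(otus, min_reads = 20, identity_threshold = 0.97) {
  kept <- filter_low_count_otus(otus, min_reads)
  summarize_amplicon(kept, assign_otus(kept, identity_threshold))
}

#' Species-level read abundances of assigned OTUs
#'
#' Collapses a filtered, assigned OTU table to per-sample species read counts
#' (unidentified OTUs are dropped). This is the abundance input used for
#' Shannon diversity on the sequencing side.
#'
#' @inheritParams summarize_amplicon
#' @return A tibble with columns `sample_id`, `species`, `reads`.
#' @export
species_read_counts <- function(otus, assignment = assign_otus(otus)) {
  otus <- as_otu_table(otus)
  left_join(otus, assignment, by = c("sample_id", "otu_id")) |>
    filter(!is.na(.data$species)) |>
    group_by(.data$sample_id, .data$species) |>
    summarise(reads = sum(.data$read_count), .groups = "drop")
}

#' Detection matrix implied by processed OTU tables
#'
#' Builds the metagenomics detection matrix from per-sample amplicon
#' summaries and a sample-to-group map.
#'
#' @param summaries Output of [summarize_amplicon()] or [process_otu_table()].
#' @param samples Data frame with columns `sample_id`, `group`.
#' @inheritParams as_detection_matrix
#' @return A detection tibble (modality `"metagenomics"`).
#' @export
amplicon_detection <- function(summaries, samples, group_aliases = NULL,
                               catalog = NULL) {
  long <- summaries |>
    select("sample_id", "species_detected") |>
    tidyr::unnest(cols = "species_detected") |>
    rename(species = "species_detected") |>
    inner_join(as_tibble(samples), by = "sample_id")
  as_detection_matrix(long, "metagenomics", group_aliases, catalog)
}
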