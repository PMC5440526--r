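# Detection matrices: which species was detected in which sample, by which
# modality. Internally a long tibble with one row per detection, columns
# modality, sample_id, group, species; group labels are fixed to
# case/control, with a user-supplied alias map for file vocabularies.

detection_modalities <- c("culturomics", "metagenomics")

map_groups <- function(x, aliases = NULL) {
  x <- tolower(trimws(x))
  if (!is.null(aliases)) {
    names(aliases) <- tolower(names(aliases))
    hit <- match(x, names(aliases))
    x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  bad <- !x %in% c("case", "control")
  if (any(bad)) {
    abort(sprintf(
      "unknown group label %s: expected 'case'/'control' or an alias supplied via group_aliases",
      dQuote(x[bad][1])
    ))
  }
  x
}

#' Build a detection matrix from a long data frame
#'
#' @param df Data frame with columns `sample_id`, `group` and `species`
#'   (a `modality` column, if present, must agree with `modality`).
#' @param modality `"culturomics"` or `"metagenomics"`.
#' @param group_aliases Optional named character vector mapping file-specific
#'   group labels to `"case"`/`"control"`, e.g.
#'   `c(kwashiorkor = "case", healthy = "control")`.
#' @param catalog Optional species catalog used to normalise species names.
#' @return A detection tibble with columns `modality`, `sample_id`, `group`,
#'   `species`; duplicate detections collapse to a single row.
#' @export
as_detection_matrix <- function(df, modality, group_aliases = NULL,
                                catalog = NULL) {
  modality <- arg_match(modality, detection_modalities)
  df <- as_tibble(df)
  need <- setdiff(c("sample_id", "group", "species"), names(df))
  if (length(need)) {
    abort(sprintf("detection table is missing column(s): %s",
                  paste(need, collapse = ", ")))
  }
  if (any(is.na(df$group) | trimws(df$group) == "")) {
    abort("every sample must carry a group label")
  }
  out <- df |>
    transmute(
      modality = modality,
      sample_id = as.character(.data$sample_id),
      group = map_groups(.data$group, group_aliases),
      species = normalize_species_name(.data$species, catalog)
    ) |>
    distinct()
  grp_per_sample <- out |> distinct(.data$sample_id, .data$group)
  if (anyDuplicated(grp_per_sample$sample_id)) {
    abort("a sample_id appears with more than one group label")
  }
  out
}

#' Read a detection matrix from a tab-separated file
#'
#' Two dialects are auto-detected from the header. Long format has columns
#' `sample_id`, `group`, `species`, one row per detection. Wide format has
#' columns `sample_id`, `group` followed by one 0/1 column per species.
#'
#' @inheritParams as_detection_matrix
#' @param path Path to a TSV file with a header row.
#' @return A long detection tibble (see [as_detection_matrix()]).
#' @export
read_detection_matrix <- function(path, modality, group_aliases = NULL,
                                  catalog = NULL) {
  if (!file.exists(path)) abort(sprintf("detection file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("detection file is empty: %s", path))
  names(raw)[1:2] <- tolower(names(raw)[1:2])
  if ("species" %in% tolower(names(raw))) {
    names(raw) <- tolower(names(raw))
    long <- raw
  } else {
    # wide boolean matrix: melt the species columns
    long <- raw |>
      pivot_longer(-c("sample_id", "group"),
                   names_to = "species", values_to = "present") |>
      filter(.data$present %in% c("1", "TRUE", "true", "yes")) |>
      select(-"present")
  }
  as_detection_matrix(long, modality, group_aliases, catalog)
}

#' Write a detection matrix to a tab-separated file
#'
#' @param det A detection tibble.
#' @param path Output path.
#' @param format `"long"` (default, one row per detection) or `"wide"`
#'   (one 0/1 column per species).
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(det, path, format = c("long", "wide")) {
  format <- arg_match(format)
  out <- det |> select("sample_id", "group", "species") |> distinct()
  if (format == "wide") {
    out <- out |>
      mutate(present = 1L) |>
      pivot_wider(names_from = "species", values_from = "present",
                  values_fill = 0L)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Species detected in at least one sample of a group
#'
#' @param det A detection tibble.
#' @param group `"case"` or `"control"`.
#' @param min_samples Minimum number of distinct samples a species must be
#'   detected in to count (default 1).
#' @return Sorted character vector of species names.
#' @export
group_species_set <- function(det, group, min_samples = 1L) {
  group <- arg_match(group, c("case", "control"))
  if (!group %in% det$group) {
    abort(sprintf("group %s has no samples in this detection matrix",
                  dQuote(group)))
  }
  det |>
    filter(.data$group == .env$group) |>
    distinct(.data$sample_id, .data$species) |>
    count(.data$species) |>
    filter(.data$n >= min_samples) |>
    pull(.data$species) |>
    sort()
}
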