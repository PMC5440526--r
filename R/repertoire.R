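# Missing repertoire: species seen by both modalities in controls but by
# neither modality in cases, with probiotic-candidate annotation.

#' Species missing from the case group
#'
#' The missing repertoire is the set of species identified by culture AND by
#' sequencing in the control group, but found by neither method in any case
#' sample: the intersection of the two control species sets minus the union
#' of the two case species sets. These are the strongest candidates for a
#' community that cases have lost, since their presence in controls is
#' confirmed by two independent methods and they are viable (cultured).
#'
#' @param cult Culturomics detection tibble.
#' @param meta Metagenomics detection tibble.
#' @param catalog Optional species catalog used to reconcile species names
#'   across the two modalities before the set operations.
#' @param min_control_samples Minimum number of control samples a species
#'   must be detected in, per modality, to count as identified in controls
#'   (default 1).
#' @return Sorted character vector of missing species.
#' @export
missing_repertoire <- function(cult, meta, catalog = NULL,
                               min_control_samples = 1L) {
  for (det in list(cult, meta)) {
    if (!"control" %in% det$group) {
      abort("both modalities need a non-empty control group")
    }
  }
  if (!is.null(catalog)) {
    cult <- mutate(cult, species = normalize_species_name(.data$species, catalog))
    meta <- mutate(meta, species = normalize_species_name(.data$species, catalog))
  }
  ctrl_both <- intersect(
    species_key(group_species_set(cult, "control", min_control_samples)),
    species_key(group_species_set(meta, "control", min_control_samples))
  )
  case_any <- union(
    if ("case" %in% cult$group) species_key(group_species_set(cult, "case")) else character(),
    if ("case" %in% meta$group) species_key(group_species_set(meta, "case")) else character()
  )
  keys <- setdiff(ctrl_both, case_any)
  # map keys back to display names (control detections carry the casing)
  pool <- bind_rows(cult, meta)
  names_by_key <- pool$species[!duplicated(species_key(pool$species))]
  sort(names_by_key[match(keys, species_key(names_by_key))])
}

#' Annotate a missing-species set with traits and probiotic candidacy
#'
#' Joins a missing-species set against the catalog's taxonomy,
#' obligate-anaerobe flags and literature-based probiotic flags, and
#' summarises the result: how many of the missing species are strict
#' anaerobes, how many are probiotic candidates, and the candidates' phylum
#' breakdown. Candidacy is data carried by the catalog (the criteria are
#' literature-based, not algorithmic).
#'
#' @param missing Character vector of missing species.
#' @param catalog Species catalog.
#' @return A `repertoire_report` object: list with `species` (per-species
#'   tibble) and `summary` (one-row tibble). Species absent from the catalog
#'   are kept in the table with `NA` traits but excluded from candidate
#'   evaluation, with a warning.
#' @export
annotate_candidates <- function(missing, catalog) {
  missing <- unique(missing)
  idx <- match(species_key(missing), species_key(catalog$species))
  if (anyNA(idx) && length(missing)) {
    warn(sprintf(
      "%d missing species not in the catalog (e.g. %s): excluded from candidate evaluation",
      sum(is.na(idx)), dQuote(missing[is.na(idx)][1])
    ))
  }
  species_tbl <- tibble(
    species = missing,
    phylum = catalog$phylum[idx],
    class = catalog$class[idx],
    family = catalog$family[idx],
    genus = catalog$genus[idx],
    obligate_anaerobe = catalog$obligate_anaerobe[idx],
    candidate = catalog$probiotic[idx],
    probiotic_function = catalog$probiotic_function[idx]
  ) |>
    arrange(.data$species)
  n_missing <- nrow(species_tbl)
  n_anaerobic <- sum(species_tbl$obligate_anaerobe, na.rm = TRUE)
  cand <- filter(species_tbl, .data$candidate %+na% FALSE)
  by_phylum <- count(cand, .data$phylum, name = "n_candidates") |>
    arrange(desc(.data$n_candidates))
  summary_tbl <- tibble(
    n_missing = n_missing,
    n_anaerobic = n_anaerobic,
    anaerobic_fraction = if (n_missing > 0) n_anaerobic / n_missing else NA_real_,
    n_candidates = nrow(cand),
    candidates_by_phylum = list(by_phylum)
  )
  structure(list(species = species_tbl, summary = summary_tbl),
            class = "repertoire_report")
}

#' @export
print.repertoire_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Missing repertoire: %d species, %d strictly anaerobic (%s), %d probiotic candidates\n",
    s$n_missing, s$n_anaerobic,
    if (s$n_missing > 0) sprintf("%.0f%%", 100 * s$anaerobic_fraction) else "-",
    s$n_candidates
  ))
  bp <- s$candidates_by_phylum[[1]]
  if (nrow(bp)) {
    cat("Candidates by phylum:",
        paste(sprintf("%s (%d)", bp$phylum, bp$n_candidates), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy a repertoire report into its per-species table
#'
#' @param x A `repertoire_report`.
#' @param ... Unused.
#' @return The per-species tibble.
#' @export
tidy.repertoire_report <- function(x, ...) x$species

#' @rdname tidy.repertoire_report
#' @export
glance.repertoire_report <- function(x, ...) {
  select(x$summary, -"candidates_by_phylum")
}
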