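# Species catalog: per-species taxonomy, oxygen tolerance, novelty class and
# probiotic-criteria annotation. The catalog is the shared namespace against
# which detections from both modalities are resolved.

#' Novelty classes recognised in a species catalog
#'
#' Six classes order a species by how novel its detection in a child's gut is:
#' already known from the human gut, known in humans but not the gut, known but
#' never found in humans, or a putative new species / genus / family.
#'
#' @export
novelty_levels <- c(
  "known_gut", "known_human_not_gut", "known_not_human",
  "new_species", "new_genus", "new_family"
)

# classes counted as "putative new species": a new genus or family is, a
# fortiori, also a species new to science
new_taxon_levels <- c("new_species", "new_genus", "new_family")

catalog_columns <- c(
  "species", "phylum", "class", "order", "family", "genus",
  "obligate_anaerobe", "novelty", "probiotic", "probiotic_function"
)

parse_flag <- function(x, column, rows) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[key %in% c("1", "yes", "true", "y")] <- TRUE
  out[key %in% c("0", "no", "false", "n")] <- FALSE
  bad <- !is.na(key) & key != "" & key != "na" & is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "invalid %s value %s in row %s: expected 1/0, yes/no or true/false",
      column, dQuote(key[bad][1]), rows[bad][1]
    ))
  }
  out[key %in% c("", "na")] <- NA
  out
}

#' Read a species catalog from a tab-separated file
#'
#' The file must have a header and a `species` column (the alias `name` is
#' accepted). Recognised optional columns: `phylum`, `class`, `order`,
#' `family`, `genus`, `obligate_anaerobe` (1/0, yes/no, true/false),
#' `novelty` (one of [novelty_levels]), `probiotic` (same flag vocabulary) and
#' `probiotic_function` (free text). Missing optional columns are filled with
#' `NA`. A genus that is not the leading word of the binomial raises a warning
#' (taxonomic reclassifications make this legitimate), never an error.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with the columns listed above, one row per species.
#' @export
#' @examples
#' cat_path <- micromiss_example("missing_repertoire_catalog.tsv")
#' read_species_catalog(cat_path)
read_species_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("catalog file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("catalog file is empty: %s", path))
  names(raw) <- tolower(names(raw))
  if ("name" %in% names(raw) && !"species" %in% names(raw)) {
    raw <- rename(raw, species = "name")
  }
  if (!"species" %in% names(raw)) {
    abort("catalog is missing the required column 'species'")
  }
  as_species_catalog(raw)
}

#' Validate and coerce a data frame to the species-catalog schema
#'
#' @param df Data frame with at least a `species` column; see
#'   [read_species_catalog()] for the recognised columns.
#' @return A validated catalog tibble.
#' @export
as_species_catalog <- function(df) {
  df <- as_tibble(df)
  if (!"species" %in% names(df)) {
    abort("catalog is missing the required column 'species'")
  }
  rows <- seq_len(nrow(df)) + 1L # +1 accounts for the header row in messages
  df$species <- normalize_species_name(df$species)
  if (anyDuplicated(species_key(df$species))) {
    dup <- df$species[duplicated(species_key(df$species))][1]
    abort(sprintf("duplicated species name in catalog: %s", dQuote(dup)))
  }
  for (col in setdiff(catalog_columns, names(df))) {
    df[[col]] <- if (col %in% c("obligate_anaerobe", "probiotic")) NA else NA_character_
  }
  df$obligate_anaerobe <- parse_flag(df$obligate_anaerobe, "obligate_anaerobe", rows)
  df$probiotic <- parse_flag(df$probiotic, "probiotic", rows)
  nov <- trimws(as.character(df$novelty))
  nov[nov %in% c("", "NA")] <- NA_character_
  bad <- !is.na(nov) & !nov %in% novelty_levels
  if (any(bad)) {
    abort(sprintf(
      "unknown novelty class %s in row %d (expected one of: %s)",
      dQuote(nov[bad][1]), rows[bad][1], paste(novelty_levels, collapse = ", ")
    ))
  }
  df$novelty <- nov
  mismatch <- !is.na(df$genus) &
    tolower(sub(" .*", "", df$species)) != tolower(trimws(df$genus))
  if (any(mismatch)) {
    warn(sprintf(
      "genus does not match the leading word of the binomial for %d species (e.g. %s / genus %s); kept as given",
      sum(mismatch), dQuote(df$species[mismatch][1]), dQuote(df$genus[mismatch][1])
    ))
  }
  select(df, all_of(catalog_columns))
}

#' Write a species catalog to a tab-separated file
#'
#' Logical flags are written as 1/0 so that files round-trip through
#' [read_species_catalog()] unchanged.
#'
#' @param catalog A catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_catalog <- function(catalog, path) {
  out <- catalog
  for (col in c("obligate_anaerobe", "probiotic")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         ifelse(out[[col]], "1", "0"))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Classify taxonomic novelty from 16S identity to the nearest named species
#'
#' Applies the standard 16S rRNA thresholds for delineating new taxa: identity
#' below 95% to any named species indicates a putative new genus, identity of
#' at least 95% but below 98.65% a putative new species, and identity of at
#' least 98.65% an already-known species ("under" thresholds are strict, so a
#' value exactly at a threshold is the less novel class). Callers refine the
#' `known` outcome into the known_* subclasses from catalog metadata.
#'
#' @param identity Numeric vector of identities in `[0, 1]`.
#' @param new_species_threshold,new_genus_threshold Strict lower identity
#'   bounds for known species (default 0.9865) and new species (default 0.95).
#' @return Character vector with values `"new_genus"`, `"new_species"` or
#'   `"known"`.
#' @export
#' @examples
#' classify_novelty(c(0.99, 0.986, 0.949))
classify_novelty <- function(identity, new_species_threshold = 0.9865,
                             new_genus_threshold = 0.95) {
  if (any(!is.finite(identity)) || any(identity < 0) || any(identity > 1)) {
    abort("identity must lie in [0, 1]")
  }
  ifelse(identity < new_genus_threshold, "new_genus",
    ifelse(identity < new_species_threshold, "new_species", "known")
  )
}

#' Path to a packaged example/fixture table
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
micromiss_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "micromiss"))
  } else {
    p <- system.file("extdata", file, package = "micromiss")
    if (p == "") abort(sprintf("no packaged file named %s", dQuote(file)))
    p
  }
}

#' Packaged catalog of the 45-species missing repertoire
#'
#' The species found by both modalities in every healthy control analysis but
#' in no case sample, with taxonomy, obligate-anaerobe flags and the
#' literature-based probiotic-candidate annotation (12 flagged species with
#' their probiotic rationale).
#'
#' @return A species-catalog tibble of 45 rows.
#' @export
missing_repertoire_catalog <- function() {
  suppressWarnings(
    read_species_catalog(micromiss_example("missing_repertoire_catalog.tsv"))
  )
}

#' Packaged catalog of putative new taxa by group of origin
#'
#' The putative new species isolated by culture, with family, oxygen
#' tolerance, the group (case or control) whose samples yielded them, and the
#' level of taxonomic novelty (new species, genus or family).
#'
#' @return A tibble with columns `species`, `family`, `obligate_anaerobe`,
#'   `origin` and `novelty`.
#' @export
new_taxa_catalog <- function() {
  path <- micromiss_example("new_taxa_catalog.tsv")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  raw$obligate_anaerobe <- parse_flag(raw$obligate_anaerobe,
                                      "obligate_anaerobe",
                                      seq_len(nrow(raw)) + 1L)
  bad <- !raw$novelty %in% new_taxon_levels
  if (any(bad)) abort("corrupt new-taxa table: unknown novelty class")
  as_tibble(raw)
}
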