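# Diversity statistics: U/T presence/absence beta-diversity, Shannon index
# (log base 2) with an oxygen-tolerance partition, hitherto-unknown-diversity
# accounting, and per-taxon frequency tables.

#' Unique/total (U/T) species ratio of a group
#'
#' For each group, U counts the species detected in exactly one sample of
#' that group ("unique microbiota") and T counts the distinct species detected
#' in at least one sample. Their ratio is a presence/absence beta-diversity
#' measure: the higher the ratio, the less species composition is shared
#' between the children of the group. Uniqueness is judged within the group
#' only, irrespective of the other group.
#'
#' @param det A detection tibble (see [as_detection_matrix()]).
#' @param group `"case"`, `"control"`, or `NULL` (default) for every group
#'   present.
#' @param species Optional character vector restricting the computation to a
#'   species subset (e.g. the obligate anaerobes of a catalog).
#' @return A tibble with one row per group: `group`, `n_samples`,
#'   `unique_count`, `total_count`, `ratio` and a formatted `label` such as
#'   `"151/335 (45%)"`.
#' @export
ut_ratio <- function(det, group = NULL, species = NULL) {
  if (!is.null(species)) {
    det <- filter(det, species_key(.data$species) %in% species_key(.env$species))
  }
  groups <- if (is.null(group)) sort(unique(det$group)) else {
    arg_match(group, c("case", "control"))
  }
  rows <- map(groups, function(g) {
    sub <- filter(det, .data$group == g)
    if (nrow(sub) == 0L) {
      abort(sprintf("no detections for group %s: U/T ratio is undefined",
                    dQuote(g)))
    }
    per_species <- sub |>
      distinct(.data$sample_id, .data$species) |>
      count(.data$species)
    U <- sum(per_species$n == 1L)
    T_ <- nrow(per_species)
    tibble(
      group = g,
      n_samples = n_distinct(sub$sample_id),
      unique_count = U,
      total_count = T_,
      ratio = U / T_,
      label = fraction_label(U, T_)
    )
  })
  list_rbind(rows)
}

#' Shannon diversity index (bits)
#'
#' Computes the Shannon index H' = -sum(p_i * log2(p_i)) on species
#' proportions, optionally restricted to a trait-defined subset of the
#' community. Proportions are renormalised within the subset by default, so
#' the result is a genuine Shannon index of the sub-community; zero entries
#' contribute nothing.
#'
#' @param x Named (species) or unnamed numeric vector of non-negative counts
#'   or proportions.
#' @param catalog Optional species catalog supplying the `obligate_anaerobe`
#'   trait; required when `scope` is not `"all"` (in which case `x` must be
#'   named by species).
#' @param scope `"all"` (default), `"anaerobic"` (obligate anaerobes only) or
#'   `"aerotolerant"`.
#' @param renormalize If `TRUE` (default), proportions are renormalised within
#'   the scope; if `FALSE`, the global proportions are kept and only the terms
#'   of in-scope species are summed (a sensitivity-analysis variant; the
#'   result is then not a standalone Shannon index).
#' @return A one-row tibble: `scope`, `n_species`, `shannon_bits`.
#' @export
#' @examples
#' shannon_index(c(a = 1, b = 1, c = 1, d = 1)) # 2 bits
shannon_index <- function(x, catalog = NULL,
                          scope = c("all", "anaerobic", "aerotolerant"),
                          renormalize = TRUE) {
  scope <- arg_match(scope)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("abundances must be non-negative and finite")
  }
  total <- sum(x)
  if (scope != "all") {
    if (is.null(catalog) || is.null(names(x))) {
      abort("trait-partitioned Shannon needs a species-named vector and a catalog")
    }
    trait <- catalog$obligate_anaerobe[match(species_key(names(x)),
                                             species_key(catalog$species))]
    keep <- if (scope == "anaerobic") trait %+na% FALSE else !(trait %+na% FALSE)
    x <- x[keep]
  }
  x <- x[x > 0]
  if (length(x) == 0L) {
    abort(sprintf("no positive abundances in scope %s", dQuote(scope)))
  }
  p <- if (renormalize) x / sum(x) else x / total
  tibble(
    scope = scope,
    n_species = length(x),
    shannon_bits = -sum(p * log2(p))
  )
}

#' Per-sample Shannon indices from species read counts
#'
#' @param abund A tibble of per-sample species abundances with columns
#'   `sample_id`, `species`, `reads` (see [species_read_counts()]).
#' @param catalog Species catalog (needed for the trait scopes).
#' @param scopes Character vector of scopes to compute (default all three).
#' @inheritParams shannon_index
#' @return A tibble with one row per sample x scope: `sample_id`, `scope`,
#'   `n_species`, `shannon_bits` (`NA` when a sample has no species in scope).
#' @export
shannon_by_sample <- function(abund, catalog = NULL,
                              scopes = c("all", "anaerobic", "aerotolerant"),
                              renormalize = TRUE) {
  samples <- unique(abund$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, scope = scopes)
  pmap(grid, function(sample_id, scope) {
    sub <- abund[abund$sample_id == sample_id, ]
    x <- setNames(sub$reads, sub$species)
    res <- tryCatch(
      shannon_index(x, catalog, scope, renormalize),
      error = function(e) tibble(scope = scope, n_species = 0L,
                                 shannon_bits = NA_real_)
    )
    mutate(res, sample_id = sample_id, .before = 1)
  }) |>
    list_rbind()
}

#' Hitherto-unknown diversity of a sample or group
#'
#' On the culture side, the unknown diversity is the number of putative new
#' species plus the number of species not previously known from the human gut
#' (whether unknown in humans altogether or known in humans outside the gut),
#' read off the catalog's novelty classes. On the sequencing side it is the
#' number of OTUs left unassigned at the species level, passed through from
#' the amplicon summary.
#'
#' @param species Character vector of detected species (culturomics side).
#' @param catalog Species catalog with a `novelty` column.
#' @param modality `"culturomics"` or `"metagenomics"`.
#' @param n_unidentified_otus Unassigned-OTU count (metagenomics side only).
#' @param unresolved What to do when a species is absent from the catalog:
#'   `"error"` (default) or `"warn"` (warn and treat as known).
#' @return A one-row tibble: `modality`, `n_new_species`, `n_not_known_human`,
#'   `n_known_human_not_gut`, `n_unidentified_otus`, `unknown_diversity`.
#' @export
unknown_diversity <- function(species = NULL, catalog = NULL,
                              modality = c("culturomics", "metagenomics"),
                              n_unidentified_otus = NULL,
                              unresolved = c("error", "warn")) {
  modality <- arg_match(modality)
  unresolved <- arg_match(unresolved)
  if (modality == "metagenomics") {
    if (is.null(n_unidentified_otus)) {
      abort("metagenomics unknown diversity needs n_unidentified_otus")
    }
    return(tibble(
      modality = modality,
      n_new_species = NA_integer_, n_not_known_human = NA_integer_,
      n_known_human_not_gut = NA_integer_,
      n_unidentified_otus = as.integer(n_unidentified_otus),
      unknown_diversity = as.integer(n_unidentified_otus)
    ))
  }
  if (!is.null(n_unidentified_otus)) {
    abort("n_unidentified_otus is a metagenomics input; culturomics unknown diversity is catalog-based")
  }
  species <- unique(species)
  nov <- catalog$novelty[match(species_key(species), species_key(catalog$species))]
  if (anyNA(match(species_key(species), species_key(catalog$species)))) {
    missing <- species[is.na(match(species_key(species),
                                   species_key(catalog$species)))]
    msg <- sprintf("%d species not found in the catalog (e.g. %s)",
                   length(missing), dQuote(missing[1]))
    if (unresolved == "error") abort(msg)
    warn(paste0(msg, "; treated as known_gut"))
    nov[is.na(nov)] <- "known_gut"
  }
  n_new <- sum(nov %in% new_taxon_levels)
  n_nh <- sum(nov == "known_not_human", na.rm = TRUE)
  n_hng <- sum(nov == "known_human_not_gut", na.rm = TRUE)
  tibble(
    modality = modality,
    n_new_species = n_new,
    n_not_known_human = n_nh,
    n_known_human_not_gut = n_hng,
    n_unidentified_otus = NA_integer_,
    unknown_diversity = n_new + n_nh + n_hng
  )
}

#' Frequency of each taxon within a group's species set
#'
#' Counts, for a set of detected species, how many belong to each taxon at
#' the requested rank, as k/N with N the total number of species in the set.
#' The proportions across taxa sum to one.
#'
#' @param species Character vector of species names (a group's species set).
#' @param catalog Species catalog supplying the taxonomy.
#' @param rank `"phylum"`, `"class"` or `"genus"`.
#' @param unresolved `"error"` (default) to fail on species absent from the
#'   catalog, `"warn"` to warn and count them under taxon `NA`.
#' @return A tibble with columns `taxon`, `k`, `n`, `proportion`, `label`,
#'   sorted by decreasing `k`.
#' @export
taxon_frequency_table <- function(species, catalog,
                                  rank = c("phylum", "class", "genus"),
                                  unresolved = c("error", "warn")) {
  rank <- arg_match(rank)
  unresolved <- arg_match(unresolved)
  species <- unique(species)
  idx <- match(species_key(species), species_key(catalog$species))
  if (anyNA(idx)) {
    missing <- species[is.na(idx)]
    msg <- sprintf("%d species not found in the catalog (e.g. %s)",
                   length(missing), dQuote(missing[1]))
    if (unresolved == "error") abort(msg)
    warn(msg)
  }
  taxon <- catalog[[rank]][idx]
  N <- length(species)
  tibble(taxon = taxon) |>
    count(.data$taxon, name = "k") |>
    mutate(
      n = N,
      proportion = .data$k / N,
      label = fraction_label(.data$k, N)
    ) |>
    arrange(desc(.data$k))
}
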