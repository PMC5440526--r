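# Shared helpers: name normalisation, fraction labels, 2x2 table coercion.

#' Normalise species names for cross-modality matching
#'
#' Culture-based and sequence-based workflows frequently format the same
#' binomial differently ("Bacillus subtilis", " bacillus  subtilis",
#' "B. subtilis"). Matching is done case-insensitively after collapsing
#' whitespace; abbreviated genus forms ("B. subtilis") are expanded against a
#' species catalog when one is supplied.
#'
#' @param x Character vector of species names.
#' @param catalog Optional species catalog (see [read_species_catalog()]) used
#'   to expand abbreviated genus names. Expansion is only applied when the
#'   abbreviation matches exactly one catalog genus with that initial and the
#'   expanded binomial exists in the catalog.
#' @return Character vector of normalised names (single spaces, original case
#'   preserved from the catalog where a catalog match is found, otherwise
#'   whitespace-collapsed input).
#' @export
#' @examples
#' normalize_species_name(c("Bacillus  subtilis ", "Escherichia coli"))
normalize_species_name <- function(x, catalog = NULL) {
  out <- gsub("\\s+", " ", trimws(x))
  if (!is.null(catalog)) {
    key <- tolower(out)
    cat_names <- catalog$species
    cat_key <- tolower(gsub("\\s+", " ", trimws(cat_names)))
    hit <- match(key, cat_key)
    out[!is.na(hit)] <- cat_names[hit[!is.na(hit)]]
    # expand "B. subtilis" style abbreviations
    abbr <- grepl("^[A-Za-z]\\.\\s", out) & is.na(hit)
    if (any(abbr)) {
      genera <- unique(stats::na.omit(catalog$genus))
      for (i in which(abbr)) {
        initial <- toupper(substr(out[i], 1, 1))
        epithet <- sub("^[A-Za-z]\\.\\s+", "", out[i])
        cand_genera <- genera[toupper(substr(genera, 1, 1)) == initial]
        cand <- tolower(paste(cand_genera, epithet))
        found <- cat_names[match(intersect(cand, cat_key), cat_key)]
        if (length(found) == 1L) out[i] <- found
      }
    }
  }
  out
}

# case-insensitive key used internally for set operations
species_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Format a count fraction the way group comparisons are reported
#'
#' Renders "k/N (pct%)", e.g. `fraction_label(151, 335)` gives
#' `"151/335 (45%)"`. Percentages of at least 1 are rounded to whole numbers;
#' smaller ones keep one significant digit (e.g. "3/335 (0.9%)").
#'
#' @param k,n Non-negative counts, `k <= n`, `n > 0`.
#' @return Character vector of labels.
#' @export
fraction_label <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  pct <- 100 * k / n
  pct_txt <- ifelse(pct >= 0.95 | pct == 0,
    sprintf("%.0f", pct),
    formatC(signif(pct, 1), format = "fg")
  )
  sprintf("%d/%d (%s%%)", as.integer(k), as.integer(n), pct_txt)
}

# Coerce a 2x2 table given as a matrix, data frame, or length-4 vector
# (a, b, c, d laid out row-wise: rows = groups, columns = outcome yes/no).
as_2x2 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) {
      abort("a 2x2 table must have exactly two rows and two columns")
    }
    m <- x
  } else if (is.numeric(x) && length(x) == 4L) {
    m <- matrix(x, nrow = 2L, byrow = TRUE)
  } else {
    abort("supply a 2x2 matrix, a 2x2 data frame, or c(a, b, c, d)")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    abort("2x2 table entries must be non-negative integers")
  }
  dimnames(m) <- list(group = c("case", "control"), outcome = c("yes", "no"))
  m
}

`%+na%` <- function(x, y) ifelse(is.na(x), y, x)
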