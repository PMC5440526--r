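# Small in-code fixtures shared across test files.

toy_catalog <- function() {
  as_species_catalog(tibble::tibble(
    species = c("Bacteroides fragilis", "Escherichia coli",
                "Lactobacillus gasseri", "Clostridium butyricum",
                "Novellum gutense"),
    phylum = c("Bacteroidetes", "Proteobacteria", "Firmicutes",
               "Firmicutes", "Firmicutes"),
    class = c("Bacteroidia", "Gammaproteobacteria", "Bacilli",
              "Clostridia", "Clostridia"),
    order = NA_character_,
    family = c("Bacteroidaceae", "Enterobacteriaceae", "Lactobacillaceae",
               "Clostridiaceae", "Clostridiaceae"),
    genus = c("Bacteroides", "Escherichia", "Lactobacillus",
              "Clostridium", "Novellum"),
    obligate_anaerobe = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    novelty = c("known_gut", "known_gut", "known_gut",
                "known_human_not_gut", "new_species"),
    probiotic = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    probiotic_function = c(NA, NA, "lactate production", NA, NA)
  ))
}

toy_detection <- function(modality = "culturomics") {
  as_detection_matrix(tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3"),
    group = c("case", "case", "case", "case", "case",
              "control", "control"),
    species = c("Bacteroides fragilis", "Escherichia coli",
                "Lactobacillus gasseri", "Escherichia coli",
                "Clostridium butyricum", "Bacteroides fragilis",
                "Novellum gutense")
  ), modality)
}

toy_otus <- function() {
  as_otu_table(tibble::tibble(
    sample_id = "s1",
    otu_id = sprintf("otu%02d", 1:5),
    read_count = c(100, 30, 70, 19, 20),
    best_hit_species = c("Bacteroides fragilis", "Bacteroides fragilis",
                         "Escherichia coli", "Lactobacillus gasseri",
                         "Clostridium butyricum"),
    best_hit_identity = c(0.99, 0.985, 0.95, 0.99, 0.97)
  ))
}

# random OTU table generator used in property-style tests
random_otus <- function(n = 100, seed = 1) {
  withr::with_seed(seed, as_otu_table(tibble::tibble(
    sample_id = sample(c("a", "b"), n, replace = TRUE),
    otu_id = sprintf("otu%04d", seq_len(n)),
    read_count = rpois(n, 40),
    best_hit_species = ifelse(runif(n) < 0.15, NA_character_,
                              sprintf("Species sp%02d", sample(1:20, n, TRUE))),
    best_hit_identity = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0.9, 1))
  )))
}

# random presence/absence detection matrix
random_detection <- function(n_samples = 5, n_species = 20, seed = 1,
                             modality = "culturomics") {
  withr::with_seed(seed, {
    grid <- expand.grid(
      sample_id = sprintf("s%02d", seq_len(n_samples)),
      species = sprintf("Genus sp%02d", seq_len(n_species)),
      stringsAsFactors = FALSE
    )
    grid <- grid[runif(nrow(grid)) < 0.4, ]
    grid$group <- ifelse(as.integer(sub("s", "", grid$sample_id)) <=
                           ceiling(n_samples / 2), "case", "control")
    as_detection_matrix(grid, modality)
  })
}

write_tsv_fixture <- function(df, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
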