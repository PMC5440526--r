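# Synthetic two-group, two-modality community generator. Emulates the
# statistical structure the analysis assumes: a shared species pool with
# taxonomy and oxygen-tolerance traits, independent per-sample detection with
# group- and trait-modified probabilities, log-normal read abundances split
# into OTUs with identity scores, and a configurable fraction of reads below
# the species-assignment identity threshold.

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study conditions of a small severe-acute-malnutrition
#' cohort: 10 cases vs 5 controls, a shared pool of 300 species of which
#' about half are obligate anaerobes, roughly 100 species detected per
#' sample, a strong depletion of anaerobe detection in cases, a moderate
#' Proteobacteria enrichment in cases, and unassigned-read fractions of 5%
#' (cases) and 26% (controls).
#'
#' @param n_case,n_control Number of samples per group.
#' @param species_pool Size of the shared species pool.
#' @param fraction_anaerobic Probability a pool species is an obligate
#'   anaerobe.
#' @param phylum_mixture Named probabilities over phyla (must sum to 1).
#' @param detect_prob_culturomics,detect_prob_metagenomics Base per-species,
#'   per-sample detection probabilities for each modality.
#' @param anaerobe_depletion_delta Multiplier applied to anaerobe detection
#'   probabilities in case samples (1 = no effect; 0.3 = strong depletion).
#' @param proteobacteria_enrichment Multiplier applied to Proteobacteria
#'   detection probabilities in case samples (> 1 = enrichment).
#' @param unknown_fraction_control,unknown_fraction_case Probability that an
#'   OTU's best hit falls below the assignment identity threshold (approx.
#'   the expected unassigned-read fraction).
#' @param reads_per_sample Sequencing depth per sample.
#' @param read_abundance_dispersion Log-normal sigma of species relative
#'   abundances.
#' @param detectability_sd Log-normal sigma of the per-species detectability
#'   multiplier shared by both groups (species differ in how easily they are
#'   found; 0 makes all species exchangeable).
#' @param force_control_only Number of species engineered to be detected in
#'   every control sample by both modalities and in no case sample (ground
#'   truth for the missing-repertoire screen; default 0).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_case = 10, n_control = 5,
                         species_pool = 300,
                         fraction_anaerobic = 0.5,
                         phylum_mixture = c(
                           Firmicutes = 0.55, Proteobacteria = 0.15,
                           Actinobacteria = 0.15, Bacteroidetes = 0.10,
                           Fusobacteria = 0.05
                         ),
                         detect_prob_culturomics = 0.30,
                         detect_prob_metagenomics = 0.35,
                         anaerobe_depletion_delta = 0.3,
                         proteobacteria_enrichment = 1.9,
                         unknown_fraction_control = 0.26,
                         unknown_fraction_case = 0.05,
                         reads_per_sample = 10000,
                         read_abundance_dispersion = 1.5,
                         detectability_sd = 0.3,
                         force_control_only = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  if (n_case < 1 || n_control < 1) abort("both groups need at least one sample")
  probs <- c(detect_prob_culturomics, detect_prob_metagenomics,
             unknown_fraction_control, unknown_fraction_case,
             fraction_anaerobic)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (anaerobe_depletion_delta <= 0 || proteobacteria_enrichment <= 0) {
    abort("effect multipliers must be positive")
  }
  if (abs(sum(phylum_mixture) - 1) > 1e-9) {
    abort("phylum_mixture probabilities must sum to 1 (within 1e-9)")
  }
  if (is.null(names(phylum_mixture))) abort("phylum_mixture must be named")
  if (force_control_only > species_pool) {
    abort("force_control_only cannot exceed the species pool")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic two-modality dataset
#'
#' Draws a species pool with traits from the configured mixture, samples
#' per-sample presence independently per modality with group- and
#' trait-modified probabilities, and, for the sequencing modality, simulates
#' per-sample OTU tables: log-normal relative abundances of the present
#' species normalised to the configured depth, reads split into 1-3 OTUs per
#' species, and best-hit identities drawn so that roughly the configured
#' unknown fraction falls below the 97% assignment threshold. The
#' metagenomics detection matrix is derived from the simulated OTU tables by
#' re-applying the standard post-processing rules (>= 20 reads, >= 97%
#' identity), so detection on the sequencing side reflects what the amplicon
#' pipeline can actually see.
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset` list: `catalog` (species catalog), `samples`
#'   (sample_id/group), `detection` (long detection tibble covering both
#'   modalities), `otus` (OTU tibble for all samples) and `ground_truth`
#'   (list with the true effect multipliers, the forced species and the
#'   realised control-only-in-both-modalities species set).
#' @export
synth_generate <- function(config) {
  if (!inherits(config, "synth_config")) abort("config must come from synth_config()")
  withr::local_seed(config$seed)
  n_sp <- config$species_pool

  phyla <- sample(names(config$phylum_mixture), n_sp, replace = TRUE,
                  prob = config$phylum_mixture)
  genus_id <- cumsum(stats::runif(n_sp) < 0.35) + 1L
  genus <- sprintf("%s_genus%03d", substr(phyla, 1, 4), genus_id)
  species <- sprintf("%s sp%03d", genus, seq_len(n_sp))
  anaerobe <- stats::runif(n_sp) < config$fraction_anaerobic
  novelty <- sample(novelty_levels, n_sp, replace = TRUE,
                    prob = c(0.75, 0.07, 0.08, 0.06, 0.03, 0.01))
  catalog <- tibble(
    species = species, phylum = phyla, class = paste0(phyla, "_class"),
    order = paste0(phyla, "_order"), family = paste0(genus, "_family"),
    genus = genus, obligate_anaerobe = anaerobe, novelty = novelty,
    probiotic = anaerobe & novelty == "known_gut" & stats::runif(n_sp) < 0.10,
    probiotic_function = NA_character_
  )

  samples <- tibble(
    sample_id = c(sprintf("case%02d", seq_len(config$n_case)),
                  sprintf("ctrl%02d", seq_len(config$n_control))),
    group = rep(c("case", "control"), c(config$n_case, config$n_control))
  )

  detectability <- rlnorm(n_sp, 0, config$detectability_sd)
  base <- list(culturomics = config$detect_prob_culturomics,
               metagenomics = config$detect_prob_metagenomics)
  case_mult <- rep(1, n_sp)
  case_mult[anaerobe] <- case_mult[anaerobe] * config$anaerobe_depletion_delta
  case_mult[phyla == "Proteobacteria"] <-
    case_mult[phyla == "Proteobacteria"] * config$proteobacteria_enrichment

  forced <- integer(0)
  if (config$force_control_only > 0) {
    forced <- sample.int(n_sp, config$force_control_only)
  }

  presence <- list()
  for (mod in names(base)) {
    p_ctrl <- pmin(1, base[[mod]] * detectability)
    p_case <- pmin(1, p_ctrl * case_mult)
    p_ctrl[forced] <- 1
    p_case[forced] <- 0
    rows <- map(seq_len(nrow(samples)), function(i) {
      p <- if (samples$group[i] == "case") p_case else p_ctrl
      hit <- stats::runif(n_sp) < p
      if (!any(hit)) return(NULL)
      tibble(modality = mod, sample_id = samples$sample_id[i],
             group = samples$group[i], species = species[hit])
    })
    presence[[mod]] <- list_rbind(rows)
  }

  # sequencing reads for species present in the metagenomics layer
  meta <- presence$metagenomics
  unknown_frac <- c(case = config$unknown_fraction_case,
                    control = config$unknown_fraction_control)
  forced_species <- species[forced]
  otu_rows <- map(unique(meta$sample_id), function(sid) {
    sub <- meta[meta$sample_id == sid, ]
    grp <- sub$group[1]
    abund <- rlnorm(nrow(sub), 0, config$read_abundance_dispersion)
    reads <- as.vector(rmultinom(1, config$reads_per_sample,
                                 abund / sum(abund)))
    # engineered control-only species must survive post-processing (>= 20
    # assignable reads); top them up, taking reads from the deepest
    # non-forced species so the sample depth is preserved
    is_forced <- sub$species %in% forced_species
    for (j in which(is_forced & reads < 20)) {
      donor <- which.max(replace(reads, is_forced, -1L))
      short <- 20L - reads[j]
      reads[donor] <- reads[donor] - short
      reads[j] <- 20L
    }
    keep <- reads > 0
    sp <- sub$species[keep]; reads <- reads[keep]
    sp_forced <- sp %in% forced_species
    k <- sample(1:3, length(sp), replace = TRUE)
    k[sp_forced] <- 1L
    k <- pmin(k, reads)
    # split each species' reads over its OTUs, accumulating plain vectors
    otu_sp <- character(0); otu_reads <- integer(0)
    for (j in seq_along(sp)) {
      split_reads <- if (k[j] == 1) reads[j] else {
        as.vector(rmultinom(1, reads[j], rep(1, k[j])))
      }
      split_reads <- split_reads[split_reads > 0]
      otu_sp <- c(otu_sp, rep(sp[j], length(split_reads)))
      otu_reads <- c(otu_reads, split_reads)
    }
    n_otu <- length(otu_sp)
    unknown <- stats::runif(n_otu) < unknown_frac[[grp]] &
      !otu_sp %in% forced_species
    identity <- ifelse(unknown, runif(n_otu, 0.90, 0.9699),
                       runif(n_otu, 0.97, 1.0))
    tibble(
      sample_id = sid,
      otu_id = sprintf("%s_otu%04d", sid, seq_len(n_otu)),
      read_count = as.integer(otu_reads),
      best_hit_species = ifelse(unknown, NA_character_, otu_sp),
      best_hit_identity = ifelse(unknown & runif(n_otu) < 0.2,
                                 NA_real_, identity)
    )
  })
  otus <- list_rbind(otu_rows) |>
    select("sample_id", "otu_id", "read_count",
           "best_hit_species", "best_hit_identity")

  # metagenomics detection as the pipeline will see it: an OTU with at least
  # 20 reads and an identity of at least 0.97 (plain recount, no package
  # machinery, so cross-module tests stay meaningful)
  seen <- otus[otus$read_count >= 20 &
                 !is.na(otus$best_hit_species) &
                 !is.na(otus$best_hit_identity) &
                 otus$best_hit_identity >= 0.97, ]
  meta_det <- unique(seen[c("sample_id", "best_hit_species")])
  meta_det <- tibble(
    modality = "metagenomics",
    sample_id = meta_det$sample_id,
    group = samples$group[match(meta_det$sample_id, samples$sample_id)],
    species = meta_det$best_hit_species
  )
  detection <- bind_rows(presence$culturomics, meta_det)

  # realised control-only set, by plain set algebra on the detection layers
  set_of <- function(d, g) unique(d$species[d$group == g])
  cult <- presence$culturomics
  control_only <- setdiff(
    intersect(set_of(cult, "control"), set_of(meta_det, "control")),
    union(set_of(cult, "case"), set_of(meta_det, "case"))
  )

  structure(
    list(
      catalog = catalog, samples = samples, detection = detection,
      otus = otus,
      ground_truth = list(
        anaerobe_depletion_delta = config$anaerobe_depletion_delta,
        proteobacteria_enrichment = config$proteobacteria_enrichment,
        forced_control_only = sort(species[forced]),
        control_only_species = sort(control_only),
        config = config
      )
    ),
    class = "synth_dataset"
  )
}

#' Ground truth of a synthetic dataset
#'
#' @param dataset A `synth_dataset` from [synth_generate()].
#' @return The ground-truth record: true effect multipliers, forced
#'   control-only species, and the realised control-only species set.
#' @export
synth_ground_truth <- function(dataset) {
  if (!inherits(dataset, "synth_dataset")) {
    abort("dataset must come from synth_generate()")
  }
  dataset$ground_truth
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits `catalog.tsv`, `samples.tsv`, `culturomics_detection.tsv` (long
#' format) and `otus.tsv` in the package's standard dialects, ready to be
#' consumed by [run_pipeline()].
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_species_catalog(dataset$catalog, file.path(dir, "catalog.tsv"))
  readr::write_tsv(dataset$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  cult <- filter(dataset$detection, .data$modality == "culturomics")
  write_detection_matrix(cult, file.path(dir, "culturomics_detection.tsv"))
  readr::write_tsv(dataset$otus, file.path(dir, "otus.tsv"), progress = FALSE)
  invisible(dir)
}
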