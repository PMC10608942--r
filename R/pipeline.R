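pipeline_config_keys <- c("simulate", "inputs", "params", "seed", "out_dir")
pipeline_param_keys <- c("normalization_constant", "offset_s",
                         "min_identity_pct", "max_evalue", "min_completeness",
                         "max_contamination", "min_abundance",
                         "spectral_display_threshold", "signal", "usicg_file")
pipeline_input_keys <- c("gene_catalog", "mag_quality", "read_counts",
                         "unmapped", "spectral_counts", "modules",
                         "key_enzymes", "process_metadata")

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with top-level
#' keys `simulate` (a [community_spec()] argument list) or `inputs` (paths to
#' the canonical TSVs), plus optional `params` overrides, `seed` and
#' `out_dir`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or a list.
#' @return The validated configuration list with parameter defaults filled
#'   in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    abort("config needs either a 'simulate' block or an 'inputs' block")
  }
  if (!is.null(config$inputs)) {
    unknown <- setdiff(names(config$inputs), pipeline_input_keys)
    if (length(unknown) > 0) {
      abort(paste0("unknown inputs key(s): ", paste(unknown, collapse = ", ")))
    }
  }
  unknown <- setdiff(names(config$params), pipeline_param_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown params key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(normalization_constant = 78119, offset_s = NULL,
                   min_identity_pct = 30, max_evalue = 1e-10,
                   min_completeness = 50, max_contamination = 10,
                   min_abundance = 0.5, spectral_display_threshold = 10,
                   signal = "reads", usicg_file = NULL)
  config$params <- utils::modifyList(defaults, config$params %||% list())
  if (config$params$normalization_constant <= 0) {
    abort("normalization_constant must be positive")
  }
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "magquant_results"
  config
}

#' Run the full quantification pipeline
#'
#' Chains simulation (or reading of canonical inputs), annotation filtering,
#' metagenome-side quantification (MAG abundance, KO counts, AGCN),
#' metaproteome-side quantification (uniqueness exclusion, two-round
#' normalization, completeness-adjusted abundance) and the downstream
#' summaries (fold changes, HQ filter, category summary, and — when module
#' and key-enzyme tables are provided — module scores and enzyme summaries).
#' All result tables are written as TSVs into the output directory together
#' with the resolved configuration (`run_config_resolved.yaml`); outputs are
#' deterministic for a fixed seed, and partial outputs are removed when a
#' stage fails.
#'
#' @param config Path to a YAML configuration or a list; see
#'   [read_run_config()].
#' @return Invisibly, a list of the in-memory result objects plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) {
      inform(paste0("pipeline failed; removing partial outputs in ", out_dir))
      unlink(file.path(out_dir, pipeline_output_files()), force = TRUE)
      if (created) unlink(out_dir, recursive = TRUE, force = TRUE)
    }
  })
  yaml::write_yaml(config, file.path(out_dir, "run_config_resolved.yaml"))
  p <- config$params

  modules <- NULL
  key_enzymes <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- lapply(config$simulate,
                       function(x) if (is.list(x)) unlist(x) else x)
    sim_args$seed <- sim_args$seed %||% config$seed
    spec <- do.call(community_spec, sim_args)
    inform(sprintf("simulating community: %d MAGs, %d x %d samples",
                   spec$n_mags, spec$n_conditions, spec$n_replicates))
    community <- generate_community(spec)
    reads <- simulate_read_counts(community)
    spectra <- simulate_spectral_counts(community)
    catalog <- community$catalog
    mags <- community$mags
    counts <- reads$counts
    samples <- reads$samples
    readr::write_tsv(community$ground_truth,
                     file.path(out_dir, "ground_truth.tsv"))
  } else {
    inp <- config$inputs
    for (key in c("gene_catalog", "mag_quality", "read_counts", "unmapped",
                  "spectral_counts")) {
      if (is.null(inp[[key]])) abort(paste0("inputs block is missing ", key))
    }
    mags <- read_mag_table(inp$mag_quality)
    catalog <- read_gene_catalog(inp$gene_catalog, mags)
    counts <- read_read_counts(inp$read_counts)
    samples <- read_sample_info(inp$unmapped)
    spectra <- read_spectral_counts(inp$spectral_counts)
    if (!is.null(inp$modules)) modules <- read_module_definitions(inp$modules)
    if (!is.null(inp$key_enzymes)) {
      key_enzymes <- read_key_enzymes(inp$key_enzymes)
    }
  }
  inform(sprintf("inputs: %d genes, %d MAGs, %d samples, %d metaprotein rows",
                 nrow(catalog), nrow(mags), nrow(samples), nrow(spectra)))

  usicg <- if (!is.null(p$usicg_file)) {
    read_canonical_tsv(p$usicg_file, required = "ko_id")$ko_id
  } else {
    default_usicg_kos()
  }

  # --- metagenome side ---
  catalog <- filter_annotations(catalog, p$min_identity_pct, p$max_evalue)
  genomic <- mag_relative_abundance(counts, samples, catalog, mags,
                                    signal = p$signal)
  ko_counts <- ko_read_counts(counts, catalog)
  ko_by_condition <- ko_counts %>%
    inner_join(samples[, c("sample_id", "condition_id")], by = "sample_id") %>%
    group_by(.data$ko_id, sample_id = .data$condition_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  agcn <- agcn_normalize(ko_by_condition, usicg, ko_mean_lengths(catalog))
  inform(sprintf("genomic: %d KO rows, %d profile rows",
                 dplyr::n_distinct(ko_counts$ko_id), nrow(genomic)))

  # --- metaproteome side ---
  unique_spectra <- exclude_nonunique(spectra)
  norm1 <- total_count_normalize(unique_spectra, p$normalization_constant)
  by_condition <- median_and_renormalize(norm1, samples, catalog,
                                         p$normalization_constant)
  proteomic <- mag_proteomic_abundance(norm1, samples, catalog, mags)
  inform(sprintf("proteomic: %d unique genes, %d profile rows",
                 dplyr::n_distinct(unique_spectra$gene_id), nrow(proteomic)))

  # --- downstream summaries ---
  ko_cond <- by_condition$ko
  offset_s <- p$offset_s %||% derive_offset(ko_cond)
  conditions <- sort(unique(samples$condition_id))
  fold_changes <- if (length(conditions) >= 2) {
    pairs <- utils::combn(conditions, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      log2_fold_change(ko_cond, pairs[, j], offset_s)
    })
  } else {
    tibble()
  }
  quality <- mags$mag_id[mags$completeness_pct > p$min_completeness &
                           mags$contamination_pct < p$max_contamination]
  hq <- hq_mag_filter(mags, genomic, proteomic, p$min_completeness,
                      p$max_contamination, p$min_abundance)
  categories <- summarize_categories(mags, quality, genomic, proteomic,
                                     p$min_abundance)
  inform(sprintf("summary: %d HQ MAGs, offset s = %s, %d fold-change rows",
                 nrow(hq), format(offset_s), nrow(fold_changes)))

  results <- list(genomic = genomic, proteomic = proteomic, agcn = agcn,
                  ko_spectra = ko_cond, fold_changes = fold_changes,
                  hq_mags = hq, categories = categories, offset_s = offset_s,
                  out_dir = out_dir)

  readr::write_tsv(long_to_wide(tidy(genomic)[1:3], "mag_id",
                                value = "abundance_pct",
                                col = "condition_id"),
                   file.path(out_dir, "genomic_abundance.tsv"))
  readr::write_tsv(long_to_wide(tidy(proteomic)[1:3], "mag_id",
                                value = "abundance_pct",
                                col = "condition_id"),
                   file.path(out_dir, "proteomic_abundance.tsv"))
  readr::write_tsv(long_to_wide(as_tibble(agcn), "ko_id", value = "agcn"),
                   file.path(out_dir, "agcn.tsv"))
  readr::write_tsv(long_to_wide(ko_cond, "ko_id", col = "condition_id"),
                   file.path(out_dir, "ko_spectra.tsv"))
  readr::write_tsv(fold_changes, file.path(out_dir, "fold_changes.tsv"))
  readr::write_tsv(hq, file.path(out_dir, "hq_mags.tsv"))
  readr::write_tsv(categories, file.path(out_dir, "category_summary.tsv"))

  if (!is.null(modules)) {
    scores <- purrr::map_dfr(hq$mag_id, function(m) {
      kos <- unique(stats::na.omit(catalog$ko_id[catalog$mag_id == m]))
      mutate(module_completeness(kos, modules), mag_id = m)
    })
    readr::write_tsv(scores, file.path(out_dir, "module_scores.tsv"))
    results$module_scores <- scores
  }
  if (!is.null(key_enzymes)) {
    enzymes <- enzyme_level_summary(agcn, ko_cond, key_enzymes) %>%
      spectral_threshold_filter(p$spectral_display_threshold)
    readr::write_tsv(enzymes, file.path(out_dir, "enzyme_summary.tsv"))
    results$enzyme_summary <- enzymes
  }
  ok <- TRUE
  invisible(results)
}

pipeline_output_files <- function() {
  c("run_config_resolved.yaml", "ground_truth.tsv", "genomic_abundance.tsv",
    "proteomic_abundance.tsv", "agcn.tsv", "ko_spectra.tsv",
    "fold_changes.tsv", "hq_mags.tsv", "category_summary.tsv",
    "module_scores.tsv", "enzyme_summary.tsv")
}
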