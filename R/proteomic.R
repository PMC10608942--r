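#' Group protein identifications into metaproteins
#'
#' Homologous, redundant protein identifications sharing the same peptide set
#' are merged into one metaprotein: spectral counts are summed per sample and
#' the gene set is the union of the members' genes. Metaproteins whose gene
#' set holds more than one gene are thereby flagged non-unique (`n_genes >
#' 1`).
#'
#' @param identifications Tibble with columns `protein_id`, `peptide_set_id`,
#'   `gene_id`, `sample_id`, `count`.
#' @return A long metaprotein tibble (`metaprotein_id`, `peptide_set_id`,
#'   `gene_ids`, `n_genes`, `sample_id`, `count`).
#' @export
group_metaproteins <- function(identifications) {
  sets <- identifications %>%
    group_by(.data$peptide_set_id) %>%
    summarise(gene_ids = paste(sort(unique(.data$gene_id)), collapse = ","),
              n_genes = dplyr::n_distinct(.data$gene_id),
              metaprotein_id = dplyr::first(sort(.data$protein_id)),
              .groups = "drop")
  counts <- identifications %>%
    group_by(.data$peptide_set_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  inner_join(sets, counts, by = "peptide_set_id") %>%
    select("metaprotein_id", "peptide_set_id", "gene_ids", "n_genes",
           "sample_id", "count") %>%
    arrange(.data$metaprotein_id, .data$sample_id)
}

#' Exclude metaproteins that cannot be uniquely assigned to one gene
#'
#' Drops every metaprotein whose gene set holds more than one gene and
#' re-keys the remainder by `gene_id`, summing counts when several unique
#' metaproteins map to the same gene. Idempotent; an all-non-unique input
#' yields an empty table with a warning, not an error.
#'
#' @param metaproteins A metaprotein tibble from [group_metaproteins()] or
#'   [read_spectral_counts()].
#' @return A long gene-level spectra tibble (`gene_id`, `sample_id`,
#'   `count`).
#' @export
exclude_nonunique <- function(metaproteins) {
  if ("n_genes" %in% names(metaproteins)) {
    unique_rows <- metaproteins[metaproteins$n_genes == 1, ]
  } else {
    unique_rows <- metaproteins[!grepl(",", metaproteins$gene_ids,
                                       fixed = TRUE), ]
  }
  if (nrow(unique_rows) == 0) {
    warn("no uniquely assigned metaproteins remain; returning empty table")
    return(tibble(gene_id = character(), sample_id = character(),
                  count = numeric()))
  }
  key <- if ("gene_ids" %in% names(unique_rows)) "gene_ids" else "gene_id"
  unique_rows %>%
    select(dplyr::all_of(c(key, "sample_id", "count"))) %>%
    rename(gene_id = dplyr::all_of(key)) %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$gene_id, .data$sample_id)
}

#' Total-count normalization of spectral counts
#'
#' Scales each sample's spectral counts so that every column sums to the same
#' constant. The default, 78,119, is a dataset-specific total and should be
#' set to whatever matches the data at hand.
#'
#' @param spectra Long tibble whose first column keys the feature (gene or
#'   KO), with `sample_id` and `count` columns.
#' @param constant Positive target column sum.
#' @return The same tibble with each column rescaled; every sample's counts
#'   sum to `constant`.
#' @export
total_count_normalize <- function(spectra, constant = 78119) {
  if (constant <= 0) abort("normalization constant must be positive")
  sums <- spectra %>% group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- sums$sample_id[sums$total <= 0]
  if (length(zero) > 0) {
    abort(paste0("zero spectral-count sum in sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  spectra %>% inner_join(sums, by = "sample_id") %>%
    mutate(count = .data$count * constant / .data$total) %>%
    select(-"total")
}

#' Replicate medians and second-round normalization
#'
#' Combines replicate samples of each condition by the element-wise median at
#' the gene level, forms KO-level values by summing gene medians over each
#' KO's genes, and total-count normalizes both resulting matrices a second
#' time to the same constant.
#'
#' @param gene_spectra Long gene-level spectra (`gene_id`, `sample_id`,
#'   `count`), typically round-1 normalized.
#' @param samples Sample table mapping `sample_id` to `condition_id`.
#' @param catalog Gene catalog carrying the KO annotation.
#' @param constant Target column sum for the second normalization round.
#' @return A list with `gene` (`gene_id`, `condition_id`, `count`) and `ko`
#'   (`ko_id`, `condition_id`, `count`), each column summing to `constant`.
#' @export
median_and_renormalize <- function(gene_spectra, samples, catalog,
                                   constant = 78119) {
  gene_median <- gene_spectra %>%
    inner_join(samples[, c("sample_id", "condition_id")], by = "sample_id") %>%
    group_by(.data$gene_id, .data$condition_id) %>%
    summarise(count = median(.data$count), .groups = "drop")
  ko_median <- gene_median %>%
    inner_join(catalog[!is.na(catalog$ko_id), c("gene_id", "ko_id")],
               by = "gene_id") %>%
    group_by(.data$ko_id, .data$condition_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  renorm <- function(df) {
    df %>% rename(sample_id = "condition_id") %>%
      total_count_normalize(constant) %>%
      rename(condition_id = "sample_id")
  }
  list(gene = renorm(gene_median), ko = renorm(ko_median))
}

#' Completeness-adjusted MAG proteomic abundance
#'
#' Sums the spectral counts of each MAG's genes, divides by the MAG's
#' completeness (as a fraction, so a complete MAG is unadjusted) to prevent
#' under-representation of incomplete MAGs, and expresses the adjusted sums
#' as percentages of the whole community including the unbinned fraction
#' (which has no completeness estimate and is never adjusted). When the
#' input holds replicate samples, per-replicate percentages are combined by
#' the median per MAG and each condition column renormalized to 100%.
#'
#' @param gene_spectra Long gene-level spectra per replicate (`gene_id`,
#'   `sample_id`, `count`), e.g. round-1 normalized unique spectra.
#' @param samples Sample table mapping `sample_id` to `condition_id`.
#' @param catalog Gene catalog (gene to MAG membership).
#' @param mags MAG quality table; `completeness_pct` must be positive.
#' @return A `mag_abundance` tibble (`mag_id`, `condition_id`,
#'   `abundance_pct`), proteomic layer, columns summing to 100.
#' @export
mag_proteomic_abundance <- function(gene_spectra, samples, catalog, mags) {
  if (any(mags$completeness_pct <= 0)) {
    abort("MAG completeness must be positive for completeness adjustment")
  }
  comp <- setNames(mags$completeness_pct / 100, mags$mag_id)
  all_rows <- unique(c(mags$mag_id,
                       if (UNBINNED %in% catalog$mag_id) UNBINNED))
  per_sample <- gene_spectra %>%
    inner_join(catalog[, c("gene_id", "mag_id")], by = "gene_id") %>%
    group_by(.data$sample_id, .data$mag_id) %>%
    summarise(raw = sum(.data$count), .groups = "drop") %>%
    tidyr::complete(sample_id = unique(samples$sample_id),
                    mag_id = all_rows, fill = list(raw = 0)) %>%
    mutate(adjusted = .data$raw /
             dplyr::coalesce(unname(comp[.data$mag_id]), 1)) %>%
    group_by(.data$sample_id) %>%
    mutate(abundance_pct = 100 * .data$adjusted / sum(.data$adjusted)) %>%
    ungroup() %>%
    inner_join(samples[, c("sample_id", "condition_id")], by = "sample_id")

  profile <- per_sample %>%
    group_by(.data$condition_id, .data$mag_id) %>%
    summarise(abundance_pct = median(.data$abundance_pct), .groups = "drop") %>%
    group_by(.data$condition_id) %>%
    mutate(abundance_pct = 100 * .data$abundance_pct /
             sum(.data$abundance_pct)) %>%
    ungroup() %>%
    select("mag_id", "condition_id", "abundance_pct") %>%
    arrange(.data$mag_id, .data$condition_id)
  new_mag_abundance(profile, layer = "proteomic")
}
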