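#' Filter gene annotations by identity and e-value
#'
#' Discards KO/EC annotations whose alignment support is weak: an annotation
#' is kept only if its sequence identity is at least `min_identity_pct` and
#' its e-value at most `max_evalue` (the discard rule is strict "below 30%" /
#' "larger than 1e-10", so both boundaries are kept). Genes keep their row —
#' membership and read counts are untouched — but lose `ko_id` and `ec_ids`.
#' Annotations whose identity or e-value is missing are kept, since the
#' criteria cannot be evaluated for them.
#'
#' @param catalog A gene-catalog tibble.
#' @param min_identity_pct Minimum sequence identity to keep, in percent.
#' @param max_evalue Maximum e-value to keep.
#' @return The catalog with failing annotations blanked.
#' @export
#' @examples
#' cat <- tibble::tibble(
#'   gene_id = c("g1", "g2"), contig_id = "c1", mag_id = "MAG001",
#'   length_bp = 900, ko_id = c("K00001", "K00002"), ec_ids = NA,
#'   annot_identity_pct = c(29.9, 95), annot_evalue = c(1e-20, 1e-5))
#' filter_annotations(cat)$ko_id   # both annotations discarded
filter_annotations <- function(catalog, min_identity_pct = 30,
                               max_evalue = 1e-10) {
  fail <- (!is.na(catalog$annot_identity_pct) &
             catalog$annot_identity_pct < min_identity_pct) |
    (!is.na(catalog$annot_evalue) & catalog$annot_evalue > max_evalue)
  catalog$ko_id[fail] <- NA_character_
  if ("ec_ids" %in% names(catalog)) catalog$ec_ids[fail] <- NA_character_
  catalog
}

new_mag_abundance <- function(df, layer) {
  structure(df, class = c("mag_abundance", class(df)), layer = layer)
}

#' Metagenome-based MAG relative abundance
#'
#' Computes per-condition MAG relative abundances from gene-level read
#' counts. Per sample, a MAG's abundance is the share of mapped reads falling
#' on its genes (unmapped reads are excluded by construction: only mapped
#' counts enter). Unbinned contigs form a first-class `UNBINNED` row so MAG
#' abundances are fractions of the whole community. Replicates of a condition
#' are combined by taking the median per MAG, and each condition column is
#' then renormalized to 100%.
#'
#' @param counts Long read-count tibble (`gene_id`, `sample_id`, `count`).
#' @param samples Sample table with `sample_id` and `condition_id`.
#' @param catalog Gene catalog (every counted gene must appear in it).
#' @param mags MAG quality table; every MAG gets a row even at zero counts.
#' @param signal `"reads"` (summed read counts, the default) or `"coverage"`
#'   (length-normalized counts, `count / length_bp`) as the mapping signal.
#' @return A `mag_abundance` tibble (`mag_id`, `condition_id`,
#'   `abundance_pct`) whose columns each sum to 100.
#' @export
mag_relative_abundance <- function(counts, samples, catalog, mags,
                                   signal = c("reads", "coverage")) {
  signal <- match.arg(signal)
  missing_genes <- setdiff(unique(counts$gene_id), catalog$gene_id)
  if (length(missing_genes) > 0) {
    abort(paste0("counted genes absent from catalog: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  per_sample <- counts %>%
    inner_join(catalog[, c("gene_id", "mag_id", "length_bp")], by = "gene_id") %>%
    mutate(weight = if (signal == "reads") .data$count
           else .data$count / .data$length_bp) %>%
    group_by(.data$sample_id, .data$mag_id) %>%
    summarise(weight = sum(.data$weight), .groups = "drop")

  totals <- per_sample %>% group_by(.data$sample_id) %>%
    summarise(total = sum(.data$weight), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(paste0("sample(s) with zero mapped reads: ",
                 paste(zero, collapse = ", ")))
  }

  all_rows <- unique(c(mags$mag_id,
                       if (UNBINNED %in% catalog$mag_id) UNBINNED))
  per_sample <- per_sample %>%
    tidyr::complete(sample_id = unique(samples$sample_id),
                    mag_id = all_rows, fill = list(weight = 0)) %>%
    inner_join(totals, by = "sample_id") %>%
    mutate(abundance_pct = 100 * .data$weight / .data$total) %>%
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
  new_mag_abundance(profile, layer = "genomic")
}

#' Sum read counts at the KEGG-orthology level
#'
#' Sums gene-level read counts over genes sharing a KO annotation; genes with
#' no (or a discarded) annotation contribute nothing. Apply
#' [filter_annotations()] first.
#'
#' @inheritParams mag_relative_abundance
#' @return A long tibble `ko_id`, `sample_id`, `count`, complete over all
#'   observed KO-sample combinations (zeros filled in).
#' @export
ko_read_counts <- function(counts, catalog) {
  annotated <- catalog[!is.na(catalog$ko_id), c("gene_id", "ko_id")]
  counts %>%
    inner_join(annotated, by = "gene_id") %>%
    group_by(.data$ko_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::complete(.data$ko_id, .data$sample_id, fill = list(count = 0)) %>%
    arrange(.data$ko_id, .data$sample_id)
}

#' Mean annotated gene length per KO
#'
#' Helper for [agcn_normalize()]: the mean length of the genes carrying each
#' KO annotation, used to length-normalize KO counts.
#'
#' @inheritParams mag_relative_abundance
#' @return A tibble `ko_id`, `mean_length_bp`.
#' @export
ko_mean_lengths <- function(catalog) {
  catalog %>% filter(!is.na(.data$ko_id)) %>%
    group_by(.data$ko_id) %>%
    summarise(mean_length_bp = mean(.data$length_bp), .groups = "drop")
}

#' Average genomic copy number (AGCN) normalization
#'
#' Converts KO-level read counts into average genomic copy numbers: how many
#' copies of a feature sit, on average, on a genome in the community. Per
#' sample, each KO count is first length-normalized (count divided by the
#' KO's mean gene length) and then divided by the median length-normalized
#' count over a universal single-copy gene (USiCG) set — genes present
#' exactly once per prokaryotic genome — so that the USiCG median is 1 by
#' construction. Only this inter-sample scaling step is performed; no learned
#' intra-sample correction is applied.
#'
#' @param ko_counts Long KO-count tibble (`ko_id`, `sample_id`, `count`).
#' @param usicg_kos Character vector of USiCG KO identifiers; defaults to the
#'   packaged ten ribosomal-protein KOs. USiCG KOs absent from `ko_counts`
#'   enter the median as zeros.
#' @param gene_lengths Tibble `ko_id`, `mean_length_bp`; see
#'   [ko_mean_lengths()].
#' @return An `agcn_profile` tibble `ko_id`, `sample_id`, `agcn` with the
#'   USiCG set attached as attribute `usicg`.
#' @export
agcn_normalize <- function(ko_counts, usicg_kos = default_usicg_kos(),
                           gene_lengths) {
  full <- ko_counts %>%
    tidyr::complete(ko_id = union(unique(ko_counts$ko_id), usicg_kos),
                    sample_id = unique(ko_counts$sample_id),
                    fill = list(count = 0)) %>%
    left_join(gene_lengths, by = "ko_id") %>%
    mutate(rate = .data$count /
             dplyr::coalesce(.data$mean_length_bp,
                             mean(gene_lengths$mean_length_bp)))
  ref <- full %>% filter(.data$ko_id %in% usicg_kos) %>%
    group_by(.data$sample_id) %>%
    summarise(ref = median(.data$rate), .groups = "drop")
  dead <- ref$sample_id[ref$ref == 0]
  if (length(dead) > 0) {
    abort(paste0("median USiCG count is zero (no usable single-copy reference) in sample(s): ",
                 paste(dead, collapse = ", ")))
  }
  out <- full %>% inner_join(ref, by = "sample_id") %>%
    mutate(agcn = .data$rate / .data$ref) %>%
    select("ko_id", "sample_id", "agcn") %>%
    arrange(.data$ko_id, .data$sample_id)
  structure(out, class = c("agcn_profile", class(out)), usicg = usicg_kos)
}
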