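#' KO-level log2 fold changes between two conditions
#'
#' Computes `log2fc = log2((count_x + s) / (count_y + s))` for every KO, where
#' `s` is a positive pseudocount offset that keeps fold changes sensible when
#' a count is zero or near zero in one condition. The default offset is 2;
#' [derive_offset()] reproduces the percentile-based derivation.
#'
#' @param ko_matrix Long KO tibble (`ko_id`, `condition_id`, `count`).
#' @param pair Length-2 character vector `(x, y)` of condition identifiers.
#' @param offset_s Positive pseudocount offset.
#' @return A tibble `ko_id`, `condition_x`, `condition_y`, `count_x`,
#'   `count_y`, `offset_s`, `log2fc`. Antisymmetric under pair swap.
#' @export
#' @examples
#' m <- tibble::tibble(ko_id = "K1", condition_id = c("D1", "D2"),
#'                     count = c(6, 0))
#' log2_fold_change(m, c("D1", "D2"))$log2fc  # log2(8/2) = 2
log2_fold_change <- function(ko_matrix, pair, offset_s = 2) {
  if (offset_s <= 0) abort("offset_s must be positive")
  if (length(pair) != 2) abort("pair must name exactly two conditions")
  missing_cond <- setdiff(pair, unique(ko_matrix$condition_id))
  if (length(missing_cond) > 0) {
    abort(paste0("condition(s) absent from matrix: ",
                 paste(missing_cond, collapse = ", ")))
  }
  wide <- ko_matrix %>%
    filter(.data$condition_id %in% pair) %>%
    tidyr::complete(.data$ko_id, condition_id = pair,
                    fill = list(count = 0)) %>%
    tidyr::pivot_wider(names_from = "condition_id", values_from = "count")
  tibble(
    ko_id = wide$ko_id,
    condition_x = pair[1], condition_y = pair[2],
    count_x = wide[[pair[1]]], count_y = wide[[pair[2]]],
    offset_s = offset_s,
    log2fc = log2((wide[[pair[1]]] + offset_s) /
                    (wide[[pair[2]]] + offset_s)))
}

#' Derive the fold-change pseudocount offset from the count distribution
#'
#' Returns the rounded 30th percentile (linear-interpolation definition,
#' half-up rounding) of the KO-level spectral counts, floored at 1. By
#' default all cells enter the distribution, zeros included; set `universe =
#' "nonzero"` to restrict to positive counts.
#'
#' @inheritParams log2_fold_change
#' @param universe `"all"` (default) or `"nonzero"`: which counts form the
#'   percentile distribution.
#' @param prob Percentile to use, as a probability.
#' @return A positive number (at least 1).
#' @export
derive_offset <- function(ko_matrix, universe = c("all", "nonzero"),
                          prob = 0.30) {
  universe <- match.arg(universe)
  values <- ko_matrix$count
  if (universe == "nonzero") values <- values[values > 0]
  if (length(values) == 0) abort("no counts to derive an offset from")
  q <- unname(quantile(values, probs = prob, type = 7))
  s <- floor(q + 0.5)  # half-up rounding
  if (s < 1) {
    warn("derived offset rounds to 0; clamping to 1")
    s <- 1
  }
  s
}

#' Maximum absolute pairwise log2 fold change across conditions
#'
#' Applies the offset fold-change formula to every unordered pair of
#' condition values and returns the largest absolute value — e.g. the maximum
#' proteomic fold change between any two of three digesters.
#'
#' @param values Numeric vector of per-condition counts (length >= 2).
#' @inheritParams log2_fold_change
#' @return A single non-negative number.
#' @export
max_pairwise_fold_change <- function(values, offset_s = 2) {
  if (length(values) < 2) abort("need at least two conditions")
  if (offset_s <= 0) abort("offset_s must be positive")
  pairs <- utils::combn(length(values), 2)
  max(abs(log2((values[pairs[1, ]] + offset_s) /
                 (values[pairs[2, ]] + offset_s))))
}

#' KEGG-module block completeness per MAG
#'
#' Scores each module against a MAG's KO repertoire: a block is satisfied
#' when any one of its alternative KO sets is fully present, module
#' completeness is the percentage of satisfied blocks, and a module is
#' retained for downstream activity analysis when it is complete or missing
#' at most one block.
#'
#' @param mag_kos Character vector of KO identifiers present in the MAG.
#' @param modules Module-definition tibble from [read_module_definitions()].
#' @return A tibble `module_id`, `blocks_total`, `blocks_satisfied`,
#'   `completeness_pct`, `retained`.
#' @export
module_completeness <- function(mag_kos, modules) {
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    blocks <- modules$blocks[[i]]
    satisfied <- vapply(blocks, function(block) {
      any(vapply(block, function(alt) all(alt %in% mag_kos), logical(1)))
    }, logical(1))
    tibble(module_id = modules$module_id[i],
           blocks_total = length(blocks),
           blocks_satisfied = sum(satisfied),
           completeness_pct = 100 * sum(satisfied) / length(blocks),
           retained = sum(satisfied) >= length(blocks) - 1L)
  })
}

#' Proteomic activity of a module within a MAG
#'
#' For each condition, the spectral counts of the MAG's genes whose KO occurs
#' anywhere in the module are summed and divided by the total spectral counts
#' originating from the MAG. A MAG with zero spectra in a condition yields
#' activity 0 with a warning.
#'
#' @param mag_id The MAG to score.
#' @param module_id The module to score.
#' @param modules Module-definition tibble.
#' @param gene_spectra Condition-level gene spectra (`gene_id`,
#'   `condition_id`, `count`).
#' @param catalog Gene catalog (membership and KO annotation).
#' @return A tibble `mag_id`, `module_id`, `condition_id`,
#'   `activity_fraction` (in \[0, 1\]).
#' @export
module_activity <- function(mag_id, module_id, modules, gene_spectra,
                            catalog) {
  row <- which(modules$module_id == module_id)
  if (length(row) != 1) abort(paste0("unknown module: ", module_id))
  module_kos <- unique(unlist(modules$blocks[[row]]))
  genes <- catalog[catalog$mag_id == mag_id, c("gene_id", "ko_id")]
  mag_spectra <- gene_spectra %>% inner_join(genes, by = "gene_id")
  out <- mag_spectra %>%
    group_by(.data$condition_id) %>%
    summarise(module_count = sum(.data$count[.data$ko_id %in% module_kos &
                                               !is.na(.data$ko_id)]),
              total_count = sum(.data$count), .groups = "drop") %>%
    tidyr::complete(condition_id = unique(gene_spectra$condition_id),
                    fill = list(module_count = 0, total_count = 0))
  if (any(out$total_count == 0)) {
    warn(paste0("MAG ", mag_id, " has zero spectra in some condition(s); ",
                "activity reported as 0 there"))
  }
  tibble(mag_id = mag_id, module_id = module_id,
         condition_id = out$condition_id,
         activity_fraction = ifelse(out$total_count > 0,
                                    out$module_count / out$total_count, 0))
}

#' Enzyme-level summary of AGCNs and spectral counts
#'
#' Aggregates KO-level metrics to the enzyme level: AGCNs of KOs with similar
#' functionality are summed (`sum_similar`), while the median AGCN is taken
#' where KOs represent individual subunits of one enzyme
#' (`median_subunits`). Spectral counts are always summed. KOs missing from a
#' matrix contribute zero.
#'
#' @param agcn An `agcn_profile` or long tibble (`ko_id`, column 2 = sample
#'   or condition key, `agcn`).
#' @param ko_spectra Long KO spectra (`ko_id`, `condition_id`, `count`).
#' @param groups Key-enzyme table from [read_key_enzymes()].
#' @return A tibble `enzyme_label`, `ad_category`, `condition_id`, `agcn`,
#'   `spectral_count`.
#' @export
enzyme_level_summary <- function(agcn, ko_spectra, groups) {
  bad <- setdiff(unique(groups$aggregation_mode),
                 c("sum_similar", "median_subunits"))
  if (length(bad) > 0) {
    abort(paste0("unknown aggregation mode: ", paste(bad, collapse = ", ")))
  }
  key_col <- intersect(c("condition_id", "sample_id"), names(agcn))[1]
  conditions <- unique(ko_spectra$condition_id)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    kos <- strsplit(groups$ko_ids[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(conditions, function(cond) {
      a <- agcn$agcn[agcn$ko_id %in% kos & agcn[[key_col]] == cond]
      a <- c(a, rep(0, length(kos) - length(a)))  # absent KOs count as 0
      s <- ko_spectra$count[ko_spectra$ko_id %in% kos &
                              ko_spectra$condition_id == cond]
      tibble(enzyme_label = groups$enzyme_label[i],
             ad_category = groups$ad_category[i],
             condition_id = cond,
             agcn = if (groups$aggregation_mode[i] == "sum_similar") sum(a)
                    else median(a),
             spectral_count = sum(s))
    })
  })
}

#' Keep enzymes above a spectral-count display threshold
#'
#' Keeps rows whose maximum spectral count over conditions is at least
#' `min_count` (boundary inclusive), mirroring the convention of showing only
#' enzymes with >= 10 spectral counts in at least one condition. Idempotent.
#'
#' @param enzyme_table Output of [enzyme_level_summary()] (or any tibble with
#'   `enzyme_label` and `spectral_count`).
#' @param min_count Inclusive threshold.
#' @return The filtered tibble.
#' @export
spectral_threshold_filter <- function(enzyme_table, min_count = 10) {
  if (nrow(enzyme_table) == 0) return(enzyme_table)
  enzyme_table %>%
    group_by(.data$enzyme_label) %>%
    filter(max(.data$spectral_count) >= min_count) %>%
    ungroup()
}

#' High-quality MAG filter
#'
#' Keeps MAGs above a completeness threshold, below a contamination
#' threshold, and above an abundance threshold in either the genomic or the
#' proteomic profile of any condition. All three comparisons are strict
#' inequalities ("above 50%", "below 10%", "above 0.5%").
#'
#' @param mags MAG quality table.
#' @param genomic,proteomic `mag_abundance` profiles covering every MAG in
#'   `mags` (an absent MAG is an error).
#' @param min_completeness,max_contamination,min_abundance Strict thresholds
#'   in percent.
#' @return The subset of `mags` passing all criteria; row order of the input
#'   does not affect membership.
#' @export
hq_mag_filter <- function(mags, genomic, proteomic, min_completeness = 50,
                          max_contamination = 10, min_abundance = 0.5) {
  for (profile in list(genomic, proteomic)) {
    missing_mag <- setdiff(mags$mag_id, profile$mag_id)
    if (length(missing_mag) > 0) {
      abort(paste0("MAG(s) missing from an abundance profile: ",
                   paste(head(missing_mag, 5), collapse = ", ")))
    }
  }
  both <- bind_rows(as_tibble(genomic), as_tibble(proteomic))
  max_ab <- both %>% group_by(.data$mag_id) %>%
    summarise(max_abundance = max(.data$abundance_pct), .groups = "drop")
  keep <- mags %>%
    inner_join(max_ab, by = "mag_id") %>%
    filter(.data$completeness_pct > min_completeness,
           .data$contamination_pct < max_contamination,
           .data$max_abundance > min_abundance)
  mags[mags$mag_id %in% keep$mag_id, ]
}

#' Three-way abundance category summary
#'
#' Partitions each abundance column into three categories: (1) unbinned
#' contigs plus low-quality MAGs (failing the completeness or contamination
#' criterion), (2) quality-passing MAGs at or below the abundance threshold in
#' both omics layers, and (3) quality-passing MAGs above it in at least one
#' layer. Every column sums to 100 because the categories partition the
#' community.
#'
#' @param mags MAG quality table.
#' @param quality_mags Character vector of MAG ids passing the
#'   completeness/contamination criteria (e.g.
#'   `hq_mag_filter(..., min_abundance = 0)` or a hand-built set).
#' @param genomic,proteomic `mag_abundance` profiles.
#' @param min_abundance Strict threshold (percent) splitting categories 2/3,
#'   evaluated as the maximum over both layers and all conditions.
#' @return A tibble `category`, `layer`, `condition_id`, `abundance_pct`;
#'   per layer and condition the three categories sum to 100.
#' @export
summarize_categories <- function(mags, quality_mags, genomic, proteomic,
                                 min_abundance = 0.5) {
  both <- bind_rows(
    mutate(as_tibble(genomic), layer = "genomic"),
    mutate(as_tibble(proteomic), layer = "proteomic"))
  max_ab <- both %>% group_by(.data$mag_id) %>%
    summarise(max_abundance = max(.data$abundance_pct), .groups = "drop")
  high <- max_ab$mag_id[max_ab$max_abundance > min_abundance]
  both %>%
    mutate(category = case_when(
      !.data$mag_id %in% quality_mags ~ "unbinned_and_low_quality",
      .data$mag_id %in% high ~ "hq_above_threshold",
      TRUE ~ "hq_below_threshold")) %>%
    group_by(.data$category, .data$layer, .data$condition_id) %>%
    summarise(abundance_pct = sum(.data$abundance_pct), .groups = "drop") %>%
    tidyr::complete(category = c("unbinned_and_low_quality",
                                 "hq_below_threshold", "hq_above_threshold"),
                    layer = unique(both$layer),
                    condition_id = unique(both$condition_id),
                    fill = list(abundance_pct = 0)) %>%
    arrange(.data$layer, .data$condition_id, .data$category)
}

#' Key-pathway presence matrix for a MAG
#'
#' Marks an anaerobic-digestion category (hydrolysis, acidogenesis,
#' acetogenesis, methanogenesis sub-pathway) as present in a condition when
#' at least one member KO of at least one key-enzyme group in that category
#' has a positive spectral count among the MAG's genes.
#'
#' @inheritParams module_activity
#' @param groups Key-enzyme table from [read_key_enzymes()].
#' @return A tibble `mag_id`, `ad_category`, `condition_id`, `present`
#'   (logical).
#' @export
key_pathway_presence <- function(mag_id, groups, gene_spectra, catalog) {
  genes <- catalog[catalog$mag_id == mag_id, c("gene_id", "ko_id")]
  mag_spectra <- gene_spectra %>%
    inner_join(genes, by = "gene_id") %>%
    filter(!is.na(.data$ko_id), .data$count > 0)
  categories <- unique(groups$ad_category)
  conditions <- unique(gene_spectra$condition_id)
  purrr::map_dfr(categories, function(cat) {
    kos <- unique(unlist(strsplit(
      groups$ko_ids[groups$ad_category == cat], ",", fixed = TRUE)))
    purrr::map_dfr(conditions, function(cond) {
      tibble(mag_id = mag_id, ad_category = cat, condition_id = cond,
             present = any(mag_spectra$ko_id %in% kos &
                             mag_spectra$condition_id == cond))
    })
  })
}

#' Pearson correlations between taxa and process parameters
#'
#' Standard Pearson correlation of each taxon's per-sample abundances with
#' each process or chemical parameter. A constant vector on either side
#' yields an undefined correlation, reported as `NA` with a warning — never
#' as 0.
#'
#' @param taxa Long tibble `taxon_id`, `sample_id`, `abundance`.
#' @param metadata Long tibble `sample_id`, `parameter`, `value`.
#' @return A tibble `taxon_id`, `parameter`, `r`.
#' @export
metadata_correlations <- function(taxa, metadata) {
  shared <- intersect(unique(taxa$sample_id), unique(metadata$sample_id))
  if (length(shared) < 3) {
    abort("need at least 3 paired samples for correlation")
  }
  pairs <- tidyr::expand_grid(taxon_id = unique(taxa$taxon_id),
                              parameter = unique(metadata$parameter))
  warned <- FALSE
  r <- purrr::map2_dbl(pairs$taxon_id, pairs$parameter, function(t, p) {
    x <- taxa$abundance[taxa$taxon_id == t][match(
      shared, taxa$sample_id[taxa$taxon_id == t])]
    y <- metadata$value[metadata$parameter == p][match(
      shared, metadata$sample_id[metadata$parameter == p])]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) abort(paste0("fewer than 3 paired observations for ",
                                  t, " vs ", p))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warned <<- TRUE
      return(NA_real_)
    }
    cor(x[ok], y[ok])
  })
  if (warned) warn("constant vector(s) encountered; correlation reported as NA")
  dplyr::bind_cols(pairs, tibble(r = r))
}
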