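#' Generate a synthetic community with known ground truth
#'
#' Builds a gene catalog and MAG quality table with the statistical structure
#' the quantification pipeline assumes, plus the ground truth needed to test
#' it: true per-condition MAG relative abundances (summing to 1, including the
#' unbinned fraction) and per-MAG activity multipliers.
#'
#' Each MAG receives `genes_per_mag` genes with log-normal lengths. Ten
#' universal single-copy KOs (the packaged USiCG set) are planted at exactly
#' one copy per complete genome, plus any `planted_multicopy` KOs at their
#' stated copy number; remaining genes draw annotations from a KO pool. A
#' random subset of each MAG's genes is withheld to realise its simulated
#' completeness, so incomplete MAGs genuinely miss genes. Unbinned genes carry
#' `unbinned_fraction` of the community abundance.
#'
#' @param spec A [community_spec()].
#' @return A list of class `mag_community` with elements `catalog` (gene
#'   catalog tibble), `mags` (MAG quality tibble), `ground_truth` (tibble
#'   `mag_id`, `condition_id`, `true_abundance`), `activity` (tibble `mag_id`,
#'   `activity_multiplier`) and `spec`.
#' @export
#' @examples
#' comm <- generate_community(community_spec(n_mags = 3, seed = 7))
#' comm$ground_truth
generate_community <- function(spec) {
  validate_community_spec(spec)
  set.seed(spec$seed)

  mag_ids <- sprintf("MAG%03d", seq_len(spec$n_mags))
  conditions <- sprintf("D%d", seq_len(spec$n_conditions))
  usicg <- default_usicg_kos()
  planted <- spec$planted_multicopy
  n_planted <- length(usicg) + sum(planted)
  if (n_planted > spec$genes_per_mag) {
    abort("genes_per_mag too small to hold the planted single/multi-copy KOs")
  }
  ko_pool <- sprintf("K%05d", seq_len(spec$ko_pool_size) + 10000L)

  # Per-MAG quality metadata; lineages cycle through a few GTDB-style strings
  # (one archaeal) so taxonomy-aware consumers have something realistic.
  lineages <- c(
    "d__Bacteria;p__Firmicutes;c__Clostridia;o__Caldicoprobacterales",
    "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales",
    "d__Bacteria;p__Firmicutes;c__Limnochordia;o__Limnochordales",
    "d__Archaea;p__Methanobacteriota;c__Methanobacteria;o__Methanobacteriales")
  completeness <- runif(spec$n_mags, spec$completeness_range[1],
                        spec$completeness_range[2])
  contamination <- runif(spec$n_mags, spec$contamination_range[1],
                         spec$contamination_range[2])

  make_mag_genes <- function(i) {
    mag <- mag_ids[i]
    n <- spec$genes_per_mag
    lengths <- pmax(90, round(rlnorm(n, spec$gene_length_meanlog,
                                     spec$gene_length_sdlog)))
    # marker genes (single-copy and planted multi-copy KOs) get the median
    # length, mirroring the conserved lengths of ribosomal proteins and
    # keeping the copy-number interpretation of length-normalized counts
    lengths[seq_len(n_planted)] <- round(exp(spec$gene_length_meanlog))
    ko <- rep(NA_character_, n)
    slot <- 1L
    for (k in usicg) {
      ko[slot] <- k
      slot <- slot + 1L
    }
    for (k in names(planted)) {
      ko[seq(slot, slot + planted[[k]] - 1L)] <- k
      slot <- slot + planted[[k]]
    }
    rest <- if (slot <= n) slot:n else integer(0)
    annotated <- rest[runif(length(rest)) < spec$annotation_rate]
    ko[annotated] <- sample(ko_pool, length(annotated), replace = TRUE)
    has_ko <- !is.na(ko)
    # marker genes (USiCG/planted) are conserved and reliably annotated;
    # only ordinary annotations can fall below the filter thresholds
    poor <- has_ko & runif(n) < spec$poor_annotation_fraction
    poor[seq_len(n_planted)] <- FALSE
    identity <- ifelse(has_ko,
                       ifelse(poor, runif(n, 5, 29.9), runif(n, 35, 100)),
                       NA_real_)
    evalue <- ifelse(has_ko,
                     ifelse(poor, 10^runif(n, -9, -2), 10^runif(n, -80, -11)),
                     NA_real_)
    # keep a deterministic-count random subset to realise completeness
    n_keep <- max(1L, round(n * completeness[i] / 100))
    keep <- sort(sample.int(n, n_keep))
    tibble(
      gene_id = sprintf("%s_g%04d", mag, seq_len(n)),
      contig_id = sprintf("%s_c%03d", mag, ((seq_len(n) - 1L) %/% 10L) + 1L),
      mag_id = mag,
      length_bp = lengths,
      ko_id = ko,
      ec_ids = NA_character_,
      annot_identity_pct = identity,
      annot_evalue = evalue
    )[keep, ]
  }
  catalog <- dplyr::bind_rows(lapply(seq_len(spec$n_mags), make_mag_genes))

  if (spec$unbinned_fraction > 0 && spec$n_unbinned_genes > 0) {
    n <- spec$n_unbinned_genes
    annotated <- runif(n) < spec$annotation_rate
    ko <- ifelse(annotated, sample(ko_pool, n, replace = TRUE), NA_character_)
    unbinned <- tibble(
      gene_id = sprintf("UNB_g%04d", seq_len(n)),
      contig_id = sprintf("UNB_c%03d", ((seq_len(n) - 1L) %/% 10L) + 1L),
      mag_id = UNBINNED,
      length_bp = pmax(90, round(rlnorm(n, spec$gene_length_meanlog,
                                        spec$gene_length_sdlog))),
      ko_id = ko,
      ec_ids = NA_character_,
      annot_identity_pct = ifelse(annotated, runif(n, 35, 100), NA_real_),
      annot_evalue = ifelse(annotated, 10^runif(n, -80, -11), NA_real_))
    catalog <- dplyr::bind_rows(catalog, unbinned)
  }

  mags <- tibble(
    mag_id = mag_ids,
    completeness_pct = completeness,
    contamination_pct = contamination,
    taxonomy = rep_len(lineages, spec$n_mags),
    genome_size_bp = as.numeric(
      vapply(mag_ids, function(m) {
        sum(catalog$length_bp[catalog$mag_id == m])
      }, numeric(1))))

  # Ground truth: log-normal weights per condition, unbinned share fixed.
  gt <- purrr::map_dfr(conditions, function(cond) {
    w <- rlnorm(spec$n_mags, spec$abundance_lognormal_mu,
                spec$abundance_lognormal_sigma)
    ab <- w / sum(w) * (1 - spec$unbinned_fraction)
    out <- tibble(mag_id = mag_ids, condition_id = cond, true_abundance = ab)
    if (spec$unbinned_fraction > 0) {
      out <- dplyr::bind_rows(out, tibble(
        mag_id = UNBINNED, condition_id = cond,
        true_abundance = spec$unbinned_fraction))
    }
    out
  })

  log_range <- log(spec$activity_multiplier_range)
  activity <- tibble(
    mag_id = c(mag_ids, if (spec$unbinned_fraction > 0) UNBINNED),
    activity_multiplier = exp(runif(spec$n_mags + (spec$unbinned_fraction > 0),
                                    log_range[1], log_range[2])))

  structure(list(catalog = catalog, mags = mags, ground_truth = gt,
                 activity = activity, spec = spec),
            class = "mag_community")
}

#' @export
print.mag_community <- function(x, ...) {
  cat("<mag_community>\n")
  cat(sprintf("  %d MAGs, %d genes (%d unbinned), %d conditions\n",
              nrow(x$mags), nrow(x$catalog),
              sum(x$catalog$mag_id == UNBINNED),
              length(unique(x$ground_truth$condition_id))))
  invisible(x)
}

sample_grid <- function(spec) {
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      condition_id = sprintf("D%d", seq_len(spec$n_conditions)),
                      stringsAsFactors = FALSE)
  tibble(sample_id = sprintf("%s_R%d", grid$condition_id, grid$replicate),
         condition_id = grid$condition_id,
         replicate = as.integer(grid$replicate))
}

#' Simulate a gene-by-sample read-count table
#'
#' The expected mapped count of a gene is proportional to the true abundance
#' of its MAG in the sample's condition times the gene length; observed counts
#' add Poisson noise. Each sample also receives an unmapped-read total drawn
#' so that the unmapped fraction lies in the spec's range (the pipeline only
#' ever consumes the count — unmapped reads are excluded from abundance
#' estimation anyway).
#'
#' @param community A `mag_community` from [generate_community()].
#' @return A list with `counts` (long tibble `gene_id`, `sample_id`, `count`)
#'   and `samples` (tibble `sample_id`, `condition_id`, `replicate`,
#'   `unmapped_reads`).
#' @export
simulate_read_counts <- function(community) {
  spec <- community$spec
  set.seed(spec$seed + 1L)
  samples <- sample_grid(spec)
  abundance <- community$ground_truth

  counts <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    cond <- samples$condition_id[i]
    ab <- abundance[abundance$condition_id == cond, ]
    cat <- dplyr::left_join(community$catalog[, c("gene_id", "mag_id",
                                                  "length_bp")],
                            ab[, c("mag_id", "true_abundance")],
                            by = "mag_id")
    w <- dplyr::coalesce(cat$true_abundance, 0) * cat$length_bp
    mu <- spec$mean_reads_per_sample * w / sum(w)
    tibble(gene_id = cat$gene_id, sample_id = samples$sample_id[i],
           count = rpois(length(mu), mu))
  })

  mapped_totals <- counts %>% group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  u <- runif(nrow(samples), spec$unmapped_fraction_range[1],
             spec$unmapped_fraction_range[2])
  samples$unmapped_reads <- round(
    mapped_totals$total[match(samples$sample_id, mapped_totals$sample_id)] *
      u / (1 - u))
  list(counts = counts, samples = samples)
}

#' Simulate a metaprotein spectral-count table
#'
#' The expected spectral count of a gene is proportional to the true
#' abundance of its MAG times the MAG's activity multiplier, shared equally
#' among the MAG's genes; observed counts are negative-binomially distributed
#' with the spec's dispersion (Poisson when dispersion is 0). One metaprotein
#' is emitted per gene with positive total count; a configurable fraction of
#' metaproteins is assigned non-uniquely (a two-gene set) to exercise the
#' uniqueness-exclusion rule.
#'
#' @inheritParams simulate_read_counts
#' @return A long metaprotein tibble with columns `metaprotein_id`,
#'   `peptide_set_id`, `gene_ids`, `n_genes`, `sample_id`, `count`
#'   (replicates are samples).
#' @export
simulate_spectral_counts <- function(community) {
  spec <- community$spec
  set.seed(spec$seed + 2L)
  samples <- sample_grid(spec)

  cat <- dplyr::left_join(
    community$catalog[, c("gene_id", "mag_id")],
    community$activity, by = "mag_id")
  genes_per <- cat %>% group_by(.data$mag_id) %>%
    summarise(n_genes_mag = n(), .groups = "drop")
  cat <- dplyr::left_join(cat, genes_per, by = "mag_id")

  spectra <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    cond <- samples$condition_id[i]
    ab <- community$ground_truth[community$ground_truth$condition_id == cond, ]
    w <- dplyr::coalesce(
      ab$true_abundance[match(cat$mag_id, ab$mag_id)], 0) *
      cat$activity_multiplier / cat$n_genes_mag
    mu <- spec$mean_spectra_per_sample * w / sum(w)
    counts <- if (spec$spectral_dispersion == 0) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), size = 1 / spec$spectral_dispersion, mu = mu)
    }
    tibble(gene_id = cat$gene_id, sample_id = samples$sample_id[i],
           count = counts)
  })

  expressed <- spectra %>% group_by(.data$gene_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    filter(.data$total > 0) %>% pull(.data$gene_id)
  spectra <- spectra[spectra$gene_id %in% expressed, ]

  gene_sets <- setNames(as.list(expressed), expressed)
  if (spec$nonunique_fraction > 0 && length(expressed) > 1) {
    n_multi <- round(spec$nonunique_fraction * length(expressed))
    if (n_multi > 0) {
      multi <- sample(expressed, n_multi)
      partners <- sample(expressed, n_multi, replace = TRUE)
      for (j in seq_len(n_multi)) {
        gene_sets[[multi[j]]] <- sort(unique(c(multi[j], partners[j])))
      }
    }
  }
  ids <- tibble(
    gene_id = expressed,
    metaprotein_id = sprintf("MP%05d", seq_along(expressed)),
    peptide_set_id = sprintf("PS%05d", seq_along(expressed)),
    gene_ids = vapply(gene_sets[expressed], paste, "", collapse = ","),
    n_genes = lengths(gene_sets[expressed]))
  dplyr::inner_join(ids, spectra, by = "gene_id") %>%
    select("metaprotein_id", "peptide_set_id", "gene_ids", "n_genes",
           "sample_id", "count")
}

#' Write a synthetic community and its count tables as canonical TSVs
#'
#' Writes `gene_catalog.tsv`, `mag_quality.tsv`, `read_counts.tsv`,
#' `unmapped.tsv`, `spectral_counts.tsv` and `ground_truth.tsv` into a
#' directory, in the dialects the package readers expect.
#'
#' @inheritParams simulate_read_counts
#' @param reads Result of [simulate_read_counts()].
#' @param spectra Result of [simulate_spectral_counts()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, reads, spectra, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(community$catalog, file.path(dir, "gene_catalog.tsv"),
                   na = "NA")
  readr::write_tsv(community$mags, file.path(dir, "mag_quality.tsv"),
                   na = "NA")
  readr::write_tsv(long_to_wide(reads$counts, "gene_id"),
                   file.path(dir, "read_counts.tsv"), na = "NA")
  readr::write_tsv(reads$samples, file.path(dir, "unmapped.tsv"), na = "NA")
  wide_sp <- tidyr::pivot_wider(
    spectra[, c("metaprotein_id", "peptide_set_id", "gene_ids", "sample_id",
                "count")],
    names_from = "sample_id", values_from = "count", values_fill = 0)
  readr::write_tsv(wide_sp, file.path(dir, "spectral_counts.tsv"), na = "NA")
  readr::write_tsv(community$ground_truth, file.path(dir, "ground_truth.tsv"),
                   na = "NA")
  invisible(dir)
}
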