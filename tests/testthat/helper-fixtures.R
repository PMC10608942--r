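# Small in-code fixtures shared across tests.

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "magquant")
}

toy_usicg <- c("K00001", "K00002")

# Minimal two-MAG catalog for arithmetic checks.
tiny_catalog <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    contig_id = c("c1", "c2", "c3"),
    mag_id = c("MAG1", "MAG2", "UNBINNED"),
    length_bp = c(1000, 1000, 1000),
    ko_id = c("K1", "K2", NA),
    ec_ids = NA_character_,
    annot_identity_pct = c(90, 90, NA),
    annot_evalue = c(1e-30, 1e-30, NA))
}

tiny_mags <- function(completeness = c(100, 100)) {
  tibble::tibble(
    mag_id = c("MAG1", "MAG2"),
    completeness_pct = completeness,
    contamination_pct = c(1, 1),
    taxonomy = "d__Bacteria")
}

one_sample <- function() {
  tibble::tibble(sample_id = "S1", condition_id = "D1", replicate = 1L,
                 unmapped_reads = 0)
}

long_counts <- function(named, sample_id = "S1") {
  tibble::tibble(gene_id = names(named), sample_id = sample_id,
                 count = unname(named))
}

# Random gene-level spectra fixture used by conservation property tests.
random_fixture <- function(seed) {
  set.seed(seed)
  n_mags <- sample(2:5, 1)
  mags <- tibble::tibble(
    mag_id = sprintf("M%02d", seq_len(n_mags)),
    completeness_pct = runif(n_mags, 40, 100),
    contamination_pct = runif(n_mags, 0, 15),
    taxonomy = "d__Bacteria")
  genes_per <- 4
  catalog <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(genes_per * (n_mags + 1))),
    contig_id = "c1",
    mag_id = rep(c(mags$mag_id, "UNBINNED"), each = genes_per),
    length_bp = sample(300:2000, genes_per * (n_mags + 1), replace = TRUE),
    ko_id = NA_character_, ec_ids = NA_character_,
    annot_identity_pct = NA_real_, annot_evalue = NA_real_)
  samples <- tibble::tibble(
    sample_id = c("D1_R1", "D1_R2", "D2_R1", "D2_R2"),
    condition_id = c("D1", "D1", "D2", "D2"),
    replicate = c(1L, 2L, 1L, 2L),
    unmapped_reads = sample(50:100, 4))
  grid <- tidyr::expand_grid(gene_id = catalog$gene_id,
                             sample_id = samples$sample_id)
  counts <- dplyr::mutate(grid, count = rpois(nrow(grid), 40) + 1)
  spectra <- dplyr::mutate(grid, count = rpois(nrow(grid), 15) + 1)
  list(catalog = catalog, mags = mags, samples = samples,
       counts = counts, spectra = spectra)
}
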