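ko_fixture <- function(values) {
  tibble::tibble(ko_id = rep(paste0("K", seq_along(values[[1]])),
                             times = length(values)),
                 condition_id = rep(names(values), each = length(values[[1]])),
                 count = unlist(values, use.names = FALSE))
}

test_that("log2 fold change matches its closed form and is antisymmetric", {
  m <- ko_fixture(list(D1 = c(6, 4, 0), D2 = c(0, 4, 6)))
  fc <- log2_fold_change(m, c("D1", "D2"), offset_s = 2)
  expect_equal(fc$log2fc[fc$ko_id == "K1"], 2)       # log2(8/2)
  expect_equal(fc$log2fc[fc$ko_id == "K2"], 0)       # equality -> 0
  expect_equal(fc$log2fc[fc$ko_id == "K3"], -2)

  # antisymmetry over random matrices
  set.seed(99)
  for (i in 1:5) {
    rand <- ko_fixture(list(D1 = rpois(20, 5), D2 = rpois(20, 5)))
    s <- runif(1, 0.5, 5)
    fwd <- log2_fold_change(rand, c("D1", "D2"), s)
    rev <- log2_fold_change(rand, c("D2", "D1"), s)
    expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  }

  expect_error(log2_fold_change(m, c("D1", "D2"), offset_s = 0), "positive")
  expect_error(log2_fold_change(m, c("D1", "D9")), "D9")
  expect_equal(formals(log2_fold_change)$offset_s, 2)  # default pseudocount
})

test_that("offset derivation: interpolated 30th percentile, half-up, floor 1", {
  counts <- c(0, 0, 1, 2, 3, 4, 5, 6, 7, 10)
  m <- tibble::tibble(ko_id = paste0("K", 1:10), condition_id = "D1",
                      count = counts)
  # brute-force linear-interpolation percentile: h = (n-1)p + 1 = 3.7
  expect_equal(unname(quantile(counts, 0.3, type = 7)), 1.7)
  expect_equal(derive_offset(m), 2)

  all5 <- tibble::tibble(ko_id = paste0("K", 1:4), condition_id = "D1",
                         count = rep(5, 4))
  expect_equal(derive_offset(all5), 5)

  zeros <- tibble::tibble(ko_id = paste0("K", 1:10), condition_id = "D1",
                          count = c(rep(0, 9), 100))
  expect_warning(s <- derive_offset(zeros), "clamping")
  expect_equal(s, 1)

  nz <- derive_offset(zeros, universe = "nonzero")
  expect_equal(nz, 100)
})

test_that("max pairwise fold change equals the exhaustive-pair maximum", {
  expect_equal(max_pairwise_fold_change(c(4, 4, 4)), 0)
  expect_equal(max_pairwise_fold_change(c(0, 0, 6), offset_s = 2), 2)
  set.seed(7)
  for (i in 1:20) {
    v <- rpois(3, 20)
    s <- runif(1, 0.5, 4)
    brute <- max(abs(c(log2((v[1] + s) / (v[2] + s)),
                       log2((v[1] + s) / (v[3] + s)),
                       log2((v[2] + s) / (v[3] + s)))))
    expect_equal(max_pairwise_fold_change(v, s), brute, tolerance = 1e-12)
  }
})

four_block_modules <- function() {
  tibble::tibble(
    module_id = "M1",
    definition = "K1 K2,K3 K4+K5 K6",
    blocks = list(parse_module_expression("K1 K2,K3 K4+K5 K6")))
}

test_that("module completeness counts satisfied blocks; retention at n-1", {
  mods <- four_block_modules()
  all4 <- module_completeness(c("K1", "K3", "K4", "K5", "K6"), mods)
  expect_equal(all4$completeness_pct, 100)
  expect_true(all4$retained)

  three <- module_completeness(c("K1", "K3", "K6"), mods)  # complex missing
  expect_equal(three$completeness_pct, 75)
  expect_true(three$retained)     # "missing one block" is retained

  two <- module_completeness(c("K1", "K4", "K5"), mods)
  expect_equal(two$completeness_pct, 50)
  expect_false(two$retained)

  # a complex requires all subunits
  partial <- module_completeness(c("K1", "K2", "K4", "K6"), mods)
  expect_equal(partial$blocks_satisfied, 3)
})

test_that("module completeness is monotone under KO addition", {
  mods <- four_block_modules()
  pool <- c("K1", "K2", "K3", "K4", "K5", "K6", "K7")
  set.seed(11)
  for (i in 1:25) {
    base <- sample(pool, sample(0:5, 1))
    extra <- unique(c(base, sample(pool, sample(1:3, 1))))
    expect_gte(module_completeness(extra, mods)$blocks_satisfied,
               module_completeness(base, mods)$blocks_satisfied)
  }
})

test_that("module activity is the module share of a MAG's spectra", {
  catalog <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), contig_id = "c", mag_id = "M1",
    length_bp = 900, ko_id = c("K1", "K6", "K9"), ec_ids = NA,
    annot_identity_pct = 90, annot_evalue = 1e-30)
  mods <- four_block_modules()
  spectra <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            condition_id = "D1",
                            count = c(3.8, 2, 94.2))
  act <- module_activity("M1", "M1", mods, spectra, catalog)
  expect_equal(act$activity_fraction, 0.058)  # (3.8 + 2) / 100

  none <- dplyr::mutate(spectra, count = c(0, 0, 50))
  expect_equal(module_activity("M1", "M1", mods, none, catalog)
               $activity_fraction, 0)
  all_in <- dplyr::mutate(spectra, count = c(5, 5, 0))
  expect_equal(module_activity("M1", "M1", mods, all_in, catalog)
               $activity_fraction, 1)
  silent_mag <- dplyr::mutate(spectra, count = 0)
  expect_warning(
    act0 <- module_activity("M1", "M1", mods, silent_mag, catalog),
    "zero spectra")
  expect_equal(act0$activity_fraction, 0)
})

test_that("enzyme aggregation: sum for similar KOs, median for subunits", {
  agcn <- tibble::tibble(ko_id = rep(c("K1", "K2"), 2),
                         condition_id = rep(c("D1", "D2"), each = 2),
                         agcn = c(1, 3, 2, 2))
  spectra <- tibble::tibble(ko_id = rep(c("K1", "K2"), 2),
                            condition_id = rep(c("D1", "D2"), each = 2),
                            count = c(5, 7, 1, 1))
  groups <- tibble::tibble(
    enzyme_label = c("similar", "subunits"),
    ko_ids = "K1,K2",
    aggregation_mode = c("sum_similar", "median_subunits"),
    ad_category = "acidogenesis")
  out <- enzyme_level_summary(agcn, spectra, groups)
  d1 <- out[out$condition_id == "D1", ]
  expect_equal(d1$agcn[d1$enzyme_label == "similar"], 4)
  expect_equal(d1$agcn[d1$enzyme_label == "subunits"], 2)
  expect_equal(d1$spectral_count, c(12, 12))  # spectra always summed

  bad <- dplyr::mutate(groups, aggregation_mode = "average")
  expect_error(enzyme_level_summary(agcn, spectra, bad), "aggregation")
})

test_that("spectral display threshold keeps rows at >= 10, idempotently", {
  tbl <- tibble::tibble(
    enzyme_label = rep(c("a", "b", "c"), each = 3),
    ad_category = "hydrolysis",
    condition_id = rep(c("D1", "D2", "D3"), 3),
    agcn = 1,
    spectral_count = c(9, 9, 9, 0, 10, 0, 50, 2, 1))
  out <- spectral_threshold_filter(tbl)
  expect_setequal(unique(out$enzyme_label), c("b", "c"))  # (0,10,0) kept
  expect_identical(spectral_threshold_filter(out), out)
  empty <- tbl[0, ]
  expect_identical(spectral_threshold_filter(empty), empty)
})

hq_profiles <- function(mags, genomic_vals, proteomic_vals) {
  mk <- function(vals, layer) {
    df <- tibble::tibble(mag_id = rep(mags$mag_id, each = length(vals[[1]])),
                         condition_id = rep(paste0("D", seq_along(vals[[1]])),
                                            nrow(mags)),
                         abundance_pct = unlist(vals, use.names = FALSE))
    structure(df, class = c("mag_abundance", class(df)), layer = layer)
  }
  list(genomic = mk(genomic_vals, "genomic"),
       proteomic = mk(proteomic_vals, "proteomic"))
}

test_that("HQ MAG filter applies strict thresholds on quality and abundance", {
  mags <- tibble::tibble(
    mag_id = c("Mexact", "Mgood", "Mlow"),
    completeness_pct = c(50, 83, 90),
    contamination_pct = c(5, 3, 9),
    taxonomy = "d__Bacteria")
  profs <- hq_profiles(
    mags,
    genomic_vals = list(Mexact = c(5, 5), Mgood = c(0.3, 0.2),
                        Mlow = c(0.4, 0.4)),
    proteomic_vals = list(Mexact = c(5, 5), Mgood = c(2.65, 0.1),
                          Mlow = c(0.4, 0.4)))
  kept <- hq_mag_filter(mags, profs$genomic, profs$proteomic)
  # completeness exactly 50 excluded (strict), proteomic 2.65% rescues Mgood,
  # 0.4% in both layers excludes Mlow
  expect_setequal(kept$mag_id, "Mgood")

  # row order of inputs does not change membership
  kept2 <- hq_mag_filter(mags[c(3, 1, 2), ], profs$genomic, profs$proteomic)
  expect_setequal(kept2$mag_id, kept$mag_id)

  expect_error(hq_mag_filter(
    dplyr::bind_rows(mags, tibble::tibble(mag_id = "Mmissing",
                                          completeness_pct = 90,
                                          contamination_pct = 1,
                                          taxonomy = "x")),
    profs$genomic, profs$proteomic), "Mmissing")
})

test_that("category summary partitions every column into 100%", {
  mags <- tibble::tibble(mag_id = c("M1", "M2", "M3"),
                         completeness_pct = c(90, 90, 30),
                         contamination_pct = c(1, 1, 20),
                         taxonomy = "t")
  profs <- hq_profiles(
    mags,
    genomic_vals = list(M1 = c(40, 50), M2 = c(0.3, 0.2), M3 = c(30, 20)),
    proteomic_vals = list(M1 = c(60, 70), M2 = c(0.4, 0.3), M3 = c(10, 5)))
  # add an UNBINNED row to both layers
  add_unb <- function(p, vals) {
    df <- dplyr::bind_rows(
      tibble::as_tibble(p),
      tibble::tibble(mag_id = "UNBINNED", condition_id = c("D1", "D2"),
                     abundance_pct = vals))
    structure(df, class = class(p), layer = attr(p, "layer"))
  }
  genomic <- add_unb(profs$genomic, c(29.7, 29.8))
  proteomic <- add_unb(profs$proteomic, c(29.6, 24.7))
  out <- summarize_categories(mags, quality_mags = c("M1", "M2"),
                              genomic, proteomic)
  sums <- out %>% dplyr::group_by(layer, condition_id) %>%
    dplyr::summarise(s = sum(abundance_pct), .groups = "drop")
  expect_equal(sums$s, rep(100, 4), tolerance = 0.01)
  d1g <- out[out$layer == "genomic" & out$condition_id == "D1", ]
  expect_equal(
    d1g$abundance_pct[d1g$category == "unbinned_and_low_quality"],
    29.7 + 30)  # UNBINNED + low-quality M3
  expect_equal(d1g$abundance_pct[d1g$category == "hq_below_threshold"], 0.3)
  expect_equal(d1g$abundance_pct[d1g$category == "hq_above_threshold"], 40)

  # all MAGs HQ and above threshold, no unbinned -> (0, 0, 100)
  simple <- hq_profiles(mags[1:2, ],
                        genomic_vals = list(M1 = c(60), M2 = c(40)),
                        proteomic_vals = list(M1 = c(55), M2 = c(45)))
  out2 <- summarize_categories(mags[1:2, ], c("M1", "M2"),
                               simple$genomic, simple$proteomic)
  g <- out2[out2$layer == "genomic", ]
  expect_equal(g$abundance_pct[g$category == "hq_above_threshold"], 100)
  expect_equal(sum(g$abundance_pct), 100)
})

test_that("key-pathway presence marks categories with any expressed KO", {
  catalog <- tibble::tibble(
    gene_id = c("g1", "g2"), contig_id = "c", mag_id = "M1",
    length_bp = 900, ko_id = c("K00399", "K01689"), ec_ids = NA,
    annot_identity_pct = 90, annot_evalue = 1e-30)
  groups <- read_key_enzymes(
    system.file("extdata", "key_enzymes.tsv", package = "magquant"))
  spectra <- tibble::tibble(gene_id = c("g1", "g2", "g1", "g2"),
                            condition_id = rep(c("D1", "D2"), each = 2),
                            count = c(5, 0, 0, 0))
  pres <- key_pathway_presence("M1", groups, spectra, catalog)
  expect_true(pres$present[
    pres$ad_category == "methanogenesis_hydrogenotrophic" &
      pres$condition_id == "D1"])
  expect_false(pres$present[pres$ad_category == "acidogenesis" &
                              pres$condition_id == "D1"])
  expect_false(any(pres$present[pres$condition_id == "D2"]))

  # exhaustive scan oracle
  for (i in seq_len(nrow(pres))) {
    kos <- unique(unlist(strsplit(
      groups$ko_ids[groups$ad_category == pres$ad_category[i]], ",")))
    genes <- catalog$gene_id[catalog$ko_id %in% kos]
    manual <- any(spectra$count[spectra$gene_id %in% genes &
                                  spectra$condition_id ==
                                    pres$condition_id[i]] > 0)
    expect_equal(pres$present[i], manual)
  }
})

test_that("metadata correlations: exact linear cases and degenerate vectors", {
  taxa <- tibble::tibble(
    taxon_id = rep(c("T1", "T2"), each = 3),
    sample_id = rep(c("S1", "S2", "S3"), 2),
    abundance = c(1, 2, 3, 6, 4, 2))
  metadata <- tibble::tibble(
    sample_id = rep(c("S1", "S2", "S3"), 2),
    parameter = rep(c("temperature", "flat"), each = 3),
    value = c(40, 50, 60, 5, 5, 5))
  expect_warning(out <- metadata_correlations(taxa, metadata), "constant")
  expect_equal(out$r[out$taxon_id == "T1" & out$parameter == "temperature"],
               1)
  expect_equal(out$r[out$taxon_id == "T2" & out$parameter == "temperature"],
               -1)
  expect_true(all(is.na(out$r[out$parameter == "flat"])))
  expect_error(metadata_correlations(taxa[1:2, ], metadata), "at least 3")
})
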