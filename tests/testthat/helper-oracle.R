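# Independent brute-force oracle for the packaged toy fixture.
#
# Everything here is computed with base R loops and matrices straight from
# the TSVs, deliberately sharing no code with the package, so that equality
# between the two routes is a meaningful check.

oracle_read <- function(file) {
  utils::read.delim(toy_path(file), sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Annotation filter: keep if identity >= 30 and evalue <= 1e-10 (missing
# metrics keep the annotation).
oracle_filtered_catalog <- function() {
  cat <- oracle_read("gene_catalog.tsv")
  for (i in seq_len(nrow(cat))) {
    id_bad <- !is.na(cat$annot_identity_pct[i]) && cat$annot_identity_pct[i] < 30
    ev_bad <- !is.na(cat$annot_evalue[i]) && cat$annot_evalue[i] > 1e-10
    if (id_bad || ev_bad) cat$ko_id[i] <- NA
  }
  cat
}

oracle_counts_matrix <- function() {
  rc <- oracle_read("read_counts.tsv")
  m <- as.matrix(rc[, -1])
  rownames(m) <- rc$gene_id
  m
}

oracle_samples <- function() oracle_read("unmapped.tsv")

# Genomic MAG abundance: per-sample percent shares of mapped reads by MAG,
# median over replicates per condition, then renormalize columns to 100.
oracle_genomic_profile <- function() {
  cat <- oracle_read("gene_catalog.tsv")
  m <- oracle_counts_matrix()
  samples <- oracle_samples()
  mags <- sort(unique(cat$mag_id))
  per_sample <- matrix(0, length(mags), ncol(m),
                       dimnames = list(mags, colnames(m)))
  for (s in colnames(m)) {
    for (g in rownames(m)) {
      mag <- cat$mag_id[cat$gene_id == g]
      per_sample[mag, s] <- per_sample[mag, s] + m[g, s]
    }
    per_sample[, s] <- 100 * per_sample[, s] / sum(per_sample[, s])
  }
  conds <- sort(unique(samples$condition_id))
  out <- matrix(0, length(mags), length(conds),
                dimnames = list(mags, conds))
  for (cond in conds) {
    reps <- samples$sample_id[samples$condition_id == cond]
    for (mag in mags) out[mag, cond] <- median(per_sample[mag, reps])
    out[, cond] <- 100 * out[, cond] / sum(out[, cond])
  }
  out
}

# KO-level read counts after annotation filtering.
oracle_ko_counts <- function() {
  cat <- oracle_filtered_catalog()
  m <- oracle_counts_matrix()
  kos <- sort(unique(cat$ko_id[!is.na(cat$ko_id)]))
  out <- matrix(0, length(kos), ncol(m), dimnames = list(kos, colnames(m)))
  for (g in rownames(m)) {
    ko <- cat$ko_id[cat$gene_id == g]
    if (!is.na(ko)) out[ko, ] <- out[ko, ] + m[g, ]
  }
  out
}

# AGCN with the toy USiCG set {K00001, K00002}: length-normalize each KO
# count by the mean length of its annotated genes, divide by the USiCG
# median rate, per sample.
oracle_agcn <- function() {
  cat <- oracle_filtered_catalog()
  ko_counts <- oracle_ko_counts()
  mean_len <- sapply(rownames(ko_counts), function(k) {
    mean(cat$length_bp[!is.na(cat$ko_id) & cat$ko_id == k])
  })
  rate <- sweep(ko_counts, 1, mean_len, "/")
  out <- rate
  for (s in colnames(rate)) {
    ref <- median(rate[toy_usicg, s])
    out[, s] <- rate[, s] / ref
  }
  out
}

oracle_spectra <- function() {
  sp <- oracle_read("spectral_counts.tsv")
  m <- as.matrix(sp[, -(1:3)])
  rownames(m) <- sp$gene_ids
  m
}

# Unique gene-level spectra, round-1 total-count normalized.
oracle_norm1 <- function(constant) {
  m <- oracle_spectra()
  unique_rows <- !grepl(",", rownames(m), fixed = TRUE)
  m <- m[unique_rows, , drop = FALSE]
  m <- m[sort(rownames(m)), , drop = FALSE]
  for (s in colnames(m)) m[, s] <- m[, s] * constant / sum(m[, s])
  m
}

# Condition-level gene and KO matrices: replicate medians, then a second
# normalization round to the same constant.
oracle_condition_spectra <- function(constant) {
  m <- oracle_norm1(constant)
  samples <- oracle_samples()
  conds <- sort(unique(samples$condition_id))
  gene <- matrix(0, nrow(m), length(conds),
                 dimnames = list(rownames(m), conds))
  for (cond in conds) {
    reps <- samples$sample_id[samples$condition_id == cond]
    for (g in rownames(m)) gene[g, cond] <- median(m[g, reps])
  }
  cat <- oracle_filtered_catalog()
  kos <- sort(unique(cat$ko_id[cat$gene_id %in% rownames(gene) &
                                 !is.na(cat$ko_id)]))
  ko <- matrix(0, length(kos), length(conds), dimnames = list(kos, conds))
  for (g in rownames(gene)) {
    k <- cat$ko_id[cat$gene_id == g]
    if (!is.na(k)) ko[k, ] <- ko[k, ] + gene[g, ]
  }
  for (cond in conds) {
    gene[, cond] <- gene[, cond] * constant / sum(gene[, cond])
    ko[, cond] <- ko[, cond] * constant / sum(ko[, cond])
  }
  list(gene = gene, ko = ko)
}

# Completeness-adjusted proteomic profile from round-1 normalized unique
# spectra: per replicate MAG sums / completeness fraction -> percent shares,
# median per condition, renormalize to 100.
oracle_proteomic_profile <- function(constant) {
  m <- oracle_norm1(constant)
  cat <- oracle_read("gene_catalog.tsv")
  mq <- oracle_read("mag_quality.tsv")
  samples <- oracle_samples()
  mags <- sort(unique(cat$mag_id))
  comp <- setNames(rep(1, length(mags)), mags)
  for (i in seq_len(nrow(mq))) comp[mq$mag_id[i]] <- mq$completeness_pct[i] / 100
  per_sample <- matrix(0, length(mags), ncol(m),
                       dimnames = list(mags, colnames(m)))
  for (s in colnames(m)) {
    for (g in rownames(m)) {
      mag <- cat$mag_id[cat$gene_id == g]
      per_sample[mag, s] <- per_sample[mag, s] + m[g, s]
    }
    adj <- per_sample[, s] / comp[mags]
    per_sample[, s] <- 100 * adj / sum(adj)
  }
  conds <- sort(unique(samples$condition_id))
  out <- matrix(0, length(mags), length(conds), dimnames = list(mags, conds))
  for (cond in conds) {
    reps <- samples$sample_id[samples$condition_id == cond]
    for (mag in mags) out[mag, cond] <- median(per_sample[mag, reps])
    out[, cond] <- 100 * out[, cond] / sum(out[, cond])
  }
  out
}

# Long package tibble -> labelled matrix, for comparison against the oracle.
as_oracle_matrix <- function(long, row_key, col_key, value) {
  rows <- sort(unique(long[[row_key]]))
  cols <- sort(unique(long[[col_key]]))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(long))) {
    m[long[[row_key]][i], long[[col_key]][i]] <- long[[value]][i]
  }
  m
}
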