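#' Read a gene catalog
#'
#' Reads the canonical tab-separated gene catalog linking every predicted gene
#' to its contig and MAG (or the reserved `UNBINNED` label), together with its
#' length and optional KEGG orthology (KO) / EC annotation and the annotation's
#' sequence identity and e-value. Empty cells are read as missing, never as
#' zero.
#'
#' Expected columns: `gene_id`, `contig_id`, `mag_id`, `length_bp`, `ko_id`,
#' `ec_ids` (comma-separated), `annot_identity_pct`, `annot_evalue`. The last
#' four may be empty.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row and `NA`
#'   as the missing-value sentinel.
#' @param mags Optional MAG quality table (see [read_mag_table()]); when
#'   supplied, every non-`UNBINNED` `mag_id` in the catalog must appear in it.
#' @return A tibble with one row per gene.
#' @export
read_gene_catalog <- function(path, mags = NULL) {
  catalog <- read_canonical_tsv(
    path,
    required = c("gene_id", "contig_id", "mag_id", "length_bp"),
    col_types = readr::cols(
      gene_id = readr::col_character(),
      contig_id = readr::col_character(),
      mag_id = readr::col_character(),
      length_bp = readr::col_double(),
      ko_id = readr::col_character(),
      ec_ids = readr::col_character(),
      annot_identity_pct = readr::col_double(),
      annot_evalue = readr::col_double()
    )
  )
  for (opt in c("ko_id", "ec_ids", "annot_identity_pct", "annot_evalue")) {
    if (!opt %in% names(catalog)) catalog[[opt]] <- NA
  }
  validate_gene_catalog(catalog, mags)
  catalog
}

#' Validate a gene catalog
#'
#' Checks the gene-catalog invariants: unique `gene_id`, `length_bp >= 1`,
#' identity in \[0, 100\], non-negative e-values, and (when a MAG table is
#' given) that every `mag_id` is either `UNBINNED` or a known MAG. Violations
#' raise an error naming the offending rows.
#'
#' @inheritParams read_gene_catalog
#' @param catalog A gene-catalog tibble.
#' @return `catalog`, invisibly.
#' @export
validate_gene_catalog <- function(catalog, mags = NULL) {
  if (nrow(catalog) == 0) abort("gene catalog contains no records")
  dup <- unique(catalog$gene_id[duplicated(catalog$gene_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "duplicated gene_id in gene catalog: ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  bad_len <- which(!is.finite(catalog$length_bp) | catalog$length_bp < 1)
  if (length(bad_len) > 0) {
    abort(paste0("length_bp must be >= 1; offending rows: ",
                 paste(head(bad_len, 5), collapse = ", ")))
  }
  ident <- catalog$annot_identity_pct
  bad_id <- which(!is.na(ident) & (ident < 0 | ident > 100))
  if (length(bad_id) > 0) {
    abort(paste0("annot_identity_pct outside [0, 100]; offending rows: ",
                 paste(head(bad_id, 5), collapse = ", ")))
  }
  ev <- catalog$annot_evalue
  bad_ev <- which(!is.na(ev) & ev < 0)
  if (length(bad_ev) > 0) {
    abort(paste0("annot_evalue must be non-negative; offending rows: ",
                 paste(head(bad_ev, 5), collapse = ", ")))
  }
  if (!is.null(mags)) {
    unknown <- setdiff(unique(catalog$mag_id), c(UNBINNED, mags$mag_id))
    if (length(unknown) > 0) {
      abort(paste0("gene catalog references unknown mag_id: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  invisible(catalog)
}

#' Read a MAG quality table
#'
#' Columns: `mag_id`, `completeness_pct` (in (0, 100\]), `contamination_pct`
#' (in \[0, 100)), `taxonomy` (GTDB-style rank string), and optionally
#' `genome_size_bp` (synthetic fixtures only).
#'
#' @inheritParams read_gene_catalog
#' @return A tibble with one row per MAG.
#' @export
read_mag_table <- function(path) {
  mags <- read_canonical_tsv(
    path,
    required = c("mag_id", "completeness_pct", "contamination_pct"),
    col_types = readr::cols(
      mag_id = readr::col_character(),
      completeness_pct = readr::col_double(),
      contamination_pct = readr::col_double(),
      taxonomy = readr::col_character(),
      genome_size_bp = readr::col_double()
    )
  )
  validate_mag_table(mags)
  mags
}

#' @rdname read_mag_table
#' @param mags A MAG quality tibble.
#' @export
validate_mag_table <- function(mags) {
  if (nrow(mags) == 0) abort("MAG table contains no records")
  dup <- unique(mags$mag_id[duplicated(mags$mag_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated mag_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- mags$mag_id[is.na(mags$completeness_pct) |
                       mags$completeness_pct <= 0 |
                       mags$completeness_pct > 100]
  if (length(bad) > 0) {
    abort(paste0("completeness_pct must lie in (0, 100]; offending MAGs: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- mags$mag_id[is.na(mags$contamination_pct) |
                       mags$contamination_pct < 0 |
                       mags$contamination_pct >= 100]
  if (length(bad) > 0) {
    abort(paste0("contamination_pct must lie in [0, 100); offending MAGs: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(mags)
}

#' Read a gene-by-sample read-count table
#'
#' The on-disk form is wide: a `gene_id` column followed by one integer column
#' per sample. The in-memory form is a long tibble (`gene_id`, `sample_id`,
#' `count`) as used by all quantification functions.
#'
#' @inheritParams read_gene_catalog
#' @return A long tibble with columns `gene_id`, `sample_id`, `count`.
#' @export
read_read_counts <- function(path) {
  wide <- read_canonical_tsv(path, required = "gene_id")
  if (ncol(wide) < 2) abort("read-count table has no sample columns")
  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "sample_id", values_to = "count")
  if (any(is.na(long$count) | long$count < 0)) {
    abort("read counts must be non-negative and non-missing")
  }
  long
}

#' Read the per-sample table of unmapped reads and condition assignments
#'
#' Columns: `sample_id`, `condition_id`, `replicate`, `unmapped_reads`.
#'
#' @inheritParams read_gene_catalog
#' @return A tibble with one row per sample.
#' @export
read_sample_info <- function(path) {
  samples <- read_canonical_tsv(
    path,
    required = c("sample_id", "condition_id", "replicate", "unmapped_reads"),
    col_types = readr::cols(
      sample_id = readr::col_character(),
      condition_id = readr::col_character(),
      replicate = readr::col_integer(),
      unmapped_reads = readr::col_double()
    )
  )
  if (any(duplicated(samples$sample_id))) abort("duplicated sample_id")
  if (any(is.na(samples$unmapped_reads) | samples$unmapped_reads < 0)) {
    abort("unmapped_reads must be non-negative")
  }
  samples
}

#' Read a metaprotein spectral-count table
#'
#' The on-disk form is wide: `metaprotein_id`, `peptide_set_id`, `gene_ids`
#' (comma-separated gene set), then one numeric column per replicate sample.
#' The in-memory form is long with an `n_genes` column, ready for
#' [exclude_nonunique()].
#'
#' @inheritParams read_gene_catalog
#' @return A long tibble with columns `metaprotein_id`, `peptide_set_id`,
#'   `gene_ids`, `n_genes`, `sample_id`, `count`.
#' @export
read_spectral_counts <- function(path) {
  wide <- read_canonical_tsv(
    path, required = c("metaprotein_id", "peptide_set_id", "gene_ids"))
  if (ncol(wide) < 4) abort("spectral-count table has no sample columns")
  if (any(is.na(wide$gene_ids) | wide$gene_ids == "")) {
    abort("every metaprotein must have a non-empty gene set")
  }
  long <- tidyr::pivot_longer(
    wide, -c("metaprotein_id", "peptide_set_id", "gene_ids"),
    names_to = "sample_id", values_to = "count")
  if (any(is.na(long$count) | long$count < 0)) {
    abort("spectral counts must be non-negative and non-missing")
  }
  long$n_genes <- lengths(strsplit(long$gene_ids, ",", fixed = TRUE))
  long[, c("metaprotein_id", "peptide_set_id", "gene_ids", "n_genes",
           "sample_id", "count")]
}

#' Read KEGG module definitions
#'
#' Each line holds a module identifier and a block expression. Blocks are
#' separated by spaces, alternatives within a block by commas, and subunits of
#' a complex by plus signs (a complex becomes one multi-KO alternative). A
#' block is satisfied when any one alternative is fully present. Nested
#' parentheses and minus-prefixed optional KOs are not part of the grammar and
#' are rejected.
#'
#' @inheritParams read_gene_catalog
#' @return A tibble with columns `module_id`, `definition` (the raw
#'   expression) and `blocks`, a list-column where each element is a list of
#'   blocks, each block a list of character vectors (the alternatives).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("module_id\tdefinition", "M0001\tK1,K2 K3"), tf)
#' read_module_definitions(tf)$blocks[[1]]
read_module_definitions <- function(path) {
  raw <- read_canonical_tsv(
    path, required = c("module_id", "definition"),
    col_types = readr::cols(.default = readr::col_character()))
  blocks <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    blocks[[i]] <- tryCatch(
      parse_module_expression(raw$definition[i]),
      error = function(e) {
        abort(paste0("malformed module expression for ", raw$module_id[i],
                     " (line ", i + 1L, "): ", conditionMessage(e)))
      })
  }
  tibble(module_id = raw$module_id, definition = raw$definition,
         blocks = blocks)
}

#' @rdname read_module_definitions
#' @param expression A single block expression string, e.g. `"K1,K2 K3+K4"`.
#' @export
parse_module_expression <- function(expression) {
  if (is.na(expression)) abort("zero blocks")
  if (grepl("[()\\-]", expression)) {
    abort("parentheses and optional (minus-prefixed) KOs are not supported")
  }
  block_strs <- strsplit(trimws(expression), "[[:space:]]+")[[1]]
  block_strs <- block_strs[block_strs != ""]
  if (length(block_strs) == 0) abort("zero blocks")
  lapply(block_strs, function(b) {
    alts <- strsplit(b, ",", fixed = TRUE)[[1]]
    if (any(alts == "")) abort(paste0("empty alternative in block '", b, "'"))
    lapply(alts, function(a) {
      kos <- strsplit(a, "+", fixed = TRUE)[[1]]
      if (length(kos) == 0 || any(kos == "")) {
        abort(paste0("empty KO in alternative '", a, "'"))
      }
      kos
    })
  })
}

#' Read a key-enzyme group table
#'
#' Columns: `enzyme_label` (EC number or enzyme name), `ko_ids`
#' (comma-separated, non-empty), `aggregation_mode` (`sum_similar` for KOs
#' with similar function, `median_subunits` for subunits of one complex) and
#' `ad_category` (the anaerobic-digestion step: hydrolysis, acidogenesis,
#' acetogenesis, or a methanogenesis sub-pathway).
#'
#' @inheritParams read_gene_catalog
#' @return A tibble with one row per enzyme group.
#' @export
read_key_enzymes <- function(path) {
  groups <- read_canonical_tsv(
    path,
    required = c("enzyme_label", "ko_ids", "aggregation_mode", "ad_category"),
    col_types = readr::cols(.default = readr::col_character()))
  bad <- groups$enzyme_label[!groups$aggregation_mode %in%
                               c("sum_similar", "median_subunits")]
  if (length(bad) > 0) {
    abort(paste0("unknown aggregation_mode for: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(is.na(groups$ko_ids) | groups$ko_ids == "")) {
    abort("every key-enzyme group needs a non-empty KO list")
  }
  groups
}

#' Read a process-metadata table
#'
#' One row per condition (`condition_id` column) and one numeric column per
#' process or chemical parameter (temperature, OLR, HRT, feed fractions,
#' concentrations). Returned in long form for correlation analysis.
#'
#' @inheritParams read_gene_catalog
#' @return A long tibble with columns `condition_id`, `parameter`, `value`.
#' @export
read_process_metadata <- function(path) {
  wide <- read_canonical_tsv(path, required = "condition_id")
  if (ncol(wide) < 2) abort("process metadata has no parameter columns")
  tidyr::pivot_longer(wide, -"condition_id",
                      names_to = "parameter", values_to = "value")
}

#' Write and read a labelled numeric matrix as TSV
#'
#' `write_matrix()` writes a fully labelled numeric matrix (or a wide data
#' frame whose first column holds row labels) to a tab-separated file with a
#' header row; `NaN` cells are written as the `NA` sentinel. `read_matrix()`
#' reads it back; write-then-read is the identity for labels and values.
#'
#' @param m A labelled numeric matrix, or a data frame whose first column is
#'   the row label.
#' @param path Output (input) file path.
#' @param row_label Name for the row-label column in the header.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   a labelled numeric matrix.
#' @export
write_matrix <- function(m, path, row_label = "id") {
  if (is.matrix(m)) {
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("matrix must be fully labelled")
    }
    df <- tibble::as_tibble(m, rownames = row_label)
  } else {
    df <- as_tibble(m)
  }
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read_canonical_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' The packaged default universal single-copy gene (USiCG) set
#'
#' Ten ribosomal-protein KEGG orthologies present exactly once per prokaryotic
#' genome, used as the reference set for AGCN scaling. Override by passing
#' your own KO vector (or a file with a `ko_id` column) to [agcn_normalize()].
#'
#' @return A character vector of KO identifiers.
#' @export
default_usicg_kos <- function() {
  path <- system.file("extdata", "usicg_default.tsv", package = "magquant")
  read_canonical_tsv(path, required = "ko_id")$ko_id
}

# Shared canonical-TSV reader: UTF-8, tab-separated, header row, "NA"
# sentinel; errors on empty files and missing required columns.
read_canonical_tsv <- function(path, required = character(), col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (!is.null(col_types)) {
    # only keep parsers for columns the file actually has, so optional
    # columns do not trigger spurious parser warnings
    first <- readLines(path, n = 1)
    if (length(first) == 1) {
      header <- strsplit(first, "\t", fixed = TRUE)[[1]]
      col_types$cols <- col_types$cols[names(col_types$cols) %in% header]
    }
  }
  df <- tryCatch(
    readr::read_tsv(path, na = "NA", col_types = col_types,
                    show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot read ", path, ": ",
                                     conditionMessage(e))))
  if (nrow(df) == 0) abort(paste0("no records in ", path))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

# Long (key, sample_id, count) -> wide tibble, used by all TSV writers.
long_to_wide <- function(long, key, value = "count", col = "sample_id") {
  tidyr::pivot_wider(long, names_from = dplyr::all_of(col),
                     values_from = dplyr::all_of(value), values_fill = 0) %>%
    arrange(.data[[key]])
}
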