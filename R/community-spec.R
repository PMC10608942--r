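#' Specify a synthetic community
#'
#' Collects and validates all parameters of the synthetic-community generator.
#' The defaults emulate the study design the pipeline targets: three digesters
#' sampled in triplicate, log-normally distributed MAG abundances, an unbinned
#' contig fraction carrying part of the community, a per-sample unmapped read
#' fraction between 11 and 18%, and spectral counts that track genomic
#' abundance modulated by per-MAG activity multipliers (over-dispersed via a
#' negative binomial). Archaeal hyperactivity — high proteomic, low genomic
#' abundance — is representable through a wide activity-multiplier range and
#' needs no special case.
#'
#' @param n_mags Number of MAGs (> 0).
#' @param n_conditions,n_replicates Conditions (digesters) and replicates per
#'   condition.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Parameters of the
#'   log-normal from which per-condition MAG abundance weights are drawn.
#' @param unbinned_fraction Share of community abundance carried by unbinned
#'   contigs, in \[0, 1).
#' @param unmapped_fraction_range Interval within \[0, 1) from which each
#'   sample's unmapped-read fraction is drawn uniformly.
#' @param mean_reads_per_sample Expected mapped reads per sample.
#' @param mean_spectra_per_sample Expected spectral counts per replicate.
#' @param activity_multiplier_range Positive interval; per-MAG protein-level
#'   activity multipliers are drawn log-uniformly from it.
#' @param completeness_range Interval within (0, 100\] for simulated MAG
#'   completeness; genes are withheld from each MAG to realise it.
#' @param contamination_range Interval within \[0, 100) for reported
#'   contamination (metadata only; no foreign genes are added).
#' @param genes_per_mag Genes per complete genome.
#' @param n_unbinned_genes Genes placed on unbinned contigs (ignored when
#'   `unbinned_fraction` is 0).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (defaults give a median of ~900 bp).
#' @param ko_pool_size Size of the KO pool from which ordinary annotations are
#'   drawn.
#' @param annotation_rate Fraction of genes that carry a KO annotation.
#' @param poor_annotation_fraction Fraction of annotated genes whose identity
#'   or e-value fails the default annotation filter.
#' @param spectral_dispersion Negative-binomial dispersion for spectral
#'   counts; 0 gives Poisson counts.
#' @param nonunique_fraction Fraction of metaproteins assigned to more than
#'   one gene, to exercise the uniqueness-exclusion rule.
#' @param planted_multicopy Named integer vector: KOs planted at a fixed copy
#'   number per complete genome (e.g. `c(K99901 = 2)`), for copy-number
#'   recovery checks. The ten default USiCG KOs are always planted at one
#'   copy.
#' @param seed Integer RNG seed; a fixed seed makes every generator output
#'   identical across runs.
#' @return A validated `community_spec` list.
#' @export
#' @examples
#' community_spec(n_mags = 5, seed = 1)
community_spec <- function(n_mags,
                           n_conditions = 3,
                           n_replicates = 3,
                           abundance_lognormal_mu = 0,
                           abundance_lognormal_sigma = 1.5,
                           unbinned_fraction = 0.2,
                           unmapped_fraction_range = c(0.11, 0.18),
                           mean_reads_per_sample = 200000,
                           mean_spectra_per_sample = 20000,
                           activity_multiplier_range = c(0.25, 4),
                           completeness_range = c(60, 100),
                           contamination_range = c(0, 8),
                           genes_per_mag = 100,
                           n_unbinned_genes = 200,
                           gene_length_meanlog = log(900),
                           gene_length_sdlog = 0.45,
                           ko_pool_size = 300,
                           annotation_rate = 0.8,
                           poor_annotation_fraction = 0.05,
                           spectral_dispersion = 0.3,
                           nonunique_fraction = 0.05,
                           planted_multicopy = integer(),
                           seed = 1) {
  spec <- list(
    n_mags = n_mags, n_conditions = n_conditions,
    n_replicates = n_replicates,
    abundance_lognormal_mu = abundance_lognormal_mu,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    unbinned_fraction = unbinned_fraction,
    unmapped_fraction_range = unmapped_fraction_range,
    mean_reads_per_sample = mean_reads_per_sample,
    mean_spectra_per_sample = mean_spectra_per_sample,
    activity_multiplier_range = activity_multiplier_range,
    completeness_range = completeness_range,
    contamination_range = contamination_range,
    genes_per_mag = genes_per_mag,
    n_unbinned_genes = n_unbinned_genes,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    ko_pool_size = ko_pool_size,
    annotation_rate = annotation_rate,
    poor_annotation_fraction = poor_annotation_fraction,
    spectral_dispersion = spectral_dispersion,
    nonunique_fraction = nonunique_fraction,
    planted_multicopy = planted_multicopy,
    seed = seed)
  validate_community_spec(spec)
  structure(spec, class = "community_spec")
}

validate_community_spec <- function(spec) {
  stop_if <- function(cond, msg) if (cond) abort(paste0("invalid spec: ", msg))
  stop_if(spec$n_mags < 1, "n_mags must be >= 1")
  stop_if(spec$n_conditions < 1, "n_conditions must be >= 1")
  stop_if(spec$n_replicates < 1, "n_replicates must be >= 1")
  stop_if(spec$unbinned_fraction < 0 || spec$unbinned_fraction >= 1,
          "unbinned_fraction must lie in [0, 1)")
  r <- spec$unmapped_fraction_range
  stop_if(length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] >= 1,
          "unmapped_fraction_range must be an interval within [0, 1)")
  stop_if(spec$mean_reads_per_sample <= 0, "mean_reads_per_sample must be > 0")
  stop_if(spec$mean_spectra_per_sample <= 0,
          "mean_spectra_per_sample must be > 0")
  a <- spec$activity_multiplier_range
  stop_if(length(a) != 2 || a[1] <= 0 || a[1] > a[2],
          "activity_multiplier_range must be a positive interval")
  cr <- spec$completeness_range
  stop_if(length(cr) != 2 || cr[1] <= 0 || cr[1] > cr[2] || cr[2] > 100,
          "completeness_range must be an interval within (0, 100]")
  stop_if(spec$genes_per_mag < 1, "genes_per_mag must be >= 1")
  stop_if(spec$spectral_dispersion < 0, "spectral_dispersion must be >= 0")
  stop_if(spec$nonunique_fraction < 0 || spec$nonunique_fraction > 1,
          "nonunique_fraction must lie in [0, 1]")
  stop_if(spec$annotation_rate < 0 || spec$annotation_rate > 1,
          "annotation_rate must lie in [0, 1]")
  pm <- spec$planted_multicopy
  stop_if(length(pm) > 0 && (is.null(names(pm)) || any(pm < 1)),
          "planted_multicopy must be a named vector of copy numbers >= 1")
  invisible(spec)
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec>\n")
  cat(sprintf("  %d MAGs, %d conditions x %d replicates\n",
              x$n_mags, x$n_conditions, x$n_replicates))
  cat(sprintf("  unbinned fraction %.2f, unmapped in [%.2f, %.2f]\n",
              x$unbinned_fraction, x$unmapped_fraction_range[1],
              x$unmapped_fraction_range[2]))
  cat(sprintf("  %s mapped reads and %s spectra per sample (expected)\n",
              format(x$mean_reads_per_sample, big.mark = ","),
              format(x$mean_spectra_per_sample, big.mark = ",")))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
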