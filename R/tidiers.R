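#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a MAG abundance profile
#'
#' Returns the profile as a plain tibble with the omics layer as a column,
#' ready for joining or plotting.
#'
#' @param x A `mag_abundance` object.
#' @param ... Unused.
#' @return A tibble `mag_id`, `condition_id`, `abundance_pct`, `layer`.
#' @method tidy mag_abundance
#' @export
tidy.mag_abundance <- function(x, ...) {
  mutate(as_tibble(x), layer = attr(x, "layer") %||% NA_character_)
}

#' One-row summary of a MAG abundance profile
#'
#' @inheritParams tidy.mag_abundance
#' @return A tibble with the layer, numbers of MAGs and conditions, the
#'   unbinned share range, and the worst column-sum deviation from 100.
#' @method glance mag_abundance
#' @export
glance.mag_abundance <- function(x, ...) {
  df <- as_tibble(x)
  col_sums <- df %>% group_by(.data$condition_id) %>%
    summarise(s = sum(.data$abundance_pct), .groups = "drop")
  unb <- df$abundance_pct[df$mag_id == UNBINNED]
  tibble(
    layer = attr(x, "layer") %||% NA_character_,
    n_mags = dplyr::n_distinct(df$mag_id[df$mag_id != UNBINNED]),
    n_conditions = dplyr::n_distinct(df$condition_id),
    unbinned_min_pct = if (length(unb)) min(unb) else NA_real_,
    unbinned_max_pct = if (length(unb)) max(unb) else NA_real_,
    max_column_sum_error = max(abs(col_sums$s - 100)))
}

#' @export
print.mag_abundance <- function(x, ...) {
  cat(sprintf("<mag_abundance: %s layer>\n",
              attr(x, "layer") %||% "unknown"))
  NextMethod()
}

#' Tidy an AGCN profile
#'
#' @param x An `agcn_profile` object.
#' @param ... Unused.
#' @return A tibble `ko_id`, `sample_id`, `agcn`, `is_usicg`.
#' @method tidy agcn_profile
#' @export
tidy.agcn_profile <- function(x, ...) {
  mutate(as_tibble(x), is_usicg = .data$ko_id %in% attr(x, "usicg"))
}

#' One-row summary of an AGCN profile
#'
#' @inheritParams tidy.agcn_profile
#' @return A tibble with KO and sample counts and the worst deviation of the
#'   per-sample USiCG median from 1.
#' @method glance agcn_profile
#' @export
glance.agcn_profile <- function(x, ...) {
  df <- tidy(x)
  med <- df %>% filter(.data$is_usicg) %>%
    group_by(.data$sample_id) %>%
    summarise(m = median(.data$agcn), .groups = "drop")
  tibble(n_kos = dplyr::n_distinct(df$ko_id),
         n_samples = dplyr::n_distinct(df$sample_id),
         max_usicg_median_error = max(abs(med$m - 1)))
}
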