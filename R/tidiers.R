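# broom-style accessors ------------------------------------------------------

#' Tidy a pipeline report
#'
#' One row per clonality tier with the tier's unique-variant count,
#' sequenced nucleotides, frequency and Wilson bounds.
#'
#' @param x a `mito_dx_report`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.mito_dx_report <- function(x, ...) {
  x$frequencies
}

#' Summarise a pipeline report in one row
#'
#' @param x a `mito_dx_report`.
#' @param ... unused.
#' @return one-row tibble: read/consensus yields, DCS and SSCS rare
#'   frequencies and their ratio, variant count.
#' @exportS3Method generics::glance
glance.mito_dx_report <- function(x, ...) {
  dplyr::bind_cols(
    x$yields,
    tibble(
      n_variants = nrow(x$variants),
      dcs_rare_frequency =
        x$frequencies$frequency[x$frequencies$tier == "rare"],
      sscs_rare_frequency = x$sscs_rare$frequency,
      sscs_dcs_ratio = x$sscs_dcs_ratio
    )
  )
}

#' Tidy a two-sample comparison
#'
#' Stacks the per-tier and per-type proportion tests into one tibble with a
#' `comparison` column.
#'
#' @param x a `mito_dx_comparison`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.mito_dx_comparison <- function(x, ...) {
  bind_rows(
    mutate(rename(x$tier_tests, term = "tier"), comparison = "tier",
           .before = 1),
    mutate(rename(x$type_tests, term = "type"), comparison = "type",
           .before = 1)
  )
}

#' One-row summary of a comparison
#'
#' @param x a `mito_dx_comparison`.
#' @param ... unused.
#' @return one-row tibble with the rare-tier p value and set sizes.
#' @exportS3Method generics::glance
glance.mito_dx_comparison <- function(x, ...) {
  tibble(
    rare_p_value = x$tier_tests$p_value[x$tier_tests$tier == "rare"],
    n_shared = nrow(x$shared_variants),
    n_only_a = nrow(x$only_a),
    n_only_b = nrow(x$only_b)
  )
}
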