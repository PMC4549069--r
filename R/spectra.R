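# Substitution-type and trinucleotide-context spectra ----------------------

#' The 12 L-strand substitution types
#'
#' All ordered base pairs `X>Y`, referenced to the light strand. Strand bias
#' is the unequal prevalence of a type and its complement (e.g. `G>A` vs
#' `C>T`), so the 12-type table is kept uncollapsed.
#'
#' @return character vector of length 12.
#' @export
substitution_types <- function() {
  out <- c()
  for (s in DNA_BASES) {
    for (a in DNA_BASES) {
      if (s != a) out <- c(out, paste0(s, ">", a))
    }
  }
  out
}

# complementary partner of a type, and its pyrimidine-keyed collapsed label
complement_type <- function(type) {
  paste0(complement_base(substr(type, 1, 1)), ">",
         complement_base(substr(type, 3, 3)))
}

collapsed_label <- function(type) {
  src <- substr(type, 1, 1)
  ifelse(src %in% c("C", "T"),
         paste0(type, "/", complement_type(type)),
         paste0(complement_type(type), "/", type))
}

#' 12-type substitution spectrum with per-type frequencies
#'
#' Counts unique point mutations of each of the 12 L-strand types. The
#' frequency denominator of a type is the number of sequenced consensus
#' nucleotides whose reference base is the type's source base, so types with
#' the same source share a denominator. Wilson intervals at `conf_level`
#' are attached, and the complementary 6-type collapse (counts and percent
#' of all point mutations) is available via [collapse_spectrum()] or the
#' `collapsed` attribute.
#'
#' @param variants point-mutation calls from one tier.
#' @param pileups matching [pileup()] tibble.
#' @param conf_level Wilson interval confidence level.
#' @return 12-row tibble: `type`, `source`, `count`, `denominator`,
#'   `frequency`, `ci_low`, `ci_high`, `pair` (collapsed label).
#' @export
substitution_spectrum <- function(variants, pileups, conf_level = 0.95) {
  point <- variants |>
    filter(.data$variant_class == "snv") |>
    distinct(.data$position, .data$ref, .data$alt)
  types <- substitution_types()
  denom_by_base <- vapply(DNA_BASES, function(b) {
    sum(pileups$depth[pileups$ref_base == b])
  }, numeric(1))
  counts <- vapply(types, function(tp) {
    s <- substr(tp, 1, 1); a <- substr(tp, 3, 3)
    sum(point$ref == s & point$alt == a)
  }, integer(1))
  denom <- denom_by_base[substr(types, 1, 1)]
  freq <- ifelse(denom > 0, counts / denom, NA_real_)
  ci <- wilson_interval(counts[denom > 0], denom[denom > 0], conf_level)
  ci_low <- ci_high <- rep(NA_real_, length(types))
  ci_low[denom > 0] <- ci$low
  ci_high[denom > 0] <- ci$high
  out <- tibble(
    type = types,
    source = substr(types, 1, 1),
    count = unname(counts),
    denominator = unname(denom),
    frequency = unname(freq),
    ci_low = ci_low,
    ci_high = ci_high,
    pair = collapsed_label(types)
  )
  attr(out, "collapsed") <- collapse_12_to_6(out)
  class(out) <- c("mito_spectrum", class(out))
  out
}

collapse_12_to_6 <- function(spectrum12) {
  total <- sum(spectrum12$count)
  spectrum12 |>
    group_by(pair = .data$pair) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(fraction_pct =
             if (total > 0) 100 * .data$count / total else 0) |>
    arrange(.data$pair)
}

#' Collapse the 12-type spectrum into 6 complementary pairs
#'
#' Sums each type with its complement (`C>T` with `G>A`, etc.) and reports
#' each pair as a percentage of all point mutations; the six percentages
#' sum to 100 whenever any mutation was observed.
#'
#' @param spectrum12 a [substitution_spectrum()] table.
#' @return 6-row tibble: `pair`, `count`, `fraction_pct`.
#' @export
collapse_spectrum <- function(spectrum12) {
  attr(spectrum12, "collapsed") %||% collapse_12_to_6(spectrum12)
}

#' Strand-bias test between complementary substitution types
#'
#' Compares the per-type frequencies of a complementary pair (e.g. `G>A` vs
#' `C>T` on the L-strand) with the two-sample proportion test with
#' continuity correction, using each type's own count and denominator.
#'
#' @param spectrum a [substitution_spectrum()] table.
#' @param type_a,type_b the two types; must be complementary partners.
#' @return one-row tibble from [two_proportion_test()] plus `type_a`,
#'   `type_b`.
#' @export
strand_bias_test <- function(spectrum, type_a, type_b) {
  if (!identical(complement_type(type_a), type_b)) {
    abort("strand bias is defined between complementary types")
  }
  ra <- spectrum[spectrum$type == type_a, ]
  rb <- spectrum[spectrum$type == type_b, ]
  if (nrow(ra) != 1L || nrow(rb) != 1L) abort("type not found in spectrum")
  if (ra$denominator == 0 || rb$denominator == 0) {
    abort("zero denominator for a substitution type")
  }
  res <- two_proportion_test(ra$count, ra$denominator,
                             rb$count, rb$denominator)
  mutate(res, type_a = type_a, type_b = type_b)
}

#' The 96 canonical trinucleotide mutation classes
#'
#' Pyrimidine-centred convention: 6 substitutions (`C>A`, `C>G`, `C>T`,
#' `T>A`, `T>C`, `T>G`) times 4 5'-bases times 4 3'-bases. Purine-centred
#' mutations are complemented into this frame, so every point mutation maps
#' to exactly one class and complements are never double counted.
#'
#' @return 96-row tibble: `substitution`, `five_prime`, `three_prime`,
#'   `context` (the trinucleotide).
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(three_prime = DNA_BASES, five_prime = DNA_BASES,
                      substitution = subs, stringsAsFactors = FALSE)
  tibble(
    substitution = grid$substitution,
    five_prime = grid$five_prime,
    three_prime = grid$three_prime,
    context = paste0(grid$five_prime, substr(grid$substitution, 1, 1),
                     grid$three_prime)
  ) |>
    arrange(.data$substitution, .data$five_prime, .data$three_prime)
}

# map L-strand (position, ref, alt) onto the canonical pyrimidine class
classify_context <- function(position, ref, alt, reference) {
  tri <- paste0(
    ref_base(reference, position - 1L),
    ref_base(reference, position),
    ref_base(reference, position + 1L)
  )
  pur <- ref %in% c("A", "G")
  sub <- ifelse(pur,
                paste0(complement_base(ref), ">", complement_base(alt)),
                paste0(ref, ">", alt))
  ctx <- ifelse(pur, revcomp(tri), tri)
  tibble(substitution = sub, context = ctx)
}

#' 96-class trinucleotide context spectrum
#'
#' Maps every unique point mutation to its canonical pyrimidine-centred
#' trinucleotide class (the mutated base plus its immediate 5' and 3'
#' neighbours; purine-centred mutations are reverse-complemented into the
#' pyrimidine frame) and reports each class's share of all classified
#' mutations. Neighbours at positions 1 and `length` wrap around the
#' circular genome.
#'
#' @param variants point-mutation calls.
#' @param reference an `mt_reference` (must be circular for variants at the
#'   termini).
#' @return 96-row tibble: `substitution`, `context`, `count`,
#'   `fraction_pct`, carrying class `mito_context_spectrum`.
#' @export
context_spectrum <- function(variants, reference) {
  point <- variants |>
    filter(.data$variant_class == "snv") |>
    distinct(.data$position, .data$ref, .data$alt)
  classes <- context_classes()
  if (nrow(point) > 0L) {
    hit <- classify_context(point$position, point$ref, point$alt, reference)
    tallied <- count(hit, .data$substitution, .data$context, name = "count")
  } else {
    tallied <- tibble(substitution = character(0), context = character(0),
                      count = integer(0))
  }
  total <- sum(tallied$count)
  out <- classes |>
    left_join(tallied, by = c("substitution", "context")) |>
    mutate(
      count = as.integer(.data$count %|na|% 0L),
      fraction_pct = if (total > 0) 100 * .data$count / total else 0
    ) |>
    select("substitution", "context", "count", "fraction_pct")
  class(out) <- c("mito_context_spectrum", class(out))
  out
}

#' Compare one context class between two spectra
#'
#' Two-sample proportion test with continuity correction on the class's
#' count out of each spectrum's total classified mutations, with the fold
#' change of the class fractions. A class absent from both spectra has an
#' undefined fold change (reported `NA` with `estimable = FALSE`).
#'
#' @param spectrum_a,spectrum_b [context_spectrum()] tables.
#' @param substitution,context the class, e.g. `"C>T"`, `"CCG"`.
#' @return one-row tibble: `substitution`, `context`, `fold`, `estimable`,
#'   and the proportion-test columns (`NA` when not estimable).
#' @export
compare_context_fractions <- function(spectrum_a, spectrum_b,
                                      substitution, context) {
  pick <- function(sp) {
    row <- sp[sp$substitution == substitution & sp$context == context, ]
    if (nrow(row) != 1L) abort("class absent from the 96-class enumeration")
    row
  }
  ra <- pick(spectrum_a)
  rb <- pick(spectrum_b)
  ta <- sum(spectrum_a$count)
  tb <- sum(spectrum_b$count)
  if (ta == 0 || tb == 0) abort("both spectra must have classified mutations")
  if (ra$count == 0 && rb$count == 0) {
    return(tibble(substitution = substitution, context = context,
                  fold = NA_real_, estimable = FALSE,
                  statistic = NA_real_, p_value = NA_real_))
  }
  res <- safe_two_proportion_test(ra$count, ta, rb$count, tb)
  tibble(
    substitution = substitution,
    context = context,
    fold = (ra$count / ta) / (rb$count / tb),
    estimable = TRUE,
    statistic = res$statistic,
    p_value = res$p_value
  )
}

#' Pool context spectra across samples
#'
#' Sums unique-variant counts across samples before recomputing fractions;
#' a variant shared by several samples counts once per sample, so the
#' per-sample panels sum to the pooled panel.
#'
#' @param ... two or more [context_spectrum()] tables.
#' @return pooled 96-row context spectrum (count-weighted pooling).
#' @export
pool_context_spectra <- function(...) {
  sps <- list(...)
  stopifnot(length(sps) >= 2L)
  out <- sps[[1]]
  for (sp in sps[-1]) out$count <- out$count + sp$count
  total <- sum(out$count)
  out$fraction_pct <- if (total > 0) 100 * out$count / total else 0
  attr(out, "pooling") <- "count-weighted"
  out
}
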