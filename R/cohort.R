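# Cross-sample variant sets, lookup flagging and per-gene burden -----------
#
# Sample variant sets are long tibbles: one row per (sample_id, position,
# ref, alt), with optional metadata columns such as cell_type and woman_id.
# Variant identity for the set algebra is (position, ref, alt) only: a
# variant that is rare in one sample and low-heteroplasmic in another still
# matches, so stratify by tier before calling into the set operations.

variant_key <- function(tbl) {
  paste0(tbl$position, ":", tbl$ref, ">", tbl$alt)
}

#' Variants common to every selected sample
#'
#' Intersection of variant identities (position, ref, alt) across all
#' selected samples.
#'
#' @param sets long variant tibble with a `sample_id` column.
#' @param sample_ids samples to intersect; default all samples present.
#' @return tibble of the shared variants (`position`, `ref`, `alt`, `name`).
#' @export
common_variants <- function(sets, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(sets$sample_id)
  if (length(sample_ids) < 2L) {
    abort("need at least two samples to intersect")
  }
  sel <- filter(sets, .data$sample_id %in% sample_ids)
  if (!setequal(unique(sel$sample_id), sample_ids)) {
    abort("some requested samples have no variant set")
  }
  sel |>
    distinct(.data$sample_id, .data$position, .data$ref, .data$alt) |>
    count(.data$position, .data$ref, .data$alt) |>
    filter(.data$n == length(sample_ids)) |>
    select(-"n") |>
    mutate(name = paste0("m.", .data$position, .data$ref, ">", .data$alt)) |>
    arrange(.data$position)
}

#' Variants exclusive to one sample group
#'
#' Variants found in every sample of `in_group` but in no sample of
#' `not_in_group`: the intersection over the first group minus the union
#' over the second.
#'
#' @param sets long variant tibble with `sample_id`.
#' @param in_group,not_in_group disjoint, nonempty vectors of sample ids.
#' @return tibble of exclusive variants.
#' @export
exclusive_variants <- function(sets, in_group, not_in_group) {
  if (length(in_group) == 0L || length(not_in_group) == 0L) {
    abort("both groups must be nonempty (use common_variants for a plain intersection)")
  }
  if (length(intersect(in_group, not_in_group)) > 0L) {
    abort("in_group and not_in_group overlap")
  }
  inside <- common_variants(sets, in_group)
  outside <- sets |>
    filter(.data$sample_id %in% not_in_group) |>
    distinct(.data$position, .data$ref, .data$alt)
  anti_join(inside, outside, by = c("position", "ref", "alt"))
}

#' Flag variants against a known-variant lookup table
#'
#' Annotates each variant as previously `reported` (with the lookup's
#' population frequency) or `new`. The lookup is a static user-supplied TSV
#' snapshot in MITOMAP style with columns `name` (`m.<pos><ref>><alt>`),
#' `gb_frequency_pct`, `associations`; malformed rows are skipped with a
#' warning. The variant set itself is never altered, only annotated.
#'
#' @param variants tibble with `position`, `ref`, `alt` (a `name` column is
#'   built if absent).
#' @param known_records lookup tibble (possibly empty).
#' @return `variants` with added `status` (`reported`/`new`),
#'   `gb_frequency_pct`, `associations`.
#' @export
flag_new_variants <- function(variants, known_records) {
  variants <- as_tibble(variants)
  if (!"name" %in% names(variants)) {
    variants$name <- paste0("m.", variants$position, variants$ref, ">",
                            variants$alt)
  }
  known_records <- as_tibble(known_records)
  if (nrow(known_records) > 0L) {
    ok <- grepl("^m\\.[0-9]+[ACGT]>[ACGT]$", known_records$name) &
      !is.na(known_records$gb_frequency_pct) &
      known_records$gb_frequency_pct >= 0 &
      known_records$gb_frequency_pct <= 100
    if (any(!ok)) {
      warn(sprintf("skipped %d malformed lookup row(s)", sum(!ok)))
      known_records <- known_records[ok, , drop = FALSE]
    }
  } else {
    known_records <- tibble(name = character(0),
                            gb_frequency_pct = numeric(0),
                            associations = character(0))
  }
  if (!"associations" %in% names(known_records)) {
    known_records$associations <- NA_character_
  }
  out <- left_join(
    variants,
    select(known_records, "name", "gb_frequency_pct", "associations"),
    by = "name"
  )
  mutate(out, status = if_else(is.na(.data$gb_frequency_pct),
                               "new", "reported"))
}

#' Read a known-variant lookup TSV
#'
#' @param tsv_path path to a TSV with columns `name`, `gb_frequency_pct`,
#'   `associations`.
#' @return lookup tibble.
#' @export
load_known_variants <- function(tsv_path) {
  readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
}

#' Per-gene nonsynonymous/synonymous burden
#'
#' Counts unique nonsynonymous and synonymous variants per protein-coding
#' gene (a variant inside two overlapping genes counts in each) and attaches
#' the Pearson correlation between gene size and nonsynonymous count —
#' under random mutation, larger genes accumulate proportionally more
#' nonsynonymous mutations. The correlation is `NA` (not estimable) with
#' fewer than three genes or zero variance.
#'
#' @param variants point-variant tibble with `position`, `ref`, `alt`.
#' @param annotation,reference annotation and reference objects.
#' @return tibble (one row per protein gene): `gene`, `size_bp`, `ns_count`,
#'   `s_count`; attribute `size_ns_correlation` holds the test row (or
#'   `NULL`).
#' @export
gene_ns_burden <- function(variants, annotation, reference) {
  prot <- annotation[annotation$category == "protein", , drop = FALSE]
  uniq <- distinct(as_tibble(variants), .data$position, .data$ref, .data$alt)
  effects <- purrr::pmap_dfr(
    list(uniq$position, uniq$ref, uniq$alt),
    function(pos, ref, alt) codon_change(pos, ref, alt, annotation, reference)
  )
  counts <- if (nrow(effects) > 0L) {
    effects |>
      count(.data$gene, .data$effect) |>
      tidyr::pivot_wider(names_from = "effect", values_from = "n",
                         values_fill = 0L)
  } else {
    tibble(gene = character(0))
  }
  for (col in c("nonsynonymous", "synonymous")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- tibble(
    gene = prot$gene,
    size_bp = record_width(prot)
  ) |>
    left_join(counts, by = "gene") |>
    mutate(
      ns_count = as.integer(.data$nonsynonymous %|na|% 0L),
      s_count = as.integer(.data$synonymous %|na|% 0L)
    ) |>
    select("gene", "size_bp", "ns_count", "s_count")
  corr <- NULL
  if (nrow(out) >= 3L && stats::sd(out$size_bp) > 0 &&
      stats::sd(out$ns_count) > 0) {
    corr <- rank_correlation(out$size_bp, out$ns_count, "pearson")
  }
  attr(out, "size_ns_correlation") <- corr
  out
}

#' Aggregate pathogenicity g scores per gene
#'
#' Sums the MutPred-style g scores (probability, 0-1, that an amino acid
#' substitution is deleterious) of nonsynonymous mutations per gene, and
#' averages the sums over all protein-coding genes; genes with no scored
#' mutation contribute a sum of 0 to the average.
#'
#' @param gscore_records tibble with `name`, `gene`, `g_score`.
#' @param annotation annotation whose protein genes define the gene universe.
#' @return tibble of per-gene sums; attribute `average_of_sums` is the
#'   pooled average.
#' @export
aggregate_gscores <- function(gscore_records, annotation) {
  gscore_records <- as_tibble(gscore_records)
  if (nrow(gscore_records) > 0L &&
      any(gscore_records$g_score < 0 | gscore_records$g_score > 1)) {
    abort("g scores must lie in [0, 1]")
  }
  prot <- annotation[annotation$category == "protein", , drop = FALSE]
  sums <- gscore_records |>
    group_by(gene = .data$gene) |>
    summarise(g_score_sum = sum(.data$g_score), .groups = "drop")
  out <- tibble(gene = prot$gene) |>
    left_join(sums, by = "gene") |>
    mutate(g_score_sum = .data$g_score_sum %|na|% 0)
  attr(out, "average_of_sums") <- mean(out$g_score_sum)
  out
}
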