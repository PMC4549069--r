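# Pileup, clonality tiers and variant calling ------------------------------

#' Pile up consensus calls against the reference
#'
#' Tallies per-position base calls from consensus records (DCS for variant
#' calling; SSCS pileups are used for the single-strand error comparison).
#' `N` calls are excluded from depth. On a circular reference, records
#' running past the end wrap to position 1. Indel events carried by the
#' records are tallied per position into the `indels` attribute.
#'
#' @param records consensus tibble with `start` and `bases` (and optionally
#'   `indels`).
#' @param reference an `mt_reference`.
#' @return tibble with one row per covered position: `position`, `ref_base`,
#'   counts `A`, `C`, `G`, `T` and `depth` (sum of the four). Attribute
#'   `indels` holds a tibble of `(position, kind, length, seq, count)`.
#' @export
pileup <- function(records, reference) {
  stopifnot(inherits(reference, "mt_reference"))
  records <- records[nchar(records$bases) > 0L, , drop = FALSE]
  if (nrow(records) == 0L) {
    out <- tibble(position = integer(0), ref_base = character(0),
                  A = integer(0), C = integer(0), G = integer(0),
                  T = integer(0), depth = integer(0))
    attr(out, "indels") <- empty_indel_pileup()
    return(out)
  }
  len <- nchar(records$bases)
  if (!reference$circular &&
      any(records$start < 1L | records$start + len - 1L > reference$length)) {
    abort("consensus record beyond linear reference bounds")
  }
  pos <- unlist(map2(records$start, len, function(s, l) seq.int(s, s + l - 1L)),
                use.names = FALSE)
  pos <- wrap_position(reference, pos)
  base <- unlist(strsplit(records$bases, ""), use.names = FALSE)
  keep <- base != "N"
  tab <- tibble(position = pos[keep], base = base[keep]) |>
    count(.data$position, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in DNA_BASES) {
    if (!b %in% names(tab)) tab[[b]] <- 0L
  }
  tab <- tab |>
    mutate(
      ref_base = ref_base(reference, .data$position),
      depth = .data$A + .data$C + .data$G + .data$T
    ) |>
    select("position", "ref_base", all_of(DNA_BASES), "depth") |>
    arrange(.data$position)
  attr(tab, "indels") <- pileup_indels(records, reference)
  tab
}

empty_indel_pileup <- function() {
  tibble(position = integer(0), kind = character(0), length = integer(0),
         seq = character(0), count = integer(0))
}

pileup_indels <- function(records, reference) {
  if (!"indels" %in% names(records)) return(empty_indel_pileup())
  nonempty <- which(map_int(records$indels, NROW) > 0L)
  if (length(nonempty) == 0L) return(empty_indel_pileup())
  ev <- bind_rows(map(records$indels[nonempty], unlist_indels))
  if (nrow(ev) == 0L) return(empty_indel_pileup())
  ev |>
    mutate(position = wrap_position(reference, .data$position)) |>
    count(.data$position, .data$kind, .data$length, .data$seq,
          name = "count")
}

#' Classify clonality percentages into heteroplasmy tiers
#'
#' Cutoffs: rare (0, 0.5], low-heteroplasmic (0.5, 20], high-heteroplasmic
#' (20, 95), homoplasmic \[95, 100\].
#'
#' @param clonality_pct numeric vector in (0, 100].
#' @return character vector of `rare`, `low_het`, `high_het`, `homoplasmic`.
#' @export
#' @examples
#' classify_clonality(c(0.5, 20, 94.99, 95))
classify_clonality <- function(clonality_pct) {
  if (any(!is.finite(clonality_pct)) ||
      any(clonality_pct <= 0 | clonality_pct > 100)) {
    abort("clonality must lie in (0, 100]")
  }
  case_when(
    clonality_pct <= 0.5 ~ "rare",
    clonality_pct <= 20 ~ "low_het",
    clonality_pct < 95 ~ "high_het",
    TRUE ~ "homoplasmic"
  )
}

TIER_LEVELS <- c("rare", "low_het", "high_het", "homoplasmic")

#' Call clonality-tiered variants from a pileup
#'
#' Emits one call per (position, alternate allele) with at least one mutant
#' consensus call at positions whose depth reaches `min_depth`; positions
#' below it still count toward frequency denominators but are too shallow
#' for a meaningful clonality. Indel events from the pileup's `indels`
#' attribute are tiered by the same cutoffs but flagged with
#' `variant_class` `ins`/`del` so they stay out of point-mutation spectra.
#'
#' @param pileups a [pileup()] tibble.
#' @param min_depth minimum consensus depth for tier assignment (default
#'   100).
#' @return tibble of calls: `name` (HGVS-like `m.<pos><ref>><alt>`),
#'   `position`, `ref`, `alt`, `variant_class`, `mutant_count`, `depth`,
#'   `clonality_pct`, `tier`.
#' @export
call_variants <- function(pileups, min_depth = 100L) {
  deep <- filter(pileups, .data$depth >= min_depth)
  long <- deep |>
    tidyr::pivot_longer(all_of(DNA_BASES), names_to = "alt",
                        values_to = "mutant_count") |>
    filter(.data$alt != .data$ref_base, .data$mutant_count > 0L) |>
    mutate(
      ref = .data$ref_base,
      variant_class = "snv",
      clonality_pct = 100 * .data$mutant_count / .data$depth,
      tier = classify_clonality(.data$clonality_pct),
      name = paste0("m.", .data$position, .data$ref, ">", .data$alt)
    ) |>
    select("name", "position", "ref", "alt", "variant_class",
           "mutant_count", "depth", "clonality_pct", "tier")
  ind <- attr(pileups, "indels") %||% empty_indel_pileup()
  if (nrow(ind) > 0L) {
    depth_at <- setNames(pileups$depth, pileups$position)
    ind <- ind |>
      mutate(depth = unname(depth_at[as.character(.data$position)])) |>
      filter(!is.na(.data$depth), .data$depth >= min_depth) |>
      mutate(
        ref = "-",
        alt = if_else(.data$kind == "ins", .data$seq,
                      paste0("del", .data$length)),
        variant_class = .data$kind,
        mutant_count = .data$count,
        clonality_pct = 100 * .data$count / .data$depth,
        tier = classify_clonality(.data$clonality_pct),
        name = paste0("m.", .data$position, .data$kind, .data$alt)
      ) |>
      select("name", "position", "ref", "alt", "variant_class",
             "mutant_count", "depth", "clonality_pct", "tier")
    long <- bind_rows(long, ind)
  }
  arrange(long, .data$position, .data$alt)
}

#' Tier-specific mutation frequency with Wilson interval
#'
#' The mutation frequency of a tier is the number of unique mutants divided
#' by the total number of sequenced (consensus) nucleotides: each distinct
#' (position, alternate allele) point mutation counts once regardless of how
#' many molecules carry it, and the denominator is the summed depth over all
#' evaluable positions. A 95% Wilson score interval is attached.
#'
#' @param variants a [call_variants()] tibble.
#' @param pileups the matching [pileup()] tibble (denominator source).
#' @param tiers tiers to report (default all four).
#' @param conf_level confidence level for the Wilson interval.
#' @return tibble with one row per tier: `tier`, `unique_mutation_count`,
#'   `total_sequenced_nt`, `frequency`, `ci_low`, `ci_high`.
#' @export
mutation_frequency <- function(variants, pileups, tiers = TIER_LEVELS,
                               conf_level = 0.95) {
  denom <- sum(pileups$depth)
  if (denom == 0) abort("zero sequenced nucleotides in pileup")
  point <- filter(variants, .data$variant_class == "snv")
  purrr::map_dfr(tiers, function(tr) {
    k <- point |>
      filter(.data$tier == tr) |>
      distinct(.data$position, .data$alt) |>
      nrow()
    ci <- wilson_interval(k, denom, conf_level)
    tibble(
      tier = tr,
      unique_mutation_count = k,
      total_sequenced_nt = denom,
      frequency = k / denom,
      ci_low = ci$low,
      ci_high = ci$high
    )
  })
}

#' Distribution of variants across clonality tiers
#'
#' Percentage of unique variants falling in each tier, over all called
#' variants (0-100% clonality); the four percentages sum to 100.
#'
#' @param variants a [call_variants()] tibble.
#' @return tibble `tier`, `n`, `percentage` (all four tiers, zero-filled).
#' @export
tier_distribution <- function(variants) {
  u <- distinct(variants, .data$position, .data$alt, .data$variant_class,
                .data$tier)
  if (nrow(u) == 0L) abort("no variants to summarise")
  counts <- table(factor(u$tier, levels = TIER_LEVELS))
  tibble(
    tier = TIER_LEVELS,
    n = as.integer(counts),
    percentage = 100 * as.integer(counts) / nrow(u)
  )
}

#' Annotate point variants with gene and codon consequence
#'
#' Expands each point variant into zero or more (variant, gene) rows via
#' [codon_change()]; a variant inside two overlapping protein genes is
#' listed once per gene. Non-protein positions get the covering gene (if
#' any) with `effect = NA`.
#'
#' @param variants a [call_variants()] tibble.
#' @param annotation,reference annotation and reference objects.
#' @return tibble of variant-by-gene rows with `gene`, `category`, `effect`,
#'   `ref_aa`, `alt_aa`, `codon_index` joined to the variant columns.
#' @export
annotate_variants <- function(variants, annotation, reference) {
  point <- filter(variants, .data$variant_class == "snv")
  if (nrow(point) == 0L) {
    return(mutate(point, gene = character(0), category = character(0),
                  effect = character(0)))
  }
  rows <- purrr::pmap(
    list(point$position, point$ref, point$alt, seq_len(nrow(point))),
    function(pos, ref, alt, i) {
      cc <- codon_change(pos, ref, alt, annotation, reference)
      if (nrow(cc) > 0L) {
        cc$category <- "protein"
        return(mutate(cc, .row = i))
      }
      cov <- covering_genes(pos, annotation, reference)
      tibble(
        gene = if (nrow(cov)) cov$gene else NA_character_,
        codon_index = NA_integer_, ref_codon = NA_character_,
        alt_codon = NA_character_, ref_aa = NA_character_,
        alt_aa = NA_character_, effect = NA_character_,
        category = if (nrow(cov)) cov$category else "intergenic",
        .row = i
      )
    }
  )
  ann_rows <- bind_rows(rows)
  point$.row <- seq_len(nrow(point))
  left_join(point, ann_rows, by = ".row") |> select(-".row")
}

covering_genes <- function(position, annotation, reference) {
  hit <- map_lgl(seq_len(nrow(annotation)), function(i) {
    position %in% record_positions(as.list(annotation[i, ]), reference)
  })
  annotation[hit & annotation$category != "noncoding",
             c("gene", "category"), drop = FALSE]
}
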