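# End-to-end orchestration --------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Collects paths/objects and parameters for [run_pipeline()]. Reads come
#' from exactly one of `reads` (a tibble), `sam_path`, or `simulate` (a list
#' with `planted`, `n_molecules` and optionally `sim` = a
#' [duplex_sim_config()]). Default parameters: tier cutoffs
#' 0.5/20/95% clonality, end clipping 5 + 6 bases, 95% confidence.
#'
#' @param reference an `mt_reference` or FASTA path.
#' @param annotation an `mt_annotation`, TSV path, or `NULL` to skip
#'   gene/effect annotation.
#' @param reads,sam_path,simulate the read source (exactly one non-`NULL`).
#' @param min_family_size,consensus_threshold SSCS parameters.
#' @param clip5,clip3 consensus end clipping.
#' @param min_depth minimum DCS depth for tier assignment.
#' @param conf_level Wilson/confidence level.
#' @param spectrum_tier tier whose variants feed the spectra (default
#'   `"rare"`).
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed seed governing any simulation randomness.
#' @return a `mito_pipeline_config` list.
#' @export
mito_pipeline_config <- function(reference, annotation = NULL,
                                 reads = NULL, sam_path = NULL,
                                 simulate = NULL,
                                 min_family_size = 3L,
                                 consensus_threshold = 0.7,
                                 clip5 = 5L, clip3 = 6L,
                                 min_depth = 100L,
                                 conf_level = 0.95,
                                 spectrum_tier = "rare",
                                 out_dir = NULL,
                                 seed = 1L) {
  n_sources <- sum(!is.null(reads), !is.null(sam_path), !is.null(simulate))
  if (n_sources != 1L) {
    abort("provide exactly one of reads, sam_path or simulate")
  }
  structure(
    list(reference = reference, annotation = annotation, reads = reads,
         sam_path = sam_path, simulate = simulate,
         min_family_size = as.integer(min_family_size),
         consensus_threshold = consensus_threshold,
         clip5 = as.integer(clip5), clip3 = as.integer(clip3),
         min_depth = as.integer(min_depth), conf_level = conf_level,
         spectrum_tier = spectrum_tier, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "mito_pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

validate_config <- function(config) {
  if (is.character(config$reference) && !file.exists(config$reference)) {
    abort("[stage validate] reference path does not exist")
  }
  if (is.character(config$annotation) && !file.exists(config$annotation)) {
    abort("[stage validate] annotation path does not exist")
  }
  if (!is.null(config$sam_path) && !file.exists(config$sam_path)) {
    abort("[stage validate] SAM path does not exist")
  }
  invisible(config)
}

#' Run the duplex consensus pipeline end to end
#'
#' Consensus building (SSCS then DCS), end clipping, pileup, tiered variant
#' calling, tier frequencies with Wilson intervals, the SSCS/DCS rare-
#' frequency comparison, substitution and context spectra, and optional
#' gene/effect annotation. Deterministic given the configuration (rerunning
#' writes byte-identical outputs).
#'
#' @param config a [mito_pipeline_config()].
#' @return a `mito_dx_report` list: `yields` (read/family/consensus
#'   bookkeeping), `variants`, `variant_effects` (when annotated),
#'   `frequencies` (per-tier DCS), `sscs_rare`, `sscs_dcs_ratio`,
#'   `tier_distribution`, `spectrum12`, `spectrum6`, `context`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mito_pipeline_config"))
  validate_config(config)
  reference <- with_stage("reference", {
    if (inherits(config$reference, "mt_reference")) config$reference
    else load_reference(config$reference)
  })
  annotation <- with_stage("annotation", {
    if (is.null(config$annotation)) NULL
    else if (inherits(config$annotation, "mt_annotation")) config$annotation
    else load_annotation(config$annotation, reference)
  })
  sim_truth <- NULL
  reads <- with_stage("reads", {
    if (!is.null(config$reads)) {
      as_tibble(config$reads)
    } else if (!is.null(config$sam_path)) {
      read_tagged_sam(config$sam_path)
    } else {
      sim <- config$simulate
      pop <- simulate_population(reference,
                                 sim$planted %||%
                                   tibble(position = integer(0),
                                          alt = character(0),
                                          clonality_pct = numeric(0)),
                                 sim$n_molecules, seed = config$seed)
      cfg <- sim$sim %||% duplex_sim_config(seed = config$seed)
      ds <- simulate_duplex_reads(pop, cfg)
      sim_truth <- ds$truth
      ds$reads
    }
  })
  families <- with_stage("consensus",
                         suppressWarnings(group_reads_by_tag(reads)))
  sscs <- with_stage("consensus", sscs_from_families(
    families, config$min_family_size, config$consensus_threshold
  ))
  dcs <- with_stage("consensus", dcs_from_sscs(sscs))
  sscs_clipped <- clip_ends(sscs, config$clip5, config$clip3)
  dcs_clipped <- clip_ends(dcs, config$clip5, config$clip3)
  dcs_pile <- with_stage("pileup", pileup(dcs_clipped, reference))
  sscs_pile <- with_stage("pileup", pileup(sscs_clipped, reference))
  variants <- with_stage("call", call_variants(dcs_pile, config$min_depth))
  sscs_variants <- with_stage("call",
                              call_variants(sscs_pile, config$min_depth))
  freqs <- with_stage("frequency", mutation_frequency(
    variants, dcs_pile, conf_level = config$conf_level
  ))
  sscs_rare <- with_stage("frequency", mutation_frequency(
    sscs_variants, sscs_pile, tiers = "rare", conf_level = config$conf_level
  ))
  dcs_rare_freq <- freqs$frequency[freqs$tier == "rare"]
  ratio <- if (dcs_rare_freq > 0) sscs_rare$frequency / dcs_rare_freq
           else NA_real_
  tier_dist <- if (nrow(variants) > 0L) tier_distribution(variants) else NULL
  spec_vars <- filter(variants, .data$tier == config$spectrum_tier)
  spectrum12 <- with_stage("spectrum", substitution_spectrum(
    spec_vars, dcs_pile, conf_level = config$conf_level
  ))
  context <- with_stage("spectrum", context_spectrum(spec_vars, reference))
  effects <- if (!is.null(annotation) && nrow(variants) > 0L) {
    with_stage("annotate", annotate_variants(variants, annotation, reference))
  } else {
    NULL
  }
  report <- structure(
    list(
      reference_name = reference$name,
      reference_length = reference$length,
      spectrum_tier = config$spectrum_tier,
      yields = tibble(
        n_reads = nrow(reads),
        n_dropped_reads = attr(families, "n_dropped") %||% 0L,
        n_families = nrow(families),
        n_sscs = nrow(sscs),
        n_unpaired_sscs = attr(dcs, "n_unpaired") %||% 0L,
        n_dcs = nrow(dcs),
        sscs_sequenced_nt = sum(sscs_pile$depth),
        dcs_sequenced_nt = sum(dcs_pile$depth),
        mean_sscs_depth = mean(sscs_pile$depth),
        mean_dcs_depth = mean(dcs_pile$depth)
      ),
      variants = variants,
      variant_effects = effects,
      frequencies = freqs,
      sscs_rare = sscs_rare,
      sscs_dcs_ratio = ratio,
      tier_distribution = tier_dist,
      spectrum12 = spectrum12,
      spectrum6 = collapse_spectrum(spectrum12),
      context = context,
      truth = sim_truth,
      dcs_pileup = dcs_pile
    ),
    class = "mito_dx_report"
  )
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$variants, out("variants.tsv"))
  readr::write_tsv(report$frequencies, out("frequencies.tsv"))
  readr::write_tsv(as_tibble(report$spectrum12), out("spectrum_12type.tsv"))
  readr::write_tsv(report$spectrum6, out("spectrum_6type.tsv"))
  readr::write_tsv(as_tibble(report$context), out("context_96class.tsv"))
  if (!is.null(report$variant_effects)) {
    readr::write_tsv(report$variant_effects, out("variant_effects.tsv"))
  }
  summary <- c(
    as.list(report$yields),
    list(sscs_rare_frequency = report$sscs_rare$frequency,
         dcs_rare_frequency =
           report$frequencies$frequency[report$frequencies$tier == "rare"],
         sscs_dcs_ratio = report$sscs_dcs_ratio)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mito_dx_report <- function(x, ...) {
  cat(sprintf("<mito_dx_report> %s (%d bp)\n", x$reference_name,
              x$reference_length))
  cat(sprintf("  reads %d -> families %d -> SSCS %d -> DCS %d\n",
              x$yields$n_reads, x$yields$n_families, x$yields$n_sscs,
              x$yields$n_dcs))
  cat(sprintf("  DCS nt %s, variants %d\n",
              format(x$yields$dcs_sequenced_nt, big.mark = ","),
              nrow(x$variants)))
  invisible(x)
}

# proportion test that tolerates empty marginals (no evidence -> p = 1)
safe_two_proportion_test <- function(k1, n1, k2, n2) {
  if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2)) {
    return(tibble(statistic = 0, p_value = 1,
                  estimate1 = k1 / n1, estimate2 = k2 / n2,
                  method = "degenerate table: identical margins"))
  }
  two_proportion_test(k1, n1, k2, n2)
}

#' Compare two pipeline reports
#'
#' Per-tier mutation-frequency comparison, per-substitution-type
#' comparison, context-class comparisons (for classes observed in either
#' sample) — all via the two-sample proportion test with continuity
#' correction — plus shared and exclusive variant sets.
#'
#' @param report_a,report_b `mito_dx_report` objects over the same
#'   reference.
#' @return a `mito_dx_comparison` list with `tier_tests`, `type_tests`,
#'   `context_tests`, `shared_variants`, `only_a`, `only_b`.
#' @export
compare_samples <- function(report_a, report_b) {
  if (!identical(report_a$reference_name, report_b$reference_name) ||
      !identical(report_a$reference_length, report_b$reference_length)) {
    abort("reports reference different genomes")
  }
  tiers <- purrr::map_dfr(TIER_LEVELS, function(tr) {
    fa <- report_a$frequencies[report_a$frequencies$tier == tr, ]
    fb <- report_b$frequencies[report_b$frequencies$tier == tr, ]
    res <- safe_two_proportion_test(
      fa$unique_mutation_count, fa$total_sequenced_nt,
      fb$unique_mutation_count, fb$total_sequenced_nt
    )
    mutate(res, tier = tr, .before = 1)
  })
  types <- purrr::map_dfr(substitution_types(), function(tp) {
    ra <- report_a$spectrum12[report_a$spectrum12$type == tp, ]
    rb <- report_b$spectrum12[report_b$spectrum12$type == tp, ]
    res <- safe_two_proportion_test(ra$count, ra$denominator,
                                    rb$count, rb$denominator)
    mutate(res, type = tp, .before = 1)
  })
  ctx_a <- report_a$context
  ctx_b <- report_b$context
  seen <- ctx_a$count > 0 | ctx_b$count > 0
  context_tests <- purrr::map_dfr(which(seen), function(i) {
    compare_context_fractions(ctx_a, ctx_b,
                              ctx_a$substitution[i], ctx_a$context[i])
  })
  va <- distinct(report_a$variants, .data$position, .data$ref, .data$alt)
  vb <- distinct(report_b$variants, .data$position, .data$ref, .data$alt)
  structure(
    list(
      tier_tests = tiers,
      type_tests = types,
      context_tests = context_tests,
      shared_variants = inner_join(va, vb, by = c("position", "ref", "alt")),
      only_a = anti_join(va, vb, by = c("position", "ref", "alt")),
      only_b = anti_join(vb, va, by = c("position", "ref", "alt"))
    ),
    class = "mito_dx_comparison"
  )
}
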