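# Synthetic duplex-read generator with planted truth -----------------------
#
# The generator emulates what a duplex-sequencing library of a circular
# mitochondrial genome looks like to the consensus caller: a population of
# source molecules carrying planted variants at chosen clonalities, two
# strand families per molecule joined by a double-stranded tag, PCR-lineage
# errors shared by all reads of one strand family, and independent per-read
# sequencing errors at the 1e-2 to 1e-3 background typical of standard
# short-read chemistry. Every stochastic choice flows from one seed, so all
# outputs are reproducible bit for bit.

#' Build a toy circular reference with a simple gene layout
#'
#' Generates a random sequence and lays out one gene per layout entry from
#' position 1 onward, with the remainder annotated as noncoding. Protein
#' gene widths are rounded down to whole codons.
#'
#' @param length genome length (>= 60).
#' @param gene_layout tibble with columns `category` and `fraction`
#'   (optionally `coding_strand`), or a named numeric vector such as
#'   `c(protein = 0.3)`. Fractions must sum to at most 1.
#' @param seed RNG seed.
#' @return list with `reference` and `annotation`.
#' @export
make_toy_reference <- function(length, gene_layout, seed = 1L) {
  length <- as.integer(length)
  if (length < 60L) abort("toy reference must be at least 60 bp")
  if (is.numeric(gene_layout) && !is.null(names(gene_layout))) {
    gene_layout <- tibble(category = names(gene_layout),
                          fraction = unname(gene_layout))
  }
  gene_layout <- as_tibble(gene_layout)
  if (!"coding_strand" %in% names(gene_layout)) {
    gene_layout$coding_strand <- "L"
  }
  if (sum(gene_layout$fraction) > 1 + 1e-12) {
    abort("gene layout fractions sum to more than 1")
  }
  withr::with_seed(seed, {
    seq <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    reference <- new_mt_reference("toy_mt", seq, circular = TRUE)
    rows <- list()
    cursor <- 1L
    counts <- c(protein = 0L, tRNA = 0L, rRNA = 0L, noncoding = 0L)
    for (i in seq_len(nrow(gene_layout))) {
      cat_i <- gene_layout$category[i]
      width <- floor(gene_layout$fraction[i] * length)
      if (cat_i == "protein") {
        width <- (width %/% 3L) * 3L
        if (width < 3L) abort("protein gene shorter than one codon")
      }
      if (width < 1L) abort("gene layout entry has zero width")
      counts[cat_i] <- counts[cat_i] + 1L
      rows[[i]] <- tibble(
        gene = paste0(toupper(substr(cat_i, 1, 1)), counts[cat_i]),
        category = cat_i,
        start = cursor,
        end = cursor + width - 1L,
        coding_strand = gene_layout$coding_strand[i],
        frame_offset = 0L
      )
      cursor <- cursor + width
    }
    ann <- bind_rows(rows)
    if (cursor <= length) {
      ann <- bind_rows(ann, tibble(
        gene = "NC1", category = "noncoding", start = cursor, end = length,
        coding_strand = "L", frame_offset = 0L
      ))
    }
    list(reference = reference, annotation = annotate_tbl(ann, reference))
  })
}

#' Plant variants into a molecule population
#'
#' Each of `n_molecules` source molecules carries each planted variant
#' independently with probability `clonality_pct / 100`, so realised
#' carrier counts are binomial; a clonality of 100 puts the variant on
#' every molecule. The realised counts and carrier sets form the truth
#' table used by recovery tests.
#'
#' @param reference an `mt_reference`.
#' @param planted_variants tibble with `position`, `alt`, `clonality_pct`
#'   (positions distinct, clonalities in (0, 100]); may be empty.
#' @param n_molecules number of source molecules.
#' @param seed RNG seed.
#' @return `duplex_population` object: reference, molecule count, and the
#'   planted-variant truth tibble (with `ref`, `expected_tier`,
#'   `realized_count`, `carriers`).
#' @export
simulate_population <- function(reference, planted_variants, n_molecules,
                                seed = 1L) {
  planted_variants <- as_tibble(planted_variants)
  if (nrow(planted_variants) > 0L) {
    if (anyDuplicated(planted_variants$position)) {
      abort("planted positions must be distinct")
    }
    if (any(planted_variants$clonality_pct <= 0 |
            planted_variants$clonality_pct > 100)) {
      abort("planted clonality must lie in (0, 100]")
    }
  }
  withr::with_seed(seed, {
    planted <- planted_variants
    if (nrow(planted) > 0L) {
      planted$ref <- ref_base(reference, planted$position)
      if (any(planted$ref == planted$alt)) {
        abort("planted alt equals the reference base")
      }
      planted$expected_tier <- classify_clonality(planted$clonality_pct)
      planted$carriers <- map(planted$clonality_pct, function(c_pct) {
        if (c_pct == 100) seq_len(n_molecules)
        else which(runif(n_molecules) < c_pct / 100)
      })
      planted$realized_count <- lengths(planted$carriers)
    } else {
      planted <- tibble(position = integer(0), alt = character(0),
                        clonality_pct = numeric(0), ref = character(0),
                        expected_tier = character(0), carriers = list(),
                        realized_count = integer(0))
    }
    structure(
      list(reference = reference, n_molecules = as.integer(n_molecules),
           planted = planted),
      class = "duplex_population"
    )
  })
}

#' Simulation configuration for duplex reads
#'
#' @param read_length bases per read (= fragment length here).
#' @param family_size reads per strand family: `list(kind = "constant",
#'   size = 3)` or `list(kind = "lognormal", meanlog = log(4), sdlog = 0.5,
#'   min = 1)` (the default; real family-size distributions are heavy
#'   tailed).
#' @param pcr_error_rate per-base probability of a strand-lineage (PCR)
#'   error, shared by all reads of that strand family.
#' @param seq_error_rate per-base, per-read sequencing error probability.
#' @param tag_half_length bases per duplex-tag half.
#' @param wrap_fragments allow fragments to span the circular origin.
#' @param seed RNG seed for read simulation.
#' @return a `duplex_sim_config` list.
#' @export
duplex_sim_config <- function(read_length = 100L,
                              family_size = list(kind = "lognormal",
                                                 meanlog = log(4),
                                                 sdlog = 0.5, min = 1L),
                              pcr_error_rate = 1e-4,
                              seq_error_rate = 1e-2,
                              tag_half_length = 10L,
                              wrap_fragments = TRUE,
                              seed = 1L) {
  stopifnot(pcr_error_rate >= 0, pcr_error_rate < 1,
            seq_error_rate >= 0, seq_error_rate < 1,
            read_length >= 12L, tag_half_length >= 4L)
  structure(
    list(read_length = as.integer(read_length), family_size = family_size,
         pcr_error_rate = pcr_error_rate, seq_error_rate = seq_error_rate,
         tag_half_length = as.integer(tag_half_length),
         wrap_fragments = isTRUE(wrap_fragments), seed = as.integer(seed)),
    class = "duplex_sim_config"
  )
}

draw_family_sizes <- function(n, family_size) {
  kind <- family_size$kind %||% "constant"
  if (kind == "constant") {
    rep(as.integer(family_size$size), n)
  } else if (kind == "lognormal") {
    pmax(as.integer(family_size$min %||% 1L),
         as.integer(round(rlnorm(n, family_size$meanlog,
                                 family_size$sdlog))))
  } else {
    abort("unknown family size distribution kind")
  }
}

# substitute each base for a uniformly chosen different base
OTHER_BASES <- matrix(
  c("C", "G", "T",
    "A", "G", "T",
    "A", "C", "T",
    "A", "C", "G"),
  nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, NULL)
)

#' Simulate tagged duplex reads from a molecule population
#'
#' Each molecule becomes one fragment at a uniformly random (circular)
#' start, with a fresh duplex tag. Both strand families (`ab` and `ba`) are
#' emitted with sizes from the configured distribution. PCR-lineage errors
#' are applied to each strand template before reads are sampled, so they are
#' shared within a strand family and removable only at the duplex stage;
#' per-read sequencing errors are independent. Reads of `ba` families are
#' reverse-complement (machine) oriented with `reversed = TRUE`.
#'
#' @param population a [simulate_population()] object.
#' @param config a [duplex_sim_config()].
#' @return `duplex_sim` object: `reads` tibble (`qname`, `tag`,
#'   `strand_order`, `start`, `seq`, `reversed`, `molecule`) and `truth`
#'   (planted table, PCR and sequencing error events).
#' @export
simulate_duplex_reads <- function(population, config) {
  stopifnot(inherits(population, "duplex_population"),
            inherits(config, "duplex_sim_config"))
  ref <- population$reference
  L <- ref$length
  rl <- config$read_length
  if (rl > L) abort("read length exceeds molecule (reference) length")
  n <- population$n_molecules
  withr::with_seed(config$seed, {
    starts <- if (config$wrap_fragments) {
      sample.int(L, n, replace = TRUE)
    } else {
      sample.int(L - rl + 1L, n, replace = TRUE)
    }
    doubled <- paste0(ref$sequence, substr(ref$sequence, 1L, rl))
    frag <- substring(doubled, starts, starts + rl - 1L)
    # plant variants on carrier molecules whose fragment covers the site
    pl <- population$planted
    for (i in seq_len(nrow(pl))) {
      car <- pl$carriers[[i]]
      if (length(car) == 0L) next
      relpos <- ((pl$position[i] - starts[car]) %% L) + 1L
      inside <- relpos <= rl
      idx <- car[inside]
      substring(frag[idx], relpos[inside], relpos[inside]) <- pl$alt[i]
    }
    # two strand templates per molecule, PCR lineage errors applied per strand
    templates <- rep(frag, each = 2L)
    n_strand <- 2L * n
    k_pcr <- rbinom(1L, n_strand * rl, config$pcr_error_rate)
    pcr_events <- tibble(strand = integer(0), position = integer(0),
                         from = character(0), to = character(0))
    if (k_pcr > 0L) {
      cells <- sample.int(n_strand * rl, k_pcr)
      s_idx <- (cells - 1L) %/% rl + 1L
      p_idx <- (cells - 1L) %% rl + 1L
      from <- substring(templates[s_idx], p_idx, p_idx)
      to <- OTHER_BASES[cbind(match(from, DNA_BASES),
                              sample.int(3L, k_pcr, replace = TRUE))]
      for (e in seq_len(k_pcr)) { # few events; duplicates per strand are fine
        substr(templates[s_idx[e]], p_idx[e], p_idx[e]) <- to[e]
      }
      mol <- (s_idx - 1L) %/% 2L + 1L
      pcr_events <- tibble(
        strand = s_idx,
        position = ((starts[mol] + p_idx - 2L) %% L) + 1L,
        from = from, to = to
      )
    }
    sizes <- draw_family_sizes(n_strand, config$family_size)
    strand_of_read <- rep(seq_len(n_strand), sizes)
    n_reads <- length(strand_of_read)
    # expand templates to a read-by-position character matrix
    Tm <- matrix(unlist(strsplit(templates, ""), use.names = FALSE),
                 nrow = n_strand, byrow = TRUE)
    R <- Tm[strand_of_read, , drop = FALSE]
    k_seq <- rbinom(1L, n_reads * rl, config$seq_error_rate)
    seq_events <- tibble(read = integer(0), position = integer(0))
    if (k_seq > 0L) {
      cells <- sample.int(n_reads * rl, k_seq)
      # matrix is column-major: cell -> (row = read, col = position)
      r_idx <- (cells - 1L) %% n_reads + 1L
      c_idx <- (cells - 1L) %/% n_reads + 1L
      cur <- R[cells]
      R[cells] <- OTHER_BASES[cbind(match(cur, DNA_BASES),
                                    sample.int(3L, k_seq, replace = TRUE))]
      mol <- (strand_of_read[r_idx] - 1L) %/% 2L + 1L
      seq_events <- tibble(
        read = r_idx,
        position = ((starts[mol] + c_idx - 2L) %% L) + 1L
      )
    }
    seqs <- do.call(paste0, asplit(R, 2))
    # duplex tags: alpha-beta on strand 1 (ab), beta-alpha on strand 2 (ba)
    h <- config$tag_half_length
    halves <- matrix(sample(DNA_BASES, 2L * n * h, replace = TRUE),
                     nrow = 2L * n)
    half_str <- do.call(paste0, asplit(halves, 2))
    alpha <- half_str[seq_len(n)]
    beta <- half_str[n + seq_len(n)]
    strand_tag <- as.vector(rbind(paste0(alpha, beta), paste0(beta, alpha)))
    strand_order <- rep(c("ab", "ba"), n)
    reversed_strand <- rep(c(FALSE, TRUE), n)
    tag <- strand_tag[strand_of_read]
    order <- strand_order[strand_of_read]
    rev_flag <- reversed_strand[strand_of_read]
    seqs[rev_flag] <- revcomp(seqs[rev_flag])
    molecule <- (strand_of_read - 1L) %/% 2L + 1L
    reads <- tibble(
      qname = paste0("mol", molecule, "_r", sequence(sizes),
                     "#", tag, "/", order),
      tag = tag,
      strand_order = order,
      start = starts[molecule],
      seq = seqs,
      reversed = rev_flag,
      molecule = molecule
    )
    truth <- list(
      planted = select(pl, -"carriers"),
      n_pcr_errors = k_pcr,
      n_seq_errors = k_seq,
      pcr_events = pcr_events,
      seq_events = seq_events
    )
    structure(list(reads = reads, truth = truth, config = config),
              class = "duplex_sim")
  })
}
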