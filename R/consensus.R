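# Duplex family grouping and consensus building ----------------------------
#
# A duplex tag is a random double-stranded barcode whose two halves (alpha,
# beta) read in opposite orders from the two strands of one source molecule:
# reads from one strand carry alpha-beta ("ab"), reads from the other carry
# beta-alpha ("ba"). All reads sharing (tag, strand order, alignment start)
# form one single-strand family; the two complementary families of a molecule
# are matched through the canonical tag (the lexicographically smaller of the
# two half orders).

#' Group duplex-tagged reads into single-strand families
#'
#' Input is a read tibble with columns `seq` (base string as sequenced),
#' `start` (1-based reference position), `reversed` (aligned to the reverse
#' strand), and either `tag` + `strand_order` columns or a `qname` ending in
#' `#<tag>/<ab|ba>` from which they are parsed. Reads with an unparseable tag
#' (odd-length or non-ACGT halves, missing strand order) are dropped with a
#' warning; the count is kept in attribute `n_dropped`. Sequences are
#' normalised to reference orientation (reverse-complemented when
#' `reversed`), so downstream consensus calls are strand-representation
#' invariant. Families mixing alignment starts are split, not averaged.
#'
#' @param reads tibble of tagged reads.
#' @return tibble of families: `family_id`, `tag`, `canonical_tag`,
#'   `strand_order`, `start`, `n_reads`, `seqs` (list of reference-oriented
#'   base strings) and, when present in the input, `indels` (list of indel
#'   event tibbles).
#' @export
group_reads_by_tag <- function(reads) {
  reads <- as_tibble(reads)
  if (!all(c("tag", "strand_order") %in% names(reads))) {
    if (!"qname" %in% names(reads)) {
      abort("reads need either tag/strand_order columns or a qname column")
    }
    m <- stringr::str_match(reads$qname, "#([ACGT]+)/(ab|ba)$")
    reads$tag <- m[, 2]
    reads$strand_order <- m[, 3]
  }
  if (!"reversed" %in% names(reads)) reads$reversed <- FALSE
  ok <- !is.na(reads$tag) & !is.na(reads$strand_order) &
    nchar(reads$tag) %% 2L == 0L & nchar(reads$tag) > 0L &
    !grepl("[^ACGT]", reads$tag) &
    reads$strand_order %in% c("ab", "ba")
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warn(sprintf("dropped %d read(s) with unparseable duplex tag", n_dropped))
  }
  reads <- reads[ok, , drop = FALSE]
  reads$seq_ref <- ifelse(reads$reversed, revcomp(reads$seq), reads$seq)
  reads$canonical_tag <- canonical_tag(reads$tag)
  has_indels <- "indels" %in% names(reads)
  fam <- reads |>
    group_by(.data$tag, .data$canonical_tag, .data$strand_order,
             .data$start) |>
    summarise(
      n_reads = n(),
      seqs = list(.data$seq_ref),
      indels = if (has_indels) list(.data$indels) else list(NULL),
      .groups = "drop"
    ) |>
    mutate(family_id = paste0(.data$tag, "/", .data$strand_order, "@",
                              .data$start)) |>
    select("family_id", "tag", "canonical_tag", "strand_order", "start",
           "n_reads", "seqs", "indels")
  if (!has_indels) fam$indels <- NULL
  attr(fam, "n_dropped") <- n_dropped
  fam
}

# canonical tag: lexicographically smaller of alpha-beta and beta-alpha
canonical_tag <- function(tag) {
  h <- nchar(tag) %/% 2L
  swapped <- paste0(substr(tag, h + 1L, nchar(tag)), substr(tag, 1L, h))
  pmin(tag, swapped)
}

# Per-column consensus of a character matrix (reads x positions).
# Returns the majority base where its fraction of non-N calls reaches the
# threshold, otherwise "N". Ties resolve alphabetically, which with a
# threshold above 0.5 can never satisfy the cutoff anyway.
consensus_calls <- function(M, consensus_threshold) {
  counts <- lapply(DNA_BASES, function(b) colSums(M == b))
  tot <- Reduce(`+`, counts)
  idx <- rep(1L, ncol(M))
  cmax <- counts[[1]]
  for (j in 2:4) {
    sel <- counts[[j]] > cmax
    idx[sel] <- j
    cmax[sel] <- counts[[j]][sel]
  }
  out <- DNA_BASES[idx]
  out[tot == 0L | cmax / pmax(tot, 1L) < consensus_threshold] <- "N"
  out
}

#' Build a single-strand consensus sequence (SSCS)
#'
#' Collapses the co-aligned reads of one strand family position by position:
#' the most frequent base is called where its fraction reaches
#' `consensus_threshold`, otherwise `N`. Families smaller than
#' `min_family_size` yield no consensus (`NULL`). Indel events (when the
#' family carries an `indels` list) are kept only when present in at least
#' the threshold fraction of member reads.
#'
#' @param family one row of a [group_reads_by_tag()] tibble (or a list with
#'   the same fields).
#' @param min_family_size minimum reads per strand family (default 3).
#' @param consensus_threshold required base fraction in (0.5, 1] (default
#'   0.7).
#' @return one-row consensus tibble (`kind = "SSCS"`) or `NULL`.
#' @export
build_sscs <- function(family, min_family_size = 3L,
                       consensus_threshold = 0.7) {
  stopifnot(min_family_size >= 1L,
            consensus_threshold > 0.5, consensus_threshold <= 1)
  fam <- as.list(family)
  seqs <- fam$seqs[[1]] %||% fam$seqs
  if (length(seqs) < min_family_size) return(NULL)
  if (length(unique(nchar(seqs))) != 1L) {
    abort("family not co-aligned")
  }
  M <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  bases <- paste(consensus_calls(M, consensus_threshold), collapse = "")
  ind <- consensus_indels(fam$indels, length(seqs), consensus_threshold)
  tibble(
    kind = "SSCS",
    tag = fam$tag,
    canonical_tag = fam$canonical_tag %||% canonical_tag(fam$tag),
    strand_order = fam$strand_order,
    start = fam$start,
    bases = bases,
    family_size = length(seqs),
    indels = list(ind)
  )
}

# indel voting within a family: identical (kind, position, length, seq)
# events supported by >= threshold of reads survive
consensus_indels <- function(indels, n_reads, consensus_threshold) {
  empty <- tibble(kind = character(0), position = integer(0),
                  length = integer(0), seq = character(0))
  if (is.null(indels)) return(empty)
  if (is.list(indels) && !is.data.frame(indels)) {
    indels <- bind_rows(indels[[1]] %||% indels)
  }
  if (is.null(indels) || nrow(indels) == 0L) return(empty)
  indels |>
    count(.data$kind, .data$position, .data$length, .data$seq) |>
    filter(.data$n / n_reads >= consensus_threshold) |>
    select(-"n")
}

#' Build SSCS for a whole family table (vectorised)
#'
#' Equivalent to mapping [build_sscs()] over the rows of `families` but
#' processes all families of equal size and read length in one matrix pass,
#' which is what makes genome-scale simulations tractable.
#'
#' @param families a [group_reads_by_tag()] tibble.
#' @inheritParams build_sscs
#' @return consensus tibble, one row per retained family.
#' @export
sscs_from_families <- function(families, min_family_size = 3L,
                               consensus_threshold = 0.7) {
  stopifnot(min_family_size >= 1L,
            consensus_threshold > 0.5, consensus_threshold <= 1)
  keep <- families$n_reads >= min_family_size
  families <- families[keep, , drop = FALSE]
  if (nrow(families) == 0L) {
    return(empty_consensus_tbl())
  }
  len <- map_int(families$seqs, function(s) {
    u <- unique(nchar(s))
    if (length(u) != 1L) abort("family not co-aligned")
    u
  })
  families$..len <- len
  cohorts <- split(seq_len(nrow(families)),
                   paste(families$n_reads, len, sep = "x"))
  out <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    rows <- cohorts[[ci]]
    fsub <- families[rows, , drop = FALSE]
    n <- fsub$n_reads[1]
    L <- fsub$..len[1]
    f <- nrow(fsub)
    chars <- unlist(strsplit(unlist(fsub$seqs, use.names = FALSE), ""),
                    use.names = FALSE)
    # read-major: dim = (position, read-in-family, family)
    arr <- array(chars, dim = c(L, n, f))
    counts <- lapply(DNA_BASES, function(b) {
      m <- arr == b
      dim(m) <- c(L, n, f)
      # sum over reads: collapse dim 2
      apply_sum_dim2(m, L, n, f)
    })
    tot <- Reduce(`+`, counts)
    idx <- matrix(1L, nrow = L, ncol = f)
    cmax <- counts[[1]]
    for (j in 2:4) {
      sel <- counts[[j]] > cmax
      idx[sel] <- j
      cmax[sel] <- counts[[j]][sel]
    }
    calls <- matrix(DNA_BASES[idx], nrow = L, ncol = f)
    calls[tot == 0L | cmax / pmax(tot, 1L) < consensus_threshold] <- "N"
    bases <- do.call(paste0, asplit(calls, 1))
    ind <- if ("indels" %in% names(fsub)) {
      map2(fsub$indels, fsub$n_reads,
           function(x, nr) consensus_indels(list(x), nr,
                                            consensus_threshold))
    } else {
      rep(list(consensus_indels(NULL, n, consensus_threshold)), f)
    }
    out[[ci]] <- tibble(
      kind = "SSCS",
      tag = fsub$tag,
      canonical_tag = fsub$canonical_tag,
      strand_order = fsub$strand_order,
      start = fsub$start,
      bases = bases,
      family_size = fsub$n_reads,
      indels = ind
    )
  }
  bind_rows(out)
}

# sum a logical (L, n, f) array over its middle dimension -> (L, f) matrix
apply_sum_dim2 <- function(m, L, n, f) {
  dim(m) <- c(L * n, f)
  # columns are families; within a column, reads are contiguous L-blocks
  acc <- matrix(0L, nrow = L, ncol = f)
  for (r in seq_len(n)) {
    acc <- acc + m[((r - 1L) * L + 1L):(r * L), , drop = FALSE]
  }
  acc
}

empty_consensus_tbl <- function() {
  tibble(
    kind = character(0), tag = character(0), canonical_tag = character(0),
    strand_order = character(0), start = integer(0), bases = character(0),
    family_size = integer(0), indels = list()
  )
}

#' Pair two complementary SSCS into a duplex consensus sequence (DCS)
#'
#' A mutation is only scored when it is present as complementary
#' substitutions in both strands of one molecule: over the reference overlap
#' of the `ab` and `ba` consensus, the DCS carries the agreed base and `N`
#' wherever the strands disagree or either strand is `N`. Indel events must
#' be present in both strand consensuses. Without a partner there is no DCS.
#'
#' @param sscs_ab,sscs_ba one-row SSCS tibbles with opposite `strand_order`
#'   and equal canonical tag.
#' @return one-row `DCS` tibble, or `NULL` when the two spans do not overlap.
#' @export
build_dcs <- function(sscs_ab, sscs_ba) {
  a <- as.list(sscs_ab)
  b <- as.list(sscs_ba)
  if (identical(a$strand_order, b$strand_order)) {
    abort("both SSCS have the same strand order; need ab + ba")
  }
  if (!identical(a$canonical_tag, b$canonical_tag)) {
    abort("SSCS canonical tags differ; not the same molecule")
  }
  a_end <- a$start + nchar(a$bases) - 1L
  b_end <- b$start + nchar(b$bases) - 1L
  o_start <- max(a$start, b$start)
  o_end <- min(a_end, b_end)
  if (o_end < o_start) return(NULL)
  sa <- substr(a$bases, o_start - a$start + 1L, o_end - a$start + 1L)
  sb <- substr(b$bases, o_start - b$start + 1L, o_end - b$start + 1L)
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  dc <- ifelse(ca == cb & ca != "N", ca, "N")
  ind_a <- unlist_indels(a$indels)
  ind_b <- unlist_indels(b$indels)
  ind <- inner_join(ind_a, ind_b,
                    by = c("kind", "position", "length", "seq"))
  tibble(
    kind = "DCS",
    tag = a$canonical_tag,
    canonical_tag = a$canonical_tag,
    strand_order = "duplex",
    start = o_start,
    bases = paste(dc, collapse = ""),
    family_size = as.integer(a$family_size + b$family_size),
    indels = list(ind)
  )
}

unlist_indels <- function(x) {
  if (is.null(x)) {
    return(tibble(kind = character(0), position = integer(0),
                  length = integer(0), seq = character(0)))
  }
  if (is.data.frame(x)) return(as_tibble(x))
  unlist_indels(x[[1]])
}

#' Pair all SSCS into DCS (vectorised)
#'
#' Joins `ab` and `ba` consensus rows on canonical tag and pairs each tag's
#' two strand consensuses. Tags present on only one strand are unpaired and
#' contribute no DCS; their count is recorded in attribute `n_unpaired`.
#'
#' @param sscs a consensus tibble from [sscs_from_families()].
#' @return DCS tibble with attribute `n_unpaired`.
#' @export
dcs_from_sscs <- function(sscs) {
  ab <- sscs[sscs$strand_order == "ab", , drop = FALSE]
  ba <- sscs[sscs$strand_order == "ba", , drop = FALSE]
  # a canonical tag must resolve to exactly one family per strand order
  ab <- ab[!duplicated(ab$canonical_tag) &
             !ab$canonical_tag %in% ab$canonical_tag[duplicated(ab$canonical_tag)], ,
           drop = FALSE]
  ba <- ba[!duplicated(ba$canonical_tag) &
             !ba$canonical_tag %in% ba$canonical_tag[duplicated(ba$canonical_tag)], ,
           drop = FALSE]
  common <- intersect(ab$canonical_tag, ba$canonical_tag)
  n_unpaired <- (nrow(ab) - length(common)) + (nrow(ba) - length(common))
  if (length(common) == 0L) {
    out <- empty_consensus_tbl()
    attr(out, "n_unpaired") <- n_unpaired
    return(out)
  }
  a <- ab[match(common, ab$canonical_tag), , drop = FALSE]
  b <- ba[match(common, ba$canonical_tag), , drop = FALSE]
  a_end <- a$start + nchar(a$bases) - 1L
  b_end <- b$start + nchar(b$bases) - 1L
  o_start <- pmax(a$start, b$start)
  o_end <- pmin(a_end, b_end)
  keep <- o_end >= o_start
  a <- a[keep, ]; b <- b[keep, ]
  o_start <- o_start[keep]; o_end <- o_end[keep]
  sa <- substr(a$bases, o_start - a$start + 1L, o_end - a$start + 1L)
  sb <- substr(b$bases, o_start - b$start + 1L, o_end - b$start + 1L)
  # cohort by overlap length for matrix comparison
  lens <- nchar(sa)
  bases <- character(length(sa))
  for (L in unique(lens)) {
    rows <- which(lens == L)
    Ma <- matrix(unlist(strsplit(sa[rows], ""), use.names = FALSE),
                 nrow = length(rows), byrow = TRUE)
    Mb <- matrix(unlist(strsplit(sb[rows], ""), use.names = FALSE),
                 nrow = length(rows), byrow = TRUE)
    Md <- ifelse(Ma == Mb & Ma != "N", Ma, "N")
    dim(Md) <- c(length(rows), L)
    bases[rows] <- do.call(paste0, asplit(Md, 2))
  }
  empty_ind <- unlist_indels(NULL)
  na_ind <- map_int(a$indels, NROW)
  nb_ind <- map_int(b$indels, NROW)
  ind <- rep(list(empty_ind), nrow(a))
  for (i in which(na_ind > 0L & nb_ind > 0L)) {
    ind[[i]] <- inner_join(unlist_indels(list(a$indels[[i]])),
                           unlist_indels(list(b$indels[[i]])),
                           by = c("kind", "position", "length", "seq"))
  }
  out <- tibble(
    kind = "DCS",
    tag = a$canonical_tag,
    canonical_tag = a$canonical_tag,
    strand_order = "duplex",
    start = o_start,
    bases = bases,
    family_size = as.integer(a$family_size + b$family_size),
    indels = ind
  )
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Clip consensus ends before counting
#'
#' End-repair and ligation artifacts concentrate at fragment termini, so the
#' first five 5' bases and the last six 3' bases of every consensus are
#' removed from all downstream counting. A consensus of length `len` retains
#' `max(0, len - clip5 - clip3)` evaluable bases. Indel events falling in a
#' clipped margin are dropped.
#'
#' @param consensus a consensus tibble (SSCS or DCS rows).
#' @param clip5,clip3 bases removed from the 5' and 3' ends (defaults 5, 6).
#' @return the consensus tibble with trimmed `bases` and shifted `start`.
#' @export
clip_ends <- function(consensus, clip5 = 5L, clip3 = 6L) {
  if (nrow(consensus) == 0L) return(consensus)
  len <- nchar(consensus$bases)
  new_len <- pmax(0L, len - clip5 - clip3)
  bases <- substr(consensus$bases, clip5 + 1L, clip5 + new_len)
  bases[new_len == 0L] <- ""
  new_start <- consensus$start + clip5
  if ("indels" %in% names(consensus)) {
    todo <- which(map_int(consensus$indels, NROW) > 0L)
    for (i in todo) {
      ind <- unlist_indels(list(consensus$indels[[i]]))
      consensus$indels[[i]] <- filter(
        ind, .data$position >= new_start[i],
        .data$position <= new_start[i] + new_len[i] - 1L
      )
    }
  }
  consensus$bases <- bases
  consensus$start <- new_start
  consensus
}
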