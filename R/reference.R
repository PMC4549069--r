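#' Load a circular mitochondrial reference from FASTA
#'
#' Reads a single-record FASTA and returns an `mt_reference` object. Human
#' mtDNA is a circular molecule and coordinates throughout the package are
#' 1-based positions on the light (L) strand, the strand conventionally
#' deposited for the revised Cambridge reference (rCRS, 16,569 bp). Position
#' `length + 1` is the circular alias of position 1.
#'
#' @param fasta_path path to a FASTA file containing exactly one record over
#'   the alphabet `A/C/G/T/N` (case-insensitive).
#' @param circular logical; treat the sequence as circular (default `TRUE`).
#'
#' @return An object of class `mt_reference`: a list with elements `name`,
#'   `sequence` (upper-cased string), `circular` and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGT"), fa)
#' ref <- load_reference(fa)
#' ref$length
load_reference <- function(fasta_path, circular = TRUE) {
  if (!file.exists(fasta_path)) {
    abort(paste0("reference FASTA not found: ", fasta_path))
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1L) {
    abort("expected single mitochondrial contig")
  }
  seq <- toupper(as.character(set[[1]]))
  if (nchar(seq) == 0L) {
    abort("reference sequence is empty")
  }
  if (grepl("[^ACGTN]", seq)) {
    abort("reference contains characters outside A/C/G/T/N")
  }
  # FASTA descriptions after the first whitespace are not part of the name
  nm <- sub("\\s.*$", "", names(set)[[1]])
  new_mt_reference(nm, seq, circular = circular)
}

new_mt_reference <- function(name, sequence, circular = TRUE) {
  structure(
    list(
      name = as.character(name),
      sequence = sequence,
      circular = isTRUE(circular),
      length = nchar(sequence)
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf(
    "<mt_reference> %s: %d bp, %s\n",
    x$name, x$length, if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

# Resolve (possibly circular) positions to 1..length.
wrap_position <- function(reference, position) {
  if (!reference$circular &&
      any(position < 1L | position > reference$length)) {
    abort("position outside linear reference bounds")
  }
  ((position - 1L) %% reference$length) + 1L
}

#' Extract reference bases at (circular) positions
#'
#' @param reference an [load_reference()] object.
#' @param position integer vector of 1-based L-strand positions; on a circular
#'   reference they wrap modulo the genome length.
#' @return character vector of single bases.
#' @export
ref_base <- function(reference, position) {
  stopifnot(inherits(reference, "mt_reference"))
  p <- wrap_position(reference, as.integer(position))
  substring(reference$sequence, p, p)
}

# Contiguous (wrapped) stretch of the reference starting at `start`.
ref_segment <- function(reference, start, width) {
  p <- wrap_position(reference, as.integer(start))
  L <- reference$length
  if (p + width - 1L <= L) {
    return(substr(reference$sequence, p, p + width - 1L))
  }
  if (!reference$circular) abort("segment runs off a linear reference")
  paste0(
    substr(reference$sequence, p, L),
    ref_segment(reference, 1L, width - (L - p + 1L))
  )
}

#' Load the 37-gene mitochondrial annotation
#'
#' Reads a tab-separated annotation with columns `gene`, `category`
#' (`protein`, `tRNA`, `rRNA` or `noncoding`), `start`, `end` (1-based,
#' inclusive, L-strand), `coding_strand` (`L` when the gene's sense sequence
#' equals the reference, `H` when it is the reverse complement) and an
#' optional `frame_offset`. Records are validated against the reference and
#' returned sorted by start. Overlapping protein genes (in human mtDNA,
#' ATP8/ATP6 and ND4L/ND4) are legitimate and are flagged, not rejected.
#'
#' @param tsv_path path to the annotation TSV.
#' @param reference the matching [load_reference()] object.
#' @return A tibble of gene records with class `mt_annotation`. The attribute
#'   `overlapping_proteins` lists protein-gene pairs that share positions.
#' @export
load_annotation <- function(tsv_path, reference) {
  stopifnot(inherits(reference, "mt_reference"))
  ann <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("gene", "category", "start", "end", "coding_strand")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    abort(paste0("annotation is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"frame_offset" %in% names(ann)) ann$frame_offset <- 0L
  ann <- ann |>
    mutate(
      gene = as.character(.data$gene),
      category = as.character(.data$category),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      coding_strand = as.character(.data$coding_strand),
      frame_offset = as.integer(.data$frame_offset)
    )
  if (!all(ann$category %in% c("protein", "tRNA", "rRNA", "noncoding"))) {
    abort("unknown annotation category")
  }
  if (!all(ann$coding_strand %in% c("L", "H"))) {
    abort("coding_strand must be 'L' or 'H'")
  }
  bad <- ann$start < 1L | ann$start > reference$length |
    ann$end < 1L | ann$end > reference$length
  if (any(bad)) {
    abort("annotation coordinates outside [1, reference length]")
  }
  if (any(ann$start > ann$end & !reference$circular)) {
    abort("origin-wrapping record on a linear reference")
  }
  ann <- arrange(ann, .data$start)
  class(ann) <- c("mt_annotation", class(ann))
  attr(ann, "overlapping_proteins") <- protein_overlaps(ann, reference)
  ann
}

# positions covered by one record, in reading order on its coding strand
record_positions <- function(rec, reference) {
  if (rec$start <= rec$end) {
    pos <- seq.int(rec$start, rec$end)
  } else {
    pos <- c(seq.int(rec$start, reference$length), seq.int(1L, rec$end))
  }
  if (identical(rec$coding_strand, "H")) pos <- rev(pos)
  pos
}

record_width <- function(ann) {
  ifelse(ann$start <= ann$end, ann$end - ann$start + 1L, NA_integer_)
}

protein_overlaps <- function(ann, reference) {
  prot <- ann[ann$category == "protein", , drop = FALSE]
  if (nrow(prot) < 2L) return(character(0))
  covered <- lapply(seq_len(nrow(prot)), function(i) {
    record_positions(as.list(prot[i, ]), reference)
  })
  out <- character(0)
  for (i in seq_len(nrow(prot) - 1L)) {
    for (j in seq.int(i + 1L, nrow(prot))) {
      if (length(intersect(covered[[i]], covered[[j]])) > 0L) {
        out <- c(out, paste(prot$gene[i], prot$gene[j], sep = "/"))
      }
    }
  }
  out
}

#' Summarise an annotation: gene counts and the noncoding share
#'
#' Counts genes by category and reports `noncoding_pct`, the percentage of
#' the genome covered by records annotated `noncoding` (for human mtDNA, the
#' control region; 1122 bp of rCRS, i.e. under 7%). The few dozen unannotated
#' intergenic nucleotides between genes are tallied separately as
#' `intergenic_bp` rather than folded into the noncoding share.
#'
#' @param annotation an [load_annotation()] tibble.
#' @param reference the matching reference.
#' @return one-row tibble with `n_genes`, `n_trna`, `n_rrna`, `n_protein`,
#'   `noncoding_pct`, `intergenic_bp`.
#' @export
mt_annotation_summary <- function(annotation, reference) {
  genes <- annotation[annotation$category != "noncoding", , drop = FALSE]
  nc <- annotation[annotation$category == "noncoding", , drop = FALSE]
  cov <- rep(FALSE, reference$length)
  for (i in seq_len(nrow(annotation))) {
    cov[record_positions(as.list(annotation[i, ]), reference)] <- TRUE
  }
  nc_pos <- integer(0)
  for (i in seq_len(nrow(nc))) {
    nc_pos <- c(nc_pos, record_positions(as.list(nc[i, ]), reference))
  }
  tibble(
    n_genes = nrow(genes),
    n_trna = sum(genes$category == "tRNA"),
    n_rrna = sum(genes$category == "rRNA"),
    n_protein = sum(genes$category == "protein"),
    noncoding_pct = 100 * length(unique(nc_pos)) / reference$length,
    intergenic_bp = sum(!cov)
  )
}

#' Translate codons under the vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: relative to the standard code, `TGA` is Trp,
#' `ATA` is Met, and `AGA`/`AGG` are stops.
#'
#' @param codon character vector of 3-mers over `A/C/G/T`.
#' @return character vector of single-letter amino acids, `*` for stop.
#' @export
#' @examples
#' translate_mt(c("ATG", "TGA", "AGA"))
translate_mt <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    abort("codons must be 3-mers over A/C/G/T")
  }
  code <- mt_genetic_code()
  unname(code[codon])
}

mt_code_env <- new.env(parent = emptyenv())

mt_genetic_code <- function() {
  if (is.null(mt_code_env$code)) {
    gc2 <- Biostrings::getGeneticCode("2")
    # Biostrings names codons with T already; ensure plain named chr vector
    mt_code_env$code <- setNames(as.character(gc2), names(gc2))
  }
  mt_code_env$code
}

# per-codon count of nonsynonymous single-base substitutions (of the 9)
ns_counts_per_codon <- function() {
  if (is.null(mt_code_env$ns)) {
    code <- mt_genetic_code()
    codons <- names(code)
    ns <- vapply(codons, function(cod) {
      n <- 0L
      for (i in 1:3) {
        for (b in DNA_BASES) {
          if (substr(cod, i, i) == b) next
          alt <- cod
          substr(alt, i, i) <- b
          if (code[[alt]] != code[[cod]]) n <- n + 1L
        }
      }
      n
    }, integer(1))
    mt_code_env$ns <- ns
  }
  mt_code_env$ns
}

# Codons of a protein gene, in reading order. Trailing bases that do not
# complete a codon are dropped: mitochondrial mRNAs with incomplete stop
# codons acquire them by polyadenylation, so no unambiguous genomic codon
# exists and those 1-2 nucleotides are excluded from codon arithmetic.
gene_codons <- function(rec, reference) {
  pos <- record_positions(rec, reference)
  if (rec$frame_offset > 0L) pos <- pos[-seq_len(rec$frame_offset)]
  n_cod <- length(pos) %/% 3L
  if (n_cod == 0L) {
    return(list(codons = character(0), positions = integer(0)))
  }
  pos <- pos[seq_len(n_cod * 3L)]
  b <- ref_base(reference, pos)
  if (identical(rec$coding_strand, "H")) b <- complement_base(b)
  m <- matrix(b, ncol = 3L, byrow = TRUE)
  list(
    codons = paste0(m[, 1], m[, 2], m[, 3]),
    positions = pos # reading order; positions[3k-2 .. 3k] belong to codon k
  )
}

#' Codon-level consequence of a point substitution
#'
#' Maps an L-strand substitution onto every protein gene covering the
#' position. For genes whose sense sequence is the reverse complement of the
#' reference (`coding_strand == "H"`), both the reference and the alternate
#' base are complemented before codon lookup. Positions in tRNA, rRNA or
#' noncoding records yield no rows, as do the 1-2 nt incomplete-stop tails of
#' protein genes.
#'
#' @param position 1-based L-strand position.
#' @param ref_base_chr,alt_base_chr reference and alternate base on the
#'   L-strand; `ref_base_chr` must match the reference sequence.
#' @param annotation,reference annotation and reference objects.
#' @return tibble with zero or more rows (one per covering protein gene):
#'   `gene`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` (`synonymous`/`nonsynonymous`).
#' @export
codon_change <- function(position, ref_base_chr, alt_base_chr,
                         annotation, reference) {
  position <- as.integer(position)
  if (position < 1L || position > reference$length) {
    abort("position outside reference")
  }
  actual <- ref_base(reference, position)
  if (!identical(actual, toupper(ref_base_chr))) {
    abort(sprintf("ref base mismatch at %d: reference has %s, got %s",
                  position, actual, ref_base_chr))
  }
  prot <- annotation[annotation$category == "protein", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(prot))) {
    rec <- as.list(prot[i, ])
    gc <- gene_codons(rec, reference)
    idx <- match(position, gc$positions)
    if (is.na(idx)) next
    codon_index <- (idx - 1L) %/% 3L + 1L
    within <- (idx - 1L) %% 3L + 1L
    ref_codon <- gc$codons[codon_index]
    sense_alt <- if (identical(rec$coding_strand, "H")) {
      complement_base(toupper(alt_base_chr))
    } else {
      toupper(alt_base_chr)
    }
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- sense_alt
    ref_aa <- translate_mt(ref_codon)
    alt_aa <- translate_mt(alt_codon)
    out[[length(out) + 1L]] <- tibble(
      gene = rec$gene,
      codon_index = codon_index,
      ref_codon = ref_codon,
      alt_codon = alt_codon,
      ref_aa = ref_aa,
      alt_aa = alt_aa,
      effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
    )
  }
  if (length(out) == 0L) {
    return(tibble(
      gene = character(0), codon_index = integer(0),
      ref_codon = character(0), alt_codon = character(0),
      ref_aa = character(0), alt_aa = character(0), effect = character(0)
    ))
  }
  bind_rows(out)
}

#' By-chance expectation for the nonsynonymous fraction
#'
#' Enumerates all three alternative bases at every protein-coding position
#' (each substitution weighted equally) and returns the fraction of
#' substitutions that change the encoded amino acid under the vertebrate
#' mitochondrial code. Stop gains and losses count as nonsynonymous; a
#' position inside two overlapping genes contributes once per gene. This is
#' the null against which observed nonsynonymous/synonymous ratios are judged
#' for evidence of selection; for the real human mtDNA coding sequence it
#' evaluates to about 0.757.
#'
#' @param annotation,reference annotation and reference objects.
#' @return a single fraction in `[0, 1]`.
#' @export
expected_ns_fraction <- function(annotation, reference) {
  prot <- annotation[annotation$category == "protein", , drop = FALSE]
  if (nrow(prot) == 0L) abort("annotation has no protein genes")
  ns_tab <- ns_counts_per_codon()
  ns <- 0
  total <- 0
  for (i in seq_len(nrow(prot))) {
    gc <- gene_codons(as.list(prot[i, ]), reference)
    if (length(gc$codons) == 0L) next
    ns <- ns + sum(ns_tab[gc$codons])
    total <- total + 9L * length(gc$codons)
  }
  if (total == 0L) abort("no complete codons in protein genes")
  ns / total
}
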