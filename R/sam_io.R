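# SAM import/export for duplex-tagged reads --------------------------------
#
# Reads travel as tibbles inside the package; SAM is supported at the
# boundary. The duplex tag and strand order ride in the read name as
# "...#<tag>/<ab|ba>". SAM stores sequences reference-oriented, while the
# read tibbles keep them as sequenced with a `reversed` flag, so both
# functions convert.

#' Write tagged reads to a SAM file
#'
#' @param reads read tibble (as produced by [simulate_duplex_reads()]).
#' @param reference the `mt_reference` the reads are aligned to.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_tagged_sam <- function(reads, reference, path) {
  len <- nchar(reads$seq)
  if (any(reads$start + len - 1L > reference$length)) {
    abort(paste0("SAM cannot represent origin-spanning alignments; ",
                 "simulate with wrap_fragments = FALSE to export"))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", reference$name, "\tLN:", reference$length)
  )
  seq_ref <- ifelse(reads$reversed, revcomp(reads$seq), reads$seq)
  body <- paste(
    reads$qname,
    ifelse(reads$reversed, 16L, 0L),
    reference$name,
    reads$start,
    60L,
    paste0(len, "M"),
    "*", 0L, 0L,
    seq_ref,
    "*",
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tagged reads from a SAM file
#'
#' Imports aligned reads via Rsamtools; unmapped records are skipped. Tags
#' are parsed downstream by [group_reads_by_tag()] from the read names.
#'
#' @param path SAM file path.
#' @return read tibble with `qname`, `start`, `seq`, `reversed`.
#' @export
read_tagged_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "seq"))
  )[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  reversed <- bitwAnd(res$flag[mapped], 16L) > 0L
  seq_ref <- as.character(res$seq[mapped])
  tibble(
    qname = res$qname[mapped],
    start = res$pos[mapped],
    seq = ifelse(reversed, revcomp(seq_ref), seq_ref),
    reversed = reversed
  )
}
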