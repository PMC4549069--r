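# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the package's own code paths: translation goes
# through the packaged 64-codon table, reverse complements and interval
# formulas are written out directly.

table2 <- local({
  tab <- read.delim(
    system.file("extdata", "mt_code_table2.tsv", package = "mitoduplex"),
    stringsAsFactors = FALSE
  )
  stats::setNames(tab$amino_acid, tab$codon)
})

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
}

# write a FASTA and load it, so tests exercise the real loader
toy_ref <- function(seq, name = "toy") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), fa)
  load_reference(fa)
}

toy_ann <- function(df, reference) {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, tsv)
  load_annotation(tsv, reference)
}

# brute-force nonsynonymous fraction: every protein position x 3 alts,
# translated via the packaged table, one contribution per covering gene
oracle_ns_fraction <- function(annotation, reference) {
  prot <- annotation[annotation$category == "protein", , drop = FALSE]
  ns <- 0L
  total <- 0L
  for (g in seq_len(nrow(prot))) {
    rec <- prot[g, ]
    if (rec$start <= rec$end) {
      pos <- rec$start:rec$end
    } else {
      pos <- c(rec$start:reference$length, 1:rec$end)
    }
    if (rec$coding_strand == "H") pos <- rev(pos)
    if (rec$frame_offset > 0) pos <- pos[-seq_len(rec$frame_offset)]
    n_cod <- length(pos) %/% 3L
    pos <- pos[seq_len(n_cod * 3L)]
    sense <- vapply(pos, function(p) {
      b <- substr(reference$sequence, p, p)
      if (rec$coding_strand == "H") chartr("ACGT", "TGCA", b) else b
    }, "")
    for (k in seq_len(n_cod)) {
      cod <- paste(sense[(3 * k - 2):(3 * k)], collapse = "")
      for (i in 1:3) {
        for (b in c("A", "C", "G", "T")) {
          if (substr(cod, i, i) == b) next
          alt <- cod
          substr(alt, i, i) <- b
          total <- total + 1L
          if (table2[[alt]] != table2[[cod]]) ns <- ns + 1L
        }
      }
    }
  }
  ns / total
}

# brute-force tier frequency: walk every pileup row, count distinct alts
oracle_mutation_frequency <- function(pileups, tier, min_depth = 100) {
  k <- 0L
  for (i in seq_len(nrow(pileups))) {
    row <- pileups[i, ]
    if (row$depth < min_depth) next
    for (b in c("A", "C", "G", "T")) {
      if (b == row$ref_base) next
      cnt <- row[[b]]
      if (cnt == 0) next
      pct <- 100 * cnt / row$depth
      tr <- if (pct <= 0.5) "rare" else if (pct <= 20) "low_het"
            else if (pct < 95) "high_het" else "homoplasmic"
      if (tr == tier) k <- k + 1L
    }
  }
  k / sum(pileups$depth)
}

# brute-force pyrimidine-centred context class
oracle_context_class <- function(position, ref, alt, reference) {
  L <- nchar(reference$sequence)
  at <- function(p) {
    p <- ((p - 1) %% L) + 1
    substr(reference$sequence, p, p)
  }
  tri <- paste0(at(position - 1), at(position), at(position + 1))
  if (ref %in% c("A", "G")) {
    list(substitution = paste0(chartr("ACGT", "TGCA", ref), ">",
                               chartr("ACGT", "TGCA", alt)),
         context = oracle_revcomp(tri))
  } else {
    list(substitution = paste0(ref, ">", alt), context = tri)
  }
}

oracle_wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  c(
    ((p + z^2 / (2 * n)) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    ((p + z^2 / (2 * n)) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n)
  )
}

# Yates-corrected chi-squared on the 2x2 table, evaluated from the printed
# formula: N(|ad - bc| - N/2)^2 / row and column products
oracle_yates <- function(k1, n1, k2, n2) {
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  N <- n1 + n2
  num <- (max(abs(a * d - b * c) - N / 2, 0))^2 * N
  chi <- num / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

# quick hand-rolled read tibble
reads_tbl <- function(seqs, tag = "ACGTACGT", order = "ab", start = 1L,
                      reversed = FALSE) {
  tibble::tibble(
    qname = paste0("r", seq_along(seqs), "#", tag, "/", order),
    tag = tag, strand_order = order, start = start, seq = seqs,
    reversed = reversed
  )
}
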