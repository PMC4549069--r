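# Synthetic stand-in for the human mitochondrial reference -----------------
#
# The package ships a SYNTHETIC 16,569-bp genome (inst/extdata/
# synthetic_rcrs.fa) rather than the real NC_012920 sequence. Its gene
# coordinates are the standard 37-gene human annotation (22 tRNA, 2 rRNA,
# 13 protein genes plus the two control-region segments), but the sequence
# itself is generated: bases are drawn iid from the documented rCRS
# composition (A .309, C .313, G .131, T .247) and protein ORFs are built
# codon-wise with in-frame stop codons rejected, an ATG start, and a TAA stop
# where the gene length permits a complete terminal codon. Codons whose
# positions were already written by an earlier overlapping gene keep those
# bases. The stand-in therefore reproduces the genome's size, gene layout and
# base composition, but not the real codon usage of the 13 proteins.

#' Standard 37-gene human mitochondrial annotation (NC_012920 coordinates)
#'
#' Returns the canonical human mtDNA gene table: 22 tRNAs, 2 rRNAs, 13
#' protein-coding genes, plus two `noncoding` rows for the control region
#' (16024-16569 and 1-576). Coordinates are 1-based inclusive on the
#' L-strand; `coding_strand == "H"` marks the genes read as the reverse
#' complement of the reference (ND6 and eight tRNAs).
#'
#' @return tibble with columns `gene`, `category`, `start`, `end`,
#'   `coding_strand`, `frame_offset`.
#' @export
mt_gene_table <- function() {
  tribble_txt <- c(
    "MT-CR,noncoding,1,576,L",
    "MT-TF,tRNA,577,647,L",
    "MT-RNR1,rRNA,648,1601,L",
    "MT-TV,tRNA,1602,1670,L",
    "MT-RNR2,rRNA,1671,3229,L",
    "MT-TL1,tRNA,3230,3304,L",
    "MT-ND1,protein,3307,4262,L",
    "MT-TI,tRNA,4263,4331,L",
    "MT-TQ,tRNA,4329,4400,H",
    "MT-TM,tRNA,4402,4469,L",
    "MT-ND2,protein,4470,5511,L",
    "MT-TW,tRNA,5512,5579,L",
    "MT-TA,tRNA,5587,5655,H",
    "MT-TN,tRNA,5657,5729,H",
    "MT-TC,tRNA,5761,5826,H",
    "MT-TY,tRNA,5826,5891,H",
    "MT-CO1,protein,5904,7445,L",
    "MT-TS1,tRNA,7446,7514,H",
    "MT-TD,tRNA,7518,7585,L",
    "MT-CO2,protein,7586,8269,L",
    "MT-TK,tRNA,8295,8364,L",
    "MT-ATP8,protein,8366,8572,L",
    "MT-ATP6,protein,8527,9207,L",
    "MT-CO3,protein,9207,9990,L",
    "MT-TG,tRNA,9991,10058,L",
    "MT-ND3,protein,10059,10404,L",
    "MT-TR,tRNA,10405,10469,L",
    "MT-ND4L,protein,10470,10766,L",
    "MT-ND4,protein,10760,12137,L",
    "MT-TH,tRNA,12138,12206,L",
    "MT-TS2,tRNA,12207,12265,L",
    "MT-TL2,tRNA,12266,12336,L",
    "MT-ND5,protein,12337,14148,L",
    "MT-ND6,protein,14149,14673,H",
    "MT-TE,tRNA,14674,14742,H",
    "MT-CYB,protein,14747,15887,L",
    "MT-TT,tRNA,15888,15953,L",
    "MT-TP,tRNA,15956,16023,H",
    "MT-CR,noncoding,16024,16569,L"
  )
  parts <- strsplit(tribble_txt, ",", fixed = TRUE)
  tibble(
    gene = map_chr(parts, 1),
    category = map_chr(parts, 2),
    start = as.integer(map_chr(parts, 3)),
    end = as.integer(map_chr(parts, 4)),
    coding_strand = map_chr(parts, 5),
    frame_offset = 0L
  )
}

# documented rCRS base composition on the L-strand
RCRS_COMPOSITION <- c(A = 0.309, C = 0.313, G = 0.131, T = 0.247)

#' Generate the synthetic mitochondrial reference genome
#'
#' Builds the 16,569-bp synthetic stand-in described above: standard gene
#' coordinates, iid rCRS-composition background, stop-free protein ORFs.
#' Deterministic for a given seed; the packaged fixture uses the default.
#'
#' @param seed integer RNG seed.
#' @return list with `reference` (an `mt_reference`) and `annotation`.
#' @export
make_synthetic_rcrs <- function(seed = 20150825L) {
  ann0 <- mt_gene_table()
  L <- 16569L
  comp <- RCRS_COMPOSITION / sum(RCRS_COMPOSITION)
  withr::with_seed(seed, {
    seq <- sample(DNA_BASES, L, replace = TRUE, prob = comp)
    claimed <- rep(FALSE, L)
    prot <- ann0[ann0$category == "protein", , drop = FALSE]
    for (i in seq_len(nrow(prot))) {
      rec <- as.list(prot[i, ])
      width <- rec$end - rec$start + 1L
      pos <- seq.int(rec$start, rec$end)
      if (identical(rec$coding_strand, "H")) pos <- rev(pos)
      n_cod <- width %/% 3L
      for (k in seq_len(n_cod)) {
        cod_pos <- pos[(3L * k - 2L):(3L * k)]
        if (any(claimed[cod_pos])) next # keep earlier overlapping gene
        cod <- if (k == 1L) {
          "ATG"
        } else if (k == n_cod && width %% 3L == 0L) {
          "TAA"
        } else {
          sample_sense_codon(comp)
        }
        b <- strsplit(cod, "")[[1]]
        if (identical(rec$coding_strand, "H")) b <- complement_base(b)
        seq[cod_pos] <- b
      }
      claimed[pos[seq_len(n_cod * 3L)]] <- TRUE
    }
    reference <- new_mt_reference(
      "synthetic_rCRS", paste(seq, collapse = ""), circular = TRUE
    )
    ann <- annotate_tbl(ann0, reference)
    list(reference = reference, annotation = ann)
  })
}

# one codon, iid composition, resampled until it is not a mito stop codon
sample_sense_codon <- function(comp) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  repeat {
    cod <- paste(sample(DNA_BASES, 3L, replace = TRUE, prob = comp),
                 collapse = "")
    if (!cod %in% stops) return(cod)
  }
}

# give an in-memory annotation tibble the mt_annotation class + attributes
annotate_tbl <- function(ann, reference) {
  ann <- arrange(ann, .data$start)
  class(ann) <- c("mt_annotation", class(ann))
  attr(ann, "overlapping_proteins") <- protein_overlaps(ann, reference)
  ann
}

#' Packaged synthetic reference and annotation fixtures
#'
#' `mt_reference_fixture()` loads `inst/extdata/synthetic_rcrs.fa` (the
#' synthetic stand-in genome) and `mt_annotation_fixture()` loads the
#' matching 37-gene annotation TSV.
#'
#' @return an `mt_reference`, respectively an `mt_annotation` tibble.
#' @export
mt_reference_fixture <- function() {
  load_reference(system.file("extdata", "synthetic_rcrs.fa",
                             package = "mitoduplex", mustWork = TRUE))
}

#' @rdname mt_reference_fixture
#' @export
mt_annotation_fixture <- function() {
  load_annotation(
    system.file("extdata", "mt_annotation.tsv",
                package = "mitoduplex", mustWork = TRUE),
    mt_reference_fixture()
  )
}
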