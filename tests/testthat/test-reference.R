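test_that("load_reference reads single-record FASTA and rejects bad input", {
  ref <- toy_ref("acgt")
  expect_s3_class(ref, "mt_reference")
  expect_equal(ref$length, 4L)
  expect_equal(ref$sequence, "ACGT") # upper-cased
  expect_true(ref$circular)

  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa2)
  expect_error(load_reference(fa2), "single mitochondrial contig")

  fa3 <- tempfile(fileext = ".fa")
  writeLines(">empty", fa3)
  expect_error(load_reference(fa3))
})

test_that("circular positions wrap: p and p + length give the same base", {
  ref <- toy_ref("ACGTTGCA")
  p <- 1:8
  expect_equal(ref_base(ref, p), ref_base(ref, p + ref$length))
  expect_equal(ref_base(ref, 0L), "A") # position 0 aliases position length
})

test_that("translate_mt matches the packaged table-2 fixture on all 64 codons", {
  expect_equal(translate_mt(names(table2)), unname(table2))
  expect_error(translate_mt("ATN"), "A/C/G/T")
  expect_error(translate_mt("AT"))
})

test_that("packaged annotation has the 37-gene structure of human mtDNA", {
  ref <- mt_reference_fixture()
  ann <- mt_annotation_fixture()
  s <- mt_annotation_summary(ann, ref)
  expect_equal(ref$length, 16569L)
  expect_equal(s$n_genes, 37L)
  expect_equal(s$n_trna, 22L)
  expect_equal(s$n_rrna, 2L)
  expect_equal(s$n_protein, 13L)
  expect_lt(s$noncoding_pct, 7)
})

test_that("annotation loader validates columns and coordinates", {
  ref <- toy_ref(strrep("ACGT", 30))
  expect_error(
    toy_ann(tibble::tibble(gene = "G1", start = 1, end = 10), ref),
    "missing columns"
  )
  expect_error(
    toy_ann(tibble::tibble(gene = "G1", category = "protein", start = 1,
                           end = 500, coding_strand = "L"), ref),
    "outside"
  )
  # one protein gene covering the whole toy genome: nothing noncoding
  ann <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                start = 1, end = 120, coding_strand = "L"),
                 ref)
  s <- mt_annotation_summary(ann, ref)
  expect_equal(s$noncoding_pct, 0)
  expect_equal(s$intergenic_bp, 0L)
})

test_that("overlapping protein genes are flagged, not fatal", {
  ann <- mt_annotation_fixture()
  ov <- attr(ann, "overlapping_proteins")
  expect_true("MT-ATP8/MT-ATP6" %in% ov)
  expect_true("MT-ND4L/MT-ND4" %in% ov)
})

test_that("codon_change resolves effects on both coding strands", {
  # gene = ATG AAA TTT, L strand
  ref <- toy_ref(paste0("ATGAAATTT", strrep("C", 51)))
  ann <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                start = 1, end = 9, coding_strand = "L"),
                 ref)
  # AAA -> AAG: Lys -> Lys, synonymous (third codon position)
  cc <- codon_change(6, "A", "G", ann, ref)
  expect_equal(cc$effect, "synonymous")
  expect_equal(cc$ref_aa, "K")
  # AAA -> CAA: Lys -> Gln, nonsynonymous (first codon position)
  cc <- codon_change(4, "A", "C", ann, ref)
  expect_equal(cc$effect, "nonsynonymous")
  expect_equal(cc$alt_aa, "Q")
  # position outside any protein gene yields no rows
  expect_equal(nrow(codon_change(20, "C", "T", ann, ref)), 0L)
  expect_error(codon_change(100, "A", "C", ann, ref), "outside")
  expect_error(codon_change(4, "G", "C", ann, ref), "mismatch")
})

test_that("codon_change complements H-strand genes", {
  # sense ORF ATG AAA: reference carries its reverse complement TTTCAT
  ref <- toy_ref(paste0("TTTCAT", strrep("G", 54)))
  ann <- toy_ann(tibble::tibble(gene = "H1", category = "protein",
                                start = 1, end = 6, coding_strand = "H"),
                 ref)
  # L-strand T>C at position 1 is sense-strand A>G at codon 2 position 3:
  # AAA -> AAG, synonymous
  cc <- codon_change(1, "T", "C", ann, ref)
  expect_equal(cc$codon_index, 2L)
  expect_equal(cc$ref_codon, "AAA")
  expect_equal(cc$alt_codon, "AAG")
  expect_equal(cc$effect, "synonymous")
})

test_that("variants in two overlapping genes are evaluated once per gene", {
  ref <- toy_ref(paste0("ATGAAATTTGGG", strrep("A", 48)))
  ann <- toy_ann(tibble::tibble(
    gene = c("G1", "G2"), category = "protein",
    start = c(1L, 4L), end = c(9L, 12L), coding_strand = "L"
  ), ref)
  cc <- codon_change(6, "A", "G", ann, ref)
  expect_equal(nrow(cc), 2L)
  expect_setequal(cc$gene, c("G1", "G2"))
})

test_that("expected_ns_fraction matches hand-enumerable toy genes", {
  # single codon AAA: only AAA->AAG is synonymous, 8 of 9 change Lys
  ref <- toy_ref(paste0("AAA", strrep("T", 57)))
  ann <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                start = 1, end = 3, coding_strand = "L"),
                 ref)
  expect_equal(expected_ns_fraction(ann, ref), 8 / 9)
  # CTC codons: third-position changes all synonymous -> 6/9
  ref2 <- toy_ref(paste0(strrep("CTC", 4), strrep("A", 48)))
  ann2 <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                 start = 1, end = 12, coding_strand = "L"),
                  ref2)
  expect_equal(expected_ns_fraction(ann2, ref2), 6 / 9)
  expect_error(
    expected_ns_fraction(
      toy_ann(tibble::tibble(gene = "T1", category = "tRNA", start = 1,
                             end = 60, coding_strand = "L"), ref2),
      ref2
    ),
    "no protein genes"
  )
})

test_that("expected_ns_fraction equals the brute-force oracle on random toys", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      toy <- make_toy_reference(
        120, tibble::tibble(category = c("protein", "protein"),
                            fraction = c(0.3, 0.2),
                            coding_strand = c("L", "H")),
        seed = rep
      )
      expect_equal(
        expected_ns_fraction(toy$annotation, toy$reference),
        oracle_ns_fraction(toy$annotation, toy$reference)
      )
    }
  })
})

test_that("incomplete terminal codons are excluded from enumeration", {
  # 10-bp 'gene': 3 complete codons, 1 dangling base
  ref <- toy_ref(paste0("ATGAAATTTG", strrep("C", 50)))
  ann <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                start = 1, end = 10, coding_strand = "L"),
                 ref)
  ann3 <- toy_ann(tibble::tibble(gene = "G1", category = "protein",
                                 start = 1, end = 9, coding_strand = "L"),
                  ref)
  expect_equal(expected_ns_fraction(ann, ref),
               expected_ns_fraction(ann3, ref))
  # the dangling base itself has no codon
  expect_equal(nrow(codon_change(10, "G", "A", ann, ref)), 0L)
})

test_that("the synthetic genome regenerates deterministically", {
  fix <- make_synthetic_rcrs()
  ref <- mt_reference_fixture()
  expect_equal(fix$reference$sequence, ref$sequence)
})
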