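flat_pileup <- function(ref, depth = 1000L) {
  p <- tibble::tibble(
    position = seq_len(ref$length),
    ref_base = strsplit(ref$sequence, "")[[1]],
    A = 0L, C = 0L, G = 0L, T = 0L
  )
  for (b in c("A", "C", "G", "T")) p[[b]][p$ref_base == b] <- depth
  p$depth <- p$A + p$C + p$G + p$T
  p
}

snv <- function(position, ref, alt, tier = "rare") {
  tibble::tibble(position = position, ref = ref, alt = alt,
                 variant_class = "snv", tier = tier)
}

test_that("the substitution-type enumeration has exactly 12 L-strand types", {
  types <- substitution_types()
  expect_length(types, 12L)
  expect_length(unique(types), 12L)
  expect_true(all(grepl("^[ACGT]>[ACGT]$", types)))
})

test_that("spectrum counts types and collapses complementary pairs", {
  ref <- toy_ref(strrep("ACGT", 25))
  p <- flat_pileup(ref)
  v <- dplyr::bind_rows(
    snv(3L, "G", "A"), snv(7L, "G", "A"), snv(2L, "C", "T")
  )
  sp <- substitution_spectrum(v, p)
  expect_equal(sp$count[sp$type == "G>A"], 2L)
  expect_equal(sp$count[sp$type == "C>T"], 1L)
  # denominator is the sequenced nt whose reference base is the source
  expect_equal(sp$denominator[sp$type == "G>A"], 25000)
  expect_equal(sp$frequency[sp$type == "G>A"], 2 / 25000)
  six <- collapse_spectrum(sp)
  expect_equal(nrow(six), 6L)
  expect_equal(six$count[six$pair == "C>T/G>A"], 3L)
  expect_equal(six$fraction_pct[six$pair == "C>T/G>A"], 100)
  expect_equal(sum(six$fraction_pct), 100)
  # complementary 12-type counts always sum to the 6-type counts
  expect_equal(sum(six$count), sum(sp$count))
})

test_that("empty input yields an all-zero spectrum, not an error", {
  ref <- toy_ref(strrep("ACGT", 25))
  sp <- substitution_spectrum(snv(integer(0), character(0), character(0)),
                              flat_pileup(ref))
  expect_equal(sum(sp$count), 0L)
  expect_equal(sum(collapse_spectrum(sp)$fraction_pct), 0)
})

test_that("strand bias uses the proportion test on complementary types", {
  ref <- toy_ref(strrep("ACGT", 25))
  p <- flat_pileup(ref)
  v <- dplyr::bind_rows(snv(3L, "G", "A"), snv(2L, "C", "T"))
  sp <- substitution_spectrum(v, p)
  # identical counts and denominators cannot show bias
  res <- strand_bias_test(sp, "G>A", "C>T")
  expect_equal(res$p_value, 1)
  expect_error(strand_bias_test(sp, "G>A", "T>C"), "complementary")
})

test_that("proportion test agrees with the hand-evaluated Yates formula", {
  o <- oracle_yates(30, 1e6, 10, 1e6)
  r <- two_proportion_test(30, 1e6, 10, 1e6)
  expect_equal(r$statistic, o$statistic)
  expect_equal(r$p_value, o$p_value)
})

test_that("the context enumeration has exactly 96 pyrimidine-centred classes", {
  cls <- context_classes()
  expect_equal(nrow(cls), 96L)
  expect_equal(nrow(dplyr::distinct(cls, substitution, context)), 96L)
  expect_true(all(substr(cls$context, 2, 2) %in% c("C", "T")))
})

test_that("context classification is strand-canonical", {
  # L-strand C>T inside A_C_A
  ref <- toy_ref(paste0("TACAT", strrep("G", 95)))
  sp <- context_spectrum(snv(3L, "C", "T"), ref)
  expect_equal(sp$count[sp$substitution == "C>T" & sp$context == "ACA"], 1L)
  expect_equal(sum(sp$count), 1L)
  expect_equal(sp$fraction_pct[sp$substitution == "C>T" &
                                 sp$context == "ACA"], 100)

  # L-strand G>A in trinucleotide TGT complements to (ACA, C>T)
  ref2 <- toy_ref(paste0("ATGTA", strrep("C", 95)))
  sp2 <- context_spectrum(snv(3L, "G", "A"), ref2)
  expect_equal(sp2$count[sp2$substitution == "C>T" &
                           sp2$context == "ACA"], 1L)
})

test_that("context neighbours wrap around the circular genome", {
  ref <- toy_ref("CATTTTTTTG") # position 1 has 5' neighbour at length
  sp <- context_spectrum(snv(1L, "C", "A"), ref)
  expect_equal(sp$count[sp$substitution == "C>A" & sp$context == "GCA"], 1L)
  # terminal position: 3' neighbour is position 1
  sp2 <- context_spectrum(snv(10L, "G", "A"), ref)
  # GCT from revcomp of TGC... L-strand tri at 10 = (T, G, C-wrapped)
  expect_equal(sum(sp2$count), 1L)
  expect_equal(sp2$count[sp2$substitution == "C>T" &
                           sp2$context == "GCA"], 1L)
})

test_that("every point mutation maps to exactly one class (oracle check)", {
  withr::with_seed(31, {
    ref <- make_toy_reference(300, c(protein = 0.5), seed = 12)$reference
    for (i in 1:100) {
      pos <- sample(300, 1)
      rb <- ref_base(ref, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      sp <- context_spectrum(snv(pos, rb, alt), ref)
      expect_equal(sum(sp$count), 1L)
      o <- oracle_context_class(pos, rb, alt, ref)
      expect_equal(sp$count[sp$substitution == o$substitution &
                              sp$context == o$context], 1L)
    }
  })
})

test_that("a pure planted C>T-in-ACA process concentrates in one class", {
  withr::with_seed(77, {
    # find ACA contexts in the synthetic genome and plant C>T at them
    ref <- mt_reference_fixture()
    hits <- stringr::str_locate_all(ref$sequence, "ACA")[[1]][, 1] + 1L
    hits <- utils::head(hits, 25)
    v <- snv(as.integer(hits), "C", "T")
    sp <- context_spectrum(v, ref)
    expect_equal(sp$fraction_pct[sp$substitution == "C>T" &
                                   sp$context == "ACA"], 100)
    expect_equal(sum(sp$fraction_pct), 100)
  })
})

test_that("context fractions compare across spectra with fold changes", {
  ref <- toy_ref(paste0("TACAT", strrep("G", 95)))
  a <- context_spectrum(snv(3L, "C", "T"), ref)
  res_same <- compare_context_fractions(a, a, "C>T", "ACA")
  expect_equal(res_same$fold, 1)
  expect_equal(res_same$p_value, 1)

  b <- a
  b$count[b$substitution == "C>T" & b$context == "ACA"] <- 0L
  b$count[b$substitution == "C>A" & b$context == "ACA"] <- 1L
  b$fraction_pct <- 100 * b$count / sum(b$count)
  res0 <- compare_context_fractions(a, b, "T>G", "ATA")
  expect_false(res0$estimable)
  expect_true(is.na(res0$fold))
  expect_error(compare_context_fractions(a, b, "C>T", "XYZ"), "absent")

  # 4-of-100 vs 1-of-100: fold 4 and the hand-computed Yates p
  big_a <- a
  big_a$count <- rep(0L, 96)
  big_a$count[big_a$substitution == "C>T" & big_a$context == "ACA"] <- 4L
  big_a$count[big_a$substitution == "C>A"] <- 6L # 16 classes x 6 = 96
  big_a$count <- big_a$count
  ta <- sum(big_a$count)
  big_b <- big_a
  big_b$count[big_b$substitution == "C>T" & big_b$context == "ACA"] <- 1L
  big_b$count[big_b$substitution == "T>A" & big_b$context == "ATA"] <-
    big_b$count[big_b$substitution == "T>A" & big_b$context == "ATA"] + 3L
  res <- compare_context_fractions(big_a, big_b, "C>T", "ACA")
  expect_equal(res$fold, 4)
  o <- oracle_yates(4, ta, 1, sum(big_b$count))
  expect_equal(res$p_value, o$p_value)
})

test_that("pooling sums counts before recomputing fractions", {
  ref <- toy_ref(paste0("TACAT", strrep("G", 95)))
  a <- context_spectrum(snv(3L, "C", "T"), ref)
  b <- a
  pooled <- pool_context_spectra(a, b)
  expect_equal(sum(pooled$count), 2L)
  expect_equal(pooled$fraction_pct[pooled$substitution == "C>T" &
                                     pooled$context == "ACA"], 100)
})
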