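test_that("reads partition into families keyed by tag, strand order, start", {
  reads <- dplyr::bind_rows(
    reads_tbl(rep("ACGT", 3), tag = "AATTCCGG", order = "ab"),
    reads_tbl(rep("ACGT", 3), tag = "AATTCCGG", order = "ba")
  )
  fam <- group_reads_by_tag(reads)
  expect_equal(nrow(fam), 2L)
  expect_equal(sort(fam$n_reads), c(3L, 3L))
  expect_equal(unique(fam$canonical_tag), "AATTCCGG")

  one <- group_reads_by_tag(reads_tbl("ACGT"))
  expect_equal(one$n_reads, 1L)

  # families mixing alignment starts split rather than average
  mixed <- dplyr::bind_rows(
    reads_tbl(rep("ACGT", 2), start = 1L),
    reads_tbl(rep("ACGT", 2), start = 5L)
  )
  expect_equal(nrow(group_reads_by_tag(mixed)), 2L)
})

test_that("unparseable tags are dropped with a warning counter", {
  reads <- reads_tbl(c("ACGT", "ACGT"))
  reads$qname[2] <- "bad_read_name"
  reads$tag <- NULL
  reads$strand_order <- NULL
  expect_warning(fam <- group_reads_by_tag(reads), "dropped 1")
  expect_equal(attr(fam, "n_dropped"), 1L)
  expect_equal(sum(fam$n_reads), 1L)
})

test_that("canonical tag pairs the two strand orders of one molecule", {
  reads <- dplyr::bind_rows(
    reads_tbl("ACGT", tag = "TTTTAAAA", order = "ab"),
    reads_tbl("ACGT", tag = "AAAATTTT", order = "ba")
  )
  fam <- group_reads_by_tag(reads)
  expect_equal(unique(fam$canonical_tag), "AAAATTTT")
})

test_that("SSCS majority calls follow the consensus threshold", {
  fam <- group_reads_by_tag(reads_tbl(rep("ACGT", 3)))
  s <- build_sscs(fam[1, ])
  expect_equal(s$bases, "ACGT")
  expect_equal(s$kind, "SSCS")

  # 2/3 agreement at position 2 is below the 0.7 threshold -> N
  fam2 <- group_reads_by_tag(reads_tbl(c("ACGT", "ACGT", "ATGT")))
  expect_equal(build_sscs(fam2[1, ])$bases, "ANGT")

  # threshold 0.6 lets 2/3 through
  expect_equal(build_sscs(fam2[1, ], consensus_threshold = 0.6)$bases,
               "ACGT")

  # undersized family yields nothing
  fam3 <- group_reads_by_tag(reads_tbl(rep("ACGT", 2)))
  expect_null(build_sscs(fam3[1, ], min_family_size = 3))

  # ragged read lengths cannot be co-aligned
  fam4 <- group_reads_by_tag(reads_tbl(c("ACGT", "ACG")))
  expect_error(build_sscs(fam4[1, ], min_family_size = 1), "co-aligned")
})

test_that("vectorised SSCS equals per-family build_sscs", {
  withr::with_seed(99, {
    reads <- purrr::map_dfr(1:40, function(i) {
      n <- sample(1:6, 1)
      base <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
      seqs <- vapply(seq_len(n), function(j) {
        s <- base
        if (runif(1) < 0.5) {
          p <- sample(30, 1)
          substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        s
      }, "")
      reads_tbl(seqs, tag = paste0(
        paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      ), order = sample(c("ab", "ba"), 1), start = sample(50, 1))
    })
    fam <- group_reads_by_tag(reads)
    fast <- sscs_from_families(fam, min_family_size = 2)
    slow <- purrr::map_dfr(seq_len(nrow(fam)), function(i) {
      out <- build_sscs(fam[i, ], min_family_size = 2)
      if (is.null(out)) tibble::tibble() else out
    })
    ord <- function(x) dplyr::arrange(x, family_size, tag, strand_order,
                                      start, bases)
    expect_equal(ord(fast)[names(slow)], ord(slow), ignore_attr = TRUE)
  })
})

test_that("DCS keeps agreement and masks disagreement", {
  mk <- function(bases, order) tibble::tibble(
    kind = "SSCS", tag = "AAGGCCTT", canonical_tag = "AAGGCCTT",
    strand_order = order, start = 1L, bases = bases, family_size = 3L,
    indels = list(NULL)
  )
  d <- build_dcs(mk("ACGTAC", "ab"), mk("ACGTAC", "ba"))
  expect_equal(d$bases, "ACGTAC")
  expect_equal(d$kind, "DCS")

  # one disagreeing position is unscorable -> N, the rest still called
  d2 <- build_dcs(mk("ACGTAC", "ab"), mk("ACTTAC", "ba"))
  expect_equal(d2$bases, "ACNTAC")

  # an N on either strand cannot be confirmed
  d3 <- build_dcs(mk("ACNTAC", "ab"), mk("ACGTAC", "ba"))
  expect_equal(d3$bases, "ACNTAC")

  expect_error(build_dcs(mk("ACGTAC", "ab"), mk("ACGTAC", "ab")),
               "same strand order")
})

test_that("unpaired SSCS produce no DCS and are counted", {
  reads <- dplyr::bind_rows(
    reads_tbl(rep("ACGTACGTACGTACGT", 3), tag = "AAAACCCC", order = "ab"),
    reads_tbl(rep("ACGTACGTACGTACGT", 3), tag = "CCCCAAAA", order = "ba"),
    reads_tbl(rep("TTTTACGTACGTACGT", 3), tag = "GGGGTTTT", order = "ab")
  )
  sscs <- sscs_from_families(group_reads_by_tag(reads))
  dcs <- dcs_from_sscs(sscs)
  expect_equal(nrow(dcs), 1L)
  expect_equal(attr(dcs, "n_unpaired"), 1L)
  expect_equal(dcs$bases, "ACGTACGTACGTACGT")
})

test_that("consensus is invariant to read order and strand representation", {
  withr::with_seed(7, {
    toy <- make_toy_reference(200, c(protein = 0.5), seed = 2)
    alt50 <- setdiff(c("A", "C", "G", "T"),
                     ref_base(toy$reference, 50L))[1]
    pop <- simulate_population(toy$reference,
                               tibble::tibble(position = 50L, alt = alt50,
                                              clonality_pct = 100),
                               40, seed = 3)
    cfg <- duplex_sim_config(read_length = 60,
                             family_size = list(kind = "constant", size = 3),
                             pcr_error_rate = 0, seq_error_rate = 0.02,
                             seed = 4)
    sim <- simulate_duplex_reads(pop, cfg)
    run <- function(reads) {
      d <- dcs_from_sscs(sscs_from_families(group_reads_by_tag(reads)))
      dplyr::arrange(d[, c("tag", "start", "bases")], tag)
    }
    base <- run(sim$reads)
    # permutation invariance
    shuffled <- sim$reads[sample(nrow(sim$reads)), ]
    expect_equal(run(shuffled), base)
    # flipping every read's representation leaves DCS calls unchanged
    flipped <- sim$reads
    flipped$seq <- vapply(flipped$seq, oracle_revcomp, "")
    flipped$reversed <- !flipped$reversed
    expect_equal(run(flipped), base)
  })
})

test_that("error-free families reproduce the source molecule exactly", {
  toy <- make_toy_reference(150, c(protein = 0.4), seed = 5)
  pop <- simulate_population(toy$reference, tibble::tibble(), 30, seed = 6)
  cfg <- duplex_sim_config(read_length = 80,
                           family_size = list(kind = "constant", size = 3),
                           pcr_error_rate = 0, seq_error_rate = 0, seed = 7)
  sim <- simulate_duplex_reads(pop, cfg)
  sscs <- sscs_from_families(group_reads_by_tag(sim$reads))
  dcs <- dcs_from_sscs(sscs)
  expect_equal(nrow(dcs), 30L)
  ref <- toy$reference
  doubled <- paste0(ref$sequence, ref$sequence)
  expect_true(all(
    dcs$bases == substring(doubled, dcs$start, dcs$start + 79L)
  ))
})

test_that("DCS depth never exceeds either strand's SSCS depth", {
  toy <- make_toy_reference(120, c(protein = 0.5), seed = 8)
  pop <- simulate_population(toy$reference, tibble::tibble(), 50, seed = 9)
  cfg <- duplex_sim_config(read_length = 60,
                           family_size = list(kind = "lognormal",
                                              meanlog = log(3), sdlog = 0.6,
                                              min = 1),
                           pcr_error_rate = 1e-3, seq_error_rate = 0.01,
                           seed = 10)
  sim <- simulate_duplex_reads(pop, cfg)
  sscs <- sscs_from_families(group_reads_by_tag(sim$reads))
  dcs <- dcs_from_sscs(sscs)
  pd <- pileup(dcs, toy$reference)
  ps <- pileup(sscs, toy$reference)
  joined <- dplyr::left_join(pd, ps, by = "position",
                             suffix = c("_dcs", "_sscs"))
  expect_true(all(joined$depth_dcs <= joined$depth_sscs))
})

test_that("end clipping removes 5 + 6 terminal bases from counting", {
  cons <- tibble::tibble(
    kind = "DCS", tag = "x", canonical_tag = "x", strand_order = "duplex",
    start = c(1L, 1L, 1L),
    bases = c(strrep("A", 100), strrep("A", 11), strrep("A", 12)),
    family_size = 6L
  )
  clipped <- clip_ends(cons)
  expect_equal(nchar(clipped$bases), c(89L, 0L, 1L))
  expect_equal(clipped$start, c(6L, 6L, 6L))
  # the surviving base of the 12-mer is its 6th
  one <- tibble::tibble(kind = "DCS", tag = "x", canonical_tag = "x",
                        strand_order = "duplex", start = 1L,
                        bases = "AAAAAGTTTTTT", family_size = 6L)
  expect_equal(clip_ends(one)$bases, "G")
})

test_that("indel events need family support and both strands", {
  ind <- tibble::tibble(kind = "del", position = 10L, length = 2L, seq = "")
  no_ind <- tibble::tibble(kind = character(0), position = integer(0),
                           length = integer(0), seq = character(0))
  reads_ab <- reads_tbl(rep(strrep("A", 20), 3), tag = "AACCGGTT",
                        order = "ab")
  reads_ab$indels <- list(ind, ind, ind)
  reads_ba <- reads_tbl(rep(strrep("A", 20), 3), tag = "GGTTAACC",
                        order = "ba")
  reads_ba$indels <- list(ind, ind, no_ind)
  fam <- group_reads_by_tag(dplyr::bind_rows(reads_ab, reads_ba))
  sscs <- sscs_from_families(fam)
  # ab: 3/3 support; ba: 2/3 < 0.7 -> dropped there
  support <- sapply(sscs$indels, nrow)[order(sscs$strand_order)]
  expect_equal(unname(support), c(1L, 0L))
  dcs <- dcs_from_sscs(sscs)
  expect_equal(nrow(dcs$indels[[1]]), 0L) # not confirmed on both strands

  reads_ba$indels <- list(ind, ind, ind)
  fam2 <- group_reads_by_tag(dplyr::bind_rows(reads_ab, reads_ba))
  dcs2 <- dcs_from_sscs(sscs_from_families(fam2))
  expect_equal(nrow(dcs2$indels[[1]]), 1L)
  # clipping drops events in the trimmed margins
  expect_equal(nrow(clip_ends(dcs2, 5, 6)$indels[[1]]), 1L)
  expect_equal(nrow(clip_ends(dcs2, 11, 6)$indels[[1]]), 0L)
})
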