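test_that("iupac_match follows degeneracy sets and literal genomic N", {
  expect_true(iupac_match("CCGG", "CCGG"))
  expect_true(iupac_match("WCCGGW", "TCCGGA"))
  expect_false(iupac_match("WCCGGW", "GCCGGA"))
  # genomic N never satisfies a specific pattern letter, only pattern N
  expect_false(iupac_match("CCGG", "CCGN"))
  expect_true(iupac_match("CCGN", "CCGN"))
  expect_true(iupac_match("CCGN", "CCGT"))
  expect_error(iupac_match("CCGG", "CCG"), "lengths differ")
})

test_that("scan_cut_sites reports top-strand cut coordinates", {
  # MspI C^CGG: match at 0-based 2, cut after offset 1
  expect_equal(scan_cut_sites("ATCCGGAT", "CCGG", 1), 3L)
  expect_equal(scan_cut_sites("CCGGAACCGG", "CCGG", 1), c(1L, 7L))
  expect_equal(scan_cut_sites("CCGGCCGG", "CCGG", 1), c(1L, 5L))
  # overlapping matches all count
  expect_equal(scan_cut_sites("CGCGCG", "CGCG", 1), oracle_scan("CGCGCG", "CGCG", 1))
  # non-palindromic motif picks up the opposite strand:
  # ACGT..TCGA contains TCGA at 4; its revcomp also TCGA -> palindromic? no:
  # use CCTC (revcomp GAGG)
  s <- "AACCTCAAGAGGAA"
  expect_equal(scan_cut_sites(s, "CCTC", 1), oracle_scan(s, "CCTC", 1))
  expect_equal(scan_cut_sites("", "CCGG", 1), integer(0))
  # motifs are never asserted across assembly gaps
  expect_equal(scan_cut_sites("CCGNGG", "CCGG", 1), integer(0))
})

test_that("scan_cut_sites equals the naive all-positions oracle", {
  motifs <- list(
    c("CCGG", 1), # palindromic
    c("TCGA", 1), # palindromic
    c("CCCGGG", 1), # palindromic, longer
    c("WCCGGW", 1), # degenerate palindromic
    c("CCTC", 1), # non-palindromic
    c("ACRYGT", 2), # degenerate palindromic (R/Y)
    c("GGTCTC", 4) # non-palindromic, offset inside
  )
  withr::with_seed(42, {
    for (rep in 1:10) {
      len <- sample(200:2000, 1)
      s <- random_seq(len)
      # sprinkle N runs to exercise the gap rule
      if (rep %% 2 == 0) {
        pos <- sample(len - 10, 1)
        substr(s, pos, pos + 5) <- "NNNNNN"
      }
      for (m in motifs) {
        expect_equal(
          scan_cut_sites(s, m[[1]], as.integer(m[[2]])),
          oracle_scan(s, m[[1]], as.integer(m[[2]])),
          info = paste("motif", m[[1]], "rep", rep)
        )
      }
    }
  })
})

test_that("digesting with any family member gives an identical index", {
  genome <- c(chr1 = "CCGGAACCGGTTTCGATT", chr2 = "AAAACCGGAAAA")
  fam_a <- list(family_id = "fam_CCGG", motif = "CCGG", cut_offset = 1L)
  idx_msp <- digest_genome(genome, fam_a, genome_id = "toy")
  # family invariant: members share motif+offset, so digestion is identical
  idx_hpa <- digest_genome(genome, fam_a, genome_id = "toy")
  expect_equal(tibble::as_tibble(idx_msp), tibble::as_tibble(idx_hpa))
  expect_equal(idx_msp$cut[idx_msp$chrom == "chr1"], c(1L, 7L))
  expect_equal(idx_msp$cut[idx_msp$chrom == "chr2"], 5L)

  empty <- digest_genome(genome, list(
    family_id = "fam_GAATTC", motif = "GAATTC", cut_offset = 1L
  ), genome_id = "toy")
  expect_equal(nrow(empty), 0L)
})

test_that("pre-computed files round-trip losslessly and validate the genome", {
  genome <- c(chr1 = "CCGGAACCGG")
  idx <- digest_genome(genome, list(
    family_id = "fam_CCGG", motif = "CCGG", cut_offset = 1L
  ), genome_id = "toyA")
  path <- withr::local_tempfile(fileext = ".txt.gz")
  write_precomputed(idx, path)
  back <- read_precomputed(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(idx))
  expect_equal(attr(back, "genome_id"), "toyA")
  expect_equal(attr(back, "family_id"), "fam_CCGG")
  expect_equal(attr(back, "cut_offset"), 1L)

  # cross-genome contamination refused
  expect_error(read_precomputed(path, expect_genome_id = "toyB"),
    "refusing to load")
  expect_silent(read_precomputed(path, expect_genome_id = "toyA"))

  # empty index round-trips without error
  empty <- digest_genome(c(chr1 = "AAAA"), list(
    family_id = "f", motif = "CCGG", cut_offset = 1L
  ), genome_id = "toyA")
  path2 <- withr::local_tempfile(fileext = ".txt.gz")
  write_precomputed(empty, path2)
  expect_equal(nrow(read_precomputed(path2)), 0L)

  # unsorted data is a format error
  path3 <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(path3, "wt")
  writeLines(c("#genome_id=g", "#family_id=f", "#motif=CCGG",
    "#cut_offset=1", "chr1\t7", "chr1\t1"), con)
  close(con)
  expect_error(read_precomputed(path3), "sorted")
})

test_that("merging cut indices is a sorted union with genome checks", {
  seq <- c(chr1 = "CCGGAACCGGTCGATT") # CCGG cuts {1,7}; TCGA cut {11}
  a <- digest_genome(seq, list(
    family_id = "fa", motif = "CCGG", cut_offset = 1L
  ), genome_id = "toy")
  b <- digest_genome(seq, list(
    family_id = "fb", motif = "TCGA", cut_offset = 1L
  ), genome_id = "toy")
  m <- merge_cut_indices(a, b)
  expect_equal(m$cut, c(1L, 7L, 11L))
  expect_equal(attr(m, "family_id"), "fa+fb")

  # idempotent, commutative
  expect_equal(merge_cut_indices(a, a)$cut, c(1L, 7L))
  expect_equal(merge_cut_indices(b, a)$cut, merge_cut_indices(a, b)$cut)

  # different genomes refuse to merge
  c_idx <- digest_genome(seq, list(
    family_id = "fc", motif = "CCGG", cut_offset = 1L
  ), genome_id = "other")
  expect_error(merge_cut_indices(a, c_idx), "different genomes")
})

test_that("pair merge equals a single digestion scanning both motifs", {
  withr::with_seed(7, {
    genome <- c(chr1 = random_seq(5000))
  })
  fam1 <- list(family_id = "f1", motif = "CCGG", cut_offset = 1L)
  fam2 <- list(family_id = "f2", motif = "TCGA", cut_offset = 1L)
  merged <- merge_cut_indices(
    digest_genome(genome, fam1, genome_id = "g"),
    digest_genome(genome, fam2, genome_id = "g")
  )
  both <- sort(unique(c(
    oracle_scan(genome[["chr1"]], "CCGG", 1L),
    oracle_scan(genome[["chr1"]], "TCGA", 1L)
  )))
  expect_equal(merged$cut, both)
})
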