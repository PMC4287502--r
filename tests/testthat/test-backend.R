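test_that("perfect unique reads map with AS 0 and no XS", {
  g <- random_genome(400, seed = 2)
  read <- substr(unclass(g)[[1]], 101, 120)
  res <- align_exhaustive(read, q40(20), g, "forward")
  ## a 20-mer of a random 400 bp genome is almost surely unique; verify
  orc <- oracle_align(unclass(g)[[1]], read, q40(20))
  expect_true(res$mapped)
  expect_equal(res$pos, orc$pos + 1L)
  expect_equal(res$AS, 0L)
  expect_equal(res$XS, as.integer(orc$XS))
})

test_that("exact repeats yield AS 0 with XS 0", {
  seg <- "ATGGATTAGTTAAGGATTAA"
  g <- bs_genome(c(chr1 = paste0("TTTTT", seg, "TTTTT", seg, "TTTTT")))
  res <- align_exhaustive(seg, q40(20), g, "forward")
  expect_true(res$mapped)
  expect_equal(res$AS, 0L)
  expect_equal(res$XS, 0L)
  expect_equal(res$pos, 6L)  # smallest coordinate wins the tie
})

test_that("a single quality-40 mismatch costs the maximum penalty (AS -6)", {
  g <- random_genome(500, seed = 3)
  read <- substr(unclass(g)[[1]], 201, 230)
  sub <- substr(read, 15, 15)
  substr(read, 15, 15) <- c(A = "C", C = "A", G = "T", T = "G")[[sub]]
  res <- align_exhaustive(read, q40(30), g, "forward")
  expect_true(res$mapped)
  expect_equal(res$AS, -6L)
  ## and at quality 0 the same mismatch costs the minimum penalty
  qual <- q40(30)
  substr(qual, 15, 15) <- "!"
  res0 <- align_exhaustive(read, qual, g, "forward")
  expect_equal(res0$AS, -2L)
})

test_that("built-in aligner equals the brute-force oracle on random reads", {
  g <- random_genome(2000, seed = 7)
  gs <- unclass(g)[[1]]
  withr::with_seed(99, {
    for (i in 1:60) {
      L <- sample(c(20L, 35L, 50L), 1)
      start <- sample(nchar(gs) - L, 1)
      read <- substr(gs, start, start + L - 1L)
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        for (p in sample(L, nmut)) {
          substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
      }
      qual <- paste(intToUtf8(33L + sample(10:40, L, TRUE),
                              multiple = TRUE), collapse = "")
      res <- align_exhaustive(read, qual, g, "forward")
      orc <- oracle_align(gs, read, qual)
      expect_equal(res$mapped, orc$mapped)
      if (orc$mapped) {
        expect_equal(res$AS, as.integer(orc$AS))
        expect_equal(res$pos, orc$pos + 1L)
        expect_equal(res$XS, as.integer(orc$XS))
      }
    }
  })
})

test_that("seeded and full-scan paths agree on an indexable genome", {
  ## genomes >= 4 kb engage the k-mer index; compare against the oracle,
  ## which is a full scan by construction
  g <- random_genome(6000, seed = 13)
  gs <- unclass(g)[[1]]
  withr::with_seed(42, {
    for (i in 1:25) {
      start <- sample(nchar(gs) - 50L, 1)
      read <- substr(gs, start, start + 49L)
      for (p in sample(50, sample(0:4, 1))) {
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      res <- align_exhaustive(read, q40(50), g, "forward")
      orc <- oracle_align(gs, read, q40(50))
      expect_equal(res$mapped, orc$mapped)
      if (orc$mapped) {
        expect_equal(res$pos, orc$pos + 1L)
        expect_equal(res$AS, as.integer(orc$AS))
        expect_equal(res$XS, as.integer(orc$XS))
      }
    }
  })
})

test_that("adding a mismatch never increases AS", {
  g <- random_genome(1500, seed = 21)
  gs <- unclass(g)[[1]]
  withr::with_seed(5, {
    for (i in 1:20) {
      start <- sample(nchar(gs) - 40L, 1)
      read <- substr(gs, start, start + 39L)
      prev <- align_exhaustive(read, q40(40), g, "forward")$AS
      for (step in 1:3) {
        p <- sample(40, 1)
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
        cur <- align_exhaustive(read, q40(40), g, "forward")
        curAS <- if (cur$mapped) cur$AS else -Inf
        expect_lte(curAS, prev)
        prev <- curAS
        if (!cur$mapped) break
      }
    }
  })
})

test_that("reverse orientation reports leftmost forward coordinates", {
  g <- random_genome(800, seed = 31)
  gs <- unclass(g)[[1]]
  frag <- substr(gs, 301, 340)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  res <- align_exhaustive(rc, q40(40), g, "reverse")
  expect_true(res$mapped)
  expect_equal(res$pos, 301L)
  expect_true(res$rev)
})

test_that("pair scores sum mate scores and missing mates drop the strand", {
  expect_equal(pair_score(-2L, -4L), -6L)
  expect_equal(pair_score(0L, 0L), 0L)
  expect_true(is.na(pair_score(NA_integer_, 0L)))
})

test_that("oversized references are refused by the built-in backend", {
  g <- random_genome(2000, seed = 1)
  expect_error(align_exhaustive("ACGT", "IIII", g, "forward", cap = 1000),
               "external backend")
  expect_error(align_bs(tibble::tibble(name = "r", mate = 0L, seq = "ACGTACGT",
                                       qual = q40(8)),
                        g, protocol("directional", "single"), cap = 1000),
               "external backend")
})

test_that("the external backend wrapper rejects a missing executable", {
  expect_error(
    align_external("reads.fq", "idx", aligner = "no-such-aligner-xyz"),
    "not found on the PATH"
  )
})
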