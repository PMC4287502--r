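test_that("total extracted calls equal the brute-force XM symbol count", {
  g <- random_genome(4000, seed = 5)
  cfg <- sim_config(n_fragments = 100, pairing = "single", error_rate = 0.01,
                    seed = 9)
  aln <- align_bs(simulate_reads(g, cfg), g, protocol("directional", "single"))
  counts <- extract_methylation(aln, g, no_filters())
  kept <- aln[aln$mapped, ]
  expect_equal(sum(counts$n_meth + counts$n_unmeth),
               oracle_xm_call_count(kept$XM))
})

test_that("overlapping mates are processed as a unit", {
  g <- bs_genome(c(chr1 = "TTACGTTACGTT"))
  ## both mates fully overlap and agree at the CpG (pos 3, 0-based 2)
  pair_agree <- as_bs_aln(
    aln_row("p1", "chr1", 2, "TACGTT", "..Z...", mate = 1),
    aln_row("p1", "chr1", 2, "TACGTT", "..Z...", mate = 2, rev = TRUE)
  )
  c1 <- extract_methylation(pair_agree, g, no_filters())
  expect_equal(c1$n_meth[c1$pos == 3], 1L)

  ## one mate has an N (no call) at the C; the other call is used
  pair_n <- as_bs_aln(
    aln_row("p2", "chr1", 2, "TANGTT", "......", mate = 1),
    aln_row("p2", "chr1", 2, "TACGTT", "..Z...", mate = 2, rev = TRUE)
  )
  c2 <- extract_methylation(pair_n, g, no_filters())
  expect_equal(c2$n_meth[c2$pos == 3], 1L)

  ## both mates carry high-quality calls that disagree: position dropped
  pair_dis <- as_bs_aln(
    aln_row("p3", "chr1", 2, "TACGTT", "..Z...", mate = 1),
    aln_row("p3", "chr1", 2, "TATGTT", "..z...", mate = 2, rev = TRUE)
  )
  c3 <- extract_methylation(pair_dis, g, no_filters())
  expect_false(3 %in% c3$pos)

  ## if one of the disagreeing calls is below the Phred floor, the survivor
  ## is used (low-quality calls are treated as absent)
  lowq <- paste0("II", "!", "III")
  pair_lowq <- as_bs_aln(
    aln_row("p4", "chr1", 2, "TACGTT", "..Z...", mate = 1),
    aln_row("p4", "chr1", 2, "TATGTT", "..z...", qual = lowq, mate = 2,
            rev = TRUE)
  )
  c4 <- extract_methylation(pair_lowq, g, filter_config(min_mapq = 0))
  expect_equal(c4$n_meth[c4$pos == 3], 1L)
})

test_that("duplicating every read as a fully overlapping pair changes nothing", {
  g <- random_genome(3000, seed = 8)
  cfg <- sim_config(n_fragments = 80, pairing = "single", error_rate = 0,
                    seed = 4)
  aln <- align_bs(simulate_reads(g, cfg), g, protocol("directional", "single"))
  single <- extract_methylation(aln, g, no_filters())
  m1 <- aln[aln$mapped, ]
  m1$mate <- 1L
  m2 <- m1
  m2$mate <- 2L
  both <- as_bs_aln(m1, m2)
  paired <- extract_methylation(both, g, no_filters())
  expect_equal(as.data.frame(single[single$chrom %in% paired$chrom, ]),
               as.data.frame(paired))
})

test_that("record-level filters are honoured", {
  g <- bs_genome(c(chr1 = "TTACGTTACGTT"))
  aln <- as_bs_aln(
    aln_row("ok", "chr1", 2, "TACGTT", "..Z..."),
    aln_row("lowmapq", "chr1", 2, "TACGTT", "..Z...", mapq = 5L),
    aln_row("dupped", "chr1", 2, "TACGTT", "..Z...", dup = TRUE)
  )
  counts <- extract_methylation(aln, g, filter_config(min_mapq = 10))
  expect_equal(counts$n_meth[counts$pos == 3], 1L)
  ## missing XM on a mapped record warns with the rejected count
  aln2 <- as_bs_aln(aln_row("noxm", "chr1", 2, "TACGTT", NA_character_))
  expect_warning(extract_methylation(aln2, g, no_filters()), "1 mapped")
})

test_that("trim bounds exclude read positions per strand and mate", {
  g <- bs_genome(c(chr1 = "TTACGTTACGTT"))
  aln <- as_bs_aln(aln_row("r", "chr1", 2, "TACGTTACG", "..Z....Z."))
  trims <- tibble::tibble(strand = "OT", mate = 1L, start = 4L, end = 9L)
  counts <- extract_methylation(aln, g,
                                filter_config(min_mapq = 0, trims = trims))
  expect_false(3 %in% counts$pos)       # read position 3: trimmed
  expect_equal(counts$n_meth[counts$pos == 8], 1L)  # read position 8: kept
  ## trims address the sequencing orientation on reverse-strand records
  rc <- aln_row("rv", "chr1", 2, "TACGTTACG", "..Z....Z.", strand = "OB",
                rev = TRUE)
  ## for a reverse record read position 1 is the rightmost SAM base
  tr2 <- tibble::tibble(strand = "OB", mate = 1L, start = 1L, end = 3L)
  c2 <- extract_methylation(as_bs_aln(rc), g,
                            filter_config(min_mapq = 0, trims = tr2))
  expect_true(all(c2$pos == 8))
})

test_that("bedGraph output matches the documented layout and round-trips", {
  g <- bs_genome(c(chr1 = paste0("TTACGTTACGTT", strrep("T", 5)),
                   chr2 = "ACGTACGT"))
  counts <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), pos = c(3L, 8L, 1L),
    strand = c("+", "+", "+"), context = "CpG",
    n_meth = c(2L, 3L, 0L), n_unmeth = c(2L, 0L, 4L)
  )
  attr(counts, "contigs") <- names(g)
  class(counts) <- c("bs_counts", class(counts))
  dir <- withr::local_tempdir()
  paths <- write_bedgraph(counts, dir, prefix = "t")
  lines <- readLines(paths[["CpG"]])
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[2], "chr1\t3\t4\t50\t2\t2")
  expect_equal(lines[3], "chr1\t8\t9\t100\t3\t0")
  back <- read_bedgraph(paths[["CpG"]], g, "CpG")
  expect_equal(as.data.frame(back), as.data.frame(counts))
  ## empty counts give a header-only file
  empty <- counts[0, ]
  attr(empty, "contigs") <- names(g)
  p2 <- write_bedgraph(empty, dir, prefix = "e", contexts = "CpG")
  expect_length(readLines(p2[["CpG"]]), 1L)
})

test_that("merge_cpg pools the two cytosines of each CpG at the + coordinate", {
  g <- bs_genome(c(chr1 = "TTTTTTTTTTCGTTTTTCGT"))
  mk <- function(df) {
    attr(df, "contigs") <- "chr1"
    class(df) <- c("bs_counts", class(df))
    df
  }
  counts <- mk(tibble::tibble(
    chrom = "chr1", pos = c(10L, 11L, 17L), strand = c("+", "-", "+"),
    context = "CpG", n_meth = c(4L, 0L, 1L), n_unmeth = c(0L, 4L, 0L)
  ))
  merged <- merge_cpg(counts, g)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$pos, c(10L, 17L))
  expect_equal(merged$n_meth[1], 4L)
  expect_equal(merged$n_unmeth[1], 4L)
  ## totals conserved
  expect_equal(sum(merged$n_meth + merged$n_unmeth),
               sum(counts$n_meth + counts$n_unmeth))
  ## minus-only coverage is still placed at the + C coordinate
  solo <- mk(tibble::tibble(chrom = "chr1", pos = 11L, strand = "-",
                            context = "CpG", n_meth = 2L, n_unmeth = 1L))
  expect_equal(merge_cpg(solo, g)$pos, 10L)
  ## a record that is not a genomic CpG cytosine is rejected
  bad <- mk(tibble::tibble(chrom = "chr1", pos = 2L, strand = "+",
                           context = "CpG", n_meth = 1L, n_unmeth = 0L))
  expect_error(merge_cpg(bad, g), "not a genomic CpG")
})

test_that("replicate merging adds counts per key", {
  mk <- function(pos, m, u) {
    df <- tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                         context = "CpG", n_meth = m, n_unmeth = u)
    attr(df, "contigs") <- "chr1"
    class(df) <- c("bs_counts", class(df))
    df
  }
  a <- mk(5L, 1L, 1L)
  b <- mk(5L, 2L, 0L)
  ab <- merge_replicates(a, b)
  expect_equal(ab$n_meth, 3L)
  expect_equal(ab$n_unmeth, 1L)
  ## single input is the identity
  expect_equal(as.data.frame(merge_replicates(a)), as.data.frame(a))
  ## disjoint positions concatenate into a sorted union
  d <- merge_replicates(mk(9L, 1L, 0L), mk(2L, 0L, 1L))
  expect_equal(d$pos, c(2L, 9L))
})

test_that("coverage table counts CpGs at each threshold, non-increasing", {
  df <- tibble::tibble(chrom = "chr1", pos = c(1L, 5L, 9L), strand = "+",
                       context = "CpG", n_meth = c(1L, 3L, 6L),
                       n_unmeth = c(0L, 2L, 6L))
  cm <- coverage_metrics(df)
  expect_equal(cm$n_cpg[cm$threshold == 1], 3L)
  expect_equal(cm$n_cpg[cm$threshold == 3], 2L)
  expect_equal(cm$n_cpg[cm$threshold == 5], 2L)
  expect_equal(cm$n_cpg[cm$threshold == 10], 1L)
  expect_true(all(diff(cm$n_cpg) <= 0L))
  expect_true(all(coverage_metrics(df[0, ])$n_cpg == 0L))
})

test_that("methylKit and BSseq exports round-trip the counts", {
  counts <- tibble::tibble(chrom = "chr1", pos = 9L, strand = "+",
                           context = "CpG", n_meth = 3L, n_unmeth = 1L)
  dir <- withr::local_tempdir()
  mk <- file.path(dir, "x.methylKit")
  export_format(counts, "methylKit", mk)
  got <- readr::read_tsv(mk, show_col_types = FALSE,
                         col_types = readr::cols(strand = readr::col_character()))
  expect_equal(got$base, 10)     # 1-based coordinate
  expect_equal(got$coverage, 4)
  expect_equal(got$freqC, 75)
  expect_equal(got$freqT, 25)
  expect_equal(got$strand, "F")
  back <- read_export(mk, "methylKit")
  expect_equal(back$pos, 9L)
  expect_equal(back$n_meth, 3L)
  expect_equal(back$n_unmeth, 1L)

  bs <- file.path(dir, "x.bsseq")
  export_format(counts, "BSseq", bs)
  got2 <- readr::read_tsv(bs, show_col_types = FALSE)
  expect_equal(got2$pos, 10)
  expect_equal(got2$Cov, 4)
  expect_equal(got2$M, 3)
  back2 <- read_export(bs, "BSseq")
  expect_equal(back2$n_meth, 3L)
  expect_equal(back2$n_unmeth, 1L)

  ## empty counts produce a header-only file
  export_format(counts[0, ], "BSseq", bs)
  expect_length(readLines(bs), 1L)
  expect_error(export_format(counts, "wig", "x"), "supported dialects")
})
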