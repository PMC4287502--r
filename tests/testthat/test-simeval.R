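test_that("simulation is byte-identical under a fixed seed", {
  g <- random_genome(5000, seed = 3)
  cfg <- sim_config(n_fragments = 200, pairing = "paired", seed = 42)
  a <- simulate_reads(g, cfg)
  b <- simulate_reads(g, cfg)
  expect_identical(a, b)
  c2 <- simulate_reads(g, sim_config(n_fragments = 200, pairing = "paired",
                                     seed = 43))
  expect_false(identical(a, c2))
})

test_that("full methylation leaves genomic cytosines unconverted", {
  g <- random_genome(3000, seed = 5)
  cfg <- sim_config(n_fragments = 50, pairing = "single", error_rate = 0,
                    meth_prob = c(CpG = 1, CHG = 1, CHH = 1), seed = 2)
  rd <- simulate_reads(g, cfg)
  tr <- parse_truth(rd$name)
  gs <- unclass(g)[[1]]
  for (i in seq_len(nrow(rd))) {
    win <- substr(gs, tr$start[i], tr$start[i] + 49L)
    expect_equal(rd$seq[i],
                 if (tr$strand[i] == "-") revcomp_chr(win) else win)
  }
  expect_true(all(grepl("^1*$", tr$mask)))
})

test_that("zero methylation with full conversion reads every fragment C as T", {
  g <- random_genome(3000, seed = 6)
  cfg <- sim_config(n_fragments = 50, pairing = "single", error_rate = 0,
                    meth_prob = c(CpG = 0, CHG = 0, CHH = 0),
                    conversion_rate = 1, seed = 2)
  rd <- simulate_reads(g, cfg)
  expect_false(any(grepl("C", rd$seq)))
  expect_true(all(grepl("^0*$", parse_truth(rd$name)$mask)))
})

test_that("truth names round-trip through FASTQ", {
  g <- random_genome(3000, seed = 7)
  rd <- simulate_reads(g, sim_config(n_fragments = 30, pairing = "paired",
                                     seed = 9))
  dir <- withr::local_tempdir()
  write_fastq(rd, file.path(dir, "r1.fastq.gz"), mate = 1L)
  write_fastq(rd, file.path(dir, "r2.fastq.gz"), mate = 2L)
  back <- read_fastq_pair(file.path(dir, "r1.fastq.gz"),
                          file.path(dir, "r2.fastq.gz"))
  expect_identical(back$seq, rd$seq)
  expect_identical(back$qual, rd$qual)
  tr <- parse_truth(unique(back$name))
  expect_false(anyNA(tr$start))
  expect_true(all(tr$strand %in% c("+", "-")))
})

test_that("accuracy classification follows the correct/incorrect/discarded rules", {
  mk <- function(qname, mapped, pos = NA_integer_, mapq = 0L,
                 chrom = NA_character_) {
    r <- aln_row(qname, chrom = chrom, pos = if (is.na(pos)) 1L else pos,
                 seq = "ACGT", xm = "....", mapq = mapq, mapped = mapped)
    r$chrom <- chrom
    r$pos <- pos
    r
  }
  aln <- as_bs_aln(
    mk("sim0000001:chr1:100:+:1", TRUE, 100L, 42L, "chr1"),  # correct
    mk("sim0000002:chr1:200:+:",  TRUE, 201L, 42L, "chr1"),  # incorrect
    mk("sim0000003:chr1:300:-:0", FALSE),                    # discarded
    mk("sim0000004:chr1:400:+:1", TRUE, 400L, 2L, "chr1")    # low MAPQ
  )
  acc <- evaluate_accuracy(aln, mapq_threshold = 10L)
  s <- acc$summary
  expect_equal(s$n_correct, c(2L, 1L))
  expect_equal(s$n_incorrect, c(1L, 1L))
  expect_equal(s$n_discarded, c(1L, 2L))
  ## the three classes always partition the input
  expect_true(all(s$n_correct + s$n_incorrect + s$n_discarded == s$n_total))
  td <- generics::tidy(acc)
  expect_equal(sum(td$n[td$stratum == "all"]), 4L)
  gl <- generics::glance(acc)
  expect_equal(gl$correct_pct, 50)
  expect_equal(gl$discarded_pct_mapq, 50)
})

test_that("unparseable truth names are rejected with a count", {
  aln <- as_bs_aln(
    aln_row("sim0000001:chr1:5:+:", "chr1", 5, "ACGT", "...."),
    aln_row("garbled", "chr1", 5, "ACGT", "....")
  )
  expect_warning(acc <- evaluate_accuracy(aln), "1 record")
  expect_equal(acc$summary$n_total[1], 1L)
})

test_that("concordance compares runs by name and start coordinate", {
  a <- as_bs_aln(
    aln_row("r1", "chr1", 10, "ACGT", "...."),
    aln_row("r2", "chr1", 20, "ACGT", "...."),
    aln_row("r3", "chr1", 30, "ACGT", "....")
  )
  ## identical runs: all concordant
  same <- concordance(a, a)
  expect_equal(same$summary$n[same$summary$status == "concordant"], 3L)
  ## a 1 bp shift makes every unit discordant
  b <- a
  b$pos <- b$pos + 1L
  shift <- concordance(a, b)
  expect_equal(shift$summary$n[shift$summary$status == "discordant"], 3L)
  ## units mapped in only one run are tallied separately with their MAPQ
  c3 <- a[a$qname != "r3", ]
  only <- concordance(a, c3)
  expect_equal(only$summary$n[only$summary$status == "only_a"], 1L)
  expect_equal(only$per_read$mapq_a[only$per_read$status == "only_a"], 42L)
  ## duplicate primary records for one name are rejected
  dupa <- as_bs_aln(aln_row("r1", "chr1", 10, "ACGT", "...."),
                    aln_row("r1", "chr1", 12, "ACGT", "...."))
  expect_error(concordance(dupa, a), "duplicate primary")
})

test_that("error-free reads on a repeat-free genome are never misplaced", {
  g <- random_genome(6000, seed = 15)
  cfg <- sim_config(n_fragments = 300, pairing = "single", error_rate = 0,
                    seed = 21)
  aln <- align_bs(simulate_reads(g, cfg), g, protocol("directional", "single"))
  acc <- evaluate_accuracy(aln)
  expect_equal(acc$summary$n_incorrect, c(0L, 0L))
})
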