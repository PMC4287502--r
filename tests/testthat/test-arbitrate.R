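test_that("cross-strand arbitration follows the tie and XS-rewrite rules", {
  ## equally good alignments on two strands: unmapped
  tie <- select_best(tibble::tibble(strand = c("OT", "OB"), AS = c(-6L, -6L)))
  expect_equal(nrow(tie), 0L)
  ## unique winner inherits the best other-strand score as XS
  win <- select_best(tibble::tibble(strand = c("OT", "OB"), AS = c(0L, -12L)))
  expect_equal(win$strand, "OT")
  expect_equal(win$XS, -12L)
  ## an existing higher XS is left unmodified
  keep <- select_best(tibble::tibble(strand = c("OT", "OB"), AS = c(0L, -12L),
                                     XS = c(-3L, NA)))
  expect_equal(keep$XS, -3L)
  ## no candidates at all: unmapped
  expect_equal(nrow(select_best(tibble::tibble(strand = character(),
                                               AS = integer()))), 0L)
})

test_that("arbitration matches a brute-force restatement on random candidate sets", {
  withr::with_seed(123, {
    for (i in 1:300) {
      k <- sample(0:4, 1)
      AS <- rep(NA_integer_, 4)
      XS <- rep(NA_integer_, 4)
      if (k > 0) {
        sel <- sample(4, k)
        AS[sel] <- -sample(0:40, k, replace = TRUE)
        has_xs <- runif(k) < 0.5
        XS[sel[has_xs]] <- AS[sel[has_xs]] - sample(0:20, sum(has_xs),
                                                    replace = TRUE)
      }
      cand <- tibble::tibble(strand = c("OT", "OB", "CTOT", "CTOB"),
                             AS = AS, XS = XS)
      got <- select_best(cand)
      exp <- oracle_select_best(AS, XS)
      if (is.null(exp)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(match(got$strand, cand$strand), exp$strand)
        expect_equal(got$AS, exp$AS)
        expect_equal(got$XS, exp$XS)
      }
    }
  })
})

test_that("MAPQ recalculation spans [0,42] with the documented extremes", {
  ## perfect unique alignment
  expect_equal(recalc_mapq(0L, NA_integer_, 50L), 42L)
  ## exact repeat: AS == XS gives at most 3
  expect_lte(recalc_mapq(0L, 0L, 50L), 3L)
  expect_lte(recalc_mapq(-10L, -10L, 50L), 3L)
  ## clamped to the valid range over a grid
  grid <- expand.grid(AS = seq(-30L, 0L, 3L), d = c(NA, 0L, 5L, 15L, 40L))
  xs <- ifelse(is.na(grid$d), NA_integer_,
               pmax(grid$AS - grid$d, -31L))
  mq <- recalc_mapq(grid$AS, xs, 50L)
  expect_true(all(mq >= 0L & mq <= 42L))
  ## AS below the minimum valid score is a caller bug
  expect_error(recalc_mapq(-100L, NA_integer_, 50L), "caller bug")
})

test_that("MAPQ is monotone: non-increasing in XS, non-decreasing in AS", {
  for (AS in c(0L, -5L, -12L, -20L)) {
    xs_grid <- c(NA_integer_, seq(-30L, AS, by = 2L))
    mq <- recalc_mapq(rep(AS, length(xs_grid)), xs_grid, 50L)
    expect_true(all(diff(mq[-1L]) <= 0L))   # rising XS can only lower MAPQ
    expect_true(all(mq[-1L] <= mq[1L]))     # never above the unique value
  }
  for (XS in c(NA_integer_, -25L, -15L)) {
    as_grid <- seq(if (is.na(XS)) -30L else XS, 0L, by = 1L)
    mq <- recalc_mapq(as_grid, rep(XS, length(as_grid)), 50L)
    expect_true(all(diff(mq) >= 0L))
  }
})

test_that("methylation strings follow the genome-C / read-base rules", {
  g <- bs_genome(c(chr1 = "TACGA"))
  ## read C at a genomic CpG C: methylated call
  expect_equal(assign_methylation("chr1", 1L, "5M", "TACGA", "CT", g),
               "..Z..")
  ## read T at the same C: unmethylated call
  expect_equal(assign_methylation("chr1", 1L, "5M", "TATGA", "CT", g),
               "..z..")
  ## any other base is a mismatch: no call
  expect_equal(assign_methylation("chr1", 1L, "5M", "TAAGA", "CT", g),
               ".....")
  ## bottom strand: G retained = methylated, A = converted
  expect_equal(assign_methylation("chr1", 1L, "5M", "TACGA", "GA", g),
               "...Z.")
  expect_equal(assign_methylation("chr1", 1L, "5M", "TACAA", "GA", g),
               "...z.")
})

test_that("contexts are classified CpG > CHG > CHH from the source genome", {
  g <- bs_genome(c(chr1 = "CGACAGACTACC"))
  ##               12345678901 2
  ## C1: CG (Z); C4: CAG -> CHG? C A G yes X; C8: CTA -> CHH (H)
  xm <- assign_methylation("chr1", 1L, "12M", "CGACAGACTACC", "CT", g)
  expect_equal(substr(xm, 1, 1), "Z")
  expect_equal(substr(xm, 4, 4), "X")
  expect_equal(substr(xm, 8, 8), "H")
  ## context running past the contig end gets no call
  expect_equal(substr(xm, 12, 12), ".")
  g2 <- bs_genome(c(chr1 = "AAC"))
  expect_equal(assign_methylation("chr1", 1L, "3M", "AAC", "CT", g2), "...")
})

test_that("CIGAR insertions and soft clips get no call; deletions skip genome", {
  g <- bs_genome(c(chr1 = "TTACGTTTTT"))
  ## 2S: clipped bases never called; the CG at 3-4 still is
  xm <- assign_methylation("chr1", 3L, "2S4M", "GGACGT", "CT", g)
  expect_equal(xm, "...Z..")
  ## insertion in the read: the inserted base gets '.'
  xm2 <- assign_methylation("chr1", 3L, "2M2I2M", "ACAAGT", "CT", g)
  expect_equal(substr(xm2, 3, 4), "..")
  ## deletion: genome advances, read positions still called correctly
  xm3 <- assign_methylation("chr1", 1L, "2M2D4M", "TTGTTT", "CT", g)
  expect_equal(nchar(xm3), 6L)
  expect_error(assign_methylation("chr1", 8L, "5M", "TTTTT", "CT", g),
               "beyond contig")
})

test_that("alignment drops cross-strand ties but keeps unique strand winners", {
  ## genome carries a segment and its reverse complement: a C/G-free read
  ## from the segment aligns equally well as OT and OB and must be unmapped
  seg <- "ATTATTAAATTTATAATTAA"
  filler1 <- "GGCGGACCGGACCAGGCAGG"
  filler2 <- "CCAGGACGGACGGATTGGAC"
  rcseg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  g <- bs_genome(c(chr1 = paste0(filler1, seg, filler2, rcseg, filler1)))
  reads <- tibble::tibble(name = c("tie", "uniq"), mate = 0L,
                          seq = c(seg, filler2), qual = q40(20))
  aln <- align_bs(reads, g, protocol("directional", "single"))
  expect_false(aln$mapped[aln$qname == "tie"])
  expect_true(aln$mapped[aln$qname == "uniq"])
  expect_equal(aln$chrom[aln$qname == "uniq"], "chr1")
  expect_equal(aln$pos[aln$qname == "uniq"], 41L)
})

test_that("emitted alignments carry consistent strand, tag and XM invariants", {
  g <- random_genome(4000, seed = 17)
  cfg <- sim_config(n_fragments = 150, pairing = "paired", error_rate = 0.002,
                    insert_mean = 120, insert_sd = 20, seed = 3)
  rd <- simulate_reads(g, cfg)
  aln <- align_bs(rd, g, protocol("directional", "paired"))
  m <- aln[aln$mapped, ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$mapq >= 0 & m$mapq <= 42))
  expect_true(all(nchar(m$XM) == nchar(m$seq)))
  expect_true(all(grepl("^[ZzXxHh.]*$", m$XM)))
  ## xg/xr consistency for mate-1 records
  m1 <- m[m$mate == 1L, ]
  tab <- dplyr::distinct(tibble::as_tibble(m1)[, c("strand", "XG", "XR")])
  exp <- tibble::tibble(strand = c("OT", "OB"), XG = c("CT", "GA"),
                        XR = c("CT", "CT"))
  expect_equal(dplyr::arrange(tab, strand),
               dplyr::arrange(exp[exp$strand %in% tab$strand, ], strand))
  ## both mates of a pair always share chrom and strand
  pairs <- m |>
    dplyr::group_by(qname) |>
    dplyr::summarise(ok = dplyr::n_distinct(chrom) == 1 &
                       dplyr::n_distinct(strand) == 1, n = dplyr::n())
  expect_true(all(pairs$ok[pairs$n == 2]))
})
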