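# Shared fixture builders. All fixtures are generated in code; nothing is
# stored on disk.

random_genome <- function(len, seed = 1L, name = "chr1",
                          prob = c(0.3, 0.2, 0.2, 0.3)) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = prob), collapse = "")
  })
  bs_genome(setNames(s, name))
}

q40 <- function(n) strrep("I", n)

# minimal single-end alignment tibble builder for extractor/dedup tests
aln_row <- function(qname, chrom, pos, seq, xm, qual = q40(nchar(seq)),
                    cigar = paste0(nchar(seq), "M"), mapq = 42L,
                    strand = "OT", mate = 0L, rev = FALSE, flag = NULL,
                    dup = FALSE, mapped = TRUE) {
  xg <- if (strand %in% c("OT", "CTOT")) "CT" else "GA"
  xr1 <- if (strand %in% c("OT", "OB")) "CT" else "GA"
  xr <- if (mate == 2L) c(CT = "GA", GA = "CT")[[xr1]] else xr1
  if (is.null(flag)) {
    flag <- if (mate == 0L) ifelse(rev, 16L, 0L) else {
      1L + 2L + ifelse(rev, 16L, 32L) + ifelse(mate == 1L, 64L, 128L)
    }
  }
  tibble::tibble(
    qname = qname, flag = flag, chrom = chrom, pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = cigar, rnext = "*", pnext = 0L,
    tlen = 0L, seq = seq, qual = qual, AS = 0L, XS = NA_integer_,
    XM = xm, XG = xg, XR = xr, strand = strand, mate = as.integer(mate),
    mapped = mapped, rev = rev, dup = dup, secondary = FALSE
  )
}

as_bs_aln <- function(...) {
  x <- dplyr::bind_rows(...)
  class(x) <- c("bs_alignments", class(x))
  x
}

no_filters <- function() filter_config(min_mapq = 0L, min_phred = 0L)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
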