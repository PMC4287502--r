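#' End-to-end alignment scoring scheme
#'
#' Scoring used by the built-in aligner and by MAPQ recalculation. Mismatch
#' penalties are interpolated between `mismatch_min` and `mismatch_max` by
#' base quality (capped at Q40), matching the convention of
#' bowtie2-compatible aligners so that alignment scores are comparable across
#' backends. A perfect end-to-end alignment scores 0; an alignment is valid
#' when its score is at least `score_min(L) = intercept + slope * L`.
#'
#' @param mismatch_max,mismatch_min penalty for a mismatch at high/zero base
#'   quality.
#' @param n_penalty penalty applied when the read or reference base is N.
#' @param gap_open,gap_extend affine gap penalties (carried for external
#'   backends; the built-in aligner is ungapped).
#' @param score_min_intercept,score_min_slope coefficients of the minimum
#'   valid score as an affine function of read length.
#' @return a `bs_scoring` object.
#' @export
scoring_scheme <- function(mismatch_max = 6L, mismatch_min = 2L,
                           n_penalty = 1L, gap_open = 5L, gap_extend = 3L,
                           score_min_intercept = -0.6,
                           score_min_slope = -0.6) {
  stopifnot(mismatch_max >= 0, mismatch_min >= 0, n_penalty >= 0,
            mismatch_min <= mismatch_max)
  if (score_min_intercept + score_min_slope > 0) {
    abort_ma("score_min must not exceed the perfect score (0) for any length")
  }
  structure(list(mismatch_max = as.integer(mismatch_max),
                 mismatch_min = as.integer(mismatch_min),
                 n_penalty = as.integer(n_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 score_min_intercept = score_min_intercept,
                 score_min_slope = score_min_slope),
            class = "bs_scoring")
}

#' Minimum valid alignment score for a read length
#'
#' @param scheme a [scoring_scheme()].
#' @param read_len read length (for pairs, the summed mate length).
#' @return numeric minimum score.
#' @export
min_score <- function(scheme, read_len) {
  scheme$score_min_intercept + scheme$score_min_slope * read_len
}

#' Quality-scaled mismatch penalty
#'
#' @param q integer Phred score(s).
#' @param scheme a [scoring_scheme()].
#' @return integer penalty, `min + (max - min) * min(q, 40) / 40`, rounded
#'   half away from zero.
#' @export
mismatch_penalty <- function(q, scheme = scoring_scheme()) {
  q <- pmax(0L, pmin(40L, as.integer(q)))
  as.integer(floor(scheme$mismatch_min +
                     (scheme$mismatch_max - scheme$mismatch_min) * q / 40 +
                     0.5))
}

## Scan one batch of (already converted, already orientation-resolved) reads
## against one converted reference. Returns per-read best/second summaries and
## the full hit lists (1-based leftmost positions). Reads for the reverse
## orientation must be reverse-complemented (with reversed qualities) by the
## caller; positions are leftmost on the forward reference either way.
scan_batch <- function(contig_seq, reads, quals, scheme, keep_hits = FALSE,
                       seed_k = 8L) {
  ms <- min_score(scheme, nchar(reads))
  use_index <- !grepl("N", contig_seq, fixed = TRUE) &&
    nchar(contig_seq) >= 4096L
  res <- cpp_scan_batch(contig_seq, reads, quals, ms,
                        scheme$mismatch_max, scheme$mismatch_min,
                        scheme$n_penalty, use_index, as.integer(seed_k),
                        keep_hits)
  res
}

#' Deterministic exhaustive alignment of one converted read
#'
#' The built-in backend: scores a read ungapped at every permissible offset of
#' a converted reference, in the orientation a strand hypothesis permits,
#' using quality-scaled mismatch penalties. The best-scoring position becomes
#' the candidate's AS and the second-best valid position (if any) its XS. Ties
#' between equally scoring positions are broken by smallest coordinate, then
#' lexicographic contig name. Intended for small references; genomes over
#' `cap` bases are refused (use an external backend for production genomes).
#'
#' @param seq_conv converted read sequence.
#' @param qual Phred+33 quality string.
#' @param genome a [bs_genome] (a converted reference).
#' @param orient `"forward"` or `"reverse"` orientation constraint.
#' @param scheme a [scoring_scheme()].
#' @param cap maximum total reference length accepted.
#' @return one-row tibble: `mapped`, `chrom`, `pos` (1-based leftmost),
#'   `cigar`, `AS`, `XS` (NA when no second valid position), `rev`.
#' @export
align_exhaustive <- function(seq_conv, qual, genome,
                             orient = c("forward", "reverse"),
                             scheme = scoring_scheme(), cap = 1e7) {
  orient <- match.arg(orient)
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  if (sum(nchar(genome)) > cap) {
    abort_ma("reference exceeds the built-in aligner cap (", format(cap),
             " bp); use the external backend")
  }
  if (nchar(seq_conv) < 1L) abort_ma("read length must be >= 1")
  rd <- if (orient == "reverse") revcomp(seq_conv) else seq_conv
  qu <- if (orient == "reverse") str_rev(qual) else qual
  best <- NULL
  second <- NA_integer_
  for (cn in names(genome)) {
    res <- scan_batch(unclass(genome)[[cn]], rd, qu, scheme)
    bs <- res$best_score[1L]
    if (is.na(bs)) next
    cand2 <- res$second_score[1L]
    takes <- is.null(best) || bs > best$AS ||
      (bs == best$AS && (res$best_pos[1L] < best$pos ||
                           (res$best_pos[1L] == best$pos && cn < best$chrom)))
    if (takes) {
      if (!is.null(best)) second <- max2(second, best$AS)
      second <- max2(second, cand2)
      best <- list(chrom = cn, pos = res$best_pos[1L], AS = bs)
    } else {
      second <- max2(second, bs)
      second <- max2(second, cand2)
    }
  }
  if (is.null(best)) {
    return(tibble(mapped = FALSE, chrom = NA_character_, pos = NA_integer_,
                  cigar = NA_character_, AS = NA_integer_, XS = NA_integer_,
                  rev = orient == "reverse"))
  }
  tibble(mapped = TRUE, chrom = best$chrom, pos = best$pos,
         cigar = paste0(nchar(seq_conv), "M"), AS = best$AS,
         XS = second, rev = orient == "reverse")
}

## max that treats NA as -Inf and returns NA when both are NA
max2 <- function(a, b) {
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  max(a, b)
}

#' Paired-end candidate score
#'
#' For paired-end reads the strand-level score is the sum of the two mates'
#' alignment scores. A strand with either mate unmapped contributes no paired
#' candidate.
#'
#' @param as1,as2 mate alignment scores (AS).
#' @return the summed score, or `NA` if either input is `NA`.
#' @export
pair_score <- function(as1, as2) {
  ifelse(is.na(as1) | is.na(as2), NA_integer_,
         as.integer(as1) + as.integer(as2))
}

#' Run an external bowtie2-compatible backend for one strand
#'
#' Invokes the external aligner in end-to-end mode with the orientation
#' constraint of one strand hypothesis and returns the path to the SAM output.
#' Mapped records missing the AS tag are rejected downstream.
#'
#' @param fastq character vector of 1 (single) or 2 (paired) converted FASTQ
#'   paths.
#' @param index_prefix backend index prefix built from a converted reference.
#' @param orient orientation constraint (`"forward"` passes `--norc`,
#'   `"reverse"` passes `--nofw`).
#' @param threads worker threads.
#' @param sam_out output SAM path.
#' @param aligner executable name.
#' @param extra_args additional command-line arguments.
#' @return `sam_out`, invisibly.
#' @export
align_external <- function(fastq, index_prefix,
                           orient = c("forward", "reverse"), threads = 1L,
                           sam_out = tempfile(fileext = ".sam"),
                           aligner = "bowtie2", extra_args = character()) {
  orient <- match.arg(orient)
  exe <- Sys.which(aligner)
  if (!nzchar(exe)) {
    abort_ma("external aligner '", aligner, "' not found on the PATH")
  }
  args <- c("--end-to-end", "--quiet", "--reorder",
            if (orient == "forward") "--norc" else "--nofw",
            "-p", threads, "-x", shQuote(index_prefix),
            if (length(fastq) == 2L) {
              c("-1", shQuote(fastq[1L]), "-2", shQuote(fastq[2L]),
                "--no-mixed", "--no-discordant")
            } else {
              c("-U", shQuote(fastq[1L]))
            },
            "-S", shQuote(sam_out), extra_args)
  err <- system2(exe, args, stdout = FALSE, stderr = TRUE)
  if (!is.null(attr(err, "status"))) {
    abort_ma("external aligner failed: ", paste(err, collapse = "\n"))
  }
  invisible(sam_out)
}
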