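#' Duplicate signatures
#'
#' The position part of the PCR-duplicate definition: two units are duplicate
#' candidates when they align to the same strand of the same contig with
#' identical soft-clip-adjusted 5' coordinates (for pairs, both mates'
#' adjusted coordinates as an ordered unit). Forward records take
#' `pos - leading soft clips`; reverse records take the rightmost aligned
#' base plus trailing soft clips.
#'
#' @param aln a `bs_alignments` tibble.
#' @return `aln` with a `clip5` column (adjusted 5' coordinate; `NA` for
#'   unmapped records).
#' @export
dup_signature <- function(aln) {
  aln$clip5 <- NA_integer_
  i <- which(aln$mapped)
  if (length(i)) {
    aln$clip5[i] <- cpp_clip5(aln$pos[i], aln$cigar[i], aln$rev[i])
  }
  aln
}

#' Do two reads' methylation calls match for duplicate purposes?
#'
#' A call is *present* when its symbol is not `.` and its base Phred score is
#' at least `min_phred`. Where both reads have a present call the symbols
#' must be identical; where at most one does, the reads are declared not to
#' differ at that position. Operates on positionally comparable strings
#' (same reference footprint).
#'
#' @param xm_a,xm_b methylation-call strings.
#' @param quals_a,quals_b Phred+33 quality strings.
#' @param min_phred Phred floor for a call to count.
#' @return `TRUE` iff no position differs.
#' @export
meth_match <- function(xm_a, quals_a, xm_b, quals_b, min_phred = 5L) {
  if (nchar(xm_a) != nchar(xm_b)) {
    abort_ma("methylation strings are not positionally comparable")
  }
  a <- strsplit(xm_a, "")[[1L]]
  b <- strsplit(xm_b, "")[[1L]]
  pa <- phred_of(quals_a)
  pb <- phred_of(quals_b)
  present_a <- a != "." & pa >= min_phred
  present_b <- b != "." & pb >= min_phred
  both <- present_a & present_b
  all(a[both] == b[both])
}

#' Mark PCR duplicates by position and methylation identity
#'
#' Within each duplicate-signature bucket (contig, strand, adjusted 5'
#' coordinate(s); pairs as units), records are greedily partitioned into
#' groups whose methylation calls match the group representative
#' (call present iff symbol != `.` and Phred >= `min_phred`; present calls
#' must agree at shared reference positions). In each group the unit with the
#' highest sum of base-call Phred scores is kept unmarked and all others
#' receive the duplicate flag. Methylation-discordant units at the same
#' position are never marked as duplicates of each other, so this method
#' marks a subset of what position-only marking would. Secondary and
#' supplementary records are never marked and never serve as representatives;
#' unmapped records are never marked.
#'
#' @param x a `bs_alignments` tibble, or a path to a coordinate-sorted BAM
#'   (an unsorted BAM is rejected).
#' @param min_phred Phred floor for methylation-call comparison.
#' @param method `"methylation"` (position + methylation identity, the
#'   default) or `"position"` (position only, for comparison).
#' @return the alignments with `dup` set (and bit 0x400 folded into `flag`).
#' @export
mark_duplicates <- function(x, min_phred = 5L,
                            method = c("methylation", "position")) {
  method <- match.arg(method)
  if (is.character(x)) {
    if (!bam_is_sorted(x)) {
      abort_ma("mark_duplicates requires a coordinate-sorted BAM")
    }
    x <- read_alignments(x)
  }
  aln <- dup_signature(x)
  aln$dup <- FALSE
  eligible <- aln$mapped & !aln$secondary

  ## build units: pairs (both mates eligible) act as one unit
  rec <- which(eligible)
  meta <- tibble(row = rec, qname = aln$qname[rec], mate = aln$mate[rec],
                 chrom = aln$chrom[rec], strand = aln$strand[rec],
                 clip5 = aln$clip5[rec], pos = aln$pos[rec])
  paired <- meta$mate > 0L
  units <- meta |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(
      rows = list(.data$row[order(.data$mate)]),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      sig = paste(sort(paste(.data$mate, .data$clip5)), collapse = "|"),
      minpos = min(.data$pos),
      .groups = "drop"
    )
  units$key <- paste(units$chrom, units$strand, units$sig, sep = "\r")
  units <- units[order(units$chrom, units$minpos, units$qname), ]

  ## per-unit methylation call maps and Phred sums
  unit_calls <- function(rows) {
    out <- list()
    for (r in rows) {
      ex <- cpp_expand_calls(aln$pos[r], aln$cigar[r], aln$XM[r],
                             aln$qual[r], aln$rev[r])
      keep <- ex$phred >= min_phred
      for (j in which(keep)) {
        k <- as.character(ex$refpos[j])
        if (is.null(out[[k]])) out[[k]] <- ex$call[j]
      }
    }
    out
  }
  phred_sum <- function(rows) sum(unlist(lapply(aln$qual[rows], phred_of)))

  calls_match <- function(a, b) {
    shared <- intersect(names(a), names(b))
    all(unlist(a[shared]) == unlist(b[shared]))
  }

  buckets <- split(seq_len(nrow(units)), units$key)
  for (bk in buckets) {
    if (length(bk) < 2L) next
    groups <- list()  # each: list(rep_calls, members = unit indices)
    for (ui in bk) {
      cl <- if (method == "methylation") unit_calls(units$rows[[ui]]) else NULL
      placed <- FALSE
      if (method == "methylation") {
        for (gi in seq_along(groups)) {
          if (calls_match(groups[[gi]]$rep_calls, cl)) {
            groups[[gi]]$members <- c(groups[[gi]]$members, ui)
            placed <- TRUE
            break
          }
        }
      } else if (length(groups)) {
        groups[[1L]]$members <- c(groups[[1L]]$members, ui)
        placed <- TRUE
      }
      if (!placed) {
        groups[[length(groups) + 1L]] <- list(rep_calls = cl, members = ui)
      }
    }
    for (g in groups) {
      if (length(g$members) < 2L) next
      sums <- vapply(g$members, function(ui) phred_sum(units$rows[[ui]]),
                     numeric(1))
      keep <- g$members[which.max(sums)]
      for (ui in setdiff(g$members, keep)) {
        aln$dup[units$rows[[ui]]] <- TRUE
      }
    }
  }
  aln$flag <- aln$flag + ifelse(aln$dup & bitwAnd(aln$flag, 1024L) == 0L,
                                1024L, 0L)
  aln$clip5 <- NULL
  aln
}
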