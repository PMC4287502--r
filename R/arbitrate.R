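#' Select the best alignment across strand hypotheses
#'
#' Arbitrates between the candidate alignments a read (or pair) produced on
#' each permitted strand. If exactly one strand attains the maximum alignment
#' score, that candidate wins; if two or more strands tie at the maximum, the
#' read is reported unmapped, since such alignments are highly unreliable. The
#' winner's XS (second-best score) is rewritten to the highest score among the
#' other strands' candidates, unless the winner already carries a higher XS of
#' its own, in which case its XS is unmodified.
#'
#' @param candidates tibble with one row per strand candidate: columns
#'   `strand`, `AS`, optionally `XS` and any others (passed through).
#' @return the winning row as a one-row tibble with `XS` rewritten, or a
#'   zero-row tibble when the read is unmapped (no candidates, or a
#'   cross-strand tie).
#' @examples
#' select_best(tibble::tibble(strand = c("OT", "OB"), AS = c(0L, -12L)))
#' @export
select_best <- function(candidates) {
  if (!"XS" %in% names(candidates)) candidates$XS <- NA_integer_
  cand <- candidates[!is.na(candidates$AS), , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  m <- max(cand$AS)
  top <- which(cand$AS == m)
  if (length(top) > 1L) return(cand[0L, , drop = FALSE])
  chosen <- cand[top, , drop = FALSE]
  others <- cand$AS[-top]
  other_best <- if (length(others)) max(others) else NA_integer_
  own <- chosen$XS
  chosen$XS <- if (!is.na(own) && (is.na(other_best) || own > other_best)) {
    own
  } else {
    other_best
  }
  chosen
}

#' Recalculate mapping quality from cross-strand AS/XS
#'
#' MAPQ is a heuristic on the percentile of the alignment score between the
#' minimum valid score and the perfect (0) end-to-end score; the gap between
#' AS and XS further lowers it. Because XS here reflects the best alternative
#' across *all* strands (see [select_best()]), the recalculated MAPQ is
#' meaningful for bisulfite alignments where per-strand MAPQs are not. The
#' value 42 is attainable only when XS is absent or at least the full
#' score range below AS; `AS == XS` yields 3 or less. Values fall in
#' \{0, 3, 8, 23..42\}.
#'
#' @param AS alignment score(s), non-positive.
#' @param XS second-best score(s); `NA` when absent.
#' @param read_len_total read length (pairs: summed mate lengths; scores are
#'   then the summed mate scores).
#' @param scheme a [scoring_scheme()].
#' @return integer MAPQ in \[0, 42\], vectorised over the inputs.
#' @export
recalc_mapq <- function(AS, XS = NA_integer_, read_len_total,
                        scheme = scoring_scheme()) {
  sc_min <- min_score(scheme, read_len_total)
  if (any(!is.na(AS) & AS < sc_min - 1e-9)) {
    abort_ma("AS below the minimum valid score: caller bug")
  }
  dd <- pmax(1, -sc_min)
  r <- (AS - sc_min) / dd
  uniq <- ifelse(r >= 0.8, 42L,
          ifelse(r >= 0.7, 40L,
          ifelse(r >= 0.6, 24L,
          ifelse(r >= 0.5, 23L,
          ifelse(r >= 0.4, 8L,
          ifelse(r >= 0.3, 3L, 0L))))))
  XS <- rep_len(XS, length(AS))
  has_xs <- !is.na(XS) & XS >= sc_min - 1e-9
  frac <- (AS - XS) / dd
  xsv <- ifelse(frac >= 1, 42L,
         ifelse(frac >= 0.9, 40L,
         ifelse(frac >= 0.8, 39L,
         ifelse(frac >= 0.7, 37L,
         ifelse(frac >= 0.6, 35L,
         ifelse(frac >= 0.5, 33L,
         ifelse(frac >= 0.4, 31L,
         ifelse(frac >= 0.3, 29L,
         ifelse(frac >= 0.2, 27L,
         ifelse(frac >= 0.1, 25L,
         ifelse(frac > 0, 23L, 3L)))))))))))
  out <- ifelse(has_xs, pmin(uniq, xsv), uniq)
  as.integer(pmax(0L, pmin(42L, out)))
}

#' Assign per-base methylation-call strings
#'
#' For each aligned base the call is made against the unconverted reference on
#' the strand the record derives from: at a reference cytosine (top-strand C
#' for `xg = "CT"` records; top-strand G, i.e. bottom-strand C, for
#' `xg = "GA"`), a retained C (G) is a methylated call (uppercase), a
#' converted T (A) an unmethylated call (lowercase), and any other read base a
#' mismatch with no call (`.`). Context letters are Z (CpG), X (CHG), H (CHH),
#' with CpG taking precedence, determined from the unconverted genome on the
#' originating strand; positions whose context runs past the contig end (or
#' into N) get no call. Inserted and soft-clipped read bases get `.`; deleted
#' reference bases contribute nothing.
#'
#' @param chrom,pos,cigar,seq,xg parallel vectors describing mapped records:
#'   contig, 1-based leftmost position, CIGAR, read sequence in SAM
#'   (reference-forward) orientation containing the *original* unconverted
#'   bases, and the genome-conversion tag (`"CT"` or `"GA"`).
#' @param genome the unconverted [bs_genome].
#' @return character vector of methylation strings, parallel to the reads.
#' @export
assign_methylation <- function(chrom, pos, cigar, seq, xg, genome) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  n <- length(seq)
  out <- character(n)
  end_ref <- pos + cigar_ref_width(cigar) - 1L
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    if (!cn %in% names(genome)) abort_ma("contig not in genome: ", cn)
    if (any(end_ref[idx] > nchar(genome[[cn]])) || any(pos[idx] < 1L)) {
      abort_ma("alignment extends beyond contig ", cn)
    }
    out[idx] <- cpp_xm_strings(unclass(genome)[[cn]], pos[idx], seq[idx],
                               cigar[idx], xg[idx] == "CT")
  }
  out
}

## reference width consumed by a CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## ---- full built-in alignment pipeline -------------------------------------

## Combine per-contig scan summaries into genome-wide best/second candidates.
## Tie-break: smallest coordinate, then lexicographic contig name.
combine_contigs <- function(per_contig, contig_names) {
  n <- length(per_contig[[1L]]$best_pos)
  b_as <- rep(NA_integer_, n)
  b_pos <- rep(NA_integer_, n)
  b_chr <- rep(NA_character_, n)
  second <- rep(NA_integer_, n)
  for (ci in seq_along(per_contig)) {
    res <- per_contig[[ci]]
    s <- res$best_score
    cn <- contig_names[ci]
    cand <- !is.na(s)
    better <- cand & (is.na(b_as) | s > b_as |
                        (s == b_as & (res$best_pos < b_pos |
                                        (res$best_pos == b_pos & cn < b_chr))))
    loser <- cand & !better
    second[loser] <- pmax(second[loser], s[loser], na.rm = TRUE)
    second[better] <- pmax(second[better], b_as[better], na.rm = TRUE)
    second[cand] <- pmax(second[cand], res$second_score[cand], na.rm = TRUE)
    b_as[better] <- s[better]
    b_pos[better] <- res$best_pos[better]
    b_chr[better] <- cn
  }
  list(AS = b_as, pos = b_pos, chrom = b_chr, XS = second)
}

#' Align bisulfite reads with the built-in backend
#'
#' Runs the full conversion, per-strand candidate alignment and cross-strand
#' arbitration for a batch of reads: reads are in-silico converted and scored
#' against the C->T and G->A references under each strand hypothesis the
#' protocol permits, strand candidates are arbitrated ([select_best()]
#' semantics, with cross-strand ties reported unmapped), MAPQ is recalculated
#' from the cross-strand AS/XS ([recalc_mapq()]), and per-base methylation
#' strings are assigned from the unconverted genome. Paired-end candidates
#' require both mates on the same strand and contig in proper orientation with
#' insert size at most `max_insert`; strand scores are the summed mate scores.
#'
#' @param reads tibble from [read_fastq()] / [read_fastq_pair()].
#' @param genome a [bs_genome] (unconverted) or path to FASTA.
#' @param protocol a [protocol()].
#' @param scheme a [scoring_scheme()].
#' @param cap built-in aligner reference-size cap in bp.
#' @param max_insert maximum paired-end insert size.
#' @param unmapped_fastq optional path prefix; unmapped reads are written to
#'   `<prefix>.fastq.gz` (single) or `<prefix>_1/2.fastq.gz` (paired).
#' @return a `bs_alignments` tibble with one row per read (mates on separate
#'   rows), SAM-like columns (`qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`) plus tags `AS`, `XS`,
#'   `XM`, `XG`, `XR`, the winning `strand`, `mate`, and logicals `mapped`,
#'   `rev`, `dup`, `secondary`. Unmapped reads are retained with
#'   `mapped = FALSE`.
#' @export
align_bs <- function(reads, genome, protocol = methalign::protocol(),
                     scheme = scoring_scheme(), cap = 1e7, max_insert = 1000L,
                     unmapped_fastq = NULL) {
  if (!inherits(genome, "bs_genome")) {
    if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
        file.exists(genome)) {
      genome <- read_fasta(genome)
    } else {
      genome <- bs_genome(genome)
    }
  }
  if (sum(nchar(genome)) > cap) {
    abort_ma("reference exceeds the built-in aligner cap; ",
             "use the external backend")
  }
  conv <- convert_genome(genome)
  paired <- protocol$pairing == "paired"
  disp <- convert_reads(reads, protocol)
  strands <- protocol_strands(protocol)

  if (paired) {
    r1 <- reads[reads$mate == 1L, ]
    m2r <- reads[reads$mate == 2L, ]
    units <- r1$name
    r2 <- m2r[match(units, m2r$name), ]
    if (nrow(r1) == 0L || any(is.na(r2$name))) {
      abort_ma("paired protocol but mates missing")
    }
  } else {
    units <- reads$name
    r1 <- reads
    r2 <- NULL
  }
  n <- length(units)
  l1 <- nchar(r1$seq)
  l2 <- if (paired) nchar(r2$seq) else 0L
  contig_names <- names(genome)

  per_strand <- vector("list", length(strands))
  names(per_strand) <- strands
  for (st in strands) {
    tgt <- conv[[strand_table()$target[strand_table()$strand == st]]]
    sub1 <- disp[disp$strand == st & disp$mate != 2L, ]
    sub1 <- sub1[match(units, sub1$name), ]
    or1 <- sub1$orient[1L]
    rd1 <- if (or1 == "reverse") revcomp(sub1$seq_conv) else sub1$seq_conv
    qu1 <- if (or1 == "reverse") str_rev(sub1$qual) else sub1$qual
    if (!paired) {
      per_contig <- lapply(contig_names, function(cn) {
        scan_batch(unclass(tgt)[[cn]], rd1, qu1, scheme)
      })
      cmb <- combine_contigs(per_contig, contig_names)
      per_strand[[st]] <- list(AS = cmb$AS, XS = cmb$XS, chrom = cmb$chrom,
                               pos1 = cmb$pos, rev1 = or1 == "reverse")
    } else {
      sub2 <- disp[disp$strand == st & disp$mate == 2L, ]
      sub2 <- sub2[match(units, sub2$name), ]
      or2 <- sub2$orient[1L]
      rd2 <- if (or2 == "reverse") revcomp(sub2$seq_conv) else sub2$seq_conv
      qu2 <- if (or2 == "reverse") str_rev(sub2$qual) else sub2$qual
      pr <- pair_strand_candidates(tgt, contig_names, rd1, qu1, rd2, qu2,
                                   scheme, or1 == "reverse", max_insert)
      pr$rev1 <- or1 == "reverse"
      per_strand[[st]] <- pr
    }
  }

  ## cross-strand arbitration (vectorised)
  as_mat <- vapply(per_strand, `[[`, numeric(n), "AS")
  as_mat <- matrix(as_mat, nrow = n)
  max_as <- suppressWarnings(apply(as_mat, 1L, max, na.rm = TRUE))
  max_as[!is.finite(max_as)] <- NA_real_
  n_top <- rowSums(as_mat == max_as, na.rm = TRUE)
  mapped <- !is.na(max_as) & n_top == 1L
  chosen_idx <- rep(NA_integer_, n)
  chosen_idx[mapped] <- max.col(
    replace(as_mat, is.na(as_mat), -Inf), ties.method = "first")[mapped]

  other_best <- rep(NA_real_, n)
  for (k in seq_along(strands)) {
    sel <- which(mapped & chosen_idx == k)
    if (!length(sel)) next
    o <- as_mat[sel, -k, drop = FALSE]
    ob <- suppressWarnings(apply(o, 1L, max, na.rm = TRUE))
    ob[!is.finite(ob)] <- NA_real_
    other_best[sel] <- ob
  }

  res <- tibble(
    unit = units, mapped = mapped,
    strand = ifelse(mapped, strands[chosen_idx], NA_character_),
    AS = rep(NA_real_, n), XS = rep(NA_real_, n),
    chrom = NA_character_, pos1 = NA_integer_, pos2 = NA_integer_,
    rev1 = NA
  )
  for (k in seq_along(strands)) {
    sel <- which(mapped & chosen_idx == k)
    if (!length(sel)) next
    ps <- per_strand[[k]]
    res$AS[sel] <- ps$AS[sel]
    own <- ps$XS[sel]
    ob <- other_best[sel]
    res$XS[sel] <- ifelse(!is.na(own) & (is.na(ob) | own > ob), own, ob)
    res$chrom[sel] <- ps$chrom[sel]
    res$pos1[sel] <- ps$pos1[sel]
    if (paired) res$pos2[sel] <- ps$pos2[sel]
    res$rev1[sel] <- ps$rev1
  }
  res$mapq <- NA_integer_
  res$mapq[mapped] <- recalc_mapq(res$AS[mapped], res$XS[mapped],
                                  (l1 + l2)[mapped], scheme)

  aln <- build_alignment_records(res, r1, r2, genome, paired)
  if (!is.null(unmapped_fastq)) {
    write_unmapped_fastq(aln, unmapped_fastq, paired)
  }
  class(aln) <- c("bs_alignments", class(aln))
  aln
}

## Enumerate proper pairs per strand (both mates same contig, fwd mate left of
## rev mate, insert <= max_insert); AS is the summed mate score, XS the
## second-best pair sum.
pair_strand_candidates <- function(tgt, contig_names, rd1, qu1, rd2, qu2,
                                   scheme, m1_rev, max_insert) {
  n <- length(rd1)
  l1 <- nchar(rd1)
  l2 <- nchar(rd2)
  b_as <- rep(NA_integer_, n)
  b_xs <- rep(NA_integer_, n)
  b_chr <- rep(NA_character_, n)
  b_p1 <- rep(NA_integer_, n)
  b_p2 <- rep(NA_integer_, n)
  for (cn in contig_names) {
    g <- unclass(tgt)[[cn]]
    h1 <- scan_batch(g, rd1, qu1, scheme, keep_hits = TRUE)
    h2 <- scan_batch(g, rd2, qu2, scheme, keep_hits = TRUE)
    i1 <- split(seq_along(h1$hit_read), h1$hit_read)
    i2 <- split(seq_along(h2$hit_read), h2$hit_read)
    common <- intersect(names(i1), names(i2))
    for (uc in common) {
      u <- as.integer(uc)
      p1 <- h1$hit_pos[i1[[uc]]]; s1 <- h1$hit_score[i1[[uc]]]
      p2 <- h2$hit_pos[i2[[uc]]]; s2 <- h2$hit_score[i2[[uc]]]
      ## orientation: if mate1 is reverse, mate2 is the forward (left) mate
      if (m1_rev) {
        fp <- p2; fs <- s2; fl <- l2[u]
        rp <- p1; rs <- s1; rl <- l1[u]
      } else {
        fp <- p1; fs <- s1; fl <- l1[u]
        rp <- p2; rs <- s2; rl <- l2[u]
      }
      best <- NULL
      second <- NA_integer_
      for (a in seq_along(fp)) {
        ok <- rp >= fp[a] & (rp + rl - fp[a]) <= max_insert
        if (!any(ok)) next
        sums <- fs[a] + rs[ok]
        rpo <- rp[ok]
        for (b in seq_along(sums)) {
          cur <- sums[b]
          if (is.null(best) || cur > best$sum ||
              (cur == best$sum && (fp[a] < best$fp ||
                                     (fp[a] == best$fp && rpo[b] < best$rp)))) {
            if (!is.null(best)) second <- max2(second, best$sum)
            best <- list(sum = cur, fp = fp[a], rp = rpo[b])
          } else {
            second <- max2(second, cur)
          }
        }
      }
      if (is.null(best)) next
      take <- is.na(b_as[u]) || best$sum > b_as[u] ||
        (best$sum == b_as[u] && cn < b_chr[u])
      if (take) {
        if (!is.na(b_as[u])) second <- max2(second, b_as[u])
        b_xs[u] <- max2(second, b_xs[u])
        b_as[u] <- best$sum
        b_chr[u] <- cn
        if (m1_rev) { b_p1[u] <- best$rp; b_p2[u] <- best$fp }
        else { b_p1[u] <- best$fp; b_p2[u] <- best$rp }
      } else {
        b_xs[u] <- max2(b_xs[u], max2(best$sum, second))
      }
    }
  }
  list(AS = b_as, XS = b_xs, chrom = b_chr, pos1 = b_p1, pos2 = b_p2)
}

## Assemble SAM-like records (both mates for pairs) incl. unmapped rows.
build_alignment_records <- function(res, r1, r2, genome, paired) {
  st_tab <- strand_table()
  n <- nrow(res)
  mk_mate <- function(rd, mate_no) {
    mapped <- res$mapped
    strand <- res$strand
    i <- match(strand, st_tab$strand)
    xg <- st_tab$xg[i]
    xr1 <- st_tab$xr1[i]
    xr <- if (mate_no == 1L) xr1 else ifelse(xr1 == "CT", "GA", "CT")
    rev <- if (mate_no == 1L) res$rev1 else !res$rev1
    pos <- if (mate_no == 1L) res$pos1 else res$pos2
    L <- nchar(rd$seq)
    seq_sam <- ifelse(mapped & rev, revcomp(rd$seq), rd$seq)
    qual_sam <- ifelse(mapped & rev, str_rev(rd$qual), rd$qual)
    flag <- ifelse(mapped, 0L, 4L) + ifelse(mapped & rev, 16L, 0L)
    if (paired) {
      mate_rev <- if (mate_no == 1L) !res$rev1 else res$rev1
      flag <- flag + 1L + ifelse(mate_no == 1L, 64L, 128L) +
        ifelse(mapped, 2L, 8L) + ifelse(mapped & mate_rev, 32L, 0L)
    }
    tibble(
      qname = res$unit, flag = flag,
      chrom = ifelse(mapped, res$chrom, NA_character_),
      pos = ifelse(mapped, pos, NA_integer_),
      mapq = ifelse(mapped, res$mapq, 0L),
      cigar = ifelse(mapped, paste0(L, "M"), NA_character_),
      rnext = if (paired) ifelse(mapped, "=", "*") else "*",
      pnext = if (paired) {
        ifelse(mapped, if (mate_no == 1L) res$pos2 else res$pos1, 0L)
      } else 0L,
      tlen = 0L,
      seq = seq_sam, qual = qual_sam,
      AS = ifelse(mapped, res$AS, NA_integer_),
      XS = ifelse(mapped, res$XS, NA_integer_),
      strand = strand,
      XG = ifelse(mapped, xg, NA_character_),
      XR = ifelse(mapped, xr, NA_character_),
      mate = if (paired) mate_no else 0L,
      mapped = mapped, rev = ifelse(mapped, rev, FALSE),
      dup = FALSE, secondary = FALSE
    )
  }
  out <- mk_mate(r1, 1L)
  if (paired) {
    m2 <- mk_mate(r2, 2L)
    ## template length: signed span of the pair
    left <- pmin(res$pos1, res$pos2)
    right <- pmax(res$pos1 + nchar(r1$seq) - 1L, res$pos2 + nchar(r2$seq) - 1L)
    span <- right - left + 1L
    out$tlen <- ifelse(res$mapped, ifelse(res$rev1, -span, span), 0L)
    m2$tlen <- -out$tlen
    out <- dplyr::bind_rows(out, m2)
    out <- out[order(match(out$qname, res$unit), out$mate), ]
  }
  ## methylation strings for mapped records
  idx <- which(out$mapped)
  out$XM <- NA_character_
  if (length(idx)) {
    out$XM[idx] <- assign_methylation(out$chrom[idx], out$pos[idx],
                                      out$cigar[idx], out$seq[idx],
                                      out$XG[idx], genome)
  }
  out
}

write_unmapped_fastq <- function(aln, prefix, paired) {
  un <- aln[!aln$mapped, , drop = FALSE]
  if (nrow(un) == 0L) return(invisible(NULL))
  un$seq_out <- ifelse(un$rev, revcomp(un$seq), un$seq)
  if (paired) {
    for (m in 1:2) {
      sub <- un[un$mate == m, ]
      if (nrow(sub)) {
        write_fastq(tibble(name = sub$qname, seq = sub$seq_out,
                           qual = sub$qual),
                    sprintf("%s_%d.fastq.gz", prefix, m))
      }
    }
  } else {
    write_fastq(tibble(name = un$qname, seq = un$seq_out, qual = un$qual),
                sprintf("%s.fastq.gz", prefix))
  }
  invisible(NULL)
}
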