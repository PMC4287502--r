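#' Simulation configuration
#'
#' Parameters of the bisulfite read simulator. Defaults reflect a typical
#' directional mammalian library sequenced as 50 bp reads: CpG methylation
#' 0.7, near-zero non-CpG methylation, complete bisulfite conversion of
#' unmethylated cytosines, and a 0.1% per-base error rate with constant Q40
#' qualities (an optional linear 3' decay is available).
#'
#' @param n_fragments number of fragments to simulate.
#' @param read_len read length in bp.
#' @param pairing `"paired"` or `"single"`.
#' @param insert_mean,insert_sd fragment-length distribution for paired-end
#'   libraries (bp); fragments are clamped to at least `read_len`.
#' @param directionality `"directional"` or `"non-directional"`; in the
#'   latter case each fragment is emitted as its PCR complement with
#'   probability 0.5.
#' @param meth_prob named vector of per-context methylation probabilities.
#' @param conversion_rate probability an unmethylated C reads as T.
#' @param error_rate per-base sequencing error probability (substitution
#'   uniform over the other three bases).
#' @param qual_constant constant Phred quality assigned to bases.
#' @param qual_decay_to if non-`NULL`, qualities decay linearly from
#'   `qual_constant` at the 5' end to this value at the 3' end.
#' @param bias_5p force the first `bias_5p` fragment positions unmethylated,
#'   emulating an end-repair artifact (used to exercise M-bias detection).
#' @param seed RNG seed; runs with the same seed are reproducible
#'   byte-for-byte.
#' @return a `bs_sim_config` object.
#' @export
sim_config <- function(n_fragments = 10000L, read_len = 50L,
                       pairing = c("paired", "single"),
                       insert_mean = 200, insert_sd = 40,
                       directionality = c("directional", "non-directional"),
                       meth_prob = c(CpG = 0.7, CHG = 0.01, CHH = 0.01),
                       conversion_rate = 1.0, error_rate = 0.001,
                       qual_constant = 40L, qual_decay_to = NULL,
                       bias_5p = 0L, seed = 1L) {
  pairing <- match.arg(pairing)
  directionality <- match.arg(directionality)
  stopifnot(read_len >= 1L, n_fragments >= 1L,
            all(meth_prob >= 0 & meth_prob <= 1),
            conversion_rate >= 0, conversion_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(n_fragments = as.integer(n_fragments),
                 read_len = as.integer(read_len), pairing = pairing,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 directionality = directionality, meth_prob = meth_prob,
                 conversion_rate = conversion_rate, error_rate = error_rate,
                 qual_constant = as.integer(qual_constant),
                 qual_decay_to = qual_decay_to,
                 bias_5p = as.integer(bias_5p), seed = as.integer(seed)),
            class = "bs_sim_config")
}

## per-contig cytosine map: positions (1-based, top coordinates) of C (strand
## +) and G (strand -) with methylation context; contexts undefined at contig
## edges fall back to CHH (simulation only).
cytosine_map <- function(contig_str) {
  ch <- strsplit(contig_str, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cpos <- which(ch == "C")
  gpos <- which(ch == "G")
  ctx_plus <- rep("CHH", length(cpos))
  nxt <- ifelse(cpos + 1L <= n, ch[pmin(cpos + 1L, n)], "")
  nx2 <- ifelse(cpos + 2L <= n, ch[pmin(cpos + 2L, n)], "")
  ctx_plus[nx2 == "G"] <- "CHG"
  ctx_plus[nxt == "G"] <- "CpG"
  ctx_minus <- rep("CHH", length(gpos))
  prv <- ifelse(gpos - 1L >= 1L, ch[pmax(gpos - 1L, 1L)], "")
  pv2 <- ifelse(gpos - 2L >= 1L, ch[pmax(gpos - 2L, 1L)], "")
  ctx_minus[pv2 == "C"] <- "CHG"
  ctx_minus[prv == "C"] <- "CpG"
  list(plus = list(pos = cpos, ctx = ctx_plus),
       minus = list(pos = gpos, ctx = ctx_minus))
}

#' Simulate bisulfite reads with ground truth in the read names
#'
#' Fragments are drawn uniformly over positions and strands, cytosines are
#' methylated per-context, unmethylated cytosines convert to T at
#' `conversion_rate` (on the fragment's strand), sequencing errors are
#' applied per base, and reads are cut from the fragment ends (mate 2
#' reverse-complemented). The truth record
#' `sim<i>:<chrom>:<start>:<strand>:<mask>` (1-based fragment start; mask of
#' the fragment's cytosines 5'->3', 1 = methylated) is encoded in each read
#' name, so no sidecar file is needed.
#'
#' @param genome a [bs_genome].
#' @param config a [sim_config()].
#' @return a tibble of reads as in [read_fastq()] (`mate` 0 for single-end).
#' @export
simulate_reads <- function(genome, config = sim_config()) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  stopifnot(inherits(config, "bs_sim_config"))
  set.seed(config$seed)
  n <- config$n_fragments
  L <- config$read_len
  paired <- config$pairing == "paired"
  clen <- nchar(genome)
  if (paired && max(clen) <= config$insert_mean + 4 * config$insert_sd) {
    abort_ma("genome too short for the configured insert distribution")
  }
  if (min(clen) < L) abort_ma("a contig is shorter than the read length")

  ci <- sample.int(length(genome), n, replace = TRUE, prob = clen)
  flen <- if (paired) {
    pmax(L, as.integer(round(rnorm(n, config$insert_mean, config$insert_sd))))
  } else {
    rep(L, n)
  }
  flen <- pmin(flen, clen[ci])
  start <- floor(runif(n, min = 1, max = clen[ci] - flen + 1 + 1))
  start <- pmin(as.integer(start), clen[ci] - flen + 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  end <- start + flen - 1L

  maps <- lapply(unclass(genome), cytosine_map)

  frag <- character(n)
  masks <- character(n)
  for (k in seq_along(genome)) {
    idx <- which(ci == k)
    if (!length(idx)) next
    top <- substring(unclass(genome)[[k]], start[idx], end[idx])
    fr <- ifelse(strand[idx] == "-", revcomp(top), top)

    ## locate the fragments' cytosines (on the fragment strand)
    res_mask <- rep("", length(idx))
    flat <- list()
    for (sd_ in c("+", "-")) {
      sub <- which(strand[idx] == sd_)
      if (!length(sub)) next
      mp <- if (sd_ == "+") maps[[k]]$plus else maps[[k]]$minus
      lo <- findInterval(start[idx][sub] - 1L, mp$pos) + 1L
      hi <- findInterval(end[idx][sub], mp$pos)
      nk <- pmax(hi - lo + 1L, 0L)
      if (sum(nk) == 0L) next
      keep <- nk > 0L
      fi <- rep(sub[keep], nk[keep])
      cj <- sequence(nk[keep], from = lo[keep])
      cpos <- mp$pos[cj]
      ctx <- mp$ctx[cj]
      off <- if (sd_ == "+") cpos - start[idx][fi] + 1L
             else end[idx][fi] - cpos + 1L
      flat[[sd_]] <- tibble(fi = fi, off = off, ctx = ctx)
    }
    fl <- dplyr::bind_rows(flat)
    if (nrow(fl)) {
      p <- config$meth_prob[fl$ctx]
      meth <- runif(nrow(fl)) < p
      if (config$bias_5p > 0L) meth[fl$off <= config$bias_5p] <- FALSE
      convert <- !meth & (runif(nrow(fl)) < config$conversion_rate)

      ## apply conversions on a flat character vector of all fragments
      ch <- strsplit(fr, "", fixed = TRUE)
      lens <- nchar(fr)
      offset0 <- cumsum(c(0L, lens[-length(lens)]))
      flatch <- unlist(ch, use.names = FALSE)
      gidx <- offset0[fl$fi] + fl$off
      flatch[gidx[convert]] <- "T"
      fr <- vapply(split(flatch, rep(seq_along(lens), lens)),
                   paste, character(1), collapse = "")

      ## methylation mask, 5'->3' on the fragment
      ord <- order(fl$fi, fl$off)
      mk <- vapply(split(ifelse(meth[ord], "1", "0"), fl$fi[ord]),
                   paste, character(1), collapse = "")
      res_mask[as.integer(names(mk))] <- mk
    }
    frag[idx] <- fr
    masks[idx] <- res_mask
  }

  r1 <- substring(frag, 1L, L)
  r2 <- if (paired) revcomp(substring(frag, flen - L + 1L, flen)) else NULL
  if (config$directionality == "non-directional") {
    flip <- runif(n) < 0.5
    if (paired) {
      tmp <- r1[flip]
      r1[flip] <- r2[flip]
      r2[flip] <- tmp
    } else {
      r1[flip] <- revcomp(r1[flip])
    }
  }
  r1 <- apply_seq_errors(r1, config$error_rate)
  if (paired) r2 <- apply_seq_errors(r2, config$error_rate)

  qual <- qual_string(config)
  names_ <- sprintf("sim%07d:%s:%d:%s:%s", seq_len(n), names(genome)[ci],
                    start, strand, masks)
  if (paired) {
    dplyr::bind_rows(
      tibble(name = names_, mate = 1L, seq = r1, qual = qual),
      tibble(name = names_, mate = 2L, seq = r2, qual = qual)
    )
  } else {
    tibble(name = names_, mate = 0L, seq = r1, qual = qual)
  }
}

apply_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  L <- nchar(reads[1L])
  total <- length(reads) * L
  k <- rbinom(1L, total, rate)
  if (k == 0L) return(reads)
  idx <- sample.int(total, k)
  ri <- (idx - 1L) %/% L + 1L
  pi_ <- (idx - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    cur <- substr(reads[ri[j]], pi_[j], pi_[j])
    alt <- sample(setdiff(bases, cur), 1L)
    substr(reads[ri[j]], pi_[j], pi_[j]) <- alt
  }
  reads
}

qual_string <- function(config) {
  L <- config$read_len
  if (is.null(config$qual_decay_to)) {
    q <- rep(config$qual_constant, L)
  } else {
    q <- round(seq(config$qual_constant, config$qual_decay_to, length.out = L))
  }
  intToUtf8(33L + as.integer(q))
}

#' Parse truth records from simulated read names
#'
#' @param qname read names produced by [simulate_reads()].
#' @return tibble `qname`, `chrom`, `start`, `strand`, `mask`; unparseable
#'   names yield `NA` fields.
#' @export
parse_truth <- function(qname) {
  parts <- strsplit(qname, ":", fixed = TRUE)
  ok <- lengths(parts) >= 4L
  tibble(
    qname = qname,
    chrom = ifelse(ok, vapply(parts, function(p) p[2], character(1)),
                   NA_character_),
    start = ifelse(ok, as.integer(vapply(parts, function(p) p[3],
                                         character(1))), NA_integer_),
    strand = ifelse(ok, vapply(parts, function(p) p[4], character(1)),
                    NA_character_),
    mask = ifelse(ok & lengths(parts) >= 5L,
                  vapply(parts, function(p) if (length(p) >= 5) p[5] else "",
                         character(1)), "")
  )
}

#' Evaluate alignment accuracy against simulated truth
#'
#' A read (pair) is *correct* iff mapped with its leftmost coordinate and
#' chromosome equal to the truth (pairs: both mates mapped), *incorrect* iff
#' mapped elsewhere, and *discarded* iff unmapped. A second stratum applies a
#' MAPQ threshold, additionally discarding alignments below it — the filter a
#' methylation extractor would apply by default.
#'
#' @param aln a `bs_alignments` tibble whose read names carry truth records.
#' @param mapq_threshold MAPQ cutoff of the thresholded stratum.
#' @return a `bs_accuracy` object; see [tidy.bs_accuracy()] /
#'   [glance.bs_accuracy()].
#' @export
evaluate_accuracy <- function(aln, mapq_threshold = 10L) {
  prim <- aln[!aln$secondary, , drop = FALSE]
  units <- prim |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(
      all_mapped = all(.data$mapped),
      chrom = dplyr::first(.data$chrom),
      left = min(.data$pos),
      mapq = min(.data$mapq),
      .groups = "drop"
    )
  tr <- parse_truth(units$qname)
  bad <- is.na(tr$chrom)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable truth names rejected",
            call. = FALSE)
    units <- units[!bad, , drop = FALSE]
    tr <- tr[!bad, , drop = FALSE]
  }
  correct <- units$all_mapped & units$chrom == tr$chrom &
    units$left == tr$start
  correct[is.na(correct)] <- FALSE
  mapped <- units$all_mapped
  summary <- tibble(
    stratum = c("all", sprintf("mapq>=%d", mapq_threshold)),
    n_total = nrow(units),
    n_correct = c(sum(correct), sum(correct & units$mapq >= mapq_threshold)),
    n_incorrect = c(sum(mapped & !correct),
                    sum(mapped & !correct & units$mapq >= mapq_threshold))
  )
  summary$n_discarded <- summary$n_total - summary$n_correct -
    summary$n_incorrect
  structure(list(summary = summary, threshold = mapq_threshold),
            class = "bs_accuracy")
}

#' @export
print.bs_accuracy <- function(x, ...) {
  s <- x$summary
  cat("<bs_accuracy>\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s correct %5.2f%%  incorrect %5.2f%%  discarded %5.2f%%  (n=%d)\n",
                s$stratum[i], 100 * s$n_correct[i] / s$n_total[i],
                100 * s$n_incorrect[i] / s$n_total[i],
                100 * s$n_discarded[i] / s$n_total[i], s$n_total[i]))
  }
  invisible(x)
}

#' Concordance between two alignment runs of the same reads
#'
#' Units present (mapped) in both runs are *concordant* when chromosome and
#' leftmost start coordinate agree, *discordant* otherwise; units mapped in
#' only one run are tallied separately with their MAPQ distributions.
#'
#' @param aln_a,aln_b `bs_alignments` tibbles over the same read set.
#' @return a list with `summary` (status counts) and `per_read` (per-unit
#'   status with both runs' coordinates and MAPQs).
#' @export
concordance <- function(aln_a, aln_b) {
  unit_tab <- function(aln, suffix) {
    prim <- aln[!aln$secondary & aln$mapped, , drop = FALSE]
    if (anyDuplicated(paste(prim$qname, prim$mate))) {
      abort_ma("duplicate primary records for one read name")
    }
    u <- prim |>
      dplyr::group_by(.data$qname) |>
      dplyr::summarise(chrom = dplyr::first(.data$chrom),
                       left = min(.data$pos), mapq = min(.data$mapq),
                       .groups = "drop")
    names(u)[-1L] <- paste0(names(u)[-1L], suffix)
    u
  }
  a <- unit_tab(aln_a, "_a")
  b <- unit_tab(aln_b, "_b")
  m <- dplyr::full_join(a, b, by = "qname")
  m$status <- dplyr::case_when(
    is.na(m$chrom_a) ~ "only_b",
    is.na(m$chrom_b) ~ "only_a",
    m$chrom_a == m$chrom_b & m$left_a == m$left_b ~ "concordant",
    TRUE ~ "discordant"
  )
  summary <- m |> dplyr::count(.data$status, name = "n")
  list(summary = summary, per_read = m)
}
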