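#' Extraction filters
#'
#' Record- and base-level filters shared by the methylation extractor, the
#' M-bias calculator and (for the Phred floor) duplicate marking.
#'
#' @param min_mapq minimum MAPQ for a record to contribute calls (default 10).
#' @param min_phred minimum base Phred score for a call to be used
#'   (default 5).
#' @param trims optional trim bounds from [suggest_bounds()]: a tibble with
#'   `strand`, `mate`, `start`, `end`; read positions outside the inclusive
#'   bounds for that stratum are ignored. Strata absent from the table are
#'   untrimmed.
#' @return a `bs_filters` object.
#' @export
filter_config <- function(min_mapq = 10L, min_phred = 5L, trims = NULL) {
  structure(list(min_mapq = as.integer(min_mapq),
                 min_phred = as.integer(min_phred), trims = trims),
            class = "bs_filters")
}

## One row per methylation call surviving record-level filters. `readpos` is
## 1-based in sequencing (5'->3') orientation. Mate 0 (single-end) is
## normalised to stratum mate 1.
call_table <- function(aln, filters = filter_config(), use_phred = TRUE,
                       use_trims = TRUE) {
  keep <- aln$mapped & !aln$dup & !aln$secondary &
    aln$mapq >= filters$min_mapq
  rec <- aln[keep, , drop = FALSE]
  n_missing_xm <- sum(is.na(rec$XM))
  if (n_missing_xm > 0L) {
    warning(n_missing_xm, " mapped record(s) lack the XM tag and were ",
            "rejected", call. = FALSE)
    rec <- rec[!is.na(rec$XM), , drop = FALSE]
  }
  if (nrow(rec) == 0L) {
    return(tibble(qname = character(), mate = integer(), strand = character(),
                  chrom = character(), xg = character(), refpos = integer(),
                  readpos = integer(), call = character(), phred = integer()))
  }
  ex <- cpp_expand_calls(rec$pos, rec$cigar, rec$XM, rec$qual, rec$rev)
  calls <- tibble(
    qname = rec$qname[ex$rec],
    mate = pmax(rec$mate[ex$rec], 1L),
    strand = rec$strand[ex$rec],
    chrom = rec$chrom[ex$rec],
    xg = rec$XG[ex$rec],
    refpos = ex$refpos,
    readpos = ex$readpos,
    call = ex$call,
    phred = ex$phred
  )
  if (use_phred) calls <- calls[calls$phred >= filters$min_phred, ]
  if (use_trims && !is.null(filters$trims)) {
    tr <- filters$trims
    calls <- dplyr::left_join(calls, tr, by = c("strand", "mate"))
    inside <- is.na(calls$start) |
      (calls$readpos >= calls$start & calls$readpos <= calls$end)
    calls <- calls[inside, setdiff(names(calls), c("start", "end"))]
  }
  calls
}

#' Extract per-cytosine methylation counts
#'
#' Converts arbitrated alignments into per-genomic-cytosine, context-
#' stratified methylated/unmethylated counts. Unmapped, duplicate-flagged and
#' low-MAPQ records are skipped, as are calls below the Phred floor or outside
#' the trim bounds of their strand/mate stratum. Overlapping portions of a
#' read pair are processed as a unit so calls are not double-counted: where
#' only one mate has a usable call it is used; where both agree the call
#' counts once; where both carry high-quality calls that disagree the position
#' is not counted.
#'
#' @param x a `bs_alignments` tibble ([align_bs()]) or a BAM/SAM path.
#' @param genome the unconverted [bs_genome] (contig order fixes output
#'   order).
#' @param filters a [filter_config()].
#' @return a `bs_counts` tibble: `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`, the strand carrying the cytosine), `context`
#'   (`CpG`/`CHG`/`CHH`), `n_meth`, `n_unmeth`.
#' @export
extract_methylation <- function(x, genome, filters = filter_config()) {
  aln <- if (is.character(x)) read_alignments(x) else x
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  bad <- setdiff(unique(aln$chrom[aln$mapped]), names(genome))
  if (length(bad)) abort_ma("alignment contigs not in genome: ",
                            paste(bad, collapse = ", "))
  calls <- call_table(aln, filters)
  calls <- collapse_mate_overlap(calls)
  counts_from_calls(calls, genome)
}

## Overlap rule: within a pair (same qname) at the same reference position,
## keep a single call when the mates agree, drop the position when two
## surviving calls disagree.
collapse_mate_overlap <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$qname, calls$chrom, calls$refpos, sep = "\r")
  dupd <- duplicated(key) | duplicated(key, fromLast = TRUE)
  singles <- calls[!dupd, , drop = FALSE]
  if (!any(dupd)) return(singles)
  over <- calls[dupd, , drop = FALSE]
  agg <- over |>
    dplyr::group_by(.data$qname, .data$chrom, .data$refpos) |>
    dplyr::summarise(
      mate = dplyr::first(.data$mate), strand = dplyr::first(.data$strand),
      xg = dplyr::first(.data$xg), readpos = dplyr::first(.data$readpos),
      phred = max(.data$phred), n_sym = dplyr::n_distinct(.data$call),
      call = dplyr::first(.data$call), .groups = "drop"
    )
  agreed <- agg[agg$n_sym == 1L, names(calls), drop = FALSE]
  dplyr::bind_rows(singles, agreed)
}

counts_from_calls <- function(calls, genome) {
  if (nrow(calls) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), n_meth = integer(),
                  n_unmeth = integer())
  } else {
    out <- calls |>
      dplyr::mutate(
        context = c(Z = "CpG", X = "CHG", H = "CHH")[toupper(.data$call)],
        strand = ifelse(.data$xg == "CT", "+", "-"),
        meth = .data$call %in% c("Z", "X", "H"),
        pos = .data$refpos - 1L
      ) |>
      dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context) |>
      dplyr::summarise(n_meth = sum(.data$meth),
                       n_unmeth = sum(!.data$meth), .groups = "drop") |>
      dplyr::arrange(match(.data$chrom, names(genome)), .data$pos)
  }
  attr(out, "contigs") <- names(genome)
  class(out) <- c("bs_counts", class(out))
  out
}

#' Methylation percentage helper
#' @param counts a `bs_counts` tibble.
#' @return `counts` with a `pct` column, `100 * n_meth / (n_meth + n_unmeth)`.
#' @export
meth_percent <- function(counts) {
  dplyr::mutate(counts, pct = 100 * n_meth / (n_meth + n_unmeth))
}

#' Write per-context bedGraph files
#'
#' One file per context, 0-based half-open single-base intervals, sorted by
#' contig (genome order) then start. Columns: chrom, start, end,
#' integer-rounded methylation percentage, methylated count, unmethylated
#' count. Zero-coverage positions are never present in `counts` and so never
#' emitted.
#'
#' @param counts a `bs_counts` tibble.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param contexts contexts to write.
#' @return named character vector of file paths, invisibly.
#' @export
write_bedgraph <- function(counts, dir, prefix = "methylation",
                           contexts = c("CpG", "CHG", "CHH")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- attr(counts, "contigs") %||% unique(counts$chrom)
  paths <- character(0)
  for (ctx in contexts) {
    sub <- counts[counts$context == ctx, , drop = FALSE]
    sub <- sub[order(match(sub$chrom, contigs), sub$pos), , drop = FALSE]
    path <- file.path(dir, sprintf("%s.%s.bedGraph", prefix, ctx))
    lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d", sub$chrom, sub$pos,
                     sub$pos + 1L,
                     as.integer(round(100 * sub$n_meth /
                                        (sub$n_meth + sub$n_unmeth))),
                     sub$n_meth, sub$n_unmeth)
    writeLines(c(sprintf('track type=bedGraph name="%s %s methylation"',
                         prefix, ctx), lines), path)
    paths[ctx] <- path
  }
  invisible(paths)
}

#' Read a methylation bedGraph back into counts
#'
#' The bedGraph layout does not store strand; it is re-derived from the
#' genome (a C at the position lies on `+`, a G on `-`).
#'
#' @param path bedGraph file written by [write_bedgraph()].
#' @param genome the unconverted [bs_genome].
#' @param context the context the file holds.
#' @return a `bs_counts` tibble.
#' @export
read_bedgraph <- function(path, genome, context) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  if (length(lines) == 0L) {
    return(counts_from_calls(
      tibble(qname = character(), mate = integer(), strand = character(),
             chrom = character(), xg = character(), refpos = integer(),
             readpos = integer(), call = character(), phred = integer())[0, ],
      genome))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(f, `[[`, character(1), 1L)
  pos <- as.integer(vapply(f, `[[`, character(1), 2L))
  n_meth <- as.integer(vapply(f, `[[`, character(1), 5L))
  n_unmeth <- as.integer(vapply(f, `[[`, character(1), 6L))
  base <- substring(unclass(genome)[chrom], pos + 1L, pos + 1L)
  strand <- ifelse(base == "C", "+", ifelse(base == "G", "-", NA_character_))
  if (anyNA(strand)) abort_ma("bedGraph position is not a genomic C or G")
  out <- tibble(chrom = chrom, pos = pos, strand = strand,
                context = context, n_meth = n_meth, n_unmeth = n_unmeth)
  attr(out, "contigs") <- names(genome)
  class(out) <- c("bs_counts", class(out))
  out
}

#' Merge the two cytosines of each CpG
#'
#' Adds the counts of the minus-strand C of a CpG (genome position p, a G on
#' the top strand) into the plus-strand C at p-1, leaving one record per CpG
#' dinucleotide at the plus-strand coordinate.
#'
#' @param counts CpG-context `bs_counts`.
#' @param genome the unconverted [bs_genome].
#' @return merged `bs_counts` (strand `+` throughout).
#' @export
merge_cpg <- function(counts, genome) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  cp <- counts[counts$context == "CpG", , drop = FALSE]
  if (nrow(cp) != nrow(counts)) {
    abort_ma("merge_cpg expects CpG-context counts only")
  }
  g <- unclass(genome)
  base <- substring(g[cp$chrom], cp$pos + 1L, cp$pos + 1L)
  nxt <- substring(g[cp$chrom], cp$pos + 2L, cp$pos + 2L)
  prv <- substring(g[cp$chrom], cp$pos, cp$pos)
  ok <- (cp$strand == "+" & base == "C" & nxt == "G") |
    (cp$strand == "-" & base == "G" & prv == "C")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    abort_ma(sprintf("record at %s:%d (%s) is not a genomic CpG cytosine",
                     cp$chrom[bad], cp$pos[bad], cp$strand[bad]))
  }
  cp$pos <- ifelse(cp$strand == "-", cp$pos - 1L, cp$pos)
  out <- cp |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     n_unmeth = sum(.data$n_unmeth), .groups = "drop") |>
    dplyr::mutate(strand = "+", context = "CpG") |>
    dplyr::select("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  contigs <- attr(counts, "contigs") %||% names(genome)
  out <- out[order(match(out$chrom, contigs), out$pos), , drop = FALSE]
  attr(out, "contigs") <- contigs
  class(out) <- c("bs_counts", class(out))
  out
}

#' Merge counts from technical replicates
#'
#' @param ... two or more `bs_counts` tibbles of the same context and genome.
#' @return per-key summed `bs_counts`. Conflicting contig sets warn and take
#'   the union.
#' @export
merge_replicates <- function(...) {
  ins <- list(...)
  if (length(ins) == 1L && is.list(ins[[1L]]) &&
      !inherits(ins[[1L]], "bs_counts")) {
    ins <- ins[[1L]]
  }
  contig_sets <- lapply(ins, function(x) attr(x, "contigs") %||%
                          unique(x$chrom))
  if (length(unique(lapply(contig_sets, sort))) > 1L) {
    warning("replicates disagree on contig sets; taking the union",
            call. = FALSE)
  }
  contigs <- Reduce(union, contig_sets)
  out <- dplyr::bind_rows(lapply(ins, as_tibble)) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context) |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     n_unmeth = sum(.data$n_unmeth), .groups = "drop")
  out <- out[order(match(out$chrom, contigs), out$pos), , drop = FALSE]
  attr(out, "contigs") <- contigs
  class(out) <- c("bs_counts", class(out))
  out
}

#' CpG coverage table
#'
#' Number of CpGs reaching each coverage threshold; counts are necessarily
#' non-increasing across thresholds.
#'
#' @param counts CpG-context `bs_counts` (merged or per-strand).
#' @param thresholds coverage thresholds.
#' @return tibble with `threshold` and `n_cpg`.
#' @export
coverage_metrics <- function(counts,
                             thresholds = c(1L, 3L, 5L, 10L, 30L, 50L,
                                            100L)) {
  cp <- counts[counts$context == "CpG", , drop = FALSE]
  total <- cp$n_meth + cp$n_unmeth
  tibble(threshold = as.integer(thresholds),
         n_cpg = vapply(thresholds, function(t) sum(total >= t), integer(1)))
}

#' Export counts for downstream R packages
#'
#' Writes per-site text files in the input dialect of common methylation
#' analysis packages. The `methylKit` dialect has columns chrBase, chr, base
#' (1-based), strand (F/R), coverage, freqC, freqT (percentages, 2 decimals);
#' the `BSseq` dialect has chr, pos (1-based), Cov (total), M (methylated
#' count).
#'
#' @param counts a `bs_counts` tibble.
#' @param dialect `"methylKit"` or `"BSseq"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_format <- function(counts, dialect, path) {
  if (!dialect %in% c("methylKit", "BSseq")) {
    abort_ma("unknown dialect '", dialect,
             "'; supported dialects: methylKit, BSseq")
  }
  total <- counts$n_meth + counts$n_unmeth
  if (dialect == "methylKit") {
    df <- tibble(
      chrBase = sprintf("%s.%d", counts$chrom, counts$pos + 1L),
      chr = counts$chrom, base = counts$pos + 1L,
      strand = ifelse(counts$strand == "+", "F", "R"),
      coverage = total,
      freqC = sprintf("%.2f", 100 * counts$n_meth / total),
      freqT = sprintf("%.2f", 100 * counts$n_unmeth / total)
    )
  } else {
    df <- tibble(chr = counts$chrom, pos = counts$pos + 1L, Cov = total,
                 M = counts$n_meth)
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an exported per-site file back
#'
#' @param path file written by [export_format()].
#' @param dialect `"methylKit"` or `"BSseq"`.
#' @return tibble with `chrom`, `pos` (0-based), `n_meth`, `n_unmeth` (plus
#'   `strand` for methylKit, which stores it).
#' @export
read_export <- function(path, dialect) {
  if (!dialect %in% c("methylKit", "BSseq")) {
    abort_ma("unknown dialect '", dialect,
             "'; supported dialects: methylKit, BSseq")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = if (dialect == "methylKit") {
                          readr::cols(strand = readr::col_character())
                        } else NULL)
  if (dialect == "methylKit") {
    tibble(chrom = df$chr, pos = df$base - 1L,
           strand = ifelse(df$strand == "F", "+", "-"),
           n_meth = as.integer(round(df$coverage * as.numeric(df$freqC) /
                                       100)),
           n_unmeth = as.integer(round(df$coverage * as.numeric(df$freqT) /
                                         100)))
  } else {
    tibble(chrom = df$chr, pos = df$pos - 1L, n_meth = as.integer(df$M),
           n_unmeth = as.integer(df$Cov - df$M))
  }
}
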