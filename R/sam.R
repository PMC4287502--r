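#' Write alignments to SAM
#'
#' Writes a `bs_alignments` tibble as SAM text with an `@SQ` header from the
#' genome and a `@PG` provenance line. Records are coordinate-sorted (header
#' contig order, then position; unmapped records last).
#'
#' @param aln a `bs_alignments` tibble (see [align_bs()]).
#' @param genome the [bs_genome] the alignments refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
           sprintf("@PG\tID:methalign\tPN:methalign\tVN:%s",
                   as.character(utils::packageVersion("methalign"))))
  ord <- order(!aln$mapped, match(aln$chrom, names(genome)), aln$pos,
               aln$qname, aln$mate)
  a <- aln[ord, , drop = FALSE]
  flag <- a$flag + ifelse(isTRUE_v(a$dup) & !bitwAnd(a$flag, 1024L), 1024L, 0L)
  fields <- cbind(
    a$qname, flag,
    ifelse(a$mapped, a$chrom, "*"),
    ifelse(a$mapped, a$pos, 0L),
    ifelse(a$mapped, a$mapq, 0L),
    ifelse(a$mapped, a$cigar, "*"),
    a$rnext %||% "*",
    a$pnext %||% 0L,
    a$tlen %||% 0L,
    a$seq, a$qual
  )
  tagcol <- function(vals, tag, type) {
    ifelse(is.na(vals), "", sprintf("\t%s:%s:%s", tag, type, vals))
  }
  tags <- paste0(
    tagcol(a$AS, "AS", "i"), tagcol(a$XS, "XS", "i"),
    tagcol(a$XM, "XM", "Z"), tagcol(a$XG, "XG", "Z"), tagcol(a$XR, "XR", "Z")
  )
  lines <- paste0(apply(fields, 1L, paste, collapse = "\t"), tags)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Write alignments to BAM
#'
#' Coordinate-sorts, converts to BAM via Rsamtools and indexes.
#'
#' @inheritParams write_sam
#' @param path output BAM path (`.bam`).
#' @return the BAM path, invisibly.
#' @export
write_bam <- function(aln, genome, path) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  write_sam(aln, genome, sam)
  dest <- sub("\\.bam$", "", path)
  out <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(out)
}

#' Read alignments from BAM or SAM into a tibble
#'
#' SAM text input is converted through Rsamtools. Records are returned with
#' the same columns `align_bs()` produces; the originating strand is derived
#' from the XG/XR tags when present.
#'
#' @param path a `.bam` or `.sam` file.
#' @return a `bs_alignments` tibble.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq", "qual"),
    tag = c("AS", "XS", "XM", "XG", "XR")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  n <- length(b$qname)
  tagv <- function(tg, mode) {
    v <- b$tag[[tg]]
    if (is.null(v)) rep(if (mode == "i") NA_integer_ else NA_character_, n)
    else v
  }
  flag <- b$flag
  xg <- tagv("XG", "z")
  xr <- tagv("XR", "z")
  strand <- dplyr::case_when(
    xg == "CT" & xr == "CT" ~ "OT",
    xg == "GA" & xr == "CT" ~ "OB",
    xg == "CT" & xr == "GA" ~ "CTOT",
    xg == "GA" & xr == "GA" ~ "CTOB",
    TRUE ~ NA_character_
  )
  ## mate-2 records carry the read-2 conversion; normalise strand to the
  ## pair's hypothesis (mate 2 of OT carries XR GA, etc.)
  is_m2 <- bitwAnd(flag, 128L) > 0L
  strand[is_m2] <- dplyr::case_when(
    xg[is_m2] == "CT" & xr[is_m2] == "GA" ~ "OT",
    xg[is_m2] == "GA" & xr[is_m2] == "GA" ~ "OB",
    xg[is_m2] == "CT" & xr[is_m2] == "CT" ~ "CTOT",
    xg[is_m2] == "GA" & xr[is_m2] == "CT" ~ "CTOB",
    TRUE ~ NA_character_
  )
  out <- tibble(
    qname = b$qname, flag = flag,
    chrom = as.character(b$rname), pos = b$pos, mapq = b$mapq,
    cigar = b$cigar,
    rnext = as.character(b$mrnm), pnext = b$mpos, tlen = b$isize,
    seq = as.character(b$seq), qual = as.character(b$qual),
    AS = tagv("AS", "i"), XS = tagv("XS", "i"),
    XM = tagv("XM", "z"), XG = xg, XR = xr,
    strand = strand,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)),
    mapped = bitwAnd(flag, 4L) == 0L,
    rev = bitwAnd(flag, 16L) > 0L,
    dup = bitwAnd(flag, 1024L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  )
  class(out) <- c("bs_alignments", class(out))
  out
}

#' Check whether a BAM file is coordinate-sorted
#' @param path BAM path.
#' @return logical.
#' @noRd
bam_is_sorted <- function(path) {
  hd <- Rsamtools::scanBamHeader(path)[[1L]]$text
  if (!"@HD" %in% names(hd)) return(FALSE)
  any(grepl("SO:coordinate", unlist(hd[names(hd) == "@HD"])))
}
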