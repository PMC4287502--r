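#' Library protocol
#'
#' Describes how a bisulfite library was constructed. Directional libraries
#' sequence only the two original (bisulfite-converted) strands, so reads are
#' aligned against two strand hypotheses (OT, OB). Non-directional libraries
#' also sequence the PCR complements, adding CTOT and CTOB.
#'
#' @param directionality `"directional"` or `"non-directional"`.
#' @param pairing `"single"` or `"paired"`.
#' @return a `bs_protocol` object.
#' @export
protocol <- function(directionality = c("directional", "non-directional"),
                     pairing = c("single", "paired")) {
  directionality <- match.arg(directionality)
  pairing <- match.arg(pairing)
  structure(list(directionality = directionality, pairing = pairing),
            class = "bs_protocol")
}

#' Alignment strands a protocol permits
#'
#' @param x a [protocol()] object.
#' @return character vector of strand names: 2 for directional, 4 for
#'   non-directional.
#' @export
protocol_strands <- function(x) {
  stopifnot(inherits(x, "bs_protocol"))
  if (x$directionality == "directional") c("OT", "OB")
  else c("OT", "OB", "CTOT", "CTOB")
}

#' @export
print.bs_protocol <- function(x, ...) {
  cat(sprintf("<bs_protocol> %s, %s-end (%d strand hypotheses)\n",
              x$directionality, x$pairing, length(protocol_strands(x))))
  invisible(x)
}

#' Read FASTQ into a tibble
#'
#' @param path path to a FASTQ file, gzip-compressed or plain.
#' @param mate mate number to record (1, 2, or 0 for single-end).
#' @return a tibble with columns `name`, `mate`, `seq`, `qual`. Sequences are
#'   uppercased; names are truncated at the first whitespace.
#' @export
read_fastq <- function(path, mate = 0L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    name = sub("\\s.*$", "", names(x)),
    mate = as.integer(mate),
    seq = unname(toupper(as.character(x))),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read a paired-end FASTQ file pair
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths.
#' @return a tibble as in [read_fastq()] with `mate` 1 and 2; names must pair
#'   up one-to-one in file order.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- read_fastq(path1, mate = 1L)
  r2 <- read_fastq(path2, mate = 2L)
  if (nrow(r1) != nrow(r2) || !all(r1$name == r2$name)) {
    abort_ma("mate files disagree on read names or counts")
  }
  dplyr::bind_rows(r1, r2)
}

#' Write reads to FASTQ
#'
#' @param reads tibble with `name`, `seq`, `qual` (and optionally `mate`).
#' @param path output path; a `.gz` suffix compresses.
#' @param mate if given, only reads with this mate value are written.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate = NULL) {
  if (!is.null(mate)) reads <- reads[reads$mate == mate, , drop = FALSE]
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

## Strand dispatch table for three-letter alignment. `conv1` is the in-silico
## conversion applied to mate 1 (mate 2 always receives the opposite), `target`
## the converted reference searched, `orient1` the orientation constraint for
## mate 1 (mate 2 is opposite), and xg/xr the genome-/read-conversion tags the
## resulting alignments carry.
strand_table <- function() {
  tibble(
    strand = c("OT", "OB", "CTOT", "CTOB"),
    conv1 = c("CT", "CT", "GA", "GA"),
    target = c("ct", "ga", "ct", "ga"),
    orient1 = c("forward", "reverse", "reverse", "forward"),
    xg = c("CT", "GA", "CT", "GA"),
    xr1 = c("CT", "CT", "GA", "GA")
  )
}

#' In-silico conversion and strand dispatch of reads
#'
#' Converts reads for every strand hypothesis a protocol permits and states
#' which converted reference and orientation constraint each variant must be
#' aligned under. Original sequences and qualities are carried unchanged in
#' every variant.
#'
#' @param reads tibble with `name`, `mate` (0 for single-end; 1/2 for pairs),
#'   `seq`, `qual`.
#' @param protocol a [protocol()] object.
#' @return a tibble with one row per (read, strand) dispatch entry: columns
#'   `strand`, `target` (`"ct"` or `"ga"` reference), `orient`
#'   (orientation constraint for this mate), `name`, `mate`, `seq_conv`,
#'   `seq`, `qual`. Exactly 2 entries per read for directional protocols and
#'   4 for non-directional ones.
#' @export
convert_reads <- function(reads, protocol = methalign::protocol()) {
  stopifnot(inherits(protocol, "bs_protocol"))
  if (nrow(reads) == 0L) abort_ma("no reads to convert")
  if (any(!nzchar(reads$seq))) abort_ma("empty read sequence")
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort_ma("sequence and quality lengths differ")
  }
  st <- strand_table()
  st <- st[st$strand %in% protocol_strands(protocol), ]
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    conv1 <- st$conv1[i]
    is_m2 <- reads$mate == 2L
    conv <- ifelse(xor(is_m2, conv1 == "CT"), seq_c2t(reads$seq),
                   seq_g2a(reads$seq))
    orient <- ifelse(xor(is_m2, st$orient1[i] == "forward"),
                     "forward", "reverse")
    out[[i]] <- tibble(
      strand = st$strand[i], target = st$target[i], orient = orient,
      name = reads$name, mate = reads$mate, seq_conv = conv,
      seq = reads$seq, qual = reads$qual
    )
  }
  dplyr::bind_rows(out)
}
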