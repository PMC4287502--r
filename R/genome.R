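#' Genome sequences for bisulfite alignment
#'
#' A `bs_genome` is a named character vector of uppercase contig sequences
#' over the alphabet A, C, G, T, N. Coordinates are 1-based at the user-facing
#' interface; methylation count tables use 0-based starts to match bedGraph.
#'
#' @param contigs named character vector of DNA sequences. Lowercase
#'   (soft-masked) bases are uppercased; masking is ignored.
#' @return a `bs_genome` object.
#' @examples
#' g <- bs_genome(c(chr1 = "ACGTACGT"))
#' @export
bs_genome <- function(contigs) {
  if (length(contigs) == 0L) abort_ma("genome must contain at least one contig")
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort_ma("all contigs must have non-empty names")
  }
  if (anyDuplicated(nm)) abort_ma("contig names must be unique")
  contigs <- toupper(contigs)
  bad <- regexpr("[^ACGTN]", contigs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort_ma(sprintf("invalid character in contig '%s' at position %d",
                     nm[i], bad[i]))
  }
  structure(as.character(contigs), names = nm, class = "bs_genome")
}

#' @export
print.bs_genome <- function(x, ...) {
  cat(sprintf("<bs_genome> %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x)) {
    cat(sprintf("  %s: %d bp\n", names(x)[i], nchar(x[i])))
  }
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return a [bs_genome] object. Contig names are truncated at the first
#'   whitespace, matching SAM conventions.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  bs_genome(setNames(as.character(x), nm))
}

#' Write a genome to FASTA
#'
#' @param genome a [bs_genome].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' In-silico bisulfite conversion of a genome
#'
#' Creates the two converted references used for three-letter alignment: one
#' with every C replaced by T (the converted top strand) and one with every G
#' replaced by A (the converted bottom strand). The unconverted source is kept
#' for methylation-context lookup.
#'
#' @param genome a [bs_genome].
#' @return an object of class `bs_converted_genome`: a list with elements
#'   `ct`, `ga` (converted [bs_genome]s) and `source`.
#' @examples
#' convert_genome(bs_genome(c(chr1 = "ACGT")))
#' @export
convert_genome <- function(genome) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  ct <- structure(seq_c2t(unclass(genome)), names = names(genome),
                  class = "bs_genome")
  ga <- structure(seq_g2a(unclass(genome)), names = names(genome),
                  class = "bs_genome")
  structure(list(ct = ct, ga = ga, source = genome),
            class = "bs_converted_genome")
}

#' @export
print.bs_converted_genome <- function(x, ...) {
  cat("<bs_converted_genome> C->T and G->A references for",
      length(x$source), "contig(s)\n")
  invisible(x)
}

#' Reduced-representation (RRBS) genome digestion
#'
#' Performs an in-silico restriction digestion and keeps the fragments whose
#' lengths fall within a size-selection window, emulating the
#' reduced-representation genome that RRBS reads are mapped against. Only
#' fragments *between* consecutive cut positions are returned (contig ends are
#' not fragments). Each retained fragment becomes a contig named
#' `<chrom>:<start>-<end>` with 0-based half-open coordinates on the source
#' contig.
#'
#' @param genome a [bs_genome].
#' @param site recognition motif (default MspI, `CCGG`).
#' @param cut_offset cut position within the motif (default 1: `C^CGG`).
#' @param min_frag,max_frag inclusive fragment-length window (default
#'   40-600 bp, a common RRBS size selection).
#' @return a [bs_genome] of retained fragments (possibly empty: a genome with
#'   no sites reduces to nothing).
#' @examples
#' reduce_genome_rrbs(bs_genome(c(c1 = "AAACCGGTTTTTCCGGAAA")), min_frag = 4)
#' @export
reduce_genome_rrbs <- function(genome, site = "CCGG", cut_offset = 1L,
                               min_frag = 40L, max_frag = 600L) {
  if (!inherits(genome, "bs_genome")) genome <- bs_genome(genome)
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) abort_ma("site must be a fixed ACGT motif")
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    abort_ma("cut_offset must lie within the motif")
  }
  if (min_frag <= 0L || min_frag > max_frag) {
    abort_ma("need 0 < min_frag <= max_frag")
  }
  out <- character()
  nms <- character()
  for (i in seq_along(genome)) {
    contig <- unclass(genome)[i]
    m <- gregexpr(site, contig, fixed = TRUE)[[1L]]
    if (m[1L] == -1L || length(m) < 2L) next
    cuts <- as.integer(m) - 1L + cut_offset  # 0-based cut points
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L]
    len <- ends - starts
    keep <- len >= min_frag & len <= max_frag
    if (!any(keep)) next
    frag <- substring(contig, starts[keep] + 1L, ends[keep])
    out <- c(out, frag)
    nms <- c(nms, sprintf("%s:%d-%d", names(genome)[i], starts[keep],
                          ends[keep]))
  }
  if (length(out) == 0L) {
    return(structure(character(), names = character(), class = "bs_genome"))
  }
  bs_genome(setNames(out, nms))
}

#' Build an alignment index directory
#'
#' Materialises the converted references to FASTA (used by an external
#' bowtie2-compatible backend; the built-in aligner keeps them in memory) and,
#' when an external aligner is discoverable, builds its indices.
#'
#' @param genome a [bs_genome] or path to a FASTA file.
#' @param out_dir directory to create.
#' @param external build external backend indices if `bowtie2-build` is on the
#'   PATH.
#' @return `out_dir`, invisibly.
#' @export
build_index <- function(genome, out_dir, external = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  conv <- convert_genome(genome)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(conv$source, file.path(out_dir, "genome.fa"))
  write_fasta(conv$ct, file.path(out_dir, "genome.CT.fa"))
  write_fasta(conv$ga, file.path(out_dir, "genome.GA.fa"))
  if (external) {
    bt2 <- Sys.which("bowtie2-build")
    if (!nzchar(bt2)) {
      abort_ma("external index requested but bowtie2-build is not on the PATH")
    }
    for (tag in c("CT", "GA")) {
      fa <- file.path(out_dir, sprintf("genome.%s.fa", tag))
      status <- system2(bt2, c(shQuote(fa),
                               shQuote(file.path(out_dir, tag))),
                        stdout = FALSE, stderr = TRUE)
      if (!is.null(attr(status, "status"))) {
        abort_ma("bowtie2-build failed: ", paste(status, collapse = "\n"))
      }
    }
  }
  invisible(out_dir)
}
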