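#' Pipeline configuration
#'
#' Bundles the paths and parameters of a full processing run. Serialisable to
#' YAML with [write_pipeline_config()]; command-line flags override file
#' values in the CLI.
#'
#' @param genome path to the reference FASTA.
#' @param fastq1,fastq2 read files (`fastq2 = NULL` for single-end).
#' @param out_dir output directory.
#' @param directionality,pairing library protocol (see [protocol()]).
#' @param min_mapq,min_phred extraction filters (see [filter_config()]).
#' @param backend `"builtin"` (default) or `"external"`.
#' @param threads worker threads for an external backend.
#' @param seed RNG seed recorded in the manifest.
#' @return a `bs_pipeline_config` object.
#' @export
pipeline_config <- function(genome, fastq1, fastq2 = NULL, out_dir,
                            directionality = "directional",
                            pairing = if (is.null(fastq2)) "single"
                                      else "paired",
                            min_mapq = 10L, min_phred = 5L,
                            backend = "builtin", threads = 1L, seed = 1L) {
  structure(list(genome = genome, fastq1 = fastq1, fastq2 = fastq2,
                 out_dir = out_dir, directionality = directionality,
                 pairing = pairing, min_mapq = as.integer(min_mapq),
                 min_phred = as.integer(min_phred), backend = backend,
                 threads = as.integer(threads), seed = as.integer(seed)),
            class = "bs_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `bs_pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the full processing pipeline
#'
#' Executes index (genome conversion), alignment (conversion, per-strand
#' candidates, arbitration), duplicate marking, M-bias computation and
#' methylation extraction in order, writing a BAM with methylation tags,
#' per-context bedGraphs, a merged-CpG bedGraph, the M-bias table/plot and a
#' manifest of produced files. Per-stage record counts are logged with
#' `message()`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest tibble (`file`, `md5`), invisibly; written to
#'   `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bs_pipeline_config"))
  for (p in c(config$genome, config$fastq1, config$fastq2)) {
    if (!is.null(p) && !file.exists(p)) {
      abort_ma("input does not exist: ", p)
    }
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      abort_ma("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  genome <- stage("index: loading and converting genome", {
    read_fasta(config$genome)
  })
  proto <- protocol(config$directionality, config$pairing)
  reads <- stage("load reads", {
    if (config$pairing == "paired") {
      read_fastq_pair(config$fastq1, config$fastq2)
    } else {
      read_fastq(config$fastq1)
    }
  })
  aln <- stage("align", {
    a <- align_bs(reads, genome, proto,
                  unmapped_fastq = file.path(out, "unmapped"))
    message(sprintf("  aligned %d/%d units (%.2f%%)",
                    sum(a$mapped & a$mate != 2L),
                    sum(a$mate != 2L),
                    100 * mean(a$mapped[a$mate != 2L])))
    a
  })
  aln <- stage("markdup", {
    a <- mark_duplicates(aln, min_phred = config$min_phred)
    message(sprintf("  marked %d duplicate record(s)", sum(a$dup)))
    a
  })
  bam <- stage("write BAM", {
    write_bam(aln, genome, file.path(out, "alignments.bam"))
  })
  filters <- filter_config(config$min_mapq, config$min_phred)
  mb <- stage("mbias", {
    m <- compute_mbias(aln, filters)
    bounds <- if (nrow(m)) suggest_bounds(m) else NULL
    write_mbias(m, out, bounds = bounds)
    if (!is.null(bounds)) {
      message(paste0("  suggested inclusion bounds: ",
                     paste(sprintf("%s/%d:%d-%d", bounds$strand, bounds$mate,
                                   bounds$start, bounds$end),
                           collapse = ", ")))
    }
    m
  })
  counts <- stage("extract", {
    ct <- extract_methylation(aln, genome, filters)
    message(sprintf("  %d covered cytosines (%d CpG)", nrow(ct),
                    sum(ct$context == "CpG")))
    write_bedgraph(ct, out)
    merged <- merge_cpg(ct[ct$context == "CpG", ], genome)
    write_bedgraph(merged, out, prefix = "methylation.merged",
                   contexts = "CpG")
    ct
  })

  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- tibble(file = basename(files),
                     md5 = as.character(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}

#' Generate a deterministic fixture bundle
#'
#' Writes a small synthetic genome (3 contigs), directional and
#' non-directional FASTQ sets with truth-encoded names, and hand-crafted SAM
#' files exercising extraction and duplicate-marking edge cases (overlapping
#' mates, N bases, soft clips, a cross-strand tie that arbitration must drop,
#' and a duplicate trio with distinct Phred sums).
#'
#' @param dir output directory.
#' @param seed RNG seed; the bundle is deterministic given the seed.
#' @return tibble of produced files and their md5 checksums, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  glen <- c(chrA = 20000L, chrB = 12000L, chrC = 8000L)
  contigs <- vapply(glen, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  }, character(1))
  genome <- bs_genome(contigs)
  write_fasta(genome, file.path(dir, "genome.fa"))

  cfg_d <- sim_config(n_fragments = 1000L, pairing = "paired",
                      directionality = "directional", seed = seed)
  rd <- simulate_reads(genome, cfg_d)
  write_fastq(rd, file.path(dir, "directional_1.fastq.gz"), mate = 1L)
  write_fastq(rd, file.path(dir, "directional_2.fastq.gz"), mate = 2L)
  cfg_n <- sim_config(n_fragments = 500L, pairing = "single",
                      directionality = "non-directional", seed = seed + 1L)
  rn <- simulate_reads(genome, cfg_n)
  write_fastq(rn, file.path(dir, "nondirectional.fastq.gz"))

  ## hand-crafted SAM: a tiny dedicated reference keeps the records readable.
  ## The reference also carries an A/T-only segment plus its reverse
  ## complement so a read of that segment scores identically on OT and OB —
  ## the cross-strand tie arbitration must drop.
  tie_seg <- "ATTATTAAATTTATAATTAA"
  g2 <- bs_genome(c(fix = paste0("TTACGTTACGTT", "CCGGTTACGTTACG",
                                 "TTTTACGCATGCAT", "ACGTACGTACGT", "GG",
                                 tie_seg, "CC", revcomp(tie_seg))))
  write_fasta(g2, file.path(dir, "fixture_ref.fa"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:fix\tLN:%d", nchar(g2)))
  q <- function(n) strrep("I", n)
  rec <- function(qname, flag, pos, cigar, seq, qual, ...) {
    tags <- c(...)
    paste(c(qname, flag, "fix", pos, 40L, cigar, "*", 0L, 0L, seq, qual,
            tags), collapse = "\t")
  }
  xm_of <- function(pos, seq, cigar = paste0(nchar(seq), "M"), xg = "CT") {
    assign_methylation("fix", pos, cigar, seq, xg, g2)
  }
  sam <- c(
    hdr,
    ## overlapping mates agreeing at a CpG (pos 3 'ACG'), plus an N in one
    rec("ovl1", 99L, 2L, "6M", "TACGTT", q(6), "AS:i:0",
        paste0("XM:Z:", xm_of(2L, "TACGTT")), "XG:Z:CT", "XR:Z:CT"),
    rec("ovl1", 147L, 2L, "6M", "TANGTT", q(6), "AS:i:0",
        paste0("XM:Z:", xm_of(2L, "TANGTT")), "XG:Z:CT", "XR:Z:GA"),
    ## soft-clipped duplicate candidate pair (clip-adjusted 5' match)
    rec("clip1", 0L, 13L, "8M", "CCGGTTAC", q(8), "AS:i:0",
        paste0("XM:Z:", xm_of(13L, "CCGGTTAC")), "XG:Z:CT", "XR:Z:CT"),
    rec("clip2", 0L, 15L, "2S6M", "AAGGTTAC", q(8), "AS:i:-2",
        paste0("XM:Z:", xm_of(15L, "AAGGTTAC", "2S6M")), "XG:Z:CT",
        "XR:Z:CT"),
    ## duplicate trio with distinct Phred sums
    rec("trio1", 0L, 41L, "8M", "ACGTACGT", strrep("I", 8), "AS:i:0",
        paste0("XM:Z:", xm_of(41L, "ACGTACGT")), "XG:Z:CT", "XR:Z:CT"),
    rec("trio2", 0L, 41L, "8M", "ACGTACGT", strrep("H", 8), "AS:i:0",
        paste0("XM:Z:", xm_of(41L, "ACGTACGT")), "XG:Z:CT", "XR:Z:CT"),
    rec("trio3", 0L, 41L, "8M", "ACGTACGT", strrep("G", 8), "AS:i:0",
        paste0("XM:Z:", xm_of(41L, "ACGTACGT")), "XG:Z:CT", "XR:Z:CT")
  )
  writeLines(sam, file.path(dir, "edge_cases.sam"))

  ## a cross-strand tie: a read matching a palindromic-ish site equally well
  ## on OT and OB; alignment of this FASTQ must drop it as unmapped
  tie <- tibble(name = "tie1", mate = 0L, seq = tie_seg,
                qual = q(nchar(tie_seg)))
  write_fastq(tie, file.path(dir, "tie.fastq.gz"))

  files <- list.files(dir, full.names = TRUE)
  manifest <- tibble(file = basename(files),
                     md5 = as.character(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(dir, "fixtures.tsv"))
  invisible(manifest)
}
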