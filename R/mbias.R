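#' Per-position methylation bias (M-bias)
#'
#' Tallies CpG methylation calls per read position, stratified by originating
#' strand and mate, after the same MAPQ and Phred filtering as the
#' methylation extractor. Apparent methylation should be flat along the read;
#' departures at the 5'/3' ends (end repair, quality decay) indicate read
#' regions to ignore during extraction.
#'
#' @param x a `bs_alignments` tibble or BAM/SAM path.
#' @param filters a [filter_config()] (trims are not applied here; M-bias is
#'   computed on the untrimmed read).
#' @return a `bs_mbias` tibble: `strand`, `mate`, `position` (1-based within
#'   the read, sequencing orientation), `n_meth`, `n_unmeth`, `pct`. The
#'   maximum observed read length is carried in attribute `max_pos`.
#' @export
compute_mbias <- function(x, filters = filter_config()) {
  aln <- if (is.character(x)) read_alignments(x) else x
  calls <- call_table(aln, filters, use_trims = FALSE)
  calls <- calls[calls$call %in% c("Z", "z"), , drop = FALSE]
  out <- calls |>
    dplyr::group_by(.data$strand, .data$mate, position = .data$readpos) |>
    dplyr::summarise(n_meth = sum(.data$call == "Z"),
                     n_unmeth = sum(.data$call == "z"), .groups = "drop") |>
    dplyr::mutate(pct = 100 * n_meth / (n_meth + n_unmeth)) |>
    dplyr::arrange(.data$strand, .data$mate, .data$position)
  attr(out, "max_pos") <- max(nchar(aln$seq[aln$mapped & !aln$secondary]),
                              0L)
  class(out) <- c("bs_mbias", class(out))
  out
}

#' Suggest per-stratum inclusion bounds from an M-bias profile
#'
#' For each (strand, mate) stratum, takes the median per-position methylation
#' percentage over the central 50% of covered positions as the plateau level,
#' then finds the longest contiguous run of positions whose percentage stays
#' within `tolerance_pct` of it. That run is the suggested inclusion region;
#' positions outside it are the regions to ignore during extraction.
#'
#' @param mbias a `bs_mbias` tibble from [compute_mbias()].
#' @param tolerance_pct tolerance around the plateau median, in percentage
#'   points.
#' @param min_positions minimum covered positions a stratum needs for a
#'   suggestion; below this (or with no coverage at all) full-length bounds
#'   are returned with a warning.
#' @return a `bs_trim_bounds` tibble: `strand`, `mate`, `start`, `end`
#'   (1-based inclusive read positions).
#' @export
suggest_bounds <- function(mbias, tolerance_pct = 2.0, min_positions = 5L) {
  max_pos <- attr(mbias, "max_pos") %||% max(mbias$position, 1L)
  strata <- unique(mbias[, c("strand", "mate")])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sub <- mbias[mbias$strand == strata$strand[i] &
                   mbias$mate == strata$mate[i], , drop = FALSE]
    sub <- sub[order(sub$position), ]
    covered <- sub$position[(sub$n_meth + sub$n_unmeth) > 0L]
    if (length(covered) < min_positions) {
      warning(sprintf("stratum %s/mate %d has <%d covered positions; %s",
                      strata$strand[i], strata$mate[i], min_positions,
                      "returning full-length bounds"), call. = FALSE)
      out[[i]] <- tibble(strand = strata$strand[i], mate = strata$mate[i],
                         start = 1L, end = as.integer(max_pos))
      next
    }
    pct <- setNames(sub$pct, sub$position)[as.character(covered)]
    nc <- length(covered)
    central <- pct[seq.int(floor(nc / 4) + 1L, ceiling(3 * nc / 4))]
    m <- median(central)
    inside <- abs(pct - m) <= tolerance_pct
    run <- longest_true_run(inside, covered)
    out[[i]] <- tibble(strand = strata$strand[i], mate = strata$mate[i],
                       start = run[1L], end = run[2L])
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bs_trim_bounds", class(res))
  res
}

## Longest contiguous run of TRUE over covered positions; contiguity is in
## read-position space (a coverage gap breaks the run). First longest wins.
longest_true_run <- function(inside, positions) {
  best <- c(NA_integer_, NA_integer_)
  best_len <- 0L
  run_start <- NA_integer_
  prev_pos <- NA_integer_
  for (j in seq_along(inside)) {
    contiguous <- !is.na(prev_pos) && positions[j] == prev_pos + 1L
    if (inside[j]) {
      if (is.na(run_start) || !contiguous) run_start <- positions[j]
      len <- positions[j] - run_start + 1L
      if (len > best_len) {
        best_len <- len
        best <- c(run_start, positions[j])
      }
    } else {
      run_start <- NA_integer_
    }
    prev_pos <- positions[j]
  }
  best
}

#' Plot an M-bias profile
#'
#' One panel per strand with one line per mate and dashed vertical lines at
#' the suggested inclusion bounds.
#'
#' @param object,x a `bs_mbias` tibble.
#' @param bounds optional `bs_trim_bounds` from [suggest_bounds()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bs_mbias <- function(object, bounds = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$pct,
                                        colour = factor(.data$mate))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~strand) +
    ggplot2::labs(x = "position in read", y = "% methylated CpG",
                  colour = "mate") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_bw()
  if (!is.null(bounds)) {
    p <- p +
      ggplot2::geom_vline(data = as_tibble(bounds),
                          ggplot2::aes(xintercept = .data$start),
                          linetype = "dashed") +
      ggplot2::geom_vline(data = as_tibble(bounds),
                          ggplot2::aes(xintercept = .data$end),
                          linetype = "dashed")
  }
  p
}

#' @rdname autoplot.bs_mbias
#' @export
plot.bs_mbias <- function(x, bounds = NULL, ...) {
  print(autoplot.bs_mbias(x, bounds = bounds))
  invisible(x)
}

#' Write M-bias outputs to disk
#'
#' Emits the underlying per-position table as TSV and, when the matrix is
#' non-empty, a PNG of the profile; an empty matrix warns and writes no
#' image.
#'
#' @param mbias a `bs_mbias` tibble.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param bounds optional `bs_trim_bounds`.
#' @return paths of the written files, invisibly.
#' @export
write_mbias <- function(mbias, dir, prefix = "mbias", bounds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  readr::write_tsv(as_tibble(mbias), tsv)
  paths <- c(table = tsv)
  if (nrow(mbias) == 0L) {
    warning("empty M-bias matrix; no plot written", call. = FALSE)
  } else {
    png_path <- file.path(dir, paste0(prefix, ".png"))
    grDevices::png(png_path, width = 1200, height = 500, res = 120)
    print(autoplot.bs_mbias(mbias, bounds = bounds))
    grDevices::dev.off()
    paths["plot"] <- png_path
  }
  invisible(paths)
}
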