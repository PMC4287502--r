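# Independent brute-force oracles. These re-derive expected values with the
# plainest possible implementations and must stay independent of the package
# code paths they check.

# score a read at one offset (0-based) of a genome string, quality-scaled
oracle_score_at <- function(genome, read, qual, off, mm_max = 6L,
                            mm_min = 2L, n_pen = 1L) {
  gb <- strsplit(substr(genome, off + 1L, off + nchar(read)), "")[[1L]]
  rb <- strsplit(read, "")[[1L]]
  q <- as.integer(utf8ToInt(qual)) - 33L
  pen <- 0L
  for (i in seq_along(rb)) {
    if (rb[i] == "N" || gb[i] == "N") {
      pen <- pen + n_pen
    } else if (rb[i] != gb[i]) {
      ## round half away from zero, the documented interpolation rule
      pen <- pen + as.integer(floor(mm_min + (mm_max - mm_min) *
                                      min(q[i], 40L) / 40 + 0.5))
    }
  }
  -pen
}

# exhaustive scan: best and second-best valid offsets over every position
oracle_align <- function(genome, read, qual, min_sc = NULL) {
  L <- nchar(read)
  if (is.null(min_sc)) min_sc <- -0.6 - 0.6 * L
  scores <- vapply(0:(nchar(genome) - L), function(off) {
    oracle_score_at(genome, read, qual, off)
  }, numeric(1))
  valid <- which(scores >= min_sc)
  if (!length(valid)) {
    return(list(mapped = FALSE, pos = NA, AS = NA, XS = NA))
  }
  best <- valid[which.max(scores[valid])]  # which.max: first max = leftmost
  rest <- setdiff(valid, best)
  list(mapped = TRUE, pos = best - 1L,     # 0-based offset
       AS = scores[best],
       XS = if (length(rest)) max(scores[rest]) else NA_integer_)
}

# plain restatement of the arbitration rules
oracle_select_best <- function(AS, XS) {
  ok <- which(!is.na(AS))
  if (!length(ok)) return(NULL)
  m <- max(AS[ok])
  top <- ok[AS[ok] == m]
  if (length(top) > 1L) return(NULL)
  others <- setdiff(ok, top)
  other_best <- if (length(others)) max(AS[others]) else NA_integer_
  own <- XS[top]
  xs <- if (!is.na(own) && (is.na(other_best) || own > other_best)) own
        else other_best
  list(strand = top, AS = AS[top], XS = as.integer(xs))
}

# brute-force in-silico digestion
oracle_rrbs <- function(contig, site = "CCGG", offset = 1L, min_frag, max_frag) {
  hits <- integer(0)
  for (i in seq_len(nchar(contig) - nchar(site) + 1L)) {
    if (substr(contig, i, i + nchar(site) - 1L) == site) hits <- c(hits, i)
  }
  cuts <- hits - 1L + offset
  out <- character(0)
  if (length(cuts) >= 2L) {
    for (j in seq_len(length(cuts) - 1L)) {
      len <- cuts[j + 1L] - cuts[j]
      if (len >= min_frag && len <= max_frag) {
        out <- c(out, substr(contig, cuts[j] + 1L, cuts[j + 1L]))
      }
    }
  }
  out
}

# exhaustive longest-run search over all (start, end) windows
oracle_longest_run <- function(pct, tol, m) {
  n <- length(pct)
  best <- c(NA, NA)
  best_len <- 0L
  for (s in 1:n) for (e in s:n) {
    if (all(abs(pct[s:e] - m) <= tol) && (e - s + 1L) > best_len) {
      best_len <- e - s + 1L
      best <- c(s, e)
    }
  }
  best
}

# count all methylation-call symbols in XM strings (extraction conservation)
oracle_xm_call_count <- function(xm) {
  sum(vapply(strsplit(xm, ""), function(ch) sum(ch != "."), integer(1)))
}
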