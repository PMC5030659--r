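# Coverage, per-base depth, normalized depth (ND) and depth ratio (DR).

#' Genome-wide coverage from read lengths
#'
#' Coverage is the mean raw read length (clipped bases included) times the
#' number of reads, divided by the total reference length.
#'
#' @param alignments Alignment table (the `seq` column supplies read lengths).
#' @param ref A [reference_genome()].
#' @return A single numeric coverage value.
#' @export
compute_coverage <- function(alignments, ref) {
  if (nrow(alignments) == 0L) stop("cannot compute coverage from zero reads")
  sum(nchar(alignments$seq)) / ref$total_length
}

# All aligned M intervals of an alignment table, as a data.frame
# (lg, start, end), 0-based half-open.
aligned_m_intervals <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0L) {
    return(data.frame(lg = character(), start = integer(), end = integer()))
  }
  # fast paths: a single M run, optionally soft-clipped on either side,
  # which covers every alignment the mapper emulation or a simple mapper emits
  pure <- grepl("^\\d+M$", alignments$cigar)
  simple <- !pure & grepl("^(\\d+S)?\\d+M(\\d+S)?$", alignments$cigar)
  lg <- character(0); start <- integer(0); end <- integer(0)
  if (any(pure)) {
    mlen <- as.integer(sub("M", "", alignments$cigar[pure], fixed = TRUE))
    lg <- alignments$lg[pure]
    start <- alignments$start[pure]
    end <- start + mlen
  }
  if (any(simple)) {
    m <- regmatches(
      alignments$cigar[simple],
      regexec("^(?:(\\d+)S)?(\\d+)M(?:(\\d+)S)?$", alignments$cigar[simple])
    )
    mlen <- as.integer(vapply(m, `[[`, "", 3L))
    s2 <- alignments$start[simple]
    lg <- c(lg, alignments$lg[simple])
    start <- c(start, s2)
    end <- c(end, s2 + mlen)
  }
  simple <- pure | simple
  for (i in which(!simple)) {
    ops <- parse_cigar(alignments$cigar[i])
    pos <- alignments$start[i]
    for (j in seq_len(nrow(ops))) {
      if (ops$op[j] == "M") {
        lg <- c(lg, alignments$lg[i])
        start <- c(start, pos)
        end <- c(end, pos + ops$len[j])
      }
      if (ops$op[j] %in% c("M", "D")) pos <- pos + ops$len[j]
    }
  }
  data.frame(lg = lg, start = start, end = end, stringsAsFactors = FALSE)
}

#' Per-base read depth
#'
#' Counts, for every base of the reference, the number of reads whose aligned
#' (M) span covers it. Soft-clipped bases contribute nothing; deletions (D)
#' in a read leave the spanned reference bases uncovered.
#'
#' @param alignments Alignment table.
#' @param ref A [reference_genome()].
#' @return An object of class `DepthTrack`: list with `depth` (named list of
#'   integer vectors, one per linkage group) and `coverage` (from
#'   [compute_coverage()], or `NA` for an empty alignment set).
#' @export
compute_depth <- function(alignments, ref) {
  iv <- aligned_m_intervals(alignments)
  depth <- lapply(names(ref$sequences), function(lg) {
    len <- genome_length(ref, lg)
    d <- integer(len + 1L)
    sel <- iv$lg == lg
    if (any(sel)) {
      s <- tabulate(iv$start[sel] + 1L, nbins = len + 1L)
      e <- tabulate(iv$end[sel] + 1L, nbins = len + 1L)
      d <- cumsum(s - e)
    }
    as.integer(d[seq_len(len)])
  })
  names(depth) <- names(ref$sequences)
  cov <- if (nrow(alignments) > 0L) compute_coverage(alignments, ref) else NA_real_
  structure(list(depth = depth, coverage = cov), class = "DepthTrack")
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat("DepthTrack: coverage", format(x$coverage, digits = 4), "\n")
  for (lg in names(x$depth)) {
    cat("  ", lg, ": mean depth ", format(mean(x$depth[[lg]]), digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Normalized depth over mapped regions
#'
#' Bases with depth strictly greater than `mapped_min` form the mapped-region
#' mask; there, the normalized depth (ND) is depth divided by genome-wide
#' coverage. Outside the mask ND is `NA`.
#'
#' @param depth A `DepthTrack` from [compute_depth()].
#' @param mapped_min Depth must exceed this value for a base to count as
#'   mapped (default 1, i.e. depth > 1).
#' @return List with `nd` (named list of numeric vectors with `NA` off-mask),
#'   `mask` (named list of logicals) and `coverage`.
#' @export
normalized_depth <- function(depth, mapped_min = 1L) {
  if (!inherits(depth, "DepthTrack")) stop("expected a DepthTrack")
  if (is.na(depth$coverage) || depth$coverage <= 0) {
    stop("normalized depth needs positive coverage")
  }
  nd <- lapply(depth$depth, function(d) {
    v <- d / depth$coverage
    v[d <= mapped_min] <- NA_real_
    v
  })
  mask <- lapply(depth$depth, function(d) d > mapped_min)
  list(nd = nd, mask = mask, coverage = depth$coverage)
}

#' Per-base depth ratio between case and control
#'
#' The depth ratio (DR) is the case ND divided by the control ND wherever
#' both samples are mapped; elsewhere it is `NA`. Low DR indicates loss of
#' copies in the case sample, DR near 2 a duplication.
#'
#' @param nd_case,nd_control Results of [normalized_depth()] on the case and
#'   control samples (same reference).
#' @return Named list of numeric per-base DR vectors (with `NA`).
#' @export
depth_ratio <- function(nd_case, nd_control) {
  if (!identical(names(nd_case$nd), names(nd_control$nd))) {
    stop("case and control depth tracks cover different linkage groups")
  }
  out <- lapply(names(nd_case$nd), function(lg) {
    a <- nd_case$nd[[lg]]; b <- nd_control$nd[[lg]]
    r <- a / b
    r[is.na(a) | is.na(b)] <- NA_real_
    r
  })
  names(out) <- names(nd_case$nd)
  out
}

# Mean DR over a candidate region [start, end) on lg; NA if no jointly
# mapped base.
region_depth_ratio <- function(dr, lg, start, end) {
  v <- dr[[lg]]
  if (is.null(v) || end <= start) return(NA_real_)
  idx <- seq.int(max(start, 0L) + 1L, min(end, length(v)))
  if (length(idx) == 0L) return(NA_real_)
  vals <- v[idx]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}
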