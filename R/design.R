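# CRISPR engineering-side computation: sgRNA site scanning, cleavage-site
# prediction, chimeric targeting-vector construction and expected-junction
# models.

#' Scan for G(N)19-25 NGG sgRNA sites
#'
#' Finds every protospacer of the form G followed by 19-25 arbitrary bases,
#' immediately followed by an NGG PAM, on both strands. Overlapping sites
#' and alternative spacer lengths at one PAM are all reported. Minus-strand
#' sites are reported in reference coordinates.
#'
#' @param ref A [reference_genome()].
#' @param lg Linkage group to scan.
#' @param interval Optional 0-based half-open interval `c(start, end)`
#'   restricting the scan (sites must lie inside it entirely, PAM included).
#' @return A data.frame with columns `lg`, `strand`, `start`, `end`
#'   (protospacer interval, 0-based half-open, reference coordinates),
#'   `protospacer` (spacer sequence, 5'->3' on the site's strand),
#'   `pam_start` (reference coordinate of the PAM's first base) and
#'   `cleavage` (from [predict_cleavage()]).
#' @export
scan_guides <- function(ref, lg, interval = NULL) {
  glen <- genome_length(ref, lg)
  if (is.null(interval)) interval <- c(0L, glen)
  stopifnot(interval[1L] >= 0L, interval[2L] <= glen,
            interval[1L] <= interval[2L])
  s <- genome_sub(ref, lg, interval[1L], interval[2L])
  scan_one <- function(seq) {
    # all GG dinucleotides are candidate PAM cores (PAM = N G G)
    gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1L]]
    if (gg[1L] == -1L) return(NULL)
    rows <- list()
    for (g in gg) {            # g = 1-based position of the first PAM G
      pam_start0 <- g - 2L     # 0-based position of the PAM's N
      if (pam_start0 < 0L) next
      for (spacer in 19:25) {
        ps_start0 <- pam_start0 - spacer - 1L
        if (ps_start0 < 0L) break
        if (substr(seq, ps_start0 + 1L, ps_start0 + 1L) != "G") next
        proto <- substr(seq, ps_start0 + 1L, pam_start0)
        if (grepl("N", proto, fixed = TRUE)) next
        rows[[length(rows) + 1L]] <- c(ps_start0, pam_start0)
      }
    }
    rows
  }
  out <- list()
  fwd <- scan_one(s)
  for (r in fwd) {
    start <- interval[1L] + r[1L]; pam <- interval[1L] + r[2L]
    out[[length(out) + 1L]] <- data.frame(
      lg = lg, strand = "+", start = start, end = pam,
      protospacer = genome_sub(ref, lg, start, pam),
      pam_start = pam, stringsAsFactors = FALSE
    )
  }
  rc <- revcomp(s)
  n <- nchar(s)
  for (r in scan_one(rc)) {
    # map rc coordinates [a, b) back to reference [n - b, n - a)
    ps_start_rc <- r[1L]; pam_rc <- r[2L]
    proto_len <- pam_rc - ps_start_rc
    start <- interval[1L] + (n - pam_rc)          # ref start of protospacer
    end <- interval[1L] + (n - ps_start_rc)
    pam <- start - 3L                             # PAM lies left of the site
    out[[length(out) + 1L]] <- data.frame(
      lg = lg, strand = "-", start = start, end = end,
      protospacer = revcomp(genome_sub(ref, lg, start, end)),
      pam_start = pam, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    res <- data.frame(lg = character(), strand = character(),
                      start = integer(), end = integer(),
                      protospacer = character(), pam_start = integer(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
  }
  res <- res[res$pam_start >= interval[1L] &
               pmax(res$end, res$pam_start + 3L) <= interval[2L] &
               res$start >= interval[1L], , drop = FALSE]
  res$cleavage <- vapply(seq_len(nrow(res)), function(i) {
    predict_cleavage(res[i, ])
  }, 1L)
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict the Cas9 cleavage coordinate of a guide site
#'
#' Uses the canonical SpCas9 blunt cut `offset` bases PAM-proximal of the
#' PAM (default 3, i.e. between protospacer positions -3 and -4 relative to
#' the PAM), expressed as a strand-independent inter-base reference
#' coordinate.
#'
#' @param site One row of [scan_guides()] output (or a list with `strand`
#'   and `pam_start`).
#' @param offset Distance of the blunt cut from the PAM (bases).
#' @return An integer inter-base reference coordinate.
#' @export
predict_cleavage <- function(site, offset = 3L) {
  if (site$strand == "+") {
    as.integer(site$pam_start - offset)
  } else {
    as.integer(site$pam_start + 3L + offset)
  }
}

#' Construct the targeting-vector pair for a planned inversion
#'
#' Each vector is a chimeric fusion of two homology arms of `arm` bases
#' around the two cleavage sites: the left vector joins the upstream
#' sequence of the first cut to the reverse-directed upstream sequence of
#' the second cut; the right vector joins the reverse-directed downstream
#' sequence of the first cut to the downstream sequence of the second cut.
#' Reading the planned inverted genome across each novel junction
#' reproduces the corresponding vector exactly.
#'
#' @param ref A [reference_genome()].
#' @param cut_a,cut_b Cleavage sites as `list(lg =, pos =)` with
#'   `cut_a$pos < cut_b$pos` on one linkage group.
#' @param arm Homology-arm length in bases (default 1000, i.e. 2 kb
#'   vectors).
#' @return A list of class `TargetingVectorPair`: `left_seq`, `right_seq`,
#'   `junction_at` (offset of the junction inside each vector), and an
#'   `arms` data.frame describing the four source arms.
#' @export
build_inversion_vectors <- function(ref, cut_a, cut_b, arm = 1000L) {
  stopifnot(cut_a$lg == cut_b$lg, cut_a$pos < cut_b$pos)
  lg <- cut_a$lg; a <- cut_a$pos; b <- cut_b$pos
  if (a - arm < 0L || b + arm > genome_length(ref, lg)) {
    stop("homology arms extend beyond ", lg)
  }
  left <- paste0(genome_sub(ref, lg, a - arm, a),
                 revcomp(genome_sub(ref, lg, b - arm, b)))
  right <- paste0(revcomp(genome_sub(ref, lg, a, a + arm)),
                  genome_sub(ref, lg, b, b + arm))
  arms <- data.frame(
    vector = c("left", "left", "right", "right"),
    arm = c(1L, 2L, 1L, 2L),
    lg = lg,
    start = c(a - arm, b - arm, a, b),
    end = c(a, b, a + arm, b + arm),
    orientation = c("+", "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  structure(list(left_seq = left, right_seq = right, junction_at = arm,
                 arms = arms, type = "inversion"),
            class = "TargetingVectorPair")
}

#' Construct the targeting-vector pair for a reciprocal translocation
#'
#' Models the two junctions of a reciprocal arm exchange between two
#' linkage groups: the left vector joins the upstream arm of the first cut
#' to the downstream arm of the second; the right vector joins the upstream
#' arm of the second cut to the downstream arm of the first.
#'
#' @param ref A [reference_genome()].
#' @param cut_a,cut_b Cleavage sites as `list(lg =, pos =)` on *different*
#'   linkage groups.
#' @param arm Homology-arm length (default 1000).
#' @return A `TargetingVectorPair` (see [build_inversion_vectors()]).
#' @export
build_translocation_vectors <- function(ref, cut_a, cut_b, arm = 1000L) {
  if (cut_a$lg == cut_b$lg) {
    stop("a reciprocal translocation needs two different linkage groups")
  }
  A <- cut_a$lg; a <- cut_a$pos; B <- cut_b$lg; b <- cut_b$pos
  if (a - arm < 0L || a + arm > genome_length(ref, A) ||
      b - arm < 0L || b + arm > genome_length(ref, B)) {
    stop("homology arms out of bounds")
  }
  left <- paste0(genome_sub(ref, A, a - arm, a),
                 genome_sub(ref, B, b, b + arm))
  right <- paste0(genome_sub(ref, B, b - arm, b),
                  genome_sub(ref, A, a, a + arm))
  arms <- data.frame(
    vector = c("left", "left", "right", "right"),
    arm = c(1L, 2L, 1L, 2L),
    lg = c(A, B, B, A),
    start = c(a - arm, b, b - arm, a),
    end = c(a, b + arm, b, a + arm),
    orientation = "+",
    stringsAsFactors = FALSE
  )
  structure(list(left_seq = left, right_seq = right, junction_at = arm,
                 arms = arms, type = "translocation"),
            class = "TargetingVectorPair")
}

#' @export
print.TargetingVectorPair <- function(x, ...) {
  cat("TargetingVectorPair (", x$type, "): vectors of ",
      nchar(x$left_seq), " and ", nchar(x$right_seq),
      " bp, junction at offset ", x$junction_at, "\n", sep = "")
  invisible(x)
}

#' Expected homologous-recombination junction sequences of a plan
#'
#' For every truth breakpoint of an applied plan, extracts the derived-
#' genome sequence `window` bases either side of the junction (the sequence
#' a perfect HR repair produces), plus primer-check windows placed strictly
#' outside the homology arms so screening primers do not anneal to the
#' targeting vectors themselves.
#'
#' @param truth A `TruthSet` from [apply_rearrangements()].
#' @param window Half-width of the junction sequence (bases).
#' @param arm Homology-arm length the primer windows must clear.
#' @param primer_window Width of each primer-check window.
#' @return A data.frame with one row per junction: `junction_id`,
#'   `der_lg`, `der_pos`, `seq`, `primer_left`, `primer_right` (NA when the
#'   derived group ends before the window clears the arm).
#' @export
expected_junctions <- function(truth, window = 100L, arm = 1000L,
                               primer_window = 100L) {
  bp <- truth$breakpoints
  g <- truth$genome
  n <- nrow(bp)
  out <- data.frame(
    junction_id = seq_len(n), der_lg = bp$der_lg, der_pos = bp$der_pos,
    seq = character(n), primer_left = rep(NA_character_, n),
    primer_right = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    len <- genome_length(g, bp$der_lg[i])
    lo <- max(0L, bp$der_pos[i] - window)
    hi <- min(len, bp$der_pos[i] + window)
    out$seq[i] <- genome_sub(g, bp$der_lg[i], lo, hi)
    pl <- bp$der_pos[i] - arm - primer_window
    if (pl >= 0L) {
      out$primer_left[i] <- genome_sub(g, bp$der_lg[i], pl, pl + primer_window)
    }
    pr <- bp$der_pos[i] + arm
    if (pr + primer_window <= len) {
      out$primer_right[i] <- genome_sub(g, bp$der_lg[i], pr, pr + primer_window)
    }
  }
  out
}

#' Write guide sites as BED
#'
#' Six-column BED (0-based half-open protospacer intervals, score =
#' spacer length, strand).
#'
#' @param sites [scan_guides()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_guides_bed <- function(sites, path) {
  lines <- paste(sites$lg, sites$start, sites$end,
                 paste0("guide_", seq_len(nrow(sites))),
                 sites$end - sites$start, sites$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
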