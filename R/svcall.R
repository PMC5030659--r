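# Split-read classification, control subtraction, candidate calling and
# depth-based filtering.

SV_CLASSES <- c("deletion", "insertion", "inversion", "translocation",
                "translocational_inversion")

COMPLEX_KINDS <- c("insertion", "local_inversion_or_inverted_insertion",
                   "translocated_insertion", "inverted_translocational_insertion")

# Reverse-complement view of a split read: swap the two placements and flip
# both strands. A split read and its flip describe the same junction.
flip_split_read <- function(sr) {
  out <- sr
  out$seg5_lg <- sr$seg3_lg; out$seg5_start <- sr$seg3_start
  out$seg5_end <- sr$seg3_end
  out$seg5_strand <- ifelse(sr$seg3_strand == "+", "-", "+")
  out$seg3_lg <- sr$seg5_lg; out$seg3_start <- sr$seg5_start
  out$seg3_end <- sr$seg5_end
  out$seg3_strand <- ifelse(sr$seg5_strand == "+", "-", "+")
  out
}

#' Classify a split read into one of five categories
#'
#' Placements on different linkage groups make a translocation-type split
#' read, or a translocational-inversion type when the two placements also
#' disagree in strand sense. On one linkage group, opposite sense means an
#' inversion-type split read; with equal sense, a 3' region placed
#' downstream of the 5' region means a deletion type and upstream an
#' insertion type. The classification is invariant under reverse
#' complementation of the read.
#'
#' @param sr One split read (a one-row data.frame or list with the
#'   `seg5_*`/`seg3_*` fields of [build_split_reads()]).
#' @return One of `"deletion"`, `"insertion"`, `"inversion"`,
#'   `"translocation"`, `"translocational_inversion"`.
#' @export
classify_split_read <- function(sr) {
  if (sr$seg5_lg == sr$seg3_lg && sr$seg5_start == sr$seg3_start &&
      sr$seg5_end == sr$seg3_end && sr$seg5_strand == sr$seg3_strand) {
    stop("identical placements do not form a split read")
  }
  if (sr$seg5_strand == "-" && sr$seg3_strand == "-") sr <- flip_split_read(sr)
  if (sr$seg5_lg != sr$seg3_lg) {
    if (sr$seg5_strand != sr$seg3_strand) return("translocational_inversion")
    return("translocation")
  }
  if (sr$seg5_strand != sr$seg3_strand) return("inversion")
  j5 <- if (sr$seg5_strand == "+") sr$seg5_end else sr$seg5_start
  j3 <- if (sr$seg3_strand == "+") sr$seg3_start else sr$seg3_end
  if (j3 == j5) stop("colinear placements do not form a split read")
  if (sr$seg5_strand == "+") {
    if (j3 > j5) "deletion" else "insertion"
  } else {
    # both segments on the reverse strand of the stored frame cannot occur
    # after flipping; kept for completeness
    if (j3 < j5) "deletion" else "insertion"
  }
}

# Vectorized classification; adds a `category` column.
classify_split_reads <- function(srs) {
  if (nrow(srs) == 0L) { srs$category <- character(0); return(srs) }
  srs$category <- vapply(seq_len(nrow(srs)), function(i) {
    classify_split_read(srs[i, ])
  }, "")
  srs
}

# The two breakpoint ends of a split read, as (lg, pos, side): `side` says
# which flank of `pos` the read covers at that end ("left" = the read runs
# into the junction from lower coordinates). Invariant under flipping.
sr_breakpoint_ends <- function(sr) {
  e5 <- if (sr$seg5_strand == "+") {
    list(lg = sr$seg5_lg, pos = sr$seg5_end, side = "left")
  } else {
    list(lg = sr$seg5_lg, pos = sr$seg5_start, side = "right")
  }
  e3 <- if (sr$seg3_strand == "+") {
    list(lg = sr$seg3_lg, pos = sr$seg3_start, side = "right")
  } else {
    list(lg = sr$seg3_lg, pos = sr$seg3_end, side = "left")
  }
  list(e5, e3)
}

# Annotate split reads with ordered breakpoint-end columns; the two ends are
# sorted by (lg, side, pos) so reads from both sequencing directions of one
# junction share a key.
annotate_sr_ends <- function(srs) {
  n <- nrow(srs)
  lg1 <- character(n); pos1 <- integer(n); side1 <- character(n)
  lg2 <- character(n); pos2 <- integer(n); side2 <- character(n)
  for (i in seq_len(n)) {
    ends <- sr_breakpoint_ends(srs[i, ])
    o <- order(vapply(ends, `[[`, "", "lg"),
               vapply(ends, `[[`, "", "side"),
               vapply(ends, function(e) e$pos, 1L))
    a <- ends[[o[1L]]]; b <- ends[[o[2L]]]
    lg1[i] <- a$lg; pos1[i] <- a$pos; side1[i] <- a$side
    lg2[i] <- b$lg; pos2[i] <- b$pos; side2[i] <- b$side
  }
  srs$lg1 <- lg1; srs$pos1 <- pos1; srs$side1 <- side1
  srs$lg2 <- lg2; srs$pos2 <- pos2; srs$side2 <- side2
  srs
}

#' Remove split reads that also occur in the control sample
#'
#' A case split read is eliminated when some control split read has the same
#' category and both breakpoint ends within `tol` bases of it.
#'
#' @param case_srs,control_srs Split-read tables from [build_split_reads()].
#' @param tol Matching tolerance in bases (default 10).
#' @return The filtered case table.
#' @export
subtract_control <- function(case_srs, control_srs, tol = 10L) {
  if (nrow(case_srs) == 0L || nrow(control_srs) == 0L) return(case_srs)
  ca <- annotate_sr_ends(classify_split_reads(case_srs))
  co <- annotate_sr_ends(classify_split_reads(control_srs))
  keep <- vapply(seq_len(nrow(ca)), function(i) {
    m <- co$category == ca$category[i] &
      co$lg1 == ca$lg1[i] & co$side1 == ca$side1[i] &
      co$lg2 == ca$lg2[i] & co$side2 == ca$side2[i] &
      abs(co$pos1 - ca$pos1[i]) <= tol & abs(co$pos2 - ca$pos2[i]) <= tol
    !any(m)
  }, TRUE)
  case_srs[keep, , drop = FALSE]
}

#' Cluster split reads by junction
#'
#' Groups classified split reads sharing a category, linkage-group pair and
#' breakpoint-end geometry, chaining reads whose two junction coordinates
#' both lie within `tol` of the cluster.
#'
#' @param srs Split-read table.
#' @param tol Clustering tolerance in bases.
#' @return A data.frame with one row per cluster: `category`,
#'   `lg1`/`pos1`/`side1`, `lg2`/`pos2`/`side2` (median junction
#'   coordinates), `n_reads` (distinct supporting reads) and the list
#'   column `read_ids`.
#' @export
cluster_split_reads <- function(srs, tol = 10L) {
  empty <- data.frame(category = character(), lg1 = character(),
                      pos1 = integer(), side1 = character(),
                      lg2 = character(), pos2 = integer(), side2 = character(),
                      n_reads = integer(), stringsAsFactors = FALSE)
  empty$read_ids <- list()
  if (nrow(srs) == 0L) return(empty)
  if (is.null(srs$category)) srs <- classify_split_reads(srs)
  srs <- annotate_sr_ends(srs)
  key <- paste(srs$category, srs$lg1, srs$side1, srs$lg2, srs$side2, sep = "\r")
  out <- list()
  for (kk in unique(key)) {
    sub <- srs[key == kk, , drop = FALSE]
    sub <- sub[order(sub$pos1, sub$pos2), , drop = FALSE]
    cl_id <- integer(nrow(sub))
    cid <- 0L
    ref1 <- ref2 <- NA_integer_
    for (i in seq_len(nrow(sub))) {
      if (cid == 0L || abs(sub$pos1[i] - ref1) > tol ||
          abs(sub$pos2[i] - ref2) > tol) {
        cid <- cid + 1L
        ref1 <- sub$pos1[i]; ref2 <- sub$pos2[i]
      }
      cl_id[i] <- cid
    }
    for (cc in unique(cl_id)) {
      s <- sub[cl_id == cc, , drop = FALSE]
      row <- data.frame(
        category = s$category[1L], lg1 = s$lg1[1L],
        pos1 = as.integer(round(median(s$pos1))), side1 = s$side1[1L],
        lg2 = s$lg2[1L], pos2 = as.integer(round(median(s$pos2))),
        side2 = s$side2[1L], n_reads = length(unique(s$read_id)),
        stringsAsFactors = FALSE
      )
      row$read_ids <- list(unique(s$read_id))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  df <- data.frame(kind = character(), lg = character(), start = integer(),
                   end = integer(), partner_lg = character(),
                   partner_pos = integer(), support = integer(),
                   dr = numeric(), status = character(), note = character(),
                   stringsAsFactors = FALSE)
  df$read_ids <- list()
  df
}

candidate_row <- function(kind, lg, start, end, support, read_ids,
                          partner_lg = NA_character_,
                          partner_pos = NA_integer_,
                          status = "kept", note = "") {
  df <- data.frame(kind = kind, lg = lg, start = as.integer(start),
                   end = as.integer(end), partner_lg = partner_lg,
                   partner_pos = as.integer(partner_pos),
                   support = as.integer(support), dr = NA_real_,
                   status = status, note = note, stringsAsFactors = FALSE)
  df$read_ids <- list(read_ids)
  df
}

rbind_candidates <- function(rows) {
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call deletion candidates from single split-read clusters
#'
#' Deletion-type split reads sharing a common gap (both junction
#' coordinates within `tol`) are clustered; clusters supported by more than
#' `min_support - 1` distinct reads (default: more than 2) become deletion
#' candidates spanning the common gap.
#'
#' @param srs Split-read table (classified or not).
#' @param tol Clustering tolerance.
#' @param min_support Minimum cluster size to call (default 3, i.e. strictly
#'   more than 2 supporting reads).
#' @return A candidate table.
#' @export
call_deletions <- function(srs, tol = 10L, min_support = 3L) {
  cl <- cluster_split_reads(srs, tol)
  cl <- cl[cl$category == "deletion" & cl$n_reads >= min_support, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    candidate_row("deletion", cl$lg1[i], cl$pos1[i], cl$pos2[i],
                  cl$n_reads[i], cl$read_ids[[i]])
  })
  rbind_candidates(rows)
}

# Does cluster `a`'s end `ia` coincide with cluster `b`'s end `ib` (same lg,
# opposite sides, coordinates within tol)?
ends_shared <- function(a, ia, b, ib, tol) {
  lg_a <- a[[paste0("lg", ia)]]; lg_b <- b[[paste0("lg", ib)]]
  s_a <- a[[paste0("side", ia)]]; s_b <- b[[paste0("side", ib)]]
  p_a <- a[[paste0("pos", ia)]]; p_b <- b[[paste0("pos", ib)]]
  lg_a == lg_b && s_a != s_b && abs(p_a - p_b) <= tol
}

cluster_end <- function(cl, i) {
  list(lg = cl[[paste0("lg", i)]], pos = cl[[paste0("pos", i)]],
       side = cl[[paste0("side", i)]])
}

# Pair two clusters that share one junction end; the two remaining ends, on
# a common linkage group with one "right" (region start) and one "left"
# (region end), bracket the candidate region.
paired_region <- function(c1, c2, tol) {
  for (i in 1:2) for (j in 1:2) {
    if (!ends_shared(c1, i, c2, j, tol)) next
    o1 <- cluster_end(c1, 3L - i); o2 <- cluster_end(c2, 3L - j)
    if (o1$lg != o2$lg || o1$side == o2$side) next
    start_end <- if (o1$side == "right") c(o1$pos, o2$pos) else c(o2$pos, o1$pos)
    if (start_end[2L] - start_end[1L] <= tol) next
    shared <- cluster_end(c1, i)
    return(list(lg = o1$lg, start = start_end[1L], end = start_end[2L],
                target_lg = shared$lg,
                target = as.integer(round(mean(c(shared$pos,
                                                 cluster_end(c2, j)$pos)))),
                border_gap = abs(shared$pos - cluster_end(c2, j)$pos),
                border_at = sort(c(shared$pos, cluster_end(c2, j)$pos))))
  }
  NULL
}

#' Call paired-cluster (complex) variant candidates
#'
#' Detects regions bracketed by two split-read clusters: a combined
#' deletion- plus insertion-type pair marks an insertion candidate (a
#' copied sequence inserted elsewhere), two inversion-type clusters mark a
#' local inversion or inverted insertion, and two translocation- or
#' translocational-inversion-type clusters mark a translocated insertion or
#' inverted translocational insertion. When the bracketing junctions leave
#' an uncovered gap near a border, that gap is additionally emitted as a
#' deletion candidate.
#'
#' @param srs Split-read table (after control subtraction).
#' @param tol Bracketing tolerance in bases.
#' @param max_span Only inversion cluster pairs spanning at most this many
#'   bases are reported here (larger ones are chromosome-scale breakpoint
#'   pairs; see [call_large_breakpoint_pairs()]).
#' @return A candidate table.
#' @export
call_paired_variants <- function(srs, tol = 10L, max_span = Inf) {
  cl <- cluster_split_reads(srs, tol)
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  emit_shared_pair <- function(kind, cats) {
    c1s <- which(cl$category == cats[1L])
    c2s <- which(cl$category == cats[2L])
    for (i in c1s) for (j in c2s) {
      if (cats[1L] == cats[2L] && j <= i) next
      pr <- paired_region(cl[i, ], cl[j, ], tol)
      if (is.null(pr)) next
      ids <- unique(c(cl$read_ids[[i]], cl$read_ids[[j]]))
      add(candidate_row(kind, pr$lg, pr$start, pr$end, length(ids), ids,
                        partner_lg = pr$target_lg, partner_pos = pr$target))
      if (pr$border_gap > 0L && pr$border_gap <= tol) {
        add(candidate_row("deletion", pr$target_lg, pr$border_at[1L],
                          pr$border_at[2L], length(ids), ids,
                          note = "border gap of paired variant"))
      }
    }
  }

  emit_shared_pair("insertion", c("deletion", "insertion"))
  emit_shared_pair("translocated_insertion",
                   c("translocation", "translocation"))
  emit_shared_pair("inverted_translocational_insertion",
                   c("translocational_inversion", "translocational_inversion"))

  # two inversion-type clusters flanking one region: a left-left cluster and
  # a right-right cluster with both coordinates matching
  inv <- cl[cl$category == "inversion", , drop = FALSE]
  ll <- inv[inv$side1 == "left" & inv$side2 == "left", , drop = FALSE]
  rr <- inv[inv$side1 == "right" & inv$side2 == "right", , drop = FALSE]
  for (i in seq_len(nrow(ll))) for (j in seq_len(nrow(rr))) {
    if (ll$lg1[i] != rr$lg1[j] || ll$lg2[i] != rr$lg2[j]) next
    if (abs(ll$pos1[i] - rr$pos1[j]) > tol ||
        abs(ll$pos2[i] - rr$pos2[j]) > tol) next
    l <- as.integer(round(mean(c(ll$pos1[i], rr$pos1[j]))))
    r <- as.integer(round(mean(c(ll$pos2[i], rr$pos2[j]))))
    if (r - l > max_span) next
    ids <- unique(c(ll$read_ids[[i]], rr$read_ids[[j]]))
    add(candidate_row("local_inversion_or_inverted_insertion",
                      ll$lg1[i], l, r, length(ids), ids))
    for (gp in list(c(ll$pos1[i], rr$pos1[j]), c(ll$pos2[i], rr$pos2[j]))) {
      g <- abs(gp[1L] - gp[2L])
      if (g > 0L && g <= tol) {
        add(candidate_row("deletion", ll$lg1[i], min(gp), max(gp),
                          length(ids), ids,
                          note = "border gap of paired variant"))
      }
    }
  }
  rbind_candidates(rows)
}

#' Pair reciprocal clusters into chromosome-scale breakpoint-pair calls
#'
#' A chromosome-scale inversion appears as two reciprocal inversion-type
#' split-read clusters at the same pair of coordinates (one joining the two
#' left flanks, one the two right flanks); a reciprocal translocation as
#' two translocation-type clusters exchanging arms. Matched pairs become
#' `inversion_breakpoint_pair` / `translocation_breakpoint_pair`
#' candidates; unmatched clusters are reported flagged.
#'
#' @param srs Split-read table (after control subtraction).
#' @param tol Junction matching tolerance.
#' @param min_span Minimum separation (bases) between the two junctions of
#'   an inversion pair to be reported here rather than as a local variant.
#' @return A candidate table; `lg`/`start`/`end` hold the two junctions of
#'   an inversion, `lg`/`start` plus `partner_lg`/`partner_pos` the two
#'   breakpoints of a translocation.
#' @export
call_large_breakpoint_pairs <- function(srs, tol = 10L, min_span = 0L) {
  cl <- cluster_split_reads(srs, tol)
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  inv <- cl[cl$category == "inversion", , drop = FALSE]
  ll <- inv[inv$side1 == "left" & inv$side2 == "left", , drop = FALSE]
  rr <- inv[inv$side1 == "right" & inv$side2 == "right", , drop = FALSE]
  used_ll <- logical(nrow(ll)); used_rr <- logical(nrow(rr))
  for (i in seq_len(nrow(ll))) for (j in seq_len(nrow(rr))) {
    if (used_rr[j]) next
    if (ll$lg1[i] != rr$lg1[j] || ll$lg2[i] != rr$lg2[j]) next
    if (abs(ll$pos1[i] - rr$pos1[j]) > tol ||
        abs(ll$pos2[i] - rr$pos2[j]) > tol) next
    l <- as.integer(round(mean(c(ll$pos1[i], rr$pos1[j]))))
    r <- as.integer(round(mean(c(ll$pos2[i], rr$pos2[j]))))
    if (r - l < min_span) next
    ids <- unique(c(ll$read_ids[[i]], rr$read_ids[[j]]))
    add(candidate_row("inversion_breakpoint_pair", ll$lg1[i], l, r,
                      length(ids), ids))
    used_ll[i] <- TRUE; used_rr[j] <- TRUE
  }
  for (i in which(!used_ll)) {
    add(candidate_row("inversion_junction", ll$lg1[i], ll$pos1[i],
                      ll$pos2[i], ll$n_reads[i], ll$read_ids[[i]],
                      status = "flagged_unpaired"))
  }
  for (j in which(!used_rr)) {
    add(candidate_row("inversion_junction", rr$lg1[j], rr$pos1[j],
                      rr$pos2[j], rr$n_reads[j], rr$read_ids[[j]],
                      status = "flagged_unpaired"))
  }

  tr <- cl[cl$category == "translocation", , drop = FALSE]
  used <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (used[i]) next
    for (j in seq_len(nrow(tr))) {
      if (j == i || used[j]) next
      # reciprocal: same lg pair, same coordinates, swapped sides
      if (tr$lg1[i] != tr$lg1[j] || tr$lg2[i] != tr$lg2[j]) next
      if (tr$side1[i] == tr$side1[j] || tr$side2[i] == tr$side2[j]) next
      if (abs(tr$pos1[i] - tr$pos1[j]) > tol ||
          abs(tr$pos2[i] - tr$pos2[j]) > tol) next
      a <- as.integer(round(mean(c(tr$pos1[i], tr$pos1[j]))))
      b <- as.integer(round(mean(c(tr$pos2[i], tr$pos2[j]))))
      ids <- unique(c(tr$read_ids[[i]], tr$read_ids[[j]]))
      add(candidate_row("translocation_breakpoint_pair", tr$lg1[i], a, a,
                        length(ids), ids, partner_lg = tr$lg2[i],
                        partner_pos = b))
      used[i] <- TRUE; used[j] <- TRUE
      break
    }
  }
  for (i in which(!used)) {
    add(candidate_row("translocation_junction", tr$lg1[i], tr$pos1[i],
                      tr$pos1[i], tr$n_reads[i], tr$read_ids[[i]],
                      partner_lg = tr$lg2[i], partner_pos = tr$pos2[i],
                      status = "flagged_unpaired"))
  }
  rbind_candidates(rows)
}

#' Remove weakly supported complex candidates
#'
#' Complex (paired-cluster) candidates supported by fewer than `min_reads`
#' distinct reads are marked `removed_support`. Single-cluster calls and
#' breakpoint pairs are untouched.
#'
#' @param candidates Candidate table.
#' @param min_reads Support threshold (default 10; "fewer than ten" is
#'   removed).
#' @return The candidate table with statuses updated.
#' @export
filter_complicated <- function(candidates, min_reads = 10L) {
  if (nrow(candidates) == 0L) return(candidates)
  hit <- candidates$kind %in% COMPLEX_KINDS &
    candidates$status == "kept" & candidates$support < min_reads
  candidates$status[hit] <- "removed_support"
  candidates
}

#' Apply depth-ratio filters to candidates
#'
#' A deletion candidate whose region depth ratio exceeds `dr_del` is not
#' copy-lost and is removed. Insertion-class candidates are relabelled
#' `multiplication` when the source-region depth ratio exceeds `dr_mult`,
#' or `duplication` when it exceeds `dr_dup`. Copy-neutral breakpoint
#' pairs (chromosome-scale inversions/translocations) are not subject to
#' depth filtering. Candidates whose region has no jointly mapped base are
#' kept and flagged.
#'
#' @param candidates Candidate table.
#' @param dr Per-base depth-ratio track from [depth_ratio()].
#' @param dr_del Deletion removal threshold (default 0.75).
#' @param dr_dup Duplication threshold (default 1.75).
#' @param dr_mult Multiplication threshold (default 2.5).
#' @return The candidate table with `dr`, `kind` and `status` updated.
#' @export
apply_depth_filters <- function(candidates, dr, dr_del = 0.75,
                                dr_dup = 1.75, dr_mult = 2.5) {
  for (i in seq_len(nrow(candidates))) {
    if (candidates$status[i] != "kept") next
    kind <- candidates$kind[i]
    if (kind == "deletion") {
      v <- region_depth_ratio(dr, candidates$lg[i], candidates$start[i],
                              candidates$end[i])
      candidates$dr[i] <- v
      if (is.na(v)) { candidates$note[i] <- "DR unavailable"; next }
      if (v > dr_del) candidates$status[i] <- "removed_depth"
    } else if (kind %in% c("insertion", "translocated_insertion",
                           "inverted_translocational_insertion")) {
      v <- region_depth_ratio(dr, candidates$lg[i], candidates$start[i],
                              candidates$end[i])
      candidates$dr[i] <- v
      if (is.na(v)) { candidates$note[i] <- "DR unavailable"; next }
      if (v > dr_mult) candidates$kind[i] <- "multiplication"
      else if (v > dr_dup) candidates$kind[i] <- "duplication"
    }
  }
  candidates
}

#' Write the variant report
#'
#' `"tsv"` writes every candidate (including removed ones, with status);
#' `"vcf"` writes kept candidates as VCF 4.2: deletions/insertions/
#' duplications/inversions as symbolic SVTYPE records with `END`,
#' translocation junctions as mated pairs of BND records.
#'
#' @param candidates Candidate table.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param ref Optional [reference_genome()] for REF bases and contig header
#'   lines (`N` placeholders without it).
#' @param sample Sample name recorded in the VCF header.
#' @return Invisibly, `path`.
#' @export
write_variant_report <- function(candidates, path, format = c("tsv", "vcf"),
                                 ref = NULL, sample = "case") {
  format <- match.arg(format)
  if (format == "tsv") {
    flat <- candidates
    flat$read_ids <- vapply(candidates$read_ids, paste, "", collapse = ",")
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ref_base <- function(lg, pos) {
    if (is.null(ref)) return("N")
    p <- max(0L, min(pos, genome_length(ref, lg) - 1L))
    genome_sub(ref, lg, p, p + 1L)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=balancerSV",
    if (!is.null(ref)) {
      paste0("##contig=<ID=", names(ref$sequences), ",length=",
             nchar(ref$sequences), ">")
    },
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##INFO=<ID=DR,Number=1,Type=Float,Description=\"Region depth ratio\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- character()
  kept <- candidates[candidates$status == "kept", , drop = FALSE]
  vid <- 0L
  for (i in seq_len(nrow(kept))) {
    vid <- vid + 1L
    kind <- kept$kind[i]
    info_tail <- paste0(";SUPPORT=", kept$support[i],
                        if (!is.na(kept$dr[i])) {
                          paste0(";DR=", format(kept$dr[i], digits = 4))
                        })
    if (kind == "translocation_breakpoint_pair" ||
        kind == "translocation_junction") {
      id1 <- sprintf("bnd_%d_1", vid); id2 <- sprintf("bnd_%d_2", vid)
      lg1 <- kept$lg[i]; p1 <- kept$start[i]
      lg2 <- kept$partner_lg[i]; p2 <- kept$partner_pos[i]
      b1 <- ref_base(lg1, p1); b2 <- ref_base(lg2, p2)
      body <- c(body,
        paste(lg1, p1 + 1L, id1, b1,
              paste0(b1, "[", lg2, ":", p2 + 1L, "["), ".", "PASS",
              paste0("SVTYPE=BND;MATEID=", id2, info_tail), sep = "\t"),
        paste(lg2, p2 + 1L, id2, b2,
              paste0("]", lg1, ":", p1 + 1L, "]", b2), ".", "PASS",
              paste0("SVTYPE=BND;MATEID=", id1, info_tail), sep = "\t"))
    } else {
      svtype <- switch(kind,
        deletion = "DEL", insertion = "INS",
        translocated_insertion = "INS",
        inverted_translocational_insertion = "INS",
        duplication = "DUP", multiplication = "DUP",
        local_inversion_or_inverted_insertion = "INV",
        inversion_breakpoint_pair = "INV",
        inversion_junction = "INV", "INS")
      body <- c(body,
        paste(kept$lg[i], kept$start[i] + 1L, sprintf("sv_%d", vid),
              ref_base(kept$lg[i], kept$start[i]), paste0("<", svtype, ">"),
              ".", "PASS",
              paste0("SVTYPE=", svtype, ";END=", kept$end[i], info_tail),
              sep = "\t"))
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a TSV variant report
#'
#' @param path Path written by [write_variant_report()] with
#'   `format = "tsv"`.
#' @return A candidate table (read ids split back into a list column).
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_candidates())
  ids <- strsplit(as.character(df$read_ids), ",", fixed = TRUE)
  df$read_ids <- NULL
  df$partner_lg <- as.character(df$partner_lg)
  df$note[is.na(df$note)] <- ""
  df$read_ids <- ids
  df[, names(empty_candidates())]
}
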