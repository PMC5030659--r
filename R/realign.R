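# Breakpoint discovery from soft-clipped read tails: harvest clips, seed them
# genome-wide with exact 16-mers (Aho-Corasick), extend with Smith-Waterman,
# resolve ties by proximity to the anchor, and emit split reads.

#' Extract soft-clipped segments from alignments
#'
#' One segment is emitted per soft clip *strictly longer* than `min_clip`.
#' The clip sequence is taken in the stored (reference-forward) orientation;
#' the anchor records the mapped span of the read on the reference. A read
#' clipped on both sides can yield two segments.
#'
#' @param alignments Alignment table ([read_sam()] / [emulate_mapping()]).
#' @param min_clip Clips must exceed this length (default 20).
#' @return A data.frame with columns `clip_id`, `read_id`, `side` (`"left"`
#'   or `"right"` of the stored read), `clip_seq`, `anchor_lg`,
#'   `anchor_start`, `anchor_end` (M-span, 0-based half-open),
#'   `anchor_strand`.
#' @export
extract_clipped <- function(alignments, min_clip = 20L) {
  rows <- list()
  # vectorized pre-filter: only records with a terminal soft clip longer
  # than min_clip need full CIGAR parsing
  lead_s <- rep(0L, nrow(alignments))
  has_lead <- grepl("^\\d+S", alignments$cigar)
  lead_s[has_lead] <- as.integer(sub("^(\\d+)S.*$", "\\1",
                                     alignments$cigar[has_lead]))
  trail_s <- rep(0L, nrow(alignments))
  has_trail <- grepl("\\d+S$", alignments$cigar) & !grepl("^\\d+S$", alignments$cigar)
  trail_s[has_trail] <- as.integer(sub("^.*?(\\d+)S$", "\\1",
                                       alignments$cigar[has_trail]))
  for (i in which(lead_s > min_clip | trail_s > min_clip)) {
    ops <- parse_cigar(alignments$cigar[i])
    lead <- if (ops$op[1L] == "S") ops$len[1L] else 0L
    trail <- if (nrow(ops) > 1L && ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
    if (lead <= min_clip && trail <= min_clip) next
    span <- cigar_ref_span(ops)
    seqlen <- nchar(alignments$seq[i])
    anchor <- list(lg = alignments$lg[i],
                   start = alignments$start[i],
                   end = alignments$start[i] + span,
                   strand = alignments$strand[i])
    if (lead > min_clip) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = alignments$read_id[i], side = "left",
        clip_seq = substr(alignments$seq[i], 1L, lead),
        anchor_lg = anchor$lg, anchor_start = anchor$start,
        anchor_end = anchor$end, anchor_strand = anchor$strand,
        stringsAsFactors = FALSE
      )
    }
    if (trail > min_clip) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = alignments$read_id[i], side = "right",
        clip_seq = substr(alignments$seq[i], seqlen - trail + 1L, seqlen),
        anchor_lg = anchor$lg, anchor_start = anchor$start,
        anchor_end = anchor$end, anchor_strand = anchor$strand,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(clip_id = integer(), read_id = character(),
                      side = character(), clip_seq = character(),
                      anchor_lg = character(), anchor_start = integer(),
                      anchor_end = integer(), anchor_strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- cbind(clip_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Build the 16-mer query set of a clipped segment
#'
#' All contiguous k-mers of the clip plus the reverse complement of each;
#' queries containing N are excluded.
#'
#' @param clip_seq Clipped sequence (length >= k).
#' @param k Query length (default 16).
#' @return A data.frame with columns `query` and `strand` (`"+"` for a
#'   forward k-mer, `"-"` for a reverse complement), deduplicated.
#' @export
build_query_set <- function(clip_seq, k = 16L) {
  L <- nchar(clip_seq)
  if (L < k) {
    return(data.frame(query = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fwd <- substring(clip_seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  fwd <- unique(fwd[!grepl("N", fwd, fixed = TRUE)])
  if (length(fwd) == 0L) {
    return(data.frame(query = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- rbind(
    data.frame(query = fwd, strand = "+", stringsAsFactors = FALSE),
    data.frame(query = revcomp(fwd), strand = "-", stringsAsFactors = FALSE)
  )
  out[!duplicated(out), , drop = FALSE]
}

#' Find all exact occurrences of queries in a genome
#'
#' A single linear Aho-Corasick scan over every linkage group reports every
#' exact occurrence of every query. N in the genome matches nothing.
#'
#' @param ref A [reference_genome()].
#' @param queries Either a character vector of queries (all reported with
#'   strand `"+"`) or a data.frame from [build_query_set()].
#' @return A data.frame with columns `query`, `lg`, `pos` (0-based start)
#'   and `strand` (the strand label of the matching query).
#' @export
find_perfect_matches <- function(ref, queries) {
  if (is.character(queries)) {
    queries <- data.frame(query = queries, strand = "+",
                          stringsAsFactors = FALSE)
  }
  queries <- queries[!grepl("N", queries$query, fixed = TRUE), , drop = FALSE]
  if (nrow(queries) == 0L) {
    return(data.frame(query = character(), lg = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  pats <- unique(queries$query)
  hits <- .ac_search_cpp(pats, ref$sequences)
  if (nrow(hits) == 0L) {
    return(data.frame(query = character(), lg = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  hit_df <- data.frame(query = pats[hits$pattern],
                       lg = names(ref$sequences)[hits$text],
                       pos = hits$pos, stringsAsFactors = FALSE)
  # expand to one row per (query row, hit): a query string carries the strand
  # label of the query that produced it
  merged <- merge(queries, hit_df, by = "query")
  merged[order(merged$lg, merged$pos, merged$query, merged$strand),
         c("query", "lg", "pos", "strand")]
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under unit-base scoring (+2 match, -1 mismatch,
#' -2 per gapped position by default; linear gap penalty). N matches
#' nothing. An empty alignment scores 0.
#'
#' @param a,b Sequences to align.
#' @param match,mismatch,gap Scoring parameters.
#' @return A list of class `LocalAlignment`: `score`, `a_start`/`a_end` and
#'   `b_start`/`b_end` (0-based half-open aligned intervals), `n_match`,
#'   and `cigar` (edit string over `=`/`X`/`I`/`D`; `I` consumes `a`,
#'   `D` consumes `b`).
#' @export
smith_waterman <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  stopifnot(nzchar(a), nzchar(b))
  res <- .sw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
  structure(res, class = "LocalAlignment")
}

#' @export
print.LocalAlignment <- function(x, ...) {
  cat("LocalAlignment: score", x$score,
      " a[", x$a_start, ",", x$a_end, ")",
      " b[", x$b_start, ",", x$b_end, ") ", x$cigar, "\n", sep = "")
  invisible(x)
}

# Merge seed hit positions on one (lg, strand) into candidate windows.
merge_hit_windows <- function(pos, clip_len, k, margin, lg_len) {
  pos <- sort(unique(pos))
  grp <- cumsum(c(1L, diff(pos) > clip_len))
  lapply(split(pos, grp), function(p) {
    c(max(0L, min(p) - (clip_len + margin)),
      min(lg_len, max(p) + k + clip_len + margin))
  })
}

# Interval distance used by the nearest-to-anchor tie-break.
interval_distance <- function(lg1, s1, e1, lg2, s2, e2) {
  if (lg1 != lg2) return(Inf)
  if (e1 <= s2) return(s2 - e1)
  if (e2 <= s1) return(s1 - e2)
  0
}

#' Realign a clipped segment against the reference
#'
#' Seeds the clip's 16-mer queries genome-wide, Smith-Waterman-aligns the
#' full clip against a reference window around each seeded locus, and keeps
#' the highest-scoring placement. Score ties are broken by minimal distance
#' to the clip's anchor (a different linkage group counts as infinitely
#' far), then by smaller linkage-group name and coordinate. Placements
#' scoring below `min_score` are rejected.
#'
#' @param segment One row of [extract_clipped()] output (or an equivalent
#'   list with `clip_seq`, `anchor_lg`, `anchor_start`, `anchor_end`).
#' @param ref A [reference_genome()].
#' @param hits Optional precomputed [find_perfect_matches()] result for this
#'   clip's query set.
#' @param k Seed length.
#' @param margin Extra reference bases on each side of the seeded window.
#' @param min_score Minimum acceptable alignment score (default 32, one
#'   perfect 16-mer's worth).
#' @param match,mismatch,gap Smith-Waterman scoring.
#' @return A list with `lg`, `start`, `end`, `strand`, `score`,
#'   `clip_start`, `clip_end` (aligned clip interval in clip coordinates)
#'   and `cigar`, or `NULL` if no placement reaches `min_score`.
#' @export
realign_clip <- function(segment, ref, hits = NULL, k = 16L, margin = 20L,
                         min_score = 32, match = 2, mismatch = -1, gap = -2) {
  clip <- segment$clip_seq
  L <- nchar(clip)
  if (is.null(hits)) {
    hits <- find_perfect_matches(ref, build_query_set(clip, k))
  }
  if (nrow(hits) == 0L) return(NULL)
  clip_rc <- revcomp(clip)
  best <- NULL
  for (lg in unique(hits$lg)) {
    for (strand in unique(hits$strand[hits$lg == lg])) {
      pos <- hits$pos[hits$lg == lg & hits$strand == strand]
      wins <- merge_hit_windows(pos, L, k, margin, genome_length(ref, lg))
      for (w in wins) {
        win_seq <- genome_sub(ref, lg, w[1L], w[2L])
        qry <- if (strand == "+") clip else clip_rc
        aln <- smith_waterman(qry, win_seq, match, mismatch, gap)
        if (aln$score <= 0) next
        cand <- list(
          lg = lg, start = w[1L] + aln$b_start, end = w[1L] + aln$b_end,
          strand = strand, score = aln$score, cigar = aln$cigar,
          clip_start = if (strand == "+") aln$a_start else L - aln$a_end,
          clip_end = if (strand == "+") aln$a_end else L - aln$a_start
        )
        if (is.null(best)) { best <- cand; next }
        if (cand$score > best$score) { best <- cand; next }
        if (cand$score < best$score) next
        d_cand <- interval_distance(cand$lg, cand$start, cand$end,
                                    segment$anchor_lg, segment$anchor_start,
                                    segment$anchor_end)
        d_best <- interval_distance(best$lg, best$start, best$end,
                                    segment$anchor_lg, segment$anchor_start,
                                    segment$anchor_end)
        if (d_cand < d_best ||
            (d_cand == d_best &&
             (cand$lg < best$lg ||
              (cand$lg == best$lg && cand$start < best$start)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  best
}

#' Realign every clipped segment with one shared seed scan
#'
#' Batch version of [realign_clip()]: builds one Aho-Corasick automaton over
#' the union of all clips' queries, scans the genome once, and dispatches
#' hits back to each clip.
#'
#' @param segments [extract_clipped()] output.
#' @param ref A [reference_genome()].
#' @inheritParams realign_clip
#' @return A data.frame with one row per successfully realigned clip:
#'   `clip_id`, `lg`, `start`, `end`, `strand`, `score`.
#' @export
realign_clips <- function(segments, ref, k = 16L, margin = 20L,
                          min_score = 32, match = 2, mismatch = -1, gap = -2) {
  empty <- data.frame(clip_id = integer(), lg = character(), start = integer(),
                      end = integer(), strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  qsets <- lapply(segments$clip_seq, build_query_set, k = k)
  all_q <- unique(unlist(lapply(qsets, `[[`, "query")))
  if (length(all_q) == 0L) return(empty)
  master <- find_perfect_matches(ref, all_q)  # strand-agnostic string hits
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    qs <- qsets[[i]]
    hit <- merge(qs, master[, c("query", "lg", "pos")], by = "query")
    if (nrow(hit) == 0L) next
    res <- realign_clip(segments[i, ], ref,
                        hits = hit[, c("query", "lg", "pos", "strand")],
                        k = k, margin = margin, min_score = min_score,
                        match = match, mismatch = mismatch, gap = gap)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      clip_id = segments$clip_id[i], lg = res$lg, start = res$start,
      end = res$end, strand = res$strand, score = res$score,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_split_reads <- function() {
  data.frame(read_id = character(), clip_id = integer(),
             seg5_lg = character(), seg5_start = integer(),
             seg5_end = integer(), seg5_strand = character(),
             seg3_lg = character(), seg3_start = integer(),
             seg3_end = integer(), seg3_strand = character(),
             gap = integer(), score = numeric(), stringsAsFactors = FALSE)
}

#' Assemble split reads from anchors and realigned clips
#'
#' Pairs each anchored read portion with its realigned clip, orders the two
#' placements by their position within the stored read (a left clip is the
#' stored 5' region), and emits one split read per clip with the signed gap
#' between placements when both lie on one linkage group. Realignments
#' exactly colinear with the anchor (same group, same sense, zero gap) are
#' not split reads and are dropped.
#'
#' Placement strands are expressed in the stored-read frame: the anchor is
#' always `"+"` there, and a split read is equivalent to its reverse
#' complement for all downstream classification.
#'
#' @param clips [extract_clipped()] output.
#' @param realignments [realign_clips()] output (matched by `clip_id`).
#' @return A data.frame of split reads with both placements
#'   (`seg5_*`/`seg3_*`), `gap` and the realignment `score`.
#' @export
build_split_reads <- function(clips, realignments) {
  if (nrow(realignments) == 0L) return(empty_split_reads())
  idx <- match(realignments$clip_id, clips$clip_id)
  if (anyNA(idx)) stop("realignment refers to an unknown clip_id")
  rows <- list()
  for (r in seq_len(nrow(realignments))) {
    cl <- clips[idx[r], ]
    re <- realignments[r, ]
    anchor <- list(lg = cl$anchor_lg, start = cl$anchor_start,
                   end = cl$anchor_end, strand = "+")
    realn <- list(lg = re$lg, start = re$start, end = re$end,
                  strand = re$strand)
    if (cl$side == "left") { seg5 <- realn; seg3 <- anchor }
    else                   { seg5 <- anchor; seg3 <- realn }
    j5 <- if (seg5$strand == "+") seg5$end else seg5$start
    j3 <- if (seg3$strand == "+") seg3$start else seg3$end
    gap <- if (seg5$lg == seg3$lg) j3 - j5 else NA_integer_
    same_sense <- seg5$strand == seg3$strand
    if (seg5$lg == seg3$lg && same_sense && !is.na(gap) && gap == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = cl$read_id, clip_id = cl$clip_id,
      seg5_lg = seg5$lg, seg5_start = seg5$start, seg5_end = seg5$end,
      seg5_strand = seg5$strand,
      seg3_lg = seg3$lg, seg3_start = seg3$start, seg3_end = seg3$end,
      seg3_strand = seg3$strand,
      gap = gap, score = re$score, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty_split_reads())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
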