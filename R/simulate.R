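# Seeded simulation of rearranged genomes, ~140 bp single-end reads, and
# mapper-emulated alignments with soft clips at breakpoints.
#
# The mapper emulation is a deliberate stand-in for a real primary mapper:
# it is deterministic, truth-aware, and guarantees the clip structure the
# split-read pipeline consumes (a breakpoint-crossing read is placed by its
# longer colinear piece, the remainder soft-clipped).

#' Simulation configuration
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param lengths Named integer vector of linkage-group lengths (>= 1000).
#' @param gc_fraction GC content of the simulated genome.
#' @param read_length_mean Mean read length (default 140 bp, Ion-Proton-like
#'   single-end fragments).
#' @param read_length_jitter Reads are discrete-uniform on mean +/- jitter.
#' @param sub_rate Per-base substitution error rate.
#' @param indel_rate Per-base small-indel (1 bp) error rate.
#' @param coverage Target genome-wide coverage.
#' @param microindel_prob Probability that a repaired junction carries a
#'   micro-indel (models imperfect end-joining repair at breakpoints).
#' @param microindel_max Maximum micro-indel size in bases.
#' @param min_seed Minimum length of the longer colinear piece for the mapper
#'   emulation to place a read at all.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       lengths = c(chrI = 50000L, chrII = 50000L),
                       gc_fraction = 0.36,
                       read_length_mean = 140L,
                       read_length_jitter = 10L,
                       sub_rate = 0.005,
                       indel_rate = 5e-4,
                       coverage = 20,
                       microindel_prob = 0,
                       microindel_max = 10L,
                       min_seed = 20L) {
  stopifnot(
    length(lengths) >= 1L, !is.null(names(lengths)), all(lengths >= 1000L),
    gc_fraction >= 0, gc_fraction <= 1,
    sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
    microindel_prob >= 0, microindel_prob <= 1,
    read_length_mean > 2L * read_length_jitter, coverage > 0
  )
  structure(
    list(seed = as.integer(seed), lengths = lengths,
         gc_fraction = gc_fraction,
         read_length_mean = as.integer(read_length_mean),
         read_length_jitter = as.integer(read_length_jitter),
         sub_rate = sub_rate, indel_rate = indel_rate, coverage = coverage,
         microindel_prob = microindel_prob,
         microindel_max = as.integer(microindel_max),
         min_seed = as.integer(min_seed)),
    class = "SimConfig"
  )
}

# Deterministic sub-seed below 2^31 for a named simulation stage.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a random reference genome
#'
#' Bases are i.i.d. at the configured GC fraction; the result is
#' deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [reference_genome()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, "genome"))
  seqs <- vapply(config$lengths, function(n) random_dna(n, config$gc_fraction), "")
  names(seqs) <- names(config$lengths)
  reference_genome(seqs)
}

# --- rearrangement plans ----------------------------------------------------

#' Rearrangement plan events
#'
#' Constructors for the events a [rearrangement_plan()] can carry. All
#' coordinates are 0-based half-open on the *source* genome.
#'
#' `insertion()` inserts either a novel sequence (`seq`) or a copy of an
#' existing region (`copy_from = c(start, end)` on `copy_lg`, orientation
#' `copy_orient`), the latter emulating a mobile-element-style copied
#' insertion whose reads map back to the source locus.
#'
#' @param lg,lg_a,lg_b Linkage-group names.
#' @param left_cut,right_cut,cut_a,cut_b,start,end,pos Cut coordinates.
#' @param seq Novel sequence to insert (for `insertion`).
#' @param copy_lg,copy_from,copy_orient Source of a copied insertion.
#' @param copies Total copy count for `duplication` (>= 2).
#' @return An event list used by [rearrangement_plan()].
#' @name plan-events
NULL

#' @rdname plan-events
#' @export
inversion <- function(lg, left_cut, right_cut) {
  stopifnot(left_cut < right_cut)
  list(type = "inversion", lg = lg, left_cut = left_cut, right_cut = right_cut)
}

#' @rdname plan-events
#' @export
reciprocal_translocation <- function(lg_a, cut_a, lg_b, cut_b) {
  stopifnot(lg_a != lg_b)
  list(type = "translocation", lg_a = lg_a, cut_a = cut_a,
       lg_b = lg_b, cut_b = cut_b)
}

#' @rdname plan-events
#' @export
deletion <- function(lg, start, end) {
  stopifnot(start < end)
  list(type = "deletion", lg = lg, start = start, end = end)
}

#' @rdname plan-events
#' @export
insertion <- function(lg, pos, seq = NULL, copy_lg = NULL, copy_from = NULL,
                      copy_orient = "+") {
  if (is.null(seq) && is.null(copy_from)) {
    stop("insertion needs either a novel `seq` or a `copy_from` region")
  }
  list(type = "insertion", lg = lg, pos = pos, seq = seq,
       copy_lg = copy_lg, copy_from = copy_from, copy_orient = copy_orient)
}

#' @rdname plan-events
#' @export
duplication <- function(lg, start, end, copies = 2L) {
  stopifnot(start < end, copies >= 2L)
  list(type = "duplication", lg = lg, start = start, end = end,
       copies = as.integer(copies))
}

#' Collect rearrangement events into a plan
#'
#' @param ... Events from [inversion()], [reciprocal_translocation()],
#'   [deletion()], [insertion()], [duplication()].
#' @return A list of class `RearrangementPlan`.
#' @export
rearrangement_plan <- function(...) {
  events <- list(...)
  structure(list(events = events), class = "RearrangementPlan")
}

# Modification footprint of an event on the source genome, for the
# non-overlap check: data.frame(lg, start, end).
event_footprint <- function(ev) {
  switch(ev$type,
    inversion = data.frame(lg = ev$lg, start = ev$left_cut, end = ev$right_cut),
    deletion = data.frame(lg = ev$lg, start = ev$start, end = ev$end),
    duplication = data.frame(lg = ev$lg, start = ev$start, end = ev$end),
    insertion = data.frame(lg = ev$lg, start = ev$pos, end = ev$pos + 1L),
    translocation = data.frame(lg = c(ev$lg_a, ev$lg_b),
                               start = c(ev$cut_a, ev$cut_b),
                               end = c(ev$cut_a, ev$cut_b) + 1L)
  )
}

validate_plan <- function(ref, plan) {
  stopifnot(inherits(plan, "RearrangementPlan"))
  fp <- do.call(rbind, lapply(plan$events, event_footprint))
  if (is.null(fp) || nrow(fp) == 0L) return(invisible(TRUE))
  for (i in seq_len(nrow(fp))) {
    len <- genome_length(ref, fp$lg[i])
    if (fp$start[i] < 0 || fp$end[i] > len) {
      stop("event footprint [", fp$start[i], ",", fp$end[i],
           ") out of bounds on ", fp$lg[i])
    }
  }
  for (lg in unique(fp$lg)) {
    sub <- fp[fp$lg == lg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("overlapping events on ", lg)
    }
  }
  n_tr <- table(unlist(lapply(plan$events, function(e) {
    if (e$type == "translocation") c(e$lg_a, e$lg_b) else character()
  })))
  if (length(n_tr) && any(n_tr > 1L)) {
    stop("a linkage group may take part in at most one translocation")
  }
  invisible(TRUE)
}

# --- derived-genome assembly ------------------------------------------------

mk_seg <- function(src_lg, src_start, src_end, strand = "+", novel = NULL,
                   junction_after = NULL) {
  list(src_lg = src_lg, src_start = src_start, src_end = src_end,
       strand = strand, novel = novel, junction_after = junction_after)
}

mk_junction <- function(type, lg_a, pos_a, side_a, lg_b, pos_b, side_b,
                        event_id) {
  list(type = type, lg_a = lg_a, pos_a = pos_a, side_a = side_a,
       lg_b = lg_b, pos_b = pos_b, side_b = side_b, event_id = event_id,
       microindel = 0L)
}

seg_len <- function(seg) {
  if (!is.null(seg$novel)) nchar(seg$novel) else seg$src_end - seg$src_start
}

# Split the segment list of one derived lg at the segment containing source
# interval [s, e) on src lg X, replacing it with `pieces`. The original
# segment must be an unrearranged "+" piece fully containing [s, e).
split_segment <- function(segs, X, s, e, make_pieces) {
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    if (is.null(sg$novel) && sg$src_lg == X && sg$strand == "+" &&
        sg$src_start <= s && e <= sg$src_end) {
      pieces <- make_pieces(sg)
      return(append(segs[-k], pieces, after = k - 1L))
    }
  }
  NULL
}

junction_expected_category <- function(j) {
  if (is.na(j$lg_b)) return(NA_character_)   # novel-sequence junction
  if (j$lg_a != j$lg_b) {
    if (j$side_a == j$side_b) "translocational_inversion" else "translocation"
  } else if (j$side_a == j$side_b) {
    "inversion"
  } else {
    # one left end at x joined to one right end at y
    x <- if (j$side_a == "left") j$pos_a else j$pos_b
    y <- if (j$side_a == "left") j$pos_b else j$pos_a
    if (x == y) NA_character_ else if (x < y) "deletion" else "insertion"
  }
}

#' Apply a rearrangement plan to a reference genome
#'
#' Builds the derived (rearranged) genome and a truth set: the derived
#' sequence, a segment map relating derived coordinates to source
#' coordinates, and a table of truth breakpoint junctions in the *original*
#' reference frame. Optional micro-indels (per `config`) are injected at
#' each junction, modelling imperfect end-joining repair.
#'
#' @param ref Source [reference_genome()].
#' @param plan A [rearrangement_plan()]; events must not overlap.
#' @param config A [sim_config()] (supplies the junction micro-indel model
#'   and the seed).
#' @return A list of class `TruthSet` with elements `genome` (derived
#'   [reference_genome()]), `segments` (data.frame mapping derived to source
#'   intervals), `breakpoints` (data.frame of truth junctions: both ends as
#'   `lg`, `pos`, `side` in source coordinates, the expected split-read
#'   category, the derived-frame junction position, and any injected
#'   micro-indel size), `plan` and `config`.
#' @export
apply_rearrangements <- function(ref, plan, config = sim_config()) {
  validate_plan(ref, plan)
  set.seed(derive_seed(config$seed, "junctions"))

  lgs <- lapply(names(ref$sequences), function(lg) {
    list(mk_seg(lg, 0L, genome_length(ref, lg)))
  })
  names(lgs) <- names(ref$sequences)

  ev_id <- 0L
  # translocations first: they restructure whole linkage groups
  for (ev in plan$events) {
    if (ev$type != "translocation") next
    ev_id <- ev_id + 1L
    a <- ev$lg_a; b <- ev$lg_b; ca <- ev$cut_a; cb <- ev$cut_b
    ja <- mk_junction("translocation", a, ca, "left", b, cb, "right", ev_id)
    jb <- mk_junction("translocation", b, cb, "left", a, ca, "right", ev_id)
    lgs[[a]] <- list(mk_seg(a, 0L, ca, junction_after = ja),
                     mk_seg(b, cb, genome_length(ref, b)))
    lgs[[b]] <- list(mk_seg(b, 0L, cb, junction_after = jb),
                     mk_seg(a, ca, genome_length(ref, a)))
  }

  for (ev in plan$events) {
    if (ev$type == "translocation") next
    ev_id <- ev_id + 1L
    X <- ev$lg
    pieces_fun <- switch(ev$type,
      inversion = {
        l <- ev$left_cut; r <- ev$right_cut
        function(sg) list(
          mk_seg(X, sg$src_start, l, junction_after =
                   mk_junction("inversion", X, l, "left", X, r, "left", ev_id)),
          mk_seg(X, l, r, strand = "-", junction_after =
                   mk_junction("inversion", X, l, "right", X, r, "right", ev_id)),
          mk_seg(X, r, sg$src_end, junction_after = sg$junction_after)
        )
      },
      deletion = {
        s <- ev$start; e <- ev$end
        function(sg) list(
          mk_seg(X, sg$src_start, s, junction_after =
                   mk_junction("deletion", X, s, "left", X, e, "right", ev_id)),
          mk_seg(X, e, sg$src_end, junction_after = sg$junction_after)
        )
      },
      insertion = {
        p <- ev$pos
        if (!is.null(ev$copy_from)) {
          clg <- if (is.null(ev$copy_lg)) X else ev$copy_lg
          cs <- ev$copy_from[1L]; ce <- ev$copy_from[2L]
          ori <- ev$copy_orient
          end_near <- if (ori == "+") list(lg = clg, pos = cs, side = "right")
                      else list(lg = clg, pos = ce, side = "left")
          end_far  <- if (ori == "+") list(lg = clg, pos = ce, side = "left")
                      else list(lg = clg, pos = cs, side = "right")
          function(sg) list(
            mk_seg(X, sg$src_start, p, junction_after =
                     mk_junction("insertion", X, p, "left",
                                 end_near$lg, end_near$pos, end_near$side, ev_id)),
            mk_seg(clg, cs, ce, strand = ori, junction_after =
                     mk_junction("insertion", end_far$lg, end_far$pos,
                                 end_far$side, X, p, "right", ev_id)),
            mk_seg(X, p, sg$src_end, junction_after = sg$junction_after)
          )
        } else {
          function(sg) list(
            mk_seg(X, sg$src_start, p, junction_after =
                     mk_junction("insertion", X, p, "left",
                                 NA_character_, NA_integer_, NA_character_, ev_id)),
            mk_seg(NA_character_, NA_integer_, NA_integer_, novel = toupper(ev$seq),
                   junction_after =
                     mk_junction("insertion", NA_character_, NA_integer_,
                                 NA_character_, X, p, "right", ev_id)),
            mk_seg(X, p, sg$src_end, junction_after = sg$junction_after)
          )
        }
      },
      duplication = {
        s <- ev$start; e <- ev$end; k <- ev$copies
        function(sg) {
          copies <- lapply(seq_len(k), function(i) {
            mk_seg(X, s, e, junction_after = if (i < k) {
              mk_junction("duplication", X, e, "left", X, s, "right", ev_id)
            })
          })
          c(list(mk_seg(X, sg$src_start, s)), copies,
            list(mk_seg(X, e, sg$src_end, junction_after = sg$junction_after)))
        }
      }
    )
    fp <- event_footprint(ev)
    fp <- fp[fp$lg == X, , drop = FALSE][1L, ]
    done <- FALSE
    for (nm in names(lgs)) {
      res <- split_segment(lgs[[nm]], X, fp$start, fp$end, pieces_fun)
      if (!is.null(res)) { lgs[[nm]] <- res; done <- TRUE; break }
    }
    if (!done) stop("event on ", X, " does not fit an unrearranged segment")
  }

  # junction micro-indels
  if (config$microindel_prob > 0) {
    for (nm in names(lgs)) {
      segs <- lgs[[nm]]
      k <- 1L
      while (k <= length(segs)) {
        j <- segs[[k]]$junction_after
        if (!is.null(j) && runif(1) < config$microindel_prob) {
          size <- sample.int(config$microindel_max, 1L)
          if (runif(1) < 0.5) {  # insertion of novel bases at the junction
            segs[[k]]$junction_after$microindel <- size
            ins <- mk_seg(NA_character_, NA_integer_, NA_integer_,
                          novel = random_dna(size, config$gc_fraction))
            segs <- append(segs, list(ins), after = k)
            k <- k + 1L
          } else {             # trim bases from one side of the junction
            left_side <- runif(1) < 0.5
            tgt <- if (left_side) k else k + 1L
            if (tgt <= length(segs)) {
              sg <- segs[[tgt]]
              trim <- min(size, seg_len(sg) - 1L)
              if (trim > 0L) {
                if (!is.null(sg$novel)) {
                  sg$novel <- if (left_side) {
                    substr(sg$novel, 1L, nchar(sg$novel) - trim)
                  } else substr(sg$novel, trim + 1L, nchar(sg$novel))
                } else if ((sg$strand == "+") == left_side) {
                  sg$src_end <- sg$src_end - trim
                } else {
                  sg$src_start <- sg$src_start + trim
                }
                segs[[tgt]] <- sg
                segs[[k]]$junction_after$microindel <- trim
              }
            }
          }
        }
        k <- k + 1L
      }
      lgs[[nm]] <- segs
    }
  }

  # materialize sequences, segment table and breakpoint table
  seq_out <- character(length(lgs)); names(seq_out) <- names(lgs)
  seg_rows <- list(); bp_rows <- list()
  for (nm in names(lgs)) {
    pos <- 0L
    for (sg in lgs[[nm]]) {
      piece <- if (!is.null(sg$novel)) sg$novel else {
        s <- genome_sub(ref, sg$src_lg, sg$src_start, sg$src_end)
        if (sg$strand == "-") revcomp(s) else s
      }
      len <- nchar(piece)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        der_lg = nm, der_start = pos, der_end = pos + len,
        src_lg = if (is.null(sg$novel)) sg$src_lg else NA_character_,
        src_start = if (is.null(sg$novel)) sg$src_start else NA_integer_,
        src_end = if (is.null(sg$novel)) sg$src_end else NA_integer_,
        strand = sg$strand, novel = !is.null(sg$novel),
        stringsAsFactors = FALSE
      )
      pos <- pos + len
      j <- sg$junction_after
      if (!is.null(j)) {
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          event_id = j$event_id, type = j$type,
          lg_a = j$lg_a, pos_a = j$pos_a, side_a = j$side_a,
          lg_b = j$lg_b, pos_b = j$pos_b, side_b = j$side_b,
          expected_category = junction_expected_category(j),
          der_lg = nm, der_pos = pos, microindel = j$microindel,
          stringsAsFactors = FALSE
        )
      }
      seq_out[nm] <- paste0(seq_out[nm], piece)
    }
  }
  breakpoints <- if (length(bp_rows)) do.call(rbind, bp_rows) else {
    data.frame(event_id = integer(), type = character(), lg_a = character(),
               pos_a = integer(), side_a = character(), lg_b = character(),
               pos_b = integer(), side_b = character(),
               expected_category = character(), der_lg = character(),
               der_pos = integer(), microindel = integer(),
               stringsAsFactors = FALSE)
  }
  if (length(plan$events) > 0L && nrow(breakpoints) == 0L) {
    stop("internal error: planned events produced no truth breakpoints")
  }
  structure(
    list(genome = reference_genome(seq_out),
         segments = do.call(rbind, seg_rows),
         breakpoints = breakpoints, plan = plan, config = config),
    class = "TruthSet"
  )
}

# --- read simulation --------------------------------------------------------

#' Simulate single-end reads from a genome
#'
#' Uniform start positions, either strand with probability 1/2, read lengths
#' discrete-uniform on mean +/- jitter, substitution and 1 bp indel errors
#' per the config. Deterministic given the config seed and `tag`.
#'
#' @param genome A [reference_genome()] (typically the derived genome of a
#'   [apply_rearrangements()] truth set).
#' @param config A [sim_config()].
#' @param tag Stage tag mixed into the sub-seed, so case and control samples
#'   from the same master seed are independent.
#' @return A data.frame with columns `id`, `seq` (the read as sequenced),
#'   `lg`, `start`, `end` (error-free span on `genome`, 0-based half-open),
#'   `strand`, and the list column `edits` (per-read 1 bp sequencing indels,
#'   offsets in the error-free span frame).
#' @export
simulate_reads <- function(genome, config, tag = "case") {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, paste0("reads:", tag)))
  out <- list()
  for (lg in names(genome$sequences)) {
    glen <- genome_length(genome, lg)
    n <- max(1L, as.integer(round(config$coverage * glen / config$read_length_mean)))
    L <- config$read_length_mean +
      sample.int(2L * config$read_length_jitter + 1L, n, replace = TRUE) -
      config$read_length_jitter - 1L
    L <- pmin(L, glen)
    start <- as.integer(floor(runif(n) * (glen - L + 1L)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$sequences[[lg]], start + 1L, start + L)

    # substitution errors
    nsub <- rbinom(n, L, config$sub_rate)
    for (i in which(nsub > 0L)) {
      pos <- sample.int(L[i], nsub[i])
      s <- seqs[i]
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      seqs[i] <- s
    }

    # 1 bp indel errors, tracked so the mapper emulation can emit I/D ops
    nind <- rbinom(n, L, config$indel_rate)
    edits <- vector("list", n)
    for (i in which(nind > 0L)) {
      is_ins <- runif(nind[i]) < 0.5
      off <- integer(nind[i]); base <- character(nind[i])
      off[is_ins] <- vapply(rep(L[i], sum(is_ins)),
                            function(m) sample.int(m + 1L, 1L) - 1L, 1L)
      off[!is_ins] <- vapply(rep(L[i], sum(!is_ins)),
                             function(m) sample.int(m, 1L) - 1L, 1L)
      base[is_ins] <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)
      keep <- !duplicated(off)
      o <- order(off[keep])
      ed <- list(offset = off[keep][o],
                 op = ifelse(is_ins, "I", "D")[keep][o],
                 base = base[keep][o])
      edits[[i]] <- ed
      # apply right-to-left so earlier offsets stay valid
      s <- seqs[i]
      for (k in rev(seq_along(ed$offset))) {
        o1 <- ed$offset[k]
        if (ed$op[k] == "I") {
          s <- paste0(substr(s, 1L, o1), ed$base[k], substr(s, o1 + 1L, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, o1), substr(s, o1 + 2L, nchar(s)))
        }
      }
      seqs[i] <- s
    }

    rev_idx <- strand == "-"
    seqs[rev_idx] <- revcomp(seqs[rev_idx])
    out[[lg]] <- data.frame(
      id = sprintf("%s_%s_%06d", tag, lg, seq_len(n)),
      seq = seqs, lg = lg, start = start, end = start + L, strand = strand,
      stringsAsFactors = FALSE
    )
    out[[lg]]$edits <- edits
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write reads to FASTQ
#'
#' @param reads Read table from [simulate_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  writeLines(
    as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
    path
  )
  invisible(path)
}

# CIGAR op list (derived-forward) for a read spanning [a, b) whose mapped
# piece is [p, q), with 1 bp sequencing indels `edits` (offsets relative to a).
piece_cigar_ops <- function(a, b, p, q, edits) {
  rel_p <- p - a; rel_q <- q - a
  pre <- rel_p; post <- b - q
  m_ops <- list()
  cur <- rel_p
  if (!is.null(edits) && length(edits$offset) > 0L) {
    for (k in seq_along(edits$offset)) {
      t <- edits$offset[k]; op <- edits$op[k]
      if (op == "I") {
        if (t <= rel_p) pre <- pre + 1L
        else if (t >= rel_q) post <- post + 1L
        else {
          m_ops[[length(m_ops) + 1L]] <- c("M", t - cur)
          m_ops[[length(m_ops) + 1L]] <- c("I", 1L)
          cur <- t
        }
      } else {  # D
        if (t < rel_p) pre <- pre - 1L
        else if (t >= rel_q) post <- post - 1L
        else {
          m_ops[[length(m_ops) + 1L]] <- c("M", t - cur)
          m_ops[[length(m_ops) + 1L]] <- c("D", 1L)
          cur <- t + 1L
        }
      }
    }
  }
  m_ops[[length(m_ops) + 1L]] <- c("M", rel_q - cur)
  ops <- do.call(rbind, m_ops)
  data.frame(
    op = c("S", ops[, 1L], "S"),
    len = as.integer(c(pre, ops[, 2L], post)),
    stringsAsFactors = FALSE
  )
}

#' Emulate primary mapping of simulated reads
#'
#' A truth-aware stand-in for a real short-read mapper. A read lying
#' entirely inside a segment colinear with the reference maps fully (single
#' M run, correct strand). A read crossing a truth breakpoint is placed by
#' its *longer* colinear piece, the remainder soft-clipped at the
#' breakpoint. Reads whose longer piece is shorter than `min_seed` (or that
#' lie entirely in novel inserted sequence) are dropped as unmapped.
#' Sequencing indel errors appear as I/D CIGAR ops.
#'
#' @param reads Read table from [simulate_reads()] on `truth$genome`.
#' @param ref The original [reference_genome()] the truth set was derived
#'   from.
#' @param truth The `TruthSet` from [apply_rearrangements()].
#' @param min_seed Minimum longer-piece length to place a read (defaults to
#'   the truth config's `min_seed`).
#' @return An alignment table in the same shape as [read_sam()] output.
#' @export
emulate_mapping <- function(reads, ref, truth, min_seed = NULL) {
  stopifnot(inherits(truth, "TruthSet"))
  if (is.null(min_seed)) min_seed <- truth$config$min_seed
  segs <- truth$segments
  n <- nrow(reads)
  if (n == 0L) return(empty_alignments())

  res_id <- character(n); res_lg <- character(n); res_start <- integer(n)
  res_strand <- character(n); res_cigar <- character(n); res_seq <- character(n)
  keep <- logical(n)

  no_edits <- vapply(reads$edits, is.null, TRUE)

  for (lg in unique(reads$lg)) {
    sl <- segs[segs$der_lg == lg, , drop = FALSE]
    sl <- sl[order(sl$der_start), , drop = FALSE]
    ridx <- which(reads$lg == lg)
    si <- findInterval(reads$start[ridx], sl$der_start)
    in_one <- reads$end[ridx] <= sl$der_end[si] & !sl$novel[si]
    # fast path: error-indel-free reads inside a single mappable segment
    fast <- in_one & no_edits[ridx]
    fi <- ridx[fast]; fs <- si[fast]
    if (length(fi)) {
      a <- reads$start[fi]; b <- reads$end[fi]
      plus <- sl$strand[fs] == "+"
      rstart <- ifelse(plus,
                       sl$src_start[fs] + (a - sl$der_start[fs]),
                       sl$src_end[fs] - (b - sl$der_start[fs]))
      astrand <- ifelse(reads$strand[fi] == sl$strand[fs], "+", "-")
      dfwd <- reads$seq[fi]
      rev_in <- reads$strand[fi] == "-"
      dfwd[rev_in] <- revcomp(dfwd[rev_in])
      stored <- dfwd
      stored[!plus] <- revcomp(stored[!plus])
      res_id[fi] <- reads$id[fi]; res_lg[fi] <- sl$src_lg[fs]
      res_start[fi] <- as.integer(rstart); res_strand[fi] <- astrand
      res_cigar[fi] <- paste0(b - a, "M"); res_seq[fi] <- stored
      keep[fi] <- TRUE
    }
    # slow path: breakpoint-crossing reads and reads carrying indel errors
    for (i in ridx[!fast]) {
      a <- reads$start[i]; b <- reads$end[i]
      ov <- which(sl$der_start < b & sl$der_end > a & !sl$novel)
      if (length(ov) == 0L) next
      plen <- pmin(b, sl$der_end[ov]) - pmax(a, sl$der_start[ov])
      best <- ov[which.max(plen)]
      if (max(plen) < min_seed) next
      p <- max(a, sl$der_start[best]); q <- min(b, sl$der_end[best])
      ops <- piece_cigar_ops(a, b, p, q, reads$edits[[i]])
      if (sl$strand[best] == "+") {
        rstart <- sl$src_start[best] + (p - sl$der_start[best])
      } else {
        rstart <- sl$src_end[best] - (q - sl$der_start[best])
        ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
      }
      dfwd <- if (reads$strand[i] == "-") revcomp(reads$seq[i]) else reads$seq[i]
      stored <- if (sl$strand[best] == "-") revcomp(dfwd) else dfwd
      res_id[i] <- reads$id[i]; res_lg[i] <- sl$src_lg[best]
      res_start[i] <- as.integer(rstart)
      res_strand[i] <- if (reads$strand[i] == sl$strand[best]) "+" else "-"
      res_cigar[i] <- cigar_string(ops$op, ops$len)
      res_seq[i] <- stored
      keep[i] <- TRUE
    }
  }
  data.frame(read_id = res_id[keep], lg = res_lg[keep],
             start = res_start[keep], strand = res_strand[keep],
             cigar = res_cigar[keep], seq = res_seq[keep],
             stringsAsFactors = FALSE)
}

#' Simulate a control (un-rearranged) sample
#'
#' Runs [simulate_reads()] plus [emulate_mapping()] on the reference itself
#' with an independent sub-seed, yielding the control alignments used for
#' split-read subtraction and depth-ratio computation.
#'
#' @param ref A [reference_genome()].
#' @param config A [sim_config()].
#' @param tag Sub-seed tag (default `"control"`).
#' @return An alignment table.
#' @export
make_control <- function(ref, config, tag = "control") {
  truth0 <- apply_rearrangements(ref, rearrangement_plan(), config)
  reads <- simulate_reads(truth0$genome, config, tag = tag)
  emulate_mapping(reads, ref, truth0)
}

#' Write a truth breakpoint table
#'
#' @param truth A `TruthSet`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth$breakpoints, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable simulation manifest
#'
#' Records the plan, configuration and seed of a simulation run as JSON.
#'
#' @param truth A `TruthSet`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(truth, path) {
  cfg <- unclass(truth$config)
  cfg$lengths <- as.list(cfg$lengths)
  jsonlite::write_json(
    list(seed = truth$config$seed, config = cfg,
         plan = lapply(truth$plan$events, function(e) e[!vapply(e, is.null, TRUE)])),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
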