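# Text SAM ingestion/emission and CIGAR helpers.
#
# Only the features the split-read pipeline consumes are supported: single-end
# primary records, flags 0x4 (unmapped -> skipped) and 0x10 (reverse strand),
# CIGAR ops M/I/D/S. Tags are ignored. Internally coordinates are 0-based
# half-open; SAM is 1-based.

# --- CIGAR helpers ----------------------------------------------------------

# Parse one CIGAR string into a data.frame(op, len).
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(data.frame(op = character(), len = integer()))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[A-Za-z=]", cigar))[[1]]
  if (!nzchar(cigar) || paste(toks, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(
    op = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
    stringsAsFactors = FALSE
  )
}

cigar_string <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  paste0(tapply(len, grp, sum), op[!duplicated(grp)], collapse = "")
}

# Reference span (M + D) consumed by a CIGAR.
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

# Read-sequence length (M + I + S) implied by a CIGAR.
cigar_read_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S")])

validate_alignment_cigar <- function(ops, read_id = "?") {
  bad <- setdiff(unique(ops$op), c("M", "I", "D", "S"))
  if (length(bad)) {
    stop("unsupported CIGAR op '", bad[1L], "' in read ", read_id,
         " (only M/I/D/S are supported)")
  }
  s_idx <- which(ops$op == "S")
  if (length(s_idx) > 2L ||
      (length(s_idx) >= 1L && !all(s_idx %in% c(1L, nrow(ops))))) {
    stop("soft clips must be terminal in read ", read_id)
  }
  if (!any(ops$op == "M")) stop("CIGAR without an M run in read ", read_id)
  invisible(TRUE)
}

empty_alignments <- function() {
  data.frame(read_id = character(), lg = character(), start = integer(),
             strand = character(), cigar = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Read single-end alignments from a SAM file
#'
#' Parses a text SAM file into the package's alignment table. Unmapped
#' records (flag 0x4) are skipped, secondary (0x100) and supplementary
#' (0x800) records are skipped (the pipeline derives split mappings itself
#' from soft clips), 1-based SAM coordinates are converted to 0-based, and
#' strand is taken from flag 0x10. Records with CIGAR ops outside M/I/D/S
#' (notably hard clips) are rejected.
#'
#' @param path Path to a SAM file.
#' @param ref A [reference_genome()]; record reference names must exist in it
#'   and aligned spans must fit inside the sequence.
#' @return A data.frame with columns `read_id`, `lg`, `start` (0-based),
#'   `strand` (`"+"`/`"-"`), `cigar`, `seq` (stored orientation, i.e.
#'   reverse-complemented for `-` strand records, as in SAM).
#' @export
read_sam <- function(path, ref) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(rec) == 0L) return(empty_alignments())
  fields <- strsplit(rec, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM record with fewer than 11 fields at data line ",
         which(nf < 11L)[1L])
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  keep <- bitwAnd(flag, 0x4L) == 0L &
    bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (length(fields) == 0L) return(empty_alignments())
  out <- data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    lg      = vapply(fields, `[[`, "", 3L),
    start   = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    strand  = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
    cigar   = vapply(fields, `[[`, "", 6L),
    seq     = toupper(vapply(fields, `[[`, "", 10L)),
    stringsAsFactors = FALSE
  )
  unknown <- !(out$lg %in% names(ref$sequences))
  if (any(unknown)) {
    stop("SAM record mapped to unknown reference '", out$lg[unknown][1L], "'")
  }
  for (i in seq_len(nrow(out))) {
    ops <- parse_cigar(out$cigar[i])
    validate_alignment_cigar(ops, out$read_id[i])
    if (cigar_read_len(ops) != nchar(out$seq[i])) {
      stop("CIGAR/sequence length mismatch in read ", out$read_id[i])
    }
    if (out$start[i] < 0L ||
        out$start[i] + cigar_ref_span(ops) > genome_length(ref, out$lg[i])) {
      stop("alignment of read ", out$read_id[i], " exceeds bounds of ",
           out$lg[i])
    }
  }
  out
}

#' Write alignments to a SAM file
#'
#' Emits a minimal valid single-end SAM (header with `@SQ` lines from the
#' reference, MAPQ 60, no tags) that [read_sam()] round-trips exactly.
#'
#' @param alignments Alignment table as returned by [read_sam()] or
#'   [emulate_mapping()].
#' @param ref A [reference_genome()] used for the `@SQ` header lines.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, ref, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(ref$sequences), "\tLN:", nchar(ref$sequences))
  )
  if (nrow(alignments) > 0L) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    body <- paste(alignments$read_id, flag, alignments$lg,
                  alignments$start + 1L, 60L, alignments$cigar,
                  "*", 0L, 0L, alignments$seq, "*", sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
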