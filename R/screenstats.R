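# Screening statistics: efficiency ratios, Fisher's exact test, and
# classification of breakpoint repair as homologous recombination (HR)
# versus end joining.

#' Construct a screening count record
#'
#' One row of a balancer-screening funnel: injected P0 worms, fluorescent
#' F1 worms, F1 strains with phenotype-positive F2 progeny, and the PCR-
#' positive counts of the first (F1) and second (F2) screening rounds.
#' Counts must be monotone down the funnel.
#'
#' @param label Strain/trial label.
#' @param p0_injected,f1_fluorescent,f2_phenotype_positive,f1_pcr_positive,f2_pcr_positive
#'   Non-negative integer counts.
#' @return A one-row data.frame of class `ScreenCounts`.
#' @export
screen_counts <- function(label, p0_injected, f1_fluorescent,
                          f2_phenotype_positive, f1_pcr_positive,
                          f2_pcr_positive) {
  counts <- c(p0_injected, f1_fluorescent, f2_phenotype_positive,
              f1_pcr_positive, f2_pcr_positive)
  if (any(counts < 0)) stop("screening counts must be non-negative")
  if (!(f2_pcr_positive <= f1_pcr_positive &&
        f1_pcr_positive <= f2_phenotype_positive &&
        f2_phenotype_positive <= f1_fluorescent)) {
    stop("screening funnel must be monotone: ",
         "f2_pcr <= f1_pcr <= f2_phenotype <= f1_fluorescent")
  }
  structure(
    data.frame(label = label, p0_injected = p0_injected,
               f1_fluorescent = f1_fluorescent,
               f2_phenotype_positive = f2_phenotype_positive,
               f1_pcr_positive = f1_pcr_positive,
               f2_pcr_positive = f2_pcr_positive, stringsAsFactors = FALSE),
    class = c("ScreenCounts", "data.frame")
  )
}

#' Read a screening count table
#'
#' Reads a TSV with the [screen_counts()] columns and validates each row.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame of screening counts.
#' @export
read_screen_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "p0_injected", "f1_fluorescent",
            "f2_phenotype_positive", "f1_pcr_positive", "f2_pcr_positive")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("screening table lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    screen_counts(df$label[i], df$p0_injected[i], df$f1_fluorescent[i],
                  df$f2_phenotype_positive[i], df$f1_pcr_positive[i],
                  df$f2_pcr_positive[i])
  }
  df[, need]
}

#' Balancer isolation efficiency ratio
#'
#' Isolated balancers (second-screening PCR positives) per fluorescent F1
#' worm, as a percentage. Published tables of this quantity are not always
#' consistently rounded, so the raw value is returned together with its
#' rounded and truncated two-decimal renderings.
#'
#' @param counts A `ScreenCounts` row (or any list with `f2_pcr_positive`
#'   and `f1_fluorescent`).
#' @return A list with `raw`, `rounded` (two decimals, round half up via
#'   base rounding) and `truncated` (two decimals, floor).
#' @export
efficiency_ratio <- function(counts) {
  f1 <- counts$f1_fluorescent
  if (is.null(f1) || f1 <= 0) stop("f1_fluorescent must be positive")
  raw <- 100 * counts$f2_pcr_positive / f1
  list(raw = raw, rounded = round(raw, 2), truncated = floor(raw * 100) / 100)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p value by direct hypergeometric enumeration:
#' with margins fixed, all tables whose probability does not exceed that of
#' the observed table (up to a relative tolerance of 1e-7) contribute.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero table")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  p_all <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

#' Classify breakpoint repair as HR or end joining
#'
#' Globally aligns the observed junction sequence to the expected
#' homologous-recombination junction (same scoring as the split-read
#' realignment: +2/-1/-2). A perfect copy of the expected junction is
#' called HR; any edit makes the call end joining, with the edits
#' (substitutions, insertions, deletions relative to the expected
#' sequence) reported.
#'
#' @param observed_junction Observed junction sequence.
#' @param expected_hr_junction Expected junction sequence under perfect HR
#'   (e.g. the corresponding targeting-vector chimera).
#' @param match,mismatch,gap Alignment scoring.
#' @return A list of class `RepairCall`: `verdict` (`"HR"` or
#'   `"end_joining"`), `score`, `n_sub`, `n_ins`, `n_del` and `edits`
#'   (data.frame of edit operations with 0-based positions on the expected
#'   sequence).
#' @export
classify_breakpoint_repair <- function(observed_junction,
                                       expected_hr_junction,
                                       match = 2, mismatch = -1, gap = -2) {
  obs <- toupper(observed_junction); exp_ <- toupper(expected_hr_junction)
  if (!nzchar(obs) || !nzchar(exp_)) {
    stop("observed sequence does not overlap the junction")
  }
  if (obs == exp_) {
    return(structure(list(verdict = "HR", score = 2 * nchar(obs),
                          n_sub = 0L, n_ins = 0L, n_del = 0L,
                          edits = data.frame(op = character(),
                                             pos = integer(),
                                             stringsAsFactors = FALSE)),
                     class = "RepairCall"))
  }
  aln <- .nw_align_cpp(obs, exp_, match, mismatch, gap)
  ops <- parse_cigar(aln$cigar)
  pos_exp <- 0L
  ed <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("X", "D")) {
      # X: substitution at expected positions; D: expected bases absent
      # from the observed sequence (a deletion in the repaired junction)
      ed[[length(ed) + 1L]] <- data.frame(
        op = if (op == "X") "substitution" else "deletion",
        pos = pos_exp, len = len, stringsAsFactors = FALSE
      )
    } else if (op == "I") {
      ed[[length(ed) + 1L]] <- data.frame(
        op = "insertion", pos = pos_exp, len = len, stringsAsFactors = FALSE
      )
    }
    if (op %in% c("=", "X", "D")) pos_exp <- pos_exp + len
  }
  edits <- do.call(rbind, ed)
  structure(list(
    verdict = "end_joining", score = aln$score,
    n_sub = sum(edits$len[edits$op == "substitution"]),
    n_ins = sum(edits$len[edits$op == "insertion"]),
    n_del = sum(edits$len[edits$op == "deletion"]),
    edits = edits
  ), class = "RepairCall")
}

#' @export
print.RepairCall <- function(x, ...) {
  cat("RepairCall:", x$verdict)
  if (x$verdict == "end_joining") {
    cat(" (", x$n_sub, " sub, ", x$n_ins, " ins, ", x$n_del, " del)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Summarize repair calls over strains and breakpoints
#'
#' @param calls A data.frame with columns `strain`, `breakpoint` and
#'   `verdict` (`"HR"`/`"end_joining"`), one row per breakpoint.
#' @return A list with `n_hr`, `n_end_joining`, and `per_strain` (counts of
#'   both-HR, mixed and both-end-joining strains).
#' @export
summarize_repair <- function(calls) {
  if (is.null(nrow(calls)) || nrow(calls) == 0L) stop("no repair calls")
  if (!all(calls$verdict %in% c("HR", "end_joining"))) {
    stop("verdicts must be 'HR' or 'end_joining'")
  }
  n_hr <- sum(calls$verdict == "HR")
  n_ej <- sum(calls$verdict == "end_joining")
  per <- vapply(split(calls$verdict, calls$strain), function(v) {
    if (all(v == "HR")) "both_HR"
    else if (all(v == "end_joining")) "both_end_joining"
    else "mixed"
  }, "")
  list(
    n_hr = n_hr, n_end_joining = n_ej,
    per_strain = c(
      both_HR = sum(per == "both_HR"),
      mixed = sum(per == "mixed"),
      both_end_joining = sum(per == "both_end_joining")
    )
  )
}
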