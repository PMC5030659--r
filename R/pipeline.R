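# End-to-end orchestration: depth/coverage -> clips -> seeds -> realignment
# -> split reads -> classification -> control subtraction -> candidates ->
# support filter -> ND/DR -> depth filters -> report.

#' Detection configuration
#'
#' All tunables of the detection pipeline with their standard defaults:
#' clips must exceed 20 bp, 16-mer seeds, +2/-1/-2 alignment scoring,
#' 10 bp clustering tolerance, deletion clusters need more than 2 reads,
#' complex candidates at least 10, mapped regions need depth greater
#' than 1, and depth-ratio thresholds 0.75 (deletion removal), 1.75
#' (duplication) and 2.5 (multiplication).
#'
#' @param min_clip Minimum (strict) soft-clip length.
#' @param kmer Seed length.
#' @param match,mismatch,gap Alignment scoring.
#' @param min_score Minimum realignment score.
#' @param margin Realignment window margin.
#' @param tol Clustering/matching tolerance (bases).
#' @param min_del_sr Minimum deletion-cluster support.
#' @param min_complex_reads Minimum complex-candidate support.
#' @param depth_mapped_min Mapped-region depth threshold (strict).
#' @param dr_del,dr_dup,dr_mult Depth-ratio thresholds.
#' @param local_max_span Inversion cluster pairs spanning less than this
#'   are reported as local variants, larger ones as breakpoint pairs.
#' @param verbose Log per-stage record counts to standard error.
#' @return A list of class `DetectConfig`.
#' @export
detect_config <- function(min_clip = 20L, kmer = 16L, match = 2,
                          mismatch = -1, gap = -2, min_score = 32,
                          margin = 20L, tol = 10L, min_del_sr = 3L,
                          min_complex_reads = 10L, depth_mapped_min = 1L,
                          dr_del = 0.75, dr_dup = 1.75, dr_mult = 2.5,
                          local_max_span = 1000L, verbose = FALSE) {
  structure(as.list(environment()), class = "DetectConfig")
}

stage_log <- function(verbose, ...) {
  if (verbose) message("[balancerSV] ", ...)
}

#' Run the full structural-variant detection pipeline
#'
#' @param ref A [reference_genome()] (or path to a FASTA).
#' @param case_aln,control_aln Alignment tables (or paths to SAM files) of
#'   the case and control samples.
#' @param config A [detect_config()].
#' @param out_prefix Optional path prefix; when given, `<prefix>.tsv`,
#'   `<prefix>.vcf` and `<prefix>.splitreads.tsv` are written.
#' @return A list with `candidates` (all, with status), `kept`,
#'   `split_reads` (case, after control subtraction), `coverage_case`,
#'   `coverage_control` and `stage_counts`.
#' @export
run_detect <- function(ref, case_aln, control_aln, config = detect_config(),
                       out_prefix = NULL) {
  if (is.character(ref)) ref <- read_fasta(ref)
  if (is.character(case_aln)) case_aln <- read_sam(case_aln, ref)
  if (is.character(control_aln)) control_aln <- read_sam(control_aln, ref)
  v <- config$verbose
  counts <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    n <- if (is.data.frame(res)) nrow(res) else length(res)
    counts[[name]] <<- n
    stage_log(v, name, ": ", n, " records")
    res
  }

  depth_case <- run_stage("depth_case", compute_depth(case_aln, ref))
  depth_control <- run_stage("depth_control", compute_depth(control_aln, ref))
  stage_log(v, "coverage: case ", format(depth_case$coverage, digits = 4),
            ", control ", format(depth_control$coverage, digits = 4))

  clips_case <- run_stage("clips_case",
                          extract_clipped(case_aln, config$min_clip))
  clips_control <- run_stage("clips_control",
                             extract_clipped(control_aln, config$min_clip))
  re_case <- run_stage("realigned_case", realign_clips(
    clips_case, ref, k = config$kmer, margin = config$margin,
    min_score = config$min_score, match = config$match,
    mismatch = config$mismatch, gap = config$gap))
  re_control <- run_stage("realigned_control", realign_clips(
    clips_control, ref, k = config$kmer, margin = config$margin,
    min_score = config$min_score, match = config$match,
    mismatch = config$mismatch, gap = config$gap))
  sr_case <- run_stage("split_reads_case",
                       classify_split_reads(
                         build_split_reads(clips_case, re_case)))
  sr_control <- run_stage("split_reads_control",
                          classify_split_reads(
                            build_split_reads(clips_control, re_control)))
  sr <- run_stage("split_reads_after_control",
                  subtract_control(sr_case, sr_control, config$tol))

  cands <- run_stage("candidates", rbind(
    call_deletions(sr, config$tol, config$min_del_sr),
    call_paired_variants(sr, config$tol,
                         max_span = config$local_max_span - 1L),
    call_large_breakpoint_pairs(sr, config$tol,
                                min_span = config$local_max_span)
  ))
  cands <- filter_complicated(cands, config$min_complex_reads)

  nd_case <- normalized_depth(depth_case, config$depth_mapped_min)
  nd_control <- normalized_depth(depth_control, config$depth_mapped_min)
  dr <- depth_ratio(nd_case, nd_control)
  cands <- apply_depth_filters(cands, dr, config$dr_del, config$dr_dup,
                               config$dr_mult)
  kept <- cands[cands$status == "kept", , drop = FALSE]
  counts$kept <- nrow(kept)
  stage_log(v, "kept candidates: ", nrow(kept))

  if (!is.null(out_prefix)) {
    write_variant_report(cands, paste0(out_prefix, ".tsv"), "tsv")
    write_variant_report(cands, paste0(out_prefix, ".vcf"), "vcf", ref = ref)
    sr_flat <- sr
    write.table(sr_flat, paste0(out_prefix, ".splitreads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(candidates = cands, kept = kept, split_reads = sr,
       coverage_case = depth_case$coverage,
       coverage_control = depth_control$coverage,
       depth_ratio = dr, stage_counts = counts)
}

#' Compare kept candidates against a simulation truth set
#'
#' Matches each planned event's junctions to the kept candidates: an
#' inversion is recovered when an inversion call (breakpoint pair or local)
#' places both junctions within `tol` plus that event's micro-indel size of
#' the truth cuts; a translocation when a translocation pair matches both
#' breakpoints; deletions/insertions/duplications by their region
#' coordinates.
#'
#' @param candidates Candidate table (kept rows are consulted).
#' @param truth A `TruthSet`.
#' @param tol Base tolerance before adding the per-junction micro-indel.
#' @return A data.frame with one row per truth event: `event_id`, `type`,
#'   `recovered`, and `max_error` (worst junction-coordinate error of the
#'   matching call, NA when unrecovered).
#' @export
evaluate_candidates <- function(candidates, truth, tol = 10L) {
  kept <- candidates[candidates$status == "kept", , drop = FALSE]
  bp <- truth$breakpoints
  events <- unique(bp$event_id)
  res <- lapply(events, function(ev) {
    sub <- bp[bp$event_id == ev, , drop = FALSE]
    type <- sub$type[1L]
    allow <- tol + max(sub$microindel)
    rec <- FALSE; err <- NA_real_
    if (type == "inversion") {
      l <- min(sub$pos_a); r <- max(sub$pos_b)
      hits <- kept[kept$kind %in% c("inversion_breakpoint_pair",
                                    "local_inversion_or_inverted_insertion") &
                     kept$lg == sub$lg_a[1L], , drop = FALSE]
      if (nrow(hits)) {
        e <- pmax(abs(hits$start - l), abs(hits$end - r))
        if (any(e <= allow)) { rec <- TRUE; err <- min(e) }
      }
    } else if (type == "translocation") {
      a_lg <- sub$lg_a[1L]; a <- sub$pos_a[1L]
      b_lg <- sub$lg_b[1L]; b <- sub$pos_b[1L]
      hits <- kept[kept$kind == "translocation_breakpoint_pair", , drop = FALSE]
      if (nrow(hits)) {
        same <- hits$lg == a_lg & hits$partner_lg == b_lg
        swap <- hits$lg == b_lg & hits$partner_lg == a_lg
        e <- rep(Inf, nrow(hits))
        e[same] <- pmax(abs(hits$start[same] - a),
                        abs(hits$partner_pos[same] - b))
        e[swap] <- pmax(abs(hits$start[swap] - b),
                        abs(hits$partner_pos[swap] - a))
        if (any(e <= allow)) { rec <- TRUE; err <- min(e) }
      }
    } else {
      kind_map <- c(deletion = "deletion", insertion = "insertion",
                    duplication = "insertion")
      want <- c(kind_map[[type]],
                if (type == "insertion") c("duplication", "multiplication"),
                if (type == "duplication") c("duplication", "multiplication"))
      reg_lg <- sub$lg_a[1L]
      lo <- min(c(sub$pos_a, sub$pos_b), na.rm = TRUE)
      hi <- max(c(sub$pos_a, sub$pos_b), na.rm = TRUE)
      hits <- kept[kept$kind %in% want & kept$lg == reg_lg, , drop = FALSE]
      if (nrow(hits)) {
        e <- pmax(abs(hits$start - lo), abs(hits$end - hi))
        if (any(e <= allow)) { rec <- TRUE; err <- min(e) }
      }
    }
    data.frame(event_id = ev, type = type, recovered = rec,
               max_error = err, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Seeded parameter-recovery experiment
#'
#' Repeatedly simulates a two-linkage-group genome (60 kb + 40 kb) carrying
#' one inversion of random size (5-50 kb) and one reciprocal translocation,
#' sequences case and control samples at the configured coverage with
#' substitution errors and junction micro-indels, runs the full detection
#' pipeline, and scores recovery against the simulation truth. A second,
#' independent control sample is additionally run against the first as a
#' null experiment.
#'
#' @param seed Master seed; replicate `r` derives its own seed.
#' @param n_reps Number of replicates.
#' @param coverage Sequencing coverage per sample.
#' @param sub_rate Per-base substitution error rate.
#' @param microindel_prob,microindel_max Junction micro-indel model.
#' @param config A [detect_config()].
#' @return A data.frame with one row per replicate and truth event:
#'   `rep`, `type`, `recovered`, `max_error`, `microindel` (largest
#'   micro-indel of that event) and `control_false_calls` (kept calls of
#'   the replicate's control-versus-control run).
#' @export
recovery_experiment <- function(seed = 1L, n_reps = 20L, coverage = 20,
                                sub_rate = 0.005, microindel_prob = 0.5,
                                microindel_max = 10L,
                                config = detect_config()) {
  out <- list()
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = seed + r,
                      lengths = c(chrI = 60000L, chrII = 40000L),
                      coverage = coverage, sub_rate = sub_rate,
                      microindel_prob = microindel_prob,
                      microindel_max = microindel_max)
    set.seed(derive_seed(cfg$seed, "recovery-plan"))
    inv_size <- sample(5000:50000, 1L)
    inv_start <- sample(2000:(52000L - inv_size), 1L)
    tr_cut_a <- sample(53000:58000, 1L)
    tr_cut_b <- sample(5000:35000, 1L)
    ref <- simulate_genome(cfg)
    truth <- apply_rearrangements(ref, rearrangement_plan(
      inversion("chrI", inv_start, inv_start + inv_size),
      reciprocal_translocation("chrI", tr_cut_a, "chrII", tr_cut_b)
    ), cfg)
    case <- emulate_mapping(simulate_reads(truth$genome, cfg, tag = "case"),
                            ref, truth)
    ctrl <- make_control(ref, cfg, tag = "control")
    det <- run_detect(ref, case, ctrl, config)
    ev <- evaluate_candidates(det$candidates, truth, tol = config$tol)

    ctrl2 <- make_control(ref, cfg, tag = "control2")
    null_det <- run_detect(ref, ctrl2, ctrl, config)

    bp <- truth$breakpoints
    ev$microindel <- vapply(ev$event_id, function(e) {
      max(bp$microindel[bp$event_id == e])
    }, 1L)
    ev$rep <- r
    ev$control_false_calls <- nrow(null_det$kept)
    out[[r]] <- ev
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("rep", "type", "recovered", "max_error", "microindel",
          "control_false_calls")]
}

#' Run a fixed-seed demonstration of the whole pipeline
#'
#' Simulates a 50 kb single-linkage-group genome carrying one 5 kb
#' inversion at coverage 20, maps case and control, runs detection and
#' targeting-vector design for the planned cuts, and writes reports plus a
#' truth-versus-call summary into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed (default 7).
#' @return Invisibly, a list with the detection result, the truth set and
#'   the evaluation table.
#' @export
run_demo <- function(out_dir, seed = 7L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, lengths = c(chrI = 50000L), coverage = 20)
  ref <- simulate_genome(cfg)
  plan <- rearrangement_plan(inversion("chrI", 20000L, 25000L))
  truth <- apply_rearrangements(ref, plan, cfg)
  case_reads <- simulate_reads(truth$genome, cfg, tag = "case")
  case_aln <- emulate_mapping(case_reads, ref, truth)
  control_aln <- make_control(ref, cfg)

  write_fasta(ref, file.path(out_dir, "reference.fasta"))
  write_fasta(truth$genome, file.path(out_dir, "derived.fasta"))
  write_fastq(case_reads, file.path(out_dir, "case.fastq"))
  write_sam(case_aln, ref, file.path(out_dir, "case.sam"))
  write_sam(control_aln, ref, file.path(out_dir, "control.sam"))
  write_truth_table(truth, file.path(out_dir, "truth.tsv"))
  write_manifest(truth, file.path(out_dir, "manifest.json"))

  det <- run_detect(ref, case_aln, control_aln,
                    out_prefix = file.path(out_dir, "calls"))
  ev <- evaluate_candidates(det$candidates, truth)
  write.table(ev, file.path(out_dir, "truth_vs_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  vec <- build_inversion_vectors(ref, list(lg = "chrI", pos = 20000L),
                                 list(lg = "chrI", pos = 25000L))
  write_fasta(c(left_vector = vec$left_seq, right_vector = vec$right_seq),
              file.path(out_dir, "targeting_vectors.fasta"))
  invisible(list(detection = det, truth = truth, evaluation = ev))
}
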