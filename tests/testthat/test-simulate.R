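# Genome/read simulation, rearrangement application and mapper emulation.

test_that("genome simulation is seed-deterministic with exact lengths", {
  cfg <- sim_config(seed = 1L, lengths = c(chrI = 10000L))
  expect_identical(simulate_genome(cfg)$sequences,
                   simulate_genome(cfg)$sequences)
  expect_equal(nchar(simulate_genome(cfg)$sequences[["chrI"]]), 10000L)

  at_only <- sim_config(seed = 2L, lengths = c(chrI = 2000L), gc_fraction = 0)
  expect_false(grepl("[GC]", simulate_genome(at_only)$sequences[["chrI"]]))
})

test_that("rearrangement application matches its definitions", {
  cfg <- sim_config(seed = 3L, lengths = c(chrI = 2000L, chrII = 1500L))
  ref <- simulate_genome(cfg)

  # inversion reverse-complements [left_cut, right_cut)
  tr <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 100L, 200L)), cfg)
  der <- tr$genome$sequences[["chrI"]]
  src <- ref$sequences[["chrI"]]
  expect_equal(substr(der, 101, 200), revcomp(substr(src, 101, 200)))
  expect_equal(substr(der, 1, 100), substr(src, 1, 100))
  expect_equal(substr(der, 201, 2000), substr(src, 201, 2000))
  expect_equal(nrow(tr$breakpoints), 2L)
  expect_setequal(tr$breakpoints$expected_category, "inversion")

  # empty plan is the identity
  t0 <- apply_rearrangements(ref, rearrangement_plan(), cfg)
  expect_identical(t0$genome$sequences, ref$sequences)
  expect_equal(nrow(t0$breakpoints), 0L)

  # re-inverting the derived genome restores the original (micro-indels off)
  t2 <- apply_rearrangements(tr$genome, rearrangement_plan(
    inversion("chrI", 100L, 200L)), cfg)
  expect_identical(t2$genome$sequences, ref$sequences)

  # reciprocal translocation exchanges distal arms
  tt <- apply_rearrangements(ref, rearrangement_plan(
    reciprocal_translocation("chrI", 800L, "chrII", 600L)), cfg)
  expect_equal(tt$genome$sequences[["chrI"]],
               paste0(substr(src, 1, 800),
                      substr(ref$sequences[["chrII"]], 601, 1500)))
  expect_equal(tt$genome$sequences[["chrII"]],
               paste0(substr(ref$sequences[["chrII"]], 1, 600),
                      substr(src, 801, 2000)))

  # copy-neutral events conserve length and (double-stranded) composition:
  # a translocation moves bases verbatim; an inversion reverse-complements,
  # which preserves A+T and G+C totals
  base_tab <- function(s) {
    v <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    as.vector(v)
  }
  expect_equal(sum(nchar(tt$genome$sequences)), ref$total_length)
  expect_equal(base_tab(paste(tt$genome$sequences, collapse = "")),
               base_tab(paste(ref$sequences, collapse = "")))
  expect_equal(nchar(der), nchar(src))
  td <- base_tab(der); ts <- base_tab(src)
  expect_equal(td[1] + td[4], ts[1] + ts[4])  # A + T conserved
  expect_equal(td[2] + td[3], ts[2] + ts[3])  # C + G conserved

  # overlapping events are rejected
  expect_error(apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 100L, 300L), deletion("chrI", 250L, 400L)), cfg),
    "overlapping")
})

test_that("read simulation hits target coverage and is reproducible", {
  cfg <- sim_config(seed = 4L, lengths = c(chrI = 100000L), coverage = 20,
                    sub_rate = 0, indel_rate = 0)
  g <- simulate_genome(cfg)
  reads <- simulate_reads(g, cfg)
  expect_lt(abs(nrow(reads) - 20 * 100000 / 140) / (20 * 100000 / 140), 0.05)
  expect_true(all(abs(nchar(reads$seq) - 140) <= 10))

  # error-free reads are exact substrings (or reverse complements)
  idx <- c(1L, 50L, 200L)
  for (i in idx) {
    span <- substr(g$sequences[["chrI"]], reads$start[i] + 1L, reads$end[i])
    expect_equal(reads$seq[i],
                 if (reads$strand[i] == "+") span else revcomp(span))
  }

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, cfg), f1)
  write_fastq(simulate_reads(g, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mapper emulation places reads by their longer colinear piece", {
  cfg <- sim_config(seed = 6L, lengths = c(chrI = 5000L), coverage = 10,
                    sub_rate = 0, indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 2000L, 3000L)), cfg)
  der <- truth$genome

  # fully colinear read: single M run
  r_full <- data.frame(id = "full", seq = substr(der$sequences[["chrI"]], 101, 240),
                       lg = "chrI", start = 100L, end = 240L, strand = "+",
                       stringsAsFactors = FALSE)
  r_full$edits <- list(NULL)
  a <- emulate_mapping(r_full, ref, truth)
  expect_equal(a$cigar, "140M")
  expect_equal(a$start, 100L)
  expect_equal(a$strand, "+")

  # 90/50 split across the left inversion junction: clip at the breakpoint
  r_split <- data.frame(
    id = "split",
    seq = substr(der$sequences[["chrI"]], 2000 - 90 + 1, 2000 + 50),
    lg = "chrI", start = 2000L - 90L, end = 2000L + 50L, strand = "+",
    stringsAsFactors = FALSE)
  r_split$edits <- list(NULL)
  a2 <- emulate_mapping(r_split, ref, truth)
  expect_equal(a2$cigar, "90M50S")
  expect_equal(a2$start, 1910L)

  # 10/130 split: the 10 bp side is clipped, the 130 bp side anchors
  r_skew <- data.frame(
    id = "skew",
    seq = substr(der$sequences[["chrI"]], 2000 - 10 + 1, 2000 + 130),
    lg = "chrI", start = 2000L - 10L, end = 2000L + 130L, strand = "+",
    stringsAsFactors = FALSE)
  r_skew$edits <- list(NULL)
  a3 <- emulate_mapping(r_skew, ref, truth)
  ops <- parse_cigar_for_test(a3$cigar)
  expect_equal(ops$len[ops$op == "S"], 10L)
  expect_equal(ops$len[ops$op == "M"], 130L)

  # longer piece under the minimum seed: dropped as unmapped
  r_tiny <- data.frame(
    id = "tiny",
    seq = substr(der$sequences[["chrI"]], 1992, 2010),
    lg = "chrI", start = 1991L, end = 2010L, strand = "+",
    stringsAsFactors = FALSE)
  r_tiny$edits <- list(NULL)
  expect_equal(nrow(emulate_mapping(r_tiny, ref, truth)), 0L)
})

test_that("emulated soft-clip boundaries sit on truth breakpoints", {
  cfg <- sim_config(seed = 7L, lengths = c(chrI = 20000L), coverage = 15,
                    sub_rate = 0, indel_rate = 0, microindel_prob = 0.5,
                    microindel_max = 8L)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 6000L, 12000L)), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clipped <- aln[grepl("S", aln$cigar), , drop = FALSE]
  expect_gt(nrow(clipped), 0L)
  bp <- truth$breakpoints
  for (i in seq_len(nrow(clipped))) {
    ops <- parse_cigar_for_test(clipped$cigar[i])
    m_span <- sum(ops$len[ops$op %in% c("M", "D")])
    bounds <- c(clipped$start[i], clipped$start[i] + m_span)
    tol_i <- max(bp$microindel) + 1L
    near <- any(vapply(bounds, function(b) {
      any(abs(c(bp$pos_a, bp$pos_b) - b) <= tol_i)
    }, TRUE))
    expect_true(near, info = paste("read", clipped$read_id[i]))
  }
})

test_that("control sample crosses no breakpoints and has flat depth", {
  cfg <- sim_config(seed = 8L, lengths = c(chrI = 30000L), coverage = 20)
  ref <- simulate_genome(cfg)
  ctrl <- make_control(ref, cfg)
  # no clips beyond the split-read threshold (terminal 1 bp sequencing
  # indels may appear as tiny clips, as with a real mapper)
  expect_equal(nrow(extract_clipped(ctrl)), 0L)
  nd <- normalized_depth(compute_depth(ctrl, ref))
  mean_nd <- mean(nd$nd$chrI, na.rm = TRUE)
  expect_lt(abs(mean_nd - 1), 0.15)
  # same master seed: reproducible control
  expect_identical(make_control(ref, cfg), ctrl)
})

test_that("truth tables and manifests are written", {
  cfg <- sim_config(seed = 10L, lengths = c(chrI = 2000L))
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    deletion("chrI", 500L, 700L)), cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".json")
  write_truth_table(truth, tf)
  write_manifest(truth, mf)
  tb <- read.delim(tf)
  expect_equal(tb$pos_a, 500L)
  expect_equal(tb$pos_b, 700L)
  man <- jsonlite::read_json(mf)
  expect_equal(man$seed, 10L)
  expect_equal(man$plan[[1]]$type, "deletion")
})
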