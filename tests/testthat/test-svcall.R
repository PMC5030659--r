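# Split-read classification, control subtraction, candidate calling and
# depth filters.

test_that("classification agrees with the hand-derived geometry table", {
  cases <- classification_oracle_cases()
  for (i in seq_len(nrow(cases))) {
    sr <- make_sr(cases$seg5[i], cases$seg3[i], cases$diff_lg[i])
    expect_equal(classify_split_read(sr), cases$expected[i],
                 info = paste(cases$seg5[i], cases$seg3[i],
                              if (cases$diff_lg[i]) "diff" else "same"))
  }
  # spec-style spot checks
  sr_del <- data.frame(seg5_lg = "chrI", seg5_start = 1000L, seg5_end = 1090L,
                       seg5_strand = "+", seg3_lg = "chrI",
                       seg3_start = 5000L, seg3_end = 5050L,
                       seg3_strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_split_read(sr_del), "deletion")
  sr_inv <- sr_del; sr_inv$seg3_strand <- "-"
  expect_equal(classify_split_read(sr_inv), "inversion")
  sr_ti <- sr_inv; sr_ti$seg3_lg <- "chrII"
  expect_equal(classify_split_read(sr_ti), "translocational_inversion")

  ident <- sr_del
  ident$seg3_start <- ident$seg5_start; ident$seg3_end <- ident$seg5_end
  expect_error(classify_split_read(ident), "identical placements")
})

test_that("every split read gets exactly one of the five categories", {
  cfg <- sim_config(seed = 31L, lengths = c(chrI = 15000L, chrII = 12000L),
                    coverage = 12)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 4000L, 9000L),
    reciprocal_translocation("chrI", 12000L, "chrII", 6000L)), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clips <- extract_clipped(aln)
  srs <- classify_split_reads(build_split_reads(clips, realign_clips(clips, ref)))
  expect_true(all(srs$category %in% c("deletion", "insertion", "inversion",
                                      "translocation",
                                      "translocational_inversion")))
})

test_that("control subtraction removes only matching category and loci", {
  sr <- function(start3, cat_strand = "+", lg3 = "chrI") {
    data.frame(read_id = paste0("r", start3), clip_id = 1L,
               seg5_lg = "chrI", seg5_start = 1000L, seg5_end = 1090L,
               seg5_strand = "+", seg3_lg = lg3, seg3_start = start3,
               seg3_end = start3 + 50L, seg3_strand = cat_strand,
               gap = NA_integer_, score = 50, stringsAsFactors = FALSE)
  }
  case <- rbind(sr(5000L), sr(8000L))
  ctrl <- rbind(sr(5004L),              # same category, within tolerance
                sr(8000L, cat_strand = "-"))  # same loci, different category
  out <- subtract_control(case, ctrl, tol = 10L)
  expect_equal(out$seg3_start, 8000L)   # the matching one was removed

  # case-only split read is kept; identical split read is removed
  expect_equal(nrow(subtract_control(case, case, tol = 10L)), 0L)
  expect_equal(nrow(subtract_control(case, case[2, ], tol = 10L)), 1L)

  # outside tolerance: kept
  out2 <- subtract_control(case[1, ], rbind(sr(5020L)), tol = 10L)
  expect_equal(nrow(out2), 1L)
})

test_that("deletion calling needs strictly more than two common-gap reads", {
  del_sr <- function(id, d1 = 2000L, d2 = 2400L) {
    data.frame(read_id = id, clip_id = 1L,
               seg5_lg = "chrI", seg5_start = d1 - 90L, seg5_end = d1,
               seg5_strand = "+", seg3_lg = "chrI", seg3_start = d2,
               seg3_end = d2 + 50L, seg3_strand = "+",
               gap = d2 - d1, score = 50, stringsAsFactors = FALSE)
  }
  three <- rbind(del_sr("a"), del_sr("b"), del_sr("c"))
  cand <- call_deletions(three)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$support, 3L)
  expect_equal(cand$start, 2000L)
  expect_equal(cand$end, 2400L)

  expect_equal(nrow(call_deletions(three[1:2, ])), 0L)

  # four reads split over two distinct gaps (2 + 2): nothing is called
  spread <- rbind(del_sr("a"), del_sr("b"),
                  del_sr("c", 3000L, 3300L), del_sr("d", 3000L, 3300L))
  expect_equal(nrow(call_deletions(spread)), 0L)
})

test_that("a small inverted segment yields one local inversion candidate", {
  cfg <- sim_config(seed = 33L, lengths = c(chrI = 20000L), coverage = 20)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 9000L, 9500L)), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clips <- extract_clipped(aln)
  srs <- classify_split_reads(build_split_reads(clips, realign_clips(clips, ref)))
  cand <- call_paired_variants(srs)
  loc <- cand[cand$kind == "local_inversion_or_inverted_insertion", ]
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$start - 9000L), 5L)
  expect_lt(abs(loc$end - 9500L), 5L)

  # single-sided evidence alone produces no paired candidate
  one_sided <- srs[srs$seg3_strand == "-" & srs$seg5_strand == "+", ]
  expect_equal(nrow(call_paired_variants(one_sided)[
    call_paired_variants(one_sided)$kind ==
      "local_inversion_or_inverted_insertion", ]), 0L)
})

test_that("a copied insertion yields del+ins clusters and one candidate", {
  cfg <- sim_config(seed = 34L, lengths = c(chrI = 20000L), coverage = 20)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    insertion("chrI", 15000L, copy_from = c(4000L, 4600L))), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clips <- extract_clipped(aln)
  srs <- classify_split_reads(build_split_reads(clips, realign_clips(clips, ref)))
  expect_setequal(unique(srs$category), c("deletion", "insertion"))
  cand <- call_paired_variants(srs)
  ins <- cand[cand$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_lt(abs(ins$start - 4000L), 5L)       # source region
  expect_lt(abs(ins$end - 4600L), 5L)
  expect_lt(abs(ins$partner_pos - 15000L), 5L)  # target locus
})

test_that("complex-candidate support filtering is strict at ten reads", {
  mk <- function(kind, support) {
    candidate_row_for_test(kind, support)
  }
  cands <- rbind(mk("insertion", 9L), mk("insertion", 10L),
                 mk("deletion", 3L))
  out <- filter_complicated(cands, 10L)
  expect_equal(out$status, c("removed_support", "kept", "kept"))
})

test_that("normalized depth masks regions at depth <= 1", {
  ref <- reference_genome(c(chrI = strrep("A", 100)))
  aln <- data.frame(read_id = sprintf("r%d", 1:20), lg = "chrI", start = 0L,
                    strand = "+", cigar = "50M", seq = strrep("A", 50),
                    stringsAsFactors = FALSE)
  d <- compute_depth(aln, ref)
  expect_equal(d$coverage, 10)          # 20 * 50 / 100
  nd <- normalized_depth(d)
  expect_equal(nd$nd$chrI[1], 2)        # depth 20 / coverage 10
  expect_true(all(is.na(nd$nd$chrI[51:100])))   # depth 0: unmapped

  aln1 <- aln[1, ]
  d1 <- compute_depth(aln1, ref)
  nd1 <- normalized_depth(d1)
  expect_true(all(is.na(nd1$nd$chrI)))  # depth 1 is NOT a mapped region
})

test_that("depth ratio reflects copy number in simulation", {
  cfg <- sim_config(seed = 36L, lengths = c(chrI = 30000L), coverage = 20)
  ref <- simulate_genome(cfg)
  ctrl <- make_control(ref, cfg)
  nd_ctrl <- normalized_depth(compute_depth(ctrl, ref))

  # identical samples: DR ~ 1 everywhere mapped
  dr_same <- depth_ratio(nd_ctrl, nd_ctrl)
  expect_equal(mean(dr_same$chrI, na.rm = TRUE), 1)

  # tandem duplication in the case: DR ~ 2 over the duplicated region
  truth <- apply_rearrangements(ref, rearrangement_plan(
    duplication("chrI", 10000L, 14000L, copies = 2L)), cfg)
  case <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  nd_case <- normalized_depth(compute_depth(case, ref))
  dr <- depth_ratio(nd_case, nd_ctrl)
  dup_dr <- mean(dr$chrI[10500:13500], na.rm = TRUE)
  flank_dr <- mean(dr$chrI[c(1000:9000, 15000:29000)], na.rm = TRUE)
  expect_lt(abs(dup_dr - 2), 0.3)
  expect_lt(abs(flank_dr - 1), 0.15)

  # hemizygous-style case (half derived-deleted, half reference): DR ~ 0.5
  cfg_half <- sim_config(seed = 37L, lengths = c(chrI = 30000L), coverage = 10)
  truth_del <- apply_rearrangements(ref, rearrangement_plan(
    deletion("chrI", 18000L, 22000L)), cfg_half)
  half1 <- emulate_mapping(simulate_reads(truth_del$genome, cfg_half, tag = "h1"),
                           ref, truth_del)
  half2 <- make_control(ref, cfg_half, tag = "h2")
  nd_het <- normalized_depth(compute_depth(rbind(half1, half2), ref))
  dr_het <- depth_ratio(nd_het, nd_ctrl)
  expect_lt(abs(mean(dr_het$chrI[18500:21500], na.rm = TRUE) - 0.5), 0.12)
})

test_that("depth-ratio thresholds remove deletions and relabel insertions", {
  dr <- list(chrI = rep(NA_real_, 3000))
  dr$chrI[1:3000] <- 1
  dr$chrI[101:200] <- 0.8    # deletion candidate region, too high
  dr$chrI[301:400] <- 0.5
  dr$chrI[501:600] <- 2.0
  dr$chrI[701:800] <- 3.0
  cands <- rbind(
    candidate_row_for_test("deletion", 5L, start = 100L, end = 200L),
    candidate_row_for_test("deletion", 5L, start = 300L, end = 400L),
    candidate_row_for_test("insertion", 12L, start = 500L, end = 600L),
    candidate_row_for_test("insertion", 12L, start = 700L, end = 800L)
  )
  out <- apply_depth_filters(cands, dr)
  expect_equal(out$status[1], "removed_depth")   # DR 0.8 > 0.75
  expect_equal(out$status[2], "kept")            # DR 0.5
  expect_equal(out$kind[3], "duplication")       # DR 2.0 > 1.75
  expect_equal(out$kind[4], "multiplication")    # DR 3.0 > 2.5
  expect_equal(out$status[3:4], c("kept", "kept"))

  # undefined DR: kept but flagged
  dr_na <- list(chrI = rep(NA_real_, 3000))
  out_na <- apply_depth_filters(
    candidate_row_for_test("deletion", 5L, start = 100L, end = 200L), dr_na)
  expect_equal(out_na$status, "kept")
  expect_equal(out_na$note, "DR unavailable")
})

test_that("filters are monotone in their thresholds", {
  cfg <- sim_config(seed = 38L, lengths = c(chrI = 20000L), coverage = 20)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    insertion("chrI", 15000L, copy_from = c(4000L, 4600L))), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clips <- extract_clipped(aln)
  srs <- classify_split_reads(build_split_reads(clips, realign_clips(clips, ref)))
  cand <- call_paired_variants(srs)
  kept_at <- function(min_reads) {
    sum(filter_complicated(cand, min_reads)$status == "kept")
  }
  thresholds <- c(1L, 5L, 10L, 20L, 50L)
  counts <- vapply(thresholds, kept_at, 1L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("variant reports round-trip as TSV and emit valid VCF", {
  cands <- rbind(
    candidate_row_for_test("deletion", 5L, start = 100L, end = 200L),
    candidate_row_for_test("inversion_breakpoint_pair", 20L,
                           start = 1000L, end = 2000L),
    candidate_row_for_test("translocation_breakpoint_pair", 20L,
                           start = 500L, end = 500L,
                           partner_lg = "chrII", partner_pos = 700L),
    candidate_row_for_test("insertion", 4L, start = 300L, end = 380L,
                           status = "removed_support")
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_report(cands, tsv, "tsv")
  back <- read_variant_table(tsv)
  expect_equal(back$kind, cands$kind)
  expect_equal(back$start, cands$start)
  expect_equal(back$status, cands$status)
  expect_equal(back$read_ids, cands$read_ids)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  ref <- reference_genome(c(chrI = strrep("ACGT", 1000),
                            chrII = strrep("AC", 500)))
  write_variant_report(cands, vcf, "vcf", ref = ref)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  # kept candidates only: DEL + INV + two mated BND lines
  expect_equal(length(body), 4L)
  expect_true(any(grepl("SVTYPE=DEL", body)))
  expect_true(any(grepl("SVTYPE=INV", body)))
  expect_equal(sum(grepl("SVTYPE=BND", body)), 2L)
  expect_true(any(grepl("MATEID=bnd_", body)))

  # empty candidate set: valid header-only outputs
  write_variant_report(empty_candidates_for_test(), vcf, "vcf", ref = ref)
  expect_false(any(!startsWith(readLines(vcf), "#")))
  write_variant_report(empty_candidates_for_test(), tsv, "tsv")
  expect_equal(nrow(read_variant_table(tsv)), 0L)
})
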