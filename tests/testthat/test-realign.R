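# Clip harvesting, k-mer seeding, Smith-Waterman extension and split-read
# assembly.

test_that("clip extraction applies the strict >20 bp rule", {
  mk_aln <- function(cigar, seq) {
    data.frame(read_id = "r", lg = "chrI", start = 1000L, strand = "+",
               cigar = cigar, seq = seq, stringsAsFactors = FALSE)
  }
  seg <- extract_clipped(mk_aln("90M50S", strrep("A", 140)))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$side, "right")
  expect_equal(seg$anchor_start, 1000L)
  expect_equal(seg$anchor_end, 1090L)
  expect_equal(nchar(seg$clip_seq), 50L)

  # exactly 20 bases is NOT longer than 20: discarded
  expect_equal(nrow(extract_clipped(mk_aln("20S120M", strrep("C", 140)))), 0L)
  expect_equal(nrow(extract_clipped(mk_aln("21S119M", strrep("C", 140)))), 1L)

  # both sides clipped: two segments from one read
  two <- extract_clipped(mk_aln("30S80M30S", strrep("G", 140)))
  expect_equal(nrow(two), 2L)
  expect_setequal(two$side, c("left", "right"))
})

test_that("query sets contain all 16-mers and their complements", {
  clip <- "AACCGGTTACGTAGCTAGCTT"            # 21 bases, all 16-mers distinct
  qs <- build_query_set(clip)
  expect_equal(sum(qs$strand == "+"), 6L)   # L - 15
  expect_equal(sum(qs$strand == "-"), 6L)
  expect_true(all(nchar(qs$query) == 16L))
  expect_true(all(qs$query[qs$strand == "-"] %in%
                    revcomp(qs$query[qs$strand == "+"])))

  # palindromic clip: forward and complement query strings coincide
  pal16 <- "ACGTACGTACGTACGT"
  pal <- paste0(pal16, revcomp(pal16))
  qpal <- build_query_set(pal)
  expect_setequal(qpal$query[qpal$strand == "+"],
                  qpal$query[qpal$strand == "-"])

  # queries containing N are excluded
  qn <- build_query_set(paste0(strrep("A", 10), "N", strrep("C", 10)))
  expect_false(any(grepl("N", qn$query)))
  expect_equal(sum(qn$strand == "+"), 0L)   # every forward 16-mer covers the N

  expect_equal(substr(build_query_set(paste0(strrep("A", 16),
                                             "CCCCC"))$query[1], 1, 16),
               strrep("A", 16))
})

test_that("automaton hits equal a naive substring scan", {
  set.seed(123)
  g <- toy_genome(seed = 11L, lengths = c(chrI = 3000L, chrII = 2000L))
  # planted and random queries
  planted <- vapply(1:40, function(i) {
    lg <- sample(names(g$sequences), 1)
    p <- sample(nchar(g$sequences[[lg]]) - 16L, 1)
    substr(g$sequences[[lg]], p, p + 15L)
  }, "")
  random <- vapply(1:60, function(i) {
    paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")
  }, "")
  queries <- unique(c(planted, random))
  got <- find_perfect_matches(g, queries)
  want <- naive_search_oracle(g$sequences, queries)
  got <- got[order(got$lg, got$pos, got$query), c("query", "lg", "pos")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  # N in the genome matches nothing
  gn <- reference_genome(c(chrI = paste0("AAAA", "N", strrep("AAAA", 3))))
  expect_equal(nrow(find_perfect_matches(gn, strrep("A", 8))),
               nrow(naive_search_oracle(gn$sequences, strrep("A", 8))))
})

test_that("repeated patterns report every overlapping occurrence", {
  g <- reference_genome(c(chrI = strrep("AT", 20)))
  hits <- find_perfect_matches(g, "ATATATATATATATAT")
  expect_equal(hits$pos, as.integer(seq(0, 24, by = 2)))
  expect_equal(nrow(find_perfect_matches(g, "GGGGGGGGGGGGGGGG")), 0L)
})

test_that("Smith-Waterman matches the scoring contract and a DP oracle", {
  expect_equal(smith_waterman("ACGT", "ACGT")$score, 8)
  aln0 <- smith_waterman("AAAA", "TTTT")
  expect_equal(aln0$score, 0)
  expect_equal(aln0$a_end - aln0$a_start, 0L)

  set.seed(99)
  for (i in 1:60) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), replace = TRUE),
               collapse = "")
    expect_equal(smith_waterman(a, b)$score, sw_score_oracle(a, b),
                 info = paste(a, b))
    # symmetry
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
  a <- "GATTACAGATTACA"
  expect_equal(smith_waterman(a, a)$score, 2 * nchar(a))
  # N is always a mismatch, even against N
  expect_equal(smith_waterman("ANA", "ANA")$score,
               sw_score_oracle("ANA", "ANA"))
})

test_that("clip realignment finds the source locus and honors tie-breaks", {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  unit <- substr(base, 1001, 1050)  # 50 bp that also appears as a repeat
  g <- reference_genome(c(
    chrI = paste0(substr(base, 1, 2000), unit, substr(base, 2051, 4000))
  ))
  # the 50-mer now occurs at 1000 and 2000
  seg <- list(clip_seq = unit, anchor_lg = "chrI", anchor_start = 900L,
              anchor_end = 990L)
  hit <- realign_clip(seg, g)
  expect_equal(hit$start, 1000L)          # nearest to the anchor
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, 2 * nchar(unit))

  seg2 <- list(clip_seq = unit, anchor_lg = "chrI", anchor_start = 2100L,
               anchor_end = 2190L)
  expect_equal(realign_clip(seg2, g)$start, 2000L)

  # absent clip: no acceptable placement
  set.seed(8)
  alien <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  expect_null(realign_clip(list(clip_seq = alien, anchor_lg = "chrI",
                                anchor_start = 0L, anchor_end = 90L),
                           reference_genome(c(chrI = strrep("AC", 2000)))))

  # strand coherence: the reverse complement realigns to the same locus
  rc_hit <- realign_clip(list(clip_seq = revcomp(unit), anchor_lg = "chrI",
                              anchor_start = 900L, anchor_end = 990L), g)
  expect_equal(rc_hit$start, hit$start)
  expect_equal(rc_hit$strand, "-")
})

test_that("any exactly occurring clip of >=16 bp is seeded and found", {
  g <- toy_genome(seed = 13L, lengths = c(chrI = 8000L))
  set.seed(13)
  for (i in 1:20) {
    len <- sample(21:60, 1)
    p <- sample(8000L - len, 1)
    clip <- substr(g$sequences[["chrI"]], p, p + len - 1L)
    res <- realign_clip(list(clip_seq = clip, anchor_lg = "chrI",
                             anchor_start = 0L, anchor_end = 50L), g)
    expect_false(is.null(res))
    expect_equal(res$score, 2 * len)
  }
})

test_that("split reads order placements by their position in the read", {
  clips <- data.frame(
    clip_id = 1:2, read_id = c("r1", "r2"), side = c("right", "left"),
    clip_seq = strrep("A", 50),
    anchor_lg = "chrI", anchor_start = 1000L, anchor_end = 1090L,
    anchor_strand = "+", stringsAsFactors = FALSE
  )
  re <- data.frame(clip_id = 1:2, lg = "chrI", start = 5000L, end = 5050L,
                   strand = "+", score = 100, stringsAsFactors = FALSE)
  srs <- build_split_reads(clips, re)
  expect_equal(nrow(srs), 2L)
  r1 <- srs[srs$read_id == "r1", ]  # right clip: anchor is the 5' region
  expect_equal(r1$seg5_start, 1000L)
  expect_equal(r1$seg3_start, 5000L)
  expect_equal(r1$gap, 5000L - 1090L)
  r2 <- srs[srs$read_id == "r2", ]  # left clip: realigned locus is 5'
  expect_equal(r2$seg5_start, 5000L)
  expect_equal(r2$seg3_start, 1000L)

  # colinear realignment (zero gap, same sense) is not a split read
  re_col <- data.frame(clip_id = 1L, lg = "chrI", start = 1090L, end = 1140L,
                       strand = "+", score = 100, stringsAsFactors = FALSE)
  expect_equal(nrow(build_split_reads(clips[1, ], re_col)), 0L)
})

test_that("reads across a simulated inversion junction become split reads", {
  cfg <- sim_config(seed = 21L, lengths = c(chrI = 20000L), coverage = 15,
                    sub_rate = 0.005)
  ref <- simulate_genome(cfg)
  truth <- apply_rearrangements(ref, rearrangement_plan(
    inversion("chrI", 8000L, 14000L)), cfg)
  aln <- emulate_mapping(simulate_reads(truth$genome, cfg), ref, truth)
  clips <- extract_clipped(aln)
  srs <- build_split_reads(clips, realign_clips(clips, ref))
  expect_gt(nrow(srs), 5L)
  srs <- classify_split_reads(srs)
  expect_true(all(srs$category == "inversion"))
  ends <- sort(unique(c(srs$seg5_start, srs$seg5_end,
                        srs$seg3_start, srs$seg3_end)))
  expect_true(any(abs(ends - 8000L) <= 2L))
  expect_true(any(abs(ends - 14000L) <= 2L))
})
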