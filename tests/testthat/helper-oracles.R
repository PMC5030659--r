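# Independent oracles and small fixture builders shared across tests.

# Brute-force Smith-Waterman score (independent of the package's C++ core):
# plain dynamic-programming matrix in R, score only.
sw_score_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + sub,
                               H[i, j + 1L] + gap, H[i + 1L, j] + gap)
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

# Naive exact-substring scan (overlapping occurrences), independent of the
# Aho-Corasick automaton.
naive_search_oracle <- function(genome_seqs, queries) {
  rows <- list()
  for (lg in names(genome_seqs)) {
    s <- genome_seqs[[lg]]
    n <- nchar(s)
    for (q in queries) {
      k <- nchar(q)
      if (k > n) next
      starts <- seq_len(n - k + 1L)
      hit <- substring(s, starts, starts + k - 1L) == q
      for (p in starts[hit]) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, lg = lg, pos = p - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(), lg = character(),
                      pos = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$lg, out$pos, out$query), , drop = FALSE]
}

# Hand-derived split-read classification table: placements A = [100,150) and
# B = [200,250), every strand/order/linkage-group combination. Derived once
# by tracing which flanks each junction joins; frozen here as the oracle.
classification_oracle_cases <- function() {
  same <- data.frame(
    seg5 = c("A+", "B+", "A+", "A-", "A-", "B-", "B-", "B+"),
    seg3 = c("B+", "A+", "B-", "B+", "B-", "A-", "A+", "A-"),
    expected = c("deletion", "insertion", "inversion", "inversion",
                 "insertion", "deletion", "inversion", "inversion"),
    diff_lg = FALSE, stringsAsFactors = FALSE
  )
  diff <- data.frame(
    seg5 = c("A+", "A-", "A+", "A-"),
    seg3 = c("B+", "B-", "B-", "B+"),
    expected = c("translocation", "translocation",
                 "translocational_inversion", "translocational_inversion"),
    diff_lg = TRUE, stringsAsFactors = FALSE
  )
  rbind(same, diff)
}

make_sr <- function(seg5, seg3, diff_lg) {
  iv <- list(A = c(100L, 150L), B = c(200L, 250L))
  dec <- function(code, which_seg) {
    nm <- substr(code, 1L, 1L)
    list(lg = if (diff_lg && nm == "B") "chrII" else "chrI",
         start = iv[[nm]][1L], end = iv[[nm]][2L],
         strand = substr(code, 2L, 2L))
  }
  s5 <- dec(seg5); s3 <- dec(seg3)
  data.frame(read_id = "r", clip_id = 1L,
             seg5_lg = s5$lg, seg5_start = s5$start, seg5_end = s5$end,
             seg5_strand = s5$strand,
             seg3_lg = s3$lg, seg3_start = s3$start, seg3_end = s3$end,
             seg3_strand = s3$strand, gap = NA_integer_, score = 40,
             stringsAsFactors = FALSE)
}

# Tiny deterministic genome for unit fixtures.
toy_genome <- function(seed = 42L, lengths = c(chrI = 5000L, chrII = 4000L),
                       gc = 0.4) {
  cfg <- sim_config(seed = seed, lengths = lengths, gc_fraction = gc)
  simulate_genome(cfg)
}

# Build a candidate-table row matching the package's candidate schema.
candidate_row_for_test <- function(kind, support, lg = "chrI", start = 0L,
                                   end = 100L, partner_lg = NA_character_,
                                   partner_pos = NA_integer_,
                                   status = "kept") {
  df <- data.frame(kind = kind, lg = lg, start = as.integer(start),
                   end = as.integer(end), partner_lg = partner_lg,
                   partner_pos = as.integer(partner_pos),
                   support = as.integer(support), dr = NA_real_,
                   status = status, note = "", stringsAsFactors = FALSE)
  df$read_ids <- list(sprintf("%s_read_%d", kind, seq_len(support)))
  df
}

empty_candidates_for_test <- function() {
  candidate_row_for_test("deletion", 1L)[0, ]
}

# Minimal independent CIGAR tokenizer for test-side bookkeeping.
parse_cigar_for_test <- function(cg) {
  toks <- regmatches(cg, gregexpr("\\d+[MIDSH]", cg))[[1]]
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(sub("[MIDSH]$", "", toks)),
             stringsAsFactors = FALSE)
}

# Path to a bundled extdata file of the installed package.
extfile <- function(name) {
  system.file("extdata", name, package = "balancerSV", mustWork = TRUE)
}
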