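test_that("six-frame translation produces the expected frames and errors", {
  fr <- six_frame_translate(c(t1 = "ATGAAA"))
  expect_equal(nrow(fr), 6)
  expect_equal(fr$peptide[fr$frame == "+1"], "MK")
  expect_equal(fr$peptide[fr$frame == "-1"], "FH") # revcomp TTTCAT
  expect_equal(six_frame_translate(c(t = "ATGTAA"))$peptide[1], "M*")
  expect_error(six_frame_translate(c(t = "AT")), "shorter")
})

test_that("frame coordinate arithmetic maps residues to codon intervals", {
  # residue 1 of frame +2 occupies nt 2-4
  fr <- six_frame_translate(c(t1 = "AATGAAACC"))
  h <- search_patterns(fr, "MK", min_pattern_len = 2)
  expect_equal(h$nt_start, 2)
  expect_equal(h$nt_end, 7)
  expect_equal(h$frame, "+2")
})

test_that("pattern validation rejects stops, X, and short patterns", {
  fr <- six_frame_translate(c(t1 = "ATGAAAGGG"))
  expect_error(search_patterns(fr, "M*K"), "\\*")
  expect_error(search_patterns(fr, "MXK"), "X")
  expect_error(search_patterns(fr, "MK"), "shorter than 3")
  expect_error(search_patterns(fr, character(0)), "no patterns")
})

test_that("search equals the naive six-frame scan on random transcriptomes", {
  set.seed(107)
  patterns <- c("IFGGLPPP", "MKL", "GGA", "PPIF")
  for (rep in 1:30) {
    n_tx <- sample(1:5, 1)
    tx <- setNames(
      vapply(seq_len(n_tx), function(i) random_nt_string(sample(60:600, 1)),
             character(1)),
      paste0("t", seq_len(n_tx)))
    hits <- search_patterns(six_frame_translate(tx), patterns)
    for (id in names(tx)) {
      got <- hits[hits$transcript_id == id,
                  c("strand", "aa_start", "pattern")]
      frame_off <- as.integer(substr(hits$frame[hits$transcript_id == id],
                                     2, 2)) - 1
      got$offset <- frame_off
      got <- got[order(got$strand, got$offset, got$aa_start, got$pattern),
                 c("strand", "offset", "aa_start", "pattern")]
      want <- oracle_six_frame_hits(tx[[id]], patterns)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("overlapping occurrences are all reported", {
  # AAAA AAAA ... encodes KKKK...; pattern KKK occurs at every offset
  tx <- c(t1 = strrep("AAA", 6))
  hits <- search_patterns(six_frame_translate(tx), "KKK")
  plus1 <- hits[hits$frame == "+1", ]
  expect_equal(plus1$aa_start, 1:4)
})

test_that("reverse-complementing transcripts flips strands, preserves counts", {
  set.seed(108)
  g <- planted_gene(strand = "+")
  fx <- generate_fixture(fixture_spec(n_transcripts = 3, genes = list(g),
                                      seed = 31))
  fwd <- search_patterns(six_frame_translate(fx$transcripts),
                         ring_openings(hb_core))
  flipped <- vapply(fx$transcripts, revcomp, character(1))
  rev_ <- search_patterns(six_frame_translate(flipped),
                          ring_openings(hb_core))
  expect_equal(nrow(fwd), nrow(rev_))
  for (id in names(fx$transcripts)) {
    L <- nchar(fx$transcripts[[id]])
    f <- fwd[fwd$transcript_id == id, ]
    r <- rev_[rev_$transcript_id == id, ]
    # each hit maps to the mirrored interval on the opposite strand
    key_f <- paste(f$pattern, ifelse(f$strand == "+", "-", "+"),
                   L - f$nt_end + 1, L - f$nt_start + 1)
    key_r <- paste(r$pattern, r$strand, r$nt_start, r$nt_end)
    expect_setequal(key_r, key_f)
  }
})

test_that("mine recovers planted genes exactly and reports Table-style counts", {
  fx <- generate_fixture(fixture_spec(n_transcripts = 20, seed = 7))
  res <- mine(fx$transcripts, hb_peptide())
  expect_equal(nrow(res$candidates), 5)
  shared <- intersect(names(res$candidates), names(fx$truth))
  got <- res$candidates[order(res$candidates$transcript_id), shared]
  want <- fx$truth[order(fx$truth$transcript_id), shared]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  counts <- res$pattern_counts
  expect_equal(counts$n_transcripts[counts$pattern == "IFGGLPPP"], 5)
  expect_true(all(counts$n_hits[counts$pattern != "IFGGLPPP"] == 0))
})

test_that("mine on an empty or decoy-only transcriptome finds nothing", {
  res <- mine(character(0), hb_peptide())
  expect_equal(nrow(res$hits), 0)
  expect_equal(nrow(res$candidates), 0)
  fx <- generate_fixture(fixture_spec(n_transcripts = 8, genes = list(),
                                      seed = 13))
  res2 <- mine(fx$transcripts, hb_peptide())
  expect_equal(nrow(res2$candidates), 0)
  expect_true(all(res2$pattern_counts$n_hits == 0))
})

test_that("no reported hit window contains a stop codon", {
  fx <- generate_fixture(fixture_spec(n_transcripts = 10, seed = 23))
  res <- mine(fx$transcripts, hb_peptide())
  fr <- six_frame_translate(fx$transcripts)
  for (i in seq_len(nrow(res$hits))) {
    h <- res$hits[i, ]
    pep <- fr$peptide[fr$transcript_id == h$transcript_id &
                        fr$frame == h$frame]
    window <- substr(pep, h$aa_start, h$aa_start + nchar(h$pattern) - 1)
    expect_false(grepl("*", window, fixed = TRUE))
    expect_equal(window, h$pattern)
  }
})
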