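test_that("ORF extension on the prePhHB-like transcript matches the published gene model", {
  fx <- prephb_gene_fixture()
  res <- mine(fx$transcripts, hb_peptide())
  expect_equal(nrow(res$candidates), 1)
  cand <- res$candidates[1, ]
  expect_equal(cand$precursor_len, 35)
  expect_equal(cand$cds_end - cand$cds_start + 1, 108)
  expect_equal(cand$precursor, prephb_precursor())
  expect_equal(cand$utr5_len, 63)
  expect_equal(cand$utr3_len, 152)
  expect_equal(cand$polya_signal_count, 1)
  expect_equal(cand$polya_tail_len, 28)
})

test_that("hits without a usable start or stop are rejected with a reason", {
  # core with an in-frame stop immediately upstream and no ATG: no-start
  core_cds <- reverse_translate(hb_core)
  t1 <- c(x = paste0("GGGGGGTAA", core_cds, "TAAGGG"))
  r1 <- mine(t1, hb_peptide())
  expect_equal(nrow(r1$candidates), 0)
  expect_true(all(r1$rejected$reason == "no-start"))

  # ATG upstream but transcript ends before any in-frame stop: no-stop
  t2 <- c(x = paste0("ATG", core_cds, "GG"))
  r2 <- mine(t2, hb_peptide())
  expect_equal(nrow(r2$candidates), 0)
  expect_true(all(r2$rejected$reason == "no-stop"))
})

test_that("the ORF start is the furthest ATG after the last in-frame stop", {
  core_cds <- reverse_translate(hb_core)
  # stop, then two in-frame ATGs before the core: the earlier one wins
  tx <- c(x = paste0("TAA", "ATG", "GCC", "ATG", core_cds, "TAA"))
  res <- mine(tx, hb_peptide())
  expect_equal(res$candidates$precursor[1],
               paste0("MAM", hb_core))
  # with a stop between them, only the later ATG is usable
  tx2 <- c(x = paste0("TAA", "ATG", "TAA", "ATG", core_cds, "TAA"))
  res2 <- mine(tx2, hb_peptide())
  expect_equal(res2$candidates$precursor[1], paste0("M", hb_core))
})

test_that("segmentation splits the published precursor 13/8/14", {
  seg <- segment_precursor(prephb_precursor(), hb_core)
  expect_equal(nchar(seg$leader), 13)
  expect_equal(seg$core_span, c(14, 21))
  expect_equal(nchar(seg$follower), 14)
  expect_equal(paste0(seg$leader, seg$core, seg$follower),
               prephb_precursor())
  expect_false(seg$multiple)
})

test_that("segmentation handles degenerate and repeated cores", {
  seg <- segment_precursor(hb_core, hb_core)
  expect_equal(seg$leader, "")
  expect_equal(seg$follower, "")
  two <- paste0("MA", hb_core, "KK", hb_core, "V")
  seg2 <- segment_precursor(two, hb_core)
  expect_equal(seg2$core_span, c(3, 10))
  expect_true(seg2$multiple)
  expect_error(segment_precursor("MAAAV", hb_core), "not found")
})

test_that("mRNA feature annotation separates UTRs, signal, and poly(A) tail", {
  fx <- prephb_gene_fixture()
  sense <- fx$transcripts[[1]]
  feats <- annotate_mrna_features(sense, 64, 171)
  expect_equal(feats$utr5_len, 63)
  expect_equal(feats$utr3_len, 152)
  expect_length(feats$polya_signal_positions, 1)
  expect_equal(feats$polya_tail_len, 28)

  # transcript ending exactly at the stop codon
  cds <- paste0("ATG", reverse_translate(hb_core), "TAA")
  f2 <- annotate_mrna_features(cds, 1, nchar(cds))
  expect_equal(f2$utr3_len, 0)
  expect_equal(f2$polya_tail_len, 0)
  expect_length(f2$polya_signal_positions, 0)

  # two signal copies are both reported at their UTR offsets
  t3 <- paste0(cds, "CC", "AATAAAA", "GG", "AATAAAA", "C")
  f3 <- annotate_mrna_features(t3, 1, nchar(cds))
  expect_equal(f3$polya_signal_positions, c(3, 12))

  expect_error(annotate_mrna_features("ATGTAA", 1, 9), "outside")
})

test_that("feature lengths partition the transcript", {
  fx <- generate_fixture(fixture_spec(n_transcripts = 6,
                                      genes = list(planted_gene(),
                                                   planted_gene(strand = "-")),
                                      seed = 41))
  res <- mine(fx$transcripts, hb_peptide())
  for (i in seq_len(nrow(res$candidates))) {
    cand <- res$candidates[i, ]
    L <- nchar(fx$transcripts[[cand$transcript_id]])
    cds_len <- cand$cds_end - cand$cds_start + 1
    expect_equal(cand$utr5_len + cds_len + cand$utr3_len +
                   cand$polya_tail_len, L)
    expect_equal(cds_len %% 3, 0)
    expect_equal(cds_len, 3 * (cand$precursor_len + 1))
    expect_false(grepl("*", cand$precursor, fixed = TRUE))
  }
})

test_that("minus-strand candidates report forward-strand CDS coordinates", {
  g <- planted_gene(strand = "-")
  fx <- generate_fixture(fixture_spec(n_transcripts = 1, genes = list(g),
                                      seed = 19))
  res <- mine(fx$transcripts, hb_peptide())
  cand <- res$candidates[1, ]
  expect_equal(cand$strand, "-")
  expect_equal(cand$cds_start, fx$truth$cds_start[1])
  expect_equal(cand$cds_end, fx$truth$cds_end[1])
  # the CDS read off the minus strand translates to the precursor
  s <- fx$transcripts[[1]]
  cds <- revcomp(substr(s, cand$cds_start, cand$cds_end))
  expect_equal(translate_nt(cds), paste0(cand$precursor, "*"))
})
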