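#' Extend a core-peptide hit to a full open reading frame
#'
#' Scans in frame upstream from the matched core for the furthest ATG not
#' preceded (in frame, since the last stop or the sequence start) by
#' another stop -- the standard maximal-ORF convention -- and downstream
#' for the first in-frame stop. Minus-strand hits are resolved on the
#' reverse complement; the reported CDS interval is in forward-strand
#' transcript coordinates.
#'
#' @param hit One row of the hit table from [search_patterns()] (or an
#'   equivalent list with `pattern`, `frame`, `strand`, `aa_start`,
#'   `transcript_id`).
#' @param transcript The transcript's nucleotide sequence.
#' @return List with either `candidate` (a `precursor_candidate` list) and
#'   `reason = NULL`, or `candidate = NULL` and `reason` one of
#'   `"no-start"`, `"no-stop"`.
#' @export
extend_to_orf <- function(hit, transcript) {
  s <- norm_nt(transcript)
  strand <- as.character(hit$strand)
  # frame may arrive as "+2"/"-2" or (via TSV round trips) as 2/-2
  offset <- abs(as.integer(as.character(hit$frame))) - 1L
  sense <- if (strand == "+") s else revcomp(s)
  pep <- translate_nt(sense, offset)
  chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
  core_aa <- as.integer(hit$aa_start)
  core_len <- nchar(hit$pattern)
  if (substr(pep, core_aa, core_aa + core_len - 1L) != hit$pattern) {
    stop("hit does not match transcript frame", call. = FALSE)
  }
  stops <- which(chars == "*")
  prev <- stops[stops < core_aa]
  win_lo <- if (length(prev)) max(prev) + 1L else 1L
  ms <- which(chars == "M")
  ms <- ms[ms >= win_lo & ms <= core_aa]
  if (length(ms) == 0L) return(list(candidate = NULL, reason = "no-start"))
  start_aa <- min(ms)
  nxt <- stops[stops >= core_aa + core_len]
  if (length(nxt) == 0L) return(list(candidate = NULL, reason = "no-stop"))
  stop_aa <- min(nxt)

  precursor <- substr(pep, start_aa, stop_aa - 1L)
  s1 <- offset + 3L * (start_aa - 1L) + 1L # CDS on sense strand, incl. stop
  e1 <- offset + 3L * stop_aa
  feats <- annotate_mrna_features(sense, s1, e1)
  seg <- segment_precursor(precursor, hit$pattern)
  tlen <- nchar(s)
  cds <- if (strand == "+") c(s1, e1) else c(tlen - e1 + 1L, tlen - s1 + 1L)

  cand <- list(
    transcript_id = as.character(hit$transcript_id),
    strand = strand,
    cds_start = cds[1L], cds_end = cds[2L],
    cds_seq = substr(sense, s1, e1),
    precursor = precursor,
    pattern = as.character(hit$pattern),
    core_start = seg$core_span[1L], core_end = seg$core_span[2L],
    leader = seg$leader, core = seg$core, follower = seg$follower,
    core_multiple = seg$multiple,
    utr5_len = feats$utr5_len, utr3_len = feats$utr3_len,
    polya_signal_positions = feats$polya_signal_positions,
    polya_tail_len = feats$polya_tail_len)
  class(cand) <- "precursor_candidate"
  list(candidate = cand, reason = NULL)
}

candidate_row <- function(cand) {
  data.frame(
    transcript_id = cand$transcript_id, strand = cand$strand,
    cds_start = cand$cds_start, cds_end = cand$cds_end,
    precursor = cand$precursor, precursor_len = nchar(cand$precursor),
    pattern = cand$pattern,
    core_start = cand$core_start, core_end = cand$core_end,
    leader = cand$leader, core = cand$core, follower = cand$follower,
    utr5_len = cand$utr5_len, utr3_len = cand$utr3_len,
    polya_signal_count = length(cand$polya_signal_positions),
    polya_tail_len = cand$polya_tail_len,
    stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(transcript_id = character(0), strand = character(0),
             cds_start = integer(0), cds_end = integer(0),
             precursor = character(0), precursor_len = integer(0),
             pattern = character(0), core_start = integer(0),
             core_end = integer(0), leader = character(0),
             core = character(0), follower = character(0),
             utr5_len = integer(0), utr3_len = integer(0),
             polya_signal_count = integer(0), polya_tail_len = integer(0),
             stringsAsFactors = FALSE)
}

#' Segment a precursor into leader, core and recognition sequence
#'
#' The core span is the first occurrence of the core pattern (1-based
#' inclusive residue positions); the prefix is the leader peptide and the
#' suffix the follower (called the recognition sequence in orbitide
#' precursors). Multiple core occurrences are flagged.
#'
#' @param precursor Precursor peptide string (no stops).
#' @param core_pattern Core peptide string; must occur in `precursor`.
#' @return List with `leader`, `core`, `follower`, `core_span`
#'   (`c(start, end)`), `multiple` (logical flag).
#' @export
segment_precursor <- function(precursor, core_pattern) {
  p <- norm_aa(precursor)
  core <- norm_aa(core_pattern)
  pos <- overlapping_starts(p, core)
  if (length(pos) == 0L) {
    stop("core pattern not found in precursor", call. = FALSE)
  }
  a <- pos[1L]
  b <- a + nchar(core) - 1L
  list(leader = substr(p, 1L, a - 1L),
       core = substr(p, a, b),
       follower = substr(p, b + 1L, nchar(p)),
       core_span = c(a, b),
       multiple = length(pos) > 1L)
}

#' Annotate mRNA features around a coding sequence
#'
#' Works on the sense (mRNA) strand. The poly(A) tail is the maximal run
#' of terminal A's (never extending into the CDS) and is detected first;
#' the 3' UTR is measured excluding it. Polyadenylation signals are exact
#' occurrences of the literal `AATAAAA` within the 3' UTR (tail excluded);
#' `signal = "AATAAA"` switches to the canonical hexamer.
#'
#' @param transcript Sense-strand nucleotide sequence.
#' @param cds_start,cds_end 1-based inclusive CDS interval (ATG through
#'   stop codon) within `transcript`.
#' @param signal Polyadenylation signal motif (default `"AATAAAA"`).
#' @return List with `utr5_len`, `utr3_len`, `polya_signal_positions`
#'   (1-based offsets within the 3' UTR), `polya_tail_len`.
#' @export
annotate_mrna_features <- function(transcript, cds_start, cds_end,
                                   signal = "AATAAAA") {
  s <- norm_nt(transcript)
  L <- nchar(s)
  if (cds_start < 1L || cds_end > L || cds_start > cds_end) {
    stop("CDS interval outside transcript", call. = FALSE)
  }
  utr5 <- cds_start - 1L
  tail_run <- nchar(s) - nchar(sub("A*$", "", s))
  tail_len <- min(tail_run, L - cds_end)
  utr3 <- L - cds_end - tail_len
  sig_pos <- integer(0)
  if (utr3 > 0L) {
    utr3_seq <- substr(s, cds_end + 1L, L - tail_len)
    sig_pos <- overlapping_starts(utr3_seq, signal)
  }
  list(utr5_len = utr5, utr3_len = utr3,
       polya_signal_positions = sig_pos, polya_tail_len = tail_len)
}
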