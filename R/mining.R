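#' Six-frame translation of transcripts
#'
#' Frames `+1,+2,+3` translate the forward strand at offsets 0,1,2;
#' frames `-1,-2,-3` translate the reverse complement at the same
#' offsets. Stops are retained as `*`.
#'
#' @param transcripts Named character vector of nucleotide sequences
#'   (ids as names), or a single unnamed sequence.
#' @return `data.frame` with one row per transcript/frame: columns
#'   `transcript_id`, `frame` (e.g. `"+2"`), `strand`, `offset`,
#'   `peptide`, `tlen` (transcript length in nt).
#' @export
six_frame_translate <- function(transcripts) {
  if (is.null(names(transcripts))) {
    if (length(transcripts) != 1L) {
      stop("multiple transcripts must be named", call. = FALSE)
    }
    names(transcripts) <- "seq1"
  }
  rows <- lapply(names(transcripts), function(id) {
    s <- norm_nt(transcripts[[id]])
    if (nchar(s) < 3L) {
      stop(sprintf("transcript '%s' is shorter than one codon", id),
           call. = FALSE)
    }
    rc <- revcomp(s)
    data.frame(
      transcript_id = id,
      frame = c("+1", "+2", "+3", "-1", "-2", "-3"),
      strand = rep(c("+", "-"), each = 3L),
      offset = rep(0:2, 2L),
      peptide = c(vapply(0:2, function(o) translate_nt(s, o), character(1)),
                  vapply(0:2, function(o) translate_nt(rc, o), character(1))),
      tlen = nchar(s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Forward-strand nt interval (1-based inclusive) of a run of residues in a
# frame. aa_start is 1-based within the frame peptide.
frame_nt_interval <- function(strand, offset, aa_start, aa_len, tlen) {
  s0 <- offset + 3L * (aa_start - 1L) # 0-based half-open on the read strand
  e0 <- s0 + 3L * aa_len
  if (strand == "+") c(s0 + 1L, e0) else c(tlen - e0 + 1L, tlen - s0)
}

# All (possibly overlapping) start positions of fixed pattern in text,
# 1-based. Patterns are plain residue strings, safe as a regex literal.
overlapping_starts <- function(text, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Exact multi-pattern search over frame translations
#'
#' Reports every occurrence of every pattern in every frame, overlapping
#' occurrences included. Matched windows are stop-free by construction
#' because patterns may not contain `*`. Minus-strand hits are reported in
#' forward-strand transcript coordinates with a strand flag.
#'
#' @param frames Output of [six_frame_translate()].
#' @param patterns Character vector of peptide patterns, or the
#'   `data.frame` from [ring_openings()] (its `sequence` column is used).
#' @param min_pattern_len Patterns shorter than this are rejected
#'   (default 3) to avoid meaningless hit floods.
#' @return `data.frame` with columns `pattern`, `transcript_id`, `frame`,
#'   `strand`, `aa_start` (1-based residue index in the frame peptide),
#'   `nt_start`, `nt_end` (1-based inclusive forward-strand coordinates),
#'   sorted by (transcript_id, frame, aa_start, pattern).
#' @export
search_patterns <- function(frames, patterns, min_pattern_len = 3L) {
  if (is.data.frame(patterns)) patterns <- patterns$sequence
  if (length(patterns) == 0L) stop("no patterns given", call. = FALSE)
  patterns <- vapply(patterns, norm_aa, character(1), USE.NAMES = FALSE)
  if (any(grepl("[X*]", patterns))) {
    stop("patterns must not contain '*' or 'X'", call. = FALSE)
  }
  if (any(nchar(patterns) < min_pattern_len)) {
    stop(sprintf("patterns shorter than %d residues are rejected",
                 min_pattern_len), call. = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    for (p in patterns) {
      starts <- overlapping_starts(fr$peptide, p)
      for (a in starts) {
        nt <- frame_nt_interval(fr$strand, fr$offset, a, nchar(p), fr$tlen)
        hits[[length(hits) + 1L]] <- data.frame(
          pattern = p, transcript_id = fr$transcript_id, frame = fr$frame,
          strand = fr$strand, aa_start = a,
          nt_start = nt[1L], nt_end = nt[2L], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(pattern = character(0), transcript_id = character(0),
                      frame = character(0), strand = character(0),
                      aa_start = integer(0), nt_start = integer(0),
                      nt_end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$transcript_id, out$frame, out$aa_start, out$pattern), ]
  rownames(out) <- NULL
  out
}

#' Screen a transcriptome for cyclic-peptide precursor genes
#'
#' The full screen: enumerate ring-openings of the query cyclic peptide,
#' search them as exact matches in six-frame translations of every
#' transcript, extend each hit to an open reading frame, and annotate
#' candidate precursors (leader/core/recognition-sequence architecture and
#' mRNA features). Per-pattern hit counts are tabulated in the style of a
#' ring-opening screening table (pattern, number of hits, number of
#' distinct transcripts).
#'
#' @param transcripts Named character vector of nucleotide sequences.
#' @param peptide Query [cyclic_peptide()] or peptide string.
#' @param include_reverse Screen reverse-orientation openings too
#'   (default `TRUE`).
#' @param min_pattern_len Passed to [search_patterns()].
#' @return Object of class `mine_result`: a list with `openings`, `hits`,
#'   `candidates` (one row per distinct ORF), `rejected` (hits that could
#'   not be extended, with reasons), and `pattern_counts`.
#' @export
mine <- function(transcripts, peptide, include_reverse = TRUE,
                 min_pattern_len = 3L) {
  openings <- ring_openings(peptide, include_reverse = include_reverse)
  empty_hits <- length(transcripts) == 0L
  if (!empty_hits) {
    frames <- six_frame_translate(transcripts)
    hits <- search_patterns(frames, openings, min_pattern_len)
  } else {
    hits <- search_patterns(
      data.frame(transcript_id = character(0), frame = character(0),
                 strand = character(0), offset = integer(0),
                 peptide = character(0), tlen = integer(0)),
      openings, min_pattern_len)
  }

  cands <- list()
  rejected <- list()
  if (nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      res <- extend_to_orf(h, transcripts[[h$transcript_id]])
      if (is.null(res$candidate)) {
        rejected[[length(rejected) + 1L]] <-
          cbind(h, reason = res$reason, stringsAsFactors = FALSE)
      } else {
        cands[[length(cands) + 1L]] <- candidate_row(res$candidate)
      }
    }
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else empty_candidates()
  # one row per distinct ORF (several openings can hit the same precursor)
  key <- with(candidates, paste(transcript_id, strand, cds_start, cds_end))
  candidates <- candidates[!duplicated(key), , drop = FALSE]
  rownames(candidates) <- NULL
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    cbind(hits[0, ], reason = character(0), stringsAsFactors = FALSE)

  counts <- data.frame(
    pattern = openings$sequence,
    n_hits = vapply(openings$sequence,
                    function(p) sum(hits$pattern == p), integer(1)),
    n_transcripts = vapply(openings$sequence, function(p) {
      length(unique(hits$transcript_id[hits$pattern == p]))
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  multi <- unique(hits$transcript_id[duplicated(hits$transcript_id)])

  structure(list(openings = openings, hits = hits, candidates = candidates,
                 rejected = rejected, pattern_counts = counts,
                 multi_hit_transcripts = multi),
            class = "mine_result")
}

#' @export
print.mine_result <- function(x, ...) {
  cat(sprintf("cyclominer screen: %d opening(s), %d hit(s), %d candidate precursor(s)\n",
              nrow(x$openings), nrow(x$hits), nrow(x$candidates)))
  nz <- x$pattern_counts[x$pattern_counts$n_hits > 0L, , drop = FALSE]
  if (nrow(nz)) {
    cat("patterns with hits:\n")
    print(nz, row.names = FALSE)
  }
  invisible(x)
}
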