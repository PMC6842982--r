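# Independent oracles used across the suite. These deliberately avoid the
# package's search / alignment / canonicalization code paths.

# Translate with a plain codon-table lookup (independent of translate_nt's
# vectorized path only in spirit; cross-checks against Biostrings are in
# test-seq-core.R).
oracle_translate <- function(s, offset) {
  gc <- Biostrings::GENETIC_CODE
  n <- (nchar(s) - offset) %/% 3
  if (n <= 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(s, offset + 3 * (i - 1) + 1, offset + 3 * i)
    out[i] <- if (grepl("N", codon)) "X" else unname(gc[codon])
  }
  paste(out, collapse = "")
}

# Naive six-frame scan: every occurrence of every pattern by direct
# substring comparison at every position.
oracle_six_frame_hits <- function(s, patterns) {
  rc <- cyclominer::revcomp(s)
  rows <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else rc
    for (o in 0:2) {
      pep <- oracle_translate(src, o)
      for (p in patterns) {
        len <- nchar(p)
        nwin <- nchar(pep) - len + 1
        if (nwin < 1) next
        starts <- seq_len(nwin)
        found <- starts[substring(pep, starts, starts + len - 1) == p]
        for (a in found) {
          rows[[length(rows) + 1]] <- data.frame(
            strand = strand, offset = o, aa_start = a, pattern = p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), offset = integer(0),
                      aa_start = integer(0), pattern = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$offset, out$aa_start, out$pattern), ,
      drop = FALSE]
}

# Exhaustive global-alignment score by enumerating every alignment path.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Ring-class signature by brute force: the sorted set of all rotations of
# a string and of its reversal.
oracle_ring_class <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  rots <- function(v) {
    vapply(seq_len(n) - 1, function(k) {
      paste(v[((seq_len(n) - 1 + k) %% n) + 1], collapse = "")
    }, character(1))
  }
  paste(sort(unique(c(rots(ch), rots(rev(ch))))), collapse = "|")
}

random_nt_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# The published prePhHB study values used by several tests.
hb_core <- "IFGGLPPP"
prephb_gene_fixture <- function(seed = 11) {
  g <- planted_gene(precursor = prephb_precursor(), core = hb_core,
                    utr5_len = 63, utr3_len = 152, polya_len = 28)
  generate_fixture(fixture_spec(n_transcripts = 1, genes = list(g),
                                seed = seed))
}
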