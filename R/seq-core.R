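NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Normalize and validate a nucleotide string
#'
#' Uppercases, converts RNA 'U' to 'T', and rejects any character outside
#' `{A,C,G,T,N}` with an error naming the offending position.
#'
#' @param seq Single nucleotide string.
#' @return The normalized string.
#' @export
norm_nt <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("U", "T", toupper(seq))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Normalize and validate a peptide string
#'
#' Uppercases and rejects characters outside the 20 standard one-letter
#' codes plus `X` (unknown) and `*` (stop).
#'
#' @param seq Single peptide string.
#' @return The normalized string.
#' @export
norm_aa <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX*]", s)
  if (bad > 0L) {
    stop(sprintf("invalid amino acid '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Single nucleotide string over `{A,C,G,T,N}` (lowercase and
#'   `U` tolerated).
#' @return The reverse complement; `N` maps to `N`, length is preserved.
#' @examples
#' revcomp("ATGC") # "GCAT"
#' @export
revcomp <- function(seq) {
  s <- norm_nt(seq)
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Translate a nucleotide sequence in one forward reading frame
#'
#' Uses the standard nuclear genetic code. Codons are read from `offset`;
#' 1-2 trailing nucleotides are dropped. Stop codons are retained as `*`;
#' any codon containing `N` translates to `X`.
#'
#' @param seq Single nucleotide string.
#' @param offset Frame offset, one of 0, 1, 2.
#' @return Peptide string of length `floor((nchar(seq) - offset)/3)`.
#' @examples
#' translate_nt("ATGAAA")    # "MK"
#' translate_nt("ATGTAAAAA") # "M*K"
#' @export
translate_nt <- function(seq, offset = 0L) {
  s <- norm_nt(seq)
  if (!offset %in% 0:2) stop("offset must be 0, 1 or 2", call. = FALSE)
  naa <- (nchar(s) - offset) %/% 3L
  if (naa <= 0L) return("")
  starts <- offset + 3L * (seq_len(naa) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # N-containing codons
  paste(aa, collapse = "")
}

#' Read a FASTA file
#'
#' Identifiers are taken up to the first whitespace; the remainder of the
#' header is kept as a `description` attribute. Duplicate identifiers are
#' an error. Sequences are normalized (uppercased; `U` to `T` for
#' nucleotide input) and validated against the declared alphabet.
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @param type `"nt"` for nucleotide records, `"aa"` for peptide records.
#' @return Named character vector of sequences with attribute
#'   `description`; empty files yield an empty vector.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record",
                 nonblank[1L]), call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(x)
  seqs <- vapply(seqs, if (type == "nt") norm_nt else norm_aa, character(1))
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences; an optional
#'   `description` attribute (as produced by [read_fasta()]) is appended
#'   to each header.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("all records must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate record ids", call. = FALSE)
  desc <- attr(seqs, "description")
  hdr <- names(seqs)
  if (!is.null(desc) && length(desc) == length(seqs)) {
    hdr <- ifelse(nzchar(desc), paste(hdr, desc), hdr)
  }
  x <- Biostrings::BStringSet(setNames(as.character(seqs), hdr))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
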