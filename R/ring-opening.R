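#' Construct a head-to-tail cyclic peptide
#'
#' Residues sit on a ring with no distinguished start; the stored order is
#' one arbitrary reading. Only the 20 standard one-letter codes are
#' allowed (no `X`, no `*`): the mature ring of an orbitide-class cyclic
#' peptide is built from proteinogenic residues.
#'
#' @param seq Peptide string giving one linear reading of the ring.
#' @param name Optional label (e.g. `"heterophyllin B"`).
#' @return An object of class `cyclic_peptide`.
#' @examples
#' hb <- cyclic_peptide("IFGGLPPP", name = "heterophyllin B")
#' @export
cyclic_peptide <- function(seq, name = NULL) {
  s <- norm_aa(seq)
  if (nchar(s) < 1L) stop("ring must have at least one residue", call. = FALSE)
  if (grepl("[X*]", s)) {
    stop("cyclic peptide residues must be standard amino acids", call. = FALSE)
  }
  structure(list(residues = strsplit(s, "", fixed = TRUE)[[1L]], name = name),
            class = "cyclic_peptide")
}

#' @export
print.cyclic_peptide <- function(x, ...) {
  label <- if (is.null(x$name)) "" else paste0(" (", x$name, ")")
  cat(sprintf("cyclo-[%s]%s, %d residues\n",
              paste(x$residues, collapse = ""), label, length(x$residues)))
  invisible(x)
}

as_cyclic <- function(x) {
  if (inherits(x, "cyclic_peptide")) x else cyclic_peptide(x)
}

rotations_of <- function(chars) {
  n <- length(chars)
  vapply(seq_len(n) - 1L, function(k) {
    paste(chars[((seq_len(n) - 1L + k) %% n) + 1L], collapse = "")
  }, character(1))
}

#' Enumerate all linear ring-openings of a cyclic peptide
#'
#' A ring of n residues can be opened at any of its n peptide bonds, and
#' (optionally) read in either direction, giving up to 2n distinct linear
#' sequences. Duplicate sequences arising from ring symmetry are collapsed
#' to their first occurrence; output order is forward rotations by offset,
#' then reverse rotations by offset. For the cyclic octapeptide
#' heterophyllin B (cyclo-[IFGGLPPP]) this yields 16 sequences.
#'
#' @param cp A [cyclic_peptide()] or plain peptide string.
#' @param include_reverse Also enumerate openings of the reversed reading
#'   (default `TRUE`). Ribosomal synthesis fixes the N-to-C direction, but
#'   screening both directions makes no assumption about which stored
#'   reading corresponds to the encoded one.
#' @return `data.frame` with columns `index`, `sequence`, `offset`
#'   (rotation, 0-based), `orientation` (`"forward"`/`"reverse"`).
#' @export
ring_openings <- function(cp, include_reverse = TRUE) {
  cp <- as_cyclic(cp)
  n <- length(cp$residues)
  fwd <- data.frame(sequence = rotations_of(cp$residues),
                    offset = seq_len(n) - 1L,
                    orientation = "forward",
                    stringsAsFactors = FALSE)
  out <- fwd
  if (include_reverse) {
    rev_ <- data.frame(sequence = rotations_of(rev(cp$residues)),
                       offset = seq_len(n) - 1L,
                       orientation = "reverse",
                       stringsAsFactors = FALSE)
    out <- rbind(fwd, rev_)
  }
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Canonical form of a cyclic peptide sequence
#'
#' The lexicographically smallest string among all rotations of the
#' sequence and all rotations of its reversal. Two linear peptides
#' canonicalize identically iff they are ring-openings of the same cyclic
#' peptide, so the canonical form is a ring identity usable as a
#' dictionary key. Idempotent.
#'
#' @param seq Linear peptide string (length >= 1).
#' @return Canonical string.
#' @examples
#' canonical_cyclic("IFGGLPPP") # "FGGLPPPI"
#' @export
canonical_cyclic <- function(seq) {
  s <- norm_aa(seq)
  if (nchar(s) < 1L) stop("sequence must be non-empty", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  min(c(rotations_of(chars), rotations_of(rev(chars))))
}
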