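#' Describe a coding-sequence indel
#'
#' Coordinates follow the convention used when reporting plant precursor
#' gene variants: 1-based positions counted from the A of the ATG, with an
#' insertion's span giving the positions the new bases occupy in the
#' mutant ORF and a deletion's span giving the removed positions in the
#' wild type.
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param start,end 1-based inclusive span.
#' @param bases Inserted nucleotides (insertions only); length must equal
#'   the span length.
#' @return Object of class `mutation_event`.
#' @examples
#' mutation_event("insertion", 54, 56, "TTC")
#' mutation_event("deletion", 61, 63)
#' @export
mutation_event <- function(kind = c("insertion", "deletion"), start, end,
                           bases = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) stop("invalid span", call. = FALSE)
  if (kind == "insertion") {
    if (is.null(bases)) stop("insertion requires bases", call. = FALSE)
    bases <- norm_nt(bases)
    if (nchar(bases) != end - start + 1L) {
      stop("inserted bases must fill the stated span", call. = FALSE)
    }
  } else if (!is.null(bases)) {
    stop("deletion takes no bases", call. = FALSE)
  }
  structure(list(kind = kind, start = start, end = end, bases = bases),
            class = "mutation_event")
}

check_cds <- function(cds) {
  s <- norm_nt(cds)
  if (nchar(s) %% 3L != 0L || nchar(s) < 6L) {
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  }
  if (!startsWith(s, "ATG")) stop("CDS must start with ATG", call. = FALSE)
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (!last %in% c("TAA", "TAG", "TGA")) {
    stop("CDS must end with a stop codon", call. = FALSE)
  }
  s
}

#' Apply an indel to a coding sequence
#'
#' Insertions place the new bases so that they occupy the stated 1-based
#' positions of the mutant sequence; deletions remove the stated wild-type
#' positions. All other bases are preserved in order.
#'
#' @param cds Wild-type CDS (ATG through stop codon).
#' @param ev A [mutation_event()].
#' @return Mutant CDS string.
#' @export
apply_indel <- function(cds, ev) {
  s <- check_cds(cds)
  n <- nchar(s)
  if (ev$kind == "insertion") {
    if (ev$start > n + 1L) stop("insertion span outside CDS", call. = FALSE)
    paste0(substr(s, 1L, ev$start - 1L), ev$bases, substr(s, ev$start, n))
  } else {
    if (ev$end > n) stop("deletion span outside CDS", call. = FALSE)
    paste0(substr(s, 1L, ev$start - 1L), substr(s, ev$end + 1L, n))
  }
}

translate_to_stop <- function(cds) {
  pep <- translate_nt(cds, 0L)
  st <- regexpr("*", pep, fixed = TRUE)
  if (st > 0L) {
    list(peptide = substr(pep, 1L, st - 1L), stop_at = as.integer(st))
  } else {
    list(peptide = pep, stop_at = NA_integer_)
  }
}

# Positional residue diff anchored on the longest common prefix/suffix.
diff_residues <- function(wt, mut) {
  w <- strsplit(wt, "", fixed = TRUE)[[1L]]
  m <- strsplit(mut, "", fixed = TRUE)[[1L]]
  lw <- length(w); lm <- length(m)
  p <- 0L
  while (p < min(lw, lm) && w[p + 1L] == m[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(lw, lm) - p && w[lw - s] == m[lm - s]) s <- s + 1L
  midw <- if (lw - s >= p + 1L) w[(p + 1L):(lw - s)] else character(0)
  midm <- if (lm - s >= p + 1L) m[(p + 1L):(lm - s)] else character(0)
  k <- max(length(midw), length(midm))
  if (k == 0L) {
    return(data.frame(position = integer(0), wt = character(0),
                      mut = character(0), stringsAsFactors = FALSE))
  }
  pad <- function(x) c(x, rep("-", k - length(x)))
  data.frame(position = p + seq_len(k), wt = pad(midw), mut = pad(midm),
             stringsAsFactors = FALSE)
}

# New core nt span (in mutant coordinates) after an indel, or NULL when the
# event disrupts the core boundary. Insertions at the exact 5' edge of the
# core are attributed to the leader; insertions strictly inside (or flush
# with the core's interior/3' boundary codons) grow the core.
shift_core_span <- function(core_span, ev) {
  a <- core_span[1L]; b <- core_span[2L]
  len <- ev$end - ev$start + 1L
  if (ev$kind == "insertion") {
    if (ev$start <= a) c(a + len, b + len)
    else if (ev$start <= b) c(a, b + len)
    else c(a, b)
  } else {
    if (ev$end < a) c(a - len, b - len)
    else if (ev$start > b) c(a, b)
    else if (ev$start >= a && ev$end <= b) c(a, b - len)
    else NULL # deletion straddles a core boundary
  }
}

#' Predict the consequence of a CDS indel on a precursor and its ring
#'
#' Translates the mutant CDS to its first stop, diffs it positionally
#' against the wild-type precursor, and -- for in-frame events that leave
#' the reading frame and the core boundaries intact -- derives the mutant
#' core peptide and the canonical form of the cyclic product it would
#' yield after head-to-tail cyclization. Frameshifts (indel length not a
#' multiple of 3), premature stops, start-loss and core-boundary
#' disruptions all yield `cyclic_product = NA`.
#'
#' The predicted ring is a hypothesis about what the mutant allele could
#' encode, not an observed metabolite.
#'
#' @param wt_cds Wild-type CDS (ATG through stop codon, internally
#'   stop-free).
#' @param core_span_nt 1-based inclusive nt interval of the core codons
#'   within the CDS, e.g. `c(40, 63)` for a core at residues 14-21.
#' @param ev A [mutation_event()].
#' @return Object of class `mutant_prediction`: list with `mutant_cds`,
#'   `mutant_precursor`, `length_delta`, `frameshift`, `start_lost`,
#'   `truncated`, `residue_diff` (data frame), `gained`, `lost`,
#'   `mutant_core`, `cyclic_product`.
#' @export
predict_mutant <- function(wt_cds, core_span_nt, ev) {
  wt <- check_cds(wt_cds)
  wt_tr <- translate_to_stop(wt)
  if (is.na(wt_tr$stop_at) || wt_tr$stop_at != nchar(wt) / 3L) {
    stop("wild-type CDS must be stop-free until its final codon",
         call. = FALSE)
  }
  core_span_nt <- as.integer(core_span_nt)
  if (length(core_span_nt) != 2L || core_span_nt[1L] %% 3L != 1L ||
      core_span_nt[2L] %% 3L != 0L || core_span_nt[2L] > nchar(wt) - 3L) {
    stop("core span must cover whole codons inside the CDS", call. = FALSE)
  }

  mut <- apply_indel(wt, ev)
  indel_len <- ev$end - ev$start + 1L
  frameshift <- (indel_len %% 3L) != 0L
  start_lost <- !startsWith(mut, "ATG")
  mut_tr <- translate_to_stop(mut)
  expected_stop <- if (!frameshift) nchar(mut) / 3L else NA_integer_
  truncated <- if (frameshift) {
    TRUE
  } else {
    is.na(mut_tr$stop_at) || mut_tr$stop_at != expected_stop
  }

  rdiff <- diff_residues(wt_tr$peptide, mut_tr$peptide)
  gained <- rdiff$mut[rdiff$mut != "-" & rdiff$wt == "-"]
  lost <- rdiff$wt[rdiff$wt != "-" & rdiff$mut == "-"]

  mutant_core <- NA_character_
  cyclic_product <- NA_character_
  core_disrupted <- FALSE
  if (!frameshift && !start_lost && !truncated) {
    span <- shift_core_span(core_span_nt, ev)
    if (is.null(span)) {
      core_disrupted <- TRUE
    } else {
      mutant_core <- translate_nt(substr(mut, span[1L], span[2L]), 0L)
      if (!grepl("[X*]", mutant_core) && nchar(mutant_core) > 0L) {
        cyclic_product <- canonical_cyclic(mutant_core)
      }
    }
  }

  structure(list(
    mutant_cds = mut,
    mutant_precursor = mut_tr$peptide,
    length_delta = nchar(mut_tr$peptide) - nchar(wt_tr$peptide),
    frameshift = frameshift, start_lost = start_lost, truncated = truncated,
    core_disrupted = core_disrupted,
    residue_diff = rdiff, gained = gained, lost = lost,
    mutant_core = mutant_core, cyclic_product = cyclic_product),
    class = "mutant_prediction")
}

#' @export
print.mutant_prediction <- function(x, ...) {
  cat(sprintf("mutant prediction: length delta %+d residue(s)%s\n",
              x$length_delta,
              if (x$frameshift) " [frameshift]" else ""))
  if (length(x$gained)) cat("gained:", paste(x$gained, collapse = ", "), "\n")
  if (length(x$lost)) cat("lost:", paste(x$lost, collapse = ", "), "\n")
  if (!is.na(x$cyclic_product)) {
    cat(sprintf("predicted cyclic product: cyclo-[%s] (canonical %s)\n",
                x$mutant_core, x$cyclic_product))
  } else {
    cat("no cyclic product predicted\n")
  }
  invisible(x)
}
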