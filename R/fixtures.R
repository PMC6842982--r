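# Codons per residue, ordered lexicographically (derived once from the
# standard code).
codons_by_residue <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a peptide into a coding nucleotide sequence
#'
#' @param pep Peptide string over the 20 standard residues.
#' @param codon_choice `"fixed"` uses the lexicographically first codon
#'   per residue (deterministic without a seed); `"seeded"` samples a
#'   synonymous codon per position from R's RNG (seed the session first).
#' @return Nucleotide string with `translate_nt(result) == pep`.
#' @examples
#' reverse_translate("MW") # "ATGTGG"
#' @export
reverse_translate <- function(pep, codon_choice = c("fixed", "seeded")) {
  codon_choice <- match.arg(codon_choice)
  p <- norm_aa(pep)
  if (grepl("[X*]", p)) {
    stop("cannot reverse-translate 'X' or '*'", call. = FALSE)
  }
  tab <- codons_by_residue()
  res <- strsplit(p, "", fixed = TRUE)[[1L]]
  codons <- vapply(res, function(r) {
    opts <- sort(tab[[r]])
    if (codon_choice == "fixed") opts[1L]
    else opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' The heterophyllin B ring and its published precursor
#'
#' `hb_peptide()` returns the cyclic octapeptide cyclo-[IFGGLPPP]
#' (heterophyllin B) as a [cyclic_peptide()]. `prephb_precursor()` returns
#' the 35-residue precursor peptide encoded by the prePhHB gene of
#' *Pseudostellaria heterophylla*. `prephb_core_cds()` returns the 24-nt
#' wild-type codon sequence of the core peptide region (codons attested by
#' the published prePhHB primer sequences).
#'
#' @return See description.
#' @export
hb_peptide <- function() cyclic_peptide("IFGGLPPP", name = "heterophyllin B")

#' @rdname hb_peptide
#' @export
prephb_precursor <- function() "MSTISAIHIMKPSIFGGLPPPSQELINGDDISLMV"

#' @rdname hb_peptide
#' @export
prephb_core_cds <- function() "ATTTTTGGGGGTCTTCCTCCTCCT"

#' Describe one planted precursor gene for the fixture generator
#'
#' Defaults mirror the architecture of the prePhHB mRNA: a 63-nt 5' UTR,
#' an ATG-initiated CDS encoding leader + core + follower + stop, a
#' 152-nt 3' UTR carrying one AATAAAA polyadenylation signal, and a 28-nt
#' poly(A) tail.
#'
#' @param core Core peptide planted in the precursor.
#' @param leader_len,follower_len Residue counts of the random leader and
#'   follower segments (ignored when `precursor` is given).
#' @param precursor Optional full precursor peptide (must contain `core`);
#'   overrides `leader_len`/`follower_len`.
#' @param utr5_len,utr3_len,polya_len Nucleotide lengths of the UTRs and
#'   poly(A) tail.
#' @param strand `"+"` or `"-"`: strand of the assembled contig carrying
#'   the gene.
#' @param with_polya_signal Plant one literal AATAAAA in the 3' UTR.
#' @return List of class `planted_gene`.
#' @export
planted_gene <- function(core = "IFGGLPPP", leader_len = 13L,
                         follower_len = 14L, precursor = NULL,
                         utr5_len = 63L, utr3_len = 152L, polya_len = 28L,
                         strand = c("+", "-"), with_polya_signal = TRUE) {
  strand <- match.arg(strand)
  core <- norm_aa(core)
  if (!is.null(precursor)) {
    precursor <- norm_aa(precursor)
    if (!grepl(core, precursor, fixed = TRUE)) {
      stop("precursor must contain the core", call. = FALSE)
    }
    if (!startsWith(precursor, "M")) {
      stop("precursor must start with M", call. = FALSE)
    }
  }
  if (with_polya_signal && utr3_len < 7L + 2L) {
    stop("3' UTR too short to carry an AATAAAA signal", call. = FALSE)
  }
  structure(list(core = core, leader_len = as.integer(leader_len),
                 follower_len = as.integer(follower_len),
                 precursor = precursor, utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 polya_len = as.integer(polya_len), strand = strand,
                 with_polya_signal = with_polya_signal),
            class = "planted_gene")
}

#' Specification for a synthetic transcriptome fixture
#'
#' Stands in for an unavailable RNA-seq unigene assembly: i.i.d. random
#' background transcripts at a stated GC fraction, with precursor genes
#' planted on either strand and optional structured decoys. Defaults
#' emulate a small de novo plant assembly screened for the heterophyllin B
#' core: 50 transcripts of 300-1500 nt at GC 0.42 carrying 5 planted
#' genes.
#'
#' @param n_transcripts Total number of transcripts (planted + decoys).
#' @param len_range Length range (nt) for decoy transcripts.
#' @param gc GC fraction of random background sequence.
#' @param seed Mandatory integer seed; generation is fully deterministic
#'   given the spec.
#' @param genes List of [planted_gene()]s (may be empty).
#' @param core Target core peptide used for decoy construction and
#'   collision screening when no genes are planted.
#' @param decoy_kind One of `"none"` (plain random), `"shuffled-core"`
#'   (decoys embed a shuffled core peptide), `"core-with-internal-stop"`
#'   (decoys embed the core with an in-frame stop immediately upstream and
#'   no start codon, so they hit but never yield an ORF),
#'   `"core-split-across-frames"` (core codons interrupted by a 1-nt
#'   insertion, destroying the in-frame match).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_transcripts = 50L, len_range = c(300L, 1500L),
                         gc = 0.42, seed,
                         genes = rep(list(planted_gene()), 5L),
                         core = "IFGGLPPP",
                         decoy_kind = c("none", "shuffled-core",
                                        "core-with-internal-stop",
                                        "core-split-across-frames")) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  decoy_kind <- match.arg(decoy_kind)
  if (length(genes) > n_transcripts) {
    stop("more planted genes than transcripts", call. = FALSE)
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 len_range = as.integer(len_range), gc = gc,
                 seed = as.integer(seed), genes = genes,
                 core = norm_aa(core), decoy_kind = decoy_kind),
            class = "fixture_spec")
}

random_nt <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_peptide <- function(n) {
  if (n <= 0L) return("")
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Post-hoc collision screen: all occurrences of any pattern in any of the
# six frames of s.
naive_pattern_hits <- function(s, patterns) {
  total <- list()
  rc <- revcomp(s)
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else rc
    for (o in 0:2) {
      pep <- translate_nt(src, o)
      for (p in patterns) {
        for (i in overlapping_starts(pep, p)) {
          total[[length(total) + 1L]] <-
            list(strand = strand, offset = o, aa_start = i, pattern = p)
        }
      }
    }
  }
  total
}

# Assemble one sense-strand transcript carrying a planted gene; returns
# list(seq, truth fields in sense coordinates).
build_gene_transcript <- function(gene, gc) {
  precursor <- if (!is.null(gene$precursor)) gene$precursor else
    paste0("M", random_peptide(gene$leader_len - 1L), gene$core,
           random_peptide(gene$follower_len))
  cds <- paste0(reverse_translate(precursor, "seeded"), "TAA")
  utr5 <- random_nt(gene$utr5_len, gc)
  if (gene$utr5_len >= 3L) {
    # in-frame stop immediately upstream of ATG pins the ORF start
    substr(utr5, gene$utr5_len - 2L, gene$utr5_len) <- "TAA"
  }
  utr3 <- random_nt(gene$utr3_len, gc)
  if (gene$utr3_len > 0L) {
    last <- sample(c("C", "G", "T"), 1L) # keep the poly(A) tail measurable
    substr(utr3, gene$utr3_len, gene$utr3_len) <- last
  }
  if (gene$with_polya_signal) {
    pos <- max(1L, gene$utr3_len - 40L)
    substr(utr3, pos, pos + 6L) <- "AATAAAA"
  }
  seq <- paste0(utr5, cds, utr3, strrep("A", gene$polya_len))
  list(seq = seq, precursor = precursor,
       cds_start = gene$utr5_len + 1L,
       cds_end = gene$utr5_len + nchar(cds))
}

#' Generate a synthetic transcriptome with planted precursor genes
#'
#' Deterministic given the spec's seed. Planted coding sequences are
#' internally stop-free by construction; decoys are guaranteed (by a
#' post-hoc naive six-frame scan, regenerating on collision) not to
#' contain any ring-opening of the target core, so planted-gene recall is
#' 100% and the decoy false-positive rate is 0 on every fixture.
#'
#' @param spec A [fixture_spec()].
#' @return List with `transcripts` (named character vector), `truth`
#'   (`data.frame` mirroring the candidate table of [mine()] for every
#'   planted gene), and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  cores <- unique(c(vapply(spec$genes, function(g) g$core, character(1)),
                    spec$core))
  patterns <- unlist(lapply(cores, function(cr) ring_openings(cr)$sequence))
  patterns <- unique(patterns)
  n_genes <- length(spec$genes)
  transcripts <- character(spec$n_transcripts)
  names(transcripts) <- sprintf("tx%04d", seq_len(spec$n_transcripts))
  truth <- list()

  for (i in seq_len(spec$n_transcripts)) {
    gene <- if (i <= n_genes) spec$genes[[i]] else NULL
    for (attempt in 0:200) {
      sub_seed <- (spec$seed + 7919L * i + attempt) %% 2147483647L
      set.seed(sub_seed)
      if (!is.null(gene)) {
        built <- build_gene_transcript(gene, spec$gc)
        seq <- built$seq
        if (gene$strand == "-") seq <- revcomp(seq)
        hits <- naive_pattern_hits(seq, patterns)
        planted_ok <- length(hits) == 1L &&
          hits[[1L]]$pattern == gene$core &&
          hits[[1L]]$strand == gene$strand
        extra_signal <- {
          utr3_seq <- substr(built$seq, built$cds_end + 1L,
                             nchar(built$seq) - gene$polya_len)
          expected <- if (gene$with_polya_signal) 1L else 0L
          length(overlapping_starts(utr3_seq, "AATAAAA")) != expected
        }
        if (planted_ok && !extra_signal) {
          transcripts[i] <- seq
          tlen <- nchar(seq)
          cds <- if (gene$strand == "+") {
            c(built$cds_start, built$cds_end)
          } else {
            c(tlen - built$cds_end + 1L, tlen - built$cds_start + 1L)
          }
          seg <- segment_precursor(built$precursor, gene$core)
          truth[[length(truth) + 1L]] <- data.frame(
            transcript_id = names(transcripts)[i], strand = gene$strand,
            cds_start = cds[1L], cds_end = cds[2L],
            precursor = built$precursor,
            precursor_len = nchar(built$precursor),
            pattern = gene$core,
            core_start = seg$core_span[1L], core_end = seg$core_span[2L],
            leader = seg$leader, core = seg$core, follower = seg$follower,
            utr5_len = gene$utr5_len, utr3_len = gene$utr3_len,
            polya_signal_count = as.integer(gene$with_polya_signal),
            polya_tail_len = gene$polya_len,
            stringsAsFactors = FALSE)
          break
        }
      } else {
        len <- sample(spec$len_range[1L]:spec$len_range[2L], 1L)
        seq <- make_decoy(len, spec$gc, spec$decoy_kind, cores[[1L]])
        if (length(naive_pattern_hits(seq, patterns)) ==
            decoy_expected_hits(spec$decoy_kind)) {
          transcripts[i] <- seq
          break
        }
      }
      if (attempt == 200L) {
        stop("could not generate a collision-free transcript", call. = FALSE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_candidates()
  rownames(truth) <- NULL
  list(transcripts = transcripts, truth = truth, spec = spec)
}

decoy_expected_hits <- function(kind) {
  if (kind == "core-with-internal-stop") 1L else 0L
}

make_decoy <- function(len, gc, kind, core) {
  if (kind == "none") return(random_nt(len, gc))
  core_cds <- reverse_translate(core, "seeded")
  insert <- switch(kind,
    "shuffled-core" = {
      shuffled <- paste(sample(strsplit(core, "", fixed = TRUE)[[1L]]),
                        collapse = "")
      reverse_translate(shuffled, "seeded")
    },
    # stop right before the core, no ATG in between: the core still hits
    # but ORF extension fails with reason "no-start"; no downstream ATG
    # rescue is possible within the same stop-bounded window
    "core-with-internal-stop" = paste0("TAA", core_cds, "TAA"),
    "core-split-across-frames" = {
      half <- 3L * (nchar(core) %/% 2L)
      paste0(substr(core_cds, 1L, half), "G",
             substr(core_cds, half + 1L, nchar(core_cds)))
    })
  body_len <- max(len - nchar(insert), 60L)
  left <- body_len %/% 2L
  at <- 3L * (left %/% 3L) # keep the insert in frame +1
  bg <- random_nt(body_len, gc)
  paste0(substr(bg, 1L, at), insert, substr(bg, at + 1L, body_len))
}
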