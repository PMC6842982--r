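#' Global pairwise alignment of two peptides
#'
#' Needleman-Wunsch dynamic programming with a simple match/mismatch/gap
#' scheme (default match +1, mismatch -1, gap -2) and deterministic
#' traceback (ties resolved diagonal > up > left). Percent identity is
#' computed over aligned columns (pairwise global alignments contain no
#' double-gap columns).
#'
#' @param a,b Peptide strings (non-empty; gaps not allowed in input).
#' @param match,mismatch,gap Scoring parameters.
#' @param submat Optional symmetric substitution matrix (residue-named
#'   rows/columns) overriding `match`/`mismatch`.
#' @return Object of class `alignment_result`: list with `a_aln`, `b_aln`,
#'   `score`, `percent_identity`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                         submat = NULL) {
  a <- norm_aa(a); b <- norm_aa(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  sc <- function(x, y) {
    if (!is.null(submat)) submat[x, y] else if (x == y) match else mismatch
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  # traceback: 1 = diagonal, 2 = up (consume a), 3 = left (consume b)
  P <- matrix(0L, n + 1L, m + 1L)
  P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- c(S[i, j] + sc(av[i], bv[j]), S[i, j + 1L] + gap,
                S[i + 1L, j] + gap)
      k <- which.max(cand) # which.max returns the first maximum: diag > up > left
      S[i + 1L, j + 1L] <- cand[k]
      P[i + 1L, j + 1L] <- k
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    k <- P[i, j]
    if (k == 1L) {
      ai <- c(av[i - 1L], ai); bi <- c(bv[j - 1L], bi)
      i <- i - 1L; j <- j - 1L
    } else if (k == 2L) {
      ai <- c(av[i - 1L], ai); bi <- c("-", bi); i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1L], bi); j <- j - 1L
    }
  }
  ncols <- length(ai)
  ident <- 100 * sum(ai == bi & ai != "-") / ncols
  structure(list(a_aln = paste(ai, collapse = ""),
                 b_aln = paste(bi, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 percent_identity = ident),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$a_aln, "\n", x$b_aln, "\n", sep = "")
  cat(sprintf("score %g, identity %.1f%%\n", x$score, x$percent_identity))
  invisible(x)
}

#' Pairwise p-distance matrix from global alignments
#'
#' `d(i,j)` is the proportion of mismatched columns (gap-against-residue
#' counts as a mismatch) over all columns of the pairwise global
#' alignment of sequences i and j.
#'
#' @param seqs Named character vector of >= 2 peptide sequences.
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix with zero diagonal and taxa labels.
#' @export
p_distance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(seqs[[i]], seqs[[j]], ...)
      d[i, j] <- d[j, i] <- 1 - al$percent_identity / 100
    }
  }
  d
}

# p-distance between two rows of an alignment matrix, ignoring
# double-gap columns.
aligned_p_dist <- function(x, y) {
  keep <- !(x == "-" & y == "-")
  if (!any(keep)) return(0)
  sum(x[keep] != y[keep]) / sum(keep)
}

aligned_dist_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- aligned_p_dist(mat[i, ], mat[j, ])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}). Negative branch lengths --
#' possible on non-additive input -- are clamped to zero with a warning.
#'
#' @param dm Symmetric distance matrix with zero diagonal (taxa as
#'   dimnames), or a `dist`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0) || any(dm < 0)) {
    stop("distance matrix must be symmetric, nonnegative, zero-diagonal",
         call. = FALSE)
  }
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(dm)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' from p-distances for each replicate, and labels each internal node of
#' the full-data tree with the percentage of replicates containing its
#' bipartition.
#'
#' @param seqs Named character vector of aligned (equal-length) peptide
#'   sequences; gaps as `-`.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Required integer seed for column resampling.
#' @return `ape::phylo` tree with integer percentage `node.label`s.
#' @export
bootstrap_support <- function(seqs, replicates, seed) {
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("need >= 1 replicate", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  mat <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  main <- nj_tree(aligned_dist_matrix(mat))
  set.seed(as.integer(seed))
  reps <- lapply(seq_len(replicates), function(r) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    suppressWarnings(nj_tree(aligned_dist_matrix(mat[, cols, drop = FALSE])))
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / replicates))
  main
}
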