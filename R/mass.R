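# Monoisotopic and average residue masses (Da) for the 20 standard
# residues, plus water and proton constants. Fixed at 5-decimal precision.
AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

AA_MASS_AVG <- c(
  G = 57.05190, A = 71.07880, S = 87.07820, P = 97.11670, V = 99.13260,
  T = 101.10510, C = 103.13880, L = 113.15940, I = 113.15940,
  N = 114.10380, D = 115.08860, Q = 128.13070, K = 128.17410,
  E = 129.11550, M = 131.19260, H = 137.14110, F = 147.17660,
  R = 156.18750, Y = 163.17600, W = 186.21320)

WATER_MONO <- 18.010565
WATER_AVG <- 18.0153
PROTON <- 1.007276

#' Residue mass table
#'
#' @return `data.frame` with columns `residue`, `mono`, `average` (Da).
#' @export
residue_masses <- function() {
  data.frame(residue = names(AA_MASS_MONO),
             mono = unname(AA_MASS_MONO),
             average = unname(AA_MASS_AVG),
             stringsAsFactors = FALSE)
}

#' Mass of a linear or head-to-tail cyclic peptide
#'
#' A linear peptide weighs the sum of its residue masses plus one water;
#' head-to-tail cyclization forms a lactam between the termini and loses
#' that water, so a cyclic peptide weighs the bare residue-mass sum (and
#' its mass is invariant under rotation and reversal of the sequence).
#'
#' @param seq Peptide string over the 20 standard residues.
#' @param cyclic Head-to-tail cyclic peptide? (default `FALSE`).
#' @param mode `"mono"` (monoisotopic) or `"average"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")                          # 75.03203
#' peptide_mass("IFGGLPPP", cyclic = TRUE)    # 778.4377
#' @export
peptide_mass <- function(seq, cyclic = FALSE, mode = c("mono", "average")) {
  mode <- match.arg(mode)
  s <- norm_aa(seq)
  if (nchar(s) == 0L) stop("empty peptide", call. = FALSE)
  if (grepl("[X*]", s)) {
    stop("mass undefined for 'X' or '*' residues", call. = FALSE)
  }
  tab <- if (mode == "mono") AA_MASS_MONO else AA_MASS_AVG
  water <- if (mode == "mono") WATER_MONO else WATER_AVG
  total <- sum(tab[strsplit(s, "", fixed = TRUE)[[1L]]])
  if (cyclic) total else total + water
}

#' Mass-to-charge ratio of a protonated peptide ion
#'
#' @param mass Neutral mass in Da.
#' @param z Positive integer charge state.
#' @return `(mass + z * 1.007276) / z`.
#' @examples
#' mz(778.4377, 1) # 779.445
#' @export
mz <- function(mass, z = 1L) {
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("charge must be a positive integer",
                               call. = FALSE)
  (mass + z * PROTON) / z
}
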