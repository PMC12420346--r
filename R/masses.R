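# Monoisotopic mass arithmetic for peptides, precursors and fragment ions.
#
# Constants follow the standard monoisotopic residue masses; the default fixed
# modification is cysteine thiomethylation (+45.98772 Da, the MMTS blocking
# chemistry used in SDC/TEAB digests). Heavy labels are C-terminal Lys
# (13C6 15N2) and Arg (13C6 15N4).

#' Monoisotopic residue masses
#'
#' Named vector of the 20 standard amino-acid residue masses (Da).
#' @export
MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

# 13C - 12C = 1.003355; 15N - 14N = 0.997035. Gives +8.01420 (K, 13C6 15N2)
# and +10.00827 (R, 13C6 15N4).
HEAVY_LABEL_SHIFT <- c(
  K = 6 * (13.003355 - 12) + 2 * (15.000109 - 14.003074),
  R = 6 * (13.003355 - 12) + 4 * (15.000109 - 14.003074)
)

#' Default fixed modifications (residue -> mass delta, Da)
#'
#' Cysteine thiomethylation (+45.98772) as used when free thiols are blocked
#' with methyl methanethiosulfonate.
#' @export
DEFAULT_FIXED_MODS <- c(C = 45.98772)

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus water, plus any fixed-modification deltas.
#'
#' @param sequence peptide sequence (one-letter codes).
#' @param fixed_mods named numeric vector mapping residue to mass delta;
#'   default cysteine thiomethylation. Use `numeric(0)` for none.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("G")  # 75.03203
#' @export
peptide_neutral_mass <- function(sequence, fixed_mods = DEFAULT_FIXED_MODS) {
  assert_sequence(sequence, "peptide")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mass <- sum(MONOISOTOPIC_RESIDUE_MASS[residues]) + WATER_MASS
  if (length(fixed_mods)) {
    hits <- residues[residues %in% names(fixed_mods)]
    if (length(hits)) mass <- mass + sum(fixed_mods[hits])
  }
  unname(mass)
}

label_shift <- function(sequence, label) {
  if (label == "light") return(0)
  cterm <- substr(sequence, nchar(sequence), nchar(sequence))
  if (!cterm %in% c("K", "R")) {
    stop("heavy label requires a C-terminal K or R (got '", cterm, "')",
         call. = FALSE)
  }
  unname(HEAVY_LABEL_SHIFT[cterm])
}

#' Precursor m/z of a peptide
#'
#' @param sequence peptide sequence.
#' @param charge precursor charge (default 2).
#' @param label `"light"` or `"heavy"`; heavy adds the C-terminal K/R
#'   stable-isotope label shift.
#' @param fixed_mods see [peptide_neutral_mass()].
#' @return m/z.
#' @export
precursor_mz <- function(sequence, charge = 2L, label = c("light", "heavy"),
                         fixed_mods = DEFAULT_FIXED_MODS) {
  label <- match.arg(label)
  stopifnot(charge >= 1)
  mass <- peptide_neutral_mass(sequence, fixed_mods) + label_shift(sequence, label)
  (mass + charge * PROTON_MASS) / charge
}

#' Fragment ion m/z (singly charged y or b)
#'
#' y ions carry the C-terminal heavy label; b ions are label-invariant.
#'
#' @param sequence peptide sequence.
#' @param ion_type `"y"` or `"b"`.
#' @param index fragment index, 1 <= index < peptide length.
#' @param label `"light"` or `"heavy"`.
#' @param fixed_mods see [peptide_neutral_mass()].
#' @return m/z at charge 1.
#' @export
fragment_mz <- function(sequence, ion_type = c("y", "b"), index,
                        label = c("light", "heavy"),
                        fixed_mods = DEFAULT_FIXED_MODS) {
  ion_type <- match.arg(ion_type)
  label <- match.arg(label)
  assert_sequence(sequence, "peptide")
  n <- nchar(sequence)
  if (index < 1 || index >= n) {
    stop("fragment index must satisfy 1 <= index < ", n, call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res_mass <- MONOISOTOPIC_RESIDUE_MASS[residues]
  if (length(fixed_mods)) {
    idx <- residues %in% names(fixed_mods)
    res_mass[idx] <- res_mass[idx] + fixed_mods[residues[idx]]
  }
  if (ion_type == "y") {
    mass <- sum(res_mass[(n - index + 1):n]) + WATER_MASS + PROTON_MASS
    if (label == "heavy") mass <- mass + label_shift(sequence, "heavy")
  } else {
    mass <- sum(res_mass[1:index]) + PROTON_MASS
  }
  unname(mass)
}
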