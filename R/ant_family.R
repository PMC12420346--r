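# A synthetic stand-in for the human ADP/ATP translocase family.
#
# The real family (ANT1/SLC25A4, ANT2/SLC25A5, ANT3/SLC25A6; UniProt P12235,
# P05141, P12236) cannot be redistributed here, so the package ships a
# SYNTHETIC three-isoform family constructed to embody the published panel
# structure of the family: three ~298-residue isoforms of high pairwise
# identity; one unique, acetylation-prone N-terminal tryptic peptide per
# isoform; one methionine-containing ANT2-unique peptide (oxidation-prone);
# one low-signal ANT3-unique peptide removed manually; and a missed-cleavage
# ANT3-unique peptide IFRDEGGK admitted by allowlist. Under the default
# selection policy the panel is 3 (ANT1), 2 (ANT2), 2 (ANT3) with exactly 3
# N-terminal exclusions.

# Tryptic building blocks. Each block ends in K/R (except the C-terminal
# tail) and contains no internal cleavage site, so the 0-missed digest of a
# concatenation returns exactly the blocks.
ant_blocks <- function() {
  shared <- list(
    S1 = "DFLAGGVAAAISK", S2 = "TAVAPIER", S3 = "VTLLLQVQHASK",
    S4 = "QISAEK", S5 = "QYTGIIDCVVR", S6 = "GYFPTQALNFAFK",
    S7 = "TQFWGLVDVYR", S8 = "YFAGNLASGGAAGATSLCFVYPLDFAR",
    S9 = "QIFLGGVDK", S10 = "NVHIFVSWLIAQSVTAVAGLTSYPFDTVR",
    S11 = "GADLVTHDELLK", S12 = "MQSGEAVK", S14 = "ADTLGSEFHQSVLGTQK",
    S13 = "YDQLQGWFHSAPLGGQ"
  )
  variants <- list(
    # slot = c(ANT1, ANT2, ANT3)
    A = c("MGDHAWSFLK", "MTDAAVSFAK", "MTEQAISFAK"),        # N-terminal
    B = c("EQGVLSFWR", "EQGILSFWR", "EQGILSFWR"),           # ANT1-unique
    C = c("GLVDHAQEFNGLGDCLVK", "GLVDHAQEFNGLGDCLTK", "GLVDHAQEFNGLGDCLTK"),
    D = c("DEGAGAFFK", "DEGASAFFK", "DEGASAFFK"),           # ANT1-unique
    G = c("SDGILGLYR", "SDGIMGLYR", "SDGILGLYR"),           # ANT2-unique, Met
    H = c("QATVEAYR", "QATVEAYR", "QATVDAYR"),              # ANT3-unique
    E = c("GTGGALVLVIYDEIK", "GTGGALVLVLYDEIK", "GTGGALVLVIYDEIK"),
    I = c("LFRDEGGK", "LFRDEGGK", "IFRDEGGK"),              # missed-cleavage region
    F = c("AADSLSTHLIVK", "AADSLSTHLLVK", "AADSLSTHLIVK"),  # ANT2-unique
    J = c("GAWSNVIR", "GAWSNVIR", "GAWSNVLR")               # ANT3-unique, low signal
  )
  list(shared = shared, variants = variants)
}

#' Synthetic ADP/ATP translocase reference family
#'
#' A deterministic, clearly synthetic three-isoform family emulating the
#' structure of the human ANT1/ANT2/ANT3 paralog family for panel-design
#' validation: ~298-residue isoforms with high pairwise identity whose
#' isoform-unique tryptic peptides reproduce the published panel layout
#' (3 ANT1-unique, 2 ANT2-unique, 2 ANT3-unique peptides under
#' [ant_selection_policy()], with three N-terminal exclusions and the
#' missed-cleavage ANT3 peptide IFRDEGGK admitted by allowlist). It is not
#' the real sequence data; to analyse the real family, supply a UniProt
#' FASTA to [read_isoform_fasta()].
#'
#' @return an [isoform_set()] with ids ANT1, ANT2, ANT3.
#' @export
ant_reference_family <- function() {
  b <- ant_blocks()
  s <- b$shared
  v <- b$variants
  build <- function(k) {
    paste0(v$A[k], s$S1, v$B[k], s$S2, s$S3, v$C[k], s$S4, v$G[k], s$S5,
           s$S6, v$D[k], s$S7, v$H[k], s$S8, v$E[k], s$S9, v$I[k], s$S10,
           v$F[k], s$S11, v$J[k], s$S12, s$S14, s$S13)
  }
  isoform_set(
    ids = c("ANT1", "ANT2", "ANT3"),
    sequences = c(build(1), build(2), build(3)),
    accessions = c("SYN-ANT1", "SYN-ANT2", "SYN-ANT3")
  )
}

#' Default ANT panel selection policy
#'
#' The selection rules used for the ANT family: tryptic peptides of 6-25
#' residues, protein N-terminal peptides excluded (acetylation-prone),
#' methionine-containing peptides excluded for ANT2 (artificial oxidation of
#' the heavy standard), the missed-cleavage ANT3-unique peptide IFRDEGGK
#' admitted by allowlist, and the low-signal ANT3-unique peptide removed
#' manually.
#'
#' @param low_signal_peptide sequence of the manually excluded low-signal
#'   peptide (default matches [ant_reference_family()]).
#' @return a [selection_policy()].
#' @export
ant_selection_policy <- function(low_signal_peptide = "GAWSNVLR") {
  manual <- stats::setNames("insufficient transition signal / RT shift",
                            low_signal_peptide)
  selection_policy(
    min_len = 6L, max_len = 25L,
    exclude_protein_nterm = TRUE,
    exclude_met = "ANT2",
    missed_cleavage_allowlist = "IFRDEGGK",
    manual_exclusions = manual
  )
}
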