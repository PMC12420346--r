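# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: uniqueness by explicit window scan, transition
# enumeration by cumulative-sum arithmetic, Spearman by the rank formula.

# Brute-force substring scan: does `pep` occur in `seq`, checked window by
# window (no regex, no grepl).
occurs_in_oracle <- function(pep, sequences) {
  k <- nchar(pep)
  names(sequences)[vapply(sequences, function(s) {
    n <- nchar(s)
    if (k > n) return(FALSE)
    any(vapply(seq_len(n - k + 1L), function(i) {
      substr(s, i, i + k - 1L) == pep
    }, logical(1)))
  }, logical(1))]
}

# Independent residue-mass table (copied from published monoisotopic values,
# typed separately from the package constant).
ORACLE_RES <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
                C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
                H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
                M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
                T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_CYS <- 45.98772
ORACLE_SHIFT_K <- 8.014199
ORACLE_SHIFT_R <- 10.008269

# Enumerate qualifying transitions for one peptide/label by cumulative sums.
enumerate_transitions_oracle <- function(pep, label, max_keep = 5L) {
  res <- ORACLE_RES[strsplit(pep, "")[[1]]]
  res[names(res) == "C"] <- res[names(res) == "C"] + ORACLE_CYS
  n <- length(res)
  cterm <- substr(pep, n, n)
  shift <- if (label == "heavy") {
    if (cterm == "K") ORACLE_SHIFT_K else ORACLE_SHIFT_R
  } else 0
  neutral <- sum(res) + ORACLE_WATER + shift
  prec <- (neutral + 2 * ORACLE_PROTON) / 2
  rows <- data.frame(type = character(0), index = integer(0), mz = numeric(0))
  for (i in seq_len(n - 1)) {
    y <- sum(res[(n - i + 1):n]) + ORACLE_WATER + ORACLE_PROTON + shift
    b <- sum(res[1:i]) + ORACLE_PROTON
    rows <- rbind(rows,
                  data.frame(type = "y", index = i, mz = y),
                  data.frame(type = "b", index = i, mz = b))
  }
  rows <- rows[rows$mz > prec, , drop = FALSE]
  rows <- rows[order(-rows$index, match(rows$type, c("y", "b"))), , drop = FALSE]
  utils::head(rows, max_keep)
}

# Spearman rho by the classical rank formula (no ties assumed).
spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

random_protein <- function(n, seed) {
  antquant::gen_isoform_family(n = 2, length = n, identity = 1, seed = seed
  )$isoforms$sequence[1]
}
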