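#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Amino-acid alphabet used throughout (20 standard residues).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assert_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(what, " must be a single non-empty amino-acid string", call. = FALSE)
  }
  bad <- setdiff(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-standard residues: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
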