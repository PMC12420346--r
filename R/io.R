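# Plain-text I/O: transition lists, panel reports, long-format tables and
# genes x samples matrices. All formats are comma/tab-separated text.

#' Write a transition list
#'
#' Vendor-neutral CSV with columns peptide, isoform, label, precursor_mz,
#' precursor_charge, fragment_type, fragment_index, fragment_charge,
#' fragment_mz, rt_window_start, rt_window_end.
#'
#' @param transitions a `transition_set` from [build_transition_list()].
#' @param path output file.
#' @export
write_transition_list <- function(transitions, path) {
  out <- as.data.frame(transitions)
  names(out)[names(out) == "isoform_id"] <- "isoform"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition list written by [write_transition_list()]
#' @param path CSV file.
#' @return data.frame of class `transition_set`.
#' @export
read_transition_list <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(out)[names(out) == "isoform"] <- "isoform_id"
  class(out) <- c("transition_set", "data.frame")
  out
}

#' Write a panel report with the per-rule rejection log
#'
#' @param selection output of [select_panel()].
#' @param path output text file.
#' @export
write_panel_report <- function(selection, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Panel peptides (isoform, start-end, missed cleavages)", con)
  p <- selection$panel
  writeLines(sprintf("%s\t%s\t%d-%d\t%d", p$isoform_id, p$sequence,
                     p$start, p$end, p$missed_cleavages), con)
  writeLines("", con)
  writeLines("# Rejections (isoform, peptide, rule, reason)", con)
  l <- selection$log
  writeLines(sprintf("%s\t%s\t%s\t%s", l$isoform_id, l$sequence,
                     l$rule, l$reason), con)
  invisible(path)
}

# Delimited table with delimiter sniffing (comma or tab).
read_table_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a genes x samples matrix
#'
#' Tab- or comma-separated, header = sample ids, first column = gene id.
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- read_table_auto(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a gene set (one id per line, '#' comments allowed)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# JSON (or YAML, if installed) config reader for CLI policy/spike/segment files.
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
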