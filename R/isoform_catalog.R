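# Isoform catalog: in-silico tryptic digestion, isoform-unique peptide
# determination, panel selection under an explicit policy, and PRM transition
# list construction.

#' Construct an isoform set
#'
#' A small container for a paralog family: the universe within which peptide
#' uniqueness is decided.
#'
#' @param ids character vector of short isoform labels (unique).
#' @param sequences character vector of amino-acid sequences (one-letter,
#'   20 standard residues).
#' @param accessions optional database accessions, same length.
#' @return an object of class `isoform_set`: a data.frame with columns
#'   `isoform_id`, `accession`, `sequence`.
#' @export
isoform_set <- function(ids, sequences, accessions = NA_character_) {
  if (length(ids) < 2L) stop("an isoform set needs at least 2 entries", call. = FALSE)
  if (anyDuplicated(ids)) stop("isoform ids must be unique", call. = FALSE)
  if (length(ids) != length(sequences)) stop("ids and sequences differ in length", call. = FALSE)
  for (i in seq_along(sequences)) {
    assert_sequence(sequences[[i]], paste0("sequence of '", ids[[i]], "'"))
  }
  out <- data.frame(
    isoform_id = as.character(ids),
    accession = rep_len(as.character(accessions), length(ids)),
    sequence = as.character(sequences),
    stringsAsFactors = FALSE
  )
  class(out) <- c("isoform_set", "data.frame")
  out
}

#' Read a paralog family from a FASTA file
#'
#' The first whitespace-delimited header token is used as the isoform id; a
#' `sp|ACC|NAME`-style token is split so the id is the entry name and the
#' accession is retained. Sequences are uppercased and a terminal `*` is
#' stripped.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return an [isoform_set()].
#' @export
read_isoform_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  headers <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  accession <- rep(NA_character_, length(headers))
  ids <- headers
  piped <- grepl("|", headers, fixed = TRUE)
  if (any(piped)) {
    parts <- strsplit(headers[piped], "|", fixed = TRUE)
    accession[piped] <- vapply(parts, function(p) p[min(2L, length(p))], character(1))
    ids[piped] <- vapply(parts, function(p) p[length(p)], character(1))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sub("\\*$", "", as.character(seqs)))
  for (i in seq_along(sequences)) {
    bad <- setdiff(strsplit(sequences[[i]], "", fixed = TRUE)[[1]], AA_ALPHABET)
    if (length(bad)) {
      stop("record '", ids[[i]], "' contains non-standard residues: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  isoform_set(ids, sequences, accession)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (trypsin `[KR|P]`),
#' returning all peptides with 0..`max_missed` internal missed cleavages.
#' No length filter is applied here; filtering is [select_panel()]'s job.
#'
#' @param sequence protein sequence.
#' @param max_missed maximum number of internal missed cleavages (>= 0).
#' @param isoform_id optional label attached to the output.
#' @return data.frame with columns `sequence`, `isoform_id`, `start`, `end`
#'   (1-based inclusive), `missed_cleavages`, `is_protein_nterm`,
#'   `contains_met`.
#' @examples
#' digest("AKPRGK", max_missed = 0)$sequence  # "AKPR" "GK"
#' @export
digest <- function(sequence, max_missed = 1L, isoform_id = NA_character_) {
  assert_sequence(sequence, "protein sequence")
  stopifnot(max_missed >= 0)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(residues)
  # cleavage after position i; the protein end is always a boundary
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | residues[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(cut_after, n))
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  ends <- bounds
  n_frag <- length(starts)

  rows <- vector("list", 0L)
  for (mc in 0:max_missed) {
    if (mc >= n_frag && mc > 0) break
    i <- seq_len(n_frag - mc)
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts[i], end = ends[i + mc], missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$sequence <- substring(sequence, out$start, out$end)
  nterm_met <- residues[1] == "M"
  out$is_protein_nterm <- out$start == 1L | (nterm_met & out$start == 2L)
  out$contains_met <- grepl("M", out$sequence, fixed = TRUE)
  out$isoform_id <- isoform_id
  out <- out[order(out$start, out$missed_cleavages),
             c("sequence", "isoform_id", "start", "end", "missed_cleavages",
               "is_protein_nterm", "contains_met")]
  rownames(out) <- NULL
  out
}

#' Digest every isoform of a family
#'
#' @param isoforms an [isoform_set()].
#' @param max_missed maximum missed cleavages (default 1, enough to surface
#'   missed-cleavage candidates that a policy allowlist may admit).
#' @return row-bound digest of all isoforms.
#' @export
digest_family <- function(isoforms, max_missed = 1L) {
  stopifnot(inherits(isoforms, "isoform_set"))
  do.call(rbind, lapply(seq_len(nrow(isoforms)), function(i) {
    digest(isoforms$sequence[i], max_missed, isoforms$isoform_id[i])
  }))
}

#' Annotate peptides with isoform uniqueness
#'
#' A peptide's `occurs_in` is the set of isoform ids whose full sequence
#' contains it as an exact substring; it is unique iff that set has size 1.
#'
#' @param peptides data.frame from [digest()]/[digest_family()].
#' @param isoforms the [isoform_set()] defining the uniqueness universe.
#' @return `peptides` with added columns `occurs_in` (list of character) and
#'   `is_unique`.
#' @export
assign_uniqueness <- function(peptides, isoforms) {
  stopifnot(inherits(isoforms, "isoform_set"))
  if (!all(peptides$isoform_id %in% c(isoforms$isoform_id, NA))) {
    stop("peptides reference isoforms absent from the set", call. = FALSE)
  }
  occurs <- lapply(peptides$sequence, function(p) {
    isoforms$isoform_id[vapply(isoforms$sequence, grepl, logical(1),
                               pattern = p, fixed = TRUE)]
  })
  peptides$occurs_in <- occurs
  peptides$is_unique <- lengths(occurs) == 1L
  peptides
}

#' Peptide selection policy
#'
#' Encodes the filters applied to uniqueness-annotated candidates: a length
#' window, exclusion of protein N-terminal peptides (acetylation-prone),
#' per-isoform exclusion of methionine-containing peptides (oxidation risk),
#' an explicit allowlist admitting named missed-cleavage peptides, and manual
#' exclusions with recorded reasons.
#'
#' @param min_len,max_len length window in residues (defaults 6 and 25).
#' @param exclude_protein_nterm reject peptides spanning residue 1 (or residue
#'   2 when residue 1 is the initiator Met). Default TRUE.
#' @param exclude_met character vector of isoform ids whose Met-containing
#'   peptides are rejected.
#' @param missed_cleavage_allowlist peptide sequences admitted despite missed
#'   cleavages.
#' @param manual_exclusions named character vector: names are peptide
#'   sequences, values the recorded reason.
#' @return an object of class `selection_policy`.
#' @export
selection_policy <- function(min_len = 6L, max_len = 25L,
                             exclude_protein_nterm = TRUE,
                             exclude_met = character(0),
                             missed_cleavage_allowlist = character(0),
                             manual_exclusions = character(0)) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (length(manual_exclusions) && is.null(names(manual_exclusions))) {
    # unnamed vector: values are the sequences, reason is generic
    manual_exclusions <- stats::setNames(
      rep("manual exclusion", length(manual_exclusions)), manual_exclusions)
  }
  if (length(intersect(missed_cleavage_allowlist, names(manual_exclusions)))) {
    stop("allowlist and manual exclusions must be disjoint", call. = FALSE)
  }
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         exclude_protein_nterm = isTRUE(exclude_protein_nterm),
         exclude_met = exclude_met,
         missed_cleavage_allowlist = missed_cleavage_allowlist,
         manual_exclusions = manual_exclusions),
    class = "selection_policy"
  )
}

#' Select the quantification panel
#'
#' Applies the policy rules in a fixed precedence order (uniqueness, length,
#' missed cleavage, protein N-terminus, methionine, manual exclusion); every
#' rejected candidate is logged with the first rule it failed. The panel is
#' ordered by isoform then start coordinate and de-duplicated, so the result
#' is independent of candidate input order.
#'
#' @param candidates uniqueness-annotated peptides (see [assign_uniqueness()]).
#' @param policy a [selection_policy()].
#' @return list with elements `panel` (data.frame of retained peptides) and
#'   `log` (data.frame: `sequence`, `isoform_id`, `rule`, `reason`). An
#'   isoform with zero panel peptides triggers a warning.
#' @export
select_panel <- function(candidates, policy = selection_policy()) {
  stopifnot(inherits(policy, "selection_policy"))
  if (is.null(candidates$is_unique)) {
    stop("candidates lack uniqueness annotation; run assign_uniqueness() first",
         call. = FALSE)
  }
  candidates <- unique(candidates[, setdiff(names(candidates), "occurs_in")])
  len <- nchar(candidates$sequence)

  rule <- rep(NA_character_, nrow(candidates))
  reason <- rep(NA_character_, nrow(candidates))
  set <- function(idx, rl, rs) {
    idx <- idx & is.na(rule)
    rule[idx] <<- rl
    reason[idx] <<- rs
  }
  set(!candidates$is_unique, "uniqueness", "shared between isoforms")
  set(len < policy$min_len | len > policy$max_len, "length",
      sprintf("length outside [%d, %d]", policy$min_len, policy$max_len))
  set(candidates$missed_cleavages > 0 &
        !candidates$sequence %in% policy$missed_cleavage_allowlist,
      "missed_cleavage", "missed cleavage not on allowlist")
  if (policy$exclude_protein_nterm) {
    set(candidates$is_protein_nterm, "protein_nterm",
        "protein N-terminus (acetylation-prone)")
  }
  if (length(policy$exclude_met)) {
    set(candidates$contains_met & candidates$isoform_id %in% policy$exclude_met,
        "methionine", "methionine oxidation risk")
  }
  if (length(policy$manual_exclusions)) {
    idx <- which(candidates$sequence %in% names(policy$manual_exclusions) & is.na(rule))
    rule[idx] <- "manual"
    reason[idx] <- unname(policy$manual_exclusions[candidates$sequence[idx]])
  }

  keep <- is.na(rule)
  panel <- candidates[keep, , drop = FALSE]
  panel <- panel[order(panel$isoform_id, panel$start), , drop = FALSE]
  rownames(panel) <- NULL
  log <- data.frame(
    sequence = candidates$sequence[!keep],
    isoform_id = candidates$isoform_id[!keep],
    rule = rule[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  log <- log[order(log$isoform_id, log$sequence), , drop = FALSE]
  rownames(log) <- NULL

  empty <- setdiff(unique(candidates$isoform_id), unique(panel$isoform_id))
  if (length(empty)) {
    warning("no panel peptides retained for isoform(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  list(panel = panel, log = log)
}

#' Build a PRM transition list
#'
#' For each panel peptide and each label (light, heavy), enumerates singly
#' charged y and b ions, keeps those with fragment m/z above that precursor's
#' own m/z, ranks by fragment index descending (y before b on ties) and keeps
#' at most `fragments_per_precursor`. Peptides with no qualifying fragment are
#' dropped with a warning.
#'
#' @param panel data.frame with at least `sequence` and `isoform_id` columns.
#' @param fragments_per_precursor maximum fragments per precursor (default 5).
#' @param precursor_charge precursor charge state (default 2).
#' @param rt named numeric vector of retention-time centers (minutes) per
#'   peptide sequence, or NULL for NA windows.
#' @param rt_window_width acquisition window width in minutes (default 3).
#' @param fixed_mods see [peptide_neutral_mass()].
#' @return data.frame of class `transition_set` with columns `peptide`,
#'   `isoform_id`, `label`, `precursor_charge`, `precursor_mz`,
#'   `fragment_type`, `fragment_index`, `fragment_charge`, `fragment_mz`,
#'   `rt_window_start`, `rt_window_end`.
#' @export
build_transition_list <- function(panel, fragments_per_precursor = 5L,
                                  precursor_charge = 2L, rt = NULL,
                                  rt_window_width = 3,
                                  fixed_mods = DEFAULT_FIXED_MODS) {
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  rows <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(panel))) {
    pep <- panel$sequence[i]
    n <- nchar(pep)
    center <- if (!is.null(rt) && pep %in% names(rt)) rt[[pep]] else NA_real_
    for (label in c("light", "heavy")) {
      pmz <- precursor_mz(pep, precursor_charge, label, fixed_mods)
      frag <- expand.grid(fragment_type = c("y", "b"),
                          fragment_index = seq_len(n - 1L),
                          stringsAsFactors = FALSE)
      frag$fragment_mz <- mapply(function(tp, ix) {
        fragment_mz(pep, tp, ix, label, fixed_mods)
      }, frag$fragment_type, frag$fragment_index)
      frag <- frag[frag$fragment_mz > pmz, , drop = FALSE]
      if (nrow(frag) == 0L) {
        if (label == "light") dropped <- c(dropped, pep)
        next
      }
      frag <- frag[order(-frag$fragment_index,
                         match(frag$fragment_type, c("y", "b"))), , drop = FALSE]
      frag <- utils::head(frag, fragments_per_precursor)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, isoform_id = panel$isoform_id[i], label = label,
        precursor_charge = precursor_charge, precursor_mz = pmz,
        fragment_type = frag$fragment_type,
        fragment_index = frag$fragment_index,
        fragment_charge = 1L, fragment_mz = frag$fragment_mz,
        rt_window_start = center - rt_window_width / 2,
        rt_window_end = center + rt_window_width / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(dropped)) {
    warning("peptide(s) with no fragment above precursor m/z excluded: ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no transitions could be built", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("transition_set", "data.frame")
  out
}
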