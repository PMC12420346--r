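# Extracellular-flux bioenergetics: per-cell normalization, segment means of
# the mitochondrial/glycolysis stress test, derived OCR/ECAR characteristics,
# and group comparison.
#
# Measurement scheme: 10 measurements per well, 2 per segment, with segments
# 1 = pre-glucose, 2 = post-glucose (port A), 3 = post-oligomycin (port B),
# 4 = post-FCCP (port C), 5 = post-rotenone/antimycin + 2-deoxyglucose
# (port D). "Characteristic a-b" means segment-mean difference s_a - s_b.

#' Map measurement indices to stress-test segments
#'
#' @param measurement integer measurement indices 1..10.
#' @return integer segment ids 1..5 (two measurements per segment).
#' @export
default_segment_map <- function(measurement) {
  stopifnot(all(measurement %in% 1:10))
  (as.integer(measurement) + 1L) %/% 2L
}

#' Normalize a flux plate per cell
#'
#' Background-well means (per measurement index and assay) are subtracted
#' first when background wells exist; OCR and ECAR are then divided by the
#' well's cell count and expressed per 1000 cells. Wells with zero cell count
#' are excluded with a warning.
#'
#' @param plate data.frame with columns `well`, `group`, `measurement`,
#'   `ocr`, `ecar`, `cell_count`, and optionally logical `is_background`.
#'   Wells with group `"background"` are also treated as background.
#' @return the plate restricted to non-background wells with `ocr`/`ecar`
#'   normalized per 1000 cells.
#' @export
normalize_per_cell <- function(plate) {
  need <- c("well", "group", "measurement", "ocr", "ecar", "cell_count")
  stopifnot(all(need %in% names(plate)))
  bg <- if ("is_background" %in% names(plate)) {
    plate$is_background
  } else plate$group == "background"

  if (any(bg)) {
    for (v in c("ocr", "ecar")) {
      bg_mean <- tapply(plate[[v]][bg], plate$measurement[bg], mean)
      plate[[v]] <- plate[[v]] -
        as.numeric(bg_mean[as.character(plate$measurement)])
    }
  }
  plate <- plate[!bg, , drop = FALSE]
  zero <- plate$cell_count <= 0
  if (any(zero)) {
    warning("excluding well(s) with zero cell count: ",
            paste(unique(plate$well[zero]), collapse = ", "), call. = FALSE)
    plate <- plate[!zero, , drop = FALSE]
  }
  plate$ocr <- plate$ocr / (plate$cell_count / 1000)
  plate$ecar <- plate$ecar / (plate$cell_count / 1000)
  rownames(plate) <- NULL
  plate
}

#' Per-well segment means
#'
#' @param plate (normalized) plate table; a `segment` column is derived from
#'   `measurement` via [default_segment_map()] when absent.
#' @return data.frame per (well, group, segment) with mean `ocr` and `ecar`;
#'   segments with a missing measurement are averaged over available points
#'   with `incomplete = TRUE`.
#' @export
segment_means <- function(plate) {
  if (is.null(plate$segment)) plate$segment <- default_segment_map(plate$measurement)
  stopifnot(all(plate$segment %in% 1:5))
  ag <- stats::aggregate(cbind(ocr, ecar) ~ well + group + segment,
                         data = plate, FUN = mean)
  cnt <- stats::aggregate(measurement ~ well + segment, data = plate, FUN = length)
  names(cnt)[3] <- "n_points"
  out <- merge(ag, cnt, by = c("well", "segment"))
  out$incomplete <- out$n_points < 2
  out <- out[order(out$well, out$segment),
             c("well", "group", "segment", "ocr", "ecar", "n_points", "incomplete")]
  rownames(out) <- NULL
  out
}

#' OCR characteristics from a 5-segment vector
#'
#' baseline = s1 - s5; ATP-linked = s1 - s3; maximal = s4 - s5;
#' spare capacity = s4 - s2; proton leak = s3 - s5. Baseline respiration is
#' computed in the absence of added glucose (segment 1) while maximal uses the
#' post-FCCP, glucose-present segment (segment 4). By construction
#' ATP-linked + proton leak = baseline. Negative values are retained and
#' flagged, not clipped.
#'
#' @param s numeric length-5 vector of segment means.
#' @return named list: `baseline`, `atp_linked`, `maximal`, `spare`,
#'   `proton_leak`, plus `negative_flag`.
#' @export
ocr_characteristics <- function(s) {
  stopifnot(length(s) == 5)
  out <- list(baseline = s[1] - s[5], atp_linked = s[1] - s[3],
              maximal = s[4] - s[5], spare = s[4] - s[2],
              proton_leak = s[3] - s[5])
  out$negative_flag <- any(unlist(out) < 0)
  out
}

#' ECAR characteristics from a 5-segment vector
#'
#' baseline = s1 - s5; glycolytic capacity = s3 - s5; glycolytic
#' reserve = s3 - s2.
#'
#' @param s numeric length-5 vector of segment means.
#' @return named list: `baseline`, `glycolytic_capacity`,
#'   `glycolytic_reserve`, `negative_flag`.
#' @export
ecar_characteristics <- function(s) {
  stopifnot(length(s) == 5)
  out <- list(baseline = s[1] - s[5], glycolytic_capacity = s[3] - s[5],
              glycolytic_reserve = s[3] - s[2])
  out$negative_flag <- any(unlist(out) < 0)
  out
}

#' OCR/ECAR ratio
#'
#' ATP-linked OCR divided by glycolytic ECAR. "Glycolytic ECAR" defaults to
#' the post-glucose minus post-2DG difference (s2 - s5); glycolytic capacity
#' (s3 - s5) is available as an alternative definition.
#'
#' @param ocr_segments,ecar_segments length-5 segment-mean vectors.
#' @param glycolytic `"post_glucose"` (s2 - s5, default) or `"capacity"`
#'   (s3 - s5).
#' @return the ratio; NA with a flag attribute when the denominator is 0.
#' @export
ocr_ecar_ratio <- function(ocr_segments, ecar_segments,
                           glycolytic = c("post_glucose", "capacity")) {
  glycolytic <- match.arg(glycolytic)
  atp <- ocr_segments[1] - ocr_segments[3]
  den <- if (glycolytic == "post_glucose") {
    ecar_segments[2] - ecar_segments[5]
  } else {
    ecar_segments[3] - ecar_segments[5]
  }
  if (den == 0) {
    out <- NA_real_
    attr(out, "flag") <- "zero glycolytic ECAR"
    return(out)
  }
  unname(atp / den)
}

#' Per-well flux characteristics for a plate
#'
#' @param plate raw plate table (see [normalize_per_cell()]).
#' @param normalize normalize per cell first (default TRUE).
#' @param glycolytic passed to [ocr_ecar_ratio()].
#' @return data.frame per well: group plus all OCR and ECAR characteristics
#'   and the OCR/ECAR ratio.
#' @export
flux_characteristics <- function(plate, normalize = TRUE,
                                 glycolytic = "post_glucose") {
  if (normalize) plate <- normalize_per_cell(plate)
  sm <- segment_means(plate)
  wells <- unique(sm[, c("well", "group")])
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    d <- sm[sm$well == wells$well[i], ]
    d <- d[order(d$segment), ]
    if (nrow(d) != 5) stop("well ", wells$well[i], " lacks segments", call. = FALSE)
    oc <- ocr_characteristics(d$ocr)
    ec <- ecar_characteristics(d$ecar)
    data.frame(
      well = wells$well[i], group = wells$group[i],
      baseline_ocr = oc$baseline, atp_linked_ocr = oc$atp_linked,
      maximal_ocr = oc$maximal, spare_ocr = oc$spare,
      proton_leak_ocr = oc$proton_leak,
      baseline_ecar = ec$baseline,
      glycolytic_capacity_ecar = ec$glycolytic_capacity,
      glycolytic_reserve_ecar = ec$glycolytic_reserve,
      ocr_ecar_ratio = as.numeric(ocr_ecar_ratio(d$ocr, d$ecar, glycolytic)),
      negative_flag = oc$negative_flag || ec$negative_flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare flux characteristics between two groups
#'
#' Two-sided Mann-Whitney U test per characteristic (exact when sample sizes
#' permit and there are no ties; the normal approximation otherwise).
#'
#' @param characteristics output of [flux_characteristics()].
#' @param group_a,group_b the two group labels (>= 3 wells each).
#' @return data.frame per characteristic: `characteristic`, `u`, `p`,
#'   `median_a`, `median_b`.
#' @export
compare_flux_groups <- function(characteristics, group_a, group_b) {
  vars <- setdiff(names(characteristics), c("well", "group", "negative_flag"))
  a <- characteristics[characteristics$group == group_a, ]
  b <- characteristics[characteristics$group == group_b, ]
  if (nrow(a) < 3 || nrow(b) < 3) stop("need >= 3 wells per group", call. = FALSE)
  rows <- lapply(vars, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(a[[v]], b[[v]], exact = NULL))
    data.frame(characteristic = v, u = unname(wt$statistic), p = wt$p.value,
               median_a = stats::median(a[[v]], na.rm = TRUE),
               median_b = stats::median(b[[v]], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
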