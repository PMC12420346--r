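# PRM quantification: extracted-ion-chromatogram integration, target-to-heavy
# ratios, technical/biological aggregation, isoform levels, and fold changes
# with replicate statistics.

#' Integrate an extracted-ion chromatogram
#'
#' Trapezoidal integral of intensity over a retention-time window, with
#' optional constant-baseline subtraction (baseline = median intensity of
#' points outside the window). The window boundaries are interpolated
#' linearly; the result is clipped at 0.
#'
#' @param time numeric vector, minutes, strictly increasing.
#' @param intensity numeric vector, same length, finite and >= 0.
#' @param rt_window length-2 numeric `c(start, end)`; must lie within the
#'   trace's time span.
#' @param baseline_mode `"none"` or `"median_outside"`.
#' @return peak area (intensity x minutes), >= 0.
#' @export
integrate_xic <- function(time, intensity,
                          rt_window = range(time),
                          baseline_mode = c("none", "median_outside")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(length(time) == length(intensity), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  lo <- rt_window[1]; hi <- rt_window[2]
  if (lo >= hi) stop("empty retention-time window", call. = FALSE)
  if (lo < min(time) || hi > max(time)) {
    stop("rt_window outside the trace time span", call. = FALSE)
  }
  if (all(intensity == 0)) {
    warning("all-zero trace; area 0", call. = FALSE)
    return(0)
  }
  y <- intensity
  if (baseline_mode == "median_outside") {
    outside <- time < lo | time > hi
    if (any(outside)) y <- pmax(intensity - stats::median(intensity[outside]), 0)
  }
  # clip the trace to [lo, hi] with interpolated boundary points
  inside <- time >= lo & time <= hi
  tt <- time[inside]; yy <- y[inside]
  if (!length(tt) || tt[1] > lo) {
    tt <- c(lo, tt); yy <- c(stats::approx(time, y, lo)$y, yy)
  }
  if (tt[length(tt)] < hi) {
    tt <- c(tt, hi); yy <- c(yy, stats::approx(time, y, hi)$y)
  }
  max(sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2), 0)
}

#' Target-to-heavy peptide ratio
#'
#' Light and heavy fragment areas are intersected by fragment id before
#' summation, so unmatched fragments cannot bias numerator or denominator.
#'
#' @param light_areas,heavy_areas named numeric vectors of peak areas per
#'   fragment id.
#' @return ratio (sum of light) / (sum of heavy) over shared fragments, or
#'   `NA` with a `"flag"` attribute when no shared fragment has heavy
#'   signal.
#' @export
peptide_ratio <- function(light_areas, heavy_areas) {
  shared <- intersect(names(light_areas), names(heavy_areas))
  if (!length(shared)) {
    stop("no shared fragments between light and heavy", call. = FALSE)
  }
  h <- sum(heavy_areas[shared])
  if (!is.finite(h) || h <= 0) {
    out <- NA_real_
    attr(out, "flag") <- "zero heavy area"
    return(out)
  }
  sum(light_areas[shared]) / h
}

#' Aggregate technical replicates
#'
#' @param ratios numeric vector of technical-replicate ratios (NAs dropped).
#' @return list with `mean` and `cv` (sd/mean; NA when < 2 usable values,
#'   with a `"flag"` attribute).
#' @export
aggregate_technical <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no usable technical-replicate ratios", call. = FALSE)
  m <- mean(ratios)
  if (length(ratios) >= 2) {
    cv <- stats::sd(ratios) / m
  } else {
    cv <- NA_real_
    attr(cv, "flag") <- "single technical replicate"
  }
  list(mean = m, cv = cv)
}

#' Isoform-level value from peptide ratios
#'
#' The isoform value is the unweighted mean over its panel peptides of
#' (ratio x heavy spike), i.e. fmol-equivalents per amount of digested
#' protein; `mode = "ratio"` returns the mean raw ratio instead. When the
#' estimated target falls below spike/5 the heavy standard exceeds fivefold
#' of the target level and the result is flagged.
#'
#' @param peptide_means numeric vector of per-peptide mean ratios (NAs are
#'   flagged peptides and are dropped).
#' @param heavy_spike_fmol spiked heavy amount per peptide (fmol).
#' @param mode `"fmol"` or `"ratio"`.
#' @return isoform value, with attribute `"spike_warning"` = TRUE when the
#'   fivefold spike policy is violated; NA when all peptides are flagged.
#' @export
isoform_level <- function(peptide_means, heavy_spike_fmol = 1,
                          mode = c("fmol", "ratio")) {
  mode <- match.arg(mode)
  usable <- peptide_means[!is.na(peptide_means)]
  if (!length(usable)) return(NA_real_)
  mean_ratio <- mean(usable)
  out <- if (mode == "fmol") mean_ratio * heavy_spike_fmol else mean_ratio
  if (mean_ratio < 1 / 5) {
    attr(out, "spike_warning") <- TRUE
    warning("heavy standard exceeds fivefold of the estimated target level",
            call. = FALSE)
  }
  out
}

#' Log2 fold change between conditions
#'
#' @param treated,control numeric vectors of biological-replicate values.
#' @return `log2(mean(treated)/mean(control))`; NA with a flag attribute when
#'   either mean is non-positive.
#' @export
fold_change <- function(treated, control) {
  mt <- mean(treated, na.rm = TRUE)
  mc <- mean(control, na.rm = TRUE)
  if (!is.finite(mt) || !is.finite(mc) || mt <= 0 || mc <= 0) {
    out <- NA_real_
    attr(out, "flag") <- "non-positive group mean"
    return(out)
  }
  log2(mt / mc)
}

#' Dunn's post hoc test against a control group
#'
#' Rank-based pairwise z tests on the joint ranking of all groups (the
#' Kruskal-Wallis follow-up), comparing each group to the control, with a
#' multiplicity adjustment across comparisons.
#'
#' @param values numeric vector.
#' @param groups factor/character of group labels.
#' @param control control group label.
#' @param p_adjust adjustment method for [stats::p.adjust()] (default "BH").
#' @return data.frame: `group`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, control, p_adjust = "BH") {
  groups <- as.character(groups)
  stopifnot(control %in% groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  r <- rank(values)
  n <- length(values)
  # tie correction for the variance of mean rank differences
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  others <- setdiff(unique(groups), control)
  res <- lapply(others, function(g) {
    ni <- sum(groups == g); nj <- sum(groups == control)
    z <- (mean(r[groups == g]) - mean(r[groups == control])) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    data.frame(group = g, z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Time-course significance for PRM levels
#'
#' Two-way analysis of variance of isoform levels across (time point, isoform)
#' followed by a configured post hoc comparing each time point to the control:
#' Dunn's rank-based test (default) or Holm-adjusted pairwise Welch t tests,
#' run per isoform. The post hoc choice is recorded in the output.
#'
#' @param data data.frame with columns `condition`, `isoform`, `value`.
#' @param control control condition label.
#' @param posthoc `"dunn"` or `"holm_t"`.
#' @return list with `anova` (the aov summary table), `posthoc` (data.frame
#'   `isoform`, `condition`, statistic, `p`, `p_adj`) and `posthoc_method`.
#' @export
prm_timecourse_test <- function(data, control, posthoc = c("dunn", "holm_t")) {
  posthoc <- match.arg(posthoc)
  stopifnot(all(c("condition", "isoform", "value") %in% names(data)),
            control %in% data$condition)
  data$condition <- factor(data$condition)
  data$isoform <- factor(data$isoform)
  fit <- stats::aov(value ~ condition * isoform, data = data)
  tab <- summary(fit)[[1]]

  ph <- lapply(levels(data$isoform), function(iso) {
    d <- data[data$isoform == iso, ]
    if (posthoc == "dunn") {
      res <- dunn_test(d$value, d$condition, control)
      data.frame(isoform = iso, condition = res$group, statistic = res$z,
                 p = res$p, p_adj = res$p_adj)
    } else {
      others <- setdiff(unique(as.character(d$condition)), control)
      res <- lapply(others, function(g) {
        tt <- stats::t.test(d$value[d$condition == g],
                            d$value[d$condition == control])
        data.frame(isoform = iso, condition = g,
                   statistic = unname(tt$statistic), p = tt$p.value)
      })
      res <- do.call(rbind, res)
      res$p_adj <- stats::p.adjust(res$p, method = "holm")
      res
    }
  })
  list(anova = tab, posthoc = do.call(rbind, ph), posthoc_method = posthoc)
}

#' Quantify a set of PRM runs end to end
#'
#' Takes long-format XIC data, integrates each trace over its peptide's
#' retention-time window, forms target-to-heavy ratios per (condition,
#' biological replicate, technical replicate, peptide), averages technical
#' replicates, aggregates peptides to isoform levels, and computes log2 fold
#' changes against a control condition.
#'
#' @param xic data.frame in long format with columns `condition`, `bio_rep`,
#'   `tech_rep`, `peptide`, `isoform_id`, `label` ("light"/"heavy"),
#'   `fragment`, `time`, `intensity`.
#' @param rt_windows named list/vector: peptide -> `c(start, end)`; NULL
#'   integrates each full trace.
#' @param spike_fmol named numeric vector: isoform id -> heavy spike (fmol).
#' @param control control condition label (optional; enables fold changes).
#' @param baseline_mode passed to [integrate_xic()].
#' @return list with `peptides` (per condition/bio_rep/peptide: mean ratio and
#'   CV over technical replicates), `isoforms` (per condition/bio_rep/isoform:
#'   level), and `fold_changes` (per condition/isoform vs control) when
#'   `control` is given.
#' @export
quantify_prm <- function(xic, rt_windows = NULL, spike_fmol = NULL,
                         control = NULL, baseline_mode = "none") {
  need <- c("condition", "bio_rep", "tech_rep", "peptide", "isoform_id",
            "label", "fragment", "time", "intensity")
  missing_cols <- setdiff(need, names(xic))
  if (length(missing_cols)) {
    stop("xic lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  # area per (condition, bio, tech, peptide, label, fragment)
  key <- interaction(xic$condition, xic$bio_rep, xic$tech_rep, xic$peptide,
                     xic$label, xic$fragment, drop = TRUE)
  traces <- split(xic, key)
  areas <- lapply(traces, function(tr) {
    pep <- tr$peptide[1]
    win <- if (!is.null(rt_windows) && pep %in% names(rt_windows)) {
      rt_windows[[pep]]
    } else range(tr$time)
    data.frame(condition = tr$condition[1], bio_rep = tr$bio_rep[1],
               tech_rep = tr$tech_rep[1], peptide = pep,
               isoform_id = tr$isoform_id[1], label = tr$label[1],
               fragment = tr$fragment[1],
               area = integrate_xic(tr$time[order(tr$time)],
                                    tr$intensity[order(tr$time)],
                                    win, baseline_mode),
               stringsAsFactors = FALSE)
  })
  areas <- do.call(rbind, areas)

  # ratio per (condition, bio, tech, peptide)
  rkey <- interaction(areas$condition, areas$bio_rep, areas$tech_rep,
                      areas$peptide, drop = TRUE)
  ratios <- lapply(split(areas, rkey), function(a) {
    li <- a[a$label == "light", ]; he <- a[a$label == "heavy", ]
    r <- peptide_ratio(stats::setNames(li$area, li$fragment),
                       stats::setNames(he$area, he$fragment))
    data.frame(condition = a$condition[1], bio_rep = a$bio_rep[1],
               tech_rep = a$tech_rep[1], peptide = a$peptide[1],
               isoform_id = a$isoform_id[1], ratio = as.numeric(r),
               stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, ratios)

  # technical aggregation
  pkey <- interaction(ratios$condition, ratios$bio_rep, ratios$peptide, drop = TRUE)
  peptides <- lapply(split(ratios, pkey), function(d) {
    ag <- aggregate_technical(d$ratio)
    data.frame(condition = d$condition[1], bio_rep = d$bio_rep[1],
               peptide = d$peptide[1], isoform_id = d$isoform_id[1],
               ratio_mean = ag$mean, ratio_cv = as.numeric(ag$cv),
               n_tech = sum(!is.na(d$ratio)), stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, peptides)
  rownames(peptides) <- NULL

  # isoform aggregation
  ikey <- interaction(peptides$condition, peptides$bio_rep,
                      peptides$isoform_id, drop = TRUE)
  isoforms <- lapply(split(peptides, ikey), function(d) {
    iso <- d$isoform_id[1]
    spk <- if (!is.null(spike_fmol) && iso %in% names(spike_fmol)) {
      spike_fmol[[iso]]
    } else 1
    lv <- suppressWarnings(isoform_level(d$ratio_mean, spk))
    data.frame(condition = d$condition[1], bio_rep = d$bio_rep[1],
               isoform_id = iso, level = as.numeric(lv),
               spike_fmol = spk,
               spike_warning = isTRUE(attr(lv, "spike_warning")),
               stringsAsFactors = FALSE)
  })
  isoforms <- do.call(rbind, isoforms)
  rownames(isoforms) <- NULL

  out <- list(peptides = peptides, isoforms = isoforms)
  if (!is.null(control)) {
    stopifnot(control %in% isoforms$condition)
    combos <- unique(isoforms[isoforms$condition != control,
                              c("condition", "isoform_id")])
    fc <- lapply(seq_len(nrow(combos)), function(i) {
      tr <- isoforms$level[isoforms$condition == combos$condition[i] &
                             isoforms$isoform_id == combos$isoform_id[i]]
      ct <- isoforms$level[isoforms$condition == control &
                             isoforms$isoform_id == combos$isoform_id[i]]
      data.frame(condition = combos$condition[i],
                 isoform_id = combos$isoform_id[i],
                 log2fc = as.numeric(fold_change(tr, ct)),
                 n_treated = sum(!is.na(tr)), n_control = sum(!is.na(ct)),
                 stringsAsFactors = FALSE)
    })
    out$fold_changes <- do.call(rbind, fc)
  }
  out
}
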