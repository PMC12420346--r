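# mRNA-protein correlation structure: per-gene Pearson/Spearman with BH
# adjustment, gene-set distribution comparison, protein-protein
# intercorrelation around focus genes, and fold-change vs flux correlation.

#' Align and filter a paired expression dataset
#'
#' Intersects the gene universes of an mRNA (FPKM, genes x samples) and a
#' protein (zero-centered intensity, genes x samples) matrix, drops genes with
#' zero mRNA signal or all-missing protein, and reports the counts.
#'
#' @param mrna,protein numeric matrices with gene ids as rownames and a shared
#'   sample axis (identical column order).
#' @param zero_mode `"all_zero"` drops genes whose FPKM sum across samples is
#'   0 (default); `"any_zero"` drops genes with any zero FPKM sample.
#' @return list with filtered `mrna`, `protein`, and `report` (named counts:
#'   `shared`, `dropped_zero_fpkm`, `dropped_all_missing_protein`, `kept`).
#' @export
filter_genes <- function(mrna, protein, zero_mode = c("all_zero", "any_zero")) {
  zero_mode <- match.arg(zero_mode)
  stopifnot(is.matrix(mrna), is.matrix(protein),
            ncol(mrna) == ncol(protein))
  shared <- intersect(rownames(mrna), rownames(protein))
  if (!length(shared)) stop("no shared genes between matrices", call. = FALSE)
  m <- mrna[shared, , drop = FALSE]
  p <- protein[shared, , drop = FALSE]
  zero <- if (zero_mode == "all_zero") {
    rowSums(m, na.rm = TRUE) == 0
  } else {
    apply(m, 1, function(x) any(x == 0, na.rm = TRUE))
  }
  all_missing <- rowSums(!is.na(p)) == 0
  keep <- !zero & !all_missing
  list(
    mrna = m[keep, , drop = FALSE],
    protein = p[keep, , drop = FALSE],
    report = c(shared = length(shared),
               dropped_zero_fpkm = sum(zero),
               dropped_all_missing_protein = sum(all_missing & !zero),
               kept = sum(keep))
  )
}

# Spearman p: large-sample t approximation for n >= 10, exact/AS89 from
# cor.test below (see methods vignette for the rationale).
spearman_p <- function(rho, n, x = NULL, y = NULL) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (n < 10 && !is.null(x)) {
    return(suppressWarnings(
      stats::cor.test(x, y, method = "spearman")$p.value))
  }
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Per-gene mRNA-protein correlation
#'
#' Row-wise Pearson and Spearman correlation across samples with
#' pairwise-complete handling of missing protein values and
#' Benjamini-Hochberg adjustment across genes. For the Pearson coefficient
#' the mRNA is log2(FPKM + 1)-transformed by default; Spearman uses raw
#' ranks (rank-invariant).
#'
#' @param mrna,protein aligned matrices (e.g. from [filter_genes()]).
#' @param log2_mrna log-transform mRNA before Pearson (default TRUE).
#' @return data.frame per gene: `gene`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `n`, `constant_flag`, `pearson_p_adj`,
#'   `spearman_p_adj`.
#' @export
per_gene_correlation <- function(mrna, protein, log2_mrna = TRUE) {
  stopifnot(identical(rownames(mrna), rownames(protein)),
            ncol(mrna) == ncol(protein))
  m_pearson <- if (log2_mrna) log2(mrna + 1) else mrna
  genes <- rownames(mrna)
  rows <- lapply(seq_along(genes), function(i) {
    x <- mrna[i, ]; xp <- m_pearson[i, ]; y <- protein[i, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(gene = genes[i], pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, n = n, constant_flag = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(xp[ok], y[ok])
    tp <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2)); 2 * stats::pt(-abs(tt), n - 2)
    }
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    data.frame(gene = genes[i], pearson_r = r, pearson_p = tp,
               spearman_rho = rho,
               spearman_p = spearman_p(rho, n, x[ok], y[ok]),
               n = n, constant_flag = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pearson_p_adj <- stats::p.adjust(out$pearson_p, method = "BH")
  out$spearman_p_adj <- stats::p.adjust(out$spearman_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Compare the correlation distribution of a gene subset to the rest
#'
#' Reports the median Spearman rho for the subset and for all genes, and a
#' two-sided Mann-Whitney test between subset and non-subset coefficients.
#'
#' @param corr_table output of [per_gene_correlation()].
#' @param gene_set character vector of member gene ids; ids absent from the
#'   table are reported, not an error.
#' @param value which coefficient to compare (default `"spearman_rho"`).
#' @return list: `median_subset`, `median_all`, `n_subset`, `n_unmatched`,
#'   `u`, `p` (test NA with a warning when the matched subset has < 3 genes;
#'   error when the complement is empty).
#' @export
subset_distribution_compare <- function(corr_table, gene_set,
                                        value = "spearman_rho") {
  in_set <- corr_table$gene %in% gene_set
  unmatched <- setdiff(gene_set, corr_table$gene)
  v <- corr_table[[value]]
  ok <- !is.na(v)
  sub <- v[ok & in_set]; rest <- v[ok & !in_set]
  if (!length(rest)) stop("subset covers all genes; empty complement", call. = FALSE)
  out <- list(median_subset = stats::median(sub),
              median_all = stats::median(v[ok]),
              n_subset = length(sub), n_unmatched = length(unmatched),
              u = NA_real_, p = NA_real_)
  if (length(sub) < 3) {
    warning("subset smaller than 3 after matching; no test", call. = FALSE)
    return(out)
  }
  wt <- suppressWarnings(stats::wilcox.test(sub, rest))
  out$u <- unname(wt$statistic); out$p <- wt$p.value
  out
}

#' Protein-protein intercorrelation around focus genes
#'
#' Pairwise Pearson and Spearman correlations among focus genes, plus, for
#' each focus gene, the distribution of its correlation with every other gene
#' in the matrix, summarized overall and within each background gene set.
#'
#' @param protein genes x samples matrix.
#' @param focus_genes character vector of focus gene ids; missing ones are
#'   listed and skipped.
#' @param background_sets optional named list of gene-id vectors.
#' @return list: `pairwise_pearson`, `pairwise_spearman` (focus x focus
#'   matrices), `distributions` (per focus gene, numeric vector of Spearman
#'   correlations with all other genes), `summaries` (data.frame of medians
#'   overall and per background set), `missing_focus`.
#' @export
protein_intercorrelation <- function(protein, focus_genes,
                                     background_sets = list()) {
  present <- intersect(focus_genes, rownames(protein))
  missing_focus <- setdiff(focus_genes, rownames(protein))
  if (!length(present)) stop("no focus genes present in matrix", call. = FALSE)

  fmat <- t(protein[present, , drop = FALSE])
  pw_p <- stats::cor(fmat, use = "pairwise.complete.obs")
  pw_s <- stats::cor(fmat, use = "pairwise.complete.obs", method = "spearman")

  others <- setdiff(rownames(protein), present)
  tmat <- t(protein[others, , drop = FALSE])
  dist <- lapply(present, function(g) {
    if (!length(others)) return(stats::setNames(numeric(0), character(0)))
    r <- suppressWarnings(
      stats::cor(protein[g, ], tmat, use = "pairwise.complete.obs",
                 method = "spearman"))
    stats::setNames(as.numeric(r), others)
  })
  names(dist) <- present

  med <- function(x) if (sum(!is.na(x))) stats::median(x, na.rm = TRUE) else NA_real_
  summaries <- do.call(rbind, lapply(present, function(g) {
    d <- dist[[g]]
    row <- data.frame(focus = g, set = "all", median_rho = med(d),
                      n = sum(!is.na(d)), stringsAsFactors = FALSE)
    for (nm in names(background_sets)) {
      sel <- d[names(d) %in% background_sets[[nm]]]
      row <- rbind(row, data.frame(focus = g, set = nm, median_rho = med(sel),
                                   n = sum(!is.na(sel)),
                                   stringsAsFactors = FALSE))
    }
    row
  }))
  rownames(summaries) <- NULL
  list(pairwise_pearson = pw_p, pairwise_spearman = pw_s,
       distributions = dist, summaries = summaries,
       missing_focus = missing_focus)
}

#' Correlate pooled protein fold changes with a flux characteristic
#'
#' Pools per-isoform fold changes within each condition (sum by default) and
#' computes the Spearman correlation with the matched flux-characteristic fold
#' changes across conditions; per-isoform correlations are reported alongside.
#'
#' @param fc_table data.frame with columns `condition`, `isoform_id`, `log2fc`.
#' @param flux_fc data.frame with columns `condition` and `value` (the flux
#'   characteristic's change per condition).
#' @param pooling function used to pool isoform fold changes (default `sum`).
#' @return list: `pooled` (rho, p, n) and `per_isoform` (data.frame).
#' @export
fc_vs_flux_correlation <- function(fc_table, flux_fc, pooling = sum) {
  stopifnot(all(c("condition", "isoform_id", "log2fc") %in% names(fc_table)),
            all(c("condition", "value") %in% names(flux_fc)))
  pooled <- stats::aggregate(log2fc ~ condition, data = fc_table,
                             FUN = pooling)
  d <- merge(pooled, flux_fc, by = "condition")
  if (nrow(d) < 3) {
    warning("fewer than 3 matched conditions; no test", call. = FALSE)
    return(list(pooled = list(rho = NA_real_, p = NA_real_, n = nrow(d)),
                per_isoform = NULL))
  }
  rho <- stats::cor(d$log2fc, d$value, method = "spearman")
  res <- list(pooled = list(rho = rho,
                            p = spearman_p(rho, nrow(d), d$log2fc, d$value),
                            n = nrow(d)))
  per <- lapply(unique(fc_table$isoform_id), function(iso) {
    di <- merge(fc_table[fc_table$isoform_id == iso, ], flux_fc,
                by = "condition")
    if (nrow(di) < 3) {
      return(data.frame(isoform_id = iso, rho = NA_real_, p = NA_real_,
                        n = nrow(di), stringsAsFactors = FALSE))
    }
    r <- stats::cor(di$log2fc, di$value, method = "spearman")
    data.frame(isoform_id = iso, rho = r,
               p = spearman_p(r, nrow(di), di$log2fc, di$value),
               n = nrow(di), stringsAsFactors = FALSE)
  })
  res$per_isoform <- do.call(rbind, per)
  res
}
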