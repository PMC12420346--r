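# Relative transcript quantification by the delta-delta-Ct method with a
# reference gene and a control condition, plus the replicate-level t test on
# log2 fold changes.

#' Delta-delta-Ct relative quantification
#'
#' Replicate Ct values are averaged on the Ct scale per (sample, gene);
#' dCt = Ct(target) - Ct(reference) per sample; ddCt = dCt - mean dCt of the
#' control condition; RQ = 2^(-ddCt); log2FC = -ddCt. Amplification
#' efficiency is fixed at 2 (classic ddCt, no efficiency correction).
#'
#' @param ct data.frame with columns `sample`, `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param target target gene id.
#' @param reference reference (normalizer) gene id, measured in every sample.
#' @param control control condition label.
#' @return data.frame per sample: `sample`, `condition`, `dct`, `ddct`, `rq`,
#'   `log2fc`. Samples lacking reference measurements are dropped with a
#'   warning.
#' @export
delta_delta_ct <- function(ct, target, reference, control) {
  need <- c("sample", "condition", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  if (!control %in% ct$condition) stop("control condition absent", call. = FALSE)
  if (!target %in% ct$gene) stop("target gene absent", call. = FALSE)
  if (!reference %in% ct$gene) stop("reference gene absent", call. = FALSE)

  mean_ct <- stats::aggregate(ct ~ sample + condition + gene,
                              data = ct, FUN = mean)
  tgt <- mean_ct[mean_ct$gene == target, c("sample", "condition", "ct")]
  ref <- mean_ct[mean_ct$gene == reference, c("sample", "ct")]
  names(tgt)[3] <- "ct_target"; names(ref)[2] <- "ct_reference"
  d <- merge(tgt, ref, by = "sample", all.x = TRUE)
  if (anyNA(d$ct_reference)) {
    warning("dropping sample(s) without reference measurements: ",
            paste(d$sample[is.na(d$ct_reference)], collapse = ", "),
            call. = FALSE)
    d <- d[!is.na(d$ct_reference), ]
  }
  d$dct <- d$ct_target - d$ct_reference
  control_dct <- mean(d$dct[d$condition == control])
  d$ddct <- d$dct - control_dct
  d$rq <- 2^(-d$ddct)
  d$log2fc <- -d$ddct
  d <- d[order(d$condition, d$sample),
         c("sample", "condition", "dct", "ddct", "rq", "log2fc")]
  rownames(d) <- NULL
  d
}

#' One-sample t test on replicate log2 fold changes
#'
#' log2(FC) is treated as normally distributed and tested against 0.
#'
#' @param log2fc numeric vector of replicate log2 fold changes (>= 2 values).
#' @return list with `mean`, `t`, `df`, `p`, and `degenerate` (TRUE when the
#'   replicate variance is zero, in which case `t`/`p` are NA).
#' @export
log2fc_test <- function(log2fc) {
  log2fc <- log2fc[!is.na(log2fc)]
  if (length(log2fc) < 2) stop("need >= 2 replicates", call. = FALSE)
  m <- mean(log2fc)
  s <- stats::sd(log2fc)
  if (s == 0) {
    return(list(mean = m, t = NA_real_, df = length(log2fc) - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  t <- m / (s / sqrt(length(log2fc)))
  df <- length(log2fc) - 1L
  list(mean = m, t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}
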