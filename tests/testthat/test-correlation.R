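toy_pair <- function(n_genes = 6, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples, 0.1), n_genes,
              dimnames = list(paste0("g", 1:n_genes),
                              paste0("s", 1:n_samples)))
  p <- matrix(rnorm(n_genes * n_samples), n_genes, dimnames = dimnames(m))
  list(mrna = m, protein = p)
}

test_that("filter_genes drops planted zero-FPKM and all-missing genes and
           reports counts", {
  g <- gen_expression_pair(n_genes = 100, n_samples = 10, n_zero_genes = 7,
                           seed = 2)
  fl <- filter_genes(g$mrna, g$protein)
  expect_equal(unname(fl$report["shared"]), 107)
  expect_equal(unname(fl$report["dropped_zero_fpkm"]), 7)
  expect_equal(unname(fl$report["kept"]), 100)
  expect_false(any(g$truth$zero_genes %in% rownames(fl$mrna)))

  tp <- toy_pair()
  tp$protein["g3", ] <- NA
  fl2 <- filter_genes(tp$mrna, tp$protein)
  expect_equal(unname(fl2$report["dropped_all_missing_protein"]), 1)

  rownames(tp$protein) <- paste0("x", 1:6)
  expect_error(filter_genes(tp$mrna, tp$protein), "no shared genes")
})

test_that("per-gene correlation: exact linear/monotone cases and the
           rank-formula oracle", {
  x <- c(1, 3, 4, 7, 9, 12, 15)
  m <- rbind(lin = x, mono = x, noisy = c(2, 1, 5, 3, 9, 7, 12))
  p <- rbind(lin = 2 * log2(x + 1) + 1, mono = exp(x / 5),
             noisy = c(1, 4, 2, 8, 6, 11, 9))
  colnames(m) <- colnames(p) <- paste0("s", 1:7)
  tab <- per_gene_correlation(m, p)
  expect_equal(tab$pearson_r[tab$gene == "lin"], 1, tolerance = 1e-12)
  expect_equal(tab$spearman_rho[tab$gene == "lin"], 1)
  # monotone transform: Spearman stays 1, Pearson drops below 1
  expect_equal(tab$spearman_rho[tab$gene == "mono"], 1)
  expect_lt(tab$pearson_r[tab$gene == "mono"], 1)
  # rank-formula oracle on the tie-free row
  expect_equal(tab$spearman_rho[tab$gene == "noisy"],
               spearman_rank_formula(m["noisy", ], p["noisy", ]))
})

test_that("Spearman is invariant to strictly monotone row-wise transforms", {
  g <- gen_expression_pair(n_genes = 30, n_samples = 20, seed = 4)
  t1 <- per_gene_correlation(g$mrna, g$protein)
  t2 <- per_gene_correlation(g$mrna^3, exp(g$protein))
  expect_equal(t1$spearman_rho, t2$spearman_rho, tolerance = 1e-12)
})

test_that("missing protein values are handled pairwise-complete with n
           reported; constant rows are flagged", {
  tp <- toy_pair(seed = 8)
  tp$protein["g1", 1:3] <- NA
  tp$mrna["g2", ] <- 5
  tab <- per_gene_correlation(tp$mrna, tp$protein)
  expect_equal(tab$n[tab$gene == "g1"], 5)
  expect_true(tab$constant_flag[tab$gene == "g2"])
  expect_true(is.na(tab$spearman_rho[tab$gene == "g2"]))
  # BH adjustment: bounded by [raw p, 1] and order-preserving
  ok <- !is.na(tab$spearman_p)
  expect_true(all(tab$spearman_p_adj[ok] >= tab$spearman_p[ok]))
  expect_true(all(tab$spearman_p_adj[ok] <= 1))
  expect_equal(order(tab$spearman_p_adj[ok], tab$spearman_p[ok]),
               order(tab$spearman_p[ok]))
})

test_that("subset comparison: null subsets are calibrated, shifted subsets are
           detected (reduced scale)", {
  g <- gen_expression_pair(n_genes = 800, n_samples = 40, rho_median = 0.47,
                           subset_size = 120, subset_median = 0.20, seed = 10)
  tab <- per_gene_correlation(g$mrna, g$protein)
  cmp <- subset_distribution_compare(tab, g$truth$subset)
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$median_subset, cmp$median_all)

  # null: random subsets give roughly uniform p (check no gross anticonservatism)
  g0 <- gen_expression_pair(n_genes = 400, n_samples = 30, seed = 11)
  tab0 <- per_gene_correlation(g0$mrna, g0$protein)
  set.seed(12)
  ps <- replicate(40, {
    subset_distribution_compare(tab0, sample(tab0$gene, 80))$p
  })
  expect_gt(mean(ps < 0.05), -1e-9)   # sanity
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)

  expect_error(subset_distribution_compare(tab0, tab0$gene), "complement")
  expect_warning(subset_distribution_compare(tab0, tab0$gene[1:2]),
                 "smaller than 3")
  expect_equal(subset_distribution_compare(tab0, c(tab0$gene[1:5], "nope")
                                           )$n_unmatched, 1)
})

test_that("protein intercorrelation recovers planted block structure", {
  set.seed(13)
  n_samples <- 60
  base <- rnorm(n_samples)
  block <- rbind(F1 = base + rnorm(n_samples, 0, 0.3),
                 F2 = base + rnorm(n_samples, 0, 0.3),
                 F3 = base + rnorm(n_samples, 0, 0.3))
  noise <- matrix(rnorm(7 * n_samples), 7,
                  dimnames = list(paste0("N", 1:7), NULL))
  mat <- rbind(block, noise)
  colnames(mat) <- paste0("s", 1:n_samples)

  res <- protein_intercorrelation(mat, c("F1", "F2", "F3", "GONE"),
                                  background_sets = list(odd = c("N1", "N3", "N5")))
  expect_equal(res$missing_focus, "GONE")
  off <- res$pairwise_pearson[upper.tri(res$pairwise_pearson)]
  expect_true(all(abs(off - 1 / (1 + 0.09)) < 0.12))  # true r ~ 0.917
  expect_equal(dim(res$pairwise_spearman), c(3, 3))
  expect_equal(names(res$distributions), c("F1", "F2", "F3"))
  expect_equal(length(res$distributions$F1), 7)
  expect_equal(nrow(res$summaries), 3 * 2)

  # duplicated / negated rows hit the r = +/-1 corners
  mat2 <- rbind(A = base, B = base, C = -base)
  colnames(mat2) <- paste0("s", 1:n_samples)
  res2 <- protein_intercorrelation(mat2, c("A", "B", "C"))
  expect_equal(res2$pairwise_pearson["A", "B"], 1)
  expect_equal(res2$pairwise_pearson["A", "C"], -1)
})

test_that("fold-change vs flux correlation matches the rank oracle and
           degenerate pooling", {
  conditions <- paste0("c", 1:7)
  set.seed(14)
  fc <- do.call(rbind, lapply(c("ANT1", "ANT2", "ANT3"), function(iso) {
    data.frame(condition = conditions, isoform_id = iso,
               log2fc = rnorm(7), stringsAsFactors = FALSE)
  }))
  flux <- data.frame(condition = conditions, value = rnorm(7))
  res <- fc_vs_flux_correlation(fc, flux)
  pooled <- aggregate(log2fc ~ condition, fc, sum)
  d <- merge(pooled, flux, by = "condition")
  expect_equal(res$pooled$rho, spearman_rank_formula(d$log2fc, d$value))
  expect_equal(nrow(res$per_isoform), 3)

  # identical vectors -> rho = 1
  flux2 <- data.frame(condition = conditions, value = pooled$log2fc)
  expect_equal(fc_vs_flux_correlation(fc, flux2)$pooled$rho, 1)

  # pooling a single isoform equals that isoform's own correlation
  fc1 <- fc[fc$isoform_id == "ANT1", ]
  res1 <- fc_vs_flux_correlation(fc1, flux)
  expect_equal(res1$pooled$rho, res1$per_isoform$rho[1])

  expect_warning(
    out <- fc_vs_flux_correlation(fc[fc$condition %in% c("c1", "c2"), ], flux),
    "fewer than 3")
  expect_true(is.na(out$pooled$rho))
})
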