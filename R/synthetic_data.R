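# Ground-truthed synthetic inputs for every pipeline stage. Every generator
# is a pure function of its arguments (seed included) and returns the data
# together with the exact truth used to generate it, so stage-level recovery
# tests consume only (data, truth) pairs.
#
# Noise conventions: multiplicative lognormal with an additive floor for MS
# intensities; Gaussian for Ct and flux values. Chromatographic peaks are
# sampled on a grid of sigma/10.

#' Generate a synthetic isoform family with known unique regions
#'
#' Starts from a random ancestor and marks a fraction of positions as
#' variable; at variable positions every isoform draws an independent random
#' residue. The expected pairwise identity is `1 - q * 19/20` for a variable
#' fraction `q`, so `q = (1 - identity) * 20/19`.
#'
#' @param n number of isoforms (>= 2).
#' @param length sequence length.
#' @param identity target pairwise identity in (0, 1].
#' @param seed integer seed.
#' @return list: `isoforms` (an [isoform_set()]), `truth` (list with
#'   `variable_positions` and the per-isoform residue matrix at those
#'   positions).
#' @export
gen_isoform_family <- function(n = 3, length = 298, identity = 0.9,
                               seed = 1) {
  stopifnot(n >= 2, length >= 10)
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]", call. = FALSE)
  q <- (1 - identity) * 20 / 19
  if (q > 1) stop("identity target incompatible with the alphabet", call. = FALSE)
  with_seed(seed, {
    # ancestor with tryptic-friendly composition (~10% K/R)
    weights <- stats::setNames(rep(1, 20), AA_ALPHABET)
    weights[c("K", "R")] <- 1.2
    weights["P"] <- 0.5
    ancestor <- sample(AA_ALPHABET, length, replace = TRUE,
                       prob = weights / sum(weights))
    variable <- which(stats::runif(length) < q)
    seqs <- matrix(rep(ancestor, n), nrow = n, byrow = TRUE)
    for (i in seq_len(n)) {
      seqs[i, variable] <- sample(AA_ALPHABET, length(variable), replace = TRUE)
    }
    ids <- paste0("ISO", seq_len(n))
    list(
      isoforms = isoform_set(ids, apply(seqs, 1, paste, collapse = "")),
      truth = list(variable_positions = variable,
                   residues = structure(seqs[, variable, drop = FALSE],
                                        dimnames = list(ids, NULL)))
    )
  })
}

gaussian_peak <- function(time, center, amplitude, sigma) {
  amplitude * exp(-(time - center)^2 / (2 * sigma^2))
}

#' Generate synthetic PRM runs with known target-to-heavy ratios
#'
#' Per transition, a Gaussian peak at the peptide's retention time (with a
#' small per-injection jitter) is sampled at step `sigma/10`. The heavy
#' amplitude is proportional to the spike, the light amplitude to
#' spike x true ratio; fragment-specific relative intensities are drawn once
#' per peptide and shared between light and heavy. Multiplicative lognormal
#' noise, an optional additive floor, and optional interfering co-eluting
#' peaks are added. Per-replicate loading variation scales light and heavy
#' together, so true ratios are unaffected.
#'
#' @param panel data.frame with `sequence` and `isoform_id` columns.
#' @param true_ratios named numeric vector: isoform id -> true target-to-heavy
#'   ratio.
#' @param condition condition label stamped on the run.
#' @param n_tech,n_bio technical and biological replicates (defaults 3, 3).
#' @param n_fragments fragments per peptide (default 5).
#' @param peak_amplitude heavy-standard peak height (default 1000).
#' @param peak_sigma chromatographic sigma in minutes (default 0.05).
#' @param noise_sd sdlog of the multiplicative lognormal noise (default 0.05).
#' @param noise_floor sd of additive non-negative baseline noise (default 0).
#' @param rt_jitter_sd per-injection retention-time jitter sd (default 0.01).
#' @param bio_cv lognormal sdlog of per-biological-replicate loading (default 0).
#' @param interference_n number of interfering peaks added to randomly chosen
#'   heavy traces (default 0).
#' @param interference_offset retention-time offset of interfering peaks in
#'   minutes (default 0.1).
#' @param interference_amplitude interfering peak height (default
#'   `peak_amplitude`).
#' @param seed integer seed.
#' @return list: `xic` (long data.frame as consumed by [quantify_prm()]),
#'   `rt_windows` (named list peptide -> c(start, end)), `truth` (list with
#'   `ratios`, `rt`, `fragment_intensities`).
#' @export
gen_prm_run <- function(panel, true_ratios, condition = "run",
                        n_tech = 3, n_bio = 3, n_fragments = 5,
                        peak_amplitude = 1000, peak_sigma = 0.05,
                        noise_sd = 0.05, noise_floor = 0,
                        rt_jitter_sd = 0.01, bio_cv = 0,
                        interference_n = 0, interference_offset = 0.1,
                        interference_amplitude = peak_amplitude,
                        seed = 1) {
  stopifnot(all(c("sequence", "isoform_id") %in% names(panel)),
            all(panel$isoform_id %in% names(true_ratios)))
  with_seed(seed, {
    n_pep <- nrow(panel)
    rt <- stats::setNames(seq(5, 20, length.out = n_pep), panel$sequence)
    frag_int <- lapply(seq_len(n_pep), function(i) {
      stats::setNames(stats::runif(n_fragments, 0.3, 1),
                      paste0("f", seq_len(n_fragments)))
    })
    names(frag_int) <- panel$sequence
    dt <- peak_sigma / 10
    half_span <- 8 * peak_sigma

    rows <- list()
    interfered <- character(0)
    for (b in seq_len(n_bio)) {
      loading <- if (bio_cv > 0) stats::rlnorm(1, 0, bio_cv) else 1
      for (tch in seq_len(n_tech)) {
        for (i in seq_len(n_pep)) {
          pep <- panel$sequence[i]
          iso <- panel$isoform_id[i]
          center <- rt[[pep]] + stats::rnorm(1, 0, rt_jitter_sd)
          tgrid <- seq(rt[[pep]] - half_span, rt[[pep]] + half_span, by = dt)
          for (label in c("light", "heavy")) {
            amp0 <- peak_amplitude * loading *
              if (label == "light") true_ratios[[iso]] else 1
            for (f in names(frag_int[[pep]])) {
              y <- gaussian_peak(tgrid, center, amp0 * frag_int[[pep]][[f]],
                                 peak_sigma)
              if (noise_sd > 0) y <- y * stats::rlnorm(length(y), 0, noise_sd)
              if (noise_floor > 0) {
                y <- y + abs(stats::rnorm(length(y), 0, noise_floor))
              }
              rows[[length(rows) + 1L]] <- data.frame(
                condition = condition, bio_rep = b, tech_rep = tch,
                peptide = pep, isoform_id = iso, label = label, fragment = f,
                time = tgrid, intensity = y, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    xic <- do.call(rbind, rows)

    if (interference_n > 0) {
      heavy_keys <- unique(xic[xic$label == "heavy",
                               c("bio_rep", "tech_rep", "peptide", "fragment")])
      pick <- heavy_keys[sample(nrow(heavy_keys),
                                min(interference_n, nrow(heavy_keys))), ]
      for (k in seq_len(nrow(pick))) {
        sel <- xic$label == "heavy" &
          xic$bio_rep == pick$bio_rep[k] & xic$tech_rep == pick$tech_rep[k] &
          xic$peptide == pick$peptide[k] & xic$fragment == pick$fragment[k]
        ctr <- rt[[pick$peptide[k]]] + interference_offset
        xic$intensity[sel] <- xic$intensity[sel] +
          gaussian_peak(xic$time[sel], ctr, interference_amplitude, peak_sigma)
        interfered <- c(interfered,
                        paste(pick$peptide[k], pick$bio_rep[k],
                              pick$tech_rep[k], pick$fragment[k], sep = "/"))
      }
    }

    windows <- lapply(panel$sequence, function(p) {
      c(rt[[p]] - 4 * peak_sigma, rt[[p]] + 4 * peak_sigma)
    })
    names(windows) <- panel$sequence
    list(xic = xic, rt_windows = windows,
         truth = list(ratios = true_ratios, rt = rt,
                      fragment_intensities = frag_int,
                      interfered = interfered))
  })
}

#' Generate a paired mRNA/protein cohort with known per-gene correlations
#'
#' Per gene, a target Spearman correlation is drawn from a truncated normal
#' distribution; samples come from a latent bivariate normal with Pearson
#' rho = 2 sin(pi * rho_s / 6) (the Spearman-Pearson relation for bivariate
#' normals). mRNA is mapped through a lognormal to an FPKM scale; protein is
#' kept zero-centered. A gene subset can be generated at a shifted target
#' correlation; all-zero-FPKM genes and missing protein values can be planted.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param rho_median,rho_sd center and spread of the target Spearman
#'   distribution (defaults 0.47 and 0.12).
#' @param subset_size number of genes in the shifted subset (default 0).
#' @param subset_median target median Spearman of the subset (default 0.33).
#' @param n_zero_genes additional genes planted with all-zero FPKM.
#' @param missing_rate fraction of protein entries set to NA.
#' @param fpkm_meanlog,fpkm_sdlog lognormal FPKM scale parameters.
#' @param seed integer seed.
#' @return list: `mrna`, `protein` (matrices), `truth` (per-gene target rho,
#'   subset membership, planted zero genes).
#' @export
gen_expression_pair <- function(n_genes = 1000, n_samples = 99,
                                rho_median = 0.47, rho_sd = 0.12,
                                subset_size = 0, subset_median = 0.33,
                                n_zero_genes = 0, missing_rate = 0,
                                fpkm_meanlog = 3, fpkm_sdlog = 1,
                                seed = 1) {
  stopifnot(subset_size <= n_genes, n_samples >= 3)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    subset <- if (subset_size > 0) sample(genes, subset_size) else character(0)
    target <- stats::setNames(
      stats::rnorm(n_genes, rho_median, rho_sd), genes)
    target[subset] <- stats::rnorm(subset_size, subset_median, rho_sd)
    target <- pmin(pmax(target, -0.45), 0.95)

    rho_pearson <- 2 * sin(pi * target / 6)
    z1 <- matrix(stats::rnorm(n_genes * n_samples), n_genes)
    z2 <- matrix(stats::rnorm(n_genes * n_samples), n_genes)
    latent_p <- rho_pearson * z1 + sqrt(1 - rho_pearson^2) * z2
    mrna <- exp(fpkm_meanlog + fpkm_sdlog * z1)
    protein <- latent_p

    zero_ids <- character(0)
    if (n_zero_genes > 0) {
      zero_ids <- sprintf("Z%04d", seq_len(n_zero_genes))
      mrna <- rbind(mrna, matrix(0, n_zero_genes, n_samples))
      protein <- rbind(protein,
                       matrix(stats::rnorm(n_zero_genes * n_samples),
                              n_zero_genes))
      genes <- c(genes, zero_ids)
    }
    samples <- sprintf("S%03d", seq_len(n_samples))
    dimnames(mrna) <- dimnames(protein) <- list(genes, samples)
    if (missing_rate > 0) {
      protein[stats::runif(length(protein)) < missing_rate] <- NA
    }
    list(mrna = mrna, protein = protein,
         truth = list(target_spearman = target, subset = subset,
                      zero_genes = zero_ids))
  })
}

#' Generate a flux plate with known per-segment means
#'
#' Each well draws two measurements per segment at the group's per-1000-cell
#' segment mean, scaled by a drawn cell count, with Gaussian measurement noise
#' and an optional ambient background level shared with empty background
#' wells. Truth characteristics come from the noiseless means.
#'
#' @param group_means named list: group -> list(ocr = 5-vector,
#'   ecar = 5-vector), in per-1000-cell units.
#' @param wells_per_group wells per group (default 5).
#' @param noise_sd Gaussian measurement noise sd, raw instrument units
#'   (default 2).
#' @param cell_count_range min/max nuclei per well (default 8000-12000).
#' @param n_background empty background wells (default 4).
#' @param background_level length-2 c(ocr, ecar) ambient signal added to every
#'   well (default c(10, 1)).
#' @param seed integer seed.
#' @return list: `plate` (long data.frame: well, group, measurement, segment,
#'   ocr, ecar, cell_count, is_background), `truth` (per-group OCR/ECAR
#'   characteristics and segment means).
#' @export
gen_flux_plate <- function(group_means, wells_per_group = 5, noise_sd = 2,
                           cell_count_range = c(8000, 12000),
                           n_background = 4,
                           background_level = c(ocr = 10, ecar = 1),
                           seed = 1) {
  stopifnot(length(group_means) >= 1)
  with_seed(seed, {
    rows <- list()
    wi <- 0L
    for (g in names(group_means)) {
      mu <- group_means[[g]]
      stopifnot(length(mu$ocr) == 5, length(mu$ecar) == 5)
      for (w in seq_len(wells_per_group)) {
        wi <- wi + 1L
        cells <- round(stats::runif(1, cell_count_range[1], cell_count_range[2]))
        seg <- default_segment_map(1:10)
        rows[[length(rows) + 1L]] <- data.frame(
          well = sprintf("W%02d", wi), group = g, measurement = 1:10,
          segment = seg,
          ocr = mu$ocr[seg] * cells / 1000 + background_level[["ocr"]] +
            stats::rnorm(10, 0, noise_sd),
          ecar = mu$ecar[seg] * cells / 1000 + background_level[["ecar"]] +
            stats::rnorm(10, 0, noise_sd / 4),
          cell_count = cells, is_background = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    for (w in seq_len(n_background)) {
      wi <- wi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("W%02d", wi), group = "background", measurement = 1:10,
        segment = default_segment_map(1:10),
        ocr = background_level[["ocr"]] + stats::rnorm(10, 0, noise_sd),
        ecar = background_level[["ecar"]] + stats::rnorm(10, 0, noise_sd / 4),
        cell_count = 1, is_background = TRUE, stringsAsFactors = FALSE)
    }
    plate <- do.call(rbind, rows)

    truth <- lapply(group_means, function(mu) {
      list(ocr = ocr_characteristics(mu$ocr),
           ecar = ecar_characteristics(mu$ecar),
           segments = mu)
    })
    list(plate = plate, truth = truth)
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Reference-gene Ct is constant per sample up to noise (plus a per-sample
#' offset affecting both genes, emulating loading); the target gene's Ct is
#' reference + baseline dCt - log2(FC) + noise.
#'
#' @param true_log2fc named numeric vector: condition -> true log2 fold
#'   change vs control (control itself is added automatically at 0).
#' @param control control condition label (default "control").
#' @param target,reference gene ids.
#' @param n_samples biological samples per condition (default 3).
#' @param n_replicates technical Ct replicates (default 3).
#' @param baseline_dct dCt of the target in the control state (default 5).
#' @param ref_ct reference-gene Ct level (default 20).
#' @param sample_offset_sd sd of the per-sample loading offset (default 0.3).
#' @param noise_sd Ct measurement noise sd (default 0.2).
#' @param seed integer seed.
#' @return list: `ct` (long data.frame: sample, condition, gene, replicate,
#'   ct), `truth` (named log2 fold changes incl. control = 0).
#' @export
gen_ct_table <- function(true_log2fc, control = "control",
                         target = "SLC25A4", reference = "ACTB",
                         n_samples = 3, n_replicates = 3,
                         baseline_dct = 5, ref_ct = 20,
                         sample_offset_sd = 0.3, noise_sd = 0.2, seed = 1) {
  fc <- c(stats::setNames(0, control), true_log2fc)
  with_seed(seed, {
    rows <- list()
    for (cond in names(fc)) {
      for (s in seq_len(n_samples)) {
        sample_id <- paste(cond, s, sep = "_")
        offset <- stats::rnorm(1, 0, sample_offset_sd)
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, condition = cond, gene = reference,
            replicate = r,
            ct = ref_ct + offset + stats::rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, condition = cond, gene = target,
            replicate = r,
            ct = ref_ct + offset + baseline_dct - fc[[cond]] +
              stats::rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = do.call(rbind, rows), truth = fc)
  })
}
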