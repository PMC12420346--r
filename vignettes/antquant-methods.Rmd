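---
title: "Methods: isoform-resolved ANT quantification, bioenergetics and correlation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-resolved ANT quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antquant)
```

# The problem

The human ADP/ATP translocases ANT1 (*SLC25A4*), ANT2 (*SLC25A5*) and ANT3
(*SLC25A6*) exchange ADP and ATP across the inner mitochondrial membrane.
The three isoforms share most of their amino-acid sequence, which makes them
hard to distinguish by antibodies, and their protein levels do not track
their transcript levels — so isoform-resolved questions (for example, how
the ANT pool shifts when a cell enters senescence) require a targeted
protein-level assay. `antquant` implements the full analysis chain for such
a study:

1. **Panel design** — in-silico tryptic digestion of the isoform family,
   determination of isoform-unique peptides, policy-based selection, and a
   vendor-neutral PRM transition list with light/heavy m/z values.
2. **PRM quantification** — extracted-ion-chromatogram integration,
   target-to-heavy ratios against spiked stable-isotope standards, replicate
   statistics, isoform levels and fold changes.
3. **ΔΔCt** — relative transcript quantification against a reference gene.
4. **Extracellular flux** — derived OCR/ECAR bioenergetic characteristics
   from mitochondrial/glycolysis stress-test plates.
5. **Correlation structure** — per-gene mRNA–protein correlations,
   gene-set distribution comparisons, protein intercorrelation, and
   fold-change-versus-flux correlation.
6. **Synthetic data** — ground-truthed generators for every stage, so the
   whole pipeline is validated without any external download.

# Panel design

## Digestion and uniqueness

`digest()` cleaves after K or R unless the next residue is proline
(trypsin `[KR|P]`) and enumerates peptides with up to `max_missed` internal
missed cleavages (default 1 during candidate generation — needed to surface
missed-cleavage candidates that a policy may admit deliberately). Peptide
coordinates are 1-based inclusive, matching protein-residue convention.

A peptide is **isoform-unique** when its sequence occurs as an exact
substring of exactly one isoform in the supplied family
(`assign_uniqueness()`). Substring containment, rather than
alignment-column inspection, is the checkable criterion: a multiple
sequence alignment can *predict* unique regions, but what the mass
spectrometer sees is the peptide sequence, and any isoform containing that
sequence anywhere will contribute signal. Uniqueness is always relative to
the supplied set; screening against a whole proteome is out of scope and
would be a separate, optional step.

## Selection policy

`selection_policy()` encodes the filters, applied in a fixed precedence
order so every rejection is logged against exactly one rule:

| rule | default | rationale |
|---|---|---|
| uniqueness | required | shared peptides cannot resolve isoforms |
| length 6–25 residues | 6, 25 | shorter peptides are ambiguous and poorly fragmented; longer ones ionize and transmit poorly |
| missed cleavages | 0 unless allowlisted | missed cleavage is variable between digests; an exception is made only for peptides with demonstrated stable behaviour (for the ANT family, `IFRDEGGK`) |
| protein N-terminus | excluded | peptides spanning residue 1 (or residue 2 when residue 1 is the initiator Met, removed co-translationally) are acetylation-prone, which shifts their mass |
| methionine | per-isoform flag | Met-containing standards oxidize artifactually during storage/analysis; flagged per isoform because the problem was observed for one isoform's standard |
| manual exclusions | named, with reasons | low signal, retention-time instability — analytical, not sequence-derived, so they are policy entries rather than hard-coded rules |

The precedence order (uniqueness → length → missed cleavage → N-terminus →
Met → manual) means, e.g., that a missed-cleavage peptide spanning the
N-terminus is logged as a missed-cleavage rejection; counts of N-terminal
exclusions therefore refer to fully tryptic candidates, which is the
convention used throughout.

## Masses and transitions

Monoisotopic residue masses, water 18.010565 Da, proton 1.007276 Da.
Default fixed modification: cysteine thiomethylation +45.98772 Da (MMTS
blocking). Heavy labels are C-terminal ^13^C~6~^15^N~2~-Lys (+8.01420 Da)
and ^13^C~6~^15^N~4~-Arg (+10.00827 Da), computed from the exact isotope
mass differences. Precursors are 2+; y and b fragments are 1+. y ions carry
the (C-terminal) label; b ions are label-invariant — both facts are tested
as algebraic identities.

`build_transition_list()` keeps fragments with m/z above their own
precursor's m/z (low-mass fragments sit in the noisy region and add little
selectivity), ranks by fragment index descending with y before b on ties
(y ions dominate PRM practice; the tie-break makes output deterministic),
and keeps at most 5 per precursor. The retention-time window defaults to
3 min.

## The synthetic stand-in family

`ant_reference_family()` is a deterministic, clearly labelled synthetic
three-isoform family (`inst/extdata/ant_family_synthetic.fasta`). The real
UniProt sequences are not redistributed with the package; the stand-in is
constructed from tryptic building blocks so that it embodies the structural
facts published for the real family — three ~298-residue isoforms of high
pairwise identity (96–97% realized), one unique N-terminal peptide per
isoform, one Met-containing ANT2-unique peptide, one low-signal ANT3-unique
peptide, and the missed-cleavage ANT3-unique peptide `IFRDEGGK` — so that
the default policy yields panels of 3 (ANT1), 2 (ANT2) and 2 (ANT3)
peptides with exactly three N-terminal exclusions. A green panel test
therefore establishes that the selection machinery implements the
documented rules, **not** that the real family was re-derived; to run the
real thing, download the three UniProt entries into a FASTA and pass it to
`read_isoform_fasta()`.

# PRM quantification

Peak areas are trapezoidal integrals over the peptide's retention-time
window, with optional constant-baseline subtraction (median of intensities
outside the window) — a deliberately simple, reproducible integrator; peak
modelling or FDR-controlled detection belongs to vendor software and is out
of scope. Light and heavy fragment sets are intersected before summation so
unmatched fragments cannot bias the ratio; the ratio estimator is
scale-invariant and maps to its reciprocal when light and heavy are swapped
(both tested as properties).

Technical replicates are averaged first (arithmetic mean, CV = sd/mean),
then panel peptides are aggregated to the isoform as an unweighted mean of
ratio × spike (fmol-equivalents); peptide-level values are retained for
audit. The order (technical averaging before peptide aggregation) is a
documented choice — the alternative ordering differs only through
technical-replicate imbalance, which the design (fixed 3×3) avoids. An
estimated target below spike/5 triggers the "heavy exceeds fivefold of
target" warning, mirroring the spike-level policy used when calibrating
standards. Undetected or flagged ratios propagate as missing values, never
as zeros.

Fold changes are `log2(mean treated / mean control)` over biological
replicates. Time-course significance uses two-way ANOVA across
(time point, isoform) followed by a configured post hoc: Dunn's rank-based
test against control (default, as printed in the source protocol — an
unusual pairing, which is why it is configurable) or Holm-adjusted pairwise
Welch t tests; the choice is recorded in the output.

# ΔΔCt

Replicates are averaged on the Ct scale (the common convention);
ΔCt = Ct~target~ − Ct~reference~; ΔΔCt subtracts the control-condition mean
ΔCt; RQ = 2^−ΔΔCt^. Amplification efficiency is fixed at 2 (the classic
method, no efficiency correction). RQ of the reference gene is identically
1 and RQ is invariant to per-sample Ct offsets — both are tested. The
replicate-level test is a one-sample t on log2(FC) against 0; zero-variance
inputs return a degenerate flag instead of a p-value.

# Extracellular flux

Ten measurements per well, two per segment: pre-glucose, post-glucose
(port A), post-oligomycin (port B), post-FCCP (port C), and
post-rotenone/antimycin + 2-deoxyglucose (port D). "Characteristic a–b" is
read as the segment-mean difference s~a~ − s~b~ — forced by the spare
capacity definition "4–2", which is only meaningful as a difference:

* OCR: baseline = s1 − s5, ATP-linked = s1 − s3, maximal = s4 − s5,
  spare = s4 − s2, proton leak = s3 − s5. Note baseline uses the
  pre-glucose segment (glucose lowers measured OCR) while maximal uses the
  post-FCCP, glucose-present segment. ATP-linked + proton leak = baseline
  is a definitional identity and is enforced to machine precision.
* ECAR: baseline = s1 − s5, glycolytic capacity = s3 − s5, glycolytic
  reserve = s3 − s2.
* OCR/ECAR ratio = ATP-linked OCR / glycolytic ECAR. "Glycolytic ECAR" is
  not pinned down by the source definitions; the default is s2 − s5
  (post-glucose minus post-2DG, i.e. glucose-stimulated acidification above
  the non-glycolytic floor), with glycolytic capacity (s3 − s5) available
  as a configuration alternative.

Background-well means are subtracted per measurement before dividing by the
well's cell count (per 1000 cells). Negative characteristics are retained
and flagged rather than clipped — clipping would bias group comparisons.
Groups are compared per characteristic with the two-sided Mann–Whitney test
(exact when possible).

# Correlation structure

Genes with zero mRNA signal are dropped before correlating; "zero" defaults
to all-sample FPKM sum = 0 (the literal reading of "an mRNA level equal to
0 FPKM" for a gene), with any-sample-zero available. Missing protein values
are handled pairwise-complete per gene with the effective n reported —
proteome matrices are sparse and casewise deletion would discard most
genes.

Pearson correlations use log2(FPKM + 1)-transformed mRNA by default (FPKM
is heavily right-skewed; the log puts it on the scale where linear
association is meaningful), with a no-transform switch; Spearman uses raw
values since ranks are transform-invariant. Spearman p-values use the
large-sample t approximation for n ≥ 10; for n < 10 the exact
null-distribution p from `stats::cor.test` is used instead of a bespoke
permutation enumeration — it is the same null distribution, computed by a
vetted routine. BH adjustment is applied across genes.

`subset_distribution_compare()` contrasts a gene set's correlation
distribution against the complement (medians + Mann–Whitney);
`protein_intercorrelation()` reports pairwise correlations among focus
genes and each focus gene's correlation distribution against the rest,
summarized per background set; `fc_vs_flux_correlation()` pools per-isoform
fold changes (sum by default — the total translocase pool is what matters
for respiration capacity) and correlates them with a flux characteristic's
change across conditions by Spearman.

# Synthetic data: what it emulates, and what a green test establishes

Every generator is a pure function of its seed and emits its ground truth
alongside the data; all recovery tests consume only (data, truth) pairs.

* **Isoform families** (`gen_isoform_family()`): an ancestor sequence with
  ~10% K/R content; a fraction q = (1 − identity)·20/19 of positions is
  variable, each isoform drawing an independent residue there. Emulates
  point-substitution divergence; does not emulate indels, so coordinates
  align trivially across isoforms.
* **PRM runs** (`gen_prm_run()`): Gaussian peaks (σ = 0.05 min, sampled at
  σ/10) with fragment-specific relative intensities shared between light
  and heavy, multiplicative lognormal noise (5% default), optional additive
  floor, per-injection retention-time jitter, per-biological-replicate
  loading factors (which cancel in the ratio, as in a real spike-in
  design), and optional co-eluting interference peaks injected into heavy
  traces. Not emulated: isotope envelopes, charge-state interference,
  chromatographic tailing, cross-run RT drift.
* **Expression cohorts** (`gen_expression_pair()`): per-gene target
  Spearman drawn from a truncated normal (median 0.47, sd 0.12; a
  designated subset at 0.33 — the generator settings mirror the magnitudes
  reported for tumor proteogenomics cohorts, as a stated world, not as a
  claim about external data); latent bivariate normal with Pearson
  ρ = 2·sin(πρ~s~/6); mRNA mapped through a lognormal to FPKM; protein kept
  zero-centered. Planted all-zero-FPKM genes and missing protein entries
  exercise the filters. Not emulated: shared covariance structure between
  genes (each gene is independent), batch effects.
* **Flux plates** (`gen_flux_plate()`): two draws per segment at the
  group's per-1000-cell segment mean, scaled by a drawn cell count
  (8,000–12,000), Gaussian instrument noise, an ambient background level
  shared with empty wells. Truth characteristics come from the noiseless
  means.
* **Ct tables** (`gen_ct_table()`): reference Ct ~20 with a per-sample
  loading offset applied to both genes (cancels in ΔCt, as it should);
  target Ct = reference + baseline ΔCt − log2(FC) + noise (sd 0.2 by
  default, a typical SYBR triplicate spread).

A green recovery test establishes that the estimators invert the stated
generative model at the stated noise — it does not establish instrument
accuracy, matrix effects, or that real biological variance resembles the
model.

# Numerical choices and degenerate inputs

* Integration: trapezoidal; window boundaries linearly interpolated; areas
  clipped at 0 after baseline subtraction.
* All-zero traces integrate to 0 with a warning; zero heavy area flags the
  ratio as missing; all-flagged peptides make the isoform value missing for
  that replicate.
* Ties in fragment ranking: y before b, then index descending.
* Zero-variance log2FC replicates: degenerate flag, no p-value.
* Mann–Whitney falls back to the normal approximation under ties (the
  `stats::wilcox.test` behaviour), exact otherwise.
* Constant expression rows: correlation undefined, flagged, excluded from
  BH.
* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state.

# Known limitations

* Peptide uniqueness is relative to the supplied family only; no proteome
  background screen.
* The integrator assumes a single chromatographic peak per window; heavy
  interference is detected only indirectly (CV inflation, ratio bias).
* Isoform aggregation weights peptides equally; response-factor differences
  between peptides are absorbed by the heavy standards and any residual is
  not modelled.
* The Dunn-after-ANOVA pairing is kept for fidelity to the source protocol
  despite being statistically unusual; `holm_t` is the recommended
  alternative.
* The flux segment map assumes the canonical 10-measurement, 4-injection
  protocol; other port layouts need an explicit `segment` column.
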