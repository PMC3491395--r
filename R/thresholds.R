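#' Default analysis thresholds
#'
#' Returns the full set of numeric cutoffs used across the decoration
#' pipeline. Each element can be overridden by name; the defaults are the
#' published operating points of the original genome-wide survey:
#' a 50 bp overlap for annotation consensus, 80%/60% sequence-identity bin
#' edges, the <90% parent-similarity cut of the total-RNA caller, a 2 kb
#' parent 3' extension scanned with a 100 bp identity window, the
#' depth >= 2 over >= half-the-locus coverage rule, per-species background
#' substitution rates of 1.5% (chimp) and 5% (mouse) at FDR 0.05, the 3x
#' TSS and 2x gene-body chromatin criteria, the 519 bp / 2.38 Pol2
#' width/signal cuts with the seven-cofactor rescue, a 2 kb upstream
#' window with a 4 kb coding-TSS exclusion, and an 8 kb (+/- 4 kb)
#' profile window.
#'
#' @param ... named overrides of individual thresholds.
#' @return A named list of thresholds, validated.
#' @examples
#' thr <- decorThresholds(fdr = 0.1)
#' thr$consensus_overlap_bp
#' @export
decorThresholds <- function(...) {
  thr <- list(
    consensus_overlap_bp  = 50L,
    identity_high         = 80,
    identity_low          = 60,
    parent_similarity_cut = 90,
    utr_extension_bp      = 2000L,
    utr_window_bp         = 100L,
    bodymap_min_depth     = 2,
    bodymap_min_frac      = 0.5,
    discordance_max_cor   = 0.5,
    background_rate_chimp = 0.015,
    background_rate_mouse = 0.05,
    fdr                   = 0.05,
    tss_ratio             = 3,
    genebody_ratio        = 2,
    pol2_width_bp         = 519,
    pol2_signal           = 2.38,
    cofactors             = c("Taf1", "Taf7", "Tbp", "Nelfe",
                              "Gtf2f1", "Gtf2b", "Ccnt2"),
    upstream_bp             = 2000L,
    coding_tss_exclusion_bp = 4000L,
    profile_halfwindow_bp   = 4000L,
    dnase_fold              = 2,
    repressive_aggregate    = "max",
    conserved_combine       = "union"
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(thr))
    if (length(bad))
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    thr[names(ov)] <- ov
  }
  .validateThresholds(thr)
  thr
}

.validateThresholds <- function(thr) {
  num <- c("consensus_overlap_bp", "identity_high", "identity_low",
           "parent_similarity_cut", "utr_extension_bp", "utr_window_bp",
           "bodymap_min_depth", "bodymap_min_frac",
           "background_rate_chimp", "background_rate_mouse", "fdr",
           "tss_ratio", "genebody_ratio", "pol2_width_bp", "pol2_signal",
           "upstream_bp", "coding_tss_exclusion_bp", "profile_halfwindow_bp",
           "dnase_fold")
  for (f in num) {
    v <- thr[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("threshold '", f, "' must be a single positive number")
  }
  if (thr$identity_low >= thr$identity_high)
    stop("identity_low must be < identity_high")
  if (thr$fdr >= 1)
    stop("fdr must lie in (0, 1)")
  stopifnot(thr$repressive_aggregate %in% c("max", "mean"),
            thr$conserved_combine %in% c("union", "chimp_only", "intersection"))
  invisible(thr)
}

#' Chromatin segmentation label vocabulary
#'
#' A 25-label vocabulary partitioned into 12 activity labels (including the
#' TSS and the gene-body start/middle/end labels used by the
#' active-chromatin classifier) and 13 repressive labels. The genome-wide
#' segmentation the original survey used carries 25 labels, roughly half
#' active and half repressive; its exact label names live in supplementary
#' material, so this synthetic stand-in vocabulary keeps the same
#' active/repressive partition semantics and the four labels the classifier
#' names (TSS, GS, GM, GE). Any vocabulary with the same structure can be
#' supplied to [Segmentation()] instead.
#'
#' @return list with character vectors `active` and `repressive`.
#' @export
segmentationLabels <- function() {
  list(
    active = c("TSS", "GS", "GM", "GE", "e/GM", "E1", "E2",
               "TF1", "TF2", "TRX1", "TRX2", "ENH"),
    repressive = c("R1", "R2", "R3", "R4", "R5", "CTCF",
                   "HET1", "HET2", "HET3", "QUI1", "QUI2", "QUI3", "LOW")
  )
}
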