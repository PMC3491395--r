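#' Strand-aware upstream window of a locus
#'
#' The `length`-bp region immediately 5' of each locus: on + (or
#' unstranded, treated as + with a warning) [start - length, start - 1];
#' on - [end + 1, end + length]; clipped at chromosome bounds when
#' seqlengths are available.
#'
#' @param loci GRanges.
#' @param length window length in bp, default 2000.
#' @return GRanges of upstream windows, same names/ids as `loci`.
#' @export
upstreamWindow <- function(loci, length = 2000L) {
  str <- as.character(strand(loci))
  if (any(str == "*")) {
    warning("unstranded loci treated as + strand for upstream windows")
    str[str == "*"] <- "+"
  }
  tss <- ifelse(str == "-", end(loci), start(loci))
  ws <- ifelse(str == "-", tss + 1L, tss - length)
  we <- ifelse(str == "-", tss + length, tss - 1L)
  ws <- pmax(ws, 1L)
  sl <- seqlengths(loci)[as.character(seqnames(loci))]
  if (!any(is.na(sl))) we <- pmin(we, sl)
  out <- GRanges(seqnames(loci), IRanges(ws, pmax(we, ws)),
                 strand = str, seqinfo = seqinfo(loci))
  mcols(out) <- mcols(loci)
  names(out) <- names(loci)
  out
}

#' Exclude pseudogenes near coding-gene TSSs
#'
#' Drops loci whose strand-aware 5' end lies strictly less than `dist` bp
#' (absolute, strand-agnostic, same chromosome) from the nearest
#' protein-coding TSS, to avoid attributing a neighbouring gene's
#' upstream signals to the pseudogene. Exactly `dist` bp away is kept.
#'
#' @param loci GRanges pseudogenes.
#' @param coding GRanges protein-coding genes (5' ends used).
#' @param dist exclusion distance in bp, default 4000.
#' @return list(kept, excluded) partitioning `loci`, plus logical
#'   `excluded_flag` in input order.
#' @export
filterNearCodingTss <- function(loci, coding, dist = 4000L) {
  fivePrime <- function(gr) {
    str <- as.character(strand(gr))
    ifelse(str == "-", end(gr), start(gr))
  }
  p5 <- fivePrime(loci); c5 <- fivePrime(coding)
  cchr <- as.character(seqnames(coding))
  excl <- vapply(seq_along(loci), function(i) {
    sel <- cchr == as.character(seqnames(loci))[i]
    if (!any(sel)) return(FALSE)
    min(abs(c5[sel] - p5[i])) < dist
  }, logical(1))
  list(kept = loci[!excl], excluded = loci[excl], excluded_flag = excl)
}

#' Count TFBS peaks assigned to an upstream window
#'
#' A ChIP-seq peak is assigned to the window iff strictly more than half
#' of the peak's width lies inside it (majority rule; exactly half does
#' not count). Returns the total assigned-peak count and the per-factor
#' presence.
#'
#' @param peaks GRanges with `factor` metadata column.
#' @param window a single GRanges window.
#' @return list(total, factors = character vector of distinct factors with
#'   an assigned peak, per_factor = named peak counts).
#' @export
countTfbs <- function(peaks, window) {
  stopifnot(length(window) == 1L)
  if (!length(peaks))
    return(list(total = 0L, factors = character(), per_factor = integer()))
  ov <- overlapBp(peaks, rep(granges(window), length(peaks)))
  inWin <- ov > width(peaks) / 2
  fac <- as.character(mcols(peaks)$factor)[inWin]
  list(total = sum(inWin),
       factors = sort(unique(fac)),
       per_factor = if (length(fac)) table(fac) else integer())
}

#' Active Pol2 binding call for one upstream window
#'
#' Active iff a single Pol2 peak assigned to the window (majority rule)
#' is simultaneously wider than `pol2_width_bp` (519 bp) and stronger
#' than `pol2_signal` (2.38) — criteria 1 + 2 on the same peak — or at
#' least one peak of a Pol2 cofactor (Taf1, Taf7, Tbp, Nelfe, Gtf2f1,
#' Gtf2b, Ccnt2) is assigned to the window (criterion 3).
#'
#' @param pol2 GRanges Pol2 peaks with `signal` column.
#' @param cofactor GRanges cofactor peaks with `factor` column.
#' @param window single GRanges window.
#' @param thresholds threshold list.
#' @param same_peak if FALSE, the width and signal criteria may be met by
#'   different peaks.
#' @return list(active, criterion in {"1+2","3","none"}).
#' @export
callPol2Active <- function(pol2, cofactor, window,
                           thresholds = decorThresholds(),
                           same_peak = TRUE) {
  assigned <- function(p) {
    if (!length(p)) return(p[0])
    ov <- overlapBp(p, rep(granges(window), length(p)))
    p[ov > width(p) / 2]
  }
  pw <- assigned(pol2)
  wide <- width(pw) > thresholds$pol2_width_bp
  strong <- mcols(pw)$signal > thresholds$pol2_signal
  crit12 <- if (same_peak) any(wide & strong) else any(wide) && any(strong)
  cf <- assigned(cofactor)
  cf <- cf[as.character(mcols(cf)$factor) %in% thresholds$cofactors]
  crit3 <- length(cf) > 0L
  list(active = crit12 || crit3,
       criterion = if (crit12) "1+2" else if (crit3) "3" else "none")
}

#' Empirical Pol2 width/signal thresholds
#'
#' The "top 5%" operating points recomputed from a pooled peak set: the
#' 95th percentile (linear interpolation) of peak widths and of signal
#' values across all contexts.
#'
#' @param peaks GRanges with `signal` column, pooled across cell contexts.
#' @param percentile percentile, default 95.
#' @return list(width_threshold, signal_threshold).
#' @export
derivePol2Thresholds <- function(peaks, percentile = 95) {
  if (length(peaks) < 20L) stop("need at least 20 peaks")
  list(width_threshold = unname(quantile(width(peaks), percentile / 100)),
       signal_threshold = unname(quantile(mcols(peaks)$signal,
                                          percentile / 100)))
}

#' Active promoter call
#'
#' Active iff any supplied promoter region overlaps the upstream window
#' by at least 1 bp.
#'
#' @param promoters GRanges promoter regions.
#' @param window single GRanges window.
#' @return logical scalar.
#' @export
callPromoterActive <- function(promoters, window) {
  length(promoters) > 0L &&
    any(overlapBp(promoters, rep(granges(window), length(promoters))) >= 1L)
}

#' Enrichment of upstream activity in transcribed pseudogenes
#'
#' For a binary activity flag, a one-sided Fisher's exact test for
#' enrichment among transcribed loci; for a count (e.g. TFBS count per
#' locus), a two-sided Wilcoxon rank-sum test (exact for small untied
#' samples, normal approximation with tie correction otherwise).
#'
#' @param transcribed logical group labels.
#' @param activity logical flag or numeric count per locus.
#' @return p-value.
#' @export
enrichmentTest <- function(transcribed, activity) {
  if (length(unique(transcribed)) < 2L)
    stop("degenerate grouping: need transcribed and non-transcribed loci")
  if (is.logical(activity)) {
    tab <- matrix(c(sum(transcribed & activity), sum(transcribed & !activity),
                    sum(!transcribed & activity), sum(!transcribed & !activity)),
                  nrow = 2, byrow = TRUE)
    fisher.test(tab, alternative = "greater")$p.value
  } else {
    wilcox.test(activity[transcribed], activity[!transcribed])$p.value
  }
}

#' Regulation pipeline for one cell context
#'
#' Builds upstream windows, applies the coding-TSS exclusion, counts
#' TFBS peaks, and calls Pol2 and promoter activity per pseudogene.
#'
#' @param loci GRanges surveyed pseudogenes (with `id`).
#' @param coding GRanges coding genes.
#' @param tf_peaks GRanges TF peaks (`factor`, `signal`).
#' @param pol2_peaks GRanges Pol2 peaks (`signal`).
#' @param cofactor_peaks GRanges cofactor peaks (`factor`).
#' @param promoters GRanges active-promoter regions.
#' @param thresholds threshold list.
#' @return data.frame (pseudogene_id, excluded, tfbs_count, tfbs_factors,
#'   pol2_active, pol2_criterion, promoter_active); calls are NA for
#'   excluded loci.
#' @export
regulationPipeline <- function(loci, coding, tf_peaks, pol2_peaks,
                               cofactor_peaks, promoters,
                               thresholds = decorThresholds()) {
  filt <- filterNearCodingTss(loci, coding,
                              thresholds$coding_tss_exclusion_bp)
  wins <- upstreamWindow(loci, thresholds$upstream_bp)
  rows <- lapply(seq_along(loci), function(i) {
    id <- as.character(mcols(loci)$id)[i]
    if (filt$excluded_flag[i])
      return(data.frame(pseudogene_id = id, excluded = TRUE,
                        tfbs_count = NA_integer_, tfbs_factors = NA_character_,
                        pol2_active = NA, pol2_criterion = NA_character_,
                        promoter_active = NA, stringsAsFactors = FALSE))
    w <- wins[i]
    tf <- countTfbs(tf_peaks, w)
    p2 <- callPol2Active(pol2_peaks, cofactor_peaks, w, thresholds)
    pr <- callPromoterActive(promoters, w)
    data.frame(pseudogene_id = id, excluded = FALSE,
               tfbs_count = tf$total,
               tfbs_factors = paste(tf$factors, collapse = ","),
               pol2_active = p2$active, pol2_criterion = p2$criterion,
               promoter_active = pr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
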