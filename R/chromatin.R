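#' TSS-anchored average signal profile
#'
#' Averages a per-base signal track over windows centred on strand-aware
#' 5' ends (default +/- 4 kb, i.e. an 8 kb span), in uniform bins.
#' Minus-strand loci are reversed so upstream is always on the left.
#' Windows running off a chromosome edge are clipped and contribute only
#' their covered bins.
#'
#' @param track RleList of per-base signal, one Rle per chromosome.
#' @param anchors GRanges of loci; the strand-aware 5' end of each range
#'   anchors its window.
#' @param half_window half-window in bp.
#' @param bin bin width in bp (must divide 2 * half_window).
#' @return data.frame (offset = bin start relative to the anchor,
#'   mean_signal, n) with one row per bin.
#' @export
aggregateProfile <- function(track, anchors, half_window = 4000L, bin = 50L) {
  if (!length(anchors)) stop("no anchor loci supplied")
  nbin <- as.integer(2 * half_window / bin)
  stopifnot(nbin * bin == 2 * half_window)
  acc <- matrix(0, nrow = 0, ncol = nbin)
  sums <- numeric(nbin); cnts <- numeric(nbin)
  for (i in seq_along(anchors)) {
    chr <- as.character(seqnames(anchors))[i]
    if (!chr %in% names(track)) next
    v <- track[[chr]]
    minus <- as.character(strand(anchors))[i] == "-"
    tss <- if (minus) end(anchors)[i] else start(anchors)[i]
    lo <- tss - half_window; hi <- tss + half_window - 1L
    idx <- pmax(1L, lo):pmin(length(v), hi)
    vals <- rep(NA_real_, 2L * half_window)
    vals[idx - lo + 1L] <- as.numeric(v[idx])
    if (minus) vals <- rev(vals)
    bm <- matrix(vals, nrow = bin)
    bmean <- colMeans(bm, na.rm = TRUE)
    ok <- !is.nan(bmean)
    sums[ok] <- sums[ok] + bmean[ok]
    cnts[ok] <- cnts[ok] + 1
  }
  if (all(cnts == 0)) stop("no anchor overlapped the track")
  data.frame(offset = (seq_len(nbin) - 1L) * bin - half_window,
             mean_signal = ifelse(cnts > 0, sums / cnts, NA_real_),
             n = cnts)
}

#' Normalized segmentation label frequencies per region
#'
#' For each query region, the bp fraction covered by every label, divided
#' by that label's genome-wide bp fraction (so 1 means "as often as
#' expected from the genome-wide segment distribution"). A label absent
#' genome-wide gets 0, with a note attribute.
#'
#' @param seg a [Segmentation-class].
#' @param regions GRanges of query regions (names or `id` column used as
#'   row names).
#' @return matrix regions x labels of normalized frequencies.
#' @export
labelFrequencies <- function(seg, regions) {
  if (!length(regions)) stop("no regions supplied")
  gr <- segments(seg)
  labels <- c(activeLabels(seg), repressiveLabels(seg))
  lab <- as.character(mcols(gr)$label)
  genomeBp <- vapply(setNames(labels, labels),
                     function(l) sum(as.numeric(width(gr[lab == l]))),
                     numeric(1))
  totalBp <- sum(as.numeric(width(gr)))
  genomeFrac <- genomeBp / totalBp
  hits <- findOverlaps(regions, gr, ignore.strand = TRUE)
  ovw <- width(pintersect(regions[queryHits(hits)], gr[subjectHits(hits)],
                          ignore.strand = TRUE))
  out <- matrix(0, nrow = length(regions), ncol = length(labels),
                dimnames = list(.regionNames(regions), labels))
  if (length(hits)) {
    key <- paste(queryHits(hits), lab[subjectHits(hits)])
    agg <- tapply(ovw, key, sum)
    parts <- strsplit(names(agg), " ", fixed = TRUE)
    ri <- as.integer(vapply(parts, `[`, "", 1L))
    lj <- match(vapply(parts, `[`, "", 2L), labels)
    out[cbind(ri, lj)] <- as.numeric(agg)
  }
  out <- out / width(regions)            # raw per-region frequency
  zero <- genomeFrac == 0
  out[, !zero] <- sweep(out[, !zero, drop = FALSE], 2, genomeFrac[!zero], "/")
  undef <- zero & apply(out > 0, 2, any)
  if (any(undef))
    attr(out, "note") <- paste("label(s) absent genome-wide reported as 0:",
                               paste(labels[undef], collapse = ","))
  out[, zero] <- 0
  out
}

.regionNames <- function(regions) {
  if (!is.null(names(regions))) names(regions)
  else if ("id" %in% names(mcols(regions))) as.character(mcols(regions)$id)
  else as.character(seq_along(regions))
}

#' Active-chromatin call from label frequencies
#'
#' Two criteria against the repressive background (aggregated as the max
#' over repressive labels by default): (1) the TSS label frequency is at
#' least `tss_ratio` (3x) the repressive level; (2) the gene-body start,
#' middle and end labels (GS, GM, GE) are all at least `genebody_ratio`
#' (2x) the repressive level. A locus is active iff either holds; both
#' comparisons are inclusive (>=) and require a positive numerator, so an
#' all-zero frequency row is inactive. Criterion 1 takes precedence in
#' the report.
#'
#' @param freqs matrix from [labelFrequencies()].
#' @param seg the [Segmentation-class] supplying the label partition.
#' @param thresholds threshold list (tss_ratio, genebody_ratio,
#'   repressive_aggregate).
#' @param genebody_all if FALSE, any of GS/GM/GE clearing the bar
#'   suffices for criterion 2 (default TRUE: all three).
#' @return data.frame (id, active, criterion in {"1","2","none"}).
#' @export
callActiveChromatin <- function(freqs, seg, thresholds = decorThresholds(),
                                genebody_all = TRUE) {
  repc <- repressiveLabels(seg)
  aggf <- if (thresholds$repressive_aggregate == "max") max else mean
  repLevel <- apply(freqs[, repc, drop = FALSE], 1, aggf)
  tss <- freqs[, "TSS"]
  crit1 <- tss > 0 & tss >= thresholds$tss_ratio * repLevel
  gb <- freqs[, c("GS", "GM", "GE"), drop = FALSE]
  gbStat <- if (genebody_all) apply(gb, 1, min) else apply(gb, 1, max)
  crit2 <- gbStat > 0 & gbStat >= thresholds$genebody_ratio * repLevel
  data.frame(id = rownames(freqs),
             active = crit1 | crit2,
             criterion = ifelse(crit1, "1", ifelse(crit2, "2", "none")),
             stringsAsFactors = FALSE)
}

#' DNase accessibility flag
#'
#' Mean DNase signal within +/- `half_window` bp of the strand-aware 5'
#' end, compared to `fold` times the genome-wide mean of the track. This
#' realizes the published 0/1 accessibility field (which integrates
#' DNase hypersensitivity in the 4 kb regions flanking the 5' end) as a
#' transparent fold-over-background rule.
#'
#' @param track RleList DNase signal.
#' @param loci GRanges of pseudogenes.
#' @param half_window window half-size in bp.
#' @param fold fold over the genome-wide mean required, default 2.
#' @return logical vector per locus.
#' @export
callDnaseAccessible <- function(track, loci, half_window = 4000L, fold = 2) {
  gmean <- sum(vapply(track, function(v) sum(as.numeric(v)), numeric(1))) /
    sum(vapply(track, length, numeric(1)))
  vapply(seq_along(loci), function(i) {
    chr <- as.character(seqnames(loci))[i]
    if (!chr %in% names(track)) return(FALSE)
    v <- track[[chr]]
    minus <- as.character(strand(loci))[i] == "-"
    tss <- if (minus) end(loci)[i] else start(loci)[i]
    idx <- max(1L, tss - half_window):min(length(v), tss + half_window - 1L)
    mean(as.numeric(v[idx])) >= fold * gmean
  }, logical(1))
}
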