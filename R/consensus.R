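#' Overlap in base pairs between two intervals
#'
#' Width of the intersection of two closed genomic intervals; 0 when the
#' chromosomes differ or the intervals do not touch. Strand is ignored,
#' matching the consensus rule (degraded automated calls can be
#' strand-ambiguous).
#'
#' @param a,b GRanges of equal length (recycled if length 1).
#' @return integer vector of overlap widths in bp.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 400))
#' overlapBp(a, b)  # 50
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Assign consensus evidence levels to pseudogene calls
#'
#' Intersects the manually annotated call set with two automated pipeline
#' call sets under a minimum-overlap criterion (default 50 bp, inclusive).
#' A manual locus supported by both pipelines is level 1; by neither (or
#' only one) it is level 2 unless both single-pipeline supports are present.
#' Following the published scheme: level 1 = manual + both pipelines;
#' level 2 = manual only (not recovered by both); 2-way consensus between
#' the pipelines that lacks manual support is "delta-2way"; remaining
#' single-pipeline calls are "A-P" / "A-R". Support is boolean per caller:
#' several overlapping calls from one pipeline count once.
#'
#' @param manual,pipeA,pipeB GRanges call sets. `manual` must carry an
#'   `id` metadata column; pipeline sets need none.
#' @param min_overlap minimum overlap in bp (inclusive), > 0.
#' @return list with `levels` (data.frame id, level, supporting_callers for
#'   manual loci), `delta2way` (GRanges of pipeline-consensus-only loci,
#'   one per pipeA call), and `singletons` (data.frame caller counts).
#' @export
assignLevels <- function(manual, pipeA, pipeB, min_overlap = 50L) {
  if (!is.numeric(min_overlap) || min_overlap <= 0)
    stop("min_overlap must be > 0")
  supA <- .supportedBy(manual, pipeA, min_overlap)
  supB <- .supportedBy(manual, pipeB, min_overlap)
  level <- ifelse(supA & supB, "1", "2")
  callers <- mapply(function(a, b) {
    paste(c("manual", if (a) "pipeA", if (b) "pipeB"), collapse = ",")
  }, supA, supB)
  lv <- data.frame(id = as.character(mcols(manual)$id),
                   level = level, supporting_callers = callers,
                   stringsAsFactors = FALSE)

  # two-way pipeline consensus checked back against manual
  abSup <- .supportedBy(pipeA, pipeB, min_overlap)
  manSup <- .supportedBy(pipeA, manual, min_overlap)
  delta <- pipeA[abSup & !manSup]
  aOnly <- sum(!abSup & !.supportedBy(pipeA, manual, min_overlap))
  bOnly <- sum(!.supportedBy(pipeB, pipeA, min_overlap) &
               !.supportedBy(pipeB, manual, min_overlap))
  list(levels = lv, delta2way = delta,
       singletons = data.frame(caller = c("A-P", "A-R"),
                               n = c(aOnly, bOnly)))
}

.supportedBy <- function(query, calls, min_overlap) {
  if (length(calls) == 0L) return(rep(FALSE, length(query)))
  hits <- findOverlaps(query, calls, minoverlap = as.integer(min_overlap),
                       ignore.strand = TRUE)
  seq_along(query) %in% queryHits(hits)
}

#' Surveyed pseudogene set
#'
#' The union of level 1 and level 2 manual loci minus polymorphic
#' pseudogenes, which are excluded from the survey (they are coding in
#' some individuals).
#'
#' @param manual GRanges with `id` and `biotype` metadata columns.
#' @param levels data.frame from [assignLevels()].
#' @return GRanges subset of `manual` carrying a `level` column.
#' @export
surveyedSet <- function(manual, levels) {
  stopifnot(all(mcols(manual)$id == levels$id))
  keep <- mcols(manual)$biotype != "polymorphic"
  out <- manual[keep]
  mcols(out)$level <- levels$level[keep]
  out
}

#' Extrapolate the genome-wide pseudogene count
#'
#' Two estimators for the total number of manually annotatable pseudogenes
#' in a genome, given counts from its fully annotated region:
#' `pipeline_ratio` scales the manual count by the genome-wide over
#' in-region counts of an automated pipeline,
#' n_manual * n_pipe_genome / n_pipe_region; `length_ratio` scales it by
#' genome over annotated nucleotides, n_manual * genome_nt / annotated_nt.
#' The result is rounded to the nearest integer (ties away from zero).
#'
#' @param method "pipeline_ratio" or "length_ratio".
#' @param n_manual manual count in the annotated region.
#' @param denom in-region pipeline count, or annotated nucleotides.
#' @param numer genome-wide pipeline count, or genome nucleotides.
#' @return integer estimate.
#' @examples
#' extrapolateCount("pipeline_ratio", 9776, 12501, 18046)      # 14112
#' extrapolateCount("length_ratio", 9776, 2383814825, 3092688347)  # 12683
#' @export
extrapolateCount <- function(method = c("pipeline_ratio", "length_ratio"),
                             n_manual, denom, numer) {
  method <- match.arg(method)
  if (any(c(n_manual, denom, numer) <= 0))
    stop("all inputs must be positive")
  x <- n_manual * numer / denom
  as.integer(floor(x + 0.5))
}
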