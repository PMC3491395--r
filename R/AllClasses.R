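#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps pintersect mcols mcols<- strand<- GRangesList coverage
#'   resize shift reduce
#' @importFrom IRanges IRanges Views viewApply RleList subsetByOverlaps
#'   overlapsAny
#' @importFrom S4Vectors Rle queryHits subjectHits DataFrame runValue
#'   runLength elementNROWS
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet DNAString pairwiseAlignment
#'   readDNAStringSet writeXStringSet pattern subject nucleotideSubstitutionMatrix
#' @importFrom stats rpois runif rnorm rbinom cor fisher.test wilcox.test
#'   ks.test quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Segmentation: labeled chromatin-state intervals
#'
#' Holds a genome segmentation as a `GRanges` whose `label` metadata column
#' draws from a fixed vocabulary partitioned into active and repressive
#' subsets (see [segmentationLabels()]). Segments must be non-overlapping
#' within a chromosome; every label must belong to exactly one subset.
#'
#' @slot segments GRanges with a `label` metadata column.
#' @slot activeLabels character, the activity-indicating labels.
#' @slot repressiveLabels character, the repressive labels.
#' @export
setClass("Segmentation",
  representation(segments = "GRanges",
                 activeLabels = "character",
                 repressiveLabels = "character"))

setValidity("Segmentation", function(object) {
  gr <- object@segments
  msgs <- character()
  if (!"label" %in% names(mcols(gr)))
    msgs <- c(msgs, "segments must carry a 'label' metadata column")
  if (length(intersect(object@activeLabels, object@repressiveLabels)))
    msgs <- c(msgs, "active and repressive label sets must be disjoint")
  if ("label" %in% names(mcols(gr))) {
    known <- c(object@activeLabels, object@repressiveLabels)
    bad <- setdiff(unique(as.character(mcols(gr)$label)), known)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown segmentation label(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (length(gr) > 1L) {
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE,
                         ignore.strand = TRUE)
    if (length(hits))
      msgs <- c(msgs, "segments overlap within a chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Segmentation
#'
#' @param segments GRanges with a `label` metadata column.
#' @param labels list with `active` and `repressive` character vectors;
#'   defaults to [segmentationLabels()].
#' @return A [Segmentation-class] object.
#' @export
Segmentation <- function(segments, labels = segmentationLabels()) {
  new("Segmentation", segments = segments,
      activeLabels = labels$active, repressiveLabels = labels$repressive)
}

#' @describeIn Segmentation-class the underlying labeled GRanges
#' @param x,object a Segmentation
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @export
setMethod("segments", "Segmentation", function(x) x@segments)

#' @export
setGeneric("activeLabels", function(x) standardGeneric("activeLabels"))
#' @export
setMethod("activeLabels", "Segmentation", function(x) x@activeLabels)

#' @export
setGeneric("repressiveLabels", function(x) standardGeneric("repressiveLabels"))
#' @export
setMethod("repressiveLabels", "Segmentation", function(x) x@repressiveLabels)

setMethod("show", "Segmentation", function(object) {
  cat("Segmentation with", length(object@segments), "segments;",
      length(object@activeLabels), "active /",
      length(object@repressiveLabels), "repressive labels\n")
  tab <- sort(table(as.character(mcols(object@segments)$label)),
              decreasing = TRUE)
  cat("  top labels:",
      paste(head(names(tab), 5L), head(as.integer(tab), 5L),
            sep = ":", collapse = " "), "\n")
})

#' DecorationTable: the per-pseudogene activity table
#'
#' One row per (pseudogene, cell context). Columns follow the decoration
#' (psiDR-style) field list: identifiers and parent metadata, the
#' sequence-identity class, the transcription flag with its evidence tags
#' and tissues, and per-context 0/1 activity flags for DNase
#' accessibility, chromatin state, Pol2 binding, active promoter, and
#' conservation. Flags for loci excluded by the coding-TSS proximity
#' filter are NA with `excluded_near_coding_tss = 1`.
#'
#' @slot table data.frame of decoration rows.
#' @export
setClass("DecorationTable", representation(table = "data.frame"))

.psidrFlagCols <- c("transcribed", "dnase_accessible", "active_chromatin",
                    "active_pol2", "active_promoter", "conserved",
                    "excluded_near_coding_tss")

.psidrCols <- c("pseudogene_id", "context", "biotype", "level",
                "parent_gene_id", "parent_chrom", "parent_start",
                "parent_end", "parent_strand", "parent_source",
                "cds_identity", "utr3_identity", "identity_class",
                "transcribed", "transcription_tags", "transcribed_tissues",
                "dnase_accessible", "active_chromatin", "chromatin_criterion",
                "active_pol2", "pol2_criterion", "active_promoter",
                "tfbs_count", "conserved", "excluded_near_coding_tss")

setValidity("DecorationTable", function(object) {
  tb <- object@table
  msgs <- character()
  miss <- setdiff(.psidrCols, names(tb))
  if (length(miss))
    msgs <- c(msgs, paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    for (f in .psidrFlagCols) {
      v <- tb[[f]]
      if (!all(v %in% c(0L, 1L, NA)))
        msgs <- c(msgs, paste0("flag column '", f, "' not in {0,1,NA}"))
    }
    key <- paste(tb$pseudogene_id, tb$context)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (pseudogene, context) rows")
    tr <- tb$transcribed
    tags <- tb$transcription_tags
    ok <- is.na(tr) | (tr == 1L) == (tags != "None")
    if (!all(ok))
      msgs <- c(msgs, "transcribed flag inconsistent with evidence tags")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DecorationTable
#' @param table data.frame with the decoration columns.
#' @return A [DecorationTable-class] object.
#' @export
DecorationTable <- function(table) {
  new("DecorationTable", table = as.data.frame(table))
}

#' @export
setGeneric("decorationTable", function(x) standardGeneric("decorationTable"))
#' @describeIn DecorationTable-class extract the underlying data.frame
#' @param x,object a DecorationTable
#' @export
setMethod("decorationTable", "DecorationTable", function(x) x@table)

setMethod("show", "DecorationTable", function(object) {
  tb <- object@table
  cat("DecorationTable:", length(unique(tb$pseudogene_id)), "pseudogenes x",
      length(unique(tb$context)), "contexts (", nrow(tb), "rows )\n")
  for (f in c("transcribed", "active_chromatin", "active_pol2",
              "active_promoter", "conserved"))
    cat(sprintf("  %-16s %d\n", f, sum(tb[[f]] == 1L, na.rm = TRUE)))
})

setMethod("dim", "DecorationTable", function(x) dim(x@table))
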