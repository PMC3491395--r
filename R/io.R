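#' Read a pseudogene/gene annotation
#'
#' GTF (1-based inclusive on disk, Ensembl-style attributes) or BED
#' (0-based half-open on disk); both are converted to the internal
#' GRanges representation on read by rtracklayer. Records with an
#' unknown biotype are kept and flagged "ambiguous" with a warning; an
#' empty file yields an empty GRanges with a warning.
#'
#' @param path file path.
#' @param format "GTF" or "BED".
#' @return GRanges with `id`, `biotype`, `parent_id`, `parent_source`
#'   metadata columns (BED carries only `id`).
#' @export
readAnnotation <- function(path, format = c("GTF", "BED")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L ||
      (format == "GTF" && !length(readLines(path, n = 5L)))) {
    warning("empty annotation file: ", path)
    return(GRanges(id = character(), biotype = character()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = tolower(format)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (format == "BED") {
    mcols(gr) <- DataFrame(id = if ("name" %in% names(mcols(gr)))
      as.character(mcols(gr)$name) else as.character(seq_along(gr)))
    return(gr)
  }
  m <- mcols(gr)
  known <- c("processed", "duplicated", "unitary", "polymorphic",
             "ambiguous", "coding")
  biotype <- if ("biotype" %in% names(m)) as.character(m$biotype)
    else rep(NA_character_, length(gr))
  if (any(!biotype %in% known)) {
    warning("unknown biotype(s) flagged 'ambiguous'")
    biotype[!biotype %in% known] <- "ambiguous"
  }
  out <- granges(gr)
  mcols(out) <- DataFrame(
    id = as.character(m$gene_id),
    biotype = biotype,
    parent_id = if ("parent_id" %in% names(m)) as.character(m$parent_id)
      else NA_character_,
    parent_source = if ("parent_source" %in% names(m))
      as.character(m$parent_source) else NA_character_,
    level = if ("level" %in% names(m)) as.character(m$level)
      else NA_character_)
  names(out) <- mcols(out)$id
  out
}

#' Write an annotation as GTF or BED
#'
#' @param gr GRanges with `id` (and for GTF: `biotype`, `parent_id`,
#'   `parent_source`) metadata columns.
#' @param path output path.
#' @param format "GTF" or "BED".
#' @export
writeAnnotation <- function(gr, path, format = c("GTF", "BED")) {
  format <- match.arg(format)
  if (format == "BED") {
    out <- granges(gr)
    mcols(out)$name <- .regionNames(gr)
    rtracklayer::export(out, path, format = "bed")
  } else {
    out <- granges(gr)
    m <- mcols(gr)
    mcols(out) <- DataFrame(source = "pseudoDecoR", type = "gene",
                            gene_id = as.character(m$id))
    for (f in c("biotype", "parent_id", "parent_source", "level"))
      if (f %in% names(m)) mcols(out)[[f]] <- as.character(m[[f]])
    rtracklayer::export(out, path, format = "gtf")
  }
  invisible(path)
}

#' Read ENCODE narrowPeak peaks
#'
#' 10-column narrowPeak (BED6+4, 0-based half-open on disk). The name
#' column is taken as the factor label; signalValue becomes `signal`.
#'
#' @param path file path.
#' @return GRanges with `factor` and `signal` metadata columns.
#' @export
readNarrowPeak <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  out <- granges(gr)
  mcols(out) <- DataFrame(factor = as.character(mcols(gr)$name),
                          signal = mcols(gr)$signalValue)
  out
}

#' Write peaks as narrowPeak
#' @param peaks GRanges with `factor` and `signal` columns.
#' @param path output path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L, end = end(peaks),
    name = as.character(mcols(peaks)$factor),
    score = 0L,
    strand = ".",
    signalValue = mcols(peaks)$signal, pValue = -1, qValue = -1, peak = -1L)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a per-base RleList
#'
#' Intervals must not overlap (bedGraph dialect); uncovered bases are 0.
#'
#' @param path file path.
#' @param seqinfo Seqinfo giving chromosome lengths.
#' @return RleList of per-base signal.
#' @export
readBedGraph <- function(path, seqinfo) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) {   # empty track: all-zero coverage
    z <- GRanges(seqinfo = seqinfo)
    return(coverage(z, width = seqlengths(seqinfo)))
  }
  if (length(gr) > 1L &&
      length(findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)))
    stop("overlapping intervals in bedGraph: ", path)
  seqlevels(gr) <- seqlevels(seqinfo)
  seqlengths(gr) <- seqlengths(seqinfo)
  coverage(gr, weight = "score")
}

#' Write an RleList as bedGraph (nonzero runs only)
#' @param track RleList.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  rows <- lapply(names(track), function(chr) {
    v <- track[[chr]]
    ends <- cumsum(runLength(v)); starts <- c(1L, head(ends, -1L) + 1L)
    val <- runValue(v)
    keep <- val != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = starts[keep] - 1L, end = ends[keep],
               score = val[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    file.create(path)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a segmentation BED (label in the name column)
#'
#' @param path file path.
#' @param labels label vocabulary list (active/repressive); labels
#'   outside the vocabulary raise an error naming the offenders.
#' @return A [Segmentation-class].
#' @export
readSegmentationBed <- function(path, labels = segmentationLabels()) {
  gr <- rtracklayer::import(path, format = "bed")
  lab <- as.character(mcols(gr)$name)
  bad <- setdiff(unique(lab), c(labels$active, labels$repressive))
  if (length(bad))
    stop("segmentation label(s) outside the label set: ",
         paste(bad, collapse = ", "))
  out <- granges(gr)
  mcols(out) <- DataFrame(label = lab)
  Segmentation(out, labels)
}

#' Write a Segmentation as BED
#' @param seg a Segmentation.
#' @param path output path.
#' @export
writeSegmentationBed <- function(seg, path) {
  gr <- segments(seg)
  out <- granges(gr)
  mcols(out)$name <- as.character(mcols(gr)$label)
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read divergence / variant TSVs
#'
#' Divergence: pseudogene_id, species, aligned_bp, substitutions,
#' length. Variants: pseudogene_id, pos, vclass, daf.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readDivergenceTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pseudogene_id", "species", "aligned_bp", "substitutions",
            "length")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("divergence TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(d$aligned_bp <= d$length),
            all(d$substitutions <= d$aligned_bp))
  d
}

#' @rdname readDivergenceTsv
#' @export
readVariantsTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(d$daf >= 0 & d$daf <= 1),
            all(d$vclass %in% c("SNP", "indel", "SV")))
  d
}

#' Write/read sequence pairs as FASTA
#'
#' Each pseudogene contributes four records named
#' `<id>|pseudo_cds`, `<id>|parent_cds`, `<id>|pseudo_utr3`,
#' `<id>|parent_utr3`, plus `<id>|parent=<parent_id>` bookkeeping in the
#' pseudo_cds header.
#'
#' @param pairs pair list as produced by [simulateSequences()].
#' @param path FASTA path.
#' @export
writeSequencePairs <- function(pairs, path) {
  seqs <- character(); nms <- character()
  for (id in names(pairs)) {
    p <- pairs[[id]]
    nms <- c(nms, paste0(id, "|pseudo_cds|parent=", p$parent_id),
             paste0(id, "|parent_cds"), paste0(id, "|pseudo_utr3"),
             paste0(id, "|parent_utr3"))
    seqs <- c(seqs, p$pseudo_cds, p$parent_cds, p$pseudo_utr3, p$parent_utr3)
  }
  writeXStringSet(DNAStringSet(setNames(seqs, nms)), path)
  invisible(path)
}

#' @rdname writeSequencePairs
#' @export
readSequencePairs <- function(path) {
  ss <- readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  ids <- unique(vapply(parts, `[`, "", 1L))
  out <- lapply(setNames(ids, ids), function(id) {
    grab <- function(region) {
      hit <- which(vapply(parts, function(p)
        p[1L] == id && p[2L] == region, logical(1)))
      as.character(ss[[hit]])
    }
    pc <- which(vapply(parts, function(p)
      p[1L] == id && p[2L] == "pseudo_cds", logical(1)))
    parent <- sub("^parent=", "", parts[[pc]][3L])
    list(parent_id = parent, pseudo_cds = grab("pseudo_cds"),
         parent_cds = grab("parent_cds"),
         pseudo_utr3 = grab("pseudo_utr3"),
         parent_utr3 = grab("parent_utr3"))
  })
  out
}

#' Write the decoration table as TSV
#'
#' Serializes one row per (pseudogene, context): flags as 0/1, evidence
#' tags comma-separated ("None" when untranscribed), NA for the
#' regulation calls of excluded loci. Duplicate (pseudogene, context)
#' keys are an error.
#'
#' @param x a [DecorationTable-class].
#' @param path output path.
#' @export
writePsidr <- function(x, path) {
  stopifnot(is(x, "DecorationTable"))
  validObject(x)
  tb <- decorationTable(x)[, .psidrCols]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePsidr
#' @export
readPsidr <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(transcription_tags = "character",
                                  transcribed_tissues = "character",
                                  level = "character",
                                  pol2_criterion = "character",
                                  chromatin_criterion = "character"))
  tb$transcribed_tissues[is.na(tb$transcribed_tissues)] <- ""
  for (f in .psidrFlagCols) tb[[f]] <- as.integer(tb[[f]])
  DecorationTable(tb)
}

#' Write/read the simulation config as key: value YAML
#' @param config simulation config list.
#' @param path output path.
#' @export
writeSimConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", paste(if (is.character(v)) v else format(v, digits = 15),
                          collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  proto <- simulationConfig()
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  cfg <- proto
  for (p in kv) {
    k <- p[1L]; raw <- strsplit(p[2L], ",", fixed = TRUE)[[1L]]
    if (!k %in% names(proto)) next
    tmpl <- proto[[k]]
    v <- if (is.character(tmpl)) raw else
      setNames(as.numeric(raw), names(tmpl))
    if (is.integer(tmpl)) v <- as.integer(v)
    cfg[[k]] <- v
  }
  cfg
}
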