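#' Extract per-base values of a track over a locus
#'
#' @param track RleList.
#' @param gr single-range GRanges.
#' @return numeric vector of per-base values (5'->3' in reference
#'   orientation).
#' @export
trackValues <- function(track, gr) {
  stopifnot(length(gr) == 1L)
  chr <- as.character(seqnames(gr))
  v <- track[[chr]]
  as.numeric(v[start(gr):min(end(gr), length(v))])
}

#' Run the full decoration pipeline on a corpus
#'
#' Consensus levels -> surveyed set -> parent identity -> transcription
#' calls -> conservation -> per-context chromatin, DNase and upstream
#' regulation -> decoration table, partial-activity classes and
#' cross-context specificity matrices.
#'
#' @param corpus a corpus from [simulateCorpus()] (or assembled from
#'   files with the readers in this package, same structure).
#' @param thresholds threshold list.
#' @return list with `levels`, `surveyed`, `identity`, `transcription`,
#'   `conservation`, `chromatin`, `dnase`, `regulation`, `psidr`
#'   (DecorationTable), `classes`, `specificity`, `summary`.
#' @export
runDecoration <- function(corpus, thresholds = decorThresholds()) {
  lv <- assignLevels(corpus$manual, corpus$pipeA, corpus$pipeB,
                     thresholds$consensus_overlap_bp)
  surveyed <- surveyedSet(corpus$manual, lv$levels)
  svIds <- as.character(mcols(surveyed)$id)

  ident <- identityPipeline(corpus$sequences$pairs[svIds], thresholds)

  depthById <- lapply(setNames(svIds, svIds), function(id) {
    g <- surveyed[match(id, svIds)]
    lapply(corpus$coverage$tracks, function(tr) trackValues(tr, g))
  })
  trans <- transcriptionPipeline(
    svIds,
    corpus$coverage$est_evidence,
    corpus$coverage$total_rna,
    depthById,
    corpus$coverage$parent_expr,
    corpus$coverage$n_similar,
    thresholds)

  cons <- conservationPipeline(
    corpus$divergence[corpus$divergence$pseudogene_id %in% svIds, ],
    rates = c(chimp = thresholds$background_rate_chimp,
              mouse = thresholds$background_rate_mouse),
    fdr = thresholds$fdr,
    combine = thresholds$conserved_combine)

  contexts <- names(corpus$fungen)
  regions <- punion(granges(surveyed),
                    granges(upstreamWindow(surveyed, thresholds$upstream_bp)),
                    fill.gap = TRUE)
  names(regions) <- svIds
  chromatin <- list(); dnase <- list(); regulation <- list()
  for (ctx in contexts) {
    fg <- corpus$fungen[[ctx]]
    freqs <- labelFrequencies(fg$segmentation, regions)
    chromatin[[ctx]] <- callActiveChromatin(freqs, fg$segmentation,
                                            thresholds)
    dn <- callDnaseAccessible(fg$dnase, surveyed,
                              thresholds$profile_halfwindow_bp,
                              thresholds$dnase_fold)
    dnase[[ctx]] <- setNames(dn, svIds)
    regulation[[ctx]] <- regulationPipeline(
      surveyed, corpus$coding, fg$tf_peaks, fg$pol2_peaks,
      fg$cofactor_peaks, fg$promoters, thresholds)
  }

  psidr <- decorate(surveyed, parents = corpus$coding, identity = ident,
                    transcription = trans, conservation = cons$conserved,
                    chromatin = chromatin, dnase = dnase,
                    regulation = regulation, contexts = contexts)

  classes <- do.call(rbind, lapply(contexts, function(ctx) {
    ret <- parentUpstreamRetained(surveyed, corpus$coding,
                                  corpus$fungen[[ctx]]$tf_peaks,
                                  thresholds$upstream_bp)
    tb <- decorationTable(psidr)
    classifyPartialActivity(tb[tb$context == ctx, ], ret)
  }))

  spec <- NULL
  if (length(contexts) >= 2L) {
    tb <- decorationTable(psidr)
    actSet <- function(col) lapply(setNames(contexts, contexts), function(ctx)
      tb$pseudogene_id[tb$context == ctx & !is.na(tb[[col]]) &
                         tb[[col]] == 1L])
    spec <- list(pol2 = specificityMatrix(actSet("active_pol2")),
                 promoter = specificityMatrix(actSet("active_promoter")))
  }

  tb <- decorationTable(psidr)
  summary <- list(
    n_manual = length(corpus$manual),
    n_level1 = sum(lv$levels$level == "1"),
    n_level2 = sum(lv$levels$level == "2"),
    n_delta2way = length(lv$delta2way),
    n_surveyed = length(surveyed),
    n_transcribed = sum(trans$transcribed),
    n_conserved = sum(cons$conserved, na.rm = TRUE),
    n_active_chromatin = vapply(chromatin, function(x) sum(x$active),
                                numeric(1)),
    n_pol2_active = vapply(contexts, function(ctx)
      sum(tb$active_pol2[tb$context == ctx] == 1L, na.rm = TRUE), numeric(1)),
    n_promoter_active = vapply(contexts, function(ctx)
      sum(tb$active_promoter[tb$context == ctx] == 1L, na.rm = TRUE),
      numeric(1)),
    class_counts = table(classes$class))

  list(levels = lv, surveyed = surveyed, identity = ident,
       transcription = trans, conservation = cons, chromatin = chromatin,
       dnase = dnase, regulation = regulation, psidr = psidr,
       classes = classes, specificity = spec, summary = summary)
}

#' Print a per-stage summary of a decoration run
#'
#' @param result list from [runDecoration()].
#' @param thresholds threshold list used (logged for auditability).
#' @export
reportSummary <- function(result, thresholds = decorThresholds()) {
  s <- result$summary
  cat("== decoration summary ==\n")
  cat(sprintf("manual loci: %d (level 1: %d, level 2: %d, 2-way only: %d)\n",
              s$n_manual, s$n_level1, s$n_level2, s$n_delta2way))
  cat(sprintf("surveyed (non-polymorphic): %d\n", s$n_surveyed))
  cat(sprintf("transcribed: %d; conserved: %d\n",
              s$n_transcribed, s$n_conserved))
  for (ctx in names(s$n_active_chromatin))
    cat(sprintf("[%s] active chromatin: %d, Pol2: %d, promoter: %d\n", ctx,
                s$n_active_chromatin[[ctx]], s$n_pol2_active[[ctx]],
                s$n_promoter_active[[ctx]]))
  cat("partial-activity classes:\n")
  print(s$class_counts)
  cat("thresholds used:\n")
  for (k in names(thresholds))
    cat(sprintf("  %s = %s\n", k,
                paste(thresholds[[k]], collapse = ",")))
  if (!is.null(result$specificity)) {
    cat("Jaccard specificity (Pol2):\n"); print(round(result$specificity$pol2, 3))
    cat("Jaccard specificity (promoter):\n")
    print(round(result$specificity$promoter, 3))
  }
  invisible(s)
}

#' Write a simulated corpus to standard-format files
#'
#' Annotation as GTF, caller call-sets as BED, sequences as FASTA,
#' per-tissue coverage as bedGraph, per-context segmentation BED /
#' narrowPeak files / promoter BED / DNase bedGraph, divergence and
#' variant TSVs, truth table TSV and the config as key: value text.
#'
#' @param corpus from [simulateCorpus()].
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  writeAnnotation(corpus$manual, fp("manual.gtf"), "GTF")
  writeAnnotation(corpus$coding, fp("coding.gtf"), "GTF")
  writeAnnotation(corpus$pipeA, fp("pipeA.bed"), "BED")
  writeAnnotation(corpus$pipeB, fp("pipeB.bed"), "BED")
  writeSequencePairs(corpus$sequences$pairs, fp("sequences.fa"))
  for (t in names(corpus$coverage$tracks))
    writeBedGraph(corpus$coverage$tracks[[t]],
                  fp(paste0("coverage_", t, ".bedGraph")))
  pe <- corpus$coverage$parent_expr
  write.table(data.frame(pseudogene_id = rownames(pe), pe,
                         check.names = FALSE),
              fp("parent_expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(corpus$coverage$total_rna, fp("total_rna.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(corpus$coverage$est_evidence, fp("est_evidence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pseudogene_id = names(corpus$coverage$n_similar),
                         n_similar = as.integer(corpus$coverage$n_similar)),
              fp("similar_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (ctx in names(corpus$fungen)) {
    fg <- corpus$fungen[[ctx]]
    writeSegmentationBed(fg$segmentation,
                         fp(paste0("segmentation_", ctx, ".bed")))
    p2 <- fg$pol2_peaks; mcols(p2)$factor <- "Pol2"
    writeNarrowPeak(p2, fp(paste0("pol2_", ctx, ".narrowPeak")))
    if (length(fg$cofactor_peaks))
      writeNarrowPeak(fg$cofactor_peaks,
                      fp(paste0("cofactor_", ctx, ".narrowPeak")))
    if (length(fg$tf_peaks))
      writeNarrowPeak(fg$tf_peaks, fp(paste0("tf_", ctx, ".narrowPeak")))
    rtracklayer::export(fg$promoters, fp(paste0("promoters_", ctx, ".bed")),
                        format = "bed")
    writeBedGraph(fg$dnase, fp(paste0("dnase_", ctx, ".bedGraph")))
  }
  write.table(corpus$divergence, fp("divergence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(corpus$variants, fp("variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(corpus$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSimConfig(corpus$config, fp("config.txt"))
  invisible(dir)
}

#' Read a corpus back from a directory written by [writeCorpus()]
#'
#' @param dir corpus directory.
#' @return corpus list, same structure as [simulateCorpus()].
#' @export
readCorpus <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  config <- readSimConfig(fp("config.txt"))
  si <- .simSeqinfo(config)
  fixsi <- function(gr) {
    seqlevels(gr) <- seqlevels(si); seqlengths(gr) <- seqlengths(si); gr
  }
  manual <- fixsi(readAnnotation(fp("manual.gtf"), "GTF"))
  coding <- fixsi(readAnnotation(fp("coding.gtf"), "GTF"))
  pipeA <- fixsi(readAnnotation(fp("pipeA.bed"), "BED"))
  pipeB <- fixsi(readAnnotation(fp("pipeB.bed"), "BED"))
  pairs <- readSequencePairs(fp("sequences.fa"))
  tracks <- lapply(setNames(config$tissues, config$tissues), function(t)
    readBedGraph(fp(paste0("coverage_", t, ".bedGraph")), si))
  pe <- read.delim(fp("parent_expression.tsv"), check.names = FALSE)
  parentExpr <- as.matrix(pe[, -1, drop = FALSE])
  rownames(parentExpr) <- pe$pseudogene_id
  sim <- read.delim(fp("similar_hits.tsv"))
  fungen <- lapply(setNames(config$contexts, config$contexts), function(ctx) {
    seg <- readSegmentationBed(fp(paste0("segmentation_", ctx, ".bed")))
    seg@segments <- fixsi(seg@segments)
    pol2 <- fixsi(readNarrowPeak(fp(paste0("pol2_", ctx, ".narrowPeak"))))
    cfp <- fp(paste0("cofactor_", ctx, ".narrowPeak"))
    cof <- if (file.exists(cfp)) fixsi(readNarrowPeak(cfp)) else
      GRanges(seqinfo = si)
    tfp <- fp(paste0("tf_", ctx, ".narrowPeak"))
    tf <- if (file.exists(tfp)) fixsi(readNarrowPeak(tfp)) else
      GRanges(seqinfo = si)
    prom <- fixsi(rtracklayer::import(fp(paste0("promoters_", ctx, ".bed")),
                                      format = "bed"))
    dnase <- readBedGraph(fp(paste0("dnase_", ctx, ".bedGraph")), si)
    list(segmentation = seg, pol2_peaks = pol2, cofactor_peaks = cof,
         tf_peaks = tf, promoters = prom, dnase = dnase)
  })
  list(coding = coding, manual = manual, pipeA = pipeA, pipeB = pipeB,
       sequences = list(pairs = pairs),
       coverage = list(tracks = tracks, parent_expr = parentExpr,
                       total_rna = read.delim(fp("total_rna.tsv")),
                       est_evidence = read.delim(fp("est_evidence.tsv")),
                       n_similar = setNames(sim$n_similar,
                                            sim$pseudogene_id)),
       fungen = fungen,
       divergence = readDivergenceTsv(fp("divergence.tsv")),
       variants = readVariantsTsv(fp("variants.tsv")),
       truth = read.delim(fp("truth.tsv")),
       config = config)
}

#' One-call pipeline entry point
#'
#' `simulate` writes a synthetic corpus (plus truth table) to `out_dir`;
#' `decorate` reads a corpus directory, runs the decoration pipeline and
#' writes the psiDR-style TSV, the class table and specificity matrices;
#' `report` reruns the pipeline and prints the per-stage summary.
#'
#' @param command "simulate", "decorate" or "report".
#' @param out_dir working directory for corpus and results.
#' @param seed master seed (simulate only).
#' @param config optional simulation config overriding `seed`.
#' @param thresholds threshold list.
#' @return invisibly, the corpus (simulate) or the run result.
#' @export
runPipeline <- function(command = c("simulate", "decorate", "report"),
                        out_dir, seed = 1L, config = NULL,
                        thresholds = decorThresholds()) {
  command <- match.arg(command)
  if (command == "simulate") {
    if (is.null(config)) config <- simulationConfig(seed = seed)
    corpus <- simulateCorpus(config)
    writeCorpus(corpus, out_dir)
    return(invisible(corpus))
  }
  if (!dir.exists(out_dir))
    stop("stage '", command, "': corpus directory not found: ", out_dir)
  corpus <- readCorpus(out_dir)
  res <- runDecoration(corpus, thresholds)
  if (command == "decorate") {
    writePsidr(res$psidr, file.path(out_dir, "psidr.tsv"))
    write.table(res$classes, file.path(out_dir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$levels$levels, file.path(out_dir, "levels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$specificity)) {
      write.table(res$specificity$pol2,
                  file.path(out_dir, "specificity_pol2.tsv"),
                  sep = "\t", quote = FALSE)
      write.table(res$specificity$promoter,
                  file.path(out_dir, "specificity_promoter.tsv"),
                  sep = "\t", quote = FALSE)
    }
  } else {
    reportSummary(res, thresholds)
  }
  invisible(res)
}
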