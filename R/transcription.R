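#' Genome-similarity category of a pseudogene
#'
#' Bins the number of non-self high-identity genomic alignments of a
#' pseudogene into the four categories used to stratify the RNA-seq
#' transcription analysis: no similar region, exactly one (most likely the
#' parent), two to five, or more than five.
#'
#' @param n_hits integer vector of similar-region counts, >= 0.
#' @return factor with levels "0", "1", "2-5", ">5".
#' @export
categorizeSimilarity <- function(n_hits) {
  stopifnot(all(n_hits >= 0))
  cut(n_hits, breaks = c(-0.5, 0.5, 1.5, 5.5, Inf),
      labels = c("0", "1", "2-5", ">5"))
}

#' EST/mRNA locus-specific transcription call
#'
#' A pseudogene is called transcribed from EST/mRNA databases when at
#' least one evidence record has both a best-in-genome alignment at the
#' pseudogene locus and clear differences from the parent locus.
#'
#' @param evidence data.frame with logical columns `best_in_genome` and
#'   `differs_from_parent` (zero rows allowed).
#' @return logical scalar.
#' @export
callEst <- function(evidence) {
  nrow(evidence) > 0L &&
    any(evidence$best_in_genome & evidence$differs_from_parent)
}

#' Total-RNA transcription call
#'
#' Transcribed iff (1) reads map to the pseudogene and none to the parent,
#' or (2) both are covered but the pair's sequence similarity is below the
#' cut (90%, strict), so reads are attributable to the pseudogene.
#'
#' @param pseudo_cov,parent_cov summed read coverage on pseudogene/parent.
#' @param pair_identity percent identity between the two loci.
#' @param cut similarity cut, default 90.
#' @return logical (vectorized).
#' @export
callTotalRna <- function(pseudo_cov, parent_cov, pair_identity, cut = 90) {
  stopifnot(all(pseudo_cov >= 0), all(parent_cov >= 0))
  (pseudo_cov > 0 & parent_cov == 0) |
    (pseudo_cov > 0 & parent_cov > 0 & pair_identity < cut)
}

#' BodyMap multi-tissue transcription call
#'
#' The coverage rule calls a pseudogene transcribed when, in at least one
#' tissue, at least half of its length is covered at depth >= 2. For loci
#' with similar regions elsewhere in the genome, a mapping artifact is
#' ruled out by requiring the pseudogene's cross-tissue expression profile
#' to be discordant with its parent's (Spearman rank correlation <= the
#' configured maximum, default 0.5); loci with no similar region pass on
#' coverage alone.
#'
#' @param depth list (one numeric per-base depth vector per tissue) over
#'   the pseudogene's exonic span.
#' @param parent_expression named per-tissue expression of the parent
#'   (same tissue order), used for the discordance rule.
#' @param n_similar number of non-self similar regions in the genome.
#' @param min_depth,min_frac coverage-rule parameters (defaults 2 reads,
#'   half the length).
#' @param max_cor discordance threshold on the rank correlation.
#' @return list(call, tissues) — the call and the tissues passing the
#'   coverage rule.
#' @export
callBodymap <- function(depth, parent_expression = NULL, n_similar = 0L,
                        min_depth = 2, min_frac = 0.5, max_cor = 0.5) {
  if (!length(depth)) stop("no tissue tracks supplied")
  if (any(!lengths(depth))) stop("zero-length locus")
  frac <- vapply(depth, function(v) mean(v >= min_depth), numeric(1))
  pass <- names(frac)[frac >= min_frac]
  covOk <- length(pass) > 0L
  discOk <- TRUE
  if (covOk && n_similar > 0L) {
    expr <- vapply(depth, mean, numeric(1))
    if (is.null(parent_expression))
      stop("parent expression required for loci with similar regions")
    rho <- suppressWarnings(
      cor(expr, parent_expression[names(expr)], method = "spearman"))
    discOk <- !is.na(rho) && rho <= max_cor
  }
  list(call = covOk && discOk, tissues = pass)
}

#' Merge per-source transcription evidence
#'
#' OR-gate over the three computational pipelines plus optional externally
#' supplied RT-PCR validation: a pseudogene is transcribed iff at least
#' one source calls it, and the evidence tags record which. With no
#' evidence the tag is "None".
#'
#' @param est,total_rna,bodymap logical per-source calls.
#' @param rtpcr optional logical external-validation evidence.
#' @param tissues tissues where the BodyMap coverage rule passed.
#' @return list(transcribed, tags, tissues).
#' @export
mergeCalls <- function(est = FALSE, total_rna = FALSE, bodymap = FALSE,
                       rtpcr = FALSE, tissues = character()) {
  tags <- c(if (isTRUE(est)) "EST", if (isTRUE(total_rna)) "TotalRNA",
            if (isTRUE(bodymap)) "BodyMap", if (isTRUE(rtpcr)) "RT-PCR")
  if (is.null(tags)) tags <- character()
  list(transcribed = length(tags) > 0L,
       tags = if (length(tags)) tags else "None",
       tissues = if (isTRUE(bodymap)) tissues else character())
}

#' Transcription pipeline over a simulated/loaded corpus
#'
#' Applies the three callers per pseudogene and merges them.
#'
#' @param ids pseudogene ids.
#' @param est_evidence data.frame (pseudogene_id, best_in_genome,
#'   differs_from_parent); several rows per id allowed.
#' @param total_rna data.frame (pseudogene_id, pseudo_cov, parent_cov,
#'   pair_identity).
#' @param depth_by_id list keyed by id: per-tissue depth vectors.
#' @param parent_expr matrix id x tissue of parent expression.
#' @param n_similar named similar-region counts per id.
#' @param thresholds threshold list.
#' @return data.frame (pseudogene_id, transcribed, tags, tissues).
#' @export
transcriptionPipeline <- function(ids, est_evidence, total_rna, depth_by_id,
                                  parent_expr, n_similar,
                                  thresholds = decorThresholds()) {
  rows <- lapply(ids, function(id) {
    est <- callEst(est_evidence[est_evidence$pseudogene_id == id, ,
                                drop = FALSE])
    tr <- total_rna[total_rna$pseudogene_id == id, , drop = FALSE]
    totalRna <- nrow(tr) > 0L && any(callTotalRna(
      tr$pseudo_cov, tr$parent_cov, tr$pair_identity,
      thresholds$parent_similarity_cut))
    bm <- callBodymap(depth_by_id[[id]], parent_expr[id, ],
                      n_similar[[id]],
                      min_depth = thresholds$bodymap_min_depth,
                      min_frac = thresholds$bodymap_min_frac,
                      max_cor = thresholds$discordance_max_cor)
    m <- mergeCalls(est, totalRna, bm$call, tissues = bm$tissues)
    data.frame(pseudogene_id = id, transcribed = m$transcribed,
               tags = paste(m$tags, collapse = ","),
               tissues = paste(m$tissues, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
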