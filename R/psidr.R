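#' Jaccard index of two sets
#'
#' |A intersect B| / |A union B|; defined as 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return value in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cross-context similarity matrix of active pseudogene sets
#'
#' Pairwise Jaccard indices between the active-pseudogene sets of each
#' pair of cell contexts, reported separately per activity type (e.g.
#' promoter-active and Pol2-active sets).
#'
#' @param active_sets named list (context -> character vector of active
#'   pseudogene ids).
#' @return symmetric numeric matrix with NA diagonal.
#' @export
specificityMatrix <- function(active_sets) {
  if (length(active_sets) < 2L) stop("need at least two contexts")
  ctx <- names(active_sets)
  m <- matrix(NA_real_, length(ctx), length(ctx), dimnames = list(ctx, ctx))
  for (i in seq_along(ctx)) for (j in seq_along(ctx)) if (i != j)
    m[i, j] <- jaccard(active_sets[[i]], active_sets[[j]])
  m
}

#' Assemble the decoration table
#'
#' Joins the outputs of the upstream modules into one row per surveyed
#' pseudogene per cell context. Missing component tables yield 0 flags;
#' ids present in a component but absent from the surveyed set are
#' dropped with a warning. Regulation calls for loci excluded by the
#' coding-TSS filter are NA with the exclusion flag set.
#'
#' @param surveyed GRanges surveyed pseudogenes (`id`, `biotype`, `level`,
#'   `parent_id`, `parent_source` metadata columns).
#' @param parents GRanges parent genes (named or with `id`), for parent
#'   locus metadata; may be NULL.
#' @param identity data.frame from [identityPipeline()].
#' @param transcription data.frame from [transcriptionPipeline()].
#' @param conservation named logical from [conservationPipeline()].
#' @param chromatin named list (context -> data.frame from
#'   [callActiveChromatin()]).
#' @param dnase named list (context -> named logical per id).
#' @param regulation named list (context -> data.frame from
#'   [regulationPipeline()]).
#' @param contexts character vector of cell contexts.
#' @return A [DecorationTable-class].
#' @export
decorate <- function(surveyed, parents = NULL, identity = NULL,
                     transcription = NULL, conservation = NULL,
                     chromatin = NULL, dnase = NULL, regulation = NULL,
                     contexts = "cell1") {
  ids <- as.character(mcols(surveyed)$id)
  .checkIds <- function(comp, nm) {
    if (is.null(comp)) return()
    extra <- setdiff(comp, ids)
    if (length(extra))
      warning(length(extra), " id(s) in ", nm,
              " absent from the surveyed set; dropped")
  }
  .checkIds(identity$pseudogene_id, "identity")
  .checkIds(transcription$pseudogene_id, "transcription")
  lookup <- function(df, col, default) {
    if (is.null(df)) return(rep(default, length(ids)))
    v <- df[[col]][match(ids, df$pseudogene_id)]
    v[is.na(df$pseudogene_id[match(ids, df$pseudogene_id)])] <- default
    v
  }
  pidx <- if (!is.null(parents))
    match(as.character(mcols(surveyed)$parent_id), .regionNames(parents))
  rows <- lapply(contexts, function(ctx) {
    chr <- chromatin[[ctx]]
    reg <- regulation[[ctx]]
    dns <- dnase[[ctx]]
    chrAct <- if (is.null(chr)) rep(FALSE, length(ids)) else
      chr$active[match(ids, chr$id)]
    chrCrit <- if (is.null(chr)) rep("none", length(ids)) else
      chr$criterion[match(ids, chr$id)]
    regIdx <- if (is.null(reg)) rep(NA_integer_, length(ids)) else
      match(ids, reg$pseudogene_id)
    excl <- if (is.null(reg)) rep(FALSE, length(ids)) else reg$excluded[regIdx]
    tr <- lookup(transcription, "transcribed", FALSE)
    tags <- lookup(transcription, "tags", "None")
    data.frame(
      pseudogene_id = ids,
      context = ctx,
      biotype = as.character(mcols(surveyed)$biotype),
      level = as.character(mcols(surveyed)$level),
      parent_gene_id = as.character(mcols(surveyed)$parent_id),
      parent_chrom = if (is.null(parents)) NA_character_ else
        as.character(seqnames(parents))[pidx],
      parent_start = if (is.null(parents)) NA_integer_ else
        start(parents)[pidx],
      parent_end = if (is.null(parents)) NA_integer_ else end(parents)[pidx],
      parent_strand = if (is.null(parents)) NA_character_ else
        as.character(strand(parents))[pidx],
      parent_source = as.character(mcols(surveyed)$parent_source),
      cds_identity = lookup(identity, "cds_identity", NA_real_),
      utr3_identity = lookup(identity, "utr3_identity", NA_real_),
      identity_class = lookup(identity, "identity_class", NA_character_),
      transcribed = as.integer(tr),
      transcription_tags = tags,
      transcribed_tissues = lookup(transcription, "tissues", ""),
      dnase_accessible = if (is.null(dns)) 0L else as.integer(dns[ids]),
      active_chromatin = as.integer(chrAct),
      chromatin_criterion = chrCrit,
      active_pol2 = if (is.null(reg)) 0L else
        ifelse(excl, NA_integer_, as.integer(reg$pol2_active[regIdx])),
      pol2_criterion = if (is.null(reg)) "none" else
        ifelse(excl, NA_character_, reg$pol2_criterion[regIdx]),
      active_promoter = if (is.null(reg)) 0L else
        ifelse(excl, NA_integer_, as.integer(reg$promoter_active[regIdx])),
      tfbs_count = if (is.null(reg)) NA_integer_ else reg$tfbs_count[regIdx],
      conserved = if (is.null(conservation)) 0L else
        as.integer(!is.na(conservation[ids]) & conservation[ids]),
      excluded_near_coding_tss = as.integer(excl),
      stringsAsFactors = FALSE)
  })
  DecorationTable(do.call(rbind, rows))
}

#' Partial-activity class of a decoration row
#'
#' Classifies each (pseudogene, context) row by an ordered rule set
#' formalizing the narrative classes of the survey:
#' (i) dying — not transcribed, active chromatin, upstream activity
#' (Pol2 or promoter) and conserved (a gene recently silenced but still
#' regulatorily poised and under constraint);
#' (ii) resurrected — transcribed with active chromatin but without
#' retention of the parent's upstream elements (novel regulatory
#' context, candidate new ncRNA);
#' (iii) fully_active — transcribed, active chromatin and upstream
#' activity; (iv) dead — every activity flag 0; (v) partially_active —
#' anything else. NA flags (excluded loci) count as 0.
#'
#' @param table a [DecorationTable-class] or its data.frame.
#' @param parent_upstream_retained named logical per pseudogene id:
#'   whether the pseudogene retains parental upstream elements (see
#'   [parentUpstreamRetained()]).
#' @return data.frame (pseudogene_id, context, class).
#' @export
classifyPartialActivity <- function(table, parent_upstream_retained) {
  tb <- if (is(table, "DecorationTable")) decorationTable(table) else table
  need <- c("transcribed", "active_chromatin", "active_pol2",
            "active_promoter", "conserved", "dnase_accessible")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("incomplete record; missing field(s): ", paste(miss, collapse = ", "))
  z <- function(v) ifelse(is.na(v), 0L, v)
  tr <- z(tb$transcribed); ch <- z(tb$active_chromatin)
  up <- z(tb$active_pol2) | z(tb$active_promoter)
  cons <- z(tb$conserved); dns <- z(tb$dnase_accessible)
  ret <- parent_upstream_retained[tb$pseudogene_id]
  ret <- !is.na(ret) & ret
  cls <- ifelse(tr == 0L & ch == 1L & up & cons == 1L, "dying",
    ifelse(tr == 1L & ch == 1L & !ret, "resurrected",
      ifelse(tr == 1L & ch == 1L & up, "fully_active",
        ifelse(tr + ch + up + cons + dns == 0L, "dead",
               "partially_active"))))
  data.frame(pseudogene_id = tb$pseudogene_id, context = tb$context,
             class = cls, stringsAsFactors = FALSE)
}

#' Parental upstream-element retention proxy
#'
#' A duplicated pseudogene "retains" its parent's upstream regulatory
#' region when at least one TF whose peak is assigned to the
#' pseudogene's upstream window also has a peak assigned to the parent's
#' upstream window. Processed pseudogenes (retrotransposed without
#' flanking sequence) never retain parental upstream elements under this
#' proxy.
#'
#' @param loci GRanges pseudogenes (`id`, `biotype`, `parent_id`).
#' @param parents GRanges parent genes (named by id).
#' @param tf_peaks GRanges TF peaks with `factor`.
#' @param upstream_bp window length.
#' @return named logical per pseudogene id.
#' @export
parentUpstreamRetained <- function(loci, parents, tf_peaks,
                                   upstream_bp = 2000L) {
  pwins <- upstreamWindow(parents, upstream_bp)
  gwins <- upstreamWindow(loci, upstream_bp)
  pnames <- .regionNames(parents)
  out <- vapply(seq_along(loci), function(i) {
    if (as.character(mcols(loci)$biotype)[i] != "duplicated") return(FALSE)
    pid <- as.character(mcols(loci)$parent_id)[i]
    j <- match(pid, pnames)
    if (is.na(j)) return(FALSE)
    fg <- countTfbs(tf_peaks, gwins[i])$factors
    fp <- countTfbs(tf_peaks, pwins[j])$factors
    length(intersect(fg, fp)) > 0L
  }, logical(1))
  setNames(out, as.character(mcols(loci)$id))
}
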