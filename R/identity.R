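#' Assign a parent gene by source priority
#'
#' When several evidence sources propose a parent for a pseudogene, the
#' highest-priority source wins, in the order manual annotation >
#' sequence-alignment match > automated pipeline. With no candidate the
#' parent is "none".
#'
#' @param candidates named list/vector mapping source (`manual`,
#'   `alignment`, `automated`) to a parent gene id.
#' @return list(parent_id, parent_source).
#' @export
assignParent <- function(candidates) {
  candidates <- candidates[!vapply(candidates, is.null, logical(1))]
  bad <- setdiff(names(candidates), c("manual", "alignment", "automated"))
  if (length(bad)) stop("unknown parent source(s): ", paste(bad, collapse = ","))
  for (src in c("manual", "alignment", "automated"))
    if (src %in% names(candidates))
      return(list(parent_id = as.character(candidates[[src]]),
                  parent_source = src))
  list(parent_id = "none", parent_source = "none")
}

.alignScoreParams <- list(match = 1, mismatch = -1,
                          gapOpening = 5, gapExtension = 1)

.alignStrings <- function(a, b, type) {
  sm <- nucleotideSubstitutionMatrix(match = .alignScoreParams$match,
                                     mismatch = .alignScoreParams$mismatch,
                                     baseOnly = TRUE)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = type,
                           substitutionMatrix = sm,
                           gapOpening = .alignScoreParams$gapOpening,
                           gapExtension = .alignScoreParams$gapExtension)
  list(pattern = as.character(pattern(aln)),
       subject = as.character(subject(aln)),
       score = BiocGenerics::score(aln))
}

#' Align a pseudogene to its parent over CDS and 3' UTR
#'
#' Global affine-gap alignment (match +1, mismatch -1, gap open 5, gap
#' extend 1) of the pseudogene CDS against the parent CDS, and of the
#' pseudogene 3' UTR against the parent 3' region. The parent 3' region is
#' expected to carry a downstream extension (2 kb by convention) for
#' fuller UTR coverage, so the UTR alignment anchors the pseudogene UTR
#' globally while letting it land anywhere within the extended parent
#' region (pattern-global / subject-local).
#'
#' @param pseudo_cds,parent_cds CDS sequences (character or DNAString).
#' @param pseudo_utr3,parent_utr3 3' UTR sequences; `parent_utr3` may
#'   include the downstream extension. Either pair may be NULL to skip.
#' @return list of per-region alignments, each with `pattern`, `subject`
#'   (aligned strings with "-") and `score`.
#' @export
alignPair <- function(pseudo_cds, parent_cds,
                      pseudo_utr3 = NULL, parent_utr3 = NULL) {
  out <- list()
  if (!is.null(pseudo_cds)) {
    if (!nchar(pseudo_cds) || !nchar(parent_cds))
      stop("empty CDS sequence")
    out$CDS <- .alignStrings(pseudo_cds, parent_cds, "global")
  }
  if (!is.null(pseudo_utr3)) {
    if (!nchar(pseudo_utr3) || !nchar(parent_utr3))
      stop("empty UTR3 sequence")
    out$UTR3 <- .alignStrings(pseudo_utr3, parent_utr3, "global-local")
  }
  out
}

.matchVector <- function(aln) {
  p <- strsplit(aln$pattern, "")[[1L]]
  s <- strsplit(aln$subject, "")[[1L]]
  p == s & p != "-"
}

#' Percent identity over an aligned region
#'
#' 100 * matching columns / total aligned columns. Gap columns count in
#' the denominator, so indel-riddled alignments are penalized.
#'
#' @param aln one region alignment from [alignPair()].
#' @return percent identity, or NA (flagged with a warning) when there are
#'   no aligned columns.
#' @export
alignmentIdentity <- function(aln) {
  m <- .matchVector(aln)
  if (!length(m)) {
    warning("zero aligned columns; identity undefined")
    return(NA_real_)
  }
  100 * sum(m) / length(m)
}

#' Best sliding-window identity over the 3' UTR alignment
#'
#' Slides a fixed-size window (default 100 columns, step 1) across the
#' aligned 3' UTR and returns the highest per-window identity; the short
#' parent-regulatory stretches that matter there (e.g. small-RNA target
#' sites) are better captured by the best local window than by the
#' regional mean. Regions shorter than the window are scored whole.
#'
#' @param aln UTR3 alignment from [alignPair()].
#' @param window window size in alignment columns.
#' @return maximum per-window percent identity.
#' @export
utr3WindowIdentity <- function(aln, window = 100L) {
  m <- as.numeric(.matchVector(aln))
  n <- length(m)
  if (!n) { warning("zero aligned columns"); return(NA_real_) }
  if (n <= window) return(100 * mean(m))
  cs <- c(0, cumsum(m))
  sums <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
  100 * max(sums) / window
}

#' Nine-way sequence-identity class
#'
#' Bins the CDS and 3' UTR identities each into low (< `identity_low`),
#' mid (closed interval) and high (> `identity_high`) and returns the
#' combined 3 x 3 class, e.g. "high-low" for a pseudogene preserving its
#' parent's CDS (> 80%) but not its 3' UTR (< 60%).
#'
#' @param cds_id,utr_id percent identities in [0, 100] (vectorized).
#' @param thresholds threshold list, see [decorThresholds()].
#' @return character vector "cdsbin-utrbin"; NA identities give NA.
#' @export
classifyIdentityGroup <- function(cds_id, utr_id,
                                  thresholds = decorThresholds()) {
  stopifnot(all(cds_id >= 0 & cds_id <= 100, na.rm = TRUE),
            all(utr_id >= 0 & utr_id <= 100, na.rm = TRUE))
  bin <- function(x) {
    ifelse(is.na(x), NA_character_,
      ifelse(x < thresholds$identity_low, "low",
        ifelse(x > thresholds$identity_high, "high", "mid")))
  }
  out <- paste(bin(cds_id), bin(utr_id), sep = "-")
  out[is.na(cds_id) | is.na(utr_id)] <- NA_character_
  out
}

#' Identity pipeline over a set of sequence pairs
#'
#' Aligns every pseudogene to its parent and tabulates CDS identity,
#' best-window 3' UTR identity, and the nine-way class.
#'
#' @param pairs list keyed by pseudogene id; each element a list with
#'   `parent_id`, `pseudo_cds`, `parent_cds`, `pseudo_utr3`, `parent_utr3`.
#' @param thresholds threshold list.
#' @return data.frame (pseudogene_id, parent_id, cds_identity,
#'   utr3_identity, identity_class).
#' @export
identityPipeline <- function(pairs, thresholds = decorThresholds()) {
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    aln <- alignPair(p$pseudo_cds, p$parent_cds, p$pseudo_utr3, p$parent_utr3)
    cds <- alignmentIdentity(aln$CDS)
    utr <- if (!is.null(aln$UTR3))
      utr3WindowIdentity(aln$UTR3, thresholds$utr_window_bp) else NA_real_
    data.frame(pseudogene_id = id, parent_id = p$parent_id,
               cds_identity = cds, utr3_identity = utr,
               identity_class = classifyIdentityGroup(cds, utr, thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
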