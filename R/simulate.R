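#' Simulation configuration
#'
#' Parameters of the synthetic corpus: a miniature two-chromosome genome
#' with coding genes and pseudogenes, three caller call-sets, sequences,
#' per-tissue RNA coverage, chromatin segmentation, ChIP-seq peaks,
#' promoter calls, DNase tracks, divergence records and variants — with
#' planted, known activity labels for every pipeline stage. Defaults are
#' a toy scale (2 x 2 Mb, 60 coding genes, 200 pseudogenes, 4 tissues,
#' 2 cell contexts) that runs the full pipeline in seconds; planted
#' effect sizes are chosen to clear or miss the published calling rules
#' by construction (see the methods vignette).
#'
#' @param seed master seed; each generator stage derives its own stream.
#' @param ... overrides of any config field.
#' @return named list of simulation parameters.
#' @export
simulationConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chrom_length_bp = 2e6,
    n_coding_genes = 60L,
    n_pseudogenes = 200L,
    processed_fraction = 0.70,
    duplicated_fraction = 0.25,
    polymorphic_count = 6L,
    level1_fraction = 0.80,
    n_delta2way = 10L,
    n_pipeA_only = 5L,
    n_pipeB_only = 5L,
    pg_length_range = c(800L, 2500L),
    coding_length_bp = 3000L,
    min_gap_bp = 11000L,
    cds_len = 600L,
    utr3_len = 400L,
    utr_extension_bp = 2000L,
    cds_identity_mean = 80, cds_identity_sd = 13,
    utr_identity_mean = 65, utr_identity_sd = 25,
    indel_rate = 0,
    transcribed_fraction = 0.25,
    evidence_mix = c(EST = 0.35, TotalRNA = 0.25, BodyMap = 0.40),
    n_concordant_decoys = 5L,
    transcribed_depth = 3,
    transcribed_cover_frac = c(0.6, 0.8),
    coverage_noise_depth = 0,
    tissues = c("brain", "liver", "testis", "heart"),
    contexts = c("K562", "GM12878"),
    active_chromatin_fraction = 0.15,
    criterion1_share = 0.4,
    pol2_active_fraction = 0.15,
    pol2_cofactor_share = 0.4,
    promoter_active_fraction = 0.15,
    context_shared_frac = 0.35,
    n_near_coding = 3L,
    dnase_extra_fraction = 0.10,
    dnase_bump_amp = 1.5,
    n_background_pol2 = 150L,
    pol2_signal_per_bp = 1 / 200,
    pol2_signal_noise_sd = 0.05,
    tf_factor_pool = paste0("TF", sprintf("%02d", 1:20)),
    tfbs_rate_transcribed = 3,
    tfbs_rate_other = 0.3,
    n_dying = 5L,
    n_resurrected = 5L,
    n_fully_active = 5L,
    conserved_fraction = 0.10,
    conserved_multiplier = 0.1,
    background_rates = c(chimp = 0.015, mouse = 0.05),
    align_frac = c(chimp = 0.95, mouse = 0.60),
    variant_rate_per_bp = 1 / 150,
    vclass_probs = c(SNP = 0.85, indel = 0.12, SV = 0.03),
    daf_shape = c(0.3, 1.2),
    upstream_bp = 2000L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ","))
  cfg[names(ov)] <- ov
  stopifnot(cfg$processed_fraction + cfg$duplicated_fraction <= 1,
            all(unlist(cfg[grep("fraction|share", names(cfg))]) >= 0))
  cfg
}

.stageSeed <- function(cfg, stage) {
  offs <- c(annotation = 11L, sequences = 23L, coverage = 37L,
            fungen = 51L, divergence = 67L, subsets = 83L)
  (cfg$seed * 101L + offs[[stage]]) %% .Machine$integer.max
}

.simSeqinfo <- function(cfg) {
  Seqinfo(paste0("chr", seq_len(cfg$n_chromosomes)),
          rep(cfg$chrom_length_bp, cfg$n_chromosomes))
}

#' Simulate the annotation and the three caller call-sets
#'
#' Places non-overlapping coding genes and pseudogenes uniformly with a
#' minimum gap, assigns each pseudogene a biotype and a parent gene, and
#' constructs three call-sets: the manual set (every pseudogene), and two
#' automated pipelines recovering a configured fraction of manual loci
#' (jittered so overlap stays well above the consensus threshold), plus
#' pipeline-only two-way consensus loci, single-pipeline calls, and
#' sub-threshold decoy overlaps.
#'
#' @param config from [simulationConfig()].
#' @return list(coding, manual, pipeA, pipeB, truth_levels).
#' @export
simulateAnnotation <- function(config) {
  set.seed(.stageSeed(config, "annotation"))
  si <- .simSeqinfo(config)
  nExtra <- config$n_delta2way + config$n_pipeA_only + config$n_pipeB_only
  nLoci <- config$n_coding_genes + config$n_pseudogenes + nExtra
  lens <- c(rep(config$coding_length_bp, config$n_coding_genes),
            sample(config$pg_length_range[1]:config$pg_length_range[2],
                   config$n_pseudogenes + nExtra, replace = TRUE))
  perChrom <- split(seq_len(nLoci),
                    rep_len(seq_len(config$n_chromosomes), nLoci))
  starts <- integer(nLoci)
  for (ci in seq_along(perChrom)) {
    idx <- perChrom[[ci]]
    need <- sum(lens[idx]) + (length(idx) + 1L) * config$min_gap_bp
    slack <- config$chrom_length_bp - need
    if (slack < 0)
      stop("loci cannot be placed at this density; increase chrom_length_bp")
    extra <- diff(c(0, sort(runif(length(idx), 0, slack))))
    pos <- config$min_gap_bp +
      cumsum(extra + c(0, lens[idx][-length(idx)] + config$min_gap_bp))
    starts[idx] <- as.integer(round(pos))
  }
  chrom <- paste0("chr", rep_len(seq_len(config$n_chromosomes), nLoci))
  ord <- seq_len(nLoci)
  gr <- GRanges(chrom, IRanges(starts, width = lens[ord]),
                strand = sample(c("+", "-"), nLoci, replace = TRUE),
                seqinfo = si)
  coding <- gr[seq_len(config$n_coding_genes)]
  mcols(coding)$id <- sprintf("G%03d", seq_along(coding))
  mcols(coding)$biotype <- "coding"
  names(coding) <- mcols(coding)$id
  pgIdx <- config$n_coding_genes + seq_len(config$n_pseudogenes)
  manual <- gr[pgIdx]
  n <- length(manual)
  ## relocate the last few pseudogenes to within 4 kb of a coding TSS so
  ## the proximity-exclusion filter is exercised
  nearIds <- character()
  kNear <- min(config$n_near_coding, config$n_coding_genes, n)
  if (kNear > 0) {
    chrv <- as.character(seqnames(manual)); st <- start(manual)
    en <- end(manual); strv <- as.character(strand(manual))
    for (m in seq_len(kNear)) {
      i <- n - kNear + m
      cg <- coding[m]
      tss <- if (as.character(strand(cg)) == "-") end(cg) else start(cg)
      chrv[i] <- as.character(seqnames(cg))
      st[i] <- tss + 1500L; en[i] <- tss + 2299L; strv[i] <- "+"
    }
    manual <- GRanges(chrv, IRanges(st, en), strand = strv, seqinfo = si)
    nearIds <- sprintf("PG%04d", (n - kNear + 1L):n)
  }
  biotype <- sample(c("processed", "duplicated", "unitary"), n, replace = TRUE,
                    prob = c(config$processed_fraction,
                             config$duplicated_fraction,
                             max(0, 1 - config$processed_fraction -
                                   config$duplicated_fraction)))
  if (config$polymorphic_count > 0)
    biotype[sample(n, config$polymorphic_count)] <- "polymorphic"
  mcols(manual)$id <- sprintf("PG%04d", seq_len(n))
  mcols(manual)$biotype <- biotype
  mcols(manual)$parent_id <- sample(mcols(coding)$id, n, replace = TRUE)
  mcols(manual)$parent_source <- sample(c("manual", "alignment", "automated"),
                                        n, replace = TRUE,
                                        prob = c(0.6, 0.25, 0.15))
  names(manual) <- mcols(manual)$id

  level1 <- runif(n) < config$level1_fraction
  jitterCall <- function(x) {
    if (!length(x)) return(GRanges(seqinfo = si))
    off <- sample(-30:30, length(x), replace = TRUE)
    GRanges(seqnames(x), IRanges(start(x) + off, end(x) + off),
            strand = "*", seqinfo = si)
  }
  extraIdx <- config$n_coding_genes + config$n_pseudogenes + seq_len(nExtra)
  extras <- gr[extraIdx]
  strand(extras) <- "*"
  d2 <- extras[seq_len(config$n_delta2way)]
  aOnly <- extras[config$n_delta2way + seq_len(config$n_pipeA_only)]
  bOnly <- extras[config$n_delta2way + config$n_pipeA_only +
                    seq_len(config$n_pipeB_only)]
  # sub-threshold decoy: a pipeA call overlapping a level-2 locus by < 50 bp
  decoy <- GRanges()
  lvl2 <- which(!level1)
  if (length(lvl2)) {
    t <- manual[lvl2[1L]]
    decoy <- GRanges(seqnames(t), IRanges(end(t) - 19L, end(t) + 400L),
                     seqinfo = si)
  }
  pipeA <- c(jitterCall(manual[level1]), granges(d2), granges(aOnly), decoy)
  pipeB <- c(jitterCall(manual[level1]), jitterCall(d2), granges(bOnly))
  list(coding = coding, manual = manual, pipeA = pipeA, pipeB = pipeB,
       near_ids = nearIds,
       truth_levels = data.frame(id = mcols(manual)$id,
                                 level = ifelse(level1, "1", "2"),
                                 stringsAsFactors = FALSE))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateSeq <- function(s, target_identity) {
  v <- strsplit(s, "")[[1L]]
  nmut <- round((100 - target_identity) / 100 * length(v))
  if (nmut > 0) {
    pos <- sample(length(v), nmut)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(v, collapse = "")
}

#' Simulate parent/pseudogene sequence pairs
#'
#' Draws a random parent CDS + 3' UTR (with downstream extension) per
#' parent gene and derives each pseudogene's sequence by point mutations
#' at rates hitting a per-pseudogene target identity (realized identity
#' within +/- 2 points). With `indel_rate` 0 (default) the alignment is
#' substitution-only.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config simulation config.
#' @return list(pairs, targets): `pairs` is the input of
#'   [identityPipeline()]; `targets` records planted identities.
#' @export
simulateSequences <- function(annotation, config) {
  set.seed(.stageSeed(config, "sequences"))
  parents <- unique(as.character(mcols(annotation$manual)$parent_id))
  pseq <- lapply(setNames(parents, parents), function(p) list(
    cds = .randomDna(config$cds_len),
    utr3 = .randomDna(config$utr3_len),
    ext = .randomDna(config$utr_extension_bp)))
  ids <- as.character(mcols(annotation$manual)$id)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  cdsT <- clamp(rnorm(length(ids), config$cds_identity_mean,
                      config$cds_identity_sd), 35, 100)
  utrT <- clamp(rnorm(length(ids), config$utr_identity_mean,
                      config$utr_identity_sd), 20, 100)
  if (any(cdsT > 100 | cdsT < 0 | utrT > 100 | utrT < 0))
    stop("target identity outside [0, 100]")
  pairs <- lapply(seq_along(ids), function(i) {
    pid <- as.character(mcols(annotation$manual)$parent_id)[i]
    ps <- pseq[[pid]]
    list(parent_id = pid,
         pseudo_cds = .mutateSeq(ps$cds, cdsT[i]),
         parent_cds = ps$cds,
         pseudo_utr3 = .mutateSeq(ps$utr3, utrT[i]),
         parent_utr3 = paste0(ps$utr3, ps$ext))
  })
  names(pairs) <- ids
  list(pairs = pairs,
       targets = data.frame(pseudogene_id = ids, cds_target = cdsT,
                            utr_target = utrT, stringsAsFactors = FALSE))
}

#' Plant the activity subsets
#'
#' Draws the planted transcribed / conserved / active-chromatin / Pol2 /
#' promoter / DNase subsets from the surveyed (non-polymorphic)
#' pseudogenes, forces a small "dying" set (non-transcribed duplicated
#' loci with chromatin + Pol2 activity, conservation and retained
#' parental upstream elements) and a "resurrected" set (transcribed
#' processed loci with chromatin activity and no parental retention),
#' and returns the truth table all downstream recovery is scored against.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config simulation config.
#' @return data.frame truth table keyed by pseudogene id.
#' @export
simulateTruth <- function(annotation, config) {
  set.seed(.stageSeed(config, "subsets"))
  man <- annotation$manual
  ids <- as.character(mcols(man)$id)
  bt <- as.character(mcols(man)$biotype)
  surveyed <- bt != "polymorphic"
  svIds <- ids[surveyed]
  nearIds <- annotation$near_ids
  pick <- function(pool, frac) sample(pool, round(frac * length(pool)))
  transcribed <- pick(svIds, config$transcribed_fraction)
  ev <- sample(names(config$evidence_mix), length(transcribed),
               replace = TRUE, prob = config$evidence_mix)
  conserved <- pick(svIds, config$conserved_fraction)
  activeChrom <- pick(svIds, config$active_chromatin_fraction)
  ## per-context Pol2/promoter sets: a shared core plus disjoint
  ## context-specific draws (loci near coding TSSs are never planted here;
  ## their upstream calls are masked by the exclusion filter)
  poolReg <- setdiff(svIds, nearIds)
  ctxSets <- function(frac) {
    nAct <- round(frac * length(svIds))
    nShared <- round(config$context_shared_frac * nAct)
    shared <- sample(poolReg, nShared)
    remaining <- setdiff(poolReg, shared)
    out <- list()
    for (ctx in config$contexts) {
      own <- sample(remaining, nAct - nShared)
      remaining <- setdiff(remaining, own)
      out[[ctx]] <- union(shared, own)
    }
    out
  }
  pol2Ctx <- ctxSets(config$pol2_active_fraction)
  promCtx <- ctxSets(config$promoter_active_fraction)
  dup <- setdiff(svIds[bt[surveyed] == "duplicated" &
                         !(svIds %in% transcribed)], nearIds)
  dying <- head(dup, config$n_dying)
  conserved <- union(conserved, dying)
  activeChrom <- union(activeChrom, dying)
  pol2Ctx <- lapply(pol2Ctx, union, dying)
  proc <- intersect(svIds[bt[surveyed] == "processed"], transcribed)
  resurrected <- head(proc, config$n_resurrected)
  activeChrom <- union(activeChrom, resurrected)
  fully <- head(setdiff(intersect(svIds[bt[surveyed] == "duplicated"],
                                  transcribed), nearIds),
                config$n_fully_active)
  activeChrom <- union(activeChrom, fully)
  pol2Ctx <- lapply(pol2Ctx, union, fully)
  dnase <- union(transcribed, pick(svIds, config$dnase_extra_fraction))
  pol2 <- Reduce(union, pol2Ctx)
  promoter <- Reduce(union, promCtx)
  critShare <- runif(length(activeChrom)) < config$criterion1_share
  pol2Cof <- runif(length(pol2)) < config$pol2_cofactor_share
  retained <- union(dying, fully)
  concordant <- sample(setdiff(svIds, transcribed),
                       config$n_concordant_decoys)
  out <- data.frame(
    pseudogene_id = ids,
    surveyed = surveyed,
    biotype = bt,
    near_coding_tss = ids %in% nearIds,
    transcribed = ids %in% transcribed,
    evidence = ifelse(ids %in% transcribed,
                      ev[match(ids, transcribed)], "None"),
    bodymap_tissue = ifelse(ids %in% transcribed,
                            sample(config$tissues, length(ids),
                                   replace = TRUE), NA_character_),
    concordant_decoy = ids %in% concordant,
    conserved = ids %in% conserved,
    active_chromatin = ids %in% activeChrom,
    chromatin_criterion = ifelse(ids %in% activeChrom,
      ifelse(critShare[match(ids, activeChrom)], "1", "2"), "none"),
    pol2_active = ids %in% pol2,
    pol2_criterion = ifelse(ids %in% pol2,
      ifelse(pol2Cof[match(ids, pol2)], "3", "1+2"), "none"),
    promoter_active = ids %in% promoter,
    dnase_accessible = ids %in% dnase,
    parent_upstream_retained = ids %in% retained,
    dying = ids %in% dying,
    resurrected = ids %in% resurrected,
    fully_active = ids %in% fully,
    stringsAsFactors = FALSE)
  for (ctx in config$contexts) {
    out[[paste0("pol2_active_", ctx)]] <- ids %in% pol2Ctx[[ctx]]
    out[[paste0("promoter_active_", ctx)]] <- ids %in% promCtx[[ctx]]
  }
  out
}

#' Simulate per-tissue RNA-seq coverage tracks
#'
#' Planted transcribed pseudogenes get depth `transcribed_depth` over a
#' contiguous 60-80% of their length in a designated tissue (clearing
#' the depth >= 2 over >= half-the-length rule by construction);
#' everything else gets sub-threshold noise (default none). Parent
#' expression profiles are drawn independently per tissue, except for
#' concordant decoys, whose parents are given expression proportional to
#' the decoy's own realized profile (rank correlation 1) so the
#' discordance rule is exercised.
#'
#' @param annotation,truth,config simulation pieces.
#' @return list(tracks = list(tissue -> RleList), parent_expr = matrix
#'   pseudogene id x tissue, total_rna, est_evidence, n_similar).
#' @export
simulateCoverage <- function(annotation, truth, config) {
  set.seed(.stageSeed(config, "coverage"))
  si <- .simSeqinfo(config)
  man <- annotation$manual
  ids <- as.character(mcols(man)$id)
  tissues <- config$tissues
  cover <- vector("list", length(tissues)); names(cover) <- tissues
  segs <- lapply(tissues, function(t) GRanges(seqinfo = si))
  names(segs) <- tissues
  depthAt <- list()
  for (i in seq_along(man)) {
    id <- ids[i]
    tri <- truth$transcribed[truth$pseudogene_id == id]
    bmTissue <- truth$bodymap_tissue[truth$pseudogene_id == id]
    decoy <- truth$concordant_decoy[truth$pseudogene_id == id]
    ev <- truth$evidence[truth$pseudogene_id == id]
    plantCov <- (tri && ev == "BodyMap") || decoy
    if (plantCov) {
      frac <- runif(1, config$transcribed_cover_frac[1],
                    config$transcribed_cover_frac[2])
      w <- round(frac * width(man)[i])
      off <- sample(0:(width(man)[i] - w), 1L)
      t <- if (decoy) sample(tissues, 1L) else bmTissue
      segs[[t]] <- c(segs[[t]],
                     GRanges(seqnames(man)[i],
                             IRanges(start(man)[i] + off, width = w),
                             seqinfo = si))
    } else if (config$coverage_noise_depth > 0 && runif(1) < 0.3) {
      w <- round(0.3 * width(man)[i])
      segs[[tissues[1L]]] <- c(segs[[tissues[1L]]],
        GRanges(seqnames(man)[i], IRanges(start(man)[i], width = w),
                seqinfo = si))
    }
  }
  for (t in tissues)
    cover[[t]] <- coverage(segs[[t]], width = seqlengths(si)) *
      config$transcribed_depth

  # parent per-tissue expression (for the BodyMap discordance rule)
  parentExpr <- matrix(runif(length(ids) * length(tissues), 1, 10),
                       nrow = length(ids),
                       dimnames = list(ids, tissues))
  for (id in truth$pseudogene_id[truth$concordant_decoy]) {
    i <- match(id, ids)
    prof <- vapply(tissues, function(t) {
      v <- cover[[t]][[as.character(seqnames(man)[i])]]
      mean(as.numeric(v[start(man)[i]:end(man)[i]]))
    }, numeric(1))
    parentExpr[i, ] <- prof + 0.01   # same ranking => concordant
  }
  nSimilar <- setNames(rpois(length(ids), 1.2), ids)
  bm <- truth$evidence == "BodyMap" & truth$transcribed
  nSimilar[truth$pseudogene_id[bm]] <- 0L
  nSimilar[truth$pseudogene_id[truth$concordant_decoy]] <- 2L

  totalRna <- do.call(rbind, lapply(seq_along(ids), function(i) {
    id <- ids[i]
    tr <- truth$transcribed[i] && truth$evidence[i] == "TotalRNA"
    if (tr) {
      if (runif(1) < 0.5)
        data.frame(pseudogene_id = id, pseudo_cov = sample(5:50, 1L),
                   parent_cov = 0, pair_identity = runif(1, 85, 99))
      else
        data.frame(pseudogene_id = id, pseudo_cov = sample(5:50, 1L),
                   parent_cov = sample(5:50, 1L),
                   pair_identity = runif(1, 60, 89.5))
    } else if (runif(1) < 0.3) {
      data.frame(pseudogene_id = id, pseudo_cov = sample(5:50, 1L),
                 parent_cov = sample(5:50, 1L),
                 pair_identity = runif(1, 91, 99))
    } else {
      data.frame(pseudogene_id = id, pseudo_cov = 0,
                 parent_cov = sample(0:50, 1L),
                 pair_identity = runif(1, 60, 99))
    }
  }))
  est <- do.call(rbind, lapply(seq_along(ids), function(i) {
    id <- ids[i]
    tr <- truth$transcribed[i] && truth$evidence[i] == "EST"
    if (tr)
      data.frame(pseudogene_id = id, best_in_genome = TRUE,
                 differs_from_parent = TRUE)
    else if (runif(1) < 0.2)
      data.frame(pseudogene_id = id, best_in_genome = TRUE,
                 differs_from_parent = FALSE)
    else NULL
  }))
  list(tracks = cover, parent_expr = parentExpr, total_rna = totalRna,
       est_evidence = est, n_similar = nSimilar)
}

#' Simulate segmentation, peaks, promoters and DNase tracks
#'
#' Per cell context: planted active-chromatin loci have their locus +
#' upstream region covered by TSS labels (criterion 1) or by equal
#' GS/GM/GE thirds (criterion 2) while all other loci sit in repressive
#' segments; planted Pol2-active loci get either one wide, strong Pol2
#' peak or a cofactor peak with its majority inside the upstream window;
#' planted promoter loci get an overlapping promoter region. Background
#' Pol2 peaks are drawn with signal a monotone (slightly noisy) function
#' of width, mirroring the empirical coupling of ChIP peak width and
#' strength. TF peaks are placed in upstream windows at a higher rate
#' for transcribed loci; "retained" duplicated loci share a factor with
#' their parent's upstream window. DNase tracks carry bumps at coding
#' TSSs (strongest), transcribed pseudogenes (intermediate) and planted
#' accessible loci over a flat background.
#'
#' @param annotation,truth,config simulation pieces.
#' @return per-context lists: segmentation, pol2_peaks, cofactor_peaks,
#'   tf_peaks, promoters, dnase.
#' @export
simulateFunctionalGenomics <- function(annotation, truth, config) {
  set.seed(.stageSeed(config, "fungen"))
  si <- .simSeqinfo(config)
  man <- annotation$manual
  ids <- as.character(mcols(man)$id)
  labels <- segmentationLabels()
  regions <- punion(granges(man),
                    granges(upstreamWindow(man, config$upstream_bp)),
                    fill.gap = TRUE)
  ## interval accumulator: collect (chrom, start, end, mcols...) rows in a
  ## list, build the GRanges once
  acc <- function() new.env(parent = emptyenv())
  put <- function(e, chrom, start, end, ...) {
    e$rows <- c(e$rows, list(data.frame(chrom = chrom, start = start,
                                        end = end, ...,
                                        stringsAsFactors = FALSE)))
  }
  build <- function(e, mcolNames = character()) {
    if (is.null(e$rows)) return(GRanges(seqinfo = si))
    df <- do.call(rbind, e$rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), seqinfo = si)
    for (nm in mcolNames) mcols(gr)[[nm]] <- df[[nm]]
    gr
  }
  out <- list()
  for (ctx in config$contexts) {
    ## segmentation: planted label runs inside locus regions, repressive fill
    segs <- acc()
    for (i in seq_along(man)) {
      r <- regions[i]
      tt <- truth[i, ]
      if (tt$active_chromatin && tt$chromatin_criterion == "1") {
        put(segs, as.character(seqnames(r)), start(r), end(r), label = "TSS")
      } else if (tt$active_chromatin && tt$chromatin_criterion == "2") {
        b <- floor(width(r) / 3)
        s <- start(r)
        put(segs, as.character(seqnames(r)),
            c(s, s + b, s + 2L * b),
            c(s + b - 1L, s + 2L * b - 1L, end(r)),
            label = c("GS", "GM", "GE"))
      } else {
        put(segs, as.character(seqnames(r)), start(r), end(r),
            label = sample(labels$repressive, 1L))
      }
    }
    ## fill intergenic space with repressive-dominated background chunks
    gaps <- GenomicRanges::gaps(reduce(regions, ignore.strand = TRUE))
    gaps <- gaps[strand(gaps) == "*"]
    chunkLab <- function(n) sample(c(labels$repressive, labels$active), n,
                                   replace = TRUE,
                                   prob = c(rep(0.06, 13), rep(0.018, 12)))
    for (g in seq_along(gaps)) {
      brk <- seq(start(gaps)[g], end(gaps)[g] + 1L, by = 5000L)
      if (tail(brk, 1L) != end(gaps)[g] + 1L) brk <- c(brk, end(gaps)[g] + 1L)
      put(segs, as.character(seqnames(gaps)[g]), brk[-length(brk)],
          brk[-1L] - 1L, label = chunkLab(length(brk) - 1L))
    }
    seg <- Segmentation(build(segs, "label"), labels)

    ## peaks
    wins <- upstreamWindow(man, config$upstream_bp)
    sigOf <- function(w) w * config$pol2_signal_per_bp *
      exp(rnorm(length(w), 0, config$pol2_signal_noise_sd))
    pol2 <- acc(); cof <- acc(); tf <- acc()
    p2col <- paste0("pol2_active_", ctx)
    p2act <- if (p2col %in% names(truth)) truth[[p2col]] else
      truth$pol2_active
    prcol <- paste0("promoter_active_", ctx)
    pract <- if (prcol %in% names(truth)) truth[[prcol]] else
      truth$promoter_active
    for (i in seq_along(man)) {
      tt <- truth[i, ]
      w <- wins[i]
      wchr <- as.character(seqnames(w))
      mid <- (start(w) + end(w)) %/% 2L
      if (p2act[i] && tt$pol2_criterion == "1+2") {
        pw <- sample(600:900, 1L)
        put(pol2, wchr, mid - pw %/% 2L, mid - pw %/% 2L + pw - 1L,
            signal = max(2.5, sigOf(pw)))
      } else if (p2act[i] && tt$pol2_criterion == "3") {
        cw <- sample(150:300, 1L)
        put(cof, wchr, mid - cw %/% 2L, mid - cw %/% 2L + cw - 1L,
            factor = sample(decorThresholds()$cofactors, 1L),
            signal = sigOf(cw))
      } else if (runif(1) < 0.4) {
        pw <- sample(100:300, 1L)
        put(pol2, wchr, mid - pw %/% 2L, mid - pw %/% 2L + pw - 1L,
            signal = min(2.0, sigOf(pw)))
      }
      ## TF peaks in the window
      lam <- if (tt$transcribed) config$tfbs_rate_transcribed else
        config$tfbs_rate_other
      k <- rpois(1L, lam)
      if (k > 0) {
        tw <- sample(120:300, k, replace = TRUE)
        cs <- sample(start(w):end(w), k, replace = TRUE)
        put(tf, wchr, cs, cs + tw - 1L,
            factor = sample(config$tf_factor_pool, k, replace = TRUE),
            signal = runif(k, 1, 5))
      }
    }
    ## shared-factor peaks for "retained" loci (pseudogene + parent windows)
    parentWins <- upstreamWindow(annotation$coding, config$upstream_bp)
    for (id in truth$pseudogene_id[truth$parent_upstream_retained]) {
      i <- match(id, ids)
      j <- match(as.character(mcols(man)$parent_id)[i],
                 names(annotation$coding))
      fac <- sample(config$tf_factor_pool, 1L)
      for (w in list(wins[i], parentWins[j])) {
        mid <- (start(w) + end(w)) %/% 2L
        put(tf, as.character(seqnames(w)), mid - 75L, mid + 74L,
            factor = fac, signal = runif(1, 1, 5))
      }
    }
    ## background Pol2 peaks in intergenic space
    nb <- config$n_background_pol2
    bw <- sample(80:500, nb, replace = TRUE)
    bchr <- sample(seqlevels(si), nb, replace = TRUE)
    bst <- sample.int(as.integer(config$chrom_length_bp - 1000L), nb)
    put(pol2, bchr, bst, bst + bw - 1L, signal = sigOf(bw))

    prom <- acc()
    for (id in truth$pseudogene_id[pract]) {
      i <- match(id, ids)
      w <- wins[i]
      put(prom, as.character(seqnames(w)), (start(w) + end(w)) %/% 2L,
          (start(w) + end(w)) %/% 2L + 499L)
    }
    promoters <- build(prom)

    ## DNase track: background 0.1 + bumps
    bump <- function(gr5, amp, half = 2000L) {
      str <- as.character(strand(gr5))
      tss <- ifelse(str == "-", end(gr5), start(gr5))
      g <- GRanges(seqnames(gr5),
                   IRanges(pmax(1L, tss - half),
                           pmin(seqlengths(si)[as.character(seqnames(gr5))],
                                tss + half)), seqinfo = si)
      coverage(g, width = seqlengths(si)) * amp
    }
    dnase <- coverage(GRanges(seqinfo = si), width = seqlengths(si)) + 0.1
    dnase <- dnase + bump(annotation$coding, 2.0)
    trIds <- truth$pseudogene_id[truth$transcribed]
    if (length(trIds))
      dnase <- dnase + bump(man[match(trIds, ids)], config$dnase_bump_amp)
    dnIds <- setdiff(truth$pseudogene_id[truth$dnase_accessible], trIds)
    if (length(dnIds))
      dnase <- dnase + bump(man[match(dnIds, ids)], config$dnase_bump_amp)

    out[[ctx]] <- list(segmentation = seg,
                       pol2_peaks = build(pol2, "signal"),
                       cofactor_peaks = build(cof, c("factor", "signal")),
                       tf_peaks = build(tf, c("factor", "signal")),
                       promoters = promoters, dnase = dnase)
  }
  out
}

#' Simulate divergence records and variants
#'
#' Null pseudogenes draw substitutions from Poisson(background rate x
#' length) per species; planted conserved loci use a reduced rate
#' (multiplier < 1). Per-species aligned fractions decay with species
#' distance. Variants are placed uniformly with DAFs from a Beta
#' spectrum skewed to low frequencies.
#'
#' @param annotation,truth,config simulation pieces.
#' @return list(divergence, variants) data.frames.
#' @export
simulateDivergenceVariants <- function(annotation, truth, config) {
  set.seed(.stageSeed(config, "divergence"))
  man <- annotation$manual
  ids <- as.character(mcols(man)$id)
  L <- width(man)
  div <- do.call(rbind, lapply(names(config$background_rates), function(sp) {
    r <- config$background_rates[[sp]]
    mult <- ifelse(truth$conserved, config$conserved_multiplier, 1)
    k <- rpois(length(ids), r * L * mult)
    ab <- round(config$align_frac[[sp]] * L * runif(length(ids), 0.9, 1))
    data.frame(pseudogene_id = ids, species = sp,
               aligned_bp = pmin(ab, L), substitutions = pmin(k, ab),
               length = L, stringsAsFactors = FALSE)
  }))
  nv <- rpois(length(ids), config$variant_rate_per_bp * L)
  variants <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (nv[i] == 0L) return(NULL)
    data.frame(pseudogene_id = ids[i],
               pos = sort(sample(start(man)[i]:end(man)[i], nv[i])),
               vclass = sample(names(config$vclass_probs), nv[i],
                               replace = TRUE, prob = config$vclass_probs),
               daf = rbeta(nv[i], config$daf_shape[1], config$daf_shape[2]),
               stringsAsFactors = FALSE)
  }))
  list(divergence = div, variants = variants)
}

#' Simulate the full corpus
#'
#' Runs every generator stage and bundles the inputs plus the planted
#' truth table. A pure function of the config (and its seed).
#'
#' @param config from [simulationConfig()].
#' @return list with annotation pieces, sequences, coverage, functional
#'   genomics per context, divergence/variants, truth, config.
#' @export
simulateCorpus <- function(config = simulationConfig()) {
  ann <- simulateAnnotation(config)
  truth <- simulateTruth(ann, config)
  seqs <- simulateSequences(ann, config)
  cov <- simulateCoverage(ann, truth, config)
  fg <- simulateFunctionalGenomics(ann, truth, config)
  dv <- simulateDivergenceVariants(ann, truth, config)
  c(ann, list(sequences = seqs, coverage = cov, fungen = fg,
              divergence = dv$divergence, variants = dv$variants,
              truth = truth, config = config))
}
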