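#' Lower-tail Poisson conservation p-value
#'
#' Probability of observing equal or fewer substitutions than seen, under a
#' null in which substitutions accumulate as Poisson with mean
#' `rate * length` (the background substitution rate times the pseudogene
#' length in bp). A small p-value marks a pseudogene with fewer
#' substitutions than neutral decay predicts, i.e. a conserved one.
#' Computed by log-space accumulation of the Poisson pmf for stability.
#'
#' @param k observed substitution count(s), non-negative integer.
#' @param L pseudogene length(s) in bp, > 0.
#' @param rate background substitution rate per site (1.5% for chimp,
#'   5% for mouse in the published survey), >= 0.
#' @return p-value(s) in [0, 1].
#' @examples
#' poissonConservationP(0, 2000, 0.015)  # exp(-30)
#' @export
poissonConservationP <- function(k, L, rate) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integers")
  if (any(L <= 0)) stop("L must be positive")
  if (any(rate < 0)) stop("rate must be non-negative")
  lambda <- rate * L
  n <- max(length(k), length(lambda))
  k <- rep_len(k, n); lambda <- rep_len(lambda, n)
  vapply(seq_len(n), function(i) {
    lam <- lambda[i]
    if (lam == 0) return(1)
    i0 <- 0:k[i]
    lp <- i0 * log(lam) - lam - lgamma(i0 + 1)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up selection
#'
#' Standard BH: rank the p-values increasingly, find the largest k with
#' p(k) <= fdr * k / n, and select all hypotheses of rank <= k. Ties are
#' broken by stable input order. Returns selection flags in input order.
#'
#' @param p numeric p-values in [0, 1].
#' @param fdr target false discovery rate in (0, 1).
#' @return logical vector, TRUE = selected (significant).
#' @export
bhSelect <- function(p, fdr = 0.05) {
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1)
    stop("fdr must lie in (0, 1)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(logical(0))
  ord <- order(p)                       # stable for ties
  ps <- p[ord]
  ok <- which(ps <= fdr * seq_len(n) / n)
  sel <- logical(n)
  if (length(ok)) sel[ord[seq_len(max(ok))]] <- TRUE
  sel
}

#' Per-species sequence preservation rate
#'
#' Percentage of pseudogene sequence aligned to each species:
#' 100 * sum(aligned_bp) / sum(length), optionally within classes.
#'
#' @param div divergence data.frame with columns `species`, `aligned_bp`,
#'   `length`, and optionally a class column named by `by`.
#' @param by optional column name to stratify by.
#' @return data.frame species (, class), preserved_pct.
#' @export
preservationRate <- function(div, by = NULL) {
  if (any(div$length <= 0)) stop("zero or negative pseudogene length")
  groups <- if (is.null(by)) list(div$species) else
    list(div$species, div[[by]])
  agg <- aggregate(div[, c("aligned_bp", "length")], by = groups, FUN = sum)
  names(agg)[seq_along(groups)] <- c("species", by)
  agg$preserved_pct <- 100 * agg$aligned_bp / agg$length
  agg[, c("species", by, "preserved_pct"), drop = FALSE]
}

#' Conservation pipeline: Poisson test + BH selection per species
#'
#' Tests every pseudogene with an ortholog in each species against that
#' species' background substitution rate, applies BH selection within the
#' species, and combines the per-species conserved flags.
#'
#' @param div data.frame with columns `pseudogene_id`, `species`,
#'   `substitutions`, `length` (and optionally `aligned_bp`).
#' @param rates named per-species background rates per site.
#' @param fdr target FDR for BH selection.
#' @param combine how per-species flags combine into the decoration flag:
#'   `"union"` (conserved in either species; default), `"chimp_only"`
#'   (first species only), or `"intersection"`.
#' @return list with `results` (per id x species: k, L, p, conserved) and
#'   `conserved` (named logical per pseudogene id).
#' @export
conservationPipeline <- function(div,
                                 rates = c(chimp = 0.015, mouse = 0.05),
                                 fdr = 0.05,
                                 combine = c("union", "chimp_only",
                                             "intersection")) {
  combine <- match.arg(combine)
  res <- do.call(rbind, lapply(names(rates), function(sp) {
    d <- div[div$species == sp, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    p <- poissonConservationP(d$substitutions, d$length, rates[[sp]])
    data.frame(pseudogene_id = d$pseudogene_id, species = sp,
               substitutions = d$substitutions, length = d$length,
               p_value = p, conserved = bhSelect(p, fdr),
               stringsAsFactors = FALSE)
  }))
  ids <- unique(div$pseudogene_id)
  flagBySp <- lapply(names(rates), function(sp) {
    d <- res[res$species == sp, ]
    setNames(d$conserved, d$pseudogene_id)[ids]
  })
  names(flagBySp) <- names(rates)
  comb <- switch(combine,
    union = Reduce(`|`, lapply(flagBySp, function(v) !is.na(v) & v)),
    chimp_only = { v <- flagBySp[[1L]]; !is.na(v) & v },
    intersection = Reduce(`&`, lapply(flagBySp, function(v) !is.na(v) & v)))
  list(results = res, conserved = setNames(as.logical(comb), ids))
}

#' Derived-allele-frequency spectra and class comparison
#'
#' Bins variant DAFs into per-class spectra (variant class x pseudogene
#' group) and compares groups within each variant class by a two-sample
#' Kolmogorov-Smirnov test. Also reports variant densities per kb where a
#' total bp per group is supplied.
#'
#' @param variants data.frame with columns `daf`, `vclass` and `group`
#'   (e.g. transcribed / non-transcribed).
#' @param breaks DAF bin edges, default 10 equal bins on [0, 1].
#' @param group_bp optional named vector of total bp per group for
#'   densities.
#' @return list with `spectra` (counts per vclass x group x bin),
#'   `tests` (per-vclass KS p-values, NA where a group is empty), and
#'   `density_per_kb` (or NULL).
#' @export
dafSpectra <- function(variants, breaks = seq(0, 1, by = 0.1),
                       group_bp = NULL) {
  stopifnot(all(variants$daf >= 0 & variants$daf <= 1))
  groups <- sort(unique(variants$group))
  vclasses <- sort(unique(variants$vclass))
  spectra <- lapply(setNames(vclasses, vclasses), function(vc) {
    sapply(setNames(groups, groups), function(g) {
      x <- variants$daf[variants$vclass == vc & variants$group == g]
      as.vector(table(cut(x, breaks, include.lowest = TRUE)))
    })
  })
  tests <- vapply(vclasses, function(vc) {
    xs <- lapply(groups, function(g)
      variants$daf[variants$vclass == vc & variants$group == g])
    if (length(xs) < 2L || any(!lengths(xs))) return(NA_real_)
    suppressWarnings(ks.test(xs[[1L]], xs[[2L]])$p.value)
  }, numeric(1))
  dens <- NULL
  if (!is.null(group_bp)) {
    cnt <- table(variants$group)
    dens <- setNames(1000 * as.numeric(cnt[names(group_bp)]) /
                       as.numeric(group_bp), names(group_bp))
  }
  list(spectra = spectra, tests = setNames(tests, vclasses),
       density_per_kb = dens)
}
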