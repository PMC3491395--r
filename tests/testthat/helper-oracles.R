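# independent oracles, kept deliberately naive

# exhaustive affine-gap global alignment score (match +1, mismatch -1,
# gap cost open + ext per base), Biostrings penalty convention
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             open = 5, ext = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); E <- M; F <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) E[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) F[i, 1] <- -(open + ext * (i - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
    E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext)
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# step-up FDR selection evaluated literally from its definition
oracleBh <- function(p, fdr) {
  n <- length(p)
  ord <- order(p)
  ks <- which(p[ord] <= fdr * seq_len(n) / n)
  sel <- logical(n)
  if (length(ks)) sel[ord[seq_len(max(ks))]] <- TRUE
  sel
}

# lower Poisson tail by direct pmf summation
oraclePoisTail <- function(k, lambda) sum(stats::dpois(0:k, lambda))

# best sliding-window identity by direct enumeration
oracleWindowIdentity <- function(m, window) {
  n <- length(m)
  if (n <= window) return(100 * mean(m))
  best <- 0
  for (s in 1:(n - window + 1))
    best <- max(best, mean(m[s:(s + window - 1)]))
  100 * best
}

# per-caller support by all-pairs interval intersection (plain arithmetic)
oracleSupport <- function(query, calls, minov) {
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  qc <- as.character(GenomicRanges::seqnames(query))
  cs <- GenomicRanges::start(calls); ce <- GenomicRanges::end(calls)
  cc <- as.character(GenomicRanges::seqnames(calls))
  vapply(seq_along(qs), function(i) {
    any(cc == qc[i] & pmin(ce, qe[i]) - pmax(cs, qs[i]) + 1L >= minov)
  }, logical(1))
}

# one-sided Fisher enrichment p by hypergeometric tail enumeration
oracleFisherGreater <- function(a, b, c, d) {
  # table rows: (transcribed: active a, inactive b), (other: active c, d)
  m <- a + c; nn <- b + d; k <- a + b
  sum(stats::dhyper(a:min(k, m), m, nn, k))
}

randomMatchVector <- function(n, p = 0.7) as.numeric(runif(n) < p)
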