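test_that("upstreamWindow is strand-aware and clips at chromosome edges", {
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  plus <- GRanges("chr1", IRanges(5001, 8000), strand = "+", seqinfo = si)
  w <- upstreamWindow(plus, 2000)
  expect_identical(c(start(w), end(w)), c(3001L, 5000L))
  minus <- GRanges("chr1", IRanges(5001, 8000), strand = "-", seqinfo = si)
  wm <- upstreamWindow(minus, 2000)
  expect_identical(c(start(wm), end(wm)), c(8001L, 10000L))
  near <- GRanges("chr1", IRanges(501, 2000), strand = "+", seqinfo = si)
  wn <- upstreamWindow(near, 2000)
  expect_identical(c(start(wn), end(wn)), c(1L, 500L))
  expect_warning(upstreamWindow(gr1("chr1", 5001, 8000, "*")), "unstranded")
})

test_that("filterNearCodingTss excludes strictly-within-4kb loci", {
  coding <- gr1("chr1", 50000, 53000, "+")          # TSS at 50000
  loci <- GRanges(c("chr1", "chr1", "chr2"),
                  IRanges(c(46001, 46000, 46001), c(47000, 47000, 47000)),
                  strand = "+")
  # 5' ends: 3999 away (excluded), exactly 4000 (kept), other chromosome
  mcols(loci)$id <- c("a", "b", "c")
  f <- filterNearCodingTss(loci, coding, 4000)
  expect_identical(f$excluded_flag, c(TRUE, FALSE, FALSE))
  expect_identical(length(f$kept) + length(f$excluded), 3L)
})

test_that("countTfbs applies a strict majority rule and matches brute force", {
  win <- gr1("chr1", 1001, 3000)
  pk <- gr1("chr1", 951, 1150)        # 150 of 200 bp inside: counts
  mcols(pk)$factor <- "Myc"
  expect_identical(countTfbs(pk, win)$total, 1L)
  half <- gr1("chr1", 901, 1100)      # exactly 100 of 200 inside: no
  mcols(half)$factor <- "Myc"
  expect_identical(countTfbs(half, win)$total, 0L)
  set.seed(51)
  st <- sample(1:9000, 1000, replace = TRUE)
  peaks <- gr1("chr1", st, st + sample(50:400, 1000, TRUE))
  mcols(peaks)$factor <- sample(c("A", "B", "C"), 1000, TRUE)
  wins <- gr1("chr1", 4001, 6000)
  got <- countTfbs(peaks, wins)
  ov <- pmin(end(peaks), 6000) - pmax(start(peaks), 4001) + 1
  want <- sum(ov > width(peaks) / 2)
  expect_identical(got$total, as.integer(want))
  expect_identical(sum(got$per_factor), as.integer(want))
})

test_that("callPol2Active combines width+signal on one peak or a cofactor", {
  win <- gr1("chr1", 10001, 12000)
  mkPeak <- function(w, sig) {
    g <- gr1("chr1", 10500, 10500 + w - 1)
    mcols(g)$signal <- sig
    g
  }
  noCof <- GRanges()
  p <- callPol2Active(mkPeak(600, 3.0), noCof, win)
  expect_true(p$active); expect_identical(p$criterion, "1+2")
  expect_false(callPol2Active(mkPeak(600, 1.0), noCof, win)$active)
  expect_false(callPol2Active(mkPeak(100, 5.0), noCof, win)$active)
  taf <- gr1("chr1", 10600, 10800); mcols(taf)$factor <- "Taf1"
  p3 <- callPol2Active(mkPeak(100, 1.0), taf, win)
  expect_true(p3$active); expect_identical(p3$criterion, "3")
  # width/signal thresholds are exclusive bounds
  expect_false(callPol2Active(mkPeak(519, 3.0), noCof, win)$active)
  expect_false(callPol2Active(mkPeak(600, 2.38), noCof, win)$active)
  # criteria 1 and 2 must hold for the same peak by default
  two <- c(mkPeak(600, 1.0), mkPeak(100, 5.0))
  expect_false(callPol2Active(two, noCof, win)$active)
  expect_true(callPol2Active(two, noCof, win, same_peak = FALSE)$active)
})

test_that("derivePol2Thresholds returns pooled 95th percentiles", {
  pk <- gr1("chr1", 1:100 * 1000, 1:100 * 1000 + (1:100) - 1)
  mcols(pk)$signal <- (1:100) / 10
  thr <- derivePol2Thresholds(pk)
  expect_equal(thr$width_threshold, unname(quantile(1:100, 0.95)))
  expect_equal(thr$signal_threshold, unname(quantile((1:100) / 10, 0.95)))
  eq <- gr1("chr1", 1:30 * 1000, 1:30 * 1000 + 199)
  mcols(eq)$signal <- rep(2, 30)
  thrEq <- derivePol2Thresholds(eq)
  expect_equal(thrEq$width_threshold, 200)
  expect_lt(derivePol2Thresholds(pk, 80)$width_threshold,
            thr$width_threshold)
  expect_error(derivePol2Thresholds(pk[1:5]), "20 peaks")
})

test_that("callPromoterActive needs only a single overlapping base", {
  win <- gr1("chr1", 1001, 3000)
  expect_true(callPromoterActive(gr1("chr1", 3000, 3500), win))
  expect_false(callPromoterActive(gr1("chr1", 13000, 13500), win))
  expect_false(callPromoterActive(GRanges(), win))
})

test_that("enrichmentTest matches hypergeometric enumeration and detects planted effects", {
  # 2x2 example: transcribed (6 active, 4 not), others (9 active, 81 not)
  tr <- rep(c(TRUE, FALSE), c(10, 90))
  act <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 9), rep(FALSE, 81))
  expect_equal(enrichmentTest(tr, act), oracleFisherGreater(6, 4, 9, 81),
               tolerance = 1e-12)
  # identical count distributions: two-sided rank-sum p = 1
  expect_equal(suppressWarnings(
    enrichmentTest(rep(c(TRUE, FALSE), each = 6), rep(c(1, 2, 3), 4))), 1)
  # planted enrichment: 50% active in 100 transcribed vs 5% in 900 others
  set.seed(52)
  tr2 <- rep(c(TRUE, FALSE), c(100, 900))
  act2 <- c(runif(100) < 0.5, runif(900) < 0.05)
  expect_lt(enrichmentTest(tr2, act2), 1e-6)
  expect_error(enrichmentTest(rep(TRUE, 5), act2[1:5]), "degenerate")
})
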