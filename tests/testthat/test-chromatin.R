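test_that("aggregateProfile is flat on constant tracks and mirrors minus strands", {
  track <- RleList(chr1 = Rle(2.5, 50000))
  anchors <- gr1("chr1", 20000, 21000, "+")
  pr <- aggregateProfile(track, anchors, half_window = 1000, bin = 50)
  expect_equal(nrow(pr), 40)
  expect_true(all(pr$mean_signal == 2.5))
  # a minus-strand profile equals the plus-strand profile on the
  # coordinate-reversed track at the reflected 5' end
  set.seed(40)
  v <- runif(50000)
  t <- 20001L                                 # minus 5' end
  prM <- aggregateProfile(RleList(chr1 = Rle(v)),
                          gr1("chr1", 15001, t, "-"), 1000, 50)
  prP <- aggregateProfile(RleList(chr1 = Rle(rev(v))),
                          gr1("chr1", 50002L - t, 50002L - t + 3000L, "+"),
                          1000, 50)
  expect_equal(prM$mean_signal, prP$mean_signal, tolerance = 1e-9)
  expect_error(aggregateProfile(track, GRanges()), "anchor")
})

test_that("aggregateProfile of two loci is the mean of their individual profiles", {
  set.seed(41)
  track <- RleList(chr1 = Rle(runif(60000)))
  a1 <- gr1("chr1", 10000, 12000, "+")
  a2 <- gr1("chr1", 40000, 42000, "-")
  both <- c(a1, a2)
  p1 <- aggregateProfile(track, a1, 2000, 100)
  p2 <- aggregateProfile(track, a2, 2000, 100)
  pb <- aggregateProfile(track, both, 2000, 100)
  expect_equal(pb$mean_signal, (p1$mean_signal + p2$mean_signal) / 2,
               tolerance = 1e-9)
})

test_that("labelFrequencies normalizes by the genome-wide label fraction", {
  labels <- segmentationLabels()
  # half the toy genome is TSS, half R1
  seg <- Segmentation(GRanges("chr1", IRanges(c(1, 5001), c(5000, 10000)),
                              label = c("TSS", "R1")), labels)
  region <- gr1("chr1", 1001, 2000)
  names(region) <- "x"
  f <- labelFrequencies(seg, region)
  expect_equal(unname(f["x", "TSS"]), 2)   # fully covered / genome frac 0.5
  expect_equal(unname(f["x", "R1"]), 0)
  expect_equal(sum(f["x", ] > 0), 1L)
})

test_that("labelFrequencies matches per-base counting on a toy segmentation", {
  set.seed(42)
  labels <- segmentationLabels()
  all25 <- c(labels$active, labels$repressive)
  brk <- sort(sample(2:9999, 40))
  st <- c(1, brk); en <- c(brk - 1, 10000)
  lab <- sample(all25, length(st), replace = TRUE)
  seg <- Segmentation(GRanges("chr1", IRanges(st, en), label = lab), labels)
  region <- gr1("chr1", 2501, 7500); names(region) <- "r"
  f <- labelFrequencies(seg, region)
  # per-base oracle
  base <- character(10000)
  for (i in seq_along(st)) base[st[i]:en[i]] <- lab[i]
  for (l in all25) {
    gfrac <- sum(base == l) / 10000
    raw <- sum(base[2501:7500] == l) / 5000
    want <- if (gfrac == 0) 0 else raw / gfrac
    expect_equal(unname(f["r", l]), want, tolerance = 1e-12, info = l)
  }
})

test_that("callActiveChromatin applies the 3x TSS and 2x gene-body criteria", {
  labels <- segmentationLabels()
  seg <- Segmentation(GRanges("chr1", IRanges(1, 100), label = "TSS"), labels)
  mk <- function(tss = 0, gs = 0, gm = 0, ge = 0, rep_max = 0) {
    f <- matrix(0, 1, 25,
                dimnames = list("x", c(labels$active, labels$repressive)))
    f[1, "TSS"] <- tss; f[1, "GS"] <- gs; f[1, "GM"] <- gm; f[1, "GE"] <- ge
    f[1, "R1"] <- rep_max
    f
  }
  c1 <- callActiveChromatin(mk(tss = 0.30, rep_max = 0.09), seg)
  expect_true(c1$active); expect_identical(c1$criterion, "1")
  c2 <- callActiveChromatin(mk(gs = .2, gm = .2, ge = .2, rep_max = .09), seg)
  expect_true(c2$active); expect_identical(c2$criterion, "2")
  # all labels equal -> inactive
  fEq <- matrix(0.5, 1, 25,
                dimnames = list("x", c(labels$active, labels$repressive)))
  expect_false(callActiveChromatin(fEq, seg)$active)
  # all-zero row is inactive, not vacuously active
  expect_false(callActiveChromatin(mk(), seg)$active)
  # criterion 2 needs all three gene-body labels by default
  cPart <- callActiveChromatin(mk(gs = .2, gm = .2, rep_max = .09), seg)
  expect_false(cPart$active)
  expect_true(callActiveChromatin(mk(gs = .2, gm = .2, rep_max = .09), seg,
                                  genebody_all = FALSE)$active)
})

test_that("callActiveChromatin is invariant under rescaling all frequencies", {
  set.seed(43)
  labels <- segmentationLabels()
  seg <- Segmentation(GRanges("chr1", IRanges(1, 100), label = "TSS"), labels)
  f <- matrix(runif(25 * 20), 20, 25,
              dimnames = list(paste0("r", 1:20),
                              c(labels$active, labels$repressive)))
  base <- callActiveChromatin(f, seg)
  for (c in c(0.01, 3, 1000)) {
    sc <- callActiveChromatin(f * c, seg)
    expect_identical(sc$active, base$active)
    expect_identical(sc$criterion, base$criterion)
  }
})

test_that("callDnaseAccessible flags loci by fold over the genome-wide mean", {
  v <- numeric(100000) + 1
  v[50000:54000] <- 10
  track <- RleList(chr1 = Rle(v))
  loci <- c(gr1("chr1", 52000, 53000, "+"), gr1("chr1", 10000, 11000, "+"))
  got <- callDnaseAccessible(track, loci, half_window = 2000, fold = 2)
  expect_identical(got, c(TRUE, FALSE))
})
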