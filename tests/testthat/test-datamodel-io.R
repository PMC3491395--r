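test_that("GTF coordinates convert 1-based inclusive to internal ranges", {
  tmp <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "1001", "2000", ".", "+", ".",
                   'gene_id "g1"; biotype "processed";', sep = "\t"), tmp)
  gr <- readAnnotation(tmp, "GTF")
  expect_identical(start(gr), 1001L)
  expect_identical(end(gr), 2000L)
  expect_identical(width(gr), 1000L)   # [1000,2000) in 0-based terms
  expect_identical(as.character(mcols(gr)$biotype), "processed")
})

test_that("empty and malformed annotation inputs are handled", {
  tmp <- tempfile(fileext = ".gtf")
  file.create(tmp)
  expect_warning(gr <- readAnnotation(tmp, "GTF"), "empty")
  expect_identical(length(gr), 0L)
  bad <- tempfile(fileext = ".gtf")
  writeLines("chr1\tonly\tthree", bad)
  expect_error(readAnnotation(bad, "GTF"), "failed to parse")
  expect_error(readAnnotation(tempfile(), "GTF"), "not found")
  unk <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "1", "100", ".", "+", ".",
                   'gene_id "g1"; biotype "weird";', sep = "\t"), unk)
  expect_warning(gru <- readAnnotation(unk, "GTF"), "ambiguous")
  expect_identical(as.character(mcols(gru)$biotype), "ambiguous")
})

test_that("annotation round-trips through GTF and BED identically", {
  corpus <- sharedCorpus()
  tmp <- tempfile(fileext = ".gtf")
  writeAnnotation(corpus$manual, tmp, "GTF")
  back <- readAnnotation(tmp, "GTF")
  expect_identical(start(back), start(corpus$manual))
  expect_identical(end(back), end(corpus$manual))
  expect_identical(as.character(strand(back)),
                   as.character(strand(corpus$manual)))
  for (f in c("id", "biotype", "parent_id", "parent_source"))
    expect_identical(as.character(mcols(back)[[f]]),
                     as.character(mcols(corpus$manual)[[f]]), info = f)
  tmpB <- tempfile(fileext = ".bed")
  writeAnnotation(corpus$pipeA, tmpB, "BED")
  backB <- readAnnotation(tmpB, "BED")
  expect_identical(ranges(backB), ranges(corpus$pipeA))
})

test_that("narrowPeak rows become peaks with width and signal", {
  tmp <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t700\tPol2\t0\t.\t3.0\t-1\t-1\t-1", tmp)
  pk <- readNarrowPeak(tmp)
  expect_identical(width(pk), 600L)
  expect_identical(mcols(pk)$signal, 3.0)
  expect_identical(as.character(mcols(pk)$factor), "Pol2")
  # write-read round trip
  tmp2 <- tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(pk, tmp2)
  pk2 <- readNarrowPeak(tmp2)
  expect_identical(ranges(pk2), ranges(pk))
  expect_identical(mcols(pk2)$signal, mcols(pk)$signal)
})

test_that("bedGraph round-trips through RleList and rejects overlaps", {
  si <- GenomeInfoDb::Seqinfo("chr1", 10000)
  v <- numeric(10000); v[101:200] <- 2; v[5001:5200] <- 0.5
  track <- RleList(chr1 = Rle(v))
  tmp <- tempfile(fileext = ".bedGraph")
  writeBedGraph(track, tmp)
  back <- readBedGraph(tmp, si)
  expect_identical(as.numeric(back$chr1), v)
  badf <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t200\t1", "chr1\t150\t250\t2"), badf)
  expect_error(readBedGraph(badf, si), "overlapping")
})

test_that("segmentation BED validates labels against the 25-label vocabulary", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tTSS", "chr1\t100\t300\tR1"), tmp)
  seg <- readSegmentationBed(tmp)
  expect_s4_class(seg, "Segmentation")
  expect_true("TSS" %in% activeLabels(seg))
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tNOT_A_LABEL", bad)
  expect_error(readSegmentationBed(bad), "NOT_A_LABEL")
})

test_that("Segmentation validity rejects overlapping or mislabeled segments", {
  labels <- segmentationLabels()
  expect_error(Segmentation(GRanges("chr1", IRanges(c(1, 50), c(100, 150)),
                                    label = c("TSS", "R1")), labels),
               "overlap")
  expect_error(Segmentation(GRanges("chr1", IRanges(1, 100), label = "XX"),
                            labels), "unknown segmentation label")
})

test_that("sequence pairs round-trip through FASTA", {
  pairs <- list(PG1 = list(parent_id = "G1", pseudo_cds = "ACGTACGT",
                           parent_cds = "ACGTACGA", pseudo_utr3 = "TTTT",
                           parent_utr3 = "TTTTGGGG"))
  tmp <- tempfile(fileext = ".fa")
  writeSequencePairs(pairs, tmp)
  back <- readSequencePairs(tmp)
  expect_identical(back, pairs)
})

test_that("the decoration TSV round-trips and serializes tags as specified", {
  run <- sharedRun()
  tmp <- tempfile(fileext = ".tsv")
  writePsidr(run$psidr, tmp)
  back <- readPsidr(tmp)
  tb0 <- decorationTable(run$psidr)[, pseudoDecoR:::.psidrCols]
  tb1 <- decorationTable(back)
  rownames(tb0) <- rownames(tb1) <- NULL
  expect_equal(tb1, tb0, tolerance = 1e-12)
  # tag cells: comma-joined evidence, "None" rows have flag 0
  expect_true(any(grepl(",", tb1$transcription_tags) |
                    tb1$transcription_tags %in%
                    c("EST", "TotalRNA", "BodyMap", "None")))
  expect_true(all(tb1$transcribed[tb1$transcription_tags == "None"] == 0L))
  # duplicate (pseudogene, context) keys are rejected
  dup <- rbind(tb0, tb0[1, ])
  expect_error(DecorationTable(dup), "duplicate")
})

test_that("divergence and variant TSV readers validate their invariants", {
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(pseudogene_id = "p", species = "chimp",
                         aligned_bp = 2000, substitutions = 10,
                         length = 1000),
              tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readDivergenceTsv(tmp))          # aligned_bp > length
  tmp2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(pseudogene_id = "p", pos = 1, vclass = "SNP",
                         daf = 1.5),
              tmp2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readVariantsTsv(tmp2))
})
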