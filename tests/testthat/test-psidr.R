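test_that("jaccard and specificityMatrix behave as set statistics", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(), character()), 0)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "a")), 1)  # set semantics
  m <- specificityMatrix(list(x = c("a", "b"), y = c("a", "b"),
                              z = c("c")))
  expect_true(all(is.na(diag(m))))
  expect_identical(m, t(m))
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "z"], 0)
  expect_error(specificityMatrix(list(x = "a")), "two contexts")
})

test_that("classifyPartialActivity follows the ordered rule set", {
  row <- function(tr, ch, p2, pr, cons, dns = 0L, id = "p1") {
    data.frame(pseudogene_id = id, context = "K562", transcribed = tr,
               active_chromatin = ch, active_pol2 = p2, active_promoter = pr,
               conserved = cons, dnase_accessible = dns)
  }
  ret <- c(p1 = TRUE); noret <- c(p1 = FALSE)
  expect_identical(classifyPartialActivity(row(0L, 1L, 1L, 0L, 1L), ret)$class,
                   "dying")
  expect_identical(classifyPartialActivity(row(1L, 1L, 0L, 0L, NA), noret)$class,
                   "resurrected")
  expect_identical(classifyPartialActivity(row(1L, 1L, 1L, 1L, 0L), ret)$class,
                   "fully_active")
  expect_identical(classifyPartialActivity(row(0L, 0L, 0L, 0L, 0L), ret)$class,
                   "dead")
  expect_identical(classifyPartialActivity(row(1L, 0L, 0L, 0L, 0L), ret)$class,
                   "partially_active")
  # NA activity flags (excluded loci) count as inactive
  expect_identical(classifyPartialActivity(row(0L, 0L, NA, NA, 0L), ret)$class,
                   "dead")
  expect_error(classifyPartialActivity(row(0L, 0L, 0L, 0L, 0L)[, -5], ret),
               "missing field")
})

test_that("class assignment on the corpus equals a brute-force rule application", {
  run <- sharedRun()
  tb <- decorationTable(run$psidr)
  got <- run$classes
  z <- function(v) ifelse(is.na(v), 0L, v)
  for (ctx in unique(tb$context)) {
    sub <- tb[tb$context == ctx, ]
    ret <- parentUpstreamRetained(run$surveyed, sharedCorpus()$coding,
                                  sharedCorpus()$fungen[[ctx]]$tf_peaks)
    want <- vapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      rt <- isTRUE(ret[r$pseudogene_id])
      up <- isTRUE(z(r$active_pol2) == 1L || z(r$active_promoter) == 1L)
      if (z(r$transcribed) == 0L && z(r$active_chromatin) == 1L && up &&
          z(r$conserved) == 1L) "dying"
      else if (z(r$transcribed) == 1L && z(r$active_chromatin) == 1L && !rt)
        "resurrected"
      else if (z(r$transcribed) == 1L && z(r$active_chromatin) == 1L && up)
        "fully_active"
      else if (z(r$transcribed) + z(r$active_chromatin) + up +
                 z(r$conserved) + z(r$dnase_accessible) == 0) "dead"
      else "partially_active"
    }, character(1))
    g <- got$class[got$context == ctx][match(sub$pseudogene_id,
                                             got$pseudogene_id[got$context == ctx])]
    expect_identical(g, want)
  }
  # planted dying/resurrected/fully-active loci carry their class
  sv <- surveyedTruth()
  cls1 <- got[got$context == unique(tb$context)[1], ]
  expect_true(all(cls1$class[match(sv$pseudogene_id[sv$dying],
                                   cls1$pseudogene_id)] == "dying"))
  expect_true(all(cls1$class[match(sv$pseudogene_id[sv$fully_active],
                                   cls1$pseudogene_id)] == "fully_active"))
  expect_true(all(cls1$class[match(sv$pseudogene_id[sv$resurrected],
                                   cls1$pseudogene_id)] == "resurrected"))
})

test_that("decorate assembles one validated row per surveyed pseudogene per context", {
  run <- sharedRun()
  tb <- decorationTable(run$psidr)
  sv <- surveyedTruth()
  expect_identical(nrow(tb),
                   nrow(sv) * length(unique(tb$context)))
  expect_true(validObject(run$psidr))
  # excluded loci carry NA upstream calls and the exclusion marker
  ex <- tb[tb$excluded_near_coding_tss == 1L, ]
  expect_identical(sort(unique(ex$pseudogene_id)),
                   sort(sv$pseudogene_id[sv$near_coding_tss]))
  expect_true(all(is.na(ex$active_pol2)), all(is.na(ex$active_promoter)))
  # transcribed flag consistent with tags everywhere
  expect_identical(tb$transcribed == 1L, tb$transcription_tags != "None")
  # evidence tags match the planted evidence source
  tr1 <- tb[tb$context == tb$context[1] & tb$transcribed == 1L, ]
  planted <- sv$evidence[match(tr1$pseudogene_id, sv$pseudogene_id)]
  expect_true(all(mapply(grepl, planted, tr1$transcription_tags)))
})

test_that("decoration flags for missing components default to zero", {
  loci <- gr1("chr1", c(1000, 5000), c(2000, 6000))
  mcols(loci) <- DataFrame(id = c("p1", "p2"), biotype = "processed",
                           level = "1", parent_id = "g1",
                           parent_source = "manual")
  dt <- decorate(loci, contexts = "X")
  tb <- decorationTable(dt)
  expect_identical(tb$transcribed, c(0L, 0L))
  expect_identical(tb$transcription_tags, c("None", "None"))
  expect_identical(tb$conserved, c(0L, 0L))
  expect_warning(
    decorate(loci, identity = data.frame(pseudogene_id = "zz",
                                         cds_identity = 1,
                                         utr3_identity = 1,
                                         identity_class = "low-low"),
             contexts = "X"),
    "absent from the surveyed set")
})
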