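test_that("generation is a pure function of config and seed", {
  cfg <- simulationConfig(seed = 99, n_pseudogenes = 40L,
                          n_coding_genes = 12L, n_concordant_decoys = 2L)
  a <- simulateCorpus(cfg)
  b <- simulateCorpus(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$manual, b$manual)
  expect_identical(a$sequences$pairs, b$sequences$pairs)
  expect_identical(a$divergence, b$divergence)
  expect_identical(as.list(a$coverage$tracks[[1]]),
                   as.list(b$coverage$tracks[[1]]))
  c2 <- simulateCorpus(simulationConfig(seed = 100, n_pseudogenes = 40L,
                                        n_coding_genes = 12L,
                                        n_concordant_decoys = 2L))
  expect_false(identical(start(a$manual), start(c2$manual)))
})

test_that("config validation and density errors fire", {
  expect_error(simulationConfig(nonsense = 1), "unknown config field")
  expect_error(simulateAnnotation(
    simulationConfig(seed = 1, chrom_length_bp = 5e4)), "density")
})

test_that("caller recovery fractions drive the level structure by construction", {
  base <- list(seed = 3, n_pseudogenes = 30L, n_coding_genes = 10L,
               polymorphic_count = 0L, n_near_coding = 0L,
               n_concordant_decoys = 2L)
  all1 <- do.call(simulationConfig, c(base, level1_fraction = 1))
  annAll <- simulateAnnotation(all1)
  lvAll <- assignLevels(annAll$manual, annAll$pipeA, annAll$pipeB)
  expect_true(all(lvAll$levels$level == "1"))
  none <- do.call(simulationConfig, c(base, level1_fraction = 0,
                                      n_delta2way = 0L, n_pipeA_only = 0L,
                                      n_pipeB_only = 0L))
  annNone <- simulateAnnotation(none)
  lvNone <- assignLevels(annNone$manual, annNone$pipeA, annNone$pipeB)
  expect_true(all(lvNone$levels$level == "2"))
  # recovered levels match the generator's own truth on the shared corpus
  corpus <- sharedCorpus()
  lv <- sharedRun()$levels$levels
  expect_identical(lv$level, corpus$truth_levels$level[
    match(lv$id, corpus$truth_levels$id)])
  expect_identical(length(sharedRun()$levels$delta2way),
                   as.integer(corpus$config$n_delta2way))
})

test_that("planted coverage clears or misses the BodyMap rule by construction", {
  corpus <- sharedCorpus()
  sv <- surveyedTruth()
  man <- corpus$manual
  frac2 <- function(id, tissue) {
    g <- man[match(id, as.character(mcols(man)$id))]
    mean(trackValues(corpus$coverage$tracks[[tissue]], g) >= 2)
  }
  bm <- sv[sv$transcribed & sv$evidence == "BodyMap", ]
  for (i in seq_len(nrow(bm)))
    expect_gte(frac2(bm$pseudogene_id[i], bm$bodymap_tissue[i]), 0.5)
  off <- sv[!sv$transcribed & !sv$concordant_decoy, ]
  for (i in seq_len(min(20, nrow(off))))
    expect_true(all(vapply(names(corpus$coverage$tracks), function(t)
      frac2(off$pseudogene_id[i], t) < 0.5, logical(1))))
})

test_that("concordant decoys have rank-correlated parent profiles and are rejected", {
  corpus <- sharedCorpus()
  sv <- surveyedTruth()
  man <- corpus$manual
  dec <- sv$pseudogene_id[sv$concordant_decoy]
  expect_gt(length(dec), 0)
  for (id in dec) {
    g <- man[match(id, as.character(mcols(man)$id))]
    prof <- vapply(corpus$coverage$tracks, function(tr)
      mean(trackValues(tr, g)), numeric(1))
    rho <- suppressWarnings(
      cor(prof, corpus$coverage$parent_expr[id, names(prof)],
          method = "spearman"))
    expect_gt(rho, 0.5)
  }
  calls <- sharedRun()$transcription
  expect_true(all(!calls$transcribed[match(dec, calls$pseudogene_id)]))
})

test_that("planted conservation effect sizes follow the Poisson null generator", {
  # multiplier 0.1 at rate 0.015 over 1 kb: mean 1.5 vs null 15
  cfg <- simulationConfig(seed = 8)
  corpus <- sharedCorpus()
  sv <- surveyedTruth()
  div <- corpus$divergence
  ch <- div[div$species == "chimp", ]
  consK <- ch$substitutions[ch$pseudogene_id %in%
                              sv$pseudogene_id[sv$conserved]]
  nullK <- ch$substitutions[ch$pseudogene_id %in%
                              sv$pseudogene_id[!sv$conserved]]
  consL <- ch$length[ch$pseudogene_id %in% sv$pseudogene_id[sv$conserved]]
  nullL <- ch$length[ch$pseudogene_id %in% sv$pseudogene_id[!sv$conserved]]
  expect_lt(mean(consK / consL), 0.005)       # ~0.1 x 0.015
  expect_gt(mean(nullK / nullL), 0.010)       # ~0.015
  # per-species preservation decays with distance (chimp > mouse)
  pr <- preservationRate(div)
  expect_gt(pr$preserved_pct[pr$species == "chimp"],
            pr$preserved_pct[pr$species == "mouse"])
})

test_that("truth table flags are consistent subsets of the annotation", {
  tr <- sharedCorpus()$truth
  expect_true(all(tr$pseudogene_id[tr$dying] %in%
                    tr$pseudogene_id[tr$conserved & tr$active_chromatin]))
  expect_true(all(!tr$transcribed[tr$dying]))
  expect_true(all(tr$transcribed[tr$resurrected]))
  expect_true(all(tr$biotype[tr$resurrected] == "processed"))
  expect_true(all(tr$biotype[tr$dying] == "duplicated"))
  expect_true(all(tr$chromatin_criterion[tr$active_chromatin] %in%
                    c("1", "2")))
  expect_true(all(tr$chromatin_criterion[!tr$active_chromatin] == "none"))
  expect_false(any(tr$transcribed[tr$concordant_decoy]))
})
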