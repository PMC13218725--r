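twoProteinFixture <- function() {
  feats <- data.frame(protein = rep(c("A1", "B1"), each = 2),
                      chain = "A", position = rep(1:2, 2),
                      wt = "A", rasa = c(0.05, 0.4, 0.05, 0.4),
                      wcn = 10, ss3 = "helix", ss8 = "H", phi = NA, psi = NA,
                      crystal_resolved = TRUE, stringsAsFactors = FALSE)
  rec <- data.frame(protein = c("A1", "A1", "A1", "B1", "B1", "B1"),
                    chain = "A", position = c(1L, 1L, 2L, 1L, 2L, 2L),
                    wt = "A", var = c("V", "L", "V", "V", "V", "L"),
                    score = c(0.15, 0.35, 0.9, 0.4, 0.7, 0.8), sd = 0.05,
                    stringsAsFactors = FALSE)
  list(pool = new("VariantPool", records = rec, proteins = c("A1", "B1")),
       features = feats)
}

test_that("LOPO predictions use only other proteins' data, with fallback", {
  fx <- twoProteinFixture()
  pred <- predictLopo(fx$pool, fx$features, "exposure")
  # B1's single buried A->V record (0.4) predicts A1's buried A->V
  a1 <- pred[pred$protein == "A1", ]
  expect_equal(a1$pred[a1$position == 1 & a1$var == "V"], 0.4)
  expect_equal(a1$provenance[a1$position == 1 & a1$var == "V"],
               "exposure:buried")
  # A->L has no buried cell in B1: falls back to B1's global mean (0.8)
  expect_equal(a1$pred[a1$var == "L"], 0.8)
  expect_equal(a1$provenance[a1$var == "L"], "fallback:global")

  # leakage: corrupting A1's scores changes no prediction for A1
  rec2 <- records(fx$pool)
  rec2$score[rec2$protein == "A1"] <- rec2$score[rec2$protein == "A1"] + 10
  pool2 <- new("VariantPool", records = rec2, proteins = c("A1", "B1"))
  pred2 <- predictLopo(pool2, fx$features, "exposure")
  expect_identical(pred2$pred[pred2$protein == "A1"],
                   pred$pred[pred$protein == "A1"])

  expect_error(predictLopo(poolSubset(fx$pool, "A1"), fx$features),
               "at least two")
  # provenance is total: every non-missing prediction names its source
  expect_true(all((pred$provenance == "missing") == is.na(pred$pred)))
})

test_that("evaluation matches textbook correlation and MAE formulas", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.7)
  y <- c(0.2, 0.5, 0.1, 0.8, 0.9)
  pred <- data.frame(protein = "p", score = x, pred = y)
  ev <- evaluatePredictions(pred)
  # independent implementations from first principles
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rx <- rank(x); ry <- rank(y)
  rsManual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ev$r, rManual, tolerance = 1e-12)
  expect_equal(ev$r_s, rsManual, tolerance = 1e-12)
  expect_equal(ev$mae, mean(abs(x - y)), tolerance = 1e-12)

  expect_equal(evaluatePredictions(data.frame(protein = "p", score = x,
                                              pred = x))$r, 1)
  expect_equal(evaluatePredictions(data.frame(protein = "p", score = x,
                                              pred = 1 - x))$r, -1)
  expect_error(evaluatePredictions(data.frame(protein = "p", score = 1:2,
                                              pred = 1:2)), "fewer than 3")
  # missing predictions are excluded pairwise and counted
  yNA <- y; yNA[2] <- NA
  ev2 <- evaluatePredictions(data.frame(protein = "p", score = x, pred = yNA))
  expect_equal(ev2$n_evaluated, 4L)
  expect_equal(ev2$n_missing, 1L)
})

test_that("grid search: cWcn = 0 row reproduces the pure-rASA LOPO path", {
  bm <- benchmarkFixture()
  gs <- gridSearchCutoffs(bm$pool, bm$featuresAnalysis,
                          cRasaGrid = 0.1, cWcnGrid = 0)
  ev <- evaluatePredictions(predictLopo(bm$pool, bm$featuresAnalysis,
                                        "exposure", cRasa = 0.1, cWcn = 0))
  expect_equal(gs$mean_r, mean(ev$r), tolerance = 1e-12)
  expect_equal(gs$mean_mae, mean(ev$mae), tolerance = 1e-12)
})

test_that("grid search recovers the planted burial cutoff", {
  bm <- benchmarkFixture()
  gs <- gridSearchCutoffs(bm$pool, bm$featuresAnalysis,
                          cRasaGrid = seq(0, 0.5, 0.05), cWcnGrid = c(0, 5))
  best <- attr(gs, "best_r")
  expect_lte(abs(best$c_rasa - 0.1), 0.05)
  # degenerate cutoff 0: only exactly-zero-rASA residues stay buried, so the
  # model collapses toward (but not below) the global scheme
  evG <- evaluatePredictions(predictLopo(bm$pool, bm$featuresAnalysis,
                                         "global"))
  r0 <- gs$mean_r[gs$c_rasa == 0 & gs$c_wcn == 0]
  expect_lt(r0, best$mean_r)
  expect_gt(r0, mean(evG$r) - 0.05)
})

test_that("combination analysis enumerates subsets and matches LOPO when full", {
  bm <- benchmarkFixture()
  pool4 <- poolSubset(bm$pool, c("SYN1", "SYN2", "SYN3", "SYN4"))
  dc <- datasetCombinationAnalysis(pool4, bm$featuresAnalysis)
  expect_equal(nrow(dc), 4 * (2^3 - 1))
  full <- dc[dc$size == 3, ]
  ev <- evaluatePredictions(predictLopo(pool4, bm$featuresAnalysis,
                                        "exposure"))
  for (p in proteinIds(pool4))
    expect_equal(full$r[full$target == p], ev$r[ev$protein == p],
                 tolerance = 1e-12)
  # more training proteins helps on average
  agg <- tapply(dc$r, dc$size, mean)
  expect_true(all(diff(agg) > -0.02))
})

test_that("ddG preparation converts REU and per-dimer values", {
  base <- data.frame(protein = "p", position = 1, wt = "A", var = "V",
                     value = 5.8)
  expect_equal(ddgPrepare(base, unit = "REU", assembly = "monomer")$ddg, 2)
  base$value <- 4
  expect_equal(ddgPrepare(base, unit = "kcal", assembly = "dimer")$ddg, 2)
  base$value <- 0
  expect_equal(ddgPrepare(base, unit = "REU", assembly = "dimer")$ddg, 0)
  expect_error(ddgPrepare(base, unit = "eV"), "arg")
})

test_that("external matrix baseline is symmetric under wt/var swap", {
  ext <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  set.seed(13)
  ext[upper.tri(ext)] <- rnorm(sum(upper.tri(ext)))
  ext <- ext + t(ext)
  fx <- randomPoolFixture(nRecords = 400)
  p1 <- baselineMatrixPredict(fx$pool, ext)
  rec <- records(fx$pool)
  swapped <- rec; swapped$wt <- rec$var; swapped$var <- rec$wt
  p2 <- baselineMatrixPredict(new("VariantPool", records = swapped,
                                  proteins = proteinIds(fx$pool)), ext)
  expect_identical(p1$pred, p2$pred)
  expect_error(baselineMatrixPredict(fx$pool, ext[1:10, ]), "20 canonical")
})

test_that("descriptor correlations recover monotone and null relationships", {
  n <- 60L
  feats <- data.frame(protein = "p1", chain = "A", position = seq_len(n),
                      wt = "A", rasa = seq(0.01, 0.6, length.out = n),
                      wcn = seq(20, 1, length.out = n), ss3 = "loop",
                      ss8 = " ", phi = NA, psi = NA, crystal_resolved = TRUE,
                      stringsAsFactors = FALSE)
  rec <- data.frame(protein = "p1", chain = "A", position = seq_len(n),
                    wt = "A", var = "V",
                    score = seq(0.1, 0.9, length.out = n), sd = 0.05,
                    stringsAsFactors = FALSE)
  pool <- new("VariantPool", records = rec, proteins = "p1")
  dc <- descriptorCorrelations(pool, feats)
  expect_equal(dc$r_s_rasa, 1)          # strictly increasing in rasa
  expect_equal(dc$r_s_wcn, 1)           # negated wcn is increasing too
  # shuffled scores: near-zero correlation
  set.seed(5)
  rec$score <- sample(rec$score)
  dcS <- descriptorCorrelations(new("VariantPool", records = rec,
                                    proteins = "p1"), feats)
  expect_lt(abs(dcS$r_s_rasa), 2 / sqrt(n) * 2)
  # constant scores: flagged as NA
  rec$score <- 0.5
  dcC <- descriptorCorrelations(new("VariantPool", records = rec,
                                    proteins = "p1"), feats)
  expect_true(is.na(dcC$r_s_rasa))
})

test_that("bootstrap CI brackets the mean and is seed-stable", {
  v <- c(0.3, 0.45, 0.5, 0.52, 0.58, 0.6)
  ci <- bootstrapMeanCI(v, nBoot = 2000, seed = 4)
  expect_equal(ci[["mean"]], mean(v))
  expect_lt(ci[["lower"]], mean(v))
  expect_gt(ci[["upper"]], mean(v))
  expect_identical(ci, bootstrapMeanCI(v, nBoot = 2000, seed = 4))
})
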