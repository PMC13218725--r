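referenceMatrices <- function(buriedRow = NULL, exposedRow = NULL,
                              wt = "A") {
  mkMean <- function(row) {
    m <- matrix(NA_real_, 20, 20, dimnames = list(AA20, AA20))
    m[wt, names(row)] <- row
    m
  }
  list(buried = matrixFromMean(mkMean(buriedRow)),
       exposed = matrixFromMean(mkMean(exposedRow)))
}

aProfile <- function(scores, sds = 0.05, wt = "A") {
  list(protein = "p", position = 1L, wt = wt, var = names(scores),
       score = unname(scores), sd = rep(sds, length.out = length(scores)))
}

test_that("profile RMSD handles identity, single-variant and hand cases", {
  row <- c(V = 0.2, L = 0.5, I = 0.8)
  m <- referenceMatrices(row, row)$buried
  expect_equal(as.numeric(profileRmsd(aProfile(row), m)), 0)
  p1 <- aProfile(c(V = 0.7))
  expect_equal(as.numeric(profileRmsd(p1, m)), 0.5)   # single shared variant
  p3 <- aProfile(c(V = 0.1, L = 0.6, I = 0.9))
  expect_equal(as.numeric(profileRmsd(p3, m)),
               sqrt(mean(c(0.1, 0.1, 0.1)^2)))
  expect_equal(attr(profileRmsd(p3, m), "n_shared"), 3L)
  # shared set restricted to defined cells
  p4 <- aProfile(c(V = 0.1, W = 0.4))
  expect_equal(attr(profileRmsd(p4, m), "n_shared"), 1L)
  expect_error(profileRmsd(aProfile(c(W = 1)), m), "no overlap")
})

test_that("burial-likeness: noise-free limits and the symmetric null", {
  bRow <- c(V = 0.1, L = 0.2, I = 0.15, F = 0.1, M = 0.2)
  eRow <- c(V = 0.9, L = 0.95, I = 0.85, F = 0.9, M = 0.95)
  mats <- referenceMatrices(bRow, eRow)
  # profile equals the buried row exactly, sd -> 0: frac 1, buried-like
  r1 <- classifyBurialLike(aProfile(bRow, sds = 0), mats$buried,
                           mats$exposed, nResamples = 200, seed = 1)
  expect_equal(r1$frac_buried_smaller, 1)
  expect_equal(r1$call, "buried-like")
  expect_equal(r1$rmsd_buried, 0)
  # identical references: every resample ties -> frac 0.5, inconclusive
  same <- referenceMatrices(bRow, bRow)
  r2 <- classifyBurialLike(aProfile(bRow), same$buried, same$exposed,
                           nResamples = 200, seed = 2)
  expect_equal(r2$frac_buried_smaller, 0.5)
  expect_equal(r2$call, "inconclusive")
  # fewer than five scores: not evaluated
  r3 <- classifyBurialLike(aProfile(bRow[1:4]), mats$buried, mats$exposed,
                           nResamples = 10, seed = 3)
  expect_equal(r3$call, "not-evaluated")
  expect_error(classifyBurialLike(aProfile(bRow, sds = NA), mats$buried,
                                  mats$exposed, seed = 1), "missing score sd")
})

test_that("burial-likeness is deterministic, monotone in the criterion, and symmetric", {
  bRow <- c(V = 0.1, L = 0.2, I = 0.15, F = 0.1, M = 0.2, K = 0.3)
  eRow <- c(V = 0.6, L = 0.55, I = 0.5, F = 0.45, M = 0.6, K = 0.65)
  mats <- referenceMatrices(bRow, eRow)
  prof <- aProfile((bRow + eRow) / 2 + c(0.05, -0.02, 0.01, 0.03, -0.04, 0),
                   sds = 0.25)
  a <- classifyBurialLike(prof, mats$buried, mats$exposed,
                          nResamples = 2000, seed = 11)
  b <- classifyBurialLike(prof, mats$buried, mats$exposed,
                          nResamples = 2000, seed = 11)
  expect_identical(a, b)                 # bit-reproducible under the seed
  # swapping references maps frac -> 1 - frac
  sw <- classifyBurialLike(prof, mats$exposed, mats$buried,
                           nResamples = 2000, seed = 11)
  expect_equal(sw$frac_buried_smaller, 1 - a$frac_buried_smaller)
  # raising the criterion never upgrades a call to a definite class
  for (prof2 in list(prof, aProfile(bRow, sds = 0.02))) {
    c95 <- classifyBurialLike(prof2, mats$buried, mats$exposed,
                              nResamples = 500, seed = 5, criterion = 0.95)
    c99 <- classifyBurialLike(prof2, mats$buried, mats$exposed,
                              nResamples = 500, seed = 5, criterion = 0.99)
    if (c95$call == "inconclusive") expect_equal(c99$call, "inconclusive")
    if (c99$call != "inconclusive") expect_equal(c99$call, c95$call)
  }
  # noise-free: frac is 0 or 1 apart from exact ties
  nf <- classifyBurialLike(aProfile(eRow, sds = 0), mats$buried,
                           mats$exposed, nResamples = 50, seed = 6)
  expect_true(nf$frac_buried_smaller %in% c(0, 1))
  expect_equal(nf$call, "exposed-like")
})

test_that("favoured classification: dominance, identical rankings, and gating", {
  sc <- c(V = 0.9, L = 0.7, I = 0.5, F = 0.3, M = 0.1)
  ddg <- c(V = 0.2, L = 1.1, I = 2.0, F = 3.2, M = 4.5)  # anti-ranks scores
  mp <- c(V = 0.5, L = 0.65, I = 0.4, F = 0.35, M = 0.2) # decent matrix
  # sd = 0: ddG wins every resample
  r1 <- classifyFavoured(aProfile(sc, sds = 0), mp, ddg, nResamples = 100,
                         seed = 1)
  expect_equal(r1$frac_ddg_better, 1)
  expect_equal(r1$call, "ddg-favoured")
  expect_equal(r1$r_s_ddg, -1)
  # identical rankings -> permanent tie -> similar
  r2 <- classifyFavoured(aProfile(sc, sds = 0.1), -ddg, ddg,
                         nResamples = 200, seed = 2)
  expect_equal(r2$frac_ddg_better, 0.5)
  expect_equal(r2$call, "similar")
  # not evaluated unless both observed correlations are positive
  badMp <- -mp
  r3 <- classifyFavoured(aProfile(sc), badMp, ddg, nResamples = 10, seed = 3)
  expect_equal(r3$call, "not-evaluated")
  expect_match(r3$reason, "not both positive")
  # insufficient overlap with predictions
  r4 <- classifyFavoured(aProfile(sc), mp[1:3], ddg, nResamples = 10,
                         seed = 4)
  expect_equal(r4$call, "not-evaluated")
  expect_match(r4$reason, "variant")
  # determinism
  r5 <- classifyFavoured(aProfile(sc, sds = 0.3), mp, ddg,
                         nResamples = 1000, seed = 9)
  r6 <- classifyFavoured(aProfile(sc, sds = 0.3), mp, ddg,
                         nResamples = 1000, seed = 9)
  expect_identical(r5, r6)
})

test_that("huge noise makes the two predictors indistinguishable", {
  sc <- c(V = 0.9, L = 0.7, I = 0.5, F = 0.3, M = 0.1, K = 0.6)
  ddg <- c(V = 0.2, L = 1.1, I = 2.0, F = 3.2, M = 4.5, K = 1.4)
  mp <- 1 - ddg / 5
  similar <- 0L
  for (s in 1:10) {
    r <- classifyFavoured(aProfile(sc, sds = 50), mp, ddg,
                          nResamples = 400, seed = s)
    if (r$call %in% c("similar", "not-evaluated")) similar <- similar + 1L
  }
  expect_gte(similar, 9L)
})

test_that("amino-acid enrichment normalises within groups and finds planted excess", {
  calls <- data.frame(wt = c(rep("D", 3), rep("K", 4), rep("E", 3),
                             rep("L", 6), rep("P", 4)))
  grpA <- c(rep(TRUE, 10), rep(FALSE, 10))
  en <- enrichmentByAa(calls, grpA, !grpA, labels = c("a", "b"))
  expect_equal(sum(en$a), 1)
  expect_equal(sum(en$b), 1)
  expect_equal(en$a[en$aa == "D"], 0.3)
  for (aa in c("D", "E", "K"))
    expect_gt(en$a[en$aa == aa], en$b[en$aa == aa])
  expect_error(enrichmentByAa(calls, rep(FALSE, 20), !grpA), "non-empty")
})

test_that("interface assessment counts buried-like calls over scored interface residues", {
  calls <- data.frame(position = 1:6, wt = "L",
                      call = c("buried-like", "buried-like", "exposed-like",
                               "not-evaluated", "buried-like",
                               "inconclusive"),
                      stringsAsFactors = FALSE)
  iface <- data.frame(position = c(1, 2, 3, 4, 6),
                      is_interface = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- interfaceAssessment(calls, iface)
  expect_equal(out$n_interface, 4L)
  expect_equal(out$n_evaluated, 3L)      # the not-evaluated row drops out
  expect_equal(out$n_buried_like, 2L)
})
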