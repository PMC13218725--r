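# Shared fixtures. The full synthetic benchmark is expensive (~10 s), so it
# is generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

benchmarkFixture <- function() {
  if (is.null(.fixtureCache$bm))
    .fixtureCache$bm <- syntheticBenchmark(seed = 1)
  .fixtureCache$bm
}

# Combined per-protein truth tables of the benchmark, keyed for joining.
benchmarkTruth <- function() {
  bm <- benchmarkFixture()
  do.call(rbind, lapply(names(bm$truth), function(p)
    cbind(protein = p, bm$truth[[p]], stringsAsFactors = FALSE)))
}

# Deterministic random pool + features (no structures involved) for matrix
# oracle tests: nRecords draws over nProteins x nPositions residues.
randomPoolFixture <- function(nRecords = 5000L, nProteins = 4L,
                              nPositions = 120L, seed = 99L) {
  set.seed(seed)
  feats <- do.call(rbind, lapply(seq_len(nProteins), function(i) {
    data.frame(protein = sprintf("P%d", i), chain = "A",
               position = seq_len(nPositions),
               wt = sample(AA20, nPositions, replace = TRUE),
               rasa = round(runif(nPositions, 0, 0.6), 3),
               wcn = round(runif(nPositions, 0, 20), 2),
               ss3 = sample(c("helix", "strand", "loop"), nPositions,
                            replace = TRUE),
               ss8 = NA_character_, phi = NA_real_, psi = NA_real_,
               crystal_resolved = TRUE, stringsAsFactors = FALSE)
  }))
  idx <- data.frame(protein = sample(sprintf("P%d", seq_len(nProteins)),
                                     nRecords, replace = TRUE),
                    position = sample.int(nPositions, nRecords, replace = TRUE))
  key <- paste(idx$protein, idx$position)
  fkey <- paste(feats$protein, feats$position)
  wt <- feats$wt[match(key, fkey)]
  var <- vapply(wt, function(w) sample(setdiff(AA20, w), 1L), "")
  rec <- data.frame(protein = idx$protein, chain = "A",
                    position = idx$position, wt = wt, var = unname(var),
                    score = round(rnorm(nRecords, 0.6, 0.3), 4),
                    sd = 0.05, stringsAsFactors = FALSE)
  rec <- rec[!duplicated(paste(key, var)), , drop = FALSE]
  rownames(rec) <- NULL
  pool <- new("VariantPool", records = rec,
              proteins = sprintf("P%d", seq_len(nProteins)))
  list(pool = pool, features = feats)
}

# Brute-force cell mean: plain loop over records, independent of the
# rowsum-based implementation path.
bruteForceCellMean <- function(rec, wt, var) {
  sel <- rec$wt == wt & rec$var == var
  if (!any(sel)) return(NA_real_)
  mean(rec$score[sel])
}

makeDatasetFromRecords <- function(proteinId, position, wt, var, score,
                                   sd = NA_real_, nResidues = NA_integer_) {
  new("AbundanceDataset", proteinId = proteinId,
      records = data.frame(chain = "A", position = as.integer(position),
                           wt = wt, var = var, score = score,
                           sd = rep(sd, length.out = length(score)),
                           stringsAsFactors = FALSE),
      nResidues = as.integer(nResidues), metadata = list())
}

# A SubstitutionMatrix wrapping a given mean matrix (unit count where
# defined), for analysis-module tests.
matrixFromMean <- function(mean, scheme = "custom", label = "test",
                           count = NULL) {
  if (is.null(count)) count <- ifelse(is.na(mean), 0, 2)
  diag(count) <- 0
  diag(mean) <- NA_real_
  sd <- ifelse(count > 1, 0, NA_real_)
  new("SubstitutionMatrix", scheme = scheme, label = label, mean = mean,
      count = count, sd = sd)
}

# Minimal DSSP-format text for parser tests.
writeDsspFixture <- function(path, resno, chain, aa, ss) {
  hdr <- c("==== Secondary Structure Definition (fixture) ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  lines <- sprintf("%5d%5d %1s %1s  %1s", seq_along(resno), resno, chain,
                   aa, ss)
  writeLines(c(hdr, lines), path)
  path
}
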