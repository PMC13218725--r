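# Abundance prediction from substitution matrices with leave-one-protein-out
# (LOPO) cross-validation, the burial-cutoff grid search, and the
# dataset-combination analysis.

# Predict each record's score by looking up its (env, wt, var) cell; missing
# environment-specific cells fall back to the global cell, then to NA.
# Provenance names the source of every non-missing prediction.
predictFromMatrices <- function(rec, matrices, globalMatrix) {
  n <- nrow(rec)
  pred <- rep(NA_real_, n)
  prov <- rep("missing", n)
  scheme <- if (length(matrices)) matrices[[1L]]@scheme else "global"
  for (lab in names(matrices)) {
    sel <- which(!is.na(rec$env) & rec$env == lab)
    if (!length(sel)) next
    v <- matrices[[lab]]@mean[cbind(rec$wt[sel], rec$var[sel])]
    ok <- !is.na(v)
    pred[sel[ok]] <- v[ok]
    prov[sel[ok]] <- sprintf("%s:%s", scheme, lab)
  }
  need <- which(is.na(pred))
  if (length(need) && !is.null(globalMatrix)) {
    v <- globalMatrix@mean[cbind(rec$wt[need], rec$var[need])]
    ok <- !is.na(v)
    pred[need[ok]] <- v[ok]
    prov[need[ok]] <- "fallback:global"
  }
  list(pred = pred, provenance = prov)
}

#' Leave-one-protein-out abundance prediction
#'
#' For each protein P in the pool, the scheme's matrices are rebuilt from all
#' other proteins and each of P's variants is predicted by the matrix cell
#' for (environment of its wild-type residue, wt -> var). Missing
#' environment-specific cells fall back to the global matrix (also built
#' without P), then to a missing prediction; no prediction for P ever derives
#' from P's own records.
#'
#' @inheritParams buildMatrix
#' @param scheme Conditioning scheme for the predictions.
#' @return data.frame with `protein`, `position`, `wt`, `var`, `score`,
#'   `sd`, `env`, `pred`, `provenance`.
#' @export
predictLopo <- function(pool, features, scheme = "exposure", cRasa = 0.1,
                        cWcn = 0) {
  if (length(pool@proteins) < 2L)
    stop("leave-one-protein-out prediction requires at least two proteins")
  rec <- joinEnvironment(pool, features, scheme, cRasa, cWcn)
  out <- vector("list", length(pool@proteins))
  for (i in seq_along(pool@proteins)) {
    p <- pool@proteins[i]
    mats <- buildMatrixSet(pool, features, scheme, excludeProteins = p,
                           cRasa = cRasa, cWcn = cWcn)
    glob <- if (scheme == "global") NULL
            else buildMatrix(pool, features, "global", "all",
                             excludeProteins = p)
    sub <- rec[rec$protein == p, , drop = FALSE]
    pr <- predictFromMatrices(sub, mats, glob)
    sub$pred <- pr$pred
    sub$provenance <- pr$provenance
    out[[i]] <- sub[, c("protein", "position", "wt", "var", "score", "sd",
                        "env", "pred", "provenance")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate predictions against experimental scores
#'
#' Pearson r, Spearman r_s (average ranks) and mean absolute error per
#' protein over variants with both a prediction and an experimental score;
#' missing predictions are counted and excluded pairwise.
#'
#' @param pred Prediction table from [predictLopo()] (or any data.frame with
#'   `protein`, `score`, `pred`).
#' @return data.frame with one row per protein: `protein`, `r`, `r_s`,
#'   `mae`, `n_evaluated`, `n_missing`.
#' @export
evaluatePredictions <- function(pred) {
  stopifnot(all(c("protein", "score", "pred") %in% names(pred)))
  res <- lapply(split(pred, pred$protein), function(d) {
    ok <- !is.na(d$pred) & !is.na(d$score)
    if (sum(ok) < 3L)
      stop(sprintf("fewer than 3 evaluable pairs for %s", d$protein[1L]))
    data.frame(protein = d$protein[1L],
               r = stats::cor(d$score[ok], d$pred[ok]),
               r_s = stats::cor(d$score[ok], d$pred[ok], method = "spearman"),
               mae = mean(abs(d$score[ok] - d$pred[ok])),
               n_evaluated = sum(ok), n_missing = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence interval for a mean of per-protein statistics
#'
#' Percentile interval from resampling the per-protein values with
#' replacement (default 10,000 draws).
#'
#' @param values Numeric vector (e.g. six per-protein r values).
#' @param nBoot Number of bootstrap draws.
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `mean`, `lower`, `upper`.
#' @export
bootstrapMeanCI <- function(values, nBoot = 10000L, level = 0.95, seed) {
  withSeed(seed, {
    bm <- vapply(seq_len(nBoot), function(i)
      mean(sample(values, replace = TRUE)), 0)
    a <- (1 - level) / 2
    c(mean = mean(values),
      lower = unname(stats::quantile(bm, a)),
      upper = unname(stats::quantile(bm, 1 - a)))
  })
}

#' Grid search over burial cutoffs
#'
#' Scans combinations of rASA and WCN cutoffs; for each pair, exposure
#' matrices are built under the two-descriptor burial rule (buried iff
#' `rasa <= cRasa` and `wcn >= cWcn`) and evaluated by leave-one-protein-out
#' prediction. Rows with `cWcn = 0` are identical to a pure-rASA scan.
#'
#' @inheritParams buildMatrix
#' @param cRasaGrid rASA cutoffs (default 0 to 0.5, step 0.05).
#' @param cWcnGrid WCN cutoffs (default 0 to 20, step 1).
#' @return data.frame of `c_rasa`, `c_wcn`, `mean_r`, `mean_mae` with
#'   attributes `best_r` and `best_mae` (the argmax/argmin rows; first in
#'   grid order on exact ties).
#' @export
gridSearchCutoffs <- function(pool, features, cRasaGrid = seq(0, 0.5, 0.05),
                              cWcnGrid = 0:20) {
  stopifnot(length(cRasaGrid) > 0L, length(cWcnGrid) > 0L)
  rec <- joinEnvironment(pool, features, "exposure")  # for rasa/wcn columns
  rec <- rec[!is.na(rec$rasa) & !is.na(rec$wcn), , drop = FALSE]
  proteins <- unique(rec$protein)
  key0 <- paste(rec$wt, rec$var)
  grid <- expand.grid(c_rasa = cRasaGrid, c_wcn = cWcnGrid,
                      KEEP.OUT.ATTRS = FALSE)
  # global fallback cell means, LOPO, cutoff-independent
  gAllS <- rowsum(rec$score, key0); gAllN <- rowsum(rep(1, nrow(rec)), key0)
  gPS <- rowsum(rec$score, paste(rec$protein, key0))
  gPN <- rowsum(rep(1, nrow(rec)), paste(rec$protein, key0))
  meanR <- meanMae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    env <- classifyResidue(rec$rasa, rec$wcn, grid$c_rasa[g], grid$c_wcn[g])
    key <- paste(env, key0)
    allS <- rowsum(rec$score, key); allN <- rowsum(rep(1, nrow(rec)), key)
    pS <- rowsum(rec$score, paste(rec$protein, key))
    pN <- rowsum(rep(1, nrow(rec)), paste(rec$protein, key))
    rs <- maes <- numeric(length(proteins))
    for (pi in seq_along(proteins)) {
      p <- proteins[pi]
      sel <- rec$protein == p
      k <- key[sel]
      mAll <- match(k, rownames(allS))
      mP <- match(paste(p, k), rownames(pS))
      sP <- ifelse(is.na(mP), 0, pS[mP, 1L])
      nP <- ifelse(is.na(mP), 0, pN[mP, 1L])
      num <- allS[mAll, 1L] - sP
      den <- allN[mAll, 1L] - nP
      pred <- ifelse(den > 0, num / den, NA_real_)
      # global fallback
      need <- is.na(pred)
      if (any(need)) {
        k0 <- key0[sel][need]
        mAll0 <- match(k0, rownames(gAllS))
        mP0 <- match(paste(p, k0), rownames(gPS))
        sP0 <- ifelse(is.na(mP0), 0, gPS[mP0, 1L])
        nP0 <- ifelse(is.na(mP0), 0, gPN[mP0, 1L])
        den0 <- gAllN[mAll0, 1L] - nP0
        pred[need] <- ifelse(den0 > 0, (gAllS[mAll0, 1L] - sP0) / den0,
                             NA_real_)
      }
      ok <- !is.na(pred)
      rs[pi] <- stats::cor(rec$score[sel][ok], pred[ok])
      maes[pi] <- mean(abs(rec$score[sel][ok] - pred[ok]))
    }
    meanR[g] <- mean(rs)
    meanMae[g] <- mean(maes)
  }
  out <- cbind(grid, mean_r = meanR, mean_mae = meanMae)
  attr(out, "best_r") <- out[which.max(meanR), , drop = FALSE]
  attr(out, "best_mae") <- out[which.min(meanMae), , drop = FALSE]
  out
}

#' Prediction accuracy versus number of training datasets
#'
#' For each target protein P and every non-empty subset S of the other
#' proteins, builds the scheme's matrices from S only, predicts P, and
#' reports Pearson r against |S|. The row with S = all-others equals
#' [predictLopo()]'s result for P.
#'
#' @inheritParams predictLopo
#' @return data.frame with `target`, `subset` (comma-joined ids), `size`,
#'   `r`, `mae`.
#' @export
datasetCombinationAnalysis <- function(pool, features, scheme = "exposure",
                                       cRasa = 0.1, cWcn = 0) {
  proteins <- pool@proteins
  if (length(proteins) < 2L) stop("need at least two proteins")
  rec <- joinEnvironment(pool, features, scheme, cRasa, cWcn)
  rows <- list()
  for (p in proteins) {
    others <- setdiff(proteins, p)
    target <- rec[rec$protein == p, , drop = FALSE]
    for (sz in seq_along(others)) {
      combos <- utils::combn(others, sz, simplify = FALSE)
      for (S in combos) {
        sub <- poolSubset(pool, S)
        mats <- buildMatrixSet(sub, features, scheme, cRasa = cRasa,
                               cWcn = cWcn)
        glob <- if (scheme == "global") NULL
                else buildMatrix(sub, features, "global", "all")
        pr <- predictFromMatrices(target, mats, glob)
        ok <- !is.na(pr$pred)
        rows[[length(rows) + 1L]] <- data.frame(
          target = p, subset = paste(S, collapse = ","), size = sz,
          r = if (sum(ok) >= 3L) stats::cor(target$score[ok], pr$pred[ok])
              else NA_real_,
          mae = mean(abs(target$score[ok] - pr$pred[ok])),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict variants from an external 20x20 scoring matrix
#'
#' Baseline predictor that scores each wt -> var substitution by the entry of
#' an externally supplied matrix (e.g. a BLOSUM-style matrix read from CSV).
#' Symmetric matrices are accepted as-is.
#'
#' @param pool A [VariantPool-class].
#' @param externalMatrix 20x20 numeric matrix with AA20 dimnames.
#' @return Prediction table as for [predictLopo()] (provenance `"external"`).
#' @export
baselineMatrixPredict <- function(pool, externalMatrix) {
  stopifnot(is.matrix(externalMatrix))
  if (!all(AA20 %in% rownames(externalMatrix)) ||
      !all(AA20 %in% colnames(externalMatrix)))
    stop("external matrix must cover all 20 canonical residues")
  rec <- pool@records
  pred <- externalMatrix[cbind(rec$wt, rec$var)]
  if (any(is.na(pred))) stop("external matrix has missing entries for observed substitutions")
  cbind(rec, pred = pred, provenance = "external", stringsAsFactors = FALSE)
}

#' Prepare a table of stability changes for comparison with abundance
#'
#' Converts per-variant folding free-energy changes to kcal/mol on a
#' per-subunit basis: Rosetta energy units are divided by 2.9 REU/(kcal/mol),
#' and values computed for a homodimer (substitution applied in both chains)
#' are halved to the per-residue stability change.
#'
#' @param ddg data.frame with columns `protein`, `position`, `wt`, `var`,
#'   `value`.
#' @param unit `"kcal"` or `"REU"`.
#' @param assembly `"monomer"` or `"dimer"`.
#' @param source Label recorded on the table.
#' @return data.frame with the converted `ddg` column (kcal/mol) and
#'   `source`.
#' @export
ddgPrepare <- function(ddg, unit = c("kcal", "REU"),
                       assembly = c("monomer", "dimer"), source = "external") {
  unit <- match.arg(unit)
  assembly <- match.arg(assembly)
  v <- ddg$value
  if (unit == "REU") v <- v / 2.9
  if (assembly == "dimer") v <- v / 2
  if (any(!is.finite(v))) stop("non-finite stability changes after conversion")
  out <- ddg
  out$ddg <- v
  out$source <- source
  out
}

#' Rank correlation of scores with structural descriptors
#'
#' Per-protein Spearman r_s between variant abundance scores and the
#' wild-type residue's rASA, and between scores and the negated WCN (negated
#' so that both descriptors are reported on the "higher = more tolerant"
#' orientation). Optionally collapses to per-residue mean scores first.
#'
#' @inheritParams buildMatrix
#' @param perResidue Correlate per-residue mean scores instead of individual
#'   variants.
#' @return data.frame with `protein`, `r_s_rasa`, `r_s_wcn`, `n`.
#' @export
descriptorCorrelations <- function(pool, features, perResidue = FALSE) {
  rec <- joinEnvironment(pool, features, "exposure")
  rec <- rec[!is.na(rec$rasa) & !is.na(rec$wcn), , drop = FALSE]
  res <- lapply(split(rec, rec$protein), function(d) {
    if (perResidue) {
      s <- rowsum(d$score, d$position)[, 1L]
      n <- rowsum(rep(1, nrow(d)), d$position)[, 1L]
      score <- s / n
      pos <- as.integer(rownames(rowsum(d$score, d$position)))
      m <- match(pos, d$position)
      rasa <- d$rasa[m]; wcn <- d$wcn[m]
    } else {
      score <- d$score; rasa <- d$rasa; wcn <- d$wcn
    }
    rsR <- if (stats::sd(score) == 0) NA_real_
           else stats::cor(score, rasa, method = "spearman")
    rsW <- if (stats::sd(score) == 0) NA_real_
           else stats::cor(score, -wcn, method = "spearman")
    data.frame(protein = d$protein[1L], r_s_rasa = rsR, r_s_wcn = rsW,
               n = length(score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
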