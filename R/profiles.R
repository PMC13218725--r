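# Resampling-based classification of individual residue substitution
# profiles: buried-like vs exposed-like (RMSD criterion) and matrix- vs
# ddG-favoured (rank-correlation criterion).

#' Extract the substitution profile of one residue
#'
#' @param pool A [VariantPool-class].
#' @param protein,position Residue identity.
#' @return List with `protein`, `position`, `wt`, `var`, `score`, `sd`
#'   (parallel vectors over the residue's observed variants).
#' @export
substitutionProfile <- function(pool, protein, position) {
  rec <- pool@records
  sel <- rec$protein == protein & rec$position == position
  if (!any(sel)) stop(sprintf("no records for %s position %d", protein, position))
  d <- rec[sel, , drop = FALSE]
  list(protein = protein, position = position, wt = d$wt[1L],
       var = d$var, score = d$score, sd = d$sd)
}

#' RMSD between a substitution profile and a matrix row
#'
#' Root-mean-square deviation over the variants shared between the residue's
#' observed profile and the (non-missing cells of the) reference matrix row
#' for its wild-type residue.
#'
#' @param profile Profile from [substitutionProfile()].
#' @param refMatrix A [SubstitutionMatrix-class].
#' @return Numeric RMSD with attribute `n_shared`.
#' @export
profileRmsd <- function(profile, refMatrix) {
  row <- refMatrix@mean[profile$wt, ]
  ref <- row[profile$var]
  ok <- !is.na(ref)
  if (!any(ok)) stop("no overlap between profile and reference matrix row")
  out <- sqrt(mean((profile$score[ok] - ref[ok])^2))
  attr(out, "n_shared") <- sum(ok)
  out
}

resampleScores <- function(profile, nResamples) {
  k <- length(profile$score)
  matrix(stats::rnorm(nResamples * k,
                      mean = rep(profile$score, each = nResamples),
                      sd = rep(profile$sd, each = nResamples)),
         nResamples, k)
}

#' Classify a residue's substitution profile as buried-like or exposed-like
#'
#' Resamples the profile from variant-specific Gaussians (independent errors
#' across variants), computes the RMSD to the buried and exposed average
#' profiles for each resample, and calls the residue buried-like when the
#' buried RMSD is smaller in more than `criterion` of resamples (exposed-like
#' for less than `1 - criterion`; inconclusive otherwise). Exact RMSD ties
#' count as "not buried-smaller". Matrices should be built leaving the
#' residue's protein out and, for interface work, from monomer-based
#' classifications.
#'
#' @param profile Profile from [substitutionProfile()]; needs >= `minScores`
#'   entries, all with a score sd.
#' @param mBuried,mExposed Reference [SubstitutionMatrix-class] objects.
#' @param nResamples Resamples (default 10,000).
#' @param criterion Call criterion (default 0.95).
#' @param seed Integer seed.
#' @param minScores Minimum profile size to evaluate (default 5).
#' @return data.frame with `protein`, `position`, `wt`, `n_scores`,
#'   `rmsd_buried`, `rmsd_exposed`, `frac_buried_smaller`, `sem_rmsd_buried`,
#'   `sem_rmsd_exposed`, `call`.
#' @export
classifyBurialLike <- function(profile, mBuried, mExposed,
                               nResamples = 10000L, criterion = 0.95, seed,
                               minScores = 5L) {
  base <- data.frame(protein = profile$protein, position = profile$position,
                     wt = profile$wt, n_scores = length(profile$score),
                     rmsd_buried = NA_real_, rmsd_exposed = NA_real_,
                     frac_buried_smaller = NA_real_,
                     sem_rmsd_buried = NA_real_, sem_rmsd_exposed = NA_real_,
                     call = "not-evaluated", stringsAsFactors = FALSE)
  if (length(profile$score) < minScores) return(base)
  if (any(is.na(profile$sd)))
    stop(sprintf("%s position %d: missing score sd(s); cannot resample",
                 profile$protein, profile$position))
  rowB <- mBuried@mean[profile$wt, ][profile$var]
  rowE <- mExposed@mean[profile$wt, ][profile$var]
  okB <- !is.na(rowB); okE <- !is.na(rowE)
  if (!any(okB) || !any(okE))
    stop("no overlap with buried and/or exposed reference row")
  base$rmsd_buried <- sqrt(mean((profile$score[okB] - rowB[okB])^2))
  base$rmsd_exposed <- sqrt(mean((profile$score[okE] - rowE[okE])^2))
  withSeed(seed, {
    S <- resampleScores(profile, nResamples)
    rb <- sqrt(rowMeans((S[, okB, drop = FALSE] -
                           rep(rowB[okB], each = nResamples))^2))
    re <- sqrt(rowMeans((S[, okE, drop = FALSE] -
                           rep(rowE[okE], each = nResamples))^2))
    # exact ties (probability zero under continuous noise, but reachable
    # with sd = 0 or identical reference rows) split evenly so a symmetric
    # comparison yields frac 0.5 (inconclusive), never a definite call
    base$frac_buried_smaller <- mean(rb < re) + 0.5 * mean(rb == re)
    base$sem_rmsd_buried <- stats::sd(rb) / sqrt(nResamples)
    base$sem_rmsd_exposed <- stats::sd(re) / sqrt(nResamples)
  })
  base$call <- if (base$frac_buried_smaller > criterion) "buried-like"
               else if (base$frac_buried_smaller < 1 - criterion) "exposed-like"
               else "inconclusive"
  base
}

#' Classify a residue as matrix-favoured or ddG-favoured
#'
#' Compares how well a substitution-matrix prediction and a stability-change
#' (ddG) prediction rank the residue's observed variant scores. Evaluated
#' only when the profile has >= `minScores` variants with both predictions
#' and the observed `-r_s(ddG)` and `r_s(matrix)` are both positive. The
#' profile is then resampled from variant-specific Gaussians and the
#' fraction of resamples with `-r_s(ddG) > r_s(matrix)` decides the call:
#' ddG-favoured at `>= criterion`, matrix-favoured at `<= 1 - criterion`,
#' otherwise similar.
#'
#' @param profile Profile from [substitutionProfile()].
#' @param matrixPred Named numeric vector (by variant residue) of matrix
#'   predictions for this residue (use leave-protein-out matrices).
#' @param ddg Named numeric vector (by variant residue) of ddG values
#'   (kcal/mol; positive destabilising).
#' @inheritParams classifyBurialLike
#' @return data.frame with `protein`, `position`, `wt`, `n_scores`,
#'   `r_s_matrix`, `r_s_ddg`, `frac_ddg_better`, `call`, `reason`.
#' @export
classifyFavoured <- function(profile, matrixPred, ddg, nResamples = 10000L,
                             criterion = 0.95, seed, minScores = 5L) {
  base <- data.frame(protein = profile$protein, position = profile$position,
                     wt = profile$wt, n_scores = length(profile$score),
                     r_s_matrix = NA_real_, r_s_ddg = NA_real_,
                     frac_ddg_better = NA_real_, call = "not-evaluated",
                     reason = "", stringsAsFactors = FALSE)
  keep <- profile$var %in% names(matrixPred) & profile$var %in% names(ddg) &
    !is.na(matrixPred[profile$var]) & !is.na(ddg[profile$var])
  if (sum(keep) < minScores) {
    base$reason <- sprintf("only %d variant(s) with score, matrix prediction and ddG",
                           sum(keep))
    return(base)
  }
  sc <- profile$score[keep]; sdv <- profile$sd[keep]
  if (any(is.na(sdv)))
    stop(sprintf("%s position %d: missing score sd(s); cannot resample",
                 profile$protein, profile$position))
  mp <- matrixPred[profile$var[keep]]
  dg <- ddg[profile$var[keep]]
  base$r_s_matrix <- stats::cor(sc, mp, method = "spearman")
  base$r_s_ddg <- stats::cor(sc, dg, method = "spearman")
  if (is.na(base$r_s_matrix) || is.na(base$r_s_ddg) ||
      !(-base$r_s_ddg > 0 && base$r_s_matrix > 0)) {
    base$reason <- "observed -r_s(ddG) and r_s(matrix) not both positive"
    return(base)
  }
  withSeed(seed, {
    S <- matrix(stats::rnorm(nResamples * length(sc),
                             mean = rep(sc, each = nResamples),
                             sd = rep(sdv, each = nResamples)),
                nResamples, length(sc))
    rsM <- rowSpearman(S, mp)
    rsD <- rowSpearman(S, dg)
    # ties split evenly (identical rankings give frac 0.5 -> "similar")
    base$frac_ddg_better <- mean(-rsD > rsM) + 0.5 * mean(-rsD == rsM)
  })
  base$call <- if (base$frac_ddg_better >= criterion) "ddg-favoured"
               else if (base$frac_ddg_better <= 1 - criterion) "matrix-favoured"
               else "similar"
  base$reason <- "evaluated"
  base
}

#' Burial-likeness calls for every residue of one protein
#'
#' Convenience driver: builds buried/exposed reference matrices excluding the
#' target protein (using the supplied, typically monomer-classified, feature
#' table), then runs [classifyBurialLike()] on every residue of the target
#' with at least `minScores` scores.
#'
#' @inheritParams buildMatrix
#' @param protein Target protein id.
#' @param nResamples,criterion,seed,minScores Passed to
#'   [classifyBurialLike()] (per-residue seeds are derived from `seed`).
#' @return data.frame, one row per scored residue, as from
#'   [classifyBurialLike()] plus `env` (the residue's own structural class)
#'   and `mean_score`.
#' @export
residueBurialCalls <- function(pool, features, protein, nResamples = 10000L,
                               criterion = 0.95, seed, cRasa = 0.1,
                               minScores = 5L) {
  mats <- buildMatrixSet(pool, features, "exposure", excludeProteins = protein,
                         cRasa = cRasa)
  rec <- pool@records[pool@records$protein == protein, , drop = FALSE]
  positions <- sort(unique(rec$position))
  feat <- features[features$protein == protein, , drop = FALSE]
  envOf <- classifyResidue(feat$rasa, feat$wcn, cRasa, 0)
  out <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    pos <- positions[i]
    prof <- substitutionProfile(pool, protein, pos)
    row <- if (length(prof$score) >= minScores)
      classifyBurialLike(prof, mats$buried, mats$exposed,
                         nResamples = nResamples, criterion = criterion,
                         seed = seed + i, minScores = minScores)
    else
      classifyBurialLike(prof, mats$buried, mats$exposed,
                         nResamples = 1L, criterion = criterion,
                         seed = seed + i, minScores = minScores)
    row$env <- envOf[match(pos, feat$position)]
    row$mean_score <- mean(prof$score)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Amino-acid enrichment between two residue groups
#'
#' For each wild-type amino acid, the count in each group divided by the
#' group size (frequencies per group sum to 1 over observed types).
#'
#' @param calls data.frame with a `wt` column (one row per residue).
#' @param groupA,groupB Logical vectors selecting the two groups.
#' @param labels Names for the two frequency columns.
#' @return data.frame with `aa`, the two frequency columns, and their
#'   difference.
#' @export
enrichmentByAa <- function(calls, groupA, groupB,
                           labels = c("freq_a", "freq_b")) {
  if (!any(groupA) || !any(groupB)) stop("both groups must be non-empty")
  fa <- table(factor(calls$wt[groupA], levels = AA20)) / sum(groupA)
  fb <- table(factor(calls$wt[groupB], levels = AA20)) / sum(groupB)
  out <- data.frame(aa = AA20, a = as.numeric(fa), b = as.numeric(fb),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- labels
  out$difference <- out[[2L]] - out[[3L]]
  out
}

#' Summarise burial calls over a dimer-interface residue set
#'
#' @param calls Output of [residueBurialCalls()] (leave-target-out,
#'   monomer-classified matrices).
#' @param interface Output of [findInterface()] (or any data.frame with
#'   `position` and `is_interface`).
#' @return List with `table` (per-interface-residue calls) and `n_buried_like`
#'   / `n_evaluated` counts; residues with fewer than the minimum number of
#'   scores are excluded from the denominator.
#' @export
interfaceAssessment <- function(calls, interface) {
  pos <- interface$position[interface$is_interface]
  tab <- calls[calls$position %in% pos, , drop = FALSE]
  evaluated <- tab$call != "not-evaluated"
  list(table = tab,
       n_interface = length(pos),
       n_evaluated = sum(evaluated),
       n_buried_like = sum(tab$call == "buried-like"))
}
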