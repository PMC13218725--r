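#' Quantify a dataset's noise ceiling by Gaussian resampling
#'
#' Resamples every score independently from `Normal(score, sd)` and computes
#' Pearson and Spearman correlations between the original and resampled score
#' vectors; the means over resamples estimate the correlation ceiling that a
#' perfect predictor could reach against this dataset. Resampled scores are
#' not clipped to \[0, 1\].
#'
#' @param ds An [AbundanceDataset-class]; every record must carry a finite
#'   `sd` (records with missing sd trigger an error listing them).
#' @param nResamples Number of resamples (default 100).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return data.frame with `protein`, `r_mean`, `r_s_mean`, `n_resamples`,
#'   `n_records`.
#' @export
noiseResample <- function(ds, nResamples = 100L, seed) {
  stopifnot(is(ds, "AbundanceDataset"), nResamples >= 1L)
  rec <- ds@records
  if (!nrow(rec)) stop("cannot resample an empty dataset")
  bad <- is.na(rec$sd)
  if (any(bad))
    stop(sprintf("%d record(s) lack a score sd (e.g. %s); resampling requires all sds",
                 sum(bad),
                 variantKey(ds@proteinId, rec$position[bad][1L],
                            rec$wt[bad][1L], rec$var[bad][1L])))
  n <- nrow(rec)
  withSeed(seed, {
    r <- rs <- numeric(nResamples)
    for (b in seq_len(nResamples)) {
      y <- stats::rnorm(n, mean = rec$score, sd = rec$sd)
      r[b] <- stats::cor(rec$score, y)
      rs[b] <- stats::cor(rec$score, y, method = "spearman")
    }
    data.frame(protein = ds@proteinId, r_mean = mean(r), r_s_mean = mean(rs),
               n_resamples = as.integer(nResamples), n_records = n,
               stringsAsFactors = FALSE)
  })
}

#' Noise ceilings for every protein in a pool
#'
#' Convenience wrapper running [noiseResample()] per protein. Records with a
#' missing sd are excluded with a logged count rather than failing the whole
#' pool.
#'
#' @param pool A [VariantPool-class].
#' @param nResamples Resamples per protein.
#' @param seed Integer seed.
#' @return data.frame, one row per protein.
#' @export
poolNoiseCeilings <- function(pool, nResamples = 100L, seed) {
  stopifnot(is(pool, "VariantPool"))
  res <- lapply(seq_along(pool@proteins), function(i) {
    p <- pool@proteins[i]
    rec <- pool@records[pool@records$protein == p, , drop = FALSE]
    drop <- is.na(rec$sd)
    if (any(drop))
      message(sprintf("%s: excluding %d record(s) without sd from resampling",
                      p, sum(drop)))
    rec <- rec[!drop, , drop = FALSE]
    ds <- new("AbundanceDataset", proteinId = p,
              records = rec[, recordColumns], nResidues = NA_integer_,
              metadata = list())
    noiseResample(ds, nResamples = nResamples, seed = seed + i)
  })
  do.call(rbind, res)
}
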