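# Downstream analyses of substitution matrices: hierarchical clustering,
# PCA of concatenated to/from profiles, helix-propensity correlation, and
# the left-handed-helix loop analysis.

#' Prepare a matrix for clustering/PCA
#'
#' Sets the (synonymous) diagonal to `diagValue` and imputes missing
#' off-diagonal cells with the row mean of defined cells. The stored
#' [SubstitutionMatrix-class] keeps its diagonal structurally missing; this
#' fill-in happens only at the entry point of clustering/PCA.
#'
#' @param m A [SubstitutionMatrix-class].
#' @param diagValue Value for synonymous cells (default 1, the wild-type
#'   anchor).
#' @return 20x20 numeric matrix without missing values.
#' @export
imputeMatrix <- function(m, diagValue = 1) {
  x <- m@mean
  for (i in seq_len(nrow(x))) {
    off <- setdiff(seq_len(ncol(x)), i)
    defined <- off[!is.na(x[i, off])]
    if (!length(defined)) stop(sprintf("row %s has no defined cells", AA20[i]))
    x[i, setdiff(off, defined)] <- mean(x[i, defined])
  }
  diag(x) <- diagValue
  x
}

#' Hierarchical clustering of a substitution matrix
#'
#' Average-linkage agglomerative clustering (Euclidean distance) along both
#' axes: rows cluster the "mutation from" profiles and columns the
#' "mutation to" profiles. Deterministic for identical input.
#'
#' @inheritParams imputeMatrix
#' @return List with `rows` and `cols` (`hclust` objects) and `rowOrder`,
#'   `colOrder` (amino acids in dendrogram order).
#' @export
clusterMatrix <- function(m, diagValue = 1) {
  x <- imputeMatrix(m, diagValue)
  hr <- stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"), method = "average")
  list(rows = hr, cols = hc,
       rowOrder = rownames(x)[hr$order], colOrder = colnames(x)[hc$order])
}

#' Concatenated to/from substitution profile vectors
#'
#' For each amino acid, the 40-vector of its 20 "mutation from" averages
#' (its matrix row) followed by its 20 "mutation to" averages (its matrix
#' column), with synonymous slots set to 1.
#'
#' @inheritParams imputeMatrix
#' @return 20x40 numeric matrix (rows = amino acids).
#' @export
profileVectors40 <- function(m, diagValue = 1) {
  x <- imputeMatrix(m, diagValue)
  out <- cbind(x, t(x))
  colnames(out) <- c(paste0("from.", AA20), paste0("to.", AA20))
  out
}

#' PCA of concatenated substitution profiles
#'
#' Centred (not scaled) principal component analysis of the 20x40 profile
#' matrix of an environment's substitution matrix. Component signs are fixed
#' by orienting each loading vector so its largest-magnitude loading is
#' positive, making results deterministic.
#'
#' @inheritParams imputeMatrix
#' @return List with `scores` (20 x k component scores), `loadings`,
#'   `explained` (variance ratios summing to 1).
#' @export
pcaProfiles <- function(m, diagValue = 1) {
  x <- profileVectors40(m, diagValue)
  if (all(apply(x, 2L, stats::sd) == 0)) stop("degenerate (zero-variance) input")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained = p$sdev^2 / sum(p$sdev^2))
}

#' Correlation of a helix substitution matrix with a propensity scale
#'
#' Builds the propensity substitution matrix `P[i, j] = ddg[i] - ddg[j]`
#' (reference minus variant helix propensity, kcal/mol) and returns the
#' Pearson correlation with the abundance matrix over defined off-diagonal
#' cells. The abundance matrix should be built from alpha-helix residues
#' only (`assignSs3(..., alphaOnly = TRUE)`).
#'
#' @param m A [SubstitutionMatrix-class] (alpha-helix environment).
#' @param scale Named numeric vector over [AA20]; default
#'   [helixPropensityScale()].
#' @return List with `r`, `n` (paired cells) and the propensity matrix `P`.
#' @export
helixPropensityCorrelation <- function(m, scale = helixPropensityScale()) {
  stopifnot(all(AA20 %in% names(scale)))
  P <- outer(scale[AA20], scale[AA20], `-`)
  dimnames(P) <- list(AA20, AA20)
  x <- m@mean
  off <- row(x) != col(x)
  ok <- off & !is.na(x)
  if (sum(ok) < 10L) stop("fewer than 10 defined paired cells")
  r <- if (stats::sd(P[ok]) == 0) {
    warning("propensity matrix has zero variance; correlation undefined")
    NA_real_
  } else stats::cor(x[ok], P[ok])
  list(r = r, n = sum(ok), P = P)
}

#' Substitution analysis of left-handed-helix-like loop residues
#'
#' Selects crystal-resolved loop residues whose backbone dihedrals fall in
#' the left-handed-helix window (0 < phi < 180, -90 < psi < 90; open
#' intervals), builds their substitution matrix, and summarises the mean
#' abundance score per variant amino acid across wild-type types (with the
#' standard deviation over all contributing scores) plus the per-wild-type
#' residue counts.
#'
#' @inheritParams buildMatrix
#' @return List with `matrix` ([SubstitutionMatrix-class], scheme
#'   `"custom"`), `byVariant` (data.frame `aa`, `mean_score`, `sd_score`,
#'   `n_scores`), `residueCounts` (per wild-type amino acid), and
#'   `positions` (selected residues).
#' @export
lefthandedLoopAnalysis <- function(pool, features) {
  sel <- !is.na(features$ss3) & features$ss3 == "loop" &
    features$crystal_resolved &
    !is.na(features$phi) & features$phi > 0 & features$phi < 180 &
    !is.na(features$psi) & features$psi > -90 & features$psi < 90
  if (!any(sel)) stop("no loop residues in the left-handed-helix dihedral window")
  fsel <- features[sel, , drop = FALSE]
  key <- paste(fsel$protein, fsel$position)
  rec <- pool@records
  rec <- rec[paste(rec$protein, rec$position) %in% key, , drop = FALSE]
  st <- cellStats(rec)
  mat <- new("SubstitutionMatrix", scheme = "custom",
             label = "loop-lefthanded", mean = st$mean, count = st$count,
             sd = st$sd)
  byVar <- do.call(rbind, lapply(split(rec$score, factor(rec$var, levels = AA20)),
                                 function(s) data.frame(mean_score = mean(s),
                                                        sd_score = stats::sd(s),
                                                        n_scores = length(s))))
  byVar <- cbind(aa = AA20, byVar)
  rownames(byVar) <- NULL
  counts <- table(factor(fsel$wt, levels = AA20))
  list(matrix = mat, byVariant = byVar,
       residueCounts = as.data.frame(counts, responseName = "n_residues",
                                     stringsAsFactors = FALSE),
       positions = fsel[, c("protein", "position", "wt", "phi", "psi")])
}
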