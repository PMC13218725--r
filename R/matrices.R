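#' Classify residues as buried or exposed
#'
#' A residue is buried iff `rasa <= cRasa` and `wcn >= cWcn`; otherwise it is
#' exposed. With the default `cWcn = 0` this reduces exactly to the
#' rASA-only rule (buried iff `rasa <= 0.1`), which is the classification
#' used throughout unless a cutoff scan is being performed.
#'
#' @param rasa,wcn Numeric vectors (recycled).
#' @param cRasa rASA cutoff (default 0.1).
#' @param cWcn WCN cutoff (default 0; any non-negative WCN passes).
#' @return Character vector over `{"buried", "exposed"}`.
#' @export
classifyResidue <- function(rasa, wcn, cRasa = 0.1, cWcn = 0) {
  stopifnot(all(is.finite(rasa)), all(is.finite(wcn)))
  ifelse(rasa <= cRasa & wcn >= cWcn, "buried", "exposed")
}

schemeLabels <- function(scheme) {
  switch(scheme,
    global    = "all",
    exposure  = c("buried", "exposed"),
    secondary = c("helix", "strand", "loop"),
    combined  = as.vector(outer(c("buried", "exposed"),
                                c("helix", "strand", "loop"), paste, sep = "-")),
    stop(sprintf("unknown scheme '%s'", scheme)))
}

# Environment label of each feature row under a scheme. NA when the needed
# descriptor is missing (such residues belong to no matrix of the scheme).
environmentLabels <- function(features, scheme, cRasa = 0.1, cWcn = 0) {
  if (scheme == "global") return(rep("all", nrow(features)))
  exp_ <- classifyResidue(features$rasa, features$wcn, cRasa, cWcn)
  lab <- switch(scheme,
    exposure  = exp_,
    secondary = features$ss3,
    combined  = ifelse(is.na(features$ss3), NA_character_,
                       paste(exp_, features$ss3, sep = "-")))
  lab
}

# Attach the wt-residue environment label (and rasa/wcn) to each pool record.
joinEnvironment <- function(pool, features, scheme, cRasa = 0.1, cWcn = 0) {
  rec <- pool@records
  fkey <- paste(features$protein, features$position)
  rkey <- paste(rec$protein, rec$position)
  m <- match(rkey, fkey)
  rec$env <- environmentLabels(features, scheme, cRasa, cWcn)[m]
  rec$rasa <- features$rasa[m]
  rec$wcn <- features$wcn[m]
  rec
}

cellStats <- function(rec) {
  if (!nrow(rec)) {
    return(list(mean = emptyAaMatrix(), count = emptyAaMatrix(0),
                sd = emptyAaMatrix()))
  }
  f <- factor(paste(rec$wt, rec$var), levels = as.vector(outer(AA20, AA20, paste)))
  n <- as.vector(table(f))
  s1 <- rowsum(rec$score, f)[, 1L]
  s1full <- numeric(400); names(s1full) <- levels(f)
  s1full[names(s1)] <- s1
  s2 <- rowsum(rec$score^2, f)[, 1L]
  s2full <- numeric(400); names(s2full) <- levels(f)
  s2full[names(s2)] <- s2
  mn <- ifelse(n > 0, s1full / n, NA_real_)
  vr <- ifelse(n > 1, (s2full - n * mn^2) / (n - 1), NA_real_)
  vr[!is.na(vr) & vr < 0] <- 0
  # level index = wt + 20*(var-1): wt varies fastest, matching column-major
  # fill of a [wt, var] matrix
  list(mean = matrix(mn, 20L, 20L, dimnames = list(AA20, AA20)),
       count = matrix(n, 20L, 20L, dimnames = list(AA20, AA20)),
       sd = matrix(sqrt(vr), 20L, 20L, dimnames = list(AA20, AA20)))
}

#' Build one environment-conditioned substitution matrix
#'
#' Averages all pooled scores for each wild-type -> variant substitution type
#' over records whose wild-type residue carries the requested environment
#' label, optionally excluding whole proteins (the leave-one-protein-out
#' primitive). Records at positions without features are ignored.
#'
#' @param pool A [VariantPool-class] of filtered records.
#' @param features Feature table covering the pool's residues (rows from
#'   [computeFeatures()], possibly concatenated across proteins).
#' @param scheme One of `"global"`, `"exposure"`, `"secondary"`, `"combined"`.
#' @param label Environment label within the scheme (see the scheme's label
#'   set; `"all"` for global).
#' @param excludeProteins Protein ids whose records are left out.
#' @param cRasa,cWcn Burial cutoffs for exposure-based labels.
#' @return A [SubstitutionMatrix-class].
#' @export
buildMatrix <- function(pool, features, scheme = "exposure", label = "buried",
                        excludeProteins = character(), cRasa = 0.1, cWcn = 0) {
  if (!label %in% schemeLabels(scheme))
    stop(sprintf("label '%s' is not in scheme '%s'", label, scheme))
  rec <- joinEnvironment(pool, features, scheme, cRasa, cWcn)
  rec <- rec[!is.na(rec$env) & rec$env == label &
               !(rec$protein %in% excludeProteins), , drop = FALSE]
  st <- cellStats(rec)
  new("SubstitutionMatrix", scheme = scheme, label = label,
      mean = st$mean, count = st$count, sd = st$sd)
}

#' Build the full matrix set of a conditioning scheme
#'
#' Returns 1 (global), 2 (exposure), 3 (secondary) or 6 (combined) matrices;
#' the labels partition the residues, so each record contributes to exactly
#' one matrix (records whose residues lack the needed descriptor contribute
#' to none).
#'
#' @inheritParams buildMatrix
#' @return Named list of [SubstitutionMatrix-class].
#' @export
buildMatrixSet <- function(pool, features, scheme = "exposure",
                           excludeProteins = character(), cRasa = 0.1,
                           cWcn = 0) {
  labs <- schemeLabels(scheme)
  out <- lapply(labs, function(l)
    buildMatrix(pool, features, scheme, l, excludeProteins, cRasa, cWcn))
  names(out) <- labs
  out
}

#' Substitution-matrix asymmetry
#'
#' `mean - t(mean)`: how differently X -> Y substitutions score compared to
#' Y -> X. Missing wherever either direction is missing.
#'
#' @param m A [SubstitutionMatrix-class].
#' @return 20x20 numeric matrix (antisymmetric where defined).
#' @export
asymmetry <- function(m) {
  stopifnot(is(m, "SubstitutionMatrix"))
  m@mean - t(m@mean)
}

#' Elementwise difference of two substitution matrices
#'
#' @param a,b [SubstitutionMatrix-class] objects over the same residue order.
#' @return 20x20 numeric matrix `a - b`, missing where either is missing.
#' @export
matrixDifference <- function(a, b) {
  stopifnot(is(a, "SubstitutionMatrix"), is(b, "SubstitutionMatrix"))
  if (!identical(dimnames(a@mean), dimnames(b@mean)))
    stop("matrices have different residue orders")
  a@mean - b@mean
}
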