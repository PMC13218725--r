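#' Sigmoidal contact weight
#'
#' The distance weight used by the weighted contact number,
#' `s(r) = (1 - (r/r0)^6) / (1 - (r/r0)^12)`, evaluated through the
#' algebraically equivalent `1 / (1 + (r/r0)^6)` which removes the removable
#' singularity at `r = r0` (where the limit is 1/2).
#'
#' @param r Distance(s), Angstrom.
#' @param r0 Midpoint distance (default 7 Angstrom).
#' @param form `"simplified"` (default) or `"rational"` (the raw two-term
#'   ratio; undefined at `r = r0`), kept for numerical cross-checks.
#' @return Weight(s) in (0, 1].
#' @export
wcnKernel <- function(r, r0 = 7, form = c("simplified", "rational")) {
  form <- match.arg(form)
  x <- r / r0
  if (form == "simplified") 1 / (1 + x^6)
  else (1 - x^6) / (1 - x^12)
}

#' Weighted contact number per residue
#'
#' `WCN_i = sum_{j != i} s(r_ij)` where `r_ij` is the shortest heavy-atom
#' distance between the side chains of residues i and j; when either residue
#' is glycine (or has no side-chain atoms), the shortest distance over all
#' atom pairs of the two residues is used instead. Contacts are evaluated
#' against every residue present in `atoms` (i.e. the full assembly).
#'
#' @param atoms Atom table from [readStructure()].
#' @param chain Chain id to report residues for.
#' @param r0 Kernel midpoint (Angstrom).
#' @return data.frame with `chain`, `position`, `wt`, `wcn`.
#' @export
computeWcn <- function(atoms, chain = "A", r0 = 7) {
  resKey <- paste(atoms$chain, atoms$resno)
  resIds <- unique(resKey)
  if (length(resIds) < 2L) stop("WCN requires at least two residues")
  idx <- split(seq_len(nrow(atoms)), factor(resKey, levels = resIds))
  isSide <- !(atoms$elety %in% BACKBONE_ATOMS)
  sideIdx <- lapply(idx, function(ii) {
    s <- ii[isSide[ii]]
    if (length(s)) s else ii            # glycine / no side chain: all atoms
  })
  useAll <- vapply(idx, function(ii) !any(isSide[ii]), TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  nRes <- length(resIds)
  minD <- matrix(Inf, nRes, nRes)
  for (i in seq_len(nRes)) {
    ai <- if (useAll[i]) idx[[i]] else sideIdx[[i]]
    for (j in seq_len(nRes)) {
      if (j <= i) next
      aj <- if (useAll[i] || useAll[j]) idx[[j]] else sideIdx[[j]]
      bi <- if (useAll[i] || useAll[j]) idx[[i]] else ai
      d2 <- outer(rowSums(xyz[bi, , drop = FALSE]^2),
                  rowSums(xyz[aj, , drop = FALSE]^2), `+`) -
        2 * xyz[bi, , drop = FALSE] %*% t(xyz[aj, , drop = FALSE])
      minD[i, j] <- minD[j, i] <- sqrt(max(0, min(d2)))
    }
  }
  w <- wcnKernel(minD, r0 = r0)
  diag(w) <- 0
  wcn <- rowSums(w)
  firstAtom <- vapply(idx, `[`, 1L, 1L)
  keep <- atoms$chain[firstAtom] == chain
  data.frame(chain = chain, position = atoms$resno[firstAtom][keep],
             wt = atoms$aa[firstAtom][keep], wcn = wcn[keep],
             stringsAsFactors = FALSE)
}
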