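# Numerical solvent accessible surface area (rolling-probe, Shrake-Rupley
# style). Heavy atoms only; per-atom areas are obtained by scattering points
# on the probe-extended sphere of each atom and counting points not covered
# by any neighbouring extended sphere.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Per-atom solvent accessible surface area
#'
#' @param atoms Atom table from [readStructure()] (or any data.frame with
#'   `x`, `y`, `z`, `elem`).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param nPoints Sphere points per atom; accuracy is ~1-2% at the default.
#' @return Numeric vector of per-atom areas (Angstrom^2).
#' @export
atomSasa <- function(atoms, probe = 1.4, nPoints = 192L) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  R <- atomRadii(atoms) + probe
  pts <- fibonacciSphere(nPoints)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (R[i] + R)^2 & d2 > 1e-12)
    sp <- pts * R[i]
    sp <- sweep(sp, 2L, xyz[i, ], `+`)
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      dj2 <- (sp[, 1L] - xyz[j, 1L])^2 + (sp[, 2L] - xyz[j, 2L])^2 +
        (sp[, 3L] - xyz[j, 3L])^2
      free <- free & dj2 >= R[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  area
}

#' Relative solvent accessibility per residue
#'
#' Computes absolute per-residue SASA (sum over the residue's heavy atoms,
#' evaluated in the context of all chains present in `atoms`) and divides by
#' the residue type's theoretical maximum accessibility to give rASA.
#'
#' @param atoms Atom table from [readStructure()]; pass the full assembly for
#'   assembly-context burial.
#' @param chain Chain id to report residues for (context still includes all
#'   chains).
#' @param maxAsa Named numeric vector of per-residue-type maximum areas
#'   (Angstrom^2); defaults to [maxAsaTable()]. Must cover every residue type
#'   present in `chain`.
#' @param probe,nPoints Passed to [atomSasa()].
#' @return data.frame with `chain`, `position`, `wt`, `asa`, `rasa`.
#' @export
computeRasa <- function(atoms, chain = "A", maxAsa = maxAsaTable(),
                        probe = 1.4, nPoints = 192L) {
  if (!any(atoms$chain == chain))
    stop(sprintf("chain '%s' absent from structure", chain))
  area <- atomSasa(atoms, probe = probe, nPoints = nPoints)
  sel <- atoms$chain == chain
  key <- atoms$resno[sel]
  asa <- rowsum(area[sel], key)
  resno <- as.integer(rownames(asa))
  aa <- atoms$aa[sel][match(resno, key)]
  if (any(is.na(aa)))
    stop("residue type(s) outside the canonical 20 in requested chain")
  mx <- maxAsa[aa]
  if (any(is.na(mx)))
    stop(sprintf("maxAsa table lacks residue type(s): %s",
                 paste(unique(aa[is.na(mx)]), collapse = ", ")))
  data.frame(chain = chain, position = resno, wt = aa,
             asa = as.numeric(asa), rasa = as.numeric(asa) / unname(mx),
             stringsAsFactors = FALSE)
}
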