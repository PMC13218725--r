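#' Read and clean a protein structure
#'
#' Reads a PDB file via bio3d and applies the standard cleaning used
#' throughout the package: HETATM records (waters, ligands, ions, co-factors)
#' and hydrogens are removed, and alternate locations are resolved to the
#' highest-occupancy (then first-encountered) conformer. All chains present
#' are retained so that downstream descriptors can be computed in the context
#' of the full assembly.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector restricting to these chain ids
#'   (e.g. `"A"` to derive a monomer from a dimer file; coordinates of the
#'   retained chain are untouched).
#' @return A data.frame of heavy atoms with columns `chain`, `resno`,
#'   `resid` (three-letter), `aa` (one-letter), `elety`, `elem`, `x`, `y`,
#'   `z`, `o`.
#' @export
readStructure <- function(path, chains = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  elem <- toupper(trimws(elem))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  # resolve altloc: highest occupancy, then first encountered
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    elem <- elem[ord]
    keep <- !duplicated(paste(at$chain, at$resno, at$elety))
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
    ord2 <- order(at$chain, at$resno)
    at <- at[ord2, , drop = FALSE]
    elem <- elem[ord2]
  }
  aa <- unname(THREE_TO_ONE[at$resid])
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    aa = aa, elety = trimws(at$elety), elem = elem,
                    x = at$x, y = at$y, z = at$z,
                    o = ifelse(is.na(at$o), 1, at$o),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

atomRadii <- function(atoms) {
  tab <- vdwRadii()
  r <- tab[atoms$elem]
  r[is.na(r)] <- tab[["C"]]
  unname(r)
}
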