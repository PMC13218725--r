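#' Compute the per-residue structural feature table
#'
#' Runs the package's descriptor stack on one chain of a (cleaned) structure:
#' relative solvent accessibility ([computeRasa()], in the context of all
#' chains present), weighted contact number ([computeWcn()]), backbone
#' dihedrals ([computeDihedrals()]), and 3-class secondary structure (from a
#' DSSP file when supplied, else `NA`).
#'
#' @param atoms Atom table from [readStructure()]; include all chains of the
#'   assembly for assembly-context burial.
#' @param protein Protein id stamped on every row.
#' @param chain Chain to report.
#' @param dssp Optional DSSP file path for secondary structure.
#' @param ss Optional data.frame with `position`, `ss8` (and optionally
#'   `ss3`) overriding/bypassing `dssp` (used for synthetic ground truth).
#' @param crystalResolved Optional integer vector of crystal-resolved
#'   positions; residues outside it get `crystal_resolved = FALSE`. `NULL`
#'   marks all residues resolved.
#' @param r0 WCN kernel midpoint (Angstrom).
#' @param probe,nPoints SASA parameters.
#' @param maxAsa Max-ASA normalisation table passed to [computeRasa()]
#'   (use [syntheticMaxAsa()] for generator output).
#' @return data.frame with `protein`, `chain`, `position`, `wt`, `rasa`,
#'   `wcn`, `ss3`, `ss8`, `phi`, `psi`, `crystal_resolved`.
#' @export
computeFeatures <- function(atoms, protein, chain = "A", dssp = NULL,
                            ss = NULL, crystalResolved = NULL, r0 = 7,
                            probe = 1.4, nPoints = 192L,
                            maxAsa = maxAsaTable()) {
  ra <- computeRasa(atoms, chain = chain, maxAsa = maxAsa, probe = probe,
                    nPoints = nPoints)
  wc <- computeWcn(atoms, chain = chain, r0 = r0)
  di <- suppressWarnings(computeDihedrals(atoms, chain = chain))
  out <- merge(ra[, c("position", "wt", "rasa")],
               wc[, c("position", "wcn")], by = "position", all.x = TRUE)
  out <- merge(out, di[, c("position", "phi", "psi")],
               by = "position", all.x = TRUE)
  out$ss8 <- NA_character_
  out$ss3 <- NA_character_
  if (!is.null(dssp)) {
    sstab <- assignSs3(dssp, chain = chain)
    m <- match(out$position, sstab$position)
    out$ss8 <- sstab$ss8[m]
    out$ss3 <- sstab$ss3[m]
  }
  if (!is.null(ss)) {
    m <- match(out$position, ss$position)
    out$ss8 <- ss$ss8[m]
    out$ss3 <- if ("ss3" %in% names(ss)) ss$ss3[m] else ss3FromSs8(out$ss8)
  }
  out$crystal_resolved <- if (is.null(crystalResolved)) TRUE
                          else out$position %in% crystalResolved
  cbind(protein = protein, chain = chain,
        out[order(out$position),
            c("position", "wt", "rasa", "wcn", "ss3", "ss8", "phi", "psi",
              "crystal_resolved")],
        stringsAsFactors = FALSE)
}

#' Identify homodimer-interface residues from monomer/dimer burial change
#'
#' Flags residues that are solvent-exposed in the monomer (rASA > `cRasa`),
#' buried in the dimer (rASA <= `cRasa`), and whose rASA drops by more than
#' `deltaMin` upon dimerisation (filtering out residues that change class
#' through a minor rASA change at the cutoff boundary).
#'
#' @param featuresMonomer,featuresDimer Feature tables (from
#'   [computeFeatures()]) for the same chain computed without and with the
#'   partner chain; positions must match.
#' @param deltaMin Minimum monomer-to-dimer rASA drop (default 0.01).
#' @param cRasa Burial cutoff (default 0.1).
#' @return data.frame with `position`, `wt`, `rasa_monomer`, `rasa_dimer`,
#'   `delta_rasa`, `is_interface`.
#' @export
findInterface <- function(featuresMonomer, featuresDimer, deltaMin = 0.01,
                          cRasa = 0.1) {
  if (!setequal(featuresMonomer$position, featuresDimer$position))
    stop("monomer and dimer feature tables cover different positions")
  m <- featuresMonomer[order(featuresMonomer$position), ]
  d <- featuresDimer[match(m$position, featuresDimer$position), ]
  delta <- m$rasa - d$rasa
  data.frame(position = m$position, wt = m$wt,
             rasa_monomer = m$rasa, rasa_dimer = d$rasa, delta_rasa = delta,
             is_interface = m$rasa > cRasa & d$rasa <= cRasa & delta > deltaMin,
             stringsAsFactors = FALSE)
}
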