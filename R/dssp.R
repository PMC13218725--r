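#' Read a DSSP secondary-structure file
#'
#' Parses the classic fixed-width DSSP output format (the data block after
#' the `#  RESIDUE AA` header). Chain-break records (`!`) are skipped.
#'
#' @param path Path to a DSSP file.
#' @param chain Optional chain id filter.
#' @return data.frame with `chain`, `position` (author numbering), `aa`,
#'   `ss8` (raw DSSP code; `" "` for irregular/loop).
#' @export
readDssp <- function(path, chain = NULL) {
  lines <- readLines(path)
  start <- grep("^\\s*#\\s+RESIDUE", lines)
  if (!length(start)) stop(sprintf("not a DSSP file (no residue header): %s", path))
  body <- lines[(start[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17L]
  aa <- substr(body, 14L, 14L)
  keep <- aa != "!"
  body <- body[keep]; aa <- aa[keep]
  resno <- suppressWarnings(as.integer(trimws(substr(body, 6L, 10L))))
  ch <- substr(body, 12L, 12L)
  ss8 <- substr(body, 17L, 17L)
  if (any(is.na(resno))) stop("unparseable residue number(s) in DSSP file")
  out <- data.frame(chain = ch, position = resno, aa = aa, ss8 = ss8,
                    stringsAsFactors = FALSE)
  if (!is.null(chain)) out <- out[out$chain == chain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map 8-class secondary structure codes to 3 classes
#'
#' Helix is alpha-, 3-10- and pi-helix (`H`, `G`, `I`); strand is extended
#' strand and isolated beta-bridge (`E`, `B`); everything else
#' (hydrogen-bonded turn `T`, bend `S`, the newer PP-helix code `P`, and
#' blank/irregular) is loop. With `alphaOnly = TRUE` only `H` counts as
#' helix (the restriction used for the helix-propensity analysis); `G` and
#' `I` then fall into loop.
#'
#' @param ss8 Character vector of DSSP codes.
#' @param alphaOnly Restrict helix to alpha-helix (`H`).
#' @return Character vector over `{"helix", "strand", "loop"}`.
#' @export
ss3FromSs8 <- function(ss8, alphaOnly = FALSE) {
  helixCodes <- if (alphaOnly) "H" else c("H", "G", "I")
  known <- c("H", "G", "I", "E", "B", "T", "S", "P", " ", "-", "C", "")
  if (any(!ss8 %in% known))
    stop(sprintf("unknown secondary structure code(s): %s",
                 paste(unique(ss8[!ss8 %in% known]), collapse = ", ")))
  out <- rep("loop", length(ss8))
  out[ss8 %in% helixCodes] <- "helix"
  out[ss8 %in% c("E", "B")] <- "strand"
  out
}

#' Per-residue 3-class secondary structure from a DSSP file
#'
#' @param path DSSP file path.
#' @param chain Chain id.
#' @param positions Optional positions that must all be present (unmapped
#'   positions are an error).
#' @param alphaOnly Passed to [ss3FromSs8()].
#' @return data.frame with `chain`, `position`, `ss8`, `ss3`.
#' @export
assignSs3 <- function(path, chain = "A", positions = NULL, alphaOnly = FALSE) {
  d <- readDssp(path, chain = chain)
  if (!is.null(positions)) {
    miss <- setdiff(positions, d$position)
    if (length(miss))
      stop(sprintf("position(s) absent from DSSP assignment: %s",
                   paste(utils::head(miss, 5L), collapse = ", ")))
  }
  d$ss3 <- ss3FromSs8(d$ss8, alphaOnly = alphaOnly)
  d[, c("chain", "position", "ss8", "ss3")]
}

#' Coarse phi/psi-based secondary structure (synthetic fixtures only)
#'
#' A deliberately simple Ramachandran-window assigner used to label synthetic
#' structures that have no hydrogen-bond pattern to analyse. It is NOT a DSSP
#' replacement and is not used on real structures anywhere in the package.
#'
#' @param phi,psi Backbone dihedrals in degrees (NA allowed).
#' @return Character vector over `{"helix", "strand", "loop"}` (`NA` in,
#'   `"loop"` out).
#' @export
ss3FromDihedrals <- function(phi, psi) {
  out <- rep("loop", length(phi))
  h <- !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 & psi > -80 & psi < -5
  e <- !is.na(phi) & !is.na(psi) & phi > -180 & phi < -90 & psi > 90 & psi <= 180
  out[h] <- "helix"
  out[e] <- "strand"
  out
}
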