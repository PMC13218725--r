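#' @import methods
NULL

recordColumns <- c("chain", "position", "wt", "var", "score", "sd")

validRecords <- function(rec, requireMissense = FALSE) {
  msg <- character()
  missing <- setdiff(recordColumns, names(rec))
  if (length(missing))
    return(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(rec)) {
    if (!is.numeric(rec$position) || any(rec$position < 1L | rec$position != round(rec$position)))
      msg <- c(msg, "positions must be integers >= 1")
    if (!all(rec$wt %in% AA20))
      msg <- c(msg, "wt residues must be canonical one-letter codes")
    if (requireMissense && any(rec$wt == rec$var))
      msg <- c(msg, "synonymous records present after filtering")
    if (any(!is.finite(rec$score)))
      msg <- c(msg, "scores must be finite")
    if (any(!is.na(rec$sd) & rec$sd < 0))
      msg <- c(msg, "score standard deviations must be >= 0")
    key <- variantKey("", rec$position, rec$wt, rec$var)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (position, wt, var) keys")
  }
  if (length(msg)) msg else TRUE
}

#' AbundanceDataset: one protein's variant abundance scores
#'
#' Container for the parsed variant abundance table of a single protein.
#' Scores follow the usual abundance normalisation (0 ~ nonsense-like, 1 ~
#' wild-type-like, unbounded). Positions use the 1-based author numbering of
#' the accompanying structure.
#'
#' @slot proteinId Single protein identifier.
#' @slot records data.frame with columns `chain`, `position`, `wt`, `var`,
#'   `score`, `sd`. `var` may contain `"*"` (nonsense) or equal `wt`
#'   (synonymous) until [filterSubstitutions()] is applied.
#' @slot nResidues Protein length considered (for completeness statistics);
#'   `NA` when unknown.
#' @slot metadata Free-form list (structure paths, excluded ranges, ...).
#'
#' @seealso [readScoreTable()], [filterSubstitutions()], [datasetSummary()]
#' @export
setClass("AbundanceDataset",
  representation(proteinId = "character", records = "data.frame",
                 nResidues = "integer", metadata = "list"),
  prototype(proteinId = NA_character_,
            records = data.frame(chain = character(), position = integer(),
                                 wt = character(), var = character(),
                                 score = numeric(), sd = numeric()),
            nResidues = NA_integer_, metadata = list()),
  validity = function(object) {
    if (length(object@proteinId) != 1L) return("proteinId must be length 1")
    validRecords(object@records)
  })

#' VariantPool: combined multi-protein record pool
#'
#' The pool produced by [combineDatasets()]: the concatenation (no rescaling)
#' of several proteins' filtered variant records, indexed by protein.
#'
#' @slot records data.frame with columns `protein`, `chain`, `position`,
#'   `wt`, `var`, `score`, `sd`.
#' @slot proteins Character vector of the unique protein ids in the pool.
#'
#' @seealso [combineDatasets()], [buildMatrix()], [predictLopo()]
#' @export
setClass("VariantPool",
  representation(records = "data.frame", proteins = "character"),
  prototype(records = data.frame(protein = character(), chain = character(),
                                 position = integer(), wt = character(),
                                 var = character(), score = numeric(),
                                 sd = numeric()),
            proteins = character()),
  validity = function(object) {
    rec <- object@records
    if (!"protein" %in% names(rec)) return("records lack `protein` column")
    if (!setequal(unique(rec$protein), object@proteins) &&
        nrow(rec) > 0L)
      return("`proteins` slot out of sync with records")
    v <- validRecords(rec[, setdiff(names(rec), "protein")])
    if (!isTRUE(v)) {
      # duplicates must be judged within protein, recheck
      v <- v[!grepl("duplicate", v)]
      key <- variantKey(rec$protein, rec$position, rec$wt, rec$var)
      if (anyDuplicated(key)) v <- c(v, "duplicate variant keys within a protein")
      if (length(v)) return(v)
    }
    TRUE
  })

#' SubstitutionMatrix: environment-conditioned mean-abundance matrix
#'
#' A 20x20 matrix of mean abundance scores for wild-type (rows) to variant
#' (columns) substitutions, with a parallel count matrix, restricted to
#' residues in one structural environment. Diagonal (synonymous) cells are
#' structurally missing; they are set to 1 only at the entry point of
#' clustering/PCA.
#'
#' @slot scheme Conditioning scheme (`"global"`, `"exposure"`, `"secondary"`,
#'   `"combined"`, or `"custom"`).
#' @slot label Environment label within the scheme (e.g. `"buried"`,
#'   `"exposed-helix"`, `"all"`).
#' @slot mean 20x20 numeric matrix of arithmetic mean scores; `NA` where no
#'   score contributes.
#' @slot count 20x20 matrix of contributing score counts.
#' @slot sd 20x20 matrix of per-cell score standard deviations (`NA` for
#'   counts < 2); used for standard errors of cell means.
#'
#' @seealso [buildMatrix()], [buildMatrixSet()], [asymmetry()]
#' @export
setClass("SubstitutionMatrix",
  representation(scheme = "character", label = "character",
                 mean = "matrix", count = "matrix", sd = "matrix"),
  validity = function(object) {
    msg <- character()
    for (s in c("mean", "count", "sd")) {
      m <- slot(object, s)
      if (!identical(dim(m), c(20L, 20L)) ||
          !identical(rownames(m), AA20) || !identical(colnames(m), AA20))
        msg <- c(msg, sprintf("`%s` must be 20x20 with AA20 dimnames", s))
    }
    if (!length(msg)) {
      if (any(diag(object@count) != 0))
        msg <- c(msg, "diagonal (synonymous) counts must be zero")
      if (!identical(is.na(object@mean), object@count == 0))
        msg <- c(msg, "mean must be NA exactly where count is zero")
      if (any(object@count < 0)) msg <- c(msg, "counts must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "AbundanceDataset", function(object) {
  cat(sprintf("AbundanceDataset '%s': %d records, %s residues considered\n",
              object@proteinId, nrow(object@records),
              ifelse(is.na(object@nResidues), "?", object@nResidues)))
})

setMethod("show", "VariantPool", function(object) {
  cat(sprintf("VariantPool: %d records across %d proteins (%s)\n",
              nrow(object@records), length(object@proteins),
              paste(object@proteins, collapse = ", ")))
})

setMethod("show", "SubstitutionMatrix", function(object) {
  n <- sum(object@count)
  cat(sprintf("SubstitutionMatrix [%s/%s]: %d scores, %d/380 cells defined\n",
              object@scheme, object@label, n, sum(!is.na(object@mean)) ))
})

#' @describeIn AbundanceDataset-class Access the record table.
#' @param x An `AbundanceDataset` or `VariantPool`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
setMethod("records", "AbundanceDataset", function(x) x@records)
#' @describeIn VariantPool-class Access the pooled record table.
#' @export
setMethod("records", "VariantPool", function(x) x@records)

#' @describeIn AbundanceDataset-class Protein identifier(s).
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
setMethod("proteinIds", "AbundanceDataset", function(x) x@proteinId)
#' @describeIn VariantPool-class Protein identifiers in the pool.
#' @export
setMethod("proteinIds", "VariantPool", function(x) x@proteins)

#' @describeIn SubstitutionMatrix-class Mean-score matrix.
#' @param x A `SubstitutionMatrix`.
#' @export
setGeneric("matrixMean", function(x) standardGeneric("matrixMean"))
setMethod("matrixMean", "SubstitutionMatrix", function(x) x@mean)

#' @describeIn SubstitutionMatrix-class Count matrix.
#' @export
setGeneric("matrixCount", function(x) standardGeneric("matrixCount"))
setMethod("matrixCount", "SubstitutionMatrix", function(x) x@count)

#' @describeIn SubstitutionMatrix-class Environment label ("scheme/label").
#' @export
setGeneric("envLabel", function(x) standardGeneric("envLabel"))
setMethod("envLabel", "SubstitutionMatrix",
          function(x) paste(x@scheme, x@label, sep = "/"))
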