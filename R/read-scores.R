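#' Read a per-protein variant abundance score table
#'
#' Parses a CSV/TSV score table into an [AbundanceDataset-class]. Variant
#' notation is configurable via `dialect`: either three explicit columns
#' (wild-type residue, position, variant residue) or a single HGVS-like
#' column such as `"p.A123V"` / `"A123V"` (with `"*"`, `"X"` or `"Ter"` as
#' the stop symbol). Rows whose variant cannot be parsed are dropped with a
#' warning; duplicate (position, wt, var) keys are an error. Nonsense and
#' synonymous rows are retained here and removed by [filterSubstitutions()].
#'
#' @param path Path to the delimited file.
#' @param proteinId Protein identifier recorded on every row.
#' @param dialect Named list mapping roles to column names. Either
#'   `list(wt=, position=, var=, score=, sd=)` or
#'   `list(variant=, score=, sd=)` for one-column notation. `sd` and
#'   `chain` are optional; `chain` defaults to `"A"`.
#' @param nResidues Protein length considered (used by [datasetSummary()]).
#' @param sep Field separator; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param metadata Optional list stored on the dataset (structure paths,
#'   excluded ranges, ...).
#' @return An [AbundanceDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(variant = c("p.A5V", "p.A5*"), score = c(0.62, 0.01),
#'                      sd = c(0.04, 0.02)), tf, row.names = FALSE)
#' ds <- readScoreTable(tf, "toy", dialect = list(variant = "variant",
#'                      score = "score", sd = "sd"), nResidues = 10)
#' records(ds)
#' @export
readScoreTable <- function(path, proteinId,
                           dialect = list(wt = "wt", position = "position",
                                          var = "var", score = "score",
                                          sd = "sd"),
                           nResidues = NA_integer_, sep = NULL,
                           metadata = list()) {
  if (!file.exists(path)) stop(sprintf("score table not found: %s", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- function(role) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(tab))
      stop(sprintf("dialect role '%s' does not resolve to a column", role))
    tab[[col]]
  }
  optional <- function(role, default) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(tab)) rep(default, nrow(tab))
    else tab[[col]]
  }

  if (!is.null(dialect$variant)) {
    raw <- as.character(need("variant"))
    s <- sub("^p\\.", "", raw)
    s <- sub("(Ter|\\*)$", "*", s)
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))
    ok <- lengths(m) == 4L
    if (any(!ok)) {
      warning(sprintf("dropped %d row(s) with unparseable variant notation (e.g. '%s')",
                      sum(!ok), raw[!ok][1L]))
    }
    wt <- vapply(m[ok], `[`, "", 2L)
    position <- as.integer(vapply(m[ok], `[`, "", 3L))
    var <- vapply(m[ok], `[`, "", 4L)
    score <- as.numeric(need("score"))[ok]
    sd <- as.numeric(optional("sd", NA_real_))[ok]
    chain <- as.character(optional("chain", "A"))[ok]
  } else {
    wt <- toupper(as.character(need("wt")))
    var <- toupper(as.character(need("var")))
    # tolerate three-letter codes
    wt <- ifelse(nchar(wt) == 3L, THREE_TO_ONE[wt], wt)
    var3 <- var %in% names(THREE_TO_ONE)
    var[var3] <- THREE_TO_ONE[var[var3]]
    var[var %in% c("TER")] <- "*"
    position <- as.integer(need("position"))
    score <- as.numeric(need("score"))
    sd <- as.numeric(optional("sd", NA_real_))
    chain <- as.character(optional("chain", "A"))
    bad <- is.na(position) | !(wt %in% AA20) | !(var %in% c(AA20, "*"))
    if (any(bad)) {
      if (all(!wt[bad] %in% AA20))
        stop("wild-type residues outside the canonical alphabet")
      warning(sprintf("dropped %d unparseable row(s)", sum(bad)))
    }
    keep <- !bad
    wt <- wt[keep]; var <- var[keep]; position <- position[keep]
    score <- score[keep]; sd <- sd[keep]; chain <- chain[keep]
  }
  checkAa(wt, "wild-type residue")
  checkAa(var, "variant residue", allowStop = TRUE)
  key <- variantKey(proteinId, position, wt, var)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate variant key in %s: %s", path, dup))
  }
  rec <- data.frame(chain = chain, position = position, wt = wt, var = var,
                    score = score, sd = sd, stringsAsFactors = FALSE)
  new("AbundanceDataset", proteinId = proteinId, records = rec,
      nResidues = as.integer(nResidues), metadata = metadata)
}

#' Restrict a dataset to single missense substitutions
#'
#' Removes synonymous (wt == var) and nonsense/stop records and records in
#' excluded position ranges (e.g. a transmembrane N-terminus), reporting the
#' number removed per category. Idempotent.
#'
#' @param ds An [AbundanceDataset-class].
#' @param excludedRanges Either `NULL`, a list of `c(start, end)` position
#'   intervals, or a 2-column matrix of intervals (inclusive).
#' @param verbose Emit a message with per-category removal counts.
#' @return The filtered [AbundanceDataset-class]; removal counts are stored in
#'   `metadata(...)$filter_counts`.
#' @export
filterSubstitutions <- function(ds, excludedRanges = NULL, verbose = FALSE) {
  stopifnot(is(ds, "AbundanceDataset"))
  rec <- ds@records
  if (is.null(excludedRanges))
    excludedRanges <- ds@metadata$excluded_ranges
  syn <- rec$wt == rec$var
  non <- rec$var %in% c("*", "X")
  inRange <- rep(FALSE, nrow(rec))
  if (!is.null(excludedRanges)) {
    if (is.matrix(excludedRanges))
      excludedRanges <- split(excludedRanges, row(excludedRanges)[, 1L])
    for (rg in excludedRanges)
      inRange <- inRange | (rec$position >= rg[1L] & rec$position <= rg[2L])
  }
  counts <- c(synonymous = sum(syn & !non), nonsense = sum(non),
              excluded_range = sum(inRange & !syn & !non))
  keep <- !(syn | non | inRange)
  if (verbose)
    message(sprintf("filterSubstitutions(%s): removed %d synonymous, %d nonsense, %d in excluded ranges",
                    ds@proteinId, counts[1L], counts[2L], counts[3L]))
  if (!any(keep)) warning(sprintf("no records remain for %s after filtering", ds@proteinId))
  md <- ds@metadata
  md$filter_counts <- counts
  initialize(ds, records = rec[keep, , drop = FALSE], metadata = md)
}

#' Min-max normalise a bin-weighted average to the abundance scale
#'
#' Maps a variant's weighted-average FACS bin signal onto the abundance score
#' scale anchored at the nonsense-variant average (score 0) and the wild-type
#' (synonymous) average (score 1):
#' `score = (wVar - wNonsense) / (wWt - wNonsense)`.
#' Published tables are already normalised and bypass this utility.
#'
#' @param wVar Weighted average for the variant (vectorised).
#' @param wNonsense Weighted average of nonsense variants.
#' @param wWt Weighted average of wild-type-like (synonymous) variants.
#' @return Normalised abundance score(s).
#' @export
normaliseFromBinWeights <- function(wVar, wNonsense, wWt) {
  if (any(wWt == wNonsense))
    stop("degenerate normalisation: wild-type and nonsense anchors coincide")
  (wVar - wNonsense) / (wWt - wNonsense)
}

#' Combine per-protein datasets into a pool
#'
#' Concatenates filtered datasets without any rescaling or transformation
#' into a [VariantPool-class] supporting per-protein and per-substitution
#' retrieval. The pooled record count equals the sum of the parts.
#'
#' @param datasets List of [AbundanceDataset-class] with unique protein ids.
#' @return A [VariantPool-class].
#' @export
combineDatasets <- function(datasets) {
  if (!length(datasets)) stop("cannot combine an empty list of datasets")
  ids <- vapply(datasets, function(d) d@proteinId, "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protein id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  recs <- lapply(datasets, function(d) {
    r <- d@records
    if (nrow(r)) cbind(protein = d@proteinId, r)
    else cbind(protein = character(), r)
  })
  pool <- do.call(rbind, recs)
  rownames(pool) <- NULL
  new("VariantPool", records = pool, proteins = ids)
}

#' Summarise a dataset's depth and completeness
#'
#' Mutational depth is the mean number of scores per position that has at
#' least one score; completeness is `100 * nRecords / (19 * nResidues)`.
#'
#' @param ds An [AbundanceDataset-class] (filtered) with known `nResidues`.
#' @return data.frame with `protein`, `n_records`, `n_positions`, `depth`,
#'   `completeness` (percent).
#' @export
datasetSummary <- function(ds) {
  stopifnot(is(ds, "AbundanceDataset"))
  n <- ds@nResidues
  if (is.na(n) || n <= 0L) stop("nResidues must be a positive integer")
  rec <- ds@records
  npos <- length(unique(rec$position))
  depth <- if (npos) nrow(rec) / npos else NA_real_
  data.frame(protein = ds@proteinId, n_records = nrow(rec),
             n_positions = npos, depth = depth,
             completeness = 100 * nrow(rec) / (19 * n),
             stringsAsFactors = FALSE)
}

#' Subset a pool by protein
#'
#' @param pool A [VariantPool-class].
#' @param proteins Protein ids to keep (or drop with `invert = TRUE`).
#' @param invert Drop instead of keep.
#' @return A [VariantPool-class].
#' @export
poolSubset <- function(pool, proteins, invert = FALSE) {
  stopifnot(is(pool, "VariantPool"))
  keepIds <- if (invert) setdiff(pool@proteins, proteins)
             else intersect(pool@proteins, proteins)
  rec <- pool@records[pool@records$protein %in% keepIds, , drop = FALSE]
  rownames(rec) <- NULL
  new("VariantPool", records = rec, proteins = keepIds)
}
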