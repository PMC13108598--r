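#' Multiple sequence alignment
#'
#' An `Msa` is a rectangular character matrix of aligned sequences: one row
#' per sequence, one column per alignment position.  Rows are named by unique
#' sequence identifiers.  The alphabet hint (`"nucleotide"`, `"amino-acid"`
#' or `"unknown"`) is advisory only: every feature computed by the package
#' has the same definition for nucleotide and amino-acid data.
#'
#' @slot chars Character matrix (sequences x columns) of single uppercase
#'   characters; `-`, `.` and `?` are gaps.
#' @slot alphabet One of `"nucleotide"`, `"amino-acid"`, `"unknown"`.
#'
#' @seealso [Msa()], [readMsa()], [computeFeatures()]
#' @exportClass Msa
setClass("Msa",
  representation(chars = "matrix", alphabet = "character"))

setValidity("Msa", function(object) {
  m <- object@chars
  if (!is.character(m) || !is.matrix(m)) {
    return("'chars' must be a character matrix")
  }
  if (nrow(m) < 1L) {
    return("an alignment needs at least one sequence")
  }
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids))) {
    return("every sequence needs a non-empty identifier")
  }
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate sequence identifier '%s'",
                   ids[duplicated(ids)][1L]))
  }
  if (length(m) && any(nchar(m) != 1L)) {
    return("'chars' must hold single characters")
  }
  if (length(object@alphabet) != 1L ||
      !object@alphabet %in% c("nucleotide", "amino-acid", "unknown")) {
    return("'alphabet' must be 'nucleotide', 'amino-acid' or 'unknown'")
  }
  TRUE
})

#' Construct an alignment from sequence strings
#'
#' @param sequences Character vector of equal-length aligned sequences
#'   (residues plus gap characters `-`, `.`, `?`).  Lowercase residues are
#'   normalised to uppercase.
#' @param ids Unique, non-empty sequence identifiers; defaults to
#'   `names(sequences)`.
#' @param alphabet Alphabet hint; `"guess"` (default) inspects the residues.
#'
#' @return An [Msa-class] object.
#' @examples
#' msa <- Msa(c(a = "AC-G", b = "ACTG"))
#' dim(msa)
#' @export
Msa <- function(sequences, ids = names(sequences),
                alphabet = c("guess", "nucleotide", "amino-acid", "unknown")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(sequences) || length(sequences) < 1L) {
    stop("'sequences' must be a non-empty character vector", call. = FALSE)
  }
  if (is.null(ids)) {
    stop("sequence identifiers are required", call. = FALSE)
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L) {
    bad <- ids[which(widths != widths[1L])[1L]]
    stop(sprintf("sequences are not aligned: '%s' has length %d, expected %d",
                 bad, nchar(sequences[widths != widths[1L]][1L]), widths[1L]),
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  L <- widths[1L]
  m <- matrix("", nrow = length(sequences), ncol = L,
              dimnames = list(as.character(ids), NULL))
  if (L > 0L) {
    m[] <- matrix(unlist(strsplit(sequences, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(sequences), byrow = TRUE)
  }
  if (alphabet == "guess") {
    alphabet <- guessAlphabet(m)
  }
  new("Msa", chars = m, alphabet = alphabet)
}

# Nucleotide if every residue is an unambiguous DNA/RNA letter.
guessAlphabet <- function(m) {
  res <- m[!(m %in% GAP_CHARS)]
  if (!length(res)) {
    return("unknown")
  }
  if (all(res %in% c("A", "C", "G", "T", "U", "N"))) "nucleotide"
  else "amino-acid"
}

#' @describeIn Msa Dimensions: `c(sequences, columns)`.
#' @param x An `Msa`.
#' @export
setMethod("dim", "Msa", function(x) dim(x@chars))

#' Sequence identifiers of an alignment
#' @param x An [Msa-class].
#' @return Character vector of identifiers.
#' @export
seqIds <- function(x) rownames(x@chars)

#' Character matrix of an alignment
#' @param x An [Msa-class].
#' @return The sequences-by-columns character matrix.
#' @export
msaMatrix <- function(x) x@chars

#' Sequence strings of an alignment
#' @param x An [Msa-class].
#' @return Named character vector, one aligned string per sequence.
#' @export
msaStrings <- function(x) {
  m <- x@chars
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

#' Keep a subset of alignment columns
#'
#' @param x An [Msa-class].
#' @param keep Logical vector of length `ncol(x)` (a mask) or an integer
#'   index of columns to keep, in increasing order.
#' @return The column-subset [Msa-class]; row order and identifiers are
#'   unchanged.
#' @export
msaSubsetColumns <- function(x, keep) {
  if (is.logical(keep)) {
    if (length(keep) != ncol(x@chars)) {
      stop(sprintf("mask length %d does not match alignment length %d",
                   length(keep), ncol(x@chars)), call. = FALSE)
    }
    keep <- which(keep)
  }
  new("Msa", chars = x@chars[, keep, drop = FALSE], alphabet = x@alphabet)
}

setMethod("show", "Msa", function(object) {
  d <- dim(object@chars)
  cat(sprintf("Msa: %d sequence%s x %d column%s (%s)\n",
              d[1L], if (d[1L] == 1L) "" else "s",
              d[2L], if (d[2L] == 1L) "" else "s",
              object@alphabet))
  ids <- rownames(object@chars)
  shown <- head(ids, 3L)
  for (id in shown) {
    s <- paste0(object@chars[id, seq_len(min(50L, d[2L]))], collapse = "")
    cat(sprintf("  %s  %s%s\n", id, s, if (d[2L] > 50L) "..." else ""))
  }
  if (length(ids) > 3L) cat(sprintf("  ... and %d more\n", length(ids) - 3L))
})

#' Logistic column-preservation model
#'
#' Holds the seven model coefficients (an intercept `m0` for the constant
#' feature `f0 = 1` plus `m1..m6` for gap proportion, percent identity,
#' distance from extremity, entropy, and the +/-1 and +/-2 windowed gap
#' proportions), the decision threshold `t`, and the sequence-bootstrap
#' settings `b` (replicates) and `tb` (pass fraction).  Unvalidated models
#' carry the defaults `t = 0.5`, `b = 0`.
#'
#' @slot coefficients Numeric vector of length 7, named `m0..m6`, all finite.
#' @slot threshold Decision threshold `t` in `[0, 1]`: a column with
#'   preservation score `p > t` is preserved, `p <= t` removed.
#' @slot bootstrapReplicates Non-negative integer `b`; 0 disables the
#'   bootstrap.
#' @slot bootstrapThreshold Fraction `tb` in `[0, 1]`: with the bootstrap on,
#'   a column is preserved only if at least `tb * b` replicates pass.
#' @slot validated Whether threshold and bootstrap settings were calibrated.
#' @slot metadata Free-form provenance list (training-set description,
#'   metric used, package version, ...).
#'
#' @seealso [filterModel()], [trainModel()], [validateModel()],
#'   [readFilterModel()]
#' @exportClass FilterModel
setClass("FilterModel",
  representation(coefficients = "numeric", threshold = "numeric",
                 bootstrapReplicates = "integer",
                 bootstrapThreshold = "numeric", validated = "logical",
                 metadata = "list"))

setValidity("FilterModel", function(object) {
  k <- object@coefficients
  if (length(k) != 7L) {
    return(sprintf("expected 7 coefficients (m0..m6), got %d", length(k)))
  }
  if (any(!is.finite(k))) {
    return("all coefficients must be finite")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold < 0 || object@threshold > 1) {
    return("'threshold' must be a single number in [0, 1]")
  }
  if (length(object@bootstrapReplicates) != 1L ||
      is.na(object@bootstrapReplicates) || object@bootstrapReplicates < 0L) {
    return("'bootstrapReplicates' must be a non-negative integer")
  }
  if (length(object@bootstrapThreshold) != 1L ||
      !is.finite(object@bootstrapThreshold) ||
      object@bootstrapThreshold < 0 || object@bootstrapThreshold > 1) {
    return("'bootstrapThreshold' must be a single number in [0, 1]")
  }
  if (length(object@validated) != 1L || is.na(object@validated)) {
    return("'validated' must be TRUE or FALSE")
  }
  if (!object@validated &&
      (object@threshold != 0.5 || object@bootstrapReplicates != 0L)) {
    return("unvalidated models must have threshold 0.5 and 0 bootstrap replicates")
  }
  TRUE
})

#' Construct a column-preservation model
#'
#' @param coefficients Numeric vector of 7 coefficients in the order `m0`
#'   (intercept), then `m1..m6` for gap proportion, percent identity,
#'   distance from extremity, entropy, gap proportion (+/-1), gap
#'   proportion (+/-2).
#' @param threshold Decision threshold `t`; unvalidated models must keep the
#'   default 0.5.
#' @param bootstrapReplicates Bootstrap replicate count `b` (0 = off).
#' @param bootstrapThreshold Bootstrap pass fraction `tb`.
#' @param validated Whether `threshold`/bootstrap settings were calibrated on
#'   a validation set.
#' @param metadata Free-form provenance list.
#'
#' @return A [FilterModel-class].
#' @examples
#' m <- filterModel(c(1, -6, 4, 0.01, -1, -2, -1))
#' coef(m)
#' @export
filterModel <- function(coefficients, threshold = 0.5,
                        bootstrapReplicates = 0L, bootstrapThreshold = 0.5,
                        validated = FALSE, metadata = list()) {
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- paste0("m", seq_along(coefficients) - 1L)
  new("FilterModel", coefficients = coefficients,
      threshold = as.numeric(threshold),
      bootstrapReplicates = as.integer(bootstrapReplicates),
      bootstrapThreshold = as.numeric(bootstrapThreshold),
      validated = isTRUE(validated), metadata = metadata)
}

#' @describeIn filterModel Model coefficients `m0..m6`.
#' @param object A [FilterModel-class].
#' @param ... Ignored.
#' @importFrom stats coef
#' @export
setMethod("coef", "FilterModel", function(object, ...) object@coefficients)

#' Decision threshold of a model
#' @param x A [FilterModel-class].
#' @return The threshold `t`.
#' @export
threshold <- function(x) x@threshold

#' Bootstrap settings of a model
#' @param x A [FilterModel-class].
#' @return Named numeric vector `c(b = replicates, tb = pass fraction)`.
#' @export
bootstrapSettings <- function(x) {
  c(b = as.numeric(x@bootstrapReplicates), tb = x@bootstrapThreshold)
}

#' Has a model been validated?
#' @param x A [FilterModel-class].
#' @return `TRUE` once threshold/bootstrap settings were calibrated.
#' @export
isValidated <- function(x) x@validated

#' Provenance metadata of a model
#' @param x A [FilterModel-class].
#' @return The metadata list.
#' @export
modelMetadata <- function(x) x@metadata

setMethod("show", "FilterModel", function(object) {
  cat("FilterModel",
      if (object@validated) "(validated)" else "(unvalidated)", "\n")
  k <- object@coefficients
  lab <- c("constant", FEATURE_NAMES)
  for (i in seq_along(k)) {
    cat(sprintf("  m%d (%s): %.6g\n", i - 1L, lab[i], k[i]))
  }
  cat(sprintf("  threshold t = %.4g\n", object@threshold))
  if (object@bootstrapReplicates > 0L) {
    cat(sprintf("  bootstrap: b = %d, tb = %.4g\n",
                object@bootstrapReplicates, object@bootstrapThreshold))
  } else {
    cat("  bootstrap: off\n")
  }
})

#' Binary-classification evaluation report
#'
#' Summarises how a model's preserve/delete calls compare with a reference
#' mask: confusion counts (positive class = "preserve"), Matthews
#' correlation, accuracy, an F-beta score, mean log loss (nats), the model
#' confidence score C, and the threshold-sweep ROC curve with its AUC.
#' ROC slots are `NA`/empty when the reference mask contains one class only.
#'
#' @slot confusion Named integer vector `c(tp, tn, fp, fn)`.
#' @slot mcc Matthews correlation coefficient in `[-1, 1]`.
#' @slot accuracy Fraction of columns on which model and mask agree.
#' @slot fBeta F-beta score for `beta`.
#' @slot beta The beta used for `fBeta`.
#' @slot logLoss Mean log loss in nats.
#' @slot confidence Confidence score C in `[0, 1)`.
#' @slot roc Data frame with columns `fpr`, `tpr`.
#' @slot auc Area under the ROC curve.
#'
#' @seealso [evaluationReport()], [testModel()]
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(confusion = "integer", mcc = "numeric",
                 accuracy = "numeric", fBeta = "numeric", beta = "numeric",
                 logLoss = "numeric", confidence = "numeric",
                 roc = "data.frame", auc = "numeric"))

setValidity("EvaluationReport", function(object) {
  if (length(object@confusion) != 4L ||
      !identical(names(object@confusion), c("tp", "tn", "fp", "fn"))) {
    return("'confusion' must be a named integer vector (tp, tn, fp, fn)")
  }
  if (any(object@confusion < 0L)) {
    return("confusion counts must be non-negative")
  }
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cc <- object@confusion
  cat("EvaluationReport over", sum(cc), "columns\n")
  cat(sprintf("  confusion: tp=%d tn=%d fp=%d fn=%d\n",
              cc["tp"], cc["tn"], cc["fp"], cc["fn"]))
  cat(sprintf("  MCC=%.4f  A=%.4f  F(beta=%g)=%.4f\n",
              object@mcc, object@accuracy, object@beta, object@fBeta))
  cat(sprintf("  log loss=%.4f nats  C=%.4f  AUC=%s\n",
              object@logLoss, object@confidence,
              if (is.na(object@auc)) "NA" else sprintf("%.4f", object@auc)))
})
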