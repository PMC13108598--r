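#' Preservation scores from features
#'
#' The logistic preservation score of a column with feature vector
#' `f1..f6` is `p = logit^-1(m0 + sum_i m_i f_i)` with
#' `logit^-1(x) = 1 / (1 + exp(-x))`.  `p` is strictly inside `(0, 1)`:
#' saturated linear predictors are clamped just inside the interval so that
#' downstream log losses stay finite.
#'
#' @param features Numeric matrix of per-column features as returned by
#'   [computeFeatures()] (or a single feature vector of length 6).
#' @param model A [FilterModel-class].
#' @return Numeric vector of preservation scores, one per column.
#' @examples
#' msa <- Msa(c(a = "AC-G", b = "ACTG"))
#' preservationScore(computeFeatures(msa), filterModel(rep(0, 7)))
#' @export
preservationScore <- function(features, model) {
  stopifnot(is(model, "FilterModel"))
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1L)
  }
  if (ncol(features) != 6L) {
    stop("'features' must have 6 columns (one per model feature)",
         call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("'features' must be finite", call. = FALSE)
  }
  k <- model@coefficients
  eta <- k[1L] + as.vector(features %*% k[-1L])
  p <- plogis(eta)
  pmin(pmax(p, P_EPS), 1 - P_EPS)
}

#' Threshold rule: preserve or remove
#'
#' Columns with preservation score strictly above the threshold are
#' preserved; `p <= t` (including exact ties) removes the column.
#'
#' @param p Numeric vector of preservation scores in `(0, 1)`.
#' @param t Threshold in `[0, 1]`.
#' @return Logical mask, `TRUE` = preserve.
#' @examples
#' classifyColumns(c(0.4, 0.5, 0.6), t = 0.5)
#' @export
classifyColumns <- function(p, t) {
  assertScalarNumber(t, "t", 0, 1)
  p > t
}

#' Confidence score of a set of preservation scores
#'
#' `C = 1 - (4 / n) * sum_k p_k (1 - p_k)` summarises how decisive the
#' per-column scores are: `C = 0` when every score is 0.5 (maximum
#' uncertainty) and `C -> 1` as scores approach 0 or 1.  Each column
#' contributes symmetrically (`p` and `1 - p` are equivalent).
#'
#' @param p Numeric vector of preservation scores in `(0, 1)`; at least one.
#' @return Confidence in `[0, 1)`.
#' @examples
#' confidenceScore(rep(0.5, 10))  # 0
#' confidenceScore(rep(0.99, 10))
#' @export
confidenceScore <- function(p) {
  if (!length(p)) {
    stop("cannot compute a confidence score from zero columns",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("preservation scores must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  1 - 4 * mean(p * (1 - p))
}

#' Serialize a model to JSON
#'
#' Models are stored as self-describing JSON text so they can be inspected
#' and imported by other software.  Numeric fields use full decimal
#' precision: a write/read round trip reproduces every coefficient
#' bit-exactly.
#'
#' @param model A [FilterModel-class].
#' @return A JSON string.
#' @seealso [modelFromJson()], [writeFilterModel()]
#' @export
modelToJson <- function(model) {
  stopifnot(is(model, "FilterModel"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    coefficients = unname(model@coefficients),
    threshold = model@threshold,
    bootstrap_replicates = model@bootstrapReplicates,
    bootstrap_threshold = model@bootstrapThreshold,
    validated = model@validated,
    metadata = model@metadata)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE, null = "null"))
}

#' Deserialize a model from JSON
#'
#' @param text JSON string produced by [modelToJson()] (or compatible).
#' @return A [FilterModel-class]; invariants are re-validated, so malformed
#'   documents (missing fields, wrong coefficient count, out-of-range
#'   threshold, unknown format version) raise errors naming the problem.
#' @export
modelFromJson <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  for (field in c("format_version", "coefficients", "threshold",
                  "bootstrap_replicates", "bootstrap_threshold",
                  "validated")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("model JSON lacks required field '%s'", field),
           call. = FALSE)
    }
  }
  if (obj$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf("unknown model format version %s (this build reads %d)",
                 format(obj$format_version), MODEL_FORMAT_VERSION),
         call. = FALSE)
  }
  if (length(obj$coefficients) != 7L) {
    stop(sprintf("expected 7 coefficients (m0..m6), got %d",
                 length(obj$coefficients)), call. = FALSE)
  }
  filterModel(coefficients = obj$coefficients, threshold = obj$threshold,
              bootstrapReplicates = obj$bootstrap_replicates,
              bootstrapThreshold = obj$bootstrap_threshold,
              validated = obj$validated,
              metadata = if (is.null(obj$metadata)) list()
                         else as.list(obj$metadata))
}

#' Write a model file
#' @param model A [FilterModel-class].
#' @param path Output path for the JSON model file.
#' @return `path`, invisibly.
#' @export
writeFilterModel <- function(model, path) {
  writeLines(modelToJson(model), path)
  invisible(path)
}

#' Read a model file
#' @param path Path to a JSON model file.
#' @return A [FilterModel-class].
#' @export
readFilterModel <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  }
  modelFromJson(paste0(readLines(path, warn = FALSE), collapse = "\n"))
}
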