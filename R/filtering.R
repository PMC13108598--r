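#' Score every column of an alignment
#'
#' @param msa An [Msa-class].
#' @param model A [FilterModel-class].
#' @return Numeric vector of preservation scores, one per column.
#' @export
scoreAlignment <- function(msa, model) {
  preservationScore(computeFeatures(msa), model)
}

#' Filter an alignment with a model
#'
#' Scores every column, applies the threshold rule (`p > t` preserved) or,
#' when the model carries bootstrap settings (`b > 0`), the bootstrap rule
#' (preserve only if at least `tb * b` sequence-resampled replicates pass),
#' and returns the column-filtered alignment.  The confidence score C is
#' always computed from the point scores of all input columns, bootstrap or
#' not.  Rows are never removed and column order is preserved; removing
#' every column yields a zero-column alignment and a warning.
#'
#' @param msa An [Msa-class].
#' @param model A [FilterModel-class].
#' @param seed Integer seed for the bootstrap replicates (required when
#'   `b > 0` for reproducibility; unused otherwise).
#' @param thresholdOverride Optional threshold to use instead of the
#'   model's.
#' @return List with `alignment` (filtered [Msa-class]), `mask` (logical),
#'   `scores` (per-column p), `confidence` (C), and `report` (input/output
#'   column counts, preserved proportion, C, model provenance).
#' @examples
#' msa <- Msa(c(a = "AAA--T", b = "AAC--T", c = "AAA--G"))
#' res <- filterAlignment(msa, filterModel(c(2, -8, 2, 0, -1, 0, 0)))
#' res$mask
#' @export
filterAlignment <- function(msa, model, seed = NULL,
                            thresholdOverride = NULL) {
  stopifnot(is(msa, "Msa"), is(model, "FilterModel"))
  t <- if (is.null(thresholdOverride)) model@threshold else {
    assertScalarNumber(thresholdOverride, "thresholdOverride", 0, 1)
  }
  p <- scoreAlignment(msa, model)
  b <- model@bootstrapReplicates
  if (b > 0L) {
    tmpModel <- filterModel(model@coefficients, threshold = t,
                            bootstrapReplicates = b,
                            bootstrapThreshold = model@bootstrapThreshold,
                            validated = TRUE, metadata = model@metadata)
    counts <- bootstrapPassCounts(msa, tmpModel, b, seed = seed)
    mask <- bootstrapDecision(counts, b, model@bootstrapThreshold)
  } else {
    mask <- classifyColumns(p, t)
  }
  if (!any(mask)) {
    warning("every column was removed; the filtered alignment has 0 columns",
            call. = FALSE)
  }
  out <- msaSubsetColumns(msa, mask)
  conf <- confidenceScore(p)
  list(alignment = out, mask = mask, scores = p, confidence = conf,
       report = list(
         input_columns = ncol(msa),
         output_columns = ncol(out),
         preserved_proportion = mean(mask),
         confidence = conf,
         threshold = t,
         bootstrap_replicates = b,
         bootstrap_threshold = model@bootstrapThreshold,
         model_metadata = model@metadata))
}

#' Combine masks column-wise
#'
#' Intersection (`AND`: preserve only where every mask preserves) or union
#' (`OR`) of masks produced by different models — useful for comparing or
#' consolidating filtering styles.
#'
#' @param masks List of at least two logical masks of equal length.
#' @param mode `"intersection"` or `"union"`.
#' @return The combined logical mask.
#' @examples
#' combineMasks(list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)))
#' @export
combineMasks <- function(masks, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!is.list(masks) || length(masks) < 2L) {
    stop("need at least two masks to combine", call. = FALSE)
  }
  lens <- lengths(masks)
  if (length(unique(lens)) > 1L) {
    stop(sprintf("mask lengths differ (%s)",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  }
  Reduce(if (mode == "intersection") `&` else `|`, masks)
}

#' Test a model against reference masks
#'
#' Applies the model to each test alignment without modifying any
#' parameter, compares the resulting masks with the reference masks, and
#' reports the pooled metrics over all columns plus one report per
#' alignment.
#'
#' @param model A [FilterModel-class].
#' @param alignments,masks Test alignments with reference masks.
#' @param seed Integer seed (used only when the model bootstraps).
#' @param beta Beta for the F-beta score in the reports.
#' @return List with `pooled` (an [EvaluationReport-class] over all
#'   columns) and `perAlignment` (list of per-alignment reports).
#' @export
testModel <- function(model, alignments, masks, seed = NULL, beta = 1) {
  stopifnot(is(model, "FilterModel"))
  if (length(alignments) != length(masks)) {
    stop("need one mask per alignment", call. = FALSE)
  }
  seeds <- deriveSeeds(seed, length(alignments))
  per <- vector("list", length(alignments))
  allP <- allPred <- allTruth <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    res <- filterAlignment(alignments[[i]], model, seed = seeds[[i]])
    allP[[i]] <- res$scores
    allPred[[i]] <- res$mask
    allTruth[[i]] <- masks[[i]]
    per[[i]] <- evaluationReport(res$scores, res$mask, masks[[i]],
                                 beta = beta)
  }
  pooled <- evaluationReport(unlist(allP), unlist(allPred),
                             unlist(allTruth), beta = beta)
  list(pooled = pooled, perAlignment = per)
}
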