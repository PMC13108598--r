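#' Find the decision threshold maximizing a metric
#'
#' Scans the fixed grid `t = 0.00, 0.01, ..., 1.00` and returns the
#' threshold maximizing the chosen metric of `p > t` against the reference
#' mask.  Metric ties are broken toward the threshold closest to 0.5, then
#' toward the smaller threshold, so the result is deterministic.
#'
#' @param p Preservation scores of the pooled validation columns.
#' @param truth Reference logical mask; both classes must be present.
#' @param metric `"mcc"` (default), `"accuracy"` or `"fbeta"`.
#' @param beta Beta for `metric = "fbeta"`.
#' @param grid Candidate thresholds.
#' @return List with `threshold` and `metricValue`.
#' @examples
#' findThreshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
findThreshold <- function(p, truth, metric = c("mcc", "accuracy", "fbeta"),
                          beta = 1, grid = seq(0, 1, by = 0.01)) {
  metric <- match.arg(metric)
  if (length(p) != length(truth)) {
    stop("scores and mask lengths differ", call. = FALSE)
  }
  if (sum(truth) == 0L || sum(!truth) == 0L) {
    stop("threshold calibration requires both classes in the mask",
         call. = FALSE)
  }
  vals <- vapply(grid, function(t) {
    metricFromCounts(confusionCounts(p > t, truth), metric, beta)
  }, numeric(1L))
  best <- max(vals)
  ties <- which(vals >= best - 1e-12)
  pick <- ties[order(abs(grid[ties] - 0.5), grid[ties])][1L]
  list(threshold = grid[pick], metricValue = vals[pick])
}

# Replicate-by-column pass matrix for the sequence bootstrap: entry (r, j)
# says whether replicate r scores column j above the model threshold.
# Replicates are drawn from one seeded stream, so for a fixed seed the
# counts for b replicates are a prefix of those for any larger b.
bootstrapPassMatrix <- function(msa, model, b, seed = NULL) {
  stopifnot(is(msa, "Msa"), is(model, "FilterModel"), b >= 1L)
  enc <- encodeMsa(msa@chars)
  n <- nrow(enc$codes)
  t <- model@threshold
  withSeed(seed, {
    pass <- matrix(FALSE, nrow = b, ncol = ncol(enc$codes))
    for (r in seq_len(b)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- featuresFromCodes(enc$codes[idx, , drop = FALSE], enc$nres)
      pass[r, ] <- preservationScore(f, model) > t
    }
    pass
  })
}

#' Bootstrap pass counts per column
#'
#' Resamples the alignment's sequences `b` times, recomputes the features
#' on every replicate, scores each replicate with the model, and counts per
#' column how many replicates exceed the model threshold.  Deterministic
#' given the seed.
#'
#' @param msa An [Msa-class].
#' @param model A [FilterModel-class] (its threshold `t` is used).
#' @param b Number of bootstrap replicates (at least 1).
#' @param seed Integer seed.
#' @return Integer vector of pass counts in `[0, b]`, one per column.
#' @export
bootstrapPassCounts <- function(msa, model, b, seed = NULL) {
  colSums(bootstrapPassMatrix(msa, model, as.integer(b), seed = seed))
}

#' Bootstrap preservation rule
#'
#' A column is preserved only if at least `tb * b` replicates passed.  The
#' comparison carries a 1e-9 slack because products like `0.7 * 100` are
#' not exact in binary floating point while pass counts are integers.
#'
#' @param count Pass count(s) from [bootstrapPassCounts()].
#' @param b Number of replicates.
#' @param tb Pass fraction in `[0, 1]`.
#' @return Logical preserve flag(s).
#' @examples
#' bootstrapDecision(c(69, 70), b = 100, tb = 0.7)
#' @export
bootstrapDecision <- function(count, b, tb) {
  assertScalarNumber(tb, "tb", 0, 1)
  if (any(count < 0) || any(count > b)) {
    stop("pass counts must lie in [0, b]", call. = FALSE)
  }
  count >= tb * b - 1e-9
}

#' Regularized validation score
#'
#' `S = M - b * E` trades the metric value `M` against the bootstrap cost:
#' with the default penalty `E = 5e-5`, a further 100 replicates must
#' improve `M` by at least 0.005 to be worth selecting.
#'
#' @param M Metric value.
#' @param b Number of bootstrap replicates.
#' @param penalty Penalizing constant `E`.
#' @return The regularized score.
#' @export
regularizedScore <- function(M, b, penalty = 5e-5) {
  M - b * penalty
}

#' Select bootstrap settings on a validation set
#'
#' With the threshold `t` already fixed, evaluates every candidate pair
#' `(b, tb)` on the pooled validation columns and returns the pair
#' maximizing the regularized score `S = M - b * E` (`b = 0` means plain
#' thresholding).  Ties prefer the smaller `b`, then the smaller `tb`.
#'
#' @param alignments,masks The validation alignments and reference masks.
#' @param model A [FilterModel-class] with its threshold set.
#' @param candidateB Candidate replicate counts (0 is always considered).
#' @param candidateTb Candidate pass fractions.
#' @param metric,beta Validation metric (see [findThreshold()]).
#' @param penalty Penalizing constant `E`.
#' @param seed Integer seed for the replicate draws.
#' @return List with `b`, `tb`, `metricValue`, `score`, and a `grid` data
#'   frame of diagnostics (one row per candidate, with `M` and `S`).
#' @export
selectBootstrap <- function(alignments, masks, model,
                            candidateB = seq(0L, 1000L, by = 100L),
                            candidateTb = seq(0.05, 0.95, by = 0.05),
                            metric = c("mcc", "accuracy", "fbeta"),
                            beta = 1, penalty = 5e-5, seed = NULL) {
  metric <- match.arg(metric)
  candidateB <- sort(unique(c(0L, as.integer(candidateB))))
  truth <- unlist(masks, use.names = FALSE)
  scores <- lapply(alignments, scoreAlignment, model = model)
  plainMask <- unlist(scores, use.names = FALSE) > model@threshold
  M0 <- metricFromCounts(confusionCounts(plainMask, truth), metric, beta)
  grid <- data.frame(b = 0L, tb = NA_real_, M = M0,
                     S = regularizedScore(M0, 0L, penalty))

  maxB <- max(candidateB)
  if (maxB > 0L) {
    seeds <- deriveSeeds(seed, length(alignments))
    # cumulative pass counts, so each candidate b reuses a prefix of the
    # same replicate stream
    cum <- vector("list", length(alignments))
    for (i in seq_along(alignments)) {
      pass <- bootstrapPassMatrix(alignments[[i]], model, maxB,
                                  seed = seeds[[i]])
      cum[[i]] <- apply(pass, 2L, cumsum)
    }
    for (b in setdiff(candidateB, 0L)) {
      countsAtB <- unlist(lapply(cum, function(m) m[b, ]),
                          use.names = FALSE)
      for (tb in candidateTb) {
        mask <- bootstrapDecision(countsAtB, b, tb)
        M <- metricFromCounts(confusionCounts(mask, truth), metric, beta)
        grid <- rbind(grid, data.frame(b = b, tb = tb, M = M,
                                       S = regularizedScore(M, b, penalty)))
      }
    }
  }
  bestS <- max(grid$S)
  ties <- which(grid$S >= bestS - 1e-12)
  tieTb <- ifelse(is.na(grid$tb[ties]), -1, grid$tb[ties])
  pick <- ties[order(grid$b[ties], tieTb)][1L]
  list(b = grid$b[pick],
       tb = if (is.na(grid$tb[pick])) model@bootstrapThreshold
            else grid$tb[pick],
       metricValue = grid$M[pick], score = grid$S[pick], grid = grid)
}

#' Validate a trained model
#'
#' Calibrates the decision threshold `t` on the pooled validation columns
#' (by MCC, accuracy, or F-beta), then — unless `bootstrap = FALSE` —
#' searches the bootstrap grids for the `(b, tb)` pair maximizing the
#' regularized score `S = M - b * E`.  Returns the validated model; the
#' validation details are attached as `attr(, "validation")`.
#'
#' @param model An unvalidated (or previously validated) [FilterModel-class].
#' @param alignments,masks Validation alignments with reference masks.
#' @param metric,beta Validation metric (default MCC).
#' @param bootstrap Whether to search bootstrap settings.
#' @param candidateB,candidateTb Bootstrap candidate grids.
#' @param penalty Penalizing constant `E` of the regularized score.
#' @param seed Integer seed for the bootstrap replicate draws.
#' @return A validated [FilterModel-class].
#' @export
validateModel <- function(model, alignments, masks,
                          metric = c("mcc", "accuracy", "fbeta"), beta = 1,
                          bootstrap = TRUE,
                          candidateB = seq(0L, 1000L, by = 100L),
                          candidateTb = seq(0.05, 0.95, by = 0.05),
                          penalty = 5e-5, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(is(model, "FilterModel"))
  truth <- unlist(masks, use.names = FALSE)
  p <- unlist(lapply(alignments, scoreAlignment, model = model),
              use.names = FALSE)
  thr <- findThreshold(p, truth, metric = metric, beta = beta)
  candModel <- filterModel(model@coefficients, threshold = thr$threshold,
                           validated = TRUE, metadata = model@metadata)
  if (bootstrap) {
    sel <- selectBootstrap(alignments, masks, candModel,
                           candidateB = candidateB,
                           candidateTb = candidateTb, metric = metric,
                           beta = beta, penalty = penalty, seed = seed)
  } else {
    sel <- list(b = 0L, tb = candModel@bootstrapThreshold,
                metricValue = thr$metricValue,
                score = thr$metricValue, grid = NULL)
  }
  meta <- model@metadata
  meta$validation <- list(
    metric = metric, beta = beta,
    metric_value = sel$metricValue,
    regularized_score = sel$score,
    penalty = penalty,
    n_validation_columns = length(truth))
  out <- filterModel(model@coefficients, threshold = thr$threshold,
                     bootstrapReplicates = sel$b, bootstrapThreshold = sel$tb,
                     validated = TRUE, metadata = meta)
  attr(out, "validation") <- list(threshold = thr$threshold,
                                  thresholdMetric = thr$metricValue,
                                  bootstrap = sel)
  out
}
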