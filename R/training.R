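#' Pool per-column training data from masked alignments
#'
#' Builds the pooled design for coefficient estimation: one row per
#' alignment column holding the six features, and one label per column from
#' the paired mask.
#'
#' @param alignments List of [Msa-class] objects.
#' @param masks List of logical masks, one per alignment, with matching
#'   lengths.
#' @return List with `features` (matrix, `sum(L_i)` rows) and `labels`
#'   (logical vector).
#' @export
poolTrainingData <- function(alignments, masks) {
  if (length(alignments) != length(masks)) {
    stop("need one mask per alignment", call. = FALSE)
  }
  feats <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    if (length(masks[[i]]) != ncol(alignments[[i]])) {
      stop(sprintf(
        "mask %d has length %d but alignment %d has %d columns",
        i, length(masks[[i]]), i, ncol(alignments[[i]])), call. = FALSE)
    }
    feats[[i]] <- computeFeatures(alignments[[i]])
  }
  list(features = do.call(rbind, feats),
       labels = unlist(masks, use.names = FALSE))
}

#' Fit the logistic preservation model by IRLS
#'
#' Estimates the seven coefficients by iteratively reweighted least squares
#' on the mean log loss.  For numerical conditioning the six features are
#' z-scored internally; the returned coefficients are back-transformed to
#' the raw feature scale, so predictions are identical either way.
#' Iterations use step-halving whenever a Newton step would increase the
#' loss, and stop when the gradient max-norm (standardized scale) drops
#' below `tol`.  Zero-variance feature columns are dropped from the solve
#' and get coefficient 0.
#'
#' Perfectly separable data have no finite optimum; non-convergence is
#' reported as an error suggesting more (or noisier) training data rather
#' than silently returning diverging coefficients.
#'
#' @param features Numeric matrix with 6 columns (see [computeFeatures()]).
#' @param labels Logical vector (TRUE = preserve), one per row; both classes
#'   must be present and there must be at least 7 rows.
#' @param maxIter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param standardize Internal z-scoring on/off (identical predictions
#'   either way when the raw fit converges; exposed for verification).
#' @return List with `coefficients` (named `m0..m6`, raw scale), `vcov`
#'   (7x7 inverse-information matrix, raw scale), `logLoss` (final mean log
#'   loss), `lossTrace` (per-iteration losses), `iterations`, `converged`.
#' @examples
#' gen <- generateLabelledFeatures(c(0, 2, 0, 0, 0, 0, 0), 500, seed = 1)
#' fitLogistic(gen$features, gen$labels)$coefficients
#' @export
fitLogistic <- function(features, labels, maxIter = 100L, tol = 1e-8,
                        standardize = TRUE) {
  if (is.null(dim(features)) || ncol(features) != 6L) {
    stop("'features' must be a matrix with 6 columns", call. = FALSE)
  }
  n <- nrow(features)
  if (length(labels) != n) {
    stop("one label per feature row is required", call. = FALSE)
  }
  if (n < 7L) {
    stop("need at least 7 columns of training data", call. = FALSE)
  }
  y <- as.numeric(labels)
  if (all(y == 1) || all(y == 0)) {
    stop(paste("training labels contain a single class;",
               "both preserved and removed columns are required"),
         call. = FALSE)
  }

  center <- rep(0, 6L)
  scale <- rep(1, 6L)
  if (standardize) {
    center <- colMeans(features)
    scale <- apply(features, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  Xs <- sweep(sweep(features, 2L, center, "-"), 2L, scale, "/")
  X <- cbind(1, Xs)
  keep <- c(TRUE, apply(Xs, 2L, function(v) stats::sd(v) > 0))
  Xk <- X[, keep, drop = FALSE]

  beta <- rep(0, ncol(Xk))
  loss <- function(b) {
    p <- plogis(as.vector(Xk %*% b))
    p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  curLoss <- loss(beta)
  lossTrace <- curLoss
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    p <- plogis(as.vector(Xk %*% beta))
    p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
    grad <- crossprod(Xk, p - y) / n
    if (max(abs(grad)) <= tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    z <- as.vector(Xk %*% beta) + (y - p) / w
    sw <- sqrt(w)
    betaFull <- qr.coef(qr(Xk * sw), z * sw)
    betaFull[is.na(betaFull)] <- 0
    # step-halving: never accept an increase in the log loss
    step <- 1
    betaNew <- betaFull
    newLoss <- loss(betaNew)
    while (newLoss > curLoss + 1e-14 && step > 2^-30) {
      step <- step / 2
      betaNew <- beta + step * (betaFull - beta)
      newLoss <- loss(betaNew)
    }
    beta <- betaNew
    curLoss <- newLoss
    lossTrace <- c(lossTrace, curLoss)
    # the gradient check happens at the top of the next iteration
  }
  if (!converged) {
    p <- plogis(as.vector(Xk %*% beta))
    p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
    converged <- max(abs(crossprod(Xk, p - y) / n)) <= tol
  }
  if (!converged) {
    stop(paste0(
      "IRLS did not converge after ", maxIter, " iterations; ",
      "add more training alignments or noisier labels"), call. = FALSE)
  }
  # a loss-free fit means the classes are completely separated: there is no
  # finite maximum-likelihood optimum, so refuse rather than return it
  pFit <- plogis(as.vector(Xk %*% beta))
  if (all(abs(y - pFit) < 1e-4)) {
    stop(paste("the training classes are perfectly separable in feature",
               "space, so the logistic coefficients are unbounded;",
               "add more training alignments or noisier labels"),
         call. = FALSE)
  }

  # expand to the full coefficient vector on the standardized scale
  betaStd <- rep(0, 7L)
  betaStd[keep] <- beta
  p <- plogis(as.vector(X %*% betaStd))
  p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
  w <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X * sqrt(w))  # observed information (std scale)
  vcovStd <- matrix(0, 7L, 7L)
  vk <- tryCatch(solve(info[keep, keep, drop = FALSE]),
                 error = function(e) NULL)
  if (!is.null(vk)) {
    vcovStd[keep, keep] <- vk
  } else {
    vcovStd[] <- NA_real_
  }

  # back-transform: m_j = beta_j / scale_j, intercept absorbs the centers
  Tm <- diag(7L)
  Tm[1L, -1L] <- -center / scale
  diag(Tm)[-1L] <- 1 / scale
  coefRaw <- as.vector(Tm %*% betaStd)
  names(coefRaw) <- paste0("m", 0:6)
  vcovRaw <- Tm %*% vcovStd %*% t(Tm)
  dimnames(vcovRaw) <- list(names(coefRaw), names(coefRaw))

  list(coefficients = coefRaw, vcov = vcovRaw, logLoss = curLoss,
       lossTrace = lossTrace, iterations = iter, converged = converged)
}

#' Train an unvalidated model on masked alignments
#'
#' Pools the per-column features and labels across the training alignments,
#' optionally injects a proportion of random label mistakes (to probe
#' robustness to annotation errors), and fits the logistic coefficients.
#' The returned model carries the unvalidated defaults `t = 0.5`, `b = 0`.
#'
#' @param alignments List of [Msa-class] training alignments.
#' @param masks List of logical masks paired with `alignments`.
#' @param mistakes Proportion of mask flags to flip before fitting
#'   (see [injectMistakes()]); 0 disables.
#' @param seed Seed used for mistake injection.
#' @param maxIter,tol Passed to [fitLogistic()].
#' @return An unvalidated [FilterModel-class]; the fit details (vcov, loss
#'   trace) are stored in `attr(, "fit")`.
#' @export
trainModel <- function(alignments, masks, mistakes = 0, seed = NULL,
                       maxIter = 100L, tol = 1e-8) {
  assertScalarNumber(mistakes, "mistakes", 0, 1)
  if (mistakes > 0) {
    seeds <- deriveSeeds(seed, length(masks))
    masks <- lapply(seq_along(masks), function(i) {
      injectMistakes(masks[[i]], mistakes, seed = seeds[[i]])
    })
  }
  pooled <- poolTrainingData(alignments, masks)
  fit <- fitLogistic(pooled$features, pooled$labels,
                     maxIter = maxIter, tol = tol)
  model <- filterModel(
    coefficients = fit$coefficients,
    metadata = list(
      trained_on = sprintf("%d alignments, %d columns",
                           length(alignments), length(pooled$labels)),
      preserved_fraction = mean(pooled$labels),
      mistakes = mistakes,
      log_loss = fit$logLoss,
      package = paste0("msafilter ", as.character(packageVersion("msafilter")))))
  attr(model, "fit") <- fit
  model
}

#' Partition masked alignments into train/validation/test sets
#'
#' Alignments are unbreakable units: every alignment lands in exactly one
#' split, so no column of a test alignment can leak into training.  Split
#' sizes follow the requested ratios by largest-remainder rounding, and the
#' assignment is a seeded uniform shuffle.
#'
#' @param nAlignments Number of alignments to partition.
#' @param ratios Numeric vector of 3 non-negative weights
#'   (train, validation, test); the conventional split is `c(2, 1, 1)`.
#' @param seed Integer seed for the shuffle.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @examples
#' partitionAlignments(4, c(2, 1, 1), seed = 1)
#' @export
partitionAlignments <- function(nAlignments, ratios = c(2, 1, 1),
                                seed = NULL) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) == 0) {
    stop("'ratios' must be 3 non-negative weights", call. = FALSE)
  }
  nonzero <- sum(ratios > 0)
  if (nAlignments < nonzero) {
    stop(sprintf("cannot split %d alignments across %d non-empty sets",
                 nAlignments, nonzero), call. = FALSE)
  }
  exact <- nAlignments * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- exact - sizes
  left <- nAlignments - sum(sizes)
  if (left > 0) {
    order_ <- order(-rem, seq_along(rem))
    sizes[order_[seq_len(left)]] <- sizes[order_[seq_len(left)]] + 1L
  }
  # every non-empty split must get at least one alignment
  while (any(sizes == 0 & ratios > 0)) {
    i <- which(sizes == 0 & ratios > 0)[1L]
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  idx <- withSeed(seed, sample.int(nAlignments))
  list(train = sort(idx[seq_len(sizes[1L])]),
       validation = sort(idx[sizes[1L] + seq_len(sizes[2L])]),
       test = sort(idx[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]))
}

#' Inject random mistakes into a mask
#'
#' Flips exactly `round(proportion * length(mask))` flags, chosen uniformly
#' without replacement — a deterministic simulation of annotation errors in
#' the reference masks.
#'
#' @param mask Logical mask.
#' @param proportion Proportion of flags to flip, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted mask.
#' @examples
#' injectMistakes(rep(TRUE, 10), 0.5, seed = 1)
#' @export
injectMistakes <- function(mask, proportion, seed = NULL) {
  assertScalarNumber(proportion, "proportion", 0, 1)
  k <- round(proportion * length(mask))
  if (k == 0) {
    return(mask)
  }
  flip <- withSeed(seed, sample.int(length(mask), k))
  mask[flip] <- !mask[flip]
  mask
}
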