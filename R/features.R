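#' Per-column alignment features
#'
#' Six numerical features summarise each alignment column; together with the
#' constant term they are the inputs of the logistic preservation model.
#' In order:
#'
#' 1. `gap` — proportion of sequences with a gap in the column;
#' 2. `identity` — frequency of the most common residue, gaps excluded;
#' 3. `dist_extremity` — number of columns between this column and the
#'    nearer alignment end, `min(i, L - 1 - i)` for 0-based index `i`;
#' 4. `entropy` — Shannon entropy (nats) of the residue frequencies, gaps
#'    excluded; at most `ln(4)` for nucleotide and `ln(20)` for amino-acid
#'    columns;
#' 5. `gap_w1` — gap proportion averaged over the column and its immediate
#'    neighbours;
#' 6. `gap_w2` — the same with a radius of two columns.
#'
#' Windowed averages near the alignment edges run over the existing columns
#' only (e.g. `gap_w2` of the first column averages columns 1-3).  All-gap
#' columns take `identity = 0` and `entropy = 0`; their gap proportion of 1
#' already marks them.  Features never depend on row order.
#'
#' @param msa An [Msa-class].
#' @return Numeric matrix with one row per column and columns
#'   `gap`, `identity`, `dist_extremity`, `entropy`, `gap_w1`, `gap_w2`.
#' @examples
#' computeFeatures(Msa(c(a = "AC-G", b = "ACTG")))
#' @export
computeFeatures <- function(msa) {
  stopifnot(is(msa, "Msa"))
  enc <- encodeMsa(msa@chars)
  featuresFromCodes(enc$codes, enc$nres)
}

# Map the character matrix to integer codes: 0 = gap, 1..K = residues.
encodeMsa <- function(m) {
  residues <- sort(setdiff(unique(as.vector(m)), GAP_CHARS))
  codes <- matrix(match(m, residues, nomatch = 0L), nrow = nrow(m))
  list(codes = codes, nres = length(residues))
}

# Vectorised feature computation on an integer-coded matrix; also the inner
# loop of the sequence bootstrap, so it avoids per-column apply() calls.
featuresFromCodes <- function(codes, nres) {
  n <- nrow(codes)
  L <- ncol(codes)
  if (L == 0L) {
    return(matrix(numeric(0), ncol = 6L,
                  dimnames = list(NULL, FEATURE_NAMES)))
  }
  gapn <- colSums(codes == 0L)
  nonGap <- n - gapn
  if (nres > 0L) {
    res <- codes > 0L
    idx <- codes[res] + (col(codes)[res] - 1L) * nres
    counts <- matrix(tabulate(idx, nbins = nres * L), nrow = nres)
    maxc <- counts[1L, ]
    if (nres > 1L) {
      for (k in 2L:nres) maxc <- pmax(maxc, counts[k, ])
    }
    denom <- ifelse(nonGap > 0L, nonGap, 1L)
    q <- counts / rep(denom, each = nres)
    qlq <- q * log(q)
    qlq[counts == 0L] <- 0
    entropy <- -colSums(qlq)
    identity <- maxc / denom
    identity[nonGap == 0L] <- 0
    entropy[nonGap == 0L] <- 0
  } else {
    identity <- numeric(L)
    entropy <- numeric(L)
  }
  gap <- gapn / n
  i0 <- seq_len(L) - 1L
  cbind(gap = gap,
        identity = identity,
        dist_extremity = pmin(i0, L - 1L - i0),
        entropy = pmax(entropy, 0),
        gap_w1 = windowMean(gap, 1L),
        gap_w2 = windowMean(gap, 2L))
}

# Mean of x over [i - r, i + r], truncated at the ends of the vector.
windowMean <- function(x, r) {
  L <- length(x)
  if (r == 0L || L == 1L) {
    return(x)
  }
  cs <- cumsum(c(0, x))
  i <- seq_len(L)
  lo <- pmax(i - r, 1L)
  hi <- pmin(i + r, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Gap proportion of one column
#'
#' @param column Character vector of single characters (one alignment
#'   column); `-`, `.`, `?` are gaps.
#' @return Fraction of gap characters.
#' @examples
#' gapProportion(c("A", "-", "A", "-"))
#' @export
gapProportion <- function(column) {
  stopifnot(length(column) >= 1L)
  mean(toupper(column) %in% GAP_CHARS)
}

#' Percent identity of one column
#'
#' Frequency of the most common residue among the non-gap characters; an
#' all-gap column scores 0.
#'
#' @inheritParams gapProportion
#' @return Fraction in `[0, 1]`.
#' @examples
#' percentIdentity(c("A", "A", "C", "-"))
#' @export
percentIdentity <- function(column) {
  stopifnot(length(column) >= 1L)
  res <- toupper(column)
  res <- res[!(res %in% GAP_CHARS)]
  if (!length(res)) {
    return(0)
  }
  max(table(res)) / length(res)
}

#' Shannon entropy of one column
#'
#' Natural-base entropy of the residue frequencies, gaps excluded; an
#' all-gap column scores 0.  The maximum is `ln(4)` for nucleotide and
#' `ln(20)` for amino-acid columns.
#'
#' @inheritParams gapProportion
#' @return Entropy in nats.
#' @examples
#' columnEntropy(c("A", "C", "G", "T"))  # ln(4)
#' @export
columnEntropy <- function(column) {
  stopifnot(length(column) >= 1L)
  res <- toupper(column)
  res <- res[!(res %in% GAP_CHARS)]
  if (!length(res)) {
    return(0)
  }
  q <- table(res) / length(res)
  -sum(q * log(q))
}

#' Distance of a column from the nearer alignment end
#'
#' @param index 0-based column index.
#' @param length Alignment length (number of columns).
#' @return `min(index, length - 1 - index)`: the number of columns strictly
#'   between this column and the closer extremity.
#' @examples
#' distanceFromExtremity(5, 11)
#' @export
distanceFromExtremity <- function(index, length) {
  stopifnot(length >= 1L)
  if (any(index < 0L) || any(index >= length)) {
    stop(sprintf("column index out of range [0, %d]", length - 1L),
         call. = FALSE)
  }
  pmin(index, length - 1L - index)
}

#' Windowed gap proportion
#'
#' Average of the per-column gap proportions over the window
#' `[index - radius, index + radius]`; columns beyond the alignment ends are
#' excluded from the average, so the +/-2 window of the first column spans
#' columns 1-3 and the +/-1 window of the last column spans the last two.
#'
#' @param perColumnGaps Numeric vector of per-column gap proportions.
#' @param index 0-based column index.
#' @param radius Window radius (1 or 2 in the feature set; 0 returns the
#'   column's own value).
#' @return The window mean.
#' @examples
#' gapProportionWindow(c(0.5, 0, 1, 0), index = 0, radius = 2)
#' @export
gapProportionWindow <- function(perColumnGaps, index, radius) {
  L <- length(perColumnGaps)
  if (index < 0L || index >= L) {
    stop(sprintf("column index out of range [0, %d]", L - 1L), call. = FALSE)
  }
  lo <- max(index - radius, 0L)
  hi <- min(index + radius, L - 1L)
  mean(perColumnGaps[(lo:hi) + 1L])
}

#' Resample alignment sequences with replacement
#'
#' Draws `nrow(msa)` rows uniformly with replacement — the sequence
#' bootstrap.  The column count is unchanged and, given a seed, the draw is
#' deterministic.  Resampled rows get suffixed identifiers to keep them
#' unique.
#'
#' @param msa An [Msa-class].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A resampled [Msa-class].
#' @export
bootstrapResample <- function(msa, seed = NULL) {
  stopifnot(is(msa, "Msa"))
  n <- nrow(msa@chars)
  idx <- withSeed(seed, sample.int(n, n, replace = TRUE))
  m <- msa@chars[idx, , drop = FALSE]
  rownames(m) <- sprintf("%s_bs%d", rownames(msa@chars)[idx], seq_len(n))
  new("Msa", chars = m, alphabet = msa@alphabet)
}

#' Export a per-column feature table
#'
#' Writes a TSV with the 1-based column number and the six features, for
#' inspection outside R.
#'
#' @param msa An [Msa-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(msa, path) {
  f <- computeFeatures(msa)
  df <- data.frame(column = seq_len(nrow(f)), f, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
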