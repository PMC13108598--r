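# Independent brute-force oracles and fixture builders shared by the tests.
# Everything here is deliberately written character-by-character, without
# touching the package's vectorised internals.

GAPS <- c("-", ".", "?")

randomMsa <- function(nSeq, L, seed, gapProb = 0.2,
                      letters_ = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
  withr::with_seed(seed, {
    m <- matrix(sample(letters_, nSeq * L, replace = TRUE), nrow = nSeq)
    gap <- matrix(runif(nSeq * L) < gapProb, nrow = nSeq)
    m[gap] <- "-"
    rownames(m) <- sprintf("s%d", seq_len(nSeq))
    Msa(apply(m, 1L, paste0, collapse = ""))
  })
}

# column-by-column recomputation of the six features from first principles
oracleFeatures <- function(msa) {
  m <- msaMatrix(msa)
  L <- ncol(m)
  gap <- numeric(L); ident <- numeric(L); ent <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    isGap <- col %in% GAPS
    gap[j] <- sum(isGap) / length(col)
    res <- col[!isGap]
    if (length(res)) {
      tab <- table(res)
      ident[j] <- max(tab) / length(res)
      q <- tab / length(res)
      ent[j] <- -sum(q * log(q))
    }
  }
  w <- function(j, r) {
    idx <- (j - r):(j + r)
    mean(gap[idx[idx >= 1 & idx <= L]])
  }
  cbind(gap = gap,
        identity = ident,
        dist_extremity = vapply(seq_len(L) - 1L,
                                function(i) min(i, L - 1L - i), numeric(1)),
        entropy = ent,
        gap_w1 = vapply(seq_len(L), w, numeric(1), r = 1L),
        gap_w2 = vapply(seq_len(L), w, numeric(1), r = 2L))
}

# pairwise-comparison AUC: P(pos > neg) + P(tie)/2, enumerated directly
oracleAuc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

oracleMcc <- function(tp, tn, fp, fn) {
  d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  unname(if (d == 0) 0 else (tp * tn - fp * fn) / d)
}

# trapezoid integration of an ROC polyline
trapezoidArea <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

corpusAlignments <- function(corpus) lapply(corpus, `[[`, "alignment")
corpusMasks <- function(corpus) lapply(corpus, `[[`, "mask")
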