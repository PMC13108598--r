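ALPHABETS <- list(
  aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
  nt = c("A", "C", "G", "T"))

#' Block specification for the synthetic generator
#'
#' @param length Number of columns in the block.
#' @param kind `"conserved"` (near-identical residues, preserved),
#'   `"variable"` (near-uniform residues, deleted by default) or `"gappy"`
#'   (per-column gap fraction at least 0.85, deleted).
#' @param preserve Optional override of the block's truth label; by default
#'   conserved blocks are preserved and the other kinds deleted.  A
#'   preserved variable block emulates an annotator deliberately keeping a
#'   fast-evolving region.
#' @return A block-spec list consumed by [generateAlignment()].
#' @export
blockSpec <- function(length, kind = c("conserved", "variable", "gappy"),
                      preserve = NULL) {
  kind <- match.arg(kind)
  stopifnot(length >= 1L)
  list(length = as.integer(length), kind = kind,
       preserve = if (is.null(preserve)) kind == "conserved"
                  else isTRUE(preserve))
}

#' Generate a synthetic alignment with a ground-truth mask
#'
#' Emulates the structure a manual annotator reacts to: runs of conserved
#' columns (kept), runs of variable columns (usually removed), and gap-rich
#' runs (removed; per-column gap content is guaranteed to be at least 0.85,
#' matching the gap pre-filter customary in manual curation).  Conserved
#' columns cap the number of deviant residues at 10% of the sequences, so
#' their percent identity is at least 0.9 by construction.  Deterministic
#' for a fixed seed.
#'
#' @param nSeq Number of sequences (at least 2).
#' @param blocks List of [blockSpec()] entries, in column order.
#' @param seed Integer seed.
#' @param alphabet `"aa"` or `"nt"`.
#' @return List with `alignment` (an [Msa-class]) and `mask` (logical
#'   ground truth, `TRUE` = preserve).
#' @examples
#' generateAlignment(5, list(blockSpec(8, "conserved"),
#'                           blockSpec(4, "gappy")), seed = 1)$mask
#' @export
generateAlignment <- function(nSeq, blocks, seed = NULL,
                              alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (nSeq < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  if (!is.list(blocks) || !length(blocks)) {
    stop("'blocks' must be a non-empty list of blockSpec() entries",
         call. = FALSE)
  }
  letters_ <- ALPHABETS[[alphabet]]
  withSeed(seed, {
    cols <- list()
    mask <- logical(0)
    for (blk in blocks) {
      for (j in seq_len(blk$length)) {
        cols[[length(cols) + 1L]] <- switch(blk$kind,
          conserved = {
            cons <- sample(letters_, 1L)
            # deviant count capped so identity >= 0.9 holds exactly
            nDev <- min(rbinom(1L, nSeq, 0.05), floor(nSeq / 10))
            col <- rep(cons, nSeq)
            if (nDev > 0L) {
              col[sample.int(nSeq, nDev)] <-
                sample(setdiff(letters_, cons), nDev, replace = TRUE)
            }
            col
          },
          variable = {
            col <- sample(letters_, nSeq, replace = TRUE)
            nGap <- round(nSeq * runif(1L, 0, 0.4))
            if (nGap > 0L) {
              col[sample.int(nSeq, nGap)] <- "-"
            }
            col
          },
          gappy = {
            nGap <- min(ceiling(runif(1L, 0.85, 1) * nSeq), nSeq)
            col <- rep("-", nSeq)
            if (nGap < nSeq) {
              col[sample.int(nSeq, nSeq - nGap)] <-
                sample(letters_, nSeq - nGap, replace = TRUE)
            }
            col
          })
        mask <- c(mask, blk$preserve)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- sprintf("seq%03d", seq_len(nSeq))
    list(alignment = new("Msa", chars = m,
                         alphabet = if (alphabet == "aa") "amino-acid"
                                    else "nucleotide"),
         mask = mask)
  })
}

#' Generate a corpus of masked synthetic alignments
#'
#' Draws a set of independent alignments from randomized block layouts:
#' per alignment, the number of sequences, the number of blocks and each
#' block's length are sampled from the stated ranges, block kinds follow
#' `kindProbs`, and each variable block is preserved (annotator-kept) with
#' probability `variablePreserveProb`.  Those occasional preserved variable
#' blocks give the corpus a realistic irreducible disagreement between
#' features and labels, which keeps the training problem from being
#' perfectly separable.
#'
#' @param nAlignments Number of alignments.
#' @param seed Integer seed.
#' @param nSeqRange,nBlocksRange,blockLenRange Integer ranges (min, max)
#'   for sequences per alignment, blocks per alignment, and columns per
#'   block.
#' @param kindProbs Named sampling probabilities for the block kinds.
#' @param variablePreserveProb Probability that a variable block is
#'   labelled preserve.
#' @param alphabet `"aa"` or `"nt"`.
#' @return List of `list(alignment =, mask =)` pairs.
#' @export
generateCorpus <- function(nAlignments, seed = NULL,
                           nSeqRange = c(10L, 30L),
                           nBlocksRange = c(4L, 10L),
                           blockLenRange = c(10L, 40L),
                           kindProbs = c(conserved = 0.45, variable = 0.30,
                                         gappy = 0.25),
                           variablePreserveProb = 0.1,
                           alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  stopifnot(nAlignments >= 1L)
  seeds <- deriveSeeds(seed, 2L * nAlignments)
  out <- vector("list", nAlignments)
  for (i in seq_len(nAlignments)) {
    layout <- withSeed(seeds[[i]], {
      nSeq <- sample(nSeqRange[1L]:nSeqRange[2L], 1L)
      nBlocks <- sample(nBlocksRange[1L]:nBlocksRange[2L], 1L)
      kinds <- sample(names(kindProbs), nBlocks, replace = TRUE,
                      prob = kindProbs)
      blocks <- lapply(kinds, function(k) {
        preserve <- if (k == "variable") {
          runif(1L) < variablePreserveProb
        } else NULL
        blockSpec(sample(blockLenRange[1L]:blockLenRange[2L], 1L), k,
                  preserve = preserve)
      })
      list(nSeq = nSeq, blocks = blocks)
    })
    out[[i]] <- generateAlignment(layout$nSeq, layout$blocks,
                                  seed = seeds[[nAlignments + i]],
                                  alphabet = alphabet)
  }
  out
}

#' Generate labelled feature rows from known coefficients
#'
#' Draws feature vectors from fixed ranges (fractions uniform on `[0, 1]`,
#' distance from extremity uniform on the integers `0..200`, entropy
#' uniform on `[0, ln 20]`) and labels them by Bernoulli draws with
#' probability `logit^-1(m . f)` — the ground truth for
#' parameter-recovery checks of [fitLogistic()].
#'
#' @param coefficients Numeric vector `m0..m6`.
#' @param nColumns Number of rows to generate (at least 100).
#' @param seed Integer seed.
#' @return List with `features` (matrix), `labels` (logical) and `prob`
#'   (the true per-row preservation probabilities).
#' @export
generateLabelledFeatures <- function(coefficients, nColumns, seed = NULL) {
  if (length(coefficients) != 7L) {
    stop("expected 7 coefficients (m0..m6)", call. = FALSE)
  }
  if (nColumns < 100L) {
    stop("generate at least 100 columns", call. = FALSE)
  }
  withSeed(seed, {
    f <- cbind(gap = runif(nColumns),
               identity = runif(nColumns),
               dist_extremity = as.numeric(sample(0:200, nColumns,
                                                  replace = TRUE)),
               entropy = runif(nColumns, 0, log(20)),
               gap_w1 = runif(nColumns),
               gap_w2 = runif(nColumns))
    prob <- plogis(coefficients[1L] + as.vector(f %*% coefficients[-1L]))
    labels <- rbinom(nColumns, 1L, prob) == 1L
    list(features = f, labels = labels, prob = prob)
  })
}

#' Write a synthetic corpus to disk
#'
#' Writes each alignment as FASTA and each ground-truth mask as a 0/1 file,
#' plus a JSON manifest pairing them — ready for the command-line
#' train/validate/test workflow.
#'
#' @param corpus A corpus from [generateCorpus()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the manifest file, invisibly.
#' @export
writeCorpus <- function(corpus, dir, prefix = "aln") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    fa <- sprintf("%s%03d.fasta", prefix, i)
    mk <- sprintf("%s%03d.mask", prefix, i)
    writeMsa(corpus[[i]]$alignment, file.path(dir, fa))
    writeMask(corpus[[i]]$mask, file.path(dir, mk))
    entries[[i]] <- list(alignment = fa, mask = mk)
  }
  manifest <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(entries, auto_unbox = TRUE,
                                           pretty = TRUE)), manifest)
  invisible(manifest)
}
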