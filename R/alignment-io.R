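#' Read an aligned FASTA file
#'
#' Parses a multi-FASTA file into an [Msa-class].  Records must all have the
#' same length (the file holds an alignment, not raw sequences); lowercase
#' residues are uppercased and `-`, `.`, `?` are interpreted as gaps
#' downstream.
#'
#' @param path Path to an aligned FASTA file.
#' @param alphabet Alphabet hint passed to [Msa()]; default guesses from the
#'   residues.
#' @return An [Msa-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-G", ">b", "ACTG"), f)
#' readMsa(f)
#' @export
readMsa <- function(path, alphabet = "guess") {
  if (!file.exists(path)) {
    stop(sprintf("alignment file not found: '%s'", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  }
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence identifier '%s' in '%s'",
                 ids[duplicated(ids)][1L], path), call. = FALSE)
  }
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf(
      "'%s' is not aligned: sequence '%s' has length %d, expected %d",
      path, ids[bad], w[bad], w[1L]), call. = FALSE)
  }
  Msa(as.character(set), ids = ids, alphabet = alphabet)
}

#' Write an alignment as FASTA
#'
#' Round-trips through [readMsa()]: identifiers and rows are reproduced
#' exactly.  A zero-column alignment (possible after filtering) is written
#' with empty sequence lines and a warning.
#'
#' @param msa An [Msa-class].
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(msa, path, width = 80L) {
  stopifnot(is(msa, "Msa"))
  if (ncol(msa@chars) == 0L) {
    warning("writing a zero-column alignment", call. = FALSE)
    # Biostrings writes no sequence line for width-0 records; emit the
    # headers with explicit empty lines instead so the file round-trips.
    writeLines(as.vector(rbind(paste0(">", seqIds(msa)), "")), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(msaStrings(msa))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a column mask
#'
#' A mask file is plain text holding one `0`/`1` character per alignment
#' column (`1` = preserve), optionally split across lines, with optional
#' `#`-prefixed comment lines and ignored whitespace.
#'
#' @param path Path to the mask file.
#' @param expectedLength Expected number of columns (usually `ncol(msa)`);
#'   `NULL` skips the check.
#' @return Logical vector, `TRUE` = preserve.
#' @examples
#' f <- tempfile(fileext = ".mask")
#' writeLines(c("#mask", "1101"), f)
#' readMask(f, expectedLength = 4)
#' @export
readMask <- function(path, expectedLength = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("mask file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  flat <- gsub("\\s+", "", paste0(lines, collapse = ""))
  chars <- strsplit(flat, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("0", "1"))
  if (length(bad)) {
    stop(sprintf("invalid mask character '%s' in '%s' (expected 0/1)",
                 bad[1L], path), call. = FALSE)
  }
  flags <- chars == "1"
  if (!is.null(expectedLength) && length(flags) != expectedLength) {
    stop(sprintf("mask length %d does not match expected length %d ('%s')",
                 length(flags), expectedLength, path), call. = FALSE)
  }
  flags
}

#' Write a column mask
#'
#' @param mask Logical vector, `TRUE` = preserve.
#' @param path Output path.
#' @param width Characters per line.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path, width = 80L) {
  stopifnot(is.logical(mask))
  digits <- paste0(ifelse(mask, "1", "0"), collapse = "")
  if (nchar(digits) > width) {
    starts <- seq(1L, nchar(digits), by = width)
    digits <- substring(digits, starts, pmin(starts + width - 1L,
                                             nchar(digits)))
  }
  writeLines(digits, path)
  invisible(path)
}

#' Read a manifest pairing alignments with masks
#'
#' A manifest is a JSON array of objects with `alignment` and `mask` keys
#' holding file paths (relative paths are resolved against the manifest's
#' directory).
#'
#' @param path Path to the manifest JSON.
#' @return List with elements `alignments` (list of [Msa-class]) and
#'   `masks` (list of logical vectors), in manifest order.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: '%s'", path), call. = FALSE)
  }
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(entries) || !length(entries)) {
    stop(sprintf("manifest '%s' is empty", path), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  alignments <- vector("list", length(entries))
  masks <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$alignment) || is.null(e$mask)) {
      stop(sprintf("manifest entry %d lacks 'alignment' or 'mask'", i),
           call. = FALSE)
    }
    alignments[[i]] <- readMsa(resolve(e$alignment))
    masks[[i]] <- readMask(resolve(e$mask),
                           expectedLength = ncol(alignments[[i]]))
  }
  list(alignments = alignments, masks = masks)
}
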