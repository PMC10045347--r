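DNA_BASES <- c("A", "C", "G", "T")

#' Parse a JASPAR-format position frequency matrix
#'
#' Reads a JASPAR flat-file PFM record: an optional `>` header line followed
#' by four base rows of equal length. Both the bracket dialect
#' (`A [ 10 0 ... ]`) and the plain whitespace dialect (`A 10 0 ...` or four
#' bare numeric rows in A, C, G, T order) are accepted.
#'
#' @param text Character vector of lines, or a single string containing the
#'   whole record (embedded newlines are split).
#' @return A `pfm` object: list with `motif_id` (character), `counts`
#'   (4 x W integer matrix, rows A/C/G/T) and `width`.
#' @examples
#' pfm <- parse_jaspar_pfm(c(">toy", "A [3 0]", "C [0 3]", "G [0 0]", "T [0 0]"))
#' pfm$width
#' @seealso [read_jaspar_pfm()], [build_pssm()]
#' @export
parse_jaspar_pfm <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty PFM record")

  motif_id <- "motif"
  if (startsWith(lines[[1L]], ">")) {
    motif_id <- strsplit(sub("^>\\s*", "", lines[[1L]]), "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    stop("PFM format error: expected 4 base rows, found ", length(lines))

  parse_row <- function(line) {
    base <- NA_character_
    m <- regmatches(line, regexec("^([ACGTacgt])\\b", line))[[1L]]
    if (length(m)) {
      base <- toupper(m[[2L]])
      line <- sub("^[ACGTacgt]", "", line)
    }
    line <- gsub("[][]", " ", line)
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("PFM format error: non-numeric count in row: ", paste(toks, collapse = " "))
    if (any(vals < 0))
      stop("PFM format error: negative count")
    list(base = base, counts = vals)
  }

  rows <- lapply(lines, parse_row)
  bases <- vapply(rows, `[[`, character(1L), "base")
  if (all(is.na(bases))) {
    bases <- DNA_BASES  # bare 4-row dialect: rows are A, C, G, T in order
  } else if (anyNA(bases) || !setequal(bases, DNA_BASES)) {
    stop("PFM format error: need exactly one row for each of A, C, G, T; got: ",
         paste(bases, collapse = ", "))
  }
  widths <- lengths(lapply(rows, `[[`, "counts"))
  if (length(unique(widths)) != 1L)
    stop("PFM format error: unequal row lengths (",
         paste(widths, collapse = ", "), ")")
  W <- widths[[1L]]
  if (W < 1L) stop("PFM format error: zero-width matrix")

  counts <- matrix(0, nrow = 4L, ncol = W, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(rows)) counts[bases[[i]], ] <- rows[[i]]$counts

  structure(list(motif_id = motif_id, counts = counts, width = W),
            class = "pfm")
}

#' Read a JASPAR PFM file
#'
#' @param path Path to a JASPAR-format PFM file.
#' @return A `pfm` object (see [parse_jaspar_pfm()]).
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  parse_jaspar_pfm(readLines(path, warn = FALSE))
}

#' Path to the vendored JASPAR MA0150.1 (NFE2L2) matrix
#'
#' The 4 x 11 count matrix of JASPAR entry MA0150.1, the NFE2L2 binding
#' profile used for ARE scanning.
#'
#' @return File path of the vendored fixture.
#' @export
ma0150_pfm_path <- function() {
  system.file("extdata", "MA0150.1.jaspar", package = "AREscan",
              mustWork = TRUE)
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix ", x$motif_id, " (width ", x$width, ")\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Build a log2-odds PSSM from a PFM
#'
#' Converts base counts to a position-specific scoring matrix of
#' log2(observed/expected) scores. A pseudocount is added to every raw count
#' before per-column normalisation, so
#' `score[b, j] = log2(((count[b, j] + pc) / (colsum_j + 4 pc)) / background[b])`.
#' The maximal and minimal achievable window scores (sums of per-column
#' maxima/minima) are cached for relative-score computation.
#'
#' @param pfm A `pfm` object.
#' @param background Per-base probabilities (A, C, G, T), strictly positive,
#'   summing to 1. Default uniform 0.25.
#' @param pseudocount Non-negative count added to every matrix cell before
#'   normalisation; default 1. With 0, any zero count is a log(0) error.
#' @return A `pssm` object: list with `scores` (4 x W), `max_score`,
#'   `min_score`, `background`, `pseudocount`, `width`, `motif_id`.
#' @examples
#' pfm <- parse_jaspar_pfm(c("A [3 0]", "C [0 3]", "G [0 0]", "T [0 0]"))
#' pssm <- build_pssm(pfm)
#' pssm$max_score  # ~2.385
#' @export
build_pssm <- function(pfm, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(inherits(pfm, "pfm"))
  background <- as.numeric(background)
  if (length(background) != 4L)
    stop("background must have 4 entries (A, C, G, T)")
  if (any(background <= 0))
    stop("background probabilities must be strictly positive (zero expected ",
         "frequency makes the odds ratio undefined)")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background probabilities must sum to 1")
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  if (pseudocount == 0 && any(pfm$counts == 0))
    stop("pseudocount 0 with a zero count would produce log(0); ",
         "use a positive pseudocount")

  names(background) <- DNA_BASES
  colsums <- colSums(pfm$counts)
  freq <- sweep(pfm$counts + pseudocount, 2L, colsums + 4 * pseudocount, "/")
  scores <- log2(freq / background)
  if (any(!is.finite(scores))) stop("non-finite PSSM score produced")

  structure(list(
    motif_id = pfm$motif_id,
    scores = scores,
    width = pfm$width,
    max_score = sum(apply(scores, 2L, max)),
    min_score = sum(apply(scores, 2L, min)),
    background = background,
    pseudocount = pseudocount
  ), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM ", x$motif_id, " (width ", x$width, ", log2-odds)\n", sep = "")
  cat(sprintf("max score %.4f, min score %.4f, pseudocount %g\n",
              x$max_score, x$min_score, x$pseudocount))
  print(round(x$scores, 3))
  invisible(x)
}

#' Absolute PSSM score of one window
#'
#' Sums the per-position log2-odds scores of a W-mer.
#'
#' @param pssm A `pssm` object.
#' @param window A string of length `pssm$width` over A/C/G/T.
#' @return Absolute score (log2-odds units).
#' @export
score_window <- function(pssm, window) {
  stopifnot(inherits(pssm, "pssm"))
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(chars) != pssm$width)
    stop("window length ", length(chars), " != PSSM width ", pssm$width)
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes))
    stop("window contains non-ACGT character: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  sum(pssm$scores[cbind(codes, seq_len(pssm$width))])
}

#' Relative PSSM score
#'
#' Maps an absolute window score onto `[0, 1]` as
#' `(absolute + |minScore|) / (|maxScore| + |minScore|)`, so the best
#' achievable W-mer scores 1 and the worst scores 0.
#'
#' @param pssm A `pssm` object.
#' @param absolute Absolute score(s), each within
#'   `[pssm$min_score, pssm$max_score]`.
#' @return Relative score(s) in `[0, 1]`.
#' @export
relative_score <- function(pssm, absolute) {
  stopifnot(inherits(pssm, "pssm"))
  tol <- 1e-9 * max(1, abs(pssm$max_score), abs(pssm$min_score))
  if (any(absolute < pssm$min_score - tol | absolute > pssm$max_score + tol))
    stop("absolute score outside the achievable [minScore, maxScore] range")
  (absolute + abs(pssm$min_score)) / (abs(pssm$max_score) + abs(pssm$min_score))
}

# Score matrix whose forward scan of a sequence equals scoring the reverse
# complement of each window with the original matrix:
# rc[b, j] = scores[complement(b), W + 1 - j].
reverse_complement_scores <- function(scores) {
  scores[4:1, rev(seq_len(ncol(scores))), drop = FALSE]
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0),
             sequence = character(0), abs_score = numeric(0),
             rel_score = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for motif hits above a relative-score threshold
#'
#' Slides a window of the PSSM width over `seq`, scoring every offset on the
#' forward strand and (optionally) the reverse complement of every window for
#' the reverse strand. Reverse-strand hits report the same forward
#' coordinates with strand `"-"` and the matched sequence as read on the
#' minus strand. Windows containing non-ACGT characters are skipped and
#' counted in the run log. Hits with relative score below `threshold` are
#' discarded (the threshold is inclusive: `rel_score >= threshold` is kept).
#'
#' @param pssm A `pssm` object.
#' @param seq A nucleotide string.
#' @param threshold Relative-score cutoff in `[0, 1]`; default 0.8.
#' @param both_strands Scan the reverse strand too? Default `TRUE`.
#' @return A data frame of hits with columns `start`, `end` (0-based
#'   half-open, relative to the sequence origin), `sequence`, `abs_score`,
#'   `rel_score`, `strand`, sorted by `(start, strand)`. A `run_log`
#'   attribute carries counters: `windows_scanned`, `windows_skipped`
#'   (non-ACGT), `candidates` (scoreable windows) and `hits` (kept).
#' @examples
#' pssm <- build_pssm(parse_jaspar_pfm(c("A [3 0]", "C [0 3]",
#'                                       "G [0 0]", "T [0 0]")))
#' scan_sequence(pssm, "AACA", threshold = 0.8, both_strands = FALSE)
#' @export
scan_sequence <- function(pssm, seq, threshold = 0.8, both_strands = TRUE) {
  stopifnot(inherits(pssm, "pssm"))
  if (length(threshold) != 1L || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  seq <- toupper(seq)
  W <- pssm$width
  L <- nchar(seq)
  log_zero <- list(windows_scanned = 0L, windows_skipped = 0L,
                   candidates = 0L, hits = 0L)
  if (L < W) {
    out <- empty_hits()
    attr(out, "run_log") <- log_zero
    return(out)
  }

  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  n <- L - W + 1L
  # W x n matrix: column i holds the codes of the window starting at offset i
  idx <- outer(seq_len(W) - 1L, seq_len(n), `+`)
  win <- matrix(codes[idx], nrow = W)
  valid <- colSums(is.na(win)) == 0L
  win0 <- win
  win0[is.na(win0)] <- 1L
  col_off <- 4L * (seq_len(W) - 1L)  # linear index into a 4 x W matrix

  window_scores <- function(score_mat) {
    colSums(matrix(score_mat[win0 + col_off], nrow = W))
  }

  denom <- abs(pssm$max_score) + abs(pssm$min_score)
  strands <- if (isTRUE(both_strands)) c("+", "-") else "+"
  pieces <- vector("list", length(strands))
  for (k in seq_along(strands)) {
    st <- strands[[k]]
    sc <- if (st == "+") window_scores(pssm$scores)
          else window_scores(reverse_complement_scores(pssm$scores))
    rel <- (sc + abs(pssm$min_score)) / denom
    keep <- valid & rel >= threshold
    if (!any(keep)) { pieces[[k]] <- empty_hits(); next }
    starts <- which(keep)  # 1-based offsets
    fwd <- substring(seq, starts, starts + W - 1L)
    pieces[[k]] <- data.frame(
      start = starts - 1L,
      end = starts - 1L + W,
      sequence = if (st == "+") fwd else reverse_complement(fwd),
      abs_score = sc[keep],
      rel_score = rel[keep],
      strand = st,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "run_log") <- list(
    windows_scanned = n * length(strands),
    windows_skipped = sum(!valid) * length(strands),
    candidates = sum(valid) * length(strands),
    hits = nrow(out))
  out
}
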