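# Independent brute-force oracle for motif scanning: enumerates every offset
# and strand with its own character loop and complement table, never calling
# scan_sequence (score_window/relative_score are also reimplemented here so
# the oracle shares no scoring path with the code under test).

oracle_rel <- function(pssm, chars) {
  abs <- 0
  for (j in seq_along(chars)) abs <- abs + pssm$scores[chars[[j]], j]
  list(abs = abs,
       rel = (abs + abs(pssm$min_score)) /
         (abs(pssm$max_score) + abs(pssm$min_score)))
}

oracle_scan <- function(pssm, seq, threshold = 0.8, both_strands = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  W <- ncol(pssm$scores)
  L <- nchar(seq)
  seq <- toupper(seq)
  res <- list()
  if (L >= W) {
    for (off in 0:(L - W)) {
      ch <- strsplit(substr(seq, off + 1L, off + W), "")[[1L]]
      if (!all(ch %in% names(comp))) next
      for (st in if (both_strands) c("+", "-") else "+") {
        chars <- if (st == "+") ch else rev(unname(comp[ch]))
        s <- oracle_rel(pssm, chars)
        if (s$rel >= threshold) {
          res[[length(res) + 1L]] <- data.frame(
            start = off, end = off + W,
            sequence = paste(chars, collapse = ""),
            abs_score = s$abs, rel_score = s$rel, strand = st,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), abs_score = numeric(0),
                      rel_score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quadratic all-pairs interval overlap oracle
oracle_intersect <- function(a, b) {
  res <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j]) {
      s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
      if (s < e) res[[length(res) + 1L]] <-
          data.frame(a_idx = i, b_idx = j, chrom = a$chrom[i],
                     overlap_start = s, overlap_end = e)
    }
  }
  if (length(res) == 0L)
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      chrom = character(0), overlap_start = integer(0),
                      overlap_end = integer(0)))
  out <- do.call(rbind, res)
  ai <- out$a_idx; bi <- out$b_idx
  out <- out[order(a$chrom[ai], a$start[ai], a$end[ai],
                   b$chrom[bi], b$start[bi], b$end[bi], bi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_pfm <- function(width, max_count = 30L) {
  counts <- matrix(sample(0:max_count, 4L * width, replace = TRUE),
                   nrow = 4L)
  txt <- c(">random",
           sprintf("%s [ %s ]", c("A", "C", "G", "T"),
                   apply(counts, 1L, paste, collapse = " ")))
  parse_jaspar_pfm(txt)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

expect_same_hits <- function(got, want, tol = 1e-10) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_equal(got$sequence, want$sequence)
  expect_equal(got$abs_score, want$abs_score, tolerance = tol)
  expect_equal(got$rel_score, want$rel_score, tolerance = tol)
}
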