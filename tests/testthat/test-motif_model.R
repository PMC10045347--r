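toy_pfm <- parse_jaspar_pfm(c(">toy", "A [3 0]", "C [0 3]",
                              "G [0 0]", "T [0 0]"))
toy <- build_pssm(toy_pfm)

test_that("parse_jaspar_pfm reads both dialects and validates the record", {
  vendored <- read_jaspar_pfm(ma0150_pfm_path())
  expect_s3_class(vendored, "pfm")
  expect_identical(vendored$width, 11L)
  expect_identical(vendored$motif_id, "MA0150.1")
  expect_true(all(colSums(vendored$counts) == 20))

  # identity round-trip of the toy record
  expect_identical(toy_pfm$width, 2L)
  expect_identical(unname(toy_pfm$counts["A", ]), c(3, 0))
  expect_identical(unname(toy_pfm$counts["C", ]), c(0, 3))

  # plain whitespace dialect, with and without base letters
  plain <- parse_jaspar_pfm(c("A 3 0", "C 0 3", "G 0 0", "T 0 0"))
  bare <- parse_jaspar_pfm(c("3 0", "0 3", "0 0", "0 0"))
  expect_identical(plain$counts, toy_pfm$counts)
  expect_identical(bare$counts, toy_pfm$counts)

  expect_error(parse_jaspar_pfm(c("A [1 2 3]", "C [1 2]", "G [1 2 3]",
                                  "T [1 2 3]")), "unequal row lengths")
  expect_error(parse_jaspar_pfm(c("A [1]", "C [1]", "G [1]")), "4 base rows")
  expect_error(parse_jaspar_pfm(c("A [1]", "C [1]", "G [1]", "A [1]")),
               "each of A, C, G, T")
  expect_error(parse_jaspar_pfm(c("A [1]", "C [x]", "G [1]", "T [1]")),
               "non-numeric")
  expect_error(parse_jaspar_pfm(c("A [1]", "C [-2]", "G [1]", "T [1]")),
               "negative")
})

test_that("build_pssm implements pseudo-counted log2 odds with cached extrema", {
  # frozen hand computation: col 1 scores log2(16/7) and log2(4/7)
  expect_equal(unname(toy$scores["A", 1L]), log2(16 / 7), tolerance = 1e-12)
  expect_equal(unname(toy$scores["T", 1L]), log2(4 / 7), tolerance = 1e-12)
  expect_equal(toy$max_score, 2 * log2(16 / 7), tolerance = 1e-12)
  expect_equal(toy$min_score, 2 * log2(4 / 7), tolerance = 1e-12)
  expect_equal(toy$max_score, 2.3852, tolerance = 1e-4)
  expect_equal(toy$min_score, -1.6147, tolerance = 1e-4)

  # equal counts + uniform background => column of zeros
  flat <- build_pssm(parse_jaspar_pfm(c("A [5]", "C [5]", "G [5]", "T [5]")))
  expect_equal(unname(flat$scores[, 1L]), rep(0, 4), tolerance = 1e-12)

  # zero counts stay finite under pseudocount 1
  vend <- build_pssm(read_jaspar_pfm(ma0150_pfm_path()))
  expect_true(all(is.finite(vend$scores)))

  expect_error(build_pssm(toy_pfm, pseudocount = 0), "log\\(0\\)")
  expect_error(build_pssm(toy_pfm, background = c(0.5, 0.5, 0, 0)),
               "strictly positive")
  expect_error(build_pssm(toy_pfm, background = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(build_pssm(toy_pfm, pseudocount = -1), "non-negative")
})

test_that("score_window sums per-position scores and validates input", {
  expect_equal(score_window(toy, "AC"), toy$max_score, tolerance = 1e-12)
  expect_equal(score_window(toy, "TT"), toy$min_score, tolerance = 1e-12)
  expect_error(score_window(toy, "ACG"), "width")
  expect_error(score_window(toy, "AN"), "non-ACGT")

  # an all-equal column contributes 0 regardless of the base
  mix <- build_pssm(parse_jaspar_pfm(c("A [3 2]", "C [0 2]",
                                       "G [0 2]", "T [0 2]")))
  for (b in c("A", "C", "G", "T"))
    expect_equal(score_window(mix, paste0("A", b)),
                 score_window(mix, "AA"), tolerance = 1e-12)
})

test_that("relative_score matches the formula fixed points", {
  expect_equal(relative_score(toy, toy$max_score), 1.0, tolerance = 1e-12)
  expect_equal(relative_score(toy, toy$min_score), 0.0, tolerance = 1e-12)
  # single symmetric substitution lands exactly half way
  expect_equal(relative_score(toy, score_window(toy, "AT")), 0.5,
               tolerance = 1e-12)
  expect_error(relative_score(toy, toy$max_score + 1), "outside")
  # monotone in the absolute score
  abs_grid <- seq(toy$min_score, toy$max_score, length.out = 20L)
  expect_true(all(diff(relative_score(toy, abs_grid)) > 0))
})

test_that("scan_sequence enumerates offsets and applies the threshold", {
  hits <- scan_sequence(toy, "AACA", threshold = 0.8, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$sequence, "AC")
  expect_equal(hits$rel_score, 1.0, tolerance = 1e-12)

  # all three forward windows rescore to the enumerated 0.5 / 1.0 / 0.0,
  # and reverse-complement windows add nothing above threshold
  both <- scan_sequence(toy, "AACA", threshold = 0.8, both_strands = TRUE)
  expect_same_hits(both, hits)

  expect_equal(nrow(scan_sequence(toy, "A")), 0L)

  # non-ACGT windows are skipped and counted
  h <- scan_sequence(toy, "ANAC", threshold = 0, both_strands = FALSE)
  expect_false(any(grepl("N", h$sequence)))
  expect_equal(attr(h, "run_log")$windows_skipped, 2L)
  expect_equal(attr(h, "run_log")$windows_scanned, 3L)

  expect_error(scan_sequence(toy, "ACGT", threshold = 1.5), "\\[0, 1\\]")
})

test_that("scan_sequence equals the brute-force oracle on random inputs", {
  withr::with_seed(101L, {
    for (rep in 1:40) {
      pssm <- build_pssm(random_pfm(sample(2:11, 1L)))
      seq <- random_seq(sample(20:200, 1L),
                        alphabet = c("A", "C", "G", "T", "N"))
      thr <- sample(c(0, 0.5, 0.8, 0.95), 1L)
      got <- scan_sequence(pssm, seq, threshold = thr, both_strands = TRUE)
      want <- oracle_scan(pssm, seq, threshold = thr, both_strands = TRUE)
      expect_same_hits(got, want)
    }
  })
})

test_that("argmax/argmin W-mers hit the 1.0 / 0.0 fixed points (property)", {
  withr::with_seed(202L, {
    for (rep in 1:25) {
      pfm <- random_pfm(sample(2:11, 1L))
      bg <- stats::runif(4, 0.05, 1); bg <- bg / sum(bg)
      pc <- sample(c(0.5, 1, 2), 1L)
      pssm <- build_pssm(pfm, background = bg, pseudocount = pc)
      best <- paste(rownames(pssm$scores)[apply(pssm$scores, 2L, which.max)],
                    collapse = "")
      worst <- paste(rownames(pssm$scores)[apply(pssm$scores, 2L, which.min)],
                     collapse = "")
      expect_equal(relative_score(pssm, score_window(pssm, best)), 1.0,
                   tolerance = 1e-12)
      expect_equal(relative_score(pssm, score_window(pssm, worst)), 0.0,
                   tolerance = 1e-12)
      # every window of a random sequence stays in [0, 1]
      sc <- scan_sequence(pssm, random_seq(100), threshold = 0)
      expect_true(all(sc$rel_score >= 0 & sc$rel_score <= 1))
    }
  })
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  withr::with_seed(303L, {
    for (rep in 1:15) {
      pssm <- build_pssm(random_pfm(sample(3:11, 1L)))
      seq <- random_seq(120)
      fwd <- scan_sequence(pssm, seq, threshold = 0.7)
      rc <- scan_sequence(pssm, reverse_complement(seq), threshold = 0.7)
      # map: start -> len - end, strand flipped
      mapped <- data.frame(start = nchar(seq) - rc$end,
                           end = nchar(seq) - rc$start,
                           sequence = rc$sequence,
                           strand = ifelse(rc$strand == "+", "-", "+"),
                           rel_score = rc$rel_score)
      mapped <- mapped[order(mapped$start, mapped$strand), ]
      expect_equal(nrow(mapped), nrow(fwd))
      expect_equal(mapped$start, fwd$start)
      expect_equal(mapped$strand, fwd$strand)
      expect_equal(mapped$sequence, fwd$sequence)
      expect_equal(mapped$rel_score, fwd$rel_score, tolerance = 1e-10)
    }
  })
})

test_that("the vendored matrix scores the consensus ARE at exactly 1", {
  pssm <- build_pssm(read_jaspar_pfm(ma0150_pfm_path()))
  expect_equal(relative_score(pssm, score_window(pssm, "ATGACTCAGCA")), 1.0,
               tolerance = 1e-12)
  # background-robust in the formula sense: under any background the
  # per-column argmax W-mer scores exactly 1.0
  gc_bg <- c(0.3, 0.2, 0.2, 0.3)
  pssm2 <- build_pssm(read_jaspar_pfm(ma0150_pfm_path()), background = gc_bg)
  best2 <- paste(rownames(pssm2$scores)[apply(pssm2$scores, 2L, which.max)],
                 collapse = "")
  expect_equal(relative_score(pssm2, score_window(pssm2, best2)), 1.0,
               tolerance = 1e-12)
})
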