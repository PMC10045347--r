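#' Construct a genomic-interval table
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (BED convention): columns `chrom`, `start`, `end` and optional `name`,
#' `strand`, `label`. `label` carries the transcription factor name for peak
#' files and the regulatory state for segmentation files.
#'
#' @param chrom,start,end,name,strand,label Column vectors (recycled).
#' @return A data frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = NA_character_, label = NA_character_) {
  chrom <- as.character(chrom)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("start must be < end (half-open intervals)")
  st <- rep_len(as.character(strand), n)
  if (any(!is.na(st) & !st %in% c("+", "-")))
    stop("strand must be '+', '-' or NA")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = rep_len(as.character(name), n), strand = st,
                    label = rep_len(as.character(label), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Read a BED file
#'
#' BED3 to BED6 lines are accepted; `track`, `browser` and `#` comment lines
#' are skipped. Column 4 becomes `name` and column 6 `strand` when present.
#'
#' @param path BED file path.
#' @param label Optional label attached to every record (e.g. the
#'   transcription factor a peak file belongs to, or a segmentation state
#'   source). Per-record labels for segmentation files come from the BED
#'   `name` column; see [read_segmentation_bed()].
#' @return A `genomic_intervals` data frame.
#' @export
read_bed <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1L))
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": non-integer coordinates")
  bad <- start >= end
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": start >= end")
  strand <- get(6L)
  strand[!strand %in% c("+", "-")] <- NA_character_
  genomic_intervals(chrom = get(1L), start = start, end = end,
                    name = get(4L), strand = strand, label = label)
}

#' Write intervals as BED
#'
#' Writes BED6 when any of `name`/`score`/`strand` is informative, BED3
#' otherwise.
#'
#' @param x A `genomic_intervals` data frame.
#' @param path Output path.
#' @param score Numeric vector for BED column 5 (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, score = 0) {
  has6 <- any(!is.na(x$name)) || any(score != 0) || any(!is.na(x$strand))
  if (has6) {
    out <- data.frame(x$chrom, x$start, x$end,
                      ifelse(is.na(x$name), ".", x$name),
                      rep_len(score, nrow(x)),
                      ifelse(is.na(x$strand), ".", x$strand))
  } else {
    out <- data.frame(x$chrom, x$start, x$end)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a segmentation / cCRE BED
#'
#' Regulatory-segmentation files carry the state label (TSS, T, R, PF, E,
#' WE, CTCF for hg19-style combined segmentations; PLS, dELS for mm10-style
#' cCREs) in the BED name column. Labels pass through verbatim; no fixed
#' vocabulary is enforced.
#'
#' @param path BED file path.
#' @return A `genomic_intervals` data frame with `label` set from column 4.
#' @export
read_segmentation_bed <- function(path) {
  x <- read_bed(path)
  x$label <- x$name
  x
}

#' Read a transcript coordinate table
#'
#' Accepts BED6 (name column = accession) or a UCSC Table-Browser-style TSV
#' with a header naming at least `name`/`chrom`/`strand`/`txStart`/`txEnd`
#' (a `#` prefix on the header is tolerated, and the column map is
#' configurable).
#'
#' @param path File path.
#' @param format `"auto"` (default), `"bed"` or `"ucsc"`.
#' @param columns Named list mapping the logical fields `accession`,
#'   `chrom`, `strand`, `txStart`, `txEnd` to column names in a UCSC-style
#'   file.
#' @return Data frame with columns `accession`, `chrom`, `strand`,
#'   `txStart`, `txEnd` (0-based half-open).
#' @export
read_transcripts <- function(path, format = c("auto", "bed", "ucsc"),
                             columns = list(accession = "name",
                                            chrom = "chrom",
                                            strand = "strand",
                                            txStart = "txStart",
                                            txEnd = "txEnd")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("txStart", first)) "ucsc" else "bed"
  }
  if (format == "bed") {
    b <- read_bed(path)
    if (any(is.na(b$name))) stop("transcript BED needs accession in column 4")
    if (any(is.na(b$strand))) stop("transcript BED needs strand in column 6")
    tx <- data.frame(accession = b$name, chrom = b$chrom, strand = b$strand,
                     txStart = b$start, txEnd = b$end,
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines[1L] <- sub("^#", "", lines[1L])
    tab <- read.table(text = lines, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    need <- unlist(columns)
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      stop("transcript table missing column(s): ",
           paste(missing_cols, collapse = ", "))
    tx <- data.frame(accession = as.character(tab[[columns$accession]]),
                     chrom = as.character(tab[[columns$chrom]]),
                     strand = as.character(tab[[columns$strand]]),
                     txStart = as.integer(tab[[columns$txStart]]),
                     txEnd = as.integer(tab[[columns$txEnd]]),
                     stringsAsFactors = FALSE)
  }
  if (any(tx$txStart >= tx$txEnd)) stop("transcript with txStart >= txEnd")
  if (any(!tx$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")
  tx
}

#' Extend a transcript upstream of its TSS
#'
#' Adds `flank` bp upstream of the transcription start site, keeping the
#' transcript body: a + strand transcript becomes
#' `[max(0, txStart - flank), txEnd)`, a - strand one
#' `[txStart, min(size, txEnd + flank))`. Coordinates are clamped to the
#' chromosome.
#'
#' @param tx Data frame as returned by [read_transcripts()] (vectorised).
#' @param flank Upstream extension in bp; default 5000.
#' @param sizes Named chromosome sizes.
#' @return A `genomic_intervals` data frame (name = accession, strand kept).
#' @export
extend_upstream <- function(tx, flank = 5000L, sizes) {
  if (flank < 0) stop("flank must be >= 0")
  unknown <- setdiff(unique(tx$chrom), names(sizes))
  if (length(unknown)) stop("unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  size <- as.integer(sizes[tx$chrom])
  plus <- tx$strand == "+"
  start <- ifelse(plus, pmax(0L, tx$txStart - as.integer(flank)), tx$txStart)
  end <- ifelse(plus, tx$txEnd, pmin(size, tx$txEnd + as.integer(flank)))
  genomic_intervals(chrom = tx$chrom, start = start, end = end,
                    name = tx$accession, strand = tx$strand)
}

#' All pairwise overlaps between two interval sets
#'
#' Reports every pair with overlap length >= 1 under half-open semantics
#' (adjacent intervals do not overlap). The overlap interval is
#' `[max(starts), min(ends))`. Output rows are ordered by the genomic order
#' of the `a` record, then of the `b` record.
#'
#' @param a,b `genomic_intervals` data frames.
#' @return Data frame with `a_idx`, `b_idx` (row indices into the inputs),
#'   `chrom`, `overlap_start`, `overlap_end`.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      chrom = character(0), overlap_start = integer(0),
                      overlap_end = integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = 1L)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    a_idx = ai, b_idx = bi, chrom = a$chrom[ai],
    overlap_start = pmax(a$start[ai], b$start[bi]),
    overlap_end = pmin(a$end[ai], b$end[bi]))
  ord <- order(a$chrom[ai], a$start[ai], a$end[ai],
               b$chrom[bi], b$start[bi], b$end[bi], bi)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segmentation state labels overlapping a site
#'
#' Returns the unique state labels of every segmentation record overlapping
#' the site, ordered by segment genomic position. An empty result is
#' rendered `"None"` by the report writer; the annotation never filters
#' sites.
#'
#' @param site A single-row `genomic_intervals` data frame (or list with
#'   `chrom`, `start`, `end`).
#' @param segmentation `genomic_intervals` with state labels in `label`.
#' @return Character vector of labels (possibly empty).
#' @export
annotate_segmentation <- function(site, segmentation) {
  if (nrow(segmentation) == 0L) return(character(0))
  seg <- segmentation[segmentation$chrom == site$chrom &
                        segmentation$start < site$end &
                        segmentation$end > site$start, , drop = FALSE]
  if (nrow(seg) == 0L) return(character(0))
  seg <- seg[order(seg$start, seg$end), , drop = FALSE]
  unique(seg$label)
}
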