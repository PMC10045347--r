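#' In-memory genome container
#'
#' A `genome` is a named character vector of uppercase nucleotide sequences
#' (one per chromosome) with a `sizes` accessor. Desk-scale genomes (tens of
#' Mb) are held fully in memory; no index file is required.
#'
#' @param sequences Named character vector (or named list of strings),
#'   chromosome name -> sequence.
#' @return A `genome` object.
#' @export
genome <- function(sequences) {
  sequences <- vapply(sequences, toupper, character(1L))
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome name: ",
                              nm[duplicated(nm)][1L])
  structure(sequences, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x), "sequence(s)\n")
  print(chrom_sizes(x))
  invisible(x)
}

#' Chromosome sizes of a genome
#'
#' @param g A `genome` object.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(g) {
  stopifnot(inherits(g, "genome"))
  setNames(nchar(unclass(g)), names(g))
}

#' Read a genome FASTA file
#'
#' Multi-record and line-wrapped FASTA are supported. Sequences are
#' uppercased; chromosome names are the header truncated at the first
#' whitespace.
#'
#' @param path FASTA file path.
#' @return A `genome` object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1L])
  genome(setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param g A `genome` object.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 60L) {
  stopifnot(inherits(g, "genome"))
  ss <- Biostrings::DNAStringSet(setNames(unclass(g), names(g)))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read / write a two-column chrom.sizes table
#'
#' @param path File path.
#' @return Named integer vector chromosome -> size.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  setNames(tab$size, tab$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named integer vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(chrom = names(sizes), size = as.integer(sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a subsequence by 0-based half-open coordinates
#'
#' @param g A `genome` object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval, `0 <= start < end <= size`.
#'   Out-of-range coordinates are an error; there is no silent clamping.
#' @return The nucleotide string of `[start, end)`.
#' @export
extract_sequence <- function(g, chrom, start, end) {
  stopifnot(inherits(g, "genome"))
  if (!chrom %in% names(g)) stop("unknown chromosome: ", chrom)
  size <- nchar(g[[chrom]])
  if (start < 0 || start >= end || end > size)
    stop(sprintf("coordinates [%d, %d) out of range for %s (size %d)",
                 start, end, chrom, size))
  substr(unclass(g)[[chrom]], start + 1L, end)
}

#' Reverse complement
#'
#' Standard complement over A/C/G/T, with N mapping to N; any other
#' character is an error. Vectorised over `seq`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Reverse-complemented strings.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad))
    stop("sequence contains characters outside ACGTN: ", seq[bad][1L])
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
}
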