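#' Pipeline configuration
#'
#' Collects every input and parameter of the ARE discovery pipeline. File
#' fields accept either a path or the already-loaded object (a `pfm`, a
#' `genome`, `genomic_intervals`, a transcript data frame), which keeps the
#' pipeline scriptable and testable without touching disk.
#'
#' @param pfm JASPAR PFM: path or `pfm` object.
#' @param genome Genome: FASTA path or `genome` object.
#' @param transcripts Transcript table: path (BED6 or UCSC TSV) or data
#'   frame from [read_transcripts()].
#' @param peaks Named list, TF name -> peak BED path or `genomic_intervals`.
#'   Multiple files for one TF should be concatenated before labeling.
#' @param segmentation Optional segmentation BED path or `genomic_intervals`
#'   with state labels.
#' @param gene_map Optional named character vector (or two-column data frame
#'   `accession`, `gene`) mapping transcript accessions to gene symbols;
#'   accessions without a mapping keep their accession as the gene name.
#' @param background Per-base background probabilities; default uniform.
#' @param pseudocount PFM pseudocount; default 1.
#' @param flank Upstream extension of the TSS in bp; default 5000.
#' @param threshold Inclusive relative-score cutoff; default 0.8.
#' @param report_digits Decimals for the reported relative score (3 matches
#'   the human tables, 2 the mouse tables); full precision is kept
#'   internally. Default 3.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pfm, genome, transcripts, peaks,
                            segmentation = NULL, gene_map = NULL,
                            background = rep(0.25, 4), pseudocount = 1,
                            flank = 5000L, threshold = 0.8,
                            report_digits = 3L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (flank < 0) stop("flank must be >= 0")
  if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
    stop("peaks must be a named list: TF name -> BED path or intervals")
  structure(list(pfm = pfm, genome = genome, transcripts = transcripts,
                 peaks = peaks, segmentation = segmentation,
                 gene_map = gene_map, background = background,
                 pseudocount = pseudocount, flank = flank,
                 threshold = threshold, report_digits = report_digits),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, what) {
  # a bare string is a path; loaded objects (incl. the character-backed
  # genome class) pass through untouched
  if (is.character(x) && is.null(oldClass(x)) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing ", what, " file: ", x)
    return(reader(x))
  }
  x
}

resolve_gene_map <- function(gene_map) {
  if (is.null(gene_map)) return(character(0))
  if (is.data.frame(gene_map))
    return(setNames(as.character(gene_map$gene),
                    as.character(gene_map$accession)))
  if (is.character(gene_map) && length(gene_map) == 1L &&
      file.exists(gene_map)) {
    tab <- read.table(gene_map, sep = "\t", header = FALSE,
                      col.names = c("accession", "gene"),
                      colClasses = "character")
    return(setNames(tab$gene, tab$accession))
  }
  gene_map
}

# round half up at d decimals (report convention; base round() is half-even)
round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

#' Format genomic coordinates as "chrom:start-end"
#'
#' @param chrom,start,end Coordinate triple(s), 0-based half-open.
#' @return Character vector like `"chr9:20946724-20946735"`.
#' @export
format_coordinates <- function(chrom, start, end) {
  if (any(start >= end)) stop("start must be < end")
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse "chrom:start-end" back to a coordinate triple
#'
#' @param x Character vector of coordinate strings.
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
parse_coordinates <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable coordinate string: ", x[bad][1L])
  data.frame(chrom = vapply(m, `[[`, character(1L), 2L),
             start = as.integer(vapply(m, `[[`, character(1L), 3L)),
             end = as.integer(vapply(m, `[[`, character(1L), 4L)),
             stringsAsFactors = FALSE)
}

#' Collapse duplicate sites found through multiple peaks
#'
#' Hits identical on (gene, chrom, start, end, strand) — the same site found
#' via peaks of several TFs or several experiments — collapse to one row
#' whose TF annotation is the sorted unique union of the merged labels.
#'
#' @param hits Data frame of located hits with columns `gene`, `chrom`,
#'   `start`, `end`, `strand`, `tf` (one TF per row) and any score columns
#'   (identical within a group).
#' @return Deduplicated data frame with `tfs` a list-column of sorted unique
#'   TF names.
#' @export
merge_tf_labels <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$tfs <- list()
    hits$tf <- NULL
    return(hits)
  }
  key <- paste(hits$gene, hits$chrom, hits$start, hits$end, hits$strand,
               sep = "\r")
  first <- !duplicated(key)
  out <- hits[first, setdiff(names(hits), "tf"), drop = FALSE]
  out$tfs <- lapply(split(hits$tf, factor(key, levels = key[first])),
                    function(v) sort(unique(v)))
  rownames(out) <- NULL
  out
}

#' Run the ARE discovery pipeline
#'
#' Implements the full analysis: transcript regions are extended `flank` bp
#' upstream of the TSS (transcript body included), intersected with every
#' labeled ChIP-seq peak set, the peak sequences are extracted from the
#' genome and scanned on both strands with the PSSM, hits below the relative
#' -score threshold are discarded, surviving hits are mapped back to genomic
#' coordinates (they must lie wholly inside the peak and inside the extended
#' region), duplicate sites found via several peaks are collapsed with their
#' TF labels unioned, and each site is annotated with the regulatory
#' -segmentation states it overlaps.
#'
#' @param config A [pipeline_config()].
#' @return Data frame of report rows, one per (gene, site, strand): `gene`,
#'   `coordinates`, `motif` (as matched on the reported strand),
#'   `rel_score` (full precision; `rel_score_rounded` at the report
#'   precision), `strand` (genomic), `tx_strand` (relative to the owning
#'   transcript), `regulatory_elements` (comma-joined labels or `"None"`),
#'   `tfs` (comma-joined sorted unique TF names), plus `chrom`, `start`,
#'   `end`, `abs_score`. Rows are sorted by (gene, chrom, start, strand).
#'   A `run_log` attribute reports windows scanned/skipped and hit counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pfm <- resolve_input(config$pfm, read_jaspar_pfm, "PFM")
  gen <- resolve_input(config$genome, read_fasta, "genome FASTA")
  tx <- resolve_input(config$transcripts, read_transcripts, "transcript")
  seg <- if (is.null(config$segmentation)) NULL
         else resolve_input(config$segmentation, read_segmentation_bed,
                            "segmentation BED")
  peaks <- lapply(names(config$peaks), function(tf) {
    p <- resolve_input(config$peaks[[tf]],
                       function(f) read_bed(f, label = tf), paste(tf, "peak"))
    p$label <- rep_len(tf, nrow(p))
    p
  })
  peaks <- do.call(rbind, peaks)

  gene_map <- resolve_gene_map(config$gene_map)
  if (nrow(tx) == 0L) stop("no transcripts after gene-map filtering")
  pssm <- build_pssm(pfm, background = config$background,
                     pseudocount = config$pseudocount)
  W <- pssm$width
  sizes <- chrom_sizes(gen)
  regions <- extend_upstream(tx, flank = config$flank, sizes = sizes)

  # clip peaks to chromosome bounds so sequence extraction stays in range
  known <- peaks$chrom %in% names(sizes)
  peaks <- peaks[known, , drop = FALSE]
  peaks$start <- pmax(peaks$start, 0L)
  peaks$end <- pmin(peaks$end, as.integer(sizes[peaks$chrom]))
  peaks <- peaks[peaks$start < peaks$end, , drop = FALSE]

  ov <- intersect_intervals(regions, peaks)
  log <- list(windows_scanned = 0L, windows_skipped = 0L,
              candidates = 0L, hits_post_threshold = 0L)
  rows <- list()
  # scan each distinct peak once per owning region (one row per gene later)
  for (i in seq_len(nrow(ov))) {
    ri <- ov$a_idx[i]; pi <- ov$b_idx[i]
    pk <- peaks[pi, ]
    region <- regions[ri, ]
    seq <- extract_sequence(gen, pk$chrom, pk$start, pk$end)
    hits <- scan_sequence(pssm, seq, threshold = config$threshold,
                          both_strands = TRUE)
    hl <- attr(hits, "run_log")
    log$windows_scanned <- log$windows_scanned + hl$windows_scanned
    log$windows_skipped <- log$windows_skipped + hl$windows_skipped
    log$candidates <- log$candidates + hl$candidates
    if (nrow(hits) == 0L) next
    gstart <- pk$start + hits$start
    gend <- pk$start + hits$end
    inside <- gstart >= region$start & gend <= region$end
    if (!any(inside)) next
    hits <- hits[inside, , drop = FALSE]
    acc <- region$name
    rows[[length(rows) + 1L]] <- data.frame(
      gene = if (acc %in% names(gene_map)) gene_map[[acc]] else acc,
      accession = acc,
      chrom = pk$chrom,
      start = gstart[inside],
      end = gend[inside],
      motif = hits$sequence,
      abs_score = hits$abs_score,
      rel_score = hits$rel_score,
      strand = hits$strand,
      tx_strand = ifelse(hits$strand == region$strand, "+", "-"),
      tf = pk$label,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene = character(0), coordinates = character(0),
                      motif = character(0), rel_score = numeric(0),
                      rel_score_rounded = numeric(0), strand = character(0),
                      tx_strand = character(0),
                      regulatory_elements = character(0),
                      tfs = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      abs_score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "run_log") <- log
    return(out)
  }
  hits <- do.call(rbind, rows)
  merged <- merge_tf_labels(hits)
  log$hits_post_threshold <- nrow(merged)

  reg_labels <- vapply(seq_len(nrow(merged)), function(i) {
    if (is.null(seg)) return("None")
    lab <- annotate_segmentation(merged[i, ], seg)
    if (length(lab) == 0L) "None" else paste(lab, collapse = ", ")
  }, character(1L))

  out <- data.frame(
    gene = merged$gene,
    coordinates = format_coordinates(merged$chrom, merged$start, merged$end),
    motif = merged$motif,
    rel_score = merged$rel_score,
    rel_score_rounded = round_half_up(merged$rel_score,
                                      config$report_digits),
    strand = merged$strand,
    tx_strand = merged$tx_strand,
    regulatory_elements = reg_labels,
    tfs = vapply(merged$tfs, paste, character(1L), collapse = ", "),
    chrom = merged$chrom,
    start = merged$start,
    end = merged$end,
    abs_score = merged$abs_score,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "run_log") <- log
  out
}

#' Write the report table
#'
#' TSV with header Gene / Coordinates / Motif / RelativeScore / Strand /
#' RegulatoryElement / TFs / TxStrand; RelativeScore is rounded half-up at
#' the configured precision.
#'
#' @param rows Output of [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  out <- data.frame(Gene = rows$gene, Coordinates = rows$coordinates,
                    Motif = rows$motif,
                    RelativeScore = rows$rel_score_rounded,
                    Strand = rows$strand,
                    RegulatoryElement = rows$regulatory_elements,
                    TFs = rows$tfs, TxStrand = rows$tx_strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export reported sites as BED6
#'
#' BED score column is `round(relative score * 1000)` per BED convention.
#'
#' @param rows Output of [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(rows, path) {
  x <- genomic_intervals(chrom = rows$chrom, start = rows$start,
                         end = rows$end, name = rows$gene,
                         strand = rows$strand)
  write_bed(x, path, score = as.integer(round(rows$rel_score * 1000)))
}
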