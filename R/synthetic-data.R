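#' Generate a random genome
#'
#' Bases are drawn i.i.d. from `base_probs`. The generator is fully
#' seeded: the global RNG stream is left untouched and identical seeds give
#' identical sequences.
#'
#' @param seed Integer seed.
#' @param sizes Named integer vector, chromosome name -> length.
#' @param base_probs Per-base probabilities (A, C, G, T); default uniform.
#' @return A `genome` object.
#' @examples
#' g <- generate_genome(1, c(chr1 = 1000))
#' @export
generate_genome <- function(seed, sizes, base_probs = rep(0.25, 4)) {
  stopifnot(all(sizes > 0))
  base_probs <- base_probs / sum(base_probs)
  withr::with_seed(seed, {
    seqs <- vapply(as.integer(sizes), function(n) {
      paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs),
            collapse = "")
    }, character(1L))
  })
  genome(setNames(seqs, names(sizes)))
}

#' Plant a motif into a genome
#'
#' Overwrites the genome in place at `[pos, pos + width)`. Strand `"-"`
#' plants the reverse complement on the forward strand, so the motif reads
#' as `sequence` on the minus strand.
#'
#' @param g A `genome` object.
#' @param chrom Chromosome name.
#' @param pos 0-based start position.
#' @param sequence Motif to plant (A/C/G/T).
#' @param strand `"+"` (default) or `"-"`.
#' @return The modified `genome`.
#' @export
plant_motif <- function(g, chrom, pos, sequence, strand = "+") {
  stopifnot(inherits(g, "genome"), strand %in% c("+", "-"))
  if (!chrom %in% names(g)) stop("unknown chromosome: ", chrom)
  W <- nchar(sequence)
  size <- nchar(g[[chrom]])
  if (pos < 0 || pos + W > size)
    stop("plant out of range: [", pos, ", ", pos + W, ") on ", chrom,
         " (size ", size, ")")
  fwd <- if (strand == "+") toupper(sequence) else reverse_complement(sequence)
  s <- unclass(g)
  substr(s[[chrom]], pos + 1L, pos + W) <- fwd
  genome(s)
}

# sample a W-mer by mutating the PSSM consensus until the relative score
# lands in [lo, hi); used to construct plants of known score class
sample_scored_motif <- function(pssm, lo, hi, max_tries = 2000L) {
  W <- pssm$width
  consensus <- DNA_BASES[apply(pssm$scores, 2L, which.max)]
  for (i in seq_len(max_tries)) {
    cand <- if (stats::runif(1) < 0.5 || lo < 0.5) {
      paste(sample(DNA_BASES, W, replace = TRUE), collapse = "")
    } else {
      mut <- consensus
      k <- sample(0:2, 1L)
      if (k > 0) {
        at <- sample(W, k)
        mut[at] <- sample(DNA_BASES, k, replace = TRUE)
      }
      paste(mut, collapse = "")
    }
    rel <- relative_score(pssm, score_window(pssm, cand))
    if (rel >= lo && rel < hi) return(list(sequence = cand, rel = rel))
  }
  stop("could not sample a motif with relative score in [", lo, ", ", hi, ")")
}

#' Generate a full synthetic scenario with a truth manifest
#'
#' Emits everything the pipeline consumes — genome FASTA, chrom.sizes,
#' per-TF peak BEDs, transcript table, segmentation BED — plus a manifest of
#' planted motifs whose expected relative scores are computed by direct
#' standalone rescoring (never by the pipeline under test). Plants are
#' spaced at least one motif width apart. Three plant classes are supported:
#' in-peak above-threshold (recoverable), off-peak above-threshold (must not
#' be reported), and in-peak below-threshold (must be discarded).
#'
#' @param seed Integer seed; the whole file set is a deterministic function
#'   of it.
#' @param out_dir Directory for the emitted files (created if needed).
#' @param pssm The scenario PSSM (defaults to MA0150.1, uniform background,
#'   pseudocount 1).
#' @param n_in_peak Above-threshold plants inside peaks and regions
#'   (default 3).
#' @param n_off_peak Above-threshold plants inside regions but outside every
#'   peak (default 1).
#' @param n_below Below-threshold plants inside peaks (default 1).
#' @param chrom_size Length of the single synthetic chromosome
#'   (default 50000).
#' @param peak_width ChIP peak width in bp (default 200).
#' @param tx_width Transcript length in bp (default 2000).
#' @param flank Upstream extension the scenario is built for (default 5000).
#' @param threshold Relative-score threshold separating plant classes
#'   (default 0.8).
#' @param tf_names TFs to distribute peaks over (default Nfe2l2/Mafk/Maff).
#' @param seg_states Segmentation state labels tiled over the region
#'   (default TSS, PF, T).
#' @return A `scenario_manifest`: list with `seed`, `sizes`, `files` (named
#'   paths), `plants` (data frame: chrom, pos, sequence, strand,
#'   expected_rel, in_peak, in_region, tf) and `config` (a ready-to-run
#'   [pipeline_config()]).
#' @export
generate_scenario <- function(seed, out_dir,
                              pssm = build_pssm(read_jaspar_pfm(ma0150_pfm_path())),
                              n_in_peak = 3L, n_off_peak = 1L, n_below = 1L,
                              chrom_size = 50000L, peak_width = 200L,
                              tx_width = 2000L, flank = 5000L,
                              threshold = 0.8,
                              tf_names = c("Nfe2l2", "Mafk", "Maff"),
                              seg_states = c("TSS", "PF", "T")) {
  W <- pssm$width
  n_plants <- n_in_peak + n_off_peak + n_below
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # one + strand transcript; its extended region is [region_start, tx_end)
  tx_start <- as.integer(flank + 1000L)
  tx_end <- tx_start + as.integer(tx_width)
  region_start <- max(0L, tx_start - as.integer(flank))
  region_end <- tx_end
  if (region_end - region_start < n_plants * (peak_width + 4L * W))
    stop("infeasible placement: region too small for requested plants")

  withr::with_seed(seed, {
    g <- genome(setNames(
      paste(sample(DNA_BASES, chrom_size, replace = TRUE), collapse = ""),
      "chrS"))

    # evenly partition the region into slots, one plant per slot
    slots <- floor(seq(region_start, region_end - peak_width,
                       length.out = n_plants + 1L))
    classes <- c(rep("in_peak", n_in_peak), rep("off_peak", n_off_peak),
                 rep("below", n_below))
    classes <- sample(classes)

    plants <- vector("list", n_plants)
    peak_rows <- vector("list", n_plants)
    for (i in seq_len(n_plants)) {
      lo_slot <- slots[i]; hi_slot <- slots[i + 1L]
      cls <- classes[[i]]
      m <- if (cls == "below") sample_scored_motif(pssm, 0, threshold - 0.02)
           else sample_scored_motif(pssm, min(threshold + 0.02, 1), 1.0001)
      strand <- sample(c("+", "-"), 1L)
      if (cls == "off_peak") {
        pos <- lo_slot + sample.int(hi_slot - lo_slot - W, 1L)
        peak <- NULL
      } else {
        pk_start <- lo_slot + sample.int(max(1L, hi_slot - lo_slot -
                                               peak_width), 1L)
        pk_end <- pk_start + peak_width
        pos <- pk_start + W + sample.int(peak_width - 3L * W, 1L)
        peak <- c(pk_start, pk_end)
      }
      g <- plant_motif(g, "chrS", pos, m$sequence, strand)
      plants[[i]] <- data.frame(
        chrom = "chrS", pos = as.integer(pos), sequence = m$sequence,
        strand = strand, expected_rel = m$rel,
        in_peak = cls != "off_peak", in_region = TRUE,
        above_threshold = cls != "below",
        tf = tf_names[(i - 1L) %% length(tf_names) + 1L],
        stringsAsFactors = FALSE)
      peak_rows[[i]] <- if (is.null(peak)) NULL else
        data.frame(tf = plants[[i]]$tf, start = peak[1L], end = peak[2L])
    }
  })
  plants <- do.call(rbind, plants)
  peak_tab <- do.call(rbind, peak_rows)

  # re-verify expected scores on the final genome: a later plant or random
  # background must not have corrupted an earlier plant's window
  for (i in seq_len(nrow(plants))) {
    got <- extract_sequence(g, plants$chrom[i], plants$pos[i],
                            plants$pos[i] + W)
    if (plants$strand[i] == "-") got <- reverse_complement(got)
    if (got != plants$sequence[i])
      stop("infeasible placement: plants collided (seed ", seed, ")")
  }

  sizes <- chrom_sizes(g)
  files <- list(
    fasta = file.path(out_dir, "genome.fa"),
    chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
    transcripts = file.path(out_dir, "transcripts.bed"),
    segmentation = file.path(out_dir, "segmentation.bed"),
    manifest = file.path(out_dir, "manifest.tsv"))
  write_fasta(g, files$fasta)
  write_chrom_sizes(sizes, files$chrom_sizes)
  write_bed(genomic_intervals("chrS", tx_start, tx_end,
                              name = "NM_000001", strand = "+"),
            files$transcripts)

  peak_paths <- list()
  for (tf in unique(plants$tf)) {
    path <- file.path(out_dir, paste0("peaks_", tf, ".bed"))
    p <- if (is.null(peak_tab)) NULL
         else peak_tab[peak_tab$tf == tf, , drop = FALSE]
    if (is.null(p) || nrow(p) == 0L) {
      writeLines(character(0), path)
    } else {
      write_bed(genomic_intervals("chrS", p$start, p$end), path)
    }
    peak_paths[[tf]] <- path
  }

  # tile segmentation states across the regulatory region
  seg_bounds <- floor(seq(region_start, region_end,
                          length.out = length(seg_states) + 1L))
  seg <- genomic_intervals("chrS", seg_bounds[-length(seg_bounds)],
                           seg_bounds[-1L], name = seg_states)
  write_bed(seg, files$segmentation)

  write.table(plants, files$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)

  config <- pipeline_config(
    pfm = ma0150_pfm_path(), genome = files$fasta,
    transcripts = files$transcripts,
    peaks = peak_paths, segmentation = files$segmentation,
    gene_map = setNames("SynGene", "NM_000001"),
    flank = flank, threshold = threshold)

  structure(list(seed = seed, sizes = sizes, files = files,
                 plants = plants, region = c(region_start, region_end),
                 config = config),
            class = "scenario_manifest")
}

#' @export
print.scenario_manifest <- function(x, ...) {
  cat("synthetic ARE scenario (seed ", x$seed, ")\n", sep = "")
  cat("chromosomes:", paste(names(x$sizes), x$sizes, collapse = ", "), "\n")
  cat("plants:\n")
  print(x$plants)
  invisible(x)
}
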