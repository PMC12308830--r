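# Windowed genomic feature densities and chromosome-level bootstrap summaries.

#' Tile chromosomes into fixed-size windows
#'
#' Each chromosome is tiled into consecutive windows of `window` bases. A
#' trailing partial window is kept only when it spans at least
#' `drop_partial_below` bases (default half a window): tiny terminal
#' windows give high-variance density estimates, while discarding up to
#' half a window avoids systematically trimming small chromosomes.
#'
#' @param chrom_sizes A data.frame with columns `chrom` and `length`, a
#'   named numeric vector, a two-column TSV path, or a FASTA
#'   path/`DNAStringSet` (lengths taken from the sequences).
#' @param window Window size in bases (default 100,000, the standard
#'   window for chromosome-scale repeat-density profiles).
#' @param drop_partial_below Minimum span for a trailing partial window.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @examples
#' make_windows(c(chr1 = 250000), window = 100000)
#' @export
make_windows <- function(chrom_sizes, window = 100000,
                         drop_partial_below = window / 2) {
  sizes <- load_chrom_sizes(chrom_sizes)
  if (any(sizes$length <= 0)) {
    stop("zero- or negative-length chromosome: ",
         paste(sizes$chrom[sizes$length <= 0], collapse = ", "))
  }
  if (window <= 0) stop("window must be positive")
  res <- lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$length[i]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    keep <- (ends - starts) >= pmin(window, drop_partial_below) |
      (ends - starts) == window
    data.frame(chrom = rep(sizes$chrom[i], sum(keep)),
               start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-window repeat density
#'
#' Density is the fraction of each window covered by the interval union of
#' the supplied annotation records: overlapping hits are merged first, so
#' densities cannot exceed 1 and never double-count nested or
#' `*`-flagged overlapping hits.
#'
#' @param windows data.frame from [make_windows()].
#' @param records TE annotation data.frame ([read_repeatmasker()]).
#' @param chrom_sizes Optional chromosome sizes; when given, records
#'   extending beyond a chromosome end raise an error.
#' @return `windows` with added columns `repeat_density` and
#'   `covered_bases`.
#' @export
repeat_density <- function(windows, records, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    sizes <- load_chrom_sizes(chrom_sizes)
    lens <- stats::setNames(sizes$length, sizes$chrom)
    over <- records$end > lens[records$chrom]
    if (any(over, na.rm = TRUE)) {
      stop("record beyond chromosome end on ",
           records$chrom[which(over)[1]])
    }
  }
  covered <- covered_per_window(windows, records)
  windows$covered_bases <- covered
  windows$repeat_density <- covered / (windows$end - windows$start)
  windows
}

#' Per-window GC content
#'
#' GC is computed over unambiguous bases only: (G+C)/(A+C+G+T),
#' case-insensitively (soft-masked lowercase counts normally). Windows
#' with no unambiguous base get `NA`.
#'
#' @param windows data.frame from [make_windows()].
#' @param fasta Genome FASTA path or `DNAStringSet`.
#' @return `windows` with added columns `gc` and `n_effective_bases` (the
#'   unambiguous-base count).
#' @export
gc_content <- function(windows, fasta) {
  genome <- load_genome(fasta)
  missing <- setdiff(unique(windows$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))
  }
  windows$gc <- NA_real_
  windows$n_effective_bases <- 0L
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = windows$start[idx] + 1L,
                           end = windows$end[idx])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
    windows$gc[idx] <- gc
    windows$n_effective_bases[idx] <- as.integer(denom)
  }
  windows
}

#' Per-window coding-sequence density
#'
#' CDS intervals from a GFF3/GTF annotation are unioned (strand-agnostic;
#' shared exons of alternative isoforms count once) and intersected with
#' each window.
#'
#' @param windows data.frame from [make_windows()].
#' @param annotation GFF3/GTF path or `GRanges` containing CDS features.
#' @return `windows` with added column `cds_density`.
#' @export
cds_density <- function(windows, annotation) {
  ann <- load_annotation(annotation)
  cds <- ann[!is.na(ann$type) & ann$type == "CDS"]
  if (length(cds) == 0) stop("annotation contains no CDS features")
  cds_df <- gr_to_ranges(cds)
  covered <- covered_per_window(windows, cds_df)
  windows$cds_density <- covered / (windows$end - windows$start)
  windows
}

#' Chromosome-level mean with percentile-bootstrap confidence interval
#'
#' For each chromosome the windows' statistic is averaged and a percentile
#' bootstrap (windows resampled with replacement, `B` replicates, all
#' windows weighted equally) yields a confidence interval. `NA` windows
#' (e.g. all-N GC windows) are dropped before resampling.
#'
#' @param window_stats data.frame of per-window statistics (must contain
#'   `chrom` and the `stat` column).
#' @param stat Name of the column to summarize.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return data.frame with one row per chromosome: `chrom`, `mean_stat`,
#'   `ci_low`, `ci_high`, `n_windows`, `stat`, `boot_reps`, `seed`.
#' @export
chromosome_summary <- function(window_stats, stat, B = 1000, seed = 1,
                               conf = 0.95) {
  if (!stat %in% names(window_stats)) stop("no column '", stat, "'")
  chroms <- unique(window_stats$chrom)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- lapply(chroms, function(ch) {
      x <- window_stats[[stat]][window_stats$chrom == ch]
      x <- x[!is.na(x)]
      if (length(x) == 0) stop("no usable windows on ", ch)
      m <- mean(x)
      if (length(x) == 1) {
        ci <- c(m, m)
      } else {
        boots <- rowMeans(matrix(sample(x, length(x) * B, replace = TRUE),
                                 nrow = B))
        ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      }
      data.frame(chrom = ch, mean_stat = m, ci_low = ci[1], ci_high = ci[2],
                 n_windows = length(x), stat = stat, boot_reps = B,
                 seed = seed, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Repeat density by distance to the nearer chromosome end
#'
#' Windows of `bin` bases are laid from both chromosome ends toward the
#' middle; repeat coverage is pooled across chromosomes within each
#' distance bin. A flat profile indicates no telomere-proximal enrichment.
#'
#' @param records TE annotation data.frame.
#' @param chrom_sizes Chromosome sizes (see [make_windows()]).
#' @param bin Bin width in bases.
#' @return data.frame with `distance_bin` (0-based bin index from the
#'   chromosome end), `dist_start`, `dist_end`, `covered_bases`,
#'   `total_bases`, `repeat_density`.
#' @export
telomere_profile <- function(records, chrom_sizes, bin = 100000) {
  sizes <- load_chrom_sizes(chrom_sizes)
  if (bin > min(sizes$length) / 2) {
    stop("bin exceeds half the smallest chromosome length")
  }
  max_bins <- floor(max(sizes$length) / 2 / bin)
  covered <- numeric(max_bins)
  total <- numeric(max_bins)
  for (i in seq_len(nrow(sizes))) {
    ch <- sizes$chrom[i]
    L <- sizes$length[i]
    nb <- floor(L / 2 / bin)
    if (nb == 0) next
    b <- seq_len(nb) - 1
    segs <- data.frame(
      chrom = ch,
      start = c(b * bin, L - (b + 1) * bin),
      end = c((b + 1) * bin, L - b * bin)
    )
    recs <- records[records$chrom == ch, , drop = FALSE]
    cov <- covered_per_window(segs, recs)
    covered[b + 1] <- covered[b + 1] + cov[seq_len(nb)] + cov[nb + seq_len(nb)]
    total[b + 1] <- total[b + 1] + 2 * bin
  }
  data.frame(distance_bin = seq_len(max_bins) - 1,
             dist_start = (seq_len(max_bins) - 1) * bin,
             dist_end = seq_len(max_bins) * bin,
             covered_bases = covered, total_bases = total,
             repeat_density = ifelse(total > 0, covered / total, NA_real_))
}
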