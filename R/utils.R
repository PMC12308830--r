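# Internal helpers shared across modules. Intervals are 0-based half-open
# everywhere inside the package; conversion to/from 1-based inclusive happens
# only at the I/O boundary (.out, GFF, VCF are 1-based; BED matches internal).

#' @importFrom stats runif rnorm rpois rbinom rlnorm quantile integrate optim
#'   cor cor.test p.adjust lm pt coef dbinom dhyper dpois pgamma setNames
#'   complete.cases
#' @importFrom utils read.table write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# data.frame(chrom, start, end) [0-based half-open] -> GRanges (1-based)
ranges_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

gr_to_ranges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Bases of `ranges` (after union/reduce) covered within each window.
# `windows` and `ranges` are 0-based half-open data.frames.
covered_per_window <- function(windows, ranges) {
  if (nrow(windows) == 0) return(integer(0))
  covered <- integer(nrow(windows))
  if (nrow(ranges) == 0) return(covered)
  win_gr <- ranges_to_gr(windows)
  red <- GenomicRanges::reduce(ranges_to_gr(ranges))
  hits <- GenomicRanges::findOverlaps(win_gr, red)
  if (length(hits) > 0) {
    pi_ <- GenomicRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                                     red[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(pi_)
    agg <- rowsum(w, group = S4Vectors::queryHits(hits))
    covered[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  }
  covered
}

# TRUE for positions (0-based) falling inside any interval of `bed`
# (data.frame chrom/start/end, 0-based half-open).
positions_in_bed <- function(chrom, pos, bed) {
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(pos)))
  pos_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  bed_gr <- ranges_to_gr(bed)
  GenomicRanges::countOverlaps(pos_gr, bed_gr) > 0
}

# Read a BED file (via rtracklayer) into the internal 0-based representation.
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr_to_ranges(gr)
}

write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  utils::write.table(df[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Deterministic TSV writer used by all report tables.
write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Load a genome as a named DNAStringSet; names truncated at first whitespace
# to match GFF/VCF seqnames.
load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' @importFrom methods is
NULL

# Load gene annotation as GRanges from GFF3/GTF path, or pass GRanges through.
load_annotation <- function(annotation) {
  if (is.character(annotation)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", annotation)))
    fmt <- if (ext %in% c("gtf")) "GTF" else "GFF3"
    annotation <- rtracklayer::import(annotation, format = fmt)
  }
  stopifnot(methods::is(annotation, "GRanges"))
  annotation
}

# chrom_sizes accessor: accepts a data.frame(chrom, length), a TSV path, a
# named numeric vector, or a DNAStringSet/FASTA path.
load_chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("fa", "fasta", "fna")) {
      g <- load_genome(x)
      return(data.frame(chrom = names(g), length = Biostrings::width(g),
                        stringsAsFactors = FALSE))
    }
    tab <- utils::read.table(x, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    if (is.character(tab[[1]]) && tab[[1]][1] %in% c("chrom", "chromosome")) {
      tab <- tab[-1, , drop = FALSE]
    }
    return(data.frame(chrom = as.character(tab[[1]]),
                      length = as.numeric(tab[[2]]),
                      stringsAsFactors = FALSE))
  }
  if (methods::is(x, "DNAStringSet")) {
    return(data.frame(chrom = names(x), length = Biostrings::width(x),
                      stringsAsFactors = FALSE))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.frame(chrom = names(x), length = as.numeric(x),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "length") %in% names(x)))
  x
}
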