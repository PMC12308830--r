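# Shared in-code fixtures and independent oracles. Oracles are written as
# directly as possible (per-base bitmaps, exhaustive searches, hand-applied
# formulas) so they never share code paths with the implementation.

rm_header <- c(
  "   SW  perc perc perc  query     position in query            matching repeat       position in repeat",
  "score  div. del. ins.  sequence  begin end        (left)   repeat class/family   begin end    (left)  ID",
  ""
)

write_rm_out <- function(lines, path = tempfile(fileext = ".out")) {
  writeLines(c(rm_header, lines), path)
  path
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  path
}

# Minimal GFF3 writer: `cds` is a data.frame with chrom, start, end
# (1-based inclusive), strand, phase, tx.
write_gff3_fixture <- function(cds, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (tx in unique(cds$tx)) {
    d <- cds[cds$tx == tx, , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
              d$chrom[1], min(d$start), max(d$end), d$strand[1], tx),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c;Parent=%s",
              d$chrom, d$start, d$end, d$strand, d$phase, tx, tx))
  }
  writeLines(lines, path)
  path
}

# Minimal all-sites VCF writer: gt is an L x n_samples matrix of genotype
# strings; ref/alt are per-site vectors (alt "." for invariant sites).
write_vcf_fixture <- function(chrom, pos, ref, alt, gt,
                              path = tempfile(fileext = ".vcf")) {
  ns <- ncol(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", unique(chrom),
            max(pos[chrom == chrom]) + 10L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%d", seq_len(ns))), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", chrom, pos, ref,
                  alt, apply(gt, 1, paste, collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# Oracle: per-base bitmap coverage of intervals within [0, len).
bitmap_covered <- function(starts, ends, win_start, win_end) {
  if (length(starts) == 0) return(0L)
  len <- max(ends, win_end)
  bm <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) bm[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(bm[(win_start + 1):win_end])
}

# Oracle: exhaustive nearest-following-neighbour gaps (distinct starts).
brute_force_gaps <- function(starts, ends) {
  n <- length(starts)
  out <- numeric(0)
  for (i in seq_len(n)) {
    later <- which(starts > starts[i])
    if (length(later) == 0) next
    j <- later[which.min(starts[later])]
    out <- c(out, max(0, starts[j] - ends[i]))
  }
  sort(out)
}

# Oracle: hand-applied Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  if (m == 1) out <- pmin(p, 1)
  out
}

# Oracle: naive average pairwise difference over haplotype rows
# (full-call data), as a per-site average.
naive_pi <- function(hap) {
  n <- nrow(hap)
  L <- ncol(hap)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(hap[i, ] != hap[j, ]) / L
    np <- np + 1
  }
  tot / np
}

# Random full-call diploid VCF built from an explicit haplotype matrix;
# returns the path and the haplotypes for the oracle.
random_fullcall_vcf <- function(n_dip, L, seed) {
  set.seed(seed)
  hap <- matrix(0L, nrow = 2 * n_dip, ncol = L)
  n_var <- rbinom(1, L, 0.3)
  var_sites <- sample(L, n_var)
  for (s in var_sites) {
    hap[, s] <- rbinom(2 * n_dip, 1, runif(1, 0.05, 0.95))
  }
  gt <- matrix("", nrow = L, ncol = n_dip)
  for (d in seq_len(n_dip)) {
    gt[, d] <- paste(hap[2 * d - 1, ], hap[2 * d, ], sep = "/")
  }
  alt <- ifelse(colSums(hap) > 0, "T", ".")
  path <- write_vcf_fixture("chr1", seq_len(L), rep("A", L), alt, gt)
  list(path = path, hap = hap, L = L)
}

# Single-gene genome/annotation pair from an explicit CDS string placed at
# `offset` (0-based) on the given strand of a padded chromosome.
single_gene_fixture <- function(cds_seq, strand = "+", offset = 10,
                                chrom = "chrA") {
  pad_left <- paste(rep("C", offset), collapse = "")
  pad_right <- paste(rep("G", 12), collapse = "")
  genomic <- if (strand == "+") cds_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  seqs <- stats::setNames(list(paste0(pad_left, genomic, pad_right)), chrom)
  fa <- write_fasta(seqs)
  gff <- write_gff3_fixture(data.frame(
    chrom = chrom, start = offset + 1, end = offset + nchar(cds_seq),
    strand = strand, phase = 0L, tx = "tx1", stringsAsFactors = FALSE
  ))
  list(fasta = fa, gff = gff, start0 = offset,
       end0 = offset + nchar(cds_seq))
}

make_te_df <- function(chrom, start, end, divergence,
                       te_class = "LINE", te_family = "L1",
                       strand = "+") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), divergence = divergence,
             pct_del = 0, pct_ins = 0,
             repeat_name = rep_len("rep", n),
             te_class = rep_len(te_class, n),
             te_family = rep_len(te_family, n),
             score = 1000, id = as.character(seq_len(n)),
             overlap_flag = FALSE, stringsAsFactors = FALSE)
}
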