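# Missing-data-aware nucleotide diversity from all-sites VCFs: the
# ratio-of-sums estimator (sum of pairwise differences over sum of pairwise
# comparisons across retained sites), which stays unbiased when genotypes
# are missing, unlike a mean of per-site ratios.

#' Read an all-sites VCF
#'
#' Thin wrapper over `vcfR::read.vcfR` returning the components the
#' diversity and SFS builders need. The VCF must retain invariant sites so
#' that diversity denominators are correct.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return List with `chrom`, `pos` (1-based), `ref`, `alt` and the
#'   genotype matrix `gt` (sites x samples, `"0/0"`-style strings).
#' @export
read_allsites_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  list(chrom = as.character(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]),
       ref = as.character(fix[, "REF"]),
       alt = as.character(fix[, "ALT"]),
       gt = gt)
}

# Per-site allele bookkeeping from a genotype matrix: called allele number
# k, pairwise comparisons k(k-1)/2, pairwise differences
# (k^2 - sum_a count_a^2)/2, and the per-allele count matrix.
site_allele_stats <- function(gt) {
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1)
  nsite <- nrow(gt)
  cells <- as.vector(gt)
  cells[is.na(cells)] <- "."
  parts <- strsplit(cells, "[/|]")
  site_of_cell <- rep(rep(seq_len(nsite), times = ncol(gt)), lengths(parts))
  alle <- unlist(parts, use.names = FALSE)
  called <- alle != "." & alle != ""
  site_of_allele <- site_of_cell[called]
  ai <- as.integer(alle[called]) + 1L
  maxa <- max(c(ai, 1L))
  counts <- matrix(
    tabulate((site_of_allele - 1L) * maxa + ai, nbins = nsite * maxa),
    nrow = nsite, ncol = maxa, byrow = TRUE
  )
  k <- rowSums(counts)
  comparisons <- k * (k - 1) / 2
  diffs <- (k^2 - rowSums(counts^2)) / 2
  list(k = k, n_diffs = diffs, n_comparisons = comparisons,
       allele_counts = counts)
}

#' Windowed nucleotide diversity from an all-sites VCF
#'
#' Per site, differences are counted over all unordered pairs of called
#' alleles and comparisons are `k(k-1)/2` for `k` called alleles; window pi
#' is the ratio of the summed differences to the summed comparisons over
#' retained sites (ratio of sums, not mean of per-site ratios). Sites in
#' `exclude_bed` are dropped; when `site_mask` is given (e.g. a 0D or 4D
#' BED), only masked sites contribute. The chromosome-level pi is the
#' unweighted mean of window pi values (windows with zero comparisons are
#' dropped and counted); the ratio-of-sums over the whole chromosome is
#' also reported.
#'
#' @param vcf Path to an all-sites VCF or the list from
#'   [read_allsites_vcf()].
#' @param windows data.frame from [make_windows()].
#' @param site_mask Optional BED data.frame/path restricting contributing
#'   sites (0-based half-open).
#' @param exclude_bed Optional BED data.frame/path of sites to drop.
#' @return List with `windows` (per-window `pi`, `n_sites`, `n_diffs`,
#'   `n_comparisons`) and `chromosomes` (`pi` = mean of window pi,
#'   `pi_ratio_of_sums`, `n_windows`, `n_windows_dropped`).
#' @export
pi_windows <- function(vcf, windows, site_mask = NULL, exclude_bed = NULL) {
  if (is.character(vcf)) vcf <- read_allsites_vcf(vcf)
  if (is.character(site_mask)) site_mask <- read_bed(site_mask)
  if (is.character(exclude_bed)) exclude_bed <- read_bed(exclude_bed)
  missing_chr <- setdiff(unique(windows$chrom), unique(vcf$chrom))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from VCF: ", paste(missing_chr, collapse = ", "))
  }
  st <- site_allele_stats(vcf$gt)
  pos0 <- vcf$pos - 1L
  keep <- rep(TRUE, length(pos0))
  if (!is.null(exclude_bed)) {
    keep <- keep & !positions_in_bed(vcf$chrom, pos0, exclude_bed)
  }
  if (!is.null(site_mask)) {
    keep <- keep & positions_in_bed(vcf$chrom, pos0, site_mask)
  }
  site_gr <- GenomicRanges::GRanges(vcf$chrom,
                                    IRanges::IRanges(vcf$pos, vcf$pos))
  win_gr <- ranges_to_gr(windows)
  hits <- GenomicRanges::findOverlaps(site_gr, win_gr)
  wi <- rep(NA_integer_, length(pos0))
  wi[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  use <- keep & !is.na(wi)
  sum_by <- function(x) {
    out <- numeric(nrow(windows))
    if (any(use)) {
      agg <- rowsum(x[use], group = wi[use])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  wd <- sum_by(st$n_diffs)
  wc <- sum_by(st$n_comparisons)
  ns <- numeric(nrow(windows))
  if (any(use)) {
    agg <- rowsum(rep(1, sum(use)), group = wi[use])
    ns[as.integer(rownames(agg))] <- agg[, 1]
  }
  wtab <- windows
  wtab$n_sites <- ns
  wtab$n_diffs <- wd
  wtab$n_comparisons <- wc
  wtab$pi <- ifelse(wc > 0, wd / wc, NA_real_)
  chroms <- unique(windows$chrom)
  ctab <- do.call(rbind, lapply(chroms, function(ch) {
    w <- wtab[wtab$chrom == ch, , drop = FALSE]
    ok <- !is.na(w$pi)
    data.frame(
      chrom = ch,
      pi = if (any(ok)) mean(w$pi[ok]) else NA_real_,
      pi_ratio_of_sums = if (sum(w$n_comparisons) > 0) {
        sum(w$n_diffs) / sum(w$n_comparisons)
      } else NA_real_,
      n_windows = sum(ok),
      n_windows_dropped = sum(!ok),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ctab) <- NULL
  list(windows = wtab, chromosomes = ctab)
}

#' Per-chromosome 0D/4D diversity ratio
#'
#' The ratio of the chromosome-mean window pi at 0-fold degenerate sites to
#' the corresponding 4-fold value, a proxy for the relative efficacy of
#' purifying selection (1 in the neutral limit, smaller under stronger
#' selection).
#'
#' @param pi_0d,pi_4d `chromosomes` data.frames from [pi_windows()] run
#'   with the 0D and 4D site masks respectively.
#' @return data.frame with `chrom`, `pi_0d`, `pi_4d`, `ratio_0d_4d` (`NA`,
#'   flagged, when the 4D mean is zero or undefined).
#' @export
chromosome_pi_ratio <- function(pi_0d, pi_4d) {
  m <- merge(pi_0d[, c("chrom", "pi")], pi_4d[, c("chrom", "pi")],
             by = "chrom", suffixes = c("_0d", "_4d"))
  names(m) <- c("chrom", "pi_0d", "pi_4d")
  m$ratio_0d_4d <- ifelse(is.finite(m$pi_4d) & m$pi_4d > 0,
                          m$pi_0d / m$pi_4d, NA_real_)
  m
}
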