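# Adjacent inter-TE distances within divergence-based age classes and the
# young/old spacing ratio, the statistic used to detect preferential loss of
# inter-TE sequence (e.g. by non-allelic homologous recombination) on small
# chromosomes.

#' Distances between adjacent TEs of one age class
#'
#' Records of the requested age class on a single chromosome are sorted by
#' start; for each consecutive pair the distance is the number of bases
#' strictly between them (`next_start - prev_end` in 0-based half-open
#' coordinates), floored at zero for overlapping or nested pairs. Pairs are
#' formed within the age class only: copies of the other class lying
#' between a pair do not break it.
#'
#' @param records TE annotation data.frame for a single chromosome.
#' @param age `"young"` or `"old"`.
#' @param young_max,old_min,old_max Divergence thresholds passed to
#'   [classify_age()].
#' @param mode `"gap"` (default, end-to-start intervening bases — the
#'   sequence that deletion would remove) or `"start-to-start"`.
#' @return Numeric vector of distances; empty when fewer than two records
#'   fall in the class.
#' @export
inter_te_distances <- function(records, age = c("young", "old"),
                               young_max = 5, old_min = 5, old_max = 10,
                               mode = c("gap", "start-to-start")) {
  age <- match.arg(age)
  mode <- match.arg(mode)
  if (nrow(records) == 0) return(numeric(0))
  if (length(unique(records$chrom)) > 1) {
    stop("records span multiple chromosomes; split by chromosome first")
  }
  cls <- classify_age(records$divergence, young_max, old_min, old_max)
  r <- records[cls == age, , drop = FALSE]
  if (nrow(r) < 2) return(numeric(0))
  o <- order(r$start, r$end)
  r <- r[o, , drop = FALSE]
  n <- nrow(r)
  if (mode == "gap") {
    pmax(0, r$start[-1] - r$end[-n])
  } else {
    r$start[-1] - r$start[-n]
  }
}

#' Per-chromosome spacing summary and young/old ratio
#'
#' Mean adjacent-pair distance per age class and their ratio
#' (young over old). The ratio is `NA` when either class has fewer than
#' two copies or the old-class mean is zero.
#'
#' @param records TE annotation data.frame (single chromosome, or pass
#'   `chrom` to subset).
#' @param chrom Optional chromosome name to subset `records`.
#' @inheritParams inter_te_distances
#' @return One-row data.frame: `chrom`, `n_pairs_young`, `mean_dist_young`,
#'   `n_pairs_old`, `mean_dist_old`, `ratio_young_over_old`.
#' @export
spacing_summary <- function(records, chrom = NULL, young_max = 5,
                            old_min = 5, old_max = 10, mode = "gap") {
  if (!is.null(chrom)) records <- records[records$chrom == chrom, ,
                                          drop = FALSE]
  ch <- if (nrow(records)) unique(records$chrom)[1] else
    if (!is.null(chrom)) chrom else NA_character_
  dy <- inter_te_distances(records, "young", young_max, old_min, old_max,
                           mode = mode)
  do <- inter_te_distances(records, "old", young_max, old_min, old_max,
                           mode = mode)
  my <- if (length(dy)) mean(dy) else NA_real_
  mo <- if (length(do)) mean(do) else NA_real_
  ratio <- if (length(dy) && length(do) && mo > 0) my / mo else NA_real_
  data.frame(chrom = ch, n_pairs_young = length(dy), mean_dist_young = my,
             n_pairs_old = length(do), mean_dist_old = mo,
             ratio_young_over_old = ratio, stringsAsFactors = FALSE)
}

#' Spacing summaries for every chromosome
#'
#' @param records TE annotation data.frame (any number of chromosomes).
#' @inheritParams spacing_summary
#' @return data.frame with one row per chromosome, as [spacing_summary()].
#' @export
spacing_by_chromosome <- function(records, young_max = 5, old_min = 5,
                                  old_max = 10, mode = "gap") {
  ch_v <- records$chrom
  st_v <- records$start
  en_v <- records$end
  cls <- if (nrow(records)) {
    classify_age(records$divergence, young_max, old_min, old_max)
  } else character(0)
  gap_stats <- function(sel) {
    if (sum(sel) < 2) return(c(0, NA_real_))
    s <- st_v[sel]
    e <- en_v[sel]
    o <- order(s, e)
    s <- s[o]
    e <- e[o]
    d <- if (mode == "gap") pmax(0, s[-1] - e[-length(e)]) else diff(s)
    c(length(d), mean(d))
  }
  chroms <- sort(unique(ch_v))
  rows <- lapply(chroms, function(ch) {
    inch <- ch_v == ch
    y <- gap_stats(inch & cls == "young")
    o <- gap_stats(inch & cls == "old")
    ratio <- if (y[1] > 0 && o[1] > 0 && !is.na(o[2]) && o[2] > 0) {
      y[2] / o[2]
    } else NA_real_
    data.frame(chrom = ch, n_pairs_young = y[1], mean_dist_young = y[2],
               n_pairs_old = o[1], mean_dist_old = o[2],
               ratio_young_over_old = ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
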