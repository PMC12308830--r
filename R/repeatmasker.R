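# RepeatMasker .out input/output and divergence-based TE age classes.

#' Read a RepeatMasker annotation (.out) file
#'
#' Parses the standard RepeatMasker `.out` layout: three header lines
#' followed by whitespace-separated columns (SW score, %div, %del, %ins,
#' query, begin, end, (left), strand, repeat, class/family, repeat begin,
#' repeat end, (left), ID, optional `*` overlap flag). Query coordinates are
#' converted from 1-based inclusive to the package-internal 0-based
#' half-open convention, strand `C` is mapped to `-`, and the class/family
#' column is split at its first `/`. Lines flagged `*` (higher-scoring
#' overlap elsewhere) are retained; filtering them is left to the caller.
#' Gzipped files are read transparently.
#'
#' @param path Path to a RepeatMasker `.out` (optionally gzipped) file.
#' @param min_length Drop hits whose query span is shorter than this many
#'   bases. Default 0 (no length filter).
#' @return A data.frame with one row per hit and columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `divergence` (the %div
#'   column), `pct_del`, `pct_ins`, `repeat_name`, `te_class`, `te_family`,
#'   `score`, `id`, `overlap_flag`.
#' @seealso [write_repeatmasker()], [classify_age()], [filter_te_records()]
#' @export
read_repeatmasker <- function(path, min_length = 0) {
  lines <- readLines(path)
  nonblank <- nzchar(trimws(lines))
  # header: leading lines whose first token is not a number (classic 2-line
  # banner + 1 blank); be liberal so bannerless files still parse
  first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)
  is_data <- nonblank & grepl("^[0-9]+$", first_tok)
  data_idx <- which(is_data)
  if (length(data_idx) == 0) {
    warning("no annotation records in ", path)
    return(empty_te_records())
  }
  recs <- vector("list", length(data_idx))
  for (j in seq_along(data_idx)) {
    i <- data_idx[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14 || length(f) > 16) {
      stop("malformed RepeatMasker record at line ", i, ": expected 14-16 ",
           "columns, found ", length(f))
    }
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    recs[[j]] <- data.frame(
      chrom = f[5],
      start = as.numeric(f[6]) - 1,
      end = as.numeric(f[7]),
      strand = if (f[9] %in% c("C", "c")) "-" else f[9],
      divergence = as.numeric(f[2]),
      pct_del = as.numeric(f[3]),
      pct_ins = as.numeric(f[4]),
      repeat_name = f[10],
      te_class = cf[1],
      te_family = if (length(cf) > 1) paste(cf[-1], collapse = "/") else NA_character_,
      score = as.numeric(f[1]),
      id = if (length(f) >= 15) f[15] else NA_character_,
      overlap_flag = length(f) == 16 && f[16] == "*",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  bad <- !is.finite(out$start) | !is.finite(out$end) | out$start < 0 |
    out$end <= out$start
  if (any(bad)) {
    stop("invalid coordinates at line ", data_idx[which(bad)[1]])
  }
  out <- out[(out$end - out$start) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_te_records <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), divergence = numeric(0),
             pct_del = numeric(0), pct_ins = numeric(0),
             repeat_name = character(0), te_class = character(0),
             te_family = character(0), score = numeric(0), id = character(0),
             overlap_flag = logical(0), stringsAsFactors = FALSE)
}

#' Write TE records in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker()]: coordinates are converted back to
#' 1-based inclusive and `-` strand to RepeatMasker's `C`. Repeat-consensus
#' coordinates are not tracked by the package and are emitted as a
#' placeholder spanning the hit length, which round-trips every field that
#' the analyses consume (coordinates, strand, divergence, names, score).
#'
#' @param records data.frame as returned by [read_repeatmasker()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query     position in query            matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin end        (left)   repeat class/family   begin end    (left)  ID",
    ""
  ), con)
  if (nrow(records) > 0) {
    fam <- ifelse(is.na(records$te_family) | records$te_family == "",
                  records$te_class,
                  paste0(records$te_class, "/", records$te_family))
    w <- records$end - records$start
    lines <- sprintf(
      "%d %.1f %.1f %.1f %s %d %d (0) %s %s %s 1 %d (0) %s%s",
      as.integer(round(records$score)), records$divergence, records$pct_del,
      records$pct_ins, records$chrom, as.integer(records$start + 1),
      as.integer(records$end),
      ifelse(records$strand == "-", "C", "+"), records$repeat_name, fam,
      as.integer(w),
      ifelse(is.na(records$id), as.character(seq_len(nrow(records))),
             records$id),
      ifelse(records$overlap_flag, " *", "")
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Classify TE copies into divergence-based age classes
#'
#' Copies under `young_max` percent divergence from their library consensus
#' are "young"; copies between `old_min` and `old_max` (both ends included)
#' are "old"; anything more diverged is "excluded". With the defaults this
#' is young = \[0, 5) and old = \[5, 10\] percent: the classes partition all
#' non-negative divergences.
#'
#' @param d Numeric vector of percent divergences (the `.out` %div column).
#' @param young_max Upper (exclusive) bound of the young class. Default 5.
#' @param old_min,old_max Inclusive bounds of the old class. Defaults 5, 10.
#' @return Character vector, one of `"young"`, `"old"`, `"excluded"`.
#' @examples
#' classify_age(c(4.9, 5, 10, 10.1))
#' @export
classify_age <- function(d, young_max = 5, old_min = 5, old_max = 10) {
  if (any(!is.finite(d))) stop("divergence must be finite")
  if (any(d < 0)) stop("divergence must be non-negative")
  ifelse(d < young_max, "young",
         ifelse(d >= old_min & d <= old_max, "old", "excluded"))
}

NON_TE_CLASSES <- c("Simple_repeat", "Low_complexity", "Satellite",
                    "rRNA", "tRNA", "snRNA", "scRNA", "srpRNA")

#' Filter TE records by repeat class
#'
#' @param records data.frame from [read_repeatmasker()].
#' @param keep_classes Optional character vector of `te_class` values to
#'   retain (e.g. `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`, `"RC"`).
#' @param drop_non_te If `TRUE`, remove non-TE repeat classes
#'   (simple repeats, low complexity, satellites and structural RNAs).
#' @return Filtered data.frame.
#' @export
filter_te_records <- function(records, keep_classes = NULL,
                              drop_non_te = FALSE) {
  out <- records
  if (drop_non_te) {
    known <- c("LINE", "SINE", "LTR", "DNA", "RC", "Rolling-circle",
               "Retroposon", "Unknown", NON_TE_CLASSES)
    odd <- setdiff(unique(out$te_class), known)
    if (length(odd)) {
      message("unrecognized repeat class(es) kept as-is: ",
              paste(odd, collapse = ", "))
    }
    out <- out[!(out$te_class %in% NON_TE_CLASSES), , drop = FALSE]
  }
  if (!is.null(keep_classes)) {
    out <- out[out$te_class %in% keep_classes, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
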