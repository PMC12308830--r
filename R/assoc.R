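# Association of chromosome-level statistics with chromosome size:
# Spearman correlation with Benjamini-Hochberg correction and ordinary
# least-squares multiple regression.

# Exact null distribution of S = sum of squared rank differences over all
# n! permutations, as permutation counts indexed by S = 0..n(n^2-1)/3.
# Computed through Ryser's permanent formula applied to the matrix
# A[i,j] = x^{(i-j)^2} over a polynomial ring: the permanent's coefficient
# of x^s counts permutations with S = s. O(2^n * n^2 * smax) — instant up
# to n = 10, cached per n.
spearman_null_env <- new.env(parent = emptyenv())

spearman_exact_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_null_env[[key]])) return(spearman_null_env[[key]])
  smax <- n * (n^2 - 1) / 3
  acc <- numeric(smax + 1)
  for (mask in seq_len(2^n - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    poly <- c(1, numeric(smax))
    for (i in seq_len(n)) {
      nxt <- numeric(smax + 1)
      for (d in (i - cols)^2) {
        idx <- seq_len(smax + 1 - d)
        nxt[idx + d] <- nxt[idx + d] + poly[idx]
      }
      poly <- nxt
    }
    sgn <- if ((n - length(cols)) %% 2 == 0) 1 else -1
    acc <- acc + sgn * poly
  }
  spearman_null_env[[key]] <- acc
  acc
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks
#' for ties). For n > 10 the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom;
#' for n <= 10 without ties the exact permutation distribution of the
#' sum of squared rank differences is enumerated (via a permanent
#' computation, so all n! permutations are counted exactly even at
#' n = 10); with ties the t approximation is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, all finite.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    counts <- spearman_exact_counts(n)
    s_obs <- sum((rx - ry)^2)
    p_le <- sum(counts[seq_len(s_obs + 1)]) / factorial(n)
    p_ge <- sum(counts[(s_obs + 1):length(counts)]) / factorial(n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Multiple linear regression with t-tests
#'
#' Ordinary least squares with an intercept; two-sided t-tests on
#' n - p - 1 degrees of freedom. Standardized coefficients (response and
#' predictors scaled to unit variance) are reported alongside the raw ones
#' so effect sizes are comparable across predictors with different units.
#'
#' @param y Numeric response (e.g. per-chromosome repeat density).
#' @param X data.frame of numeric predictors (e.g. chromosome length, GC
#'   content, CDS density).
#' @return List with `coefficients` (term, estimate, std_error, t_value,
#'   p_value), `std_coefficients`, `r_squared`, `adj_r_squared`, `n`,
#'   `residuals`.
#' @export
ols_regression <- function(y, X) {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1)))) stop("predictors must be numeric")
  n <- length(y)
  if (n <= ncol(X) + 1) stop("need n > number of predictors + 1")
  d <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending predictor(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      std_error = ct[, 2], t_value = ct[, 3],
                      p_value = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  ds <- data.frame(.y = as.numeric(scale(y)), lapply(X, function(c) {
    as.numeric(scale(c))
  }), check.names = FALSE)
  sfit <- summary(stats::lm(.y ~ ., data = ds))$coefficients
  std <- data.frame(term = rownames(sfit), estimate = sfit[, 1],
                    std_error = sfit[, 2], t_value = sfit[, 3],
                    p_value = sfit[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(coefficients = coefs, std_coefficients = std,
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       n = n, residuals = stats::residuals(fit))
}

#' Correlate per-chromosome statistics with chromosome size
#'
#' Spearman correlation of each named statistic against chromosome length,
#' with BH-FDR correction applied across the supplied family of tests
#' (declare the family explicitly: p_adjusted values are only comparable
#' within one call). Chromosomes with a missing statistic are dropped
#' pairwise.
#'
#' @param summaries data.frame with a `chrom` column and one column per
#'   statistic.
#' @param stats_cols Character vector of statistic column names forming the
#'   FDR family.
#' @param size_table Chromosome sizes (see [make_windows()]); lengths are
#'   taken from here, not from windowed coverage.
#' @param exclude_chroms Chromosomes to drop before testing (e.g. `"Z"`).
#' @return data.frame: `variable`, `rho`, `p_value`, `p_adjusted`, `n`.
#' @export
correlate_across_chromosomes <- function(summaries, stats_cols, size_table,
                                         exclude_chroms = character(0)) {
  sizes <- load_chrom_sizes(size_table)
  d <- merge(summaries, sizes, by = "chrom")
  d <- d[!(d$chrom %in% exclude_chroms), , drop = FALSE]
  rows <- lapply(stats_cols, function(v) {
    if (!v %in% names(d)) stop("no column '", v, "' in summaries")
    keep <- is.finite(d[[v]]) & is.finite(d$length)
    if (sum(keep) < 3) {
      stop("fewer than 3 chromosomes with defined '", v, "'")
    }
    st <- spearman_test(d$length[keep], d[[v]][keep])
    data.frame(variable = v, rho = st$rho, p_value = st$p_value,
               n = st$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out[, c("variable", "rho", "p_value", "p_adjusted", "n")]
}
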