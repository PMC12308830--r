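# Folded site-frequency spectra: expected spectra under the Poisson random
# field model with genic selection, hypergeometric projection of observed
# counts, and folding utilities. The convention throughout is that the
# neutral unfolded expectation is proportional to 1/i, i.e. the density of
# segregating sites at population frequency x is tau(x; S) with
# tau(x; 0) = 1/x, and S = 4Ns is the scaled selection coefficient
# (negative for deleterious mutations).

# Stable log(expm1(z)) for z > 0 of any magnitude.
log_expm1 <- function(z) ifelse(z > 33, z, log(expm1(z)))

# Density of segregating sites at frequency x under genic selection.
# For S < 0 written via expm1 ratios so it is stable down to S ~ -1e6.
sfs_density <- function(x, S) {
  if (S == 0) return(1 / x)
  g <- -S
  if (g > 0) {
    exp(log_expm1(g * (1 - x)) - log_expm1(g)) / (x * (1 - x))
  } else {
    # positive selection (not used by the gamma DFE, kept for completeness)
    (1 - exp(-S * (1 - x))) / ((1 - exp(-S)) * x * (1 - x))
  }
}

#' Expected unfolded SFS under genic selection
#'
#' Expected relative number of segregating sites with derived-allele count
#' i = 1..n-1 in a sample of n alleles: the binomial sampling integral of
#' the population-frequency density `tau(x; S)`, normalized so that the
#' neutral case gives exactly 1/i. Computed by adaptive quadrature; for
#' strongly deleterious S the integral is split at the boundary layer
#' near x = 0 where all the mass concentrates.
#'
#' @param S Scaled selection coefficient 4Ns (<= 0 for deleterious; 0 is
#'   the neutral limit).
#' @param n Haploid sample size (>= 4).
#' @return Numeric vector of length n - 1.
#' @export
expected_unfolded_sfs <- function(S, n) {
  if (n < 4) stop("need n >= 4")
  g <- max(-S, 0)
  cut <- if (g > 50) min(0.5, 50 / g) else NULL
  vapply(seq_len(n - 1), function(i) {
    f <- function(x) dbinom(i, n, x) * sfs_density(x, S)
    if (is.null(cut)) {
      stats::integrate(f, 0, 1, rel.tol = 1e-8,
                       subdivisions = 500L)$value
    } else {
      stats::integrate(f, 0, cut, rel.tol = 1e-8,
                       subdivisions = 500L)$value +
        stats::integrate(f, cut, 1, rel.tol = 1e-8,
                         subdivisions = 500L)$value
    }
  }, numeric(1))
}

# Fold an unfolded spectrum u[1..n-1] into minor-allele classes 1..floor(n/2).
fold_sfs <- function(u) {
  n <- length(u) + 1
  K <- floor(n / 2)
  f <- numeric(K)
  for (i in seq_len(K)) {
    f[i] <- if (i < n - i) u[i] + u[n - i] else u[i]
  }
  f
}

#' Expected folded SFS under genic selection
#'
#' Folds [expected_unfolded_sfs()] into minor-allele count classes
#' 1..floor(n/2). In the neutral case with n = 4 the folded classes are
#' proportional to (1 + 1/3, 1/2).
#'
#' @inheritParams expected_unfolded_sfs
#' @return Numeric vector of length floor(n/2).
#' @export
expected_folded_sfs <- function(S, n) {
  fold_sfs(expected_unfolded_sfs(S, n))
}

# ---- gamma-DFE mixture machinery ------------------------------------------
# The expected spectrum under a gamma distribution of deleterious effects is
# a mixture over S = -g, g ~ Gamma(shape = beta, mean = Es). Because the
# spectrum at each grid value of g does not depend on (beta, Es), the grid is
# precomputed once per sample size and each likelihood evaluation only
# recomputes the gamma bin masses.

sfs_grid_env <- new.env(parent = emptyenv())

sfs_grid_points <- function() c(0, 10^seq(-3, 5, length.out = 81))

# Matrix [n-1, length(grid)] of unfolded spectra at S = -g over the grid.
unfolded_grid <- function(n) {
  key <- as.character(n)
  if (is.null(sfs_grid_env[[key]])) {
    g <- sfs_grid_points()
    sfs_grid_env[[key]] <- vapply(g, function(gi) {
      expected_unfolded_sfs(-gi, n)
    }, numeric(n - 1))
  }
  sfs_grid_env[[key]]
}

# Gamma bin masses over the grid: each grid point owns the probability mass
# of its geometric-midpoint bin; the sub-grid near-neutral mass goes to the
# g = 0 point and the upper tail to the last point, so masses sum to 1.
gamma_grid_weights <- function(beta, Es) {
  g <- sfs_grid_points()
  np <- length(g)
  edges <- c(0, g[2] / sqrt(10), sqrt(g[3:np] * g[2:(np - 1)]), Inf)
  rate <- beta / Es
  cdf <- pgamma(edges, shape = beta, rate = rate)
  diff(cdf)
}

# Expected unfolded spectrum under the gamma DFE (neutral-1/i scaling).
expected_unfolded_sfs_gamma <- function(beta, Es, n) {
  as.numeric(unfolded_grid(n) %*% gamma_grid_weights(beta, Es))
}

#' Expected folded SFS under a gamma distribution of deleterious effects
#'
#' @param beta Gamma shape parameter (> 0).
#' @param Es Mean of the scaled selection-coefficient magnitude
#'   `E[-4Ns]` (> 0).
#' @param n Haploid sample size.
#' @return Numeric vector of length floor(n/2).
#' @export
expected_folded_sfs_gamma <- function(beta, Es, n) {
  fold_sfs(expected_unfolded_sfs_gamma(beta, Es, n))
}

#' Build folded SFS from genotype data and SNP effect labels
#'
#' Minor-allele counts are computed per biallelic variant site; sites with
#' at least `n_target` called alleles are hypergeometrically projected down
#' to `n_target` (expected fractional class contributions), and sites with
#' fewer called alleles are excluded. Projected contributions landing in
#' class 0 (monomorphic after projection) are discarded.
#'
#' @param vcf Path or list from [read_allsites_vcf()].
#' @param effects Character vector aligned with VCF rows
#'   (`"synonymous"` / `"nonsynonymous"` / `"other"`), e.g. from
#'   [classify_snp_effect()].
#' @param n_target Haploid sample size to project to.
#' @param L_syn,L_nonsyn Numbers of surveyed sites per class (e.g. counts
#'   of 4D and 0D sites); carried into the SFS objects.
#' @return List with elements `syn` and `nonsyn`, each a `folded_sfs` list
#'   (`n`, `counts`, `L`, `site_class`, `n_sites_used`, `n_sites_skipped`).
#' @export
build_folded_sfs <- function(vcf, effects, n_target, L_syn = NA,
                             L_nonsyn = NA) {
  if (is.character(vcf)) vcf <- read_allsites_vcf(vcf)
  st <- site_allele_stats(vcf$gt)
  if (n_target > max(st$k)) {
    stop("n_target exceeds the maximum called allele number (", max(st$k), ")")
  }
  biallelic <- rowSums(st$allele_counts > 0) == 2 &
    ncol(st$allele_counts) >= 2
  one_class <- function(which_class, L) {
    idx <- which(effects == which_class & biallelic)
    K <- floor(n_target / 2)
    counts <- numeric(K)
    used <- 0L
    skipped <- 0L
    for (s in idx) {
      k <- st$k[s]
      if (k < n_target) {
        skipped <- skipped + 1L
        next
      }
      c_alt <- st$allele_counts[s, 2]
      j <- 0:n_target
      w <- dhyper(j, c_alt, k - c_alt, n_target)
      fold_i <- pmin(j, n_target - j)
      for (cl in seq_len(K)) {
        counts[cl] <- counts[cl] + sum(w[fold_i == cl])
      }
      used <- used + 1L
    }
    structure(list(n = n_target, counts = counts, L = L,
                   site_class = which_class, n_sites_used = used,
                   n_sites_skipped = skipped),
              class = "folded_sfs")
  }
  list(syn = one_class("synonymous", L_syn),
       nonsyn = one_class("nonsynonymous", L_nonsyn))
}

#' Construct a folded SFS object directly from class counts
#'
#' @param counts Numeric vector of minor-allele class counts
#'   (classes 1..floor(n/2)).
#' @param n Haploid sample size.
#' @param L Number of surveyed sites.
#' @param site_class `"synonymous"` or `"nonsynonymous"`.
#' @return A `folded_sfs` list.
#' @export
folded_sfs <- function(counts, n, L = NA,
                       site_class = c("synonymous", "nonsynonymous")) {
  site_class <- match.arg(site_class)
  if (length(counts) != floor(n / 2)) {
    stop("counts must have floor(n/2) classes")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(n = n, counts = as.numeric(counts), L = L,
                 site_class = site_class, n_sites_used = sum(counts),
                 n_sites_skipped = 0L),
            class = "folded_sfs")
}
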