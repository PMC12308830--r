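# Maximum-likelihood estimation of a gamma distribution of deleterious
# fitness effects from paired synonymous/nonsynonymous folded spectra.
#
# Demographic (and other) distortions of the spectrum are absorbed by
# per-frequency-class nuisance factors r_i shared between the synonymous
# and nonsynonymous spectra and anchored at r_1 = 1, in the spirit of the
# Eyre-Walker nuisance-parameter approach: expected counts are
#   E[syn_i]    = theta_s * e_i(0)            * r_i
#   E[nonsyn_i] = theta_n * E_gamma[e_i(S)]   * r_i
# with Poisson likelihoods per class. Given the other parameters the
# optimal r_i has a closed form, so the optimizer works in the
# 4-dimensional (log beta, log Es, log theta_s, log theta_n) space.

#' Fit a gamma DFE to folded synonymous/nonsynonymous spectra
#'
#' Joint Poisson maximum likelihood over the gamma shape `beta`, the mean
#' scaled selection-coefficient magnitude `Es = E[-4Ns]`, the mutational
#' scale(s) and per-class nuisance factors `r_i` (profiled in closed form,
#' `r_1 = 1`). When both spectra carry their surveyed-site totals `L`, the
#' synonymous and nonsynonymous mutational scales are tied through the
#' shared per-site mutation rate (`theta_n = theta_s * L_n / L_s`): the
#' overall deficit of nonsynonymous polymorphism then directly informs the
#' deleterious mass, which is what makes `Es` identifiable from folded
#' data. Without site totals the nonsynonymous scale floats free and only
#' the spectrum shape informs the fit (wide `Es` uncertainty).
#' Optimization is bounded quasi-Newton (L-BFGS-B) from a deterministic
#' grid of starts spanning `beta` in \{0.1, 0.3, 1, 3\} and `Es` in
#' \{10, 1000\}.
#'
#' @param sfs_syn,sfs_nonsyn `folded_sfs` objects (see [folded_sfs()] /
#'   [build_folded_sfs()]) at the same sample size `n`.
#' @param profile_ci If `TRUE`, also compute a 95% profile-likelihood
#'   confidence interval for `Es` (slower).
#' @param beta_bounds,Es_bounds Box constraints for the optimizer.
#' @return List of class `dfe_fit`: `beta`, `Es` (mean magnitude of the
#'   scaled selection coefficient of deleterious mutations), `S_mean`
#'   (`-Es`, signed), `theta_syn`, `theta_nonsyn`, `tied_theta`, `r`
#'   (nuisance factors), `log_likelihood`, `n`, `neutral_boundary` (TRUE
#'   when `Es` collapsed to its lower bound, i.e. the nonsynonymous
#'   spectrum is indistinguishable from neutral), `convergence`, and
#'   optionally `Es_ci`.
#' @export
fit_gamma_dfe <- function(sfs_syn, sfs_nonsyn, profile_ci = FALSE,
                          beta_bounds = c(1e-3, 100),
                          Es_bounds = c(1e-2, 1e6)) {
  stopifnot(inherits(sfs_syn, "folded_sfs"), inherits(sfs_nonsyn, "folded_sfs"))
  if (sfs_syn$n != sfs_nonsyn$n) stop("spectra must share the sample size n")
  n <- sfs_syn$n
  K <- floor(n / 2)
  if (K < 3) stop("fewer than 3 folded classes: model unidentifiable")
  s_obs <- sfs_syn$counts
  m_obs <- sfs_nonsyn$counts
  if (any(s_obs[1] <= 0)) stop("empty synonymous singleton class")
  tie <- is.finite(sfs_syn$L) && is.finite(sfs_nonsyn$L) &&
    sfs_syn$L > 0 && sfs_nonsyn$L > 0
  Lratio <- if (tie) sfs_nonsyn$L / sfs_syn$L else NA_real_
  e0 <- fold_sfs(unfolded_grid(n)[, 1])  # neutral folded spectrum
  U <- unfolded_grid(n)

  nll_at <- function(beta, Es, th_s, th_n) {
    h <- fold_sfs(as.numeric(U %*% gamma_grid_weights(beta, Es)))
    r <- c(1, (s_obs[-1] + m_obs[-1]) / (th_s * e0[-1] + th_n * h[-1]))
    r[!is.finite(r) | r < 0] <- 0
    mu_s <- th_s * e0 * r
    mu_m <- th_n * h * r
    # continuous Poisson kernel so hypergeometrically projected
    # (fractional) class counts are handled; equals dpois for integers
    ll <- sum(s_obs * log(pmax(mu_s, 1e-12)) - mu_s - lgamma(s_obs + 1) +
                m_obs * log(pmax(mu_m, 1e-12)) - mu_m - lgamma(m_obs + 1))
    list(nll = -ll, r = r, h = h)
  }

  # parameter vector: log(beta), log(Es), log(theta_s) [, log(theta_n)]
  unpack <- function(par) {
    th_s <- exp(par[3])
    th_n <- if (tie) th_s * Lratio else exp(par[4])
    list(beta = exp(par[1]), Es = exp(par[2]), th_s = th_s, th_n = th_n)
  }
  obj <- function(par) {
    q <- unpack(par)
    v <- nll_at(q$beta, q$Es, q$th_s, q$th_n)
    if (!is.finite(v$nll)) 1e12 else v$nll
  }

  npar <- if (tie) 3L else 4L
  lower <- log(c(beta_bounds[1], Es_bounds[1], rep(1e-10, npar - 2)))
  upper <- log(c(beta_bounds[2], Es_bounds[2], rep(1e12, npar - 2)))
  th_s0 <- sum(s_obs) / sum(e0)
  starts <- expand.grid(beta = c(0.1, 0.3, 1, 3), Es = c(10, 1000))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    b0 <- starts$beta[i]
    g0 <- starts$Es[i]
    h0 <- fold_sfs(as.numeric(U %*% gamma_grid_weights(b0, g0)))
    th_n0 <- sum(m_obs) / sum(h0)
    p0 <- if (tie) log(c(b0, g0, th_s0)) else {
      log(c(b0, g0, th_s0, max(th_n0, 1e-10)))
    }
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("DFE optimization failed from every start")
  q <- unpack(best$par)
  at <- nll_at(q$beta, q$Es, q$th_s, q$th_n)
  out <- list(beta = q$beta, Es = q$Es, S_mean = -q$Es,
              theta_syn = q$th_s, theta_nonsyn = q$th_n, tied_theta = tie,
              r = at$r, log_likelihood = -at$nll, n = n,
              neutral_boundary = q$Es <= Es_bounds[1] * 1.0001,
              convergence = best$convergence)
  if (profile_ci) {
    target <- at$nll + stats::qchisq(0.95, 1) / 2
    grid <- q$Es * 2^seq(-4, 4, length.out = 17)
    grid <- grid[grid >= Es_bounds[1] & grid <= Es_bounds[2]]
    prof <- vapply(grid, function(g) {
      o <- function(par) {
        full <- c(par[1], log(g), par[-1])
        obj(full)
      }
      stats::optim(best$par[-2], o, method = "L-BFGS-B",
                   lower = lower[-2], upper = upper[-2],
                   control = list(maxit = 300))$value
    }, numeric(1))
    inside <- grid[prof <= target]
    out$Es_ci <- if (length(inside)) range(inside) else c(NA_real_, NA_real_)
  }
  class(out) <- "dfe_fit"
  out
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat("Gamma DFE fit (folded SFS, n =", x$n, ")\n")
  cat(sprintf("  shape beta     : %.4g\n", x$beta))
  cat(sprintf("  mean |4Ns| (Es): %.4g\n", x$Es))
  cat(sprintf("  log-likelihood : %.3f\n", x$log_likelihood))
  if (x$neutral_boundary) cat("  note: Es at neutral boundary\n")
  invisible(x)
}
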