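#' Configuration for the synthetic evaluation data
#'
#' Describes the simulated imaging dataset used by the evaluation
#' harness: N subject images on a regular grid, Gaussian or standardized
#' Weibull noise, frequency-domain Gaussian smoothing (no zero padding,
#' so the grid is treated as periodic and no edge artefacts arise), and
#' an optional additive effect calibrated for approximately 50 percent
#' power at the test level.
#'
#' The Weibull noise uses scale 1 and shape 1/3, shifted and scaled to
#' zero mean and unit variance: the analytic moments give a mean of
#' Gamma(4) = 6 and a variance of Gamma(7) - Gamma(4)^2 = 684. After
#' smoothing, fields are rescaled by the analytic kernel l2 norm so the
#' per-voxel variance remains 1 and the calibrated effect size keeps its
#' interpretation.
#'
#' @param grid integer vector of grid dimensions (default 12 x 12 x 12).
#' @param N number of subject images (default 20).
#' @param dist "gaussian" or "weibull".
#' @param fwhm smoothing kernel full width at half maximum, in voxels.
#' @param signal logical: add the calibrated effect.
#' @param alpha level at which the effect is calibrated (default 0.05).
#' @param weibull_factor attenuation of the Gaussian-calibrated effect
#'   under Weibull errors (default 5/8).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(grid = c(12, 12, 12), N = 20,
                       dist = c("gaussian", "weibull"), fwhm = 4,
                       signal = FALSE, alpha = 0.05,
                       weibull_factor = 5 / 8) {
  dist <- match.arg(dist)
  structure(list(grid = grid, N = N, dist = dist, fwhm = fwhm,
                 signal = signal, alpha = alpha,
                 weibull_factor = weibull_factor),
            class = "sim_config")
}

# Gaussian kernel on the periodic grid and its fft; sum(k) = 1.
smoothing_kernel <- function(grid, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  idx <- arrayInd(seq_len(prod(grid)), grid)
  d2 <- 0
  for (k in seq_along(grid)) {
    x <- idx[, k] - 1
    d2 <- d2 + pmin(x, grid[k] - x)^2
  }
  kern <- array(exp(-d2 / (2 * sigma^2)), grid)
  kern <- kern / sum(kern)
  list(fft = stats::fft(kern), l2 = sqrt(sum(kern^2)))
}

draw_noise <- function(n, dist) {
  if (dist == "gaussian") stats::rnorm(n)
  else (stats::rweibull(n, shape = 1 / 3, scale = 1) - 6) / sqrt(684)
}

#' Generate smoothed noise images
#'
#' Draws per-subject noise fields (zero mean, unit variance per voxel),
#' smooths them by multiplication in the frequency domain without zero
#' padding, and rescales so the post-smoothing per-voxel variance is 1.
#'
#' @param config a \code{\link{sim_config}}.
#' @return N x V matrix (V = prod(grid)), with the grid dimensions in
#'   attribute \code{grid}.
#' @export
make_noise <- function(config) {
  V <- prod(config$grid)
  kern <- smoothing_kernel(config$grid, config$fwhm)
  out <- matrix(NA_real_, config$N, V)
  for (i in seq_len(config$N)) {
    e <- array(draw_noise(V, config$dist), config$grid)
    sm <- Re(stats::fft(stats::fft(e) * kern$fft, inverse = TRUE)) / V
    out[i, ] <- as.vector(sm) / kern$l2
  }
  attr(out, "grid") <- config$grid
  out
}

#' Calibrated effect size for approximately 50 percent power
#'
#' \eqn{\psi_1 = t^{-1}_{cdf}(1 - \alpha;\, N - rank(M)) \cdot
#' (C'(M'M)^{+}C)^{1/2}}: with unit-variance Gaussian errors the
#' standard error of the contrast estimate is
#' \eqn{(C'(M'M)^{+}C)^{1/2}}, so this choice sets the noncentrality of
#' the contrast's t statistic equal to the one-sided critical value,
#' giving approximately 50 percent power at level alpha irrespective of
#' the sample size. For Weibull errors the signal is further attenuated
#' by \code{weibull_factor} (5/8), which restores approximately 50
#' percent power for the permutation test.
#'
#' @param M design matrix.
#' @param C contrast vector/matrix.
#' @param alpha test level.
#' @param dist "gaussian" or "weibull".
#' @param weibull_factor attenuation under Weibull errors.
#' @return the scalar effect \eqn{\psi_1}.
#' @export
calibrated_effect <- function(M, C, alpha = 0.05,
                              dist = c("gaussian", "weibull"),
                              weibull_factor = 5 / 8) {
  dist <- match.arg(dist)
  M <- as.matrix(M); C <- as.matrix(C)
  df <- nrow(M) - mat_rank(M)
  psi1 <- stats::qt(1 - alpha, df) *
    sqrt(drop(t(C) %*% pinv(crossprod(M)) %*% C))
  if (dist == "weibull") psi1 <- psi1 * weibull_factor
  psi1
}

#' Simulate one synthetic dataset
#'
#' Builds the evaluation design (a standard-Gaussian regressor of
#' interest plus an intercept, contrast [1 0]'), generates smoothed
#' noise, and, for signal runs, adds the calibrated effect to all
#' voxels (avoiding signal bleeding into pure-noise regions).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{Y} (N x V), \code{M}, \code{C},
#'   \code{design} (a \code{\link{make_design}} object), \code{psi1},
#'   \code{grid}.
#' @export
simulate_dataset <- function(config) {
  g <- stats::rnorm(config$N)
  M <- cbind(g, 1)
  C <- c(1, 0)
  Y <- make_noise(config)
  psi1 <- 0
  if (config$signal) {
    psi1 <- calibrated_effect(M, C, config$alpha, config$dist,
                              config$weibull_factor)
    Y <- Y + g * psi1
  }
  list(Y = Y, M = M, C = C, design = make_design(M, C), psi1 = psi1,
       grid = config$grid)
}

#' Evaluation harness: error rate, power, and resampling risk
#'
#' Repeats the synthetic simulation, analyses each realisation with a
#' large-J counting reference and with the requested acceleration
#' methods, and reports empirical type-I error (null runs), power
#' (signal runs), and the resampling risk of FWER-corrected decisions
#' against the reference.
#'
#' @param config a \code{\link{sim_config}} (its \code{signal} field is
#'   overridden per run).
#' @param methods subset of \code{c("fewperm", "negbin", "tail",
#'   "gamma", "noperm", "lowrank")}.
#' @param n_realisations repetitions per signal condition.
#' @param J number of rearrangements for the accelerated methods.
#' @param J_ref rearrangements for the counting reference.
#' @param negbin_n exceedance target for the negative binomial.
#' @param lowrank_v sampled tests per sparse rearrangement.
#' @param alpha decision level.
#' @param seed root seed; per-realisation sub-seeds are derived from it.
#' @param include_unpermuted passed to the tail and gamma fits.
#' @return data.frame with one row per method x condition: rejection
#'   rate of uncorrected p-values and mean FWER resampling risk against
#'   the reference.
#' @export
run_benchmark <- function(config, methods = c("fewperm", "tail", "gamma"),
                          n_realisations = 10, J = 500, J_ref = 5000,
                          negbin_n = 10, lowrank_v = NULL, alpha = 0.05,
                          seed = 1, include_unpermuted = TRUE) {
  conds <- c(FALSE, TRUE)
  rows <- list()
  for (sig in conds) {
    cfg <- config; cfg$signal <- sig
    rej <- stats::setNames(numeric(length(methods)), methods)
    risk <- stats::setNames(numeric(length(methods)), methods)
    ntest <- 0
    for (r in seq_len(n_realisations)) {
      set.seed(seed + 1000 * sig + r)
      ds <- simulate_dataset(cfg)
      V <- ncol(ds$Y)
      ntest <- ntest + V
      sh_ref <- generate_shuffles(cfg$N, J_ref, "ee")
      dref <- run_shuffled_glm(ds$Y, ds$design, "t", "freedman_lane",
                               sh_ref)
      ref_fwer <- decide(fwer_pvalues(dref), alpha, "fwer")
      sh <- generate_shuffles(cfg$N, J, "ee")
      dj <- run_shuffled_glm(ds$Y, ds$design, "t", "freedman_lane", sh)
      maxd <- apply(dj$stats, 1, max)
      for (m in methods) {
        res <- switch(
          m,
          fewperm = list(p = counting_pvalue(dj),
                         pf = fwer_pvalues(dj)),
          negbin = {
            nb <- negbin_scan(ds$Y, ds$design, "t", n = negbin_n,
                              J_cap = J_ref)
            fw <- negbin_fwer(ds$Y, ds$design, "t", n = negbin_n,
                              J_cap = J_ref)
            list(p = nb$p, pf = fw$p_fwer)
          },
          tail = list(
            p = tail_pvalues(dj,
                             include_unpermuted = include_unpermuted)$p,
            pf = fwer_tail_or_gamma(maxd, dj$stats[1, ], "tail")),
          gamma = list(
            p = gamma_pvalues_empirical(
              dj, include_unpermuted = include_unpermuted)$p,
            pf = fwer_tail_or_gamma(maxd, dj$stats[1, ], "gamma")),
          noperm = {
            np <- noperm_pvalue(ds$Y, ds$design)
            list(p = np$p, pf = NULL)  # no extremum distribution exists
          },
          lowrank = {
            lr <- lowrank_test(ds$Y, ds$design, J = J, v = lowrank_v)
            list(p = lr$p, pf = lr$p_fwer)
          },
          stop("unknown method: ", m))
        rej[m] <- rej[m] + sum(res$p <= alpha)
        if (!is.null(res$pf))
          risk[m] <- risk[m] +
            resampling_risk(decide(res$pf, alpha, "fwer"), ref_fwer)$risk
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      signal = sig, method = methods,
      rejection_rate = as.numeric(rej) / ntest,
      fwer_risk = as.numeric(risk) / n_realisations,
      row.names = NULL)
  }
  do.call(rbind, rows)
}
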