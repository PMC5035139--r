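#' Familywise error corrected p-values from the extremum distribution
#'
#' Corrects for multiplicity across the V tests of a permutation
#' distribution using the distribution of the image-wise extremum:
#' \eqn{p_{corr}(v) = J^{-1}\sum_j I(\max_{v'} T^*_{jv'} \ge T_v)}.
#' Corrected p-values are never smaller than the uncorrected ones.
#'
#' @param dist a \code{\link{run_shuffled_glm}} permutation
#'   distribution.
#' @return numeric vector of corrected p-values.
#' @export
fwer_pvalues <- function(dist) {
  upper <- dist$tail == "upper"
  ext <- if (upper) apply(dist$stats, 1, max) else apply(dist$stats, 1, min)
  T1 <- dist$stats[1, ]
  if (upper) vapply(T1, function(tv) mean(ext >= tv), numeric(1))
  else vapply(T1, function(tv) mean(ext <= tv), numeric(1))
}

#' FWER correction via a tail or gamma fit to the extremum distribution
#'
#' Fits a single generalised Pareto tail (or a single Pearson III
#' distribution) to the J-vector of image-wise extrema, and evaluates
#' corrected p-values from its survival function. A single fit is cheap
#' regardless of V. On fit failure the empirical counting correction is
#' returned with a warning.
#'
#' @param max_dist numeric vector of per-rearrangement extrema (first
#'   element unpermuted).
#' @param T statistic values at which corrected p-values are required.
#' @param method "tail" (GPD, refined below \code{refine_below}) or
#'   "gamma" (Pearson III on the whole extremum distribution).
#' @param refine_below tail-method gate: only statistics whose counting
#'   corrected p falls below this level are refined.
#' @param alpha_ad,min_exceed tail-fit controls (see
#'   \code{\link{tail_pvalues}}).
#' @return numeric vector of corrected p-values.
#' @export
fwer_tail_or_gamma <- function(max_dist, T, method = c("tail", "gamma"),
                               refine_below = 0.10, alpha_ad = 0.05,
                               min_exceed = 10) {
  method <- match.arg(method)
  J <- length(max_dist)
  p_count <- vapply(T, function(tv) mean(max_dist >= tv), numeric(1))
  if (method == "gamma") {
    if (stats::var(max_dist) <= 0) {
      warning("degenerate extremum distribution: counting correction used")
      return(p_count)
    }
    fit <- withCallingHandlers(
      fit_pearson3(mean(max_dist), stats::var(max_dist),
                   sample_skewness(max_dist)),
      warning = function(w) invokeRestart("muffleWarning"))
    p <- pearson3_sf(T, fit)
    if (!fit$normal && fit$skewness < 0)
      p[T >= fit$location] <- 1 / J
    if (!fit$normal && fit$skewness > 0)
      p[T <= fit$location] <- 1
    return(pmin(pmax(p, 0), 1))
  }
  # tail: one GPD fit on the extrema, applied where the counting
  # correction falls below the refinement gate
  p <- p_count
  ref <- which(p_count < refine_below)
  if (!length(ref)) return(p)
  ft <- tail_fit_one(max_dist, max(T), alpha_ad, min_exceed)
  if (!ft$accepted) {
    warning("tail fit of the extremum distribution rejected: ",
            "counting correction used")
    return(p)
  }
  p[ref] <- (ft$n_exceed / J) * gpd_sf(T[ref] - ft$u, ft$sigma, ft$xi)
  p
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR at level \code{q}. With discrete permutation p-values and
#' few permutations the procedure is expected to be conservative.
#'
#' @param p vector of p-values in (0, 1].
#' @param q acceptable false discovery rate.
#' @return An object of class \code{decision_set}: list with \code{p}
#'   (adjusted p-values), \code{reject} (logical), \code{alpha} = q,
#'   \code{kind} = "fdr".
#' @export
fdr_bh <- function(p, q = 0.05) {
  padj <- stats::p.adjust(p, method = "BH")
  structure(list(p = padj, reject = padj <= q, alpha = q, kind = "fdr"),
            class = "decision_set")
}

#' Rejection decisions at a fixed level
#'
#' @param p p-values (uncorrected or FWER-corrected).
#' @param alpha significance level.
#' @param kind label: "uncorrected" or "fwer".
#' @return a \code{decision_set}.
#' @export
decide <- function(p, alpha = 0.05, kind = "uncorrected") {
  structure(list(p = p, reject = p <= alpha, alpha = alpha, kind = kind),
            class = "decision_set")
}

#' Wilson score confidence interval for a permutation p-value
#'
#' A permutation p-value over J rearrangements is a binomial proportion;
#' the Wilson method gives its confidence interval. Fewer permutations
#' give wider intervals.
#'
#' @param p_hat estimated p-value in [0, 1].
#' @param J number of rearrangements.
#' @param level confidence level (default 0.95).
#' @return named vector \code{c(lower, upper)}.
#' @examples
#' round(wilson_ci(0.05, 10000), 4)  # 0.0459 0.0544
#' @export
wilson_ci <- function(p_hat, J, level = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, J >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / J
  centre <- (p_hat + z^2 / (2 * J)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / J + z^2 / (4 * J^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Resampling risk between two sets of decisions
#'
#' The probability of taking a different decision regarding rejection of
#' the null when the same data are analysed with different methods (or
#' repeated runs of stochastic methods). Computed as the per-test
#' disagreement indicator and its mean.
#'
#' @param decisions_a,decisions_b \code{decision_set} objects over the
#'   same tests at the same level.
#' @return list with \code{disagree} (logical per test) and \code{risk}
#'   (mean disagreement).
#' @export
resampling_risk <- function(decisions_a, decisions_b) {
  if (length(decisions_a$reject) != length(decisions_b$reject))
    stop("decision sets cover different numbers of tests")
  if (!isTRUE(all.equal(decisions_a$alpha, decisions_b$alpha)))
    stop("decision sets use different significance levels")
  dis <- decisions_a$reject != decisions_b$reject
  list(disagree = dis, risk = mean(dis))
}
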