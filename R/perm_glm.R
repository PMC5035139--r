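#' Permutation inference for the general linear model
#'
#' Fits the GLM \eqn{Y = M\psi + \epsilon} at every test (column of Y),
#' assesses the contrast \eqn{C'\psi = 0} by permutations and/or sign
#' flips, and optionally accelerates the p-value computation by one of
#' five strategies: negative-binomial early stopping, generalised
#' Pareto tail refinement, empirical gamma (Pearson III) moment
#' matching, analytic-moment gamma without any permutations, or exact
#' low-rank matrix completion. Familywise error correction uses the
#' distribution of the image-wise extremum; FDR uses the
#' Benjamini-Hochberg step-up rule.
#'
#' @param Y N x V response matrix (tests in columns). An attribute
#'   \code{grid} (integer dimensions) enables spatial statistics.
#' @param M N x R design matrix.
#' @param C R x S contrast (vector for a single contrast).
#' @param stat test statistic: "t" (S = 1), "F", "pillai", or "wilks"
#'   (the multivariate statistics expect Y with K response columns for
#'   a single test).
#' @param strategy rearrangement strategy: "freedman_lane" (default),
#'   "manly", or "draper_stoneman".
#' @param J number of rearrangements (including the unpermuted case).
#' @param mode "ee" (permutations), "ise" (sign flips), or "both".
#' @param accel acceleration method: "none", "negbin", "tail", "gamma",
#'   "noperm", or "lowrank".
#' @param accel_opts list of method options: \code{n}, \code{J_cap}
#'   (negbin); \code{refine_below}, \code{include_unpermuted},
#'   \code{alpha_ad} (tail/gamma); \code{v}, \code{allow_approximate}
#'   (lowrank).
#' @param fwer compute FWER-corrected p-values.
#' @param fdr if non-NULL, the FDR level q for Benjamini-Hochberg.
#' @param alpha significance level used by \code{summary} and the
#'   decision sets.
#' @param seed RNG seed.
#' @param exhaustive enumerate all rearrangements when feasible.
#' @return An object of class \code{perm_glm} with elements
#'   \code{stat} (unpermuted statistic values), \code{beta} (contrast
#'   estimates, t only), \code{p}, \code{p_fwer}, \code{p_fdr},
#'   \code{accel}, \code{fits} (tail/gamma records where applicable),
#'   \code{design}, \code{J}, and the matched call. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{plot}.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(20 * 50), 20)
#' M <- cbind(rnorm(20), 1)
#' fit <- perm_glm(Y, M, c(1, 0), J = 200, seed = 2)
#' summary(fit)
#' @export
perm_glm <- function(Y, M, C, stat = c("t", "F", "pillai", "wilks"),
                     strategy = c("freedman_lane", "manly",
                                  "draper_stoneman"),
                     J = 500, mode = c("ee", "ise", "both"),
                     accel = c("none", "negbin", "tail", "gamma",
                               "noperm", "lowrank"),
                     accel_opts = list(), fwer = FALSE, fdr = NULL,
                     alpha = 0.05, seed = NULL, exhaustive = FALSE) {
  stat <- match.arg(stat)
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  accel <- match.arg(accel)
  Y <- as.matrix(Y)
  design <- make_design(M, C)
  if (nrow(Y) != design$N)
    stop("Y has ", nrow(Y), " rows but the design has ", design$N)
  if (accel %in% c("negbin", "noperm", "lowrank") && stat != "t")
    stop("acceleration '", accel, "' supports the t statistic only")
  opts <- accel_opts
  grid <- attr(Y, "grid")
  out <- list(call = match.call(), stat_name = stat, accel = accel,
              strategy = strategy, mode = mode, design = design,
              J = J, alpha = alpha, seed = seed, grid = grid)

  if (accel == "noperm") {
    np <- noperm_pvalue(Y, design)
    out$p <- np$p
    out$stat <- np$pillai
    out$moments <- np$moments
    out$J <- NA_integer_
    if (fwer)
      stop("the no-permutation method cannot produce FWER-corrected ",
           "p-values (the extremum is not of the form trace(AW))")
  } else if (accel == "negbin") {
    nb <- negbin_scan(Y, design, "t", n = opts$n %||% 10,
                      J_cap = opts$J_cap %||% 50000, seed = seed,
                      mode = mode, strategy = strategy)
    out$p <- nb$p
    out$j_stop <- nb$j_stop
    out$stat <- t_statistic(Y, design$X, design$Z)$stat
    if (fwer) {
      fw <- negbin_fwer(Y, design, "t", n = opts$n %||% 10,
                        J_cap = opts$J_cap %||% 50000,
                        seed = if (is.null(seed)) NULL else seed + 1L,
                        mode = mode, strategy = strategy)
      out$p_fwer <- fw$p_fwer
    }
  } else if (accel == "lowrank") {
    lr <- lowrank_test(Y, design, J = J, v = opts$v,
                       strategy = strategy, mode = mode, seed = seed,
                       allow_approximate =
                         isTRUE(opts$allow_approximate))
    out$p <- lr$p
    out$stat <- lr$stat
    if (fwer) out$p_fwer <- lr$p_fwer
  } else {
    shuffles <- generate_shuffles(design$N, J, mode, seed = seed,
                                  exhaustive = exhaustive)
    dist <- run_shuffled_glm(Y, design, stat, strategy, shuffles)
    out$J <- shuffles$J
    out$stat <- dist$stats[1, ]
    out$beta_sign <- dist$beta_sign
    if (accel == "none") {
      out$p <- counting_pvalue(dist)
    } else if (accel == "tail") {
      tp <- tail_pvalues(dist,
                         refine_below = opts$refine_below %||% 0.10,
                         include_unpermuted =
                           opts$include_unpermuted %||% TRUE,
                         alpha_ad = opts$alpha_ad %||% 0.05)
      out$p <- tp$p
      out$fits <- tp$fits
    } else {
      gp <- gamma_pvalues_empirical(dist,
                                    include_unpermuted =
                                      opts$include_unpermuted %||% TRUE)
      out$p <- gp$p
      out$fits <- gp$fits
    }
    if (fwer) {
      if (dist$tail != "upper") {
        out$p_fwer <- fwer_pvalues(dist)
      } else {
        maxd <- apply(dist$stats, 1, max)
        out$p_fwer <- switch(accel,
          none = fwer_pvalues(dist),
          tail = fwer_tail_or_gamma(maxd, dist$stats[1, ], "tail",
                                    refine_below =
                                      opts$refine_below %||% 0.10,
                                    alpha_ad = opts$alpha_ad %||% 0.05),
          gamma = fwer_tail_or_gamma(maxd, dist$stats[1, ], "gamma"))
      }
    }
    if (ncol(dist$stats) * nrow(dist$stats) <= 5e6) out$dist <- dist
  }
  if (stat == "t") {
    a <- drop(design$X) / drop(crossprod(design$X))
    out$beta <- drop(a %*% Y)
  }
  if (!is.null(fdr)) out$p_fdr <- fdr_bh(out$p, fdr)
  class(out) <- "perm_glm"
  out
}

#' @export
print.perm_glm <- function(x, ...) {
  cat("Permutation GLM inference\n")
  cat("  statistic: ", x$stat_name, " (", x$strategy, ", mode ",
      x$mode, ")\n", sep = "")
  cat("  tests: ", length(x$p), "; rearrangements: ",
      if (is.na(x$J)) "none (analytic moments)" else x$J, "\n", sep = "")
  cat("  acceleration: ", x$accel, "\n", sep = "")
  cat("  min p: ", format(min(x$p), digits = 4), "; tests with p <= ",
      x$alpha, ": ", sum(x$p <= x$alpha), "\n", sep = "")
  if (!is.null(x$p_fwer))
    cat("  FWER-corrected rejections: ", sum(x$p_fwer <= x$alpha), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.perm_glm <- function(object, ...) {
  s <- list(
    stat_name = object$stat_name, accel = object$accel,
    J = object$J, V = length(object$p), alpha = object$alpha,
    n_reject = sum(object$p <= object$alpha),
    n_reject_fwer = if (!is.null(object$p_fwer))
      sum(object$p_fwer <= object$alpha) else NA_integer_,
    n_reject_fdr = if (!is.null(object$p_fdr))
      sum(object$p_fdr$reject) else NA_integer_,
    p_quantiles = stats::quantile(object$p, c(0, .01, .05, .25, .5, 1)),
    ci_min_p = if (!is.na(object$J))
      wilson_ci(min(object$p), object$J) else NULL)
  class(s) <- "summary.perm_glm"
  s
}

#' @export
print.summary.perm_glm <- function(x, ...) {
  cat("Permutation GLM (", x$stat_name, ", acceleration: ", x$accel,
      ")\n", sep = "")
  cat(x$V, "tests,",
      if (is.na(x$J)) "analytic moments (no permutations)" else
        paste(x$J, "rearrangements"), "\n")
  cat("Rejections at alpha =", x$alpha, ":", x$n_reject, "uncorrected")
  if (!is.na(x$n_reject_fwer)) cat(";", x$n_reject_fwer, "FWER")
  if (!is.na(x$n_reject_fdr)) cat(";", x$n_reject_fdr, "FDR")
  cat("\np-value quantiles:\n")
  print(signif(x$p_quantiles, 4))
  if (!is.null(x$ci_min_p))
    cat("Wilson 95% CI of the smallest p-value: [",
        signif(x$ci_min_p[1], 4), ", ", signif(x$ci_min_p[2], 4), "]\n",
        sep = "")
  invisible(x)
}

#' @export
coef.perm_glm <- function(object, ...) {
  if (is.null(object$beta))
    stop("contrast estimates are available for the t statistic only")
  object$beta
}

#' @export
plot.perm_glm <- function(x, which = c("pvalues", "null"), test = NULL,
                          ...) {
  which <- match.arg(which)
  if (which == "pvalues") {
    graphics::hist(x$p, breaks = 20, main = "Permutation p-values",
                   xlab = "p", col = "grey85", ...)
    graphics::abline(v = x$alpha, col = "red3", lty = 2)
  } else {
    if (is.null(x$dist))
      stop("the permutation distribution was not retained")
    if (is.null(test)) test <- which.min(x$p)
    vals <- x$dist$stats[, test]
    graphics::hist(vals, breaks = 30, freq = FALSE,
                   main = paste("Null distribution, test", test),
                   xlab = x$stat_name, col = "grey85", ...)
    graphics::abline(v = vals[1], col = "red3", lwd = 2)
  }
  invisible(x)
}
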