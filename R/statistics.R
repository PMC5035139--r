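#' Test statistics for the (partitioned) general linear model
#'
#' These functions compute pivotal statistics from the partitioned model
#' \eqn{Y = X\beta + Z\gamma + \epsilon} with \eqn{X'Z = 0}. All return a
#' \code{stat_result}: a list with the statistic values, the sign of the
#' estimated coefficient of interest (for directional tests), the
#' statistic name, and the tail in which evidence against the null lies
#' (\code{"upper"} for t/F/Pillai, \code{"lower"} for Wilks' lambda).
#'
#' @name glm_statistics
NULL

stat_result <- function(stat, name, tail = "upper", beta_sign = NULL) {
  structure(list(stat = as.numeric(stat), stat_name = name, tail = tail,
                 beta_sign = beta_sign),
            class = "stat_result")
}

#' @describeIn glm_statistics Student's t for a single regressor of
#'   interest: \eqn{T = \hat\beta (X'X)^{1/2} / \hat\sigma}, with
#'   \eqn{\hat\sigma^2 = \hat\epsilon'\hat\epsilon / (N - rank(M))}.
#'   \code{Y} may have several columns (one test per column). A perfect
#'   fit (zero residual) yields a signed infinite statistic with a
#'   warning.
#' @param Y numeric matrix of responses, N rows (columns are separate
#'   tests for \code{t_statistic}/\code{f_statistic}, response variables
#'   for the multivariate statistics).
#' @param X N x S matrix of regressors of interest (S = 1 for t).
#' @param Z N x (R - S) matrix of nuisance regressors, orthogonal to X;
#'   may have zero columns.
#' @export
t_statistic <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != 1L) stop("t_statistic requires a single column of interest")
  N <- nrow(Y)
  rank_M <- ncol(X) + ncol(Z)
  df <- N - rank_M
  xtx <- drop(crossprod(X))
  beta <- drop(crossprod(X, Y)) / xtx
  fit <- X %*% rbind(beta)
  if (ncol(Z) > 0) {
    gz <- solve(crossprod(Z), crossprod(Z, Y))
    fit <- fit + Z %*% gz
  }
  rss <- colSums((Y - fit)^2)
  sigma <- sqrt(rss / df)
  tt <- beta * sqrt(xtx) / sigma
  if (any(sigma == 0)) {
    z <- sigma == 0
    if (any(beta[z] != 0))
      warning("zero residual variance: statistic set to signed infinity")
    tt[z] <- sign(beta[z]) * Inf
    tt[z][beta[z] == 0] <- 0
  }
  stat_result(tt, "t", "upper", beta_sign = sign(beta))
}

#' @describeIn glm_statistics F statistic for S regressors of interest
#'   (univariate response), one-tailed upper, with \eqn{N - rank(M)}
#'   denominator degrees of freedom.
#' @export
f_statistic <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  N <- nrow(Y); S <- ncol(X)
  df <- N - S - ncol(Z)
  bX <- solve(crossprod(X), crossprod(X, Y))
  fit <- X %*% bX
  if (ncol(Z) > 0) fit <- fit + Z %*% solve(crossprod(Z), crossprod(Z, Y))
  rss <- colSums((Y - fit)^2)
  mss <- colSums((X %*% bX)^2)
  ff <- (mss / S) / (rss / df)
  if (any(rss == 0)) {
    warning("zero residual variance: statistic set to infinity")
    ff[rss == 0] <- Inf
  }
  stat_result(ff, "F", "upper")
}

#' @describeIn glm_statistics Pillai's trace
#'   \eqn{T = trace(\tilde Y' H_X \tilde Y (\tilde Y'\tilde Y)^{-1})}
#'   for one multivariate test (\code{Y} is N x K). Equivalently
#'   \eqn{T = trace(H_X U U')} with \eqn{U} the left singular vectors of
#'   \eqn{\tilde Y = R_Z Y}. For S = K = 1 the signed square root of T is
#'   the partial correlation of Y and X given Z.
#' @export
pillai_trace <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  X <- residualize(X, Z)   # no-op for an already-orthogonal partition
  Yt <- residualize(Y, Z)
  if (all(abs(Yt) < .Machine$double.eps * 1e2)) {
    warning("degenerate data: residualized Y is zero")
    return(stat_result(0, "pillai", "upper"))
  }
  U <- orth(Yt)
  HU <- X %*% solve(crossprod(X), crossprod(X, U))
  tr <- sum(HU * U)
  bs <- if (ncol(X) == 1L && ncol(Y) == 1L)
    sign(drop(crossprod(X, Yt))) else NULL
  stat_result(tr, "pillai", "upper", beta_sign = bs)
}

#' @describeIn glm_statistics Wilks' lambda
#'   \eqn{\lambda = det(E)/det(H + E)} with hypothesis and error
#'   cross-product matrices formed from \eqn{\tilde Y = R_Z Y}; values lie
#'   in (0, 1], smaller meaning stronger evidence (lower tail).
#' @export
wilks_lambda <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  X <- residualize(X, Z)   # no-op for an already-orthogonal partition
  Yt <- residualize(Y, Z)
  U <- orth(Yt)  # work in the non-null column space of Yt
  Yu <- Yt %*% svd(Yt)$v[, seq_len(ncol(U)), drop = FALSE]
  fitX <- X %*% solve(crossprod(X), crossprod(X, Yu))
  E <- crossprod(Yu - fitX)
  Tt <- crossprod(Yu)
  lam <- det(E) / det(Tt)
  lam <- min(max(lam, .Machine$double.xmin), 1)
  stat_result(lam, "wilks", "lower")
}

residualize <- function(Y, Z) {
  if (ncol(Z) == 0) return(Y)
  Y - Z %*% solve(crossprod(Z), crossprod(Z, Y))
}

#' Non-parametric combination of partial-test p-values
#'
#' Combines the p-values of K partial tests into a joint statistic using
#' Tippett's (minimum p; smaller = stronger) or Fisher's
#' (\eqn{-2\sum \ln p}; larger = stronger) combining function. Partial
#' tests must have been evaluated under one synchronized shuffle set; the
#' combining function itself is agnostic to that, and the contract is
#' enforced by \code{\link{npc_test}}.
#'
#' @param p numeric vector (or matrix, combined row-wise) of partial-test
#'   p-values in (0, 1].
#' @param method "tippett" or "fisher".
#' @param p_floor smallest attainable p-value (1/J); zeros are clamped to
#'   it with a warning. Without a floor, zero p-values are an error for
#'   Fisher's method.
#' @return a \code{stat_result} with the combined statistic(s).
#' @export
npc_combine <- function(p, method = c("tippett", "fisher"), p_floor = NULL) {
  method <- match.arg(method)
  pm <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  if (any(pm <= 0)) {
    if (is.null(p_floor))
      stop("p-values must be in (0, 1]; supply p_floor = 1/J to clamp")
    warning("p-value of zero clamped to the smallest attainable (1/J)")
    pm[pm <= 0] <- p_floor
  }
  if (any(pm > 1)) stop("p-values must be in (0, 1]")
  if (method == "tippett") {
    stat_result(apply(pm, 1, min), "npc_tippett", "lower")
  } else {
    stat_result(rowSums(-2 * log(pm)), "npc_fisher", "upper")
  }
}
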