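#' Build a GLM design with contrast-conformant partitioning
#'
#' Represents the general linear model \eqn{Y = M\psi + \epsilon} together
#' with a contrast \eqn{C} on the regression coefficients, and the
#' equivalent partitioned form \eqn{Y = X\beta + Z\gamma + \epsilon} in
#' which \eqn{X} spans the contrast space, \eqn{Z} the nuisance space, and
#' the columns of \eqn{X} and \eqn{Z} are mutually orthogonal. Inference on
#' \eqn{\beta} is then equivalent to inference on \eqn{C'\psi}.
#'
#' The partitioning is not unique; this implementation uses the
#' contrast-conformant projection \eqn{X = M (M'M)^{+} C}, with \eqn{Z} an
#' orthonormal basis of the residual column space of \eqn{M} after removing
#' the span of \eqn{X}. Only partition invariants (identical test
#' statistics from the original and partitioned forms) are guaranteed, not
#' any particular basis.
#'
#' @param M numeric N x R design matrix, full rank.
#' @param C numeric R x S contrast matrix (a vector is taken as one
#'   contrast column), full rank, S <= R.
#' @param D optional K x Q response-side contrast; the identity by default.
#'   When supplied, responses should be premultiplied as \code{Y \%*\% D}
#'   before testing.
#' @return An object of class \code{perm_design}: a list with elements
#'   \code{M}, \code{C}, \code{D}, \code{X}, \code{Z}, and the dimensions
#'   \code{N}, \code{R}, \code{S}, plus \code{rank_M} and the projectors
#'   used downstream.
#' @examples
#' M <- cbind(rnorm(12), 1)
#' d <- make_design(M, c(1, 0))
#' max(abs(crossprod(d$X, d$Z)))  # orthogonal partition
#' @export
make_design <- function(M, C, D = NULL) {
  M <- as.matrix(M)
  C <- as.matrix(C)
  storage.mode(M) <- "double"
  storage.mode(C) <- "double"
  N <- nrow(M); R <- ncol(M); S <- ncol(C)
  if (nrow(C) != R)
    stop("contrast C must have one row per column of M (", R, ")")
  if (mat_rank(M) < R)
    stop("invalid design: M is rank deficient")
  if (mat_rank(C) < S || S > R)
    stop("invalid design: C must be full rank with S <= R")
  pm <- partition_model(M, C)
  rank_M <- R
  str <- list(
    M = M, C = C, D = D,
    X = pm$X, Z = pm$Z,
    N = N, R = R, S = S,
    rank_M = rank_M,
    df = N - rank_M
  )
  class(str) <- "perm_design"
  str
}

#' Partition a design matrix by a contrast
#'
#' Splits the design \code{M} into regressors of interest \code{X}
#' (spanning the contrast space of \code{C}) and nuisance regressors
#' \code{Z}, with \code{X} and \code{Z} column-orthogonal. The test of
#' \eqn{C'\psi = 0} in the original model is equivalent to the test of
#' \eqn{\beta = 0} in the partitioned one.
#'
#' @inheritParams make_design
#' @return list with components \code{X} (N x S) and \code{Z}
#'   (N x (R - S), zero columns when the whole design is of interest).
#' @export
partition_model <- function(M, C) {
  M <- as.matrix(M); C <- as.matrix(C)
  N <- nrow(M); R <- ncol(M); S <- ncol(C)
  if (mat_rank(M) < R) stop("invalid design: M is rank deficient")
  if (mat_rank(C) < S) stop("invalid design: C is rank deficient")
  X <- M %*% pinv(crossprod(M)) %*% C
  if (S >= R) {
    Z <- matrix(0, N, 0)
  } else {
    Px <- X %*% pinv(X)
    Z <- orth((diag(N) - Px) %*% M)
    if (ncol(Z) != R - S)
      stop("partition failed: nuisance space has unexpected rank")
  }
  list(X = X, Z = Z)
}

# Residual-forming and hat matrices of a (possibly empty) block.
proj_hat <- function(A) {
  if (ncol(A) == 0) return(matrix(0, nrow(A), nrow(A)))
  A %*% pinv(A)
}
proj_res <- function(A) diag(nrow(A)) - proj_hat(A)

#' Read a headerless design or contrast matrix from CSV
#'
#' @param path file path; plain CSV, rows are observations (for designs) or
#'   contrast rows.
#' @param header logical; the files are headerless by default.
#' @return numeric matrix.
#' @export
read_matrix_csv <- function(path, header = FALSE) {
  m <- as.matrix(utils::read.csv(path, header = header))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}
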