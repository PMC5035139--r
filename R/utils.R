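#' @keywords internal
"_PACKAGE"

# Moore-Penrose pseudoinverse; singular values below
# max(dim) * eps * sigma_max are treated as zero.
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

mat_rank <- function(A, tol = NULL) {
  d <- svd(as.matrix(A), nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

# Orthonormal basis for the column space of A.
orth <- function(A, tol = NULL) {
  sv <- svd(as.matrix(A))
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  sv$u[, sv$d > tol, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
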