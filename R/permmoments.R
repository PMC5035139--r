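# Exact moments of T = trace(A P W P') over the N! permutations P.
#
# E[T^m] is a sum over index tuples (i1,j1,...,im,jm) of products of W
# entries times the permutation expectation of the matching product of A
# entries. Grouping tuples by their exact coincidence pattern (a set
# partition of the 2m positions) turns the expectation into
#   E[T^m] = sum_sigma D_W(sigma) * D_A(sigma) / fall(N, b(sigma)),
# where D_M(sigma) is the sum over tuples with *distinct* block values of
# the entry product, b(sigma) the number of blocks, and fall() the falling
# factorial. D is recovered from unconstrained ("free") pattern sums F by
# Mobius inversion on the partition lattice: F(sigma) = sum over
# coarsenings tau of D(tau). Free sums are small tensor contractions (a
# multigraph with at most 3 edges per component), computed exactly.
#
# The approach is fully general in A and W; correctness is gated on the
# exhaustive-enumeration oracle in the test suite.

# Set partitions of 1..k as restricted-growth block-label vectors.
set_partitions <- function(k) {
  out <- list()
  rec <- function(labels, maxlab) {
    pos <- length(labels) + 1L
    if (pos > k) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(labels, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Does sigma refine tau (tau coarser or equal)?
refines <- function(sigma, tau) {
  # positions equal under sigma must be equal under tau
  all(tapply(tau, sigma, function(v) length(unique(v)) == 1L))
}

# Cached combinatorial structure for moment order m.
perm_moment_structure <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- 2L * m
    parts <- set_partitions(k)
    P <- length(parts)
    nblocks <- vapply(parts, max, integer(1))
    # edges: factor t connects blocks of positions 2t-1 and 2t
    edges <- lapply(parts, function(p)
      cbind(p[seq(1, k, by = 2)], p[seq(2, k, by = 2)]))
    degs <- lapply(seq_len(P), function(i) {
      d <- integer(nblocks[i])
      for (t in seq_len(m)) {
        e <- edges[[i]][t, ]
        d[e[1]] <- d[e[1]] + 1L
        d[e[2]] <- d[e[2]] + 1L
      }
      d
    })
    # strictly coarser partitions of each sigma (fewer or equal blocks,
    # sigma refines tau, tau != sigma)
    coarser <- lapply(seq_len(P), function(i) {
      which(vapply(seq_len(P), function(j)
        j != i && nblocks[j] <= nblocks[i] && refines(parts[[i]], parts[[j]]),
        logical(1)))
    })
    ord <- order(nblocks)  # process coarsest first in Mobius recursion
    st <- list(parts = parts, nblocks = nblocks, edges = edges,
               degs = degs, coarser = coarser, ord = ord, m = m)
    cache[[key]] <<- st
    st
  }
})

# Free pattern sum for one partition: contraction of the block multigraph
# against a symmetric matrix. Components have at most 4 vertices here.
free_sum_matrix <- function(Mat, edges, nblocks) {
  N <- nrow(Mat)
  # connected components of the block graph (isolated blocks included)
  adj <- lapply(seq_len(nblocks), function(i) integer(0))
  for (t in seq_len(nrow(edges))) {
    u <- edges[t, 1]; v <- edges[t, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  comp <- integer(nblocks); cc <- 0L
  for (s in seq_len(nblocks)) {
    if (comp[s] > 0L) next
    cc <- cc + 1L
    stack <- s
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[x] > 0L) next
      comp[x] <- cc
      stack <- c(stack, adj[[x]][comp[adj[[x]]] == 0L])
    }
  }
  total <- 1
  for (c0 in seq_len(cc)) {
    vs <- which(comp == c0)
    es <- edges[edges[, 1] %in% vs | edges[, 2] %in% vs, , drop = FALSE]
    if (nrow(es) == 0L) { total <- total * N; next }
    cmap <- match(seq_len(nblocks), vs)
    nv <- length(vs)
    labs <- as.matrix(expand.grid(rep(list(seq_len(N)), nv)))
    val <- rep(1, nrow(labs))
    for (t in seq_len(nrow(es))) {
      u <- cmap[es[t, 1]]; v <- cmap[es[t, 2]]
      val <- val * Mat[cbind(labs[, u], labs[, v])]
    }
    total <- total * sum(val)
  }
  total
}

falling <- function(N, b) prod(N - seq_len(b) + 1)

# Distinct-pattern sums for a symmetric matrix, all partitions of order m.
distinct_sums_matrix <- function(Mat, st) {
  P <- length(st$parts)
  Fv <- vapply(seq_len(P), function(i)
    free_sum_matrix(Mat, st$edges[[i]], st$nblocks[i]), numeric(1))
  Dv <- numeric(P)
  for (i in st$ord)
    Dv[i] <- Fv[i] - sum(Dv[st$coarser[[i]]])
  Dv
}

# Distinct-pattern sums for a rank-one matrix u u' via power sums of u.
distinct_sums_rank1 <- function(u, st) {
  N <- length(u)
  s <- c(N, vapply(1:6, function(m) sum(u^m), numeric(1)))
  Fv <- vapply(seq_along(st$parts), function(i)
    prod(s[st$degs[[i]] + 1L]), numeric(1))
  Dv <- numeric(length(Fv))
  for (i in st$ord)
    Dv[i] <- Fv[i] - sum(Dv[st$coarser[[i]]])
  Dv
}

# Engine: precomputes everything that depends only on A, returning a
# function mapping W (or a rank-one factor u) to the first three moments
# (mean, variance, skewness) of trace(A P W P') over permutations.
traceAW_moment_engine <- function(A) {
  N <- nrow(A)
  sts <- lapply(1:3, perm_moment_structure)
  DA <- lapply(sts, function(st) distinct_sums_matrix(A, st))
  coefs <- lapply(1:3, function(m) {
    st <- sts[[m]]
    ff <- vapply(st$nblocks, function(b) falling(N, b), numeric(1))
    ok <- ff != 0
    list(coef = ifelse(ok, DA[[m]] / ff, 0), ok = ok)
  })
  raw_to_central <- function(r) {
    mu <- r[1]
    v <- r[2] - mu^2
    m3 <- r[3] - 3 * mu * r[2] + 2 * mu^3
    c(mean = mu, variance = v,
      skewness = if (v > 0) m3 / v^1.5 else 0)
  }
  function(W = NULL, u = NULL) {
    raw <- vapply(1:3, function(m) {
      DW <- if (!is.null(u)) distinct_sums_rank1(u, sts[[m]])
      else distinct_sums_matrix(W, sts[[m]])
      sum(coefs[[m]]$coef * DW)
    }, numeric(1))
    raw_to_central(raw)
  }
}

#' Analytic moments of the permutation distribution of trace(AW)
#'
#' For statistics expressible as \eqn{T = trace(AW)} with
#' \eqn{A = H_X = XX^{+}} and \eqn{W = UU'} (U the left singular vectors
#' of \eqn{\tilde Y = R_Z Y}), the first three moments of the
#' distribution of T over all N! permutations are computed exactly in
#' closed form, without performing any permutation. Both A and W must be
#' symmetric with mean-centered columns, which requires the model
#' intercept to be entirely represented in Z and all columns of X to
#' have zero mean; designs violating this are refused.
#'
#' @param X,Z partitioned design blocks (X of interest, Z nuisance,
#'   orthogonal).
#' @param Y N x K response matrix for one test.
#' @return named vector with \code{mean}, \code{variance},
#'   \code{skewness} of the exact permutation distribution of Pillai's
#'   trace.
#' @export
analytic_moments_traceAW <- function(X, Z, Y) {
  X <- as.matrix(X); Z <- as.matrix(Z); Y <- as.matrix(Y)
  check_centered_design(X, Z)
  A <- X %*% pinv(X)
  Yt <- residualize(Y, Z)
  U <- orth(Yt)
  W <- U %*% t(U)
  if (max(abs(colMeans(W))) > 1e-8)
    stop("W = UU' does not have mean-centered columns; ",
         "the intercept must be entirely represented in Z")
  eng <- traceAW_moment_engine(A)
  if (ncol(U) == 1L) eng(u = drop(U)) else eng(W = W)
}

check_centered_design <- function(X, Z) {
  N <- nrow(X)
  if (max(abs(colMeans(X))) > 1e-8 * max(1, max(abs(X))))
    stop("all columns of X must have zero mean for the analytic moments ",
         "of trace(AW); this restricts the admissible designs")
  ones <- rep(1, N)
  if (ncol(Z) == 0 || max(abs(ones - Z %*% pinv(Z) %*% ones)) > 1e-8)
    stop("the model intercept must be entirely represented in Z ",
         "for the analytic moments of trace(AW)")
  invisible(TRUE)
}

#' Directional p-value from a two-tailed gamma-fit p-value
#'
#' The two-tailed p-value from the gamma fit to Pillai's trace is
#' halved; when the sign of the regression coefficient of the
#' partitioned model is negative, the halved value is subtracted from
#' unity. A zero coefficient is treated as positive.
#'
#' @param p_two two-tailed p-value in (0, 1].
#' @param beta_sign sign of the coefficient of interest.
#' @return the one-sided (directional) p-value.
#' @examples
#' directional_p(0.04, +1)  # 0.02
#' directional_p(0.04, -1)  # 0.98
#' @export
directional_p <- function(p_two, beta_sign) {
  ifelse(beta_sign >= 0, p_two / 2, 1 - p_two / 2)
}

#' p-values without permutations via analytic moments of Pillai's trace
#'
#' For a single regressor of interest and univariate response, Pillai's
#' trace has a monotone relationship with the t statistic:
#' \eqn{sign(\beta)\sqrt{T}} is the partial correlation. A Pearson III
#' distribution is fitted to the exact analytic moments of the
#' permutation distribution of T, a two-tailed p-value read from its
#' upper tail, halved, and subtracted from unity when the sign of the
#' regression coefficient in the partitioned model is negative (a zero
#' coefficient is treated as positive). Errors are assumed symmetric:
#' the result approximates permutations proper, not sign flippings, and
#' is unreliable for skewed errors.
#'
#' @param Y N x V response matrix.
#' @param design a \code{\link{make_design}} object whose X block is a
#'   single mean-centered column and whose Z block contains the
#'   intercept.
#' @return list with \code{p} (directional p-values), \code{pillai}
#'   (the statistic values), \code{moments} (V x 3 matrix).
#' @export
noperm_pvalue <- function(Y, design) {
  Y <- as.matrix(Y)
  X <- design$X; Z <- design$Z
  if (ncol(X) != 1L)
    stop("the no-permutation method requires a single regressor of interest")
  check_centered_design(X, Z)
  A <- X %*% pinv(X)
  eng <- traceAW_moment_engine(A)
  Yt <- residualize(Y, Z)
  V <- ncol(Y)
  p <- numeric(V); tr <- numeric(V)
  mom <- matrix(NA_real_, V, 3,
                dimnames = list(NULL, c("mean", "variance", "skewness")))
  hx <- drop(X) / sqrt(drop(crossprod(X)))   # unit vector spanning X
  for (v in seq_len(V)) {
    yt <- Yt[, v]
    nrm <- sqrt(sum(yt^2))
    if (nrm == 0) {
      warning("degenerate data: residualized response is zero")
      p[v] <- 1; tr[v] <- 0
      next
    }
    u <- yt / nrm
    Tv <- sum(hx * u)^2
    m <- eng(u = u)
    mom[v, ] <- m
    fit <- withCallingHandlers(
      fit_pearson3(m["mean"], m["variance"], m["skewness"]),
      warning = function(w) invokeRestart("muffleWarning"))
    p2 <- pearson3_sf(Tv, fit)
    p2 <- min(max(p2, .Machine$double.xmin), 1)
    p[v] <- directional_p(p2, sign(sum(X * yt)))
    tr[v] <- Tv
  }
  list(p = p, pillai = tr, moments = mom)
}
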