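#' Run the GLM under a set of rearrangements
#'
#' Executes one of the implemented shuffling strategies (Freedman-Lane,
#' Manly, or Draper-Stoneman) for every rearrangement in \code{shuffles},
#' producing the J x V matrix of test statistics whose first row is the
#' unpermuted case.
#'
#' For the t statistic the computation uses the factorisation
#' \eqn{T = \kappa B \odot \Sigma^{[-1/2]}}: the coefficient matrix B is a
#' product of a J x N matrix (rows determined by the rearrangements and
#' the strategy) and an N x V data matrix, and the residual
#' sum-of-squares matrix is obtained from projections onto the model's
#' orthonormal column basis. This is algebraically identical to refitting
#' the model per rearrangement, and is also the representation that the
#' low-rank completion accelerator samples sparsely.
#'
#' @param Y N x V response matrix (t/F), N x K matrix (single
#'   multivariate test), or a list of K N x V matrices (voxelwise
#'   multivariate tests).
#' @param design a \code{\link{make_design}} object.
#' @param stat_name one of "t", "F", "pillai", "wilks".
#' @param strategy "freedman_lane" (default), "manly", or
#'   "draper_stoneman".
#' @param shuffles a \code{\link{generate_shuffles}} object.
#' @return An object of class \code{perm_dist}: list with \code{stats}
#'   (J x V, row 1 unpermuted), \code{stat_name}, \code{tail},
#'   \code{beta_sign} (unpermuted, for directional t), \code{shuffles}.
#' @export
run_shuffled_glm <- function(Y, design, stat_name = "t",
                             strategy = c("freedman_lane", "manly",
                                          "draper_stoneman"),
                             shuffles = NULL) {
  strategy <- match.arg(strategy)
  if (!stat_name %in% c("t", "F", "pillai", "wilks"))
    stop("unsupported statistic: ", stat_name)
  if (is.null(shuffles)) stop("a shuffle_set is required")
  if (stat_name == "t") {
    bs <- compute_BSigma(as.matrix(Y), design, strategy, shuffles)
    stats <- bs$kappa * bs$B / sqrt(pmax(bs$Sigma, 0))
    stats[!is.finite(stats)] <- 0
    # restore signed infinities for genuinely zero residuals
    zero <- bs$Sigma <= 0 & bs$B != 0
    if (any(zero)) stats[zero] <- sign(bs$B[zero]) * Inf
    res <- list(stats = stats, stat_name = "t", tail = "upper",
                beta_sign = sign(bs$B[1, ]), shuffles = shuffles)
  } else {
    res <- perm_generic_dist(Y, design, stat_name, strategy, shuffles)
  }
  class(res) <- "perm_dist"
  res
}

# Strategy table: the J x N row operators and residual bases.
# scatter places entries so that row j represents the row vector a P_j
# (P_j the signed permutation), i.e. out[perm] = a * sign.
scatter_rows <- function(a, shuffles) {
  J <- shuffles$J; N <- length(a)
  out <- matrix(0, J, N)
  lin <- (shuffles$perms - 1L) * J + seq_len(J)
  out[lin] <- rep(a, each = J) * shuffles$signs
  out
}

compute_BSigma <- function(Y, design, strategy, shuffles,
                           voxels = NULL) {
  X <- design$X; Z <- design$Z
  N <- design$N
  if (!is.null(voxels)) Y <- Y[, voxels, drop = FALSE]
  V <- ncol(Y)
  J <- shuffles$J
  kappa <- sqrt(drop(crossprod(X)) * design$df)
  Ytil <- if (strategy == "freedman_lane") residualize(Y, Z) else Y
  if (strategy == "draper_stoneman") {
    # pseudoinverse and basis depend on the shuffled X each time
    Xtil <- matrix(0, J, N)
    rnk <- design$rank_M
    Qbig <- vector("list", rnk)
    for (r in seq_len(rnk)) Qbig[[r]] <- matrix(0, J, N)
    for (j in seq_len(J)) {
      Xs <- shuffles$signs[j, ] * X[shuffles$perms[j, ], , drop = FALSE]
      Mj <- cbind(Xs, Z)
      Xtil[j, ] <- pinv(Mj)[1, ]
      Qj <- orth(Mj)
      for (r in seq_len(ncol(Qj))) Qbig[[r]][j, ] <- Qj[, r]
    }
  } else {
    a <- drop(X) / drop(crossprod(X))   # effective-contrast row of pinv(M)
    Q <- orth(cbind(X, Z))
    Xtil <- scatter_rows(a, shuffles)
    Qbig <- lapply(seq_len(ncol(Q)),
                   function(r) scatter_rows(Q[, r], shuffles))
  }
  B <- Xtil %*% Ytil
  Sigma <- matrix(colSums(Ytil^2), J, V, byrow = TRUE)
  for (r in seq_along(Qbig)) Sigma <- Sigma - (Qbig[[r]] %*% Ytil)^2
  list(B = B, Sigma = Sigma, kappa = kappa, Ytil = Ytil)
}

# Naive per-rearrangement path for F and multivariate statistics.
perm_generic_dist <- function(Y, design, stat_name, strategy, shuffles) {
  X <- design$X; Z <- design$Z
  J <- shuffles$J
  multilist <- is.list(Y)
  statfun <- switch(stat_name, F = f_statistic,
                    pillai = pillai_trace, wilks = wilks_lambda)
  shuffle_mat <- function(M, j)
    shuffles$signs[j, ] * M[shuffles$perms[j, ], , drop = FALSE]
  one <- function(Yv, j) {
    if (strategy == "freedman_lane") {
      Ys <- shuffle_mat(residualize(Yv, Z), j) + (Yv - residualize(Yv, Z))
      statfun(Ys, X, Z)$stat
    } else if (strategy == "manly") {
      statfun(shuffle_mat(Yv, j), X, Z)$stat
    } else {
      Xs <- residualize(shuffle_mat(X, j), Z)
      statfun(Yv, Xs, Z)$stat
    }
  }
  if (!multilist && stat_name == "F") {
    Y <- as.matrix(Y)
    stats <- t(vapply(seq_len(J), function(j) one(Y, j), numeric(ncol(Y))))
    if (ncol(Y) == 1L) stats <- matrix(stats, ncol = 1)
  } else {
    if (multilist) {
      K <- length(Y); V <- ncol(Y[[1]])
      stats <- matrix(NA_real_, J, V)
      for (v in seq_len(V)) {
        Yv <- vapply(Y, function(m) m[, v], numeric(design$N))
        for (j in seq_len(J)) stats[j, v] <- one(Yv, j)
      }
    } else {
      Y <- as.matrix(Y)
      stats <- matrix(vapply(seq_len(J), function(j) one(Y, j),
                             numeric(1)), ncol = 1)
    }
  }
  list(stats = stats, stat_name = stat_name,
       tail = if (stat_name == "wilks") "lower" else "upper",
       beta_sign = NULL, shuffles = shuffles)
}

#' Counting p-values from a permutation distribution
#'
#' The fraction of rearrangements (including the unpermuted case, row 1)
#' whose statistic is at least as extreme as the unpermuted one; ties are
#' counted inclusively.
#'
#' @param dist a \code{perm_dist}.
#' @return numeric vector of p-values in [1/J, 1].
#' @export
counting_pvalue <- function(dist) {
  J <- nrow(dist$stats)
  T1 <- matrix(dist$stats[1, ], J, ncol(dist$stats), byrow = TRUE)
  if (dist$tail == "upper") colMeans(dist$stats >= T1)
  else colMeans(dist$stats <= T1)
}

#' @export
print.perm_dist <- function(x, ...) {
  cat("Permutation distribution: ", nrow(x$stats), " rearrangements x ",
      ncol(x$stats), " tests (", x$stat_name, ", ", x$tail, " tail)\n",
      sep = "")
  invisible(x)
}

#' Joint inference by non-parametric combination (NPC)
#'
#' Runs the t statistic for each of K modalities under one synchronized
#' shuffle set, converts each modality's statistics to within-column
#' empirical p-values, combines them with Tippett's or Fisher's function,
#' and evaluates the combined statistic by counting over the same
#' rearrangements. Unsynchronized input (per-modality shuffle sets) is
#' rejected by construction: a single \code{shuffles} object drives all
#' modalities.
#'
#' @param Ylist list of K response matrices (N x V each).
#' @inheritParams run_shuffled_glm
#' @param method combining function, "tippett" or "fisher".
#' @return list with combined \code{perm_dist}, the combined p-values
#'   \code{p}, and the per-modality partial p-values of the unpermuted
#'   case.
#' @export
npc_test <- function(Ylist, design, method = c("tippett", "fisher"),
                     strategy = "freedman_lane", shuffles = NULL) {
  method <- match.arg(method)
  if (!is.list(Ylist) || length(Ylist) < 2)
    stop("NPC requires a list of at least two modalities")
  V <- ncol(Ylist[[1]]); J <- shuffles$J
  U <- vector("list", length(Ylist))
  for (k in seq_along(Ylist)) {
    d <- run_shuffled_glm(Ylist[[k]], design, "t", strategy, shuffles)
    # within-column inclusive exceedance probability of each row
    U[[k]] <- apply(d$stats, 2, function(col)
      (J - rank(col, ties.method = "min") + 1) / J)
  }
  comb <- if (method == "tippett") Reduce(pmin, U)
  else Reduce(`+`, lapply(U, function(u) -2 * log(u)))
  dist <- structure(
    list(stats = comb,
         stat_name = paste0("npc_", method),
         tail = if (method == "tippett") "lower" else "upper",
         beta_sign = NULL, shuffles = shuffles),
    class = "perm_dist")
  list(dist = dist, p = counting_pvalue(dist),
       partial_p = vapply(U, function(u) u[1, ], numeric(V)))
}
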