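#' Exact low-rank completion of the permutation t-statistic matrix
#'
#' The J x V matrix of t statistics factorises as
#' \eqn{T = \kappa B \odot \Sigma^{[-1/2]}} where B (regression
#' coefficients) has rank at most N and \eqn{\Sigma} (residual sums of
#' squares) rank at most N(N+1)/2. Running an initial
#' \eqn{J_0 = N(N+1)/2} permutations over all V tests yields fully
#' sampled \eqn{B_0} and \eqn{\Sigma_0} whose SVD provides orthonormal
#' row-space bases; every subsequent permutation needs only
#' \eqn{v \ge v_0 = N(N+1)/2} randomly sampled tests, the remaining
#' entries being recovered exactly by projection onto the bases. The
#' column mean of \eqn{\Sigma_0} is subtracted before the SVD and added
#' back after recovery, to limit sign-ambiguity effects (all entries of
#' \eqn{\Sigma} are positive).
#'
#' @name lowrank
NULL

#' @describeIn lowrank Run the initial fully sampled permutations and
#'   assemble the bases. Requires \code{min(J, V) > N(N+1)/2}
#'   (condition I); in particular completion cannot help when V is not
#'   larger than \eqn{v_0}.
#' @param Y N x V response matrix.
#' @param design a \code{\link{make_design}} object (single regressor
#'   of interest; the factorisation is specific to the t statistic).
#' @param strategy shuffling strategy (a Table-of-strategies row whose B
#'   factorises as a J x N times an N x V matrix): "freedman_lane",
#'   "manly", or "draper_stoneman".
#' @param shuffles shuffle set whose first \eqn{J_0} rows are used for
#'   the fully sampled phase.
#' @return \code{build_bases}: an object of class \code{lowrank_state}:
#'   \code{J0}, \code{U_B} (r_B x V), \code{U_S} (r_S x V),
#'   \code{sigma_mean} (1 x V), ranks \code{r_B}, \code{r_S},
#'   \code{kappa}, \code{v0}.
#' @export
build_bases <- function(Y, design, strategy = "freedman_lane",
                        shuffles = NULL) {
  Y <- as.matrix(Y)
  N <- design$N; V <- ncol(Y)
  if (ncol(design$X) != 1L)
    stop("low-rank completion supports the t statistic only")
  J0 <- N * (N + 1) / 2
  if (V <= J0)
    stop("condition I violated: completion requires more tests than ",
         "v0 = N(N+1)/2 = ", J0)
  if (shuffles$J < J0)
    stop("need at least J0 = ", J0, " rearrangements to build the bases")
  sh0 <- subset_shuffles(shuffles, seq_len(J0))
  bs <- compute_BSigma(Y, design, strategy, sh0)
  rowbasis <- function(M) {
    sv <- svd(M)
    tol <- max(dim(M)) * .Machine$double.eps * max(sv$d)
    r <- sum(sv$d > tol)
    t(sv$v[, seq_len(r), drop = FALSE])   # r x V, orthonormal rows
  }
  U_B <- rowbasis(bs$B)
  mu <- colMeans(bs$Sigma)
  U_S <- rowbasis(sweep(bs$Sigma, 2, mu))
  structure(list(J0 = J0, U_B = U_B, U_S = U_S, sigma_mean = mu,
                 r_B = nrow(U_B), r_S = nrow(U_S),
                 kappa = bs$kappa, v0 = J0, N = N, V = V),
            class = "lowrank_state")
}

subset_shuffles <- function(shuffles, rows) {
  out <- shuffles
  out$perms <- shuffles$perms[rows, , drop = FALSE]
  out$signs <- shuffles$signs[rows, , drop = FALSE]
  out$J <- length(rows)
  out$exhaustive <- FALSE
  out
}

#' @describeIn lowrank Recover a complete row of B and Sigma from
#'   sampled entries: \eqn{\beta_j = \tilde\beta_j \tilde U^{+} U}, and
#'   the same for the residual row after removing/adding back the
#'   stored column mean. Recovery is exact when at least as many entries
#'   as the corresponding rank are sampled; with fewer, an approximate
#'   recovery is returned with a warning.
#' @param beta_sampled,sigma_sampled sampled entries of the row.
#' @param sampled_idx column indices of the sampled entries.
#' @param state a \code{lowrank_state}.
#' @return \code{complete_row}: list with \code{beta} and \code{sigma}
#'   full rows, and \code{exact} (logical).
#' @export
complete_row <- function(beta_sampled, sigma_sampled, sampled_idx, state) {
  v <- length(sampled_idx)
  exact <- v >= max(state$r_B, state$r_S)
  if (!exact)
    warning("fewer sampled entries (", v, ") than the basis rank (",
            max(state$r_B, state$r_S), "): approximate recovery")
  Ub <- state$U_B[, sampled_idx, drop = FALSE]
  beta <- drop((beta_sampled %*% pinv(Ub)) %*% state$U_B)
  Us <- state$U_S[, sampled_idx, drop = FALSE]
  sc <- sigma_sampled - state$sigma_mean[sampled_idx]
  sig <- drop((sc %*% pinv(Us)) %*% state$U_S) + state$sigma_mean
  list(beta = beta, sigma = sig, exact = exact)
}

#' @describeIn lowrank Full permutation test through completion: the
#'   initial \eqn{J_0} permutations build the bases and are then
#'   revisited through completion so that all J rearrangements are
#'   treated equally; each subsequent rearrangement computes the
#'   statistic on \code{v} sampled tests only. Rows of T are used to
#'   update exceedance counters and the image-wise maxima, then
#'   discarded (the full matrix is only retained if
#'   \code{return_t = TRUE}, for verification).
#' @param J total number of rearrangements.
#' @param v tests sampled per sparse rearrangement; defaults to
#'   \eqn{v_0}. Values below \eqn{v_0} are refused unless
#'   \code{allow_approximate = TRUE}.
#' @param mode rearrangement mode ("ee", "ise", "both").
#' @param seed RNG seed (shuffles and voxel sampling).
#' @param allow_approximate permit v below the exact-recovery minimum.
#' @param return_t keep the completed J x V matrix.
#' @return \code{lowrank_test}: list with \code{p} (uncorrected),
#'   \code{p_fwer}, \code{stat} (unpermuted row), \code{state},
#'   \code{exact} (all rows exactly recoverable), and optionally
#'   \code{T}.
#' @export
lowrank_test <- function(Y, design, J, v = NULL,
                         strategy = "freedman_lane", mode = "ee",
                         seed = NULL, allow_approximate = FALSE,
                         return_t = FALSE) {
  Y <- as.matrix(Y)
  N <- design$N; V <- ncol(Y)
  J0 <- N * (N + 1) / 2
  if (J < J0) stop("J must be at least J0 = ", J0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  shuffles <- generate_shuffles(N, J, mode)
  state <- build_bases(Y, design, strategy, shuffles)
  if (is.null(v)) v <- state$v0
  if (v < max(state$r_B, state$r_S)) {
    if (!allow_approximate)
      stop("v = ", v, " is below the exact-recovery minimum ",
           max(state$r_B, state$r_S), "; pass allow_approximate = TRUE ",
           "to proceed (error rates are then not guaranteed)")
    warning("v = ", v, " is below the exact-recovery minimum ",
            max(state$r_B, state$r_S), ": approximate recovery")
  }
  v <- min(v, V)
  exceed <- NULL; maxima <- numeric(J); T1 <- NULL
  Tm <- if (return_t) matrix(NA_real_, J, V) else NULL
  all_exact <- TRUE
  for (j in seq_len(J)) {
    shj <- subset_shuffles(shuffles, j)
    idx <- sort(sample.int(V, v))   # redrawn per rearrangement
    bs <- compute_BSigma(Y, design, strategy, shj, voxels = idx)
    cr <- suppressWarnings(complete_row(bs$B[1, ], bs$Sigma[1, ], idx,
                                        state))
    all_exact <- all_exact && cr$exact
    Trow <- state$kappa * cr$beta / sqrt(pmax(cr$sigma,
                                              .Machine$double.xmin))
    if (j == 1L) {
      T1 <- Trow
      exceed <- rep(0L, V)
    }
    exceed <- exceed + (Trow >= T1)
    maxima[j] <- max(Trow)
    if (return_t) Tm[j, ] <- Trow
  }
  p <- exceed / J
  p_fwer <- vapply(T1, function(tv) mean(maxima >= tv), numeric(1))
  out <- list(p = p, p_fwer = p_fwer, stat = T1, state = state,
              exact = all_exact, maxima = maxima, shuffles = shuffles)
  if (return_t) out$T <- Tm
  out
}
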