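#' Sequential negative-binomial p-value estimation
#'
#' Early-stopping permutation testing: each test runs until a predefined
#' number \code{n} of exceedances of the unpermuted statistic has been
#' observed, at which point the p-value is the negative-binomial estimate
#' \eqn{\hat p = n / j}, where \eqn{j} is the rearrangement at which the
#' n-th exceedance occurred. The unpermuted case counts both as the first
#' rearrangement and as one exceedance of itself (T >= T), so that the
#' estimate reduces to the plain counting p-value when the cap is hit.
#' Tests that never reach \code{n} within \code{J_cap} rearrangements
#' fall back to the counting p-value over the cap.
#'
#' Weak effects are exceeded quickly and stop after a few rearrangements;
#' strong effects consume more. Only still-active tests are recomputed at
#' each step, which is where the acceleration comes from.
#'
#' @param Y N x V response matrix.
#' @param design a \code{\link{make_design}} object.
#' @param stat_name only "t" is supported (spatial statistics cannot be
#'   computed under pointwise early stopping).
#' @param n target number of exceedances (>= 1).
#' @param J_cap fall-back maximum number of rearrangements.
#' @param seed RNG seed for the random (non-lexicographic) shuffles.
#' @param mode,strategy passed to the shuffle machinery.
#' @param block internal batch size for shuffle generation.
#' @return An object of class \code{negbin_scan}: list with \code{p},
#'   \code{j_stop} (rearrangements consumed per test, including the
#'   unpermuted case), \code{exceed}, \code{capped} (logical), \code{n},
#'   \code{J_cap}.
#' @export
negbin_scan <- function(Y, design, stat_name = "t", n = 10, J_cap = 50000,
                        seed = NULL, mode = "ee",
                        strategy = "freedman_lane", block = 512L) {
  if (stat_name != "t")
    stop("negative-binomial early stopping is implemented for t only")
  if (n < 1) stop("n must be >= 1")
  Y <- as.matrix(Y)
  V <- ncol(Y); N <- design$N
  T1 <- t_statistic(Y, design$X, design$Z)$stat
  exceed <- rep(1L, V)      # the unpermuted case exceeds itself
  j_stop <- rep(1L, V)
  active <- exceed < n      # n = 1 stops immediately at j = 1
  j <- 1L
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  while (any(active) && j < J_cap) {
    nb <- min(block, J_cap - j)
    sh <- generate_shuffles(N, nb + 1L, mode)  # row 1 identity, dropped
    idx <- which(active)
    bs <- compute_BSigma(Y, design, strategy, sh, voxels = idx)
    Tb <- bs$kappa * bs$B[-1, , drop = FALSE] /
      sqrt(pmax(bs$Sigma[-1, , drop = FALSE], .Machine$double.xmin))
    exc <- Tb >= matrix(T1[idx], nb, length(idx), byrow = TRUE)
    cum <- apply(exc, 2, cumsum)
    if (nb == 1L) cum <- matrix(cum, 1)
    tot <- exceed[idx] + cum[nb, ]
    reached <- tot >= n
    # first row index at which the running count hits n
    hit <- rep(NA_integer_, length(idx))
    if (any(reached)) {
      need <- n - exceed[idx[reached]]
      hit[reached] <- vapply(seq_along(which(reached)), function(k) {
        which(cum[, which(reached)[k]] >= need[k])[1]
      }, integer(1))
    }
    done <- reached
    exceed[idx[done]] <- n
    j_stop[idx[done]] <- j + hit[done]
    active[idx[done]] <- FALSE
    notdone <- !reached
    exceed[idx[notdone]] <- tot[notdone]
    j_stop[idx[notdone]] <- j + nb
    j <- j + nb
  }
  capped <- j_stop >= J_cap & exceed < n
  j_stop[capped] <- J_cap
  st <- structure(list(exceed = exceed, j_stop = j_stop, capped = capped,
                       n = n, J_cap = J_cap,
                       active = rep(FALSE, V)),
                  class = "negbin_state")
  structure(list(p = negbin_pvalue(st), j_stop = j_stop, exceed = exceed,
                 capped = capped, n = n, J_cap = J_cap, state = st),
            class = "negbin_scan")
}

#' p-value from a stopped negative-binomial state
#'
#' \eqn{\hat p = n/j} when the target exceedance count was reached at
#' rearrangement \eqn{j}; otherwise the counting estimate
#' \code{exceed / J_cap} over the capped run. Querying a still-active
#' test is an error.
#'
#' @param state a \code{negbin_state} (fields \code{exceed},
#'   \code{j_stop}, \code{capped}, \code{n}, \code{J_cap},
#'   \code{active}).
#' @return numeric vector of p-values.
#' @export
negbin_pvalue <- function(state) {
  if (any(state$active))
    stop("cannot compute a p-value for a still-active test")
  p <- state$n / state$j_stop
  p[state$capped] <- state$exceed[state$capped] / state$J_cap
  p
}

#' FWER workaround for the negative binomial
#'
#' Early stopping driven by the image-wise extremum: the statistic is
#' computed image-wide at each rearrangement, and shuffling stops once
#' the extremum across tests has exceeded the unpermuted extremum
#' \code{n} times (ties count as exceedances). The empirical distribution
#' of the maxima collected up to the stop is then used to adjust the
#' p-values of all tests. Note that every test's adjusted p-value hinges
#' on the single most extreme unpermuted test.
#'
#' @inheritParams negbin_scan
#' @return list with \code{p_fwer}, \code{j_stop}, and the collected
#'   \code{maxima} (first element unpermuted).
#' @export
negbin_fwer <- function(Y, design, stat_name = "t", n = 10, J_cap = 50000,
                        seed = NULL, mode = "ee",
                        strategy = "freedman_lane", block = 512L) {
  if (stat_name != "t")
    stop("negative-binomial FWER workaround is implemented for t only")
  Y <- as.matrix(Y)
  N <- design$N
  T1 <- t_statistic(Y, design$X, design$Z)$stat
  m1 <- max(T1)
  maxima <- m1
  exceed <- 1L; j <- 1L
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  while (exceed < n && j < J_cap) {
    nb <- min(block, J_cap - j)
    sh <- generate_shuffles(N, nb + 1L, mode)
    bs <- compute_BSigma(Y, design, strategy, sh)
    Tb <- bs$kappa * bs$B[-1, , drop = FALSE] /
      sqrt(pmax(bs$Sigma[-1, , drop = FALSE], .Machine$double.xmin))
    mx <- apply(Tb, 1, max)
    cum <- cumsum(mx >= m1)
    if (exceed + cum[nb] >= n) {
      stop_at <- which(exceed + cum >= n)[1]
      maxima <- c(maxima, mx[seq_len(stop_at)])
      exceed <- n
      j <- j + stop_at
    } else {
      maxima <- c(maxima, mx)
      exceed <- exceed + cum[nb]
      j <- j + nb
    }
  }
  p_fwer <- vapply(T1, function(tv) mean(maxima >= tv), numeric(1))
  list(p_fwer = p_fwer, j_stop = j, maxima = maxima)
}
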