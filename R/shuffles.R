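#' Generate a set of rearrangements (permutations and/or sign flips)
#'
#' Builds the shuffle set used by all permutation machinery: permutations
#' of observation indices (for exchangeable errors, EE), sign flips (for
#' independent symmetric errors, ISE), or both combined. The first row is
#' always the identity rearrangement, corresponding to the unpermuted
#' data.
#'
#' Random rearrangements are drawn independently, so duplicates are
#' possible; exhaustive enumeration is selected automatically when the
#' number of unique rearrangements does not exceed the request.
#'
#' @param N number of observations.
#' @param J number of rearrangements (including the identity).
#' @param mode "ee" (permutations), "ise" (sign flips), or "both".
#' @param seed optional integer seed (local to this call).
#' @param exhaustive if TRUE, enumerate all unique rearrangements; J is
#'   then ignored (an error is raised if J was requested larger than the
#'   number available, \code{J_max}).
#' @param max_exhaustive safety cap on enumerable rearrangements.
#' @return An object of class \code{shuffle_set}: list with integer
#'   matrix \code{perms} (J x N), numeric matrix \code{signs} (J x N,
#'   entries +/-1), \code{mode}, \code{J}, \code{J_max},
#'   \code{exhaustive}, \code{seed}.
#' @examples
#' generate_shuffles(3, J = 6, mode = "ee", exhaustive = TRUE)$J  # 3! = 6
#' @export
generate_shuffles <- function(N, J, mode = c("ee", "ise", "both"),
                              seed = NULL, exhaustive = FALSE,
                              max_exhaustive = 1e5) {
  mode <- match.arg(mode)
  jmax_perm <- factorial(N)
  jmax_sign <- 2^N
  J_max <- switch(mode, ee = jmax_perm, ise = jmax_sign,
                  both = jmax_perm * jmax_sign)
  if (!exhaustive && J_max <= J && J_max <= max_exhaustive) {
    exhaustive <- TRUE
    J <- J_max        # auto-selected enumeration: all unique rearrangements
  }
  if (exhaustive) {
    if (J_max > max_exhaustive)
      stop("exhaustive enumeration of ", J_max, " rearrangements exceeds cap")
    if (J > J_max)
      stop("J = ", J, " exceeds the number of unique rearrangements (",
           J_max, ")")
    perms1 <- if (mode %in% c("ee", "both")) all_perms(N) else
      matrix(seq_len(N), 1)
    signs1 <- if (mode %in% c("ise", "both")) all_signs(N) else
      matrix(1, 1, N)
    idx <- expand.grid(s = seq_len(nrow(signs1)), p = seq_len(nrow(perms1)))
    perms <- perms1[idx$p, , drop = FALSE]
    signs <- signs1[idx$s, , drop = FALSE]
    J <- nrow(perms)
    # move identity to row 1
    id <- which(apply(perms, 1, function(r) all(r == seq_len(N))) &
                apply(signs, 1, function(r) all(r == 1)))[1]
    if (id != 1L) {
      perms[c(1L, id), ] <- perms[c(id, 1L), ]
      signs[c(1L, id), ] <- signs[c(id, 1L), ]
    }
  } else {
    if (J > J_max) {
      warning("J truncated to the number of unique rearrangements (",
              J_max, ")")
      J <- J_max
    }
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    perms <- matrix(rep(seq_len(N), each = J), J, N)
    signs <- matrix(1, J, N)
    if (J > 1) {
      if (mode %in% c("ee", "both"))
        perms[-1, ] <- t(replicate(J - 1, sample.int(N)))
      if (mode %in% c("ise", "both"))
        signs[-1, ] <- matrix(sample(c(-1, 1), (J - 1) * N, replace = TRUE),
                              J - 1, N)
    }
  }
  structure(list(perms = perms, signs = signs, mode = mode, J = J,
                 J_max = J_max, exhaustive = exhaustive, seed = seed),
            class = "shuffle_set")
}

all_perms <- function(N) {
  if (N == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(N - 1L)
  out <- vector("list", N)
  for (pos in seq_len(N)) {
    m <- cbind(sub, N)
    if (pos < N) {
      tmp <- m[, pos]
      m[, pos] <- N
      m[, ncol(m)] <- tmp
    }
    out[[pos]] <- m
  }
  res <- do.call(rbind, out)
  storage.mode(res) <- "integer"
  dimnames(res) <- NULL
  res
}

all_signs <- function(N) {
  g <- as.matrix(expand.grid(rep(list(c(1, -1)), N)))
  dimnames(g) <- NULL
  # identity (all +1) first
  g[order(rowSums(g == -1)), , drop = FALSE]
}

#' @export
print.shuffle_set <- function(x, ...) {
  cat("Shuffle set:", x$J, "rearrangements of", ncol(x$perms),
      "observations (mode ", x$mode,
      if (x$exhaustive) ", exhaustive" else "", ")\n", sep = "")
  invisible(x)
}
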