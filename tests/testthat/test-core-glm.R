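test_that("partitioning is orthogonal and preserves the contrast test", {
  set.seed(101)
  for (rep in 1:5) {
    N <- 10
    M <- cbind(rnorm(N), rnorm(N), 1)
    C <- c(1, 0, 0)
    d <- make_design(M, C)
    expect_lt(max(abs(crossprod(d$X, d$Z))), 1e-10)
    Y <- matrix(rnorm(N * 4), N)
    t_part <- t_statistic(Y, d$X, d$Z)$stat
    t_ref <- oracle_t(Y, M, C)
    expect_lt(max(abs(t_part - t_ref)) / max(abs(t_ref)), 1e-10)
  }
})

test_that("identity design with a one-column contrast partitions trivially", {
  M <- diag(2)
  pm <- partition_model(M, c(1, 0))
  expect_equal(drop(crossprod(pm$X, pm$Z)), 0)
  expect_equal(ncol(pm$Z), 1)
})

test_that("a full contrast leaves no nuisance space", {
  set.seed(5)
  M <- cbind(rnorm(8), 1)
  pm <- partition_model(M, diag(2))
  expect_equal(ncol(pm$Z), 0)
  # X spans M's column space
  expect_lt(max(abs(M - pm$X %*% permaccel:::pinv(pm$X) %*% M)), 1e-10)
})

test_that("rank-deficient designs or contrasts are refused", {
  M <- cbind(1:6, 2 * (1:6))
  expect_error(make_design(M, c(1, 0)), "rank deficient")
  M2 <- cbind(rnorm(6), 1)
  expect_error(make_design(M2, matrix(c(1, 0, 2, 0), 2)), "full rank")
})

test_that("t statistic matches the closed-form oracle and handles edges", {
  set.seed(7)
  N <- 12
  M <- cbind(rnorm(N), rnorm(N), 1)
  d <- make_design(M, c(1, 0, 0))
  Y <- matrix(rnorm(N * 6), N)
  expect_lt(max(abs(t_statistic(Y, d$X, d$Z)$stat -
                    oracle_t(Y, M, c(1, 0, 0)))), 1e-10)
  # all-zero data
  expect_equal(t_statistic(matrix(0, N, 1), d$X, d$Z)$stat, 0)
  # exact fit: signed infinity with warning
  X1 <- matrix(rnorm(N), N)
  expect_warning(r <- t_statistic(3 * X1, X1, matrix(0, N, 0)),
                 "zero residual")
  expect_equal(r$stat, Inf)
})

test_that("Pillai's trace: both formulas agree, bounds hold, edges work", {
  set.seed(11)
  N <- 8
  M <- cbind(rnorm(N), 1)
  d <- make_design(M, c(1, 0))
  Y <- matrix(rnorm(N * 3), N)
  r <- pillai_trace(Y, d$X, d$Z)
  # independent computation of the first formula
  Yt <- permaccel:::residualize(Y, d$Z)
  Hx <- d$X %*% permaccel:::pinv(d$X)
  f1 <- sum(diag(t(Yt) %*% Hx %*% Yt %*% permaccel:::pinv(crossprod(Yt))))
  expect_equal(r$stat, f1, tolerance = 1e-10)
  expect_gte(r$stat, 0)
  expect_lte(r$stat, min(ncol(d$X), ncol(Y)) + 1e-12)
  # orthogonal response: T = 0
  Yo <- matrix(d$Z[, 1], N)  # in the nuisance space
  expect_warning(r0 <- pillai_trace(Yo, d$X, d$Z), "degenerate")
  expect_equal(r0$stat, 0)
  # perfect fit: K = 1, Y = X, intercept-only nuisance: T = 1
  r1 <- pillai_trace(d$X, d$X, matrix(1, N, 1))
  expect_equal(r1$stat, 1, tolerance = 1e-10)
})

test_that("signed sqrt of Pillai equals the partial correlation (S=K=1)", {
  set.seed(13)
  N <- 15
  M <- cbind(rnorm(N), rnorm(N), 1)
  d <- make_design(M, c(1, 0, 0))
  y <- matrix(rnorm(N), N)
  r <- pillai_trace(y, d$X, d$Z)
  yt <- permaccel:::residualize(y, d$Z)
  xt <- d$X  # already orthogonal to Z
  pc <- cor(yt, xt)
  expect_equal(r$beta_sign * sqrt(r$stat), drop(pc), tolerance = 1e-10)
})

test_that("Wilks' lambda lies in (0,1] and is 1 without any effect", {
  set.seed(17)
  N <- 10
  M <- cbind(rnorm(N), 1)
  d <- make_design(M, c(1, 0))
  Y <- matrix(rnorm(N * 2), N)
  lam <- wilks_lambda(Y, d$X, d$Z)$stat
  expect_gt(lam, 0); expect_lte(lam, 1)
  # response orthogonal to X after nuisance removal -> lambda = 1
  Yn <- permaccel:::residualize(Y, cbind(d$X, d$Z))
  expect_equal(wilks_lambda(Yn, d$X, d$Z)$stat, 1, tolerance = 1e-10)
})

test_that("Pillai and t are permutationally equivalent for S = K = 1", {
  set.seed(19)
  N <- 9
  M <- cbind(rnorm(N), 1)
  d <- make_design(M, c(1, 0))
  y <- matrix(rnorm(N), N)
  sh <- generate_shuffles(N, 60, "ee", seed = 3)
  tt <- run_shuffled_glm(y, d, "t", "manly", sh)$stats[, 1]
  pt <- vapply(seq_len(sh$J), function(j) {
    ys <- y[sh$perms[j, ], , drop = FALSE]
    r <- pillai_trace(ys, d$X, d$Z)
    r$beta_sign * sqrt(r$stat)
  }, numeric(1))
  expect_equal(order(tt), order(pt))
})

test_that("npc_combine follows Tippett and Fisher conventions", {
  expect_equal(npc_combine(c(1, 1, 1), "fisher")$stat, 0)
  expect_equal(npc_combine(c(0.2, 0.05, 0.9), "tippett")$stat, 0.05)
  expect_equal(npc_combine(c(0.1, 0.5), "fisher")$stat,
               -2 * (log(0.1) + log(0.5)))
  expect_error(npc_combine(c(0, 0.5), "fisher"), "p_floor")
  expect_warning(r <- npc_combine(c(0, 0.5), "fisher", p_floor = 0.01),
                 "clamped")
  expect_equal(r$stat, -2 * (log(0.01) + log(0.5)))
  expect_error(npc_combine(c(0.5, 1.2)), "must be in")
})

test_that("NPC p-values are uniform on the attainable grid under the null", {
  set.seed(23)
  N <- 5
  sh <- generate_shuffles(N, 120, "ee", exhaustive = TRUE)
  nrep <- 150
  pvals <- numeric(nrep)
  for (r in seq_len(nrep)) {
    des <- rand_design(N)
    d <- make_design(des$M, des$C)
    Ys <- list(matrix(rnorm(N), N), matrix(rnorm(N), N))
    pvals[r] <- npc_test(Ys, d, "fisher", shuffles = sh)$p
  }
  # exactness: P(p <= alpha) ~= alpha at attainable levels
  for (al in c(0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(pvals <= al) - al), 4 * sqrt(al * (1 - al) / nrep))
  }
})

test_that("uncorrected p-values agree between (M,C) and (X,Z) forms", {
  set.seed(29)
  N <- 10
  M <- cbind(rnorm(N), rnorm(N), 1)
  C <- c(1, 0, 0)
  d <- make_design(M, C)
  Y <- matrix(rnorm(N * 8), N)
  sh <- generate_shuffles(N, 100, "ee", seed = 9)
  p_part <- counting_pvalue(run_shuffled_glm(Y, d, "t", "manly", sh))
  # same shuffles, statistic recomputed from the original (M, C) form
  stats <- t(vapply(seq_len(sh$J), function(j)
    oracle_t(Y[sh$perms[j, ], ], M, C), numeric(ncol(Y))))
  p_orig <- colMeans(stats >= matrix(stats[1, ], sh$J, ncol(Y),
                                     byrow = TRUE))
  expect_equal(p_part, p_orig)
})
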