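test_that("shuffle counts match the combinatorics", {
  expect_equal(generate_shuffles(3, 6, "ee", exhaustive = TRUE)$J, 6)
  expect_equal(generate_shuffles(3, 8, "ise", exhaustive = TRUE)$J, 8)
  expect_equal(generate_shuffles(2, 8, "both", exhaustive = TRUE)$J, 8)
})

test_that("the first rearrangement is always the identity", {
  for (mode in c("ee", "ise", "both")) {
    sh <- generate_shuffles(6, 20, mode, seed = 1)
    expect_equal(sh$perms[1, ], 1:6)
    expect_equal(sh$signs[1, ], rep(1, 6))
    she <- generate_shuffles(3, 1, mode, exhaustive = TRUE)
    expect_equal(she$perms[1, ], 1:3)
    expect_equal(she$signs[1, ], rep(1, 3))
  }
})

test_that("every row is a valid signed permutation", {
  sh <- generate_shuffles(7, 50, "both", seed = 2)
  expect_true(all(apply(sh$perms, 1, function(r) all(sort(r) == 1:7))))
  expect_true(all(sh$signs %in% c(-1, 1)))
})

test_that("J beyond the unique count errors (exhaustive) or truncates", {
  expect_error(generate_shuffles(3, 10, "ee", exhaustive = TRUE),
               "exceeds the number of unique")
  # J_max small enough that enumeration kicks in automatically instead
  sh <- generate_shuffles(3, 10, "ee")
  expect_true(sh$exhaustive)
  expect_equal(sh$J, 6)
})

test_that("identical seed and configuration reproduce bit-identically", {
  a <- generate_shuffles(10, 40, "both", seed = 7)
  b <- generate_shuffles(10, 40, "both", seed = 7)
  expect_identical(a, b)
  des <- rand_design(10, seed = 3)
  d <- make_design(des$M, des$C)
  Y <- matrix(rnorm(10 * 5), 10)
  expect_identical(run_shuffled_glm(Y, d, "t", "freedman_lane", a)$stats,
                   run_shuffled_glm(Y, d, "t", "freedman_lane", b)$stats)
})

test_that("counting p-values follow the inclusive-ties definition", {
  fake <- structure(list(stats = matrix(c(3, 1, 2, 2, 0), 5),
                         tail = "upper"), class = "perm_dist")
  expect_equal(counting_pvalue(fake), 1 / 5)
  fake$stats <- matrix(rep(2, 100), 100)
  expect_equal(counting_pvalue(fake), 1)
  fake$stats <- matrix(c(5, sort(rnorm(99))), 100)  # strictly largest
  expect_equal(counting_pvalue(fake), 0.01)
})

test_that("an identity-only shuffle set reproduces the plain statistic", {
  set.seed(31)
  des <- rand_design(9)
  d <- make_design(des$M, des$C)
  Y <- matrix(rnorm(9 * 4), 9)
  sh <- generate_shuffles(9, 1, "ee")
  pd <- run_shuffled_glm(Y, d, "t", "freedman_lane", sh)
  expect_equal(drop(pd$stats), t_statistic(Y, d$X, d$Z)$stat)
  expect_equal(counting_pvalue(pd), rep(1, 4))
})

test_that("exhaustive null p-values are uniform on the attainable grid", {
  set.seed(37)
  N <- 5
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  sh <- generate_shuffles(N, 120, "ee", exhaustive = TRUE)
  Y <- matrix(rnorm(N * 400), N)
  p <- counting_pvalue(run_shuffled_glm(Y, d, "t", "freedman_lane", sh))
  expect_true(all(p >= 1 / 120 & p <= 1))
  # P(p <= alpha) = alpha at attainable alpha, within Monte Carlo error
  for (al in c(10 / 120, 30 / 120, 60 / 120)) {
    se <- sqrt(al * (1 - al) / 400)
    expect_lt(abs(mean(p <= al) - al), 4 * se)
  }
})

test_that("Freedman-Lane equals Manly when the nuisance is an intercept", {
  set.seed(41)
  N <- 10
  M <- cbind(rnorm(N), 1)
  d <- make_design(M, c(1, 0))
  Y <- matrix(rnorm(N * 6), N)
  sh <- generate_shuffles(N, 200, "ee", seed = 11)
  p_fl <- counting_pvalue(run_shuffled_glm(Y, d, "t", "freedman_lane", sh))
  p_ma <- counting_pvalue(run_shuffled_glm(Y, d, "t", "manly", sh))
  expect_equal(p_fl, p_ma)
})

test_that("unsupported strategies are rejected with the available list", {
  des <- rand_design(8, seed = 1)
  d <- make_design(des$M, des$C)
  sh <- generate_shuffles(8, 10, "ee", seed = 1)
  expect_error(run_shuffled_glm(matrix(rnorm(8), 8), d, "t",
                                "still_white", sh))
  expect_error(run_shuffled_glm(matrix(rnorm(8), 8), d, "tfce",
                                shuffles = sh), "unsupported statistic")
})

test_that("sign flipping gives exact inference for symmetric errors", {
  set.seed(43)
  N <- 7
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  sh <- generate_shuffles(N, 2^N, "ise", exhaustive = TRUE)
  Y <- matrix(rnorm(N * 300), N)
  p <- counting_pvalue(run_shuffled_glm(Y, d, "t", "freedman_lane", sh))
  al <- 0.1
  expect_lt(abs(mean(p <= al) - al), 4 * sqrt(al * (1 - al) / 300))
})
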