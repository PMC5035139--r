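test_that("moment estimators of the GPD match hand substitution", {
  # ybar = 2, s^2 = 1 ((n-1) denominator) -> xi = 1.5, sigma = 5
  f <- fit_gpd_moments(c(1, 2, 3))
  expect_equal(f$xi, 1.5)
  expect_equal(f$sigma, 5)
  # ybar^2 = s^2 -> exponential-tail limit xi = 0, sigma = ybar
  y <- c(1, 3)  # mean 2, var 2... construct exactly: need ybar^2 = s2
  y <- c(2 - sqrt(2), 2 + sqrt(2))  # mean 2, var 4 = ybar^2
  f0 <- fit_gpd_moments(y)
  expect_equal(f0$xi, 0)
  expect_equal(f0$sigma, 2)
  expect_error(fit_gpd_moments(c(1, 1, 1)), "zero variance")
  expect_error(fit_gpd_moments(2), "at least two")
})

test_that("moment estimators recover known GPD parameters", {
  set.seed(71)
  y <- rgpd(1e5, sigma = 1, xi = 0.2)
  f <- fit_gpd_moments(y)
  expect_lt(abs(f$sigma - 1), 0.02)
  expect_lt(abs(f$xi - 0.2), 0.02 * 1.5)  # shape is harder; ~2% scale
})

test_that("the GPD survival function honours the support", {
  expect_equal(permaccel:::gpd_sf(0, 1, 0.3), 1)
  # finite endpoint sigma/xi for xi > 0
  expect_equal(permaccel:::gpd_sf(11, 2, 0.2), 0)
  # exponential limit
  expect_equal(permaccel:::gpd_sf(1.3, 1, 0), exp(-1.3))
})

test_that("Anderson-Darling p-values are roughly uniform for true fits", {
  set.seed(73)
  nrep <- 300
  pv <- numeric(nrep)
  for (r in seq_len(nrep)) {
    y <- rgpd(100, 1, 0.1)
    f <- fit_gpd_moments(y)
    pv[r] <- anderson_darling_gof(y, f$sigma, f$xi)$p.value
  }
  expect_lt(abs(mean(pv) - 0.5), 0.07)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.05)
  expect_lt(abs(mean(pv < 0.25) - 0.25), 0.1)
})

test_that("Anderson-Darling rejects grossly misfit (bimodal) data", {
  set.seed(79)
  rej <- vapply(1:60, function(r) {
    y <- c(rnorm(60, 1, 0.05), rnorm(60, 6, 0.05))
    f <- fit_gpd_moments(y)
    anderson_darling_gof(y, f$sigma, f$xi)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("only small p-values are refined; the rest remain unchanged", {
  set.seed(83)
  N <- 16
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  g <- des$M[, 1]
  Y <- cbind(matrix(rnorm(N * 30), N),
             matrix(rnorm(N * 10), N) + 1.2 * g)
  sh <- generate_shuffles(N, 400, "ee", seed = 12)
  dist <- run_shuffled_glm(Y, d, "t", "freedman_lane", sh)
  tp <- tail_pvalues(dist, refine_below = 0.10)
  unref <- tp$p_counting >= 0.10
  expect_equal(tp$p[unref], tp$p_counting[unref])
  # refined tests stay below the gate
  expect_true(all(tp$p[!unref] <= 0.10 + 1e-12))
  # accepted fits recorded with threshold and parameters
  acc <- Filter(function(f) !is.null(f) && f$accepted, tp$fits)
  if (length(acc)) {
    expect_true(all(vapply(acc, function(f) f$n_exceed >= 10, logical(1))))
    expect_true(all(vapply(acc, function(f) f$sigma > 0, logical(1))))
  }
})

test_that("the refined p is continuous at the threshold", {
  # at T = u the GPD survival is 1 and p equals the tail mass at u
  set.seed(89)
  y <- rgpd(200, 1, 0.1)
  f <- fit_gpd_moments(y)
  expect_equal(permaccel:::gpd_sf(0, f$sigma, f$xi), 1)
})

test_that("tail refinement agrees with a large-J counting reference", {
  # signal added to all tests (the evaluation design), so the refine
  # region holds genuinely small p-values rather than selected noise
  set.seed(97)
  N <- 20
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  g <- des$M[, 1]
  V <- 250
  psi1 <- calibrated_effect(des$M, des$C)
  Y <- matrix(rnorm(N * V), N) + psi1 * g
  J_ref <- 6000
  sh_ref <- generate_shuffles(N, J_ref, "ee", seed = 21)
  p_ref <- counting_pvalue(run_shuffled_glm(Y, d, "t", "freedman_lane",
                                            sh_ref))
  sh <- generate_shuffles(N, 500, "ee", seed = 22)
  dist <- run_shuffled_glm(Y, d, "t", "freedman_lane", sh)
  tp <- tail_pvalues(dist)
  # PP comparison: the proportion of refined p-values at or below each
  # refined test's reference p matches the reference proportion within
  # the reference's Wilson interval
  sel <- which(tp$p_counting < 0.10 & p_ref >= 2 / 500)
  agree <- vapply(sel, function(v) {
    ci <- wilson_ci(mean(p_ref <= p_ref[v]), V)
    Fm <- mean(tp$p <= p_ref[v])
    Fm >= ci[1] && Fm <= ci[2]
  }, logical(1))
  expect_gt(mean(agree), 0.9)
})
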