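test_that("FWER correction reduces to the uncorrected p for one test", {
  set.seed(229)
  stats <- matrix(rnorm(200), 200, 1)
  dist <- structure(list(stats = stats, tail = "upper"),
                    class = "perm_dist")
  expect_equal(fwer_pvalues(dist), counting_pvalue(dist))
})

test_that("a test attaining the maximum everywhere keeps its p-value", {
  set.seed(233)
  other <- matrix(rnorm(100 * 3), 100, 3)
  lead <- apply(other, 1, max) + abs(rnorm(100)) + 0.1
  dist <- structure(list(stats = cbind(lead, other), tail = "upper"),
                    class = "perm_dist")
  expect_equal(fwer_pvalues(dist)[1], counting_pvalue(dist)[1])
})

test_that("corrected p-values match brute-force enumeration of maxima", {
  set.seed(239)
  N <- 5
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  Y <- matrix(rnorm(N * 6), N)
  sh <- generate_shuffles(N, 120, "ee", exhaustive = TRUE)
  dist <- run_shuffled_glm(Y, d, "t", "manly", sh)
  # independent enumeration over the same rearrangements
  stats_bf <- t(vapply(seq_len(120), function(j)
    oracle_t(Y[sh$perms[j, ], ], des$M, des$C), numeric(6)))
  mx <- apply(stats_bf, 1, max)
  p_bf <- vapply(stats_bf[1, ], function(tv) mean(mx >= tv),
                 numeric(1))
  expect_equal(fwer_pvalues(dist), p_bf, tolerance = 1e-12)
  # corrected >= uncorrected always
  expect_true(all(fwer_pvalues(dist) >= counting_pvalue(dist) - 1e-15))
})

test_that("tail/gamma extremum fits agree with counting at large J", {
  set.seed(241)
  N <- 18; V <- 150
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  # a gradient of effects so corrected p-values span the whole range
  eff <- seq(0, 1.8, length.out = V)
  Y <- matrix(rnorm(N * V), N) + des$M[, 1] %o% eff
  sh <- generate_shuffles(N, 4000, "ee", seed = 3)
  dist <- run_shuffled_glm(Y, d, "t", "freedman_lane", sh)
  maxd <- apply(dist$stats, 1, max)
  p_count <- fwer_pvalues(dist)
  sel <- p_count < 0.5 & p_count > 2 / 4000
  expect_gt(sum(sel), 5)
  for (meth in c("tail", "gamma")) {
    p_fit <- fwer_tail_or_gamma(maxd, dist$stats[1, ], meth)
    expect_lt(max(abs(p_fit[sel] - p_count[sel])), 0.06)
  }
  # below the extremum distribution's minimum the corrected p is 1
  expect_equal(fwer_tail_or_gamma(maxd, min(maxd) - 5, "tail"), 1)
})

test_that("Benjamini-Hochberg step-up arithmetic and monotonicity", {
  ds <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(ds$reject))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)$reject))
  set.seed(251)
  p <- runif(50)
  adj <- fdr_bh(p, 0.1)$p
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("Wilson intervals reproduce the printed table and shrink with J", {
  expect_equal(round(wilson_ci(0.05, 10000), 4),
               c(lower = 0.0459, upper = 0.0544))
  expect_equal(round(wilson_ci(0.05, 50000), 4),
               c(lower = 0.0481, upper = 0.0519))
  expect_equal(wilson_ci(0, 100)[["lower"]], 0)
  Js <- c(40, 60, 100, 200, 300, 500, 1000, 2000, 5000, 10000, 50000)
  w <- vapply(Js, function(J) diff(wilson_ci(0.05, J)), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("resampling risk is 0 for identical and 1 for opposite decisions", {
  a <- decide(c(0.01, 0.2, 0.6), 0.05)
  expect_equal(resampling_risk(a, a)$risk, 0)
  b <- decide(c(0.9, 0.01, 0.01), 0.05)
  expect_equal(resampling_risk(a, b)$risk, 1)
  expect_error(resampling_risk(a, decide(c(0.1, 0.2), 0.05)),
               "different numbers")
  expect_error(resampling_risk(a, decide(c(0.1, 0.2, 0.3), 0.01)),
               "different significance")
})

test_that("disagreements concentrate where p sits near the level", {
  set.seed(257)
  N <- 12; V <- 200
  des <- rand_design(N)
  d <- make_design(des$M, des$C)
  Y <- matrix(rnorm(N * V), N)
  p1 <- counting_pvalue(run_shuffled_glm(
    Y, d, "t", "freedman_lane", generate_shuffles(N, 100, "ee", seed = 1)))
  p2 <- counting_pvalue(run_shuffled_glm(
    Y, d, "t", "freedman_lane", generate_shuffles(N, 100, "ee", seed = 2)))
  rr <- resampling_risk(decide(p1, 0.05), decide(p2, 0.05))
  near <- abs(p1 - 0.05) < 0.03
  if (any(rr$disagree))
    expect_gt(mean(near[rr$disagree]), mean(near))
})
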