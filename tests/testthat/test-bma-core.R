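test_that("lagged design stacks n = S*(T-1) observations", {
  # arithmetic of the stacking: T=6, S=97 -> n = 485
  expect_equal(97 * (6 - 1), 485)

  ts <- toy_ts(genes = 4, times = 6, reps = 3, seed = 2)
  d <- build_lagged_design(ts, "g1")
  expect_equal(d$n, 3 * 5)
  expect_equal(colnames(d$X), c("g2", "g3", "g4"))
  expect_equal(d$y, as.vector(ts$values[1, 2:6, ]))
  expect_equal(d$X[, "g3"], as.vector(ts$values[3, 1:5, ]))

  tiny <- toy_ts(genes = 4, times = 2, reps = 1, seed = 2)
  d2 <- build_lagged_design(tiny, "g1")
  expect_equal(length(d2$y), 1L)
  expect_equal(dim(d2$X), c(1L, 3L))

  expect_error(build_lagged_design(ts, "nope"), "unknown target")
  expect_error(build_lagged_design(ts, "g1", candidates = c("g2", "zz")),
               "unknown candidate")
})

test_that("model scores are invariant to observation order and column scaling", {
  ts <- toy_ts(genes = 5, times = 6, reps = 4, seed = 14)
  d <- build_lagged_design(ts, "g1")
  key <- c(1L, 3L)
  base <- g_prior_two_log_odds(r_squared(d, key), 2, d$n, 10)
  # permute the stacked observations (t-major vs s-major etc.)
  perm <- sample(d$n)
  dp <- structure(list(y = d$y[perm], X = d$X[perm, , drop = FALSE],
                       n = d$n, candidates = d$candidates),
                  class = "regression_data")
  expect_equal(g_prior_two_log_odds(r_squared(dp, key), 2, d$n, 10), base,
               tolerance = 1e-10)
  # affine rescaling of a selected column leaves R^2 unchanged
  ds <- d; ds$X[, 1] <- 5 * ds$X[, 1] - 2
  expect_equal(g_prior_two_log_odds(r_squared(ds, key), 2, d$n, 10), base,
               tolerance = 1e-10)
})

test_that("R-squared matches a reference OLS fit and handles edge cases", {
  d <- random_regression_data(20, 5, seed = 33, signal = c(1, -2, 0, 0, 0))
  expect_equal(r_squared(d, integer(0)), 0)
  key <- c(1L, 2L, 4L)
  ref <- summary(lm(d$y ~ d$X[, key]))$r.squared
  expect_equal(r_squared(d, key), ref, tolerance = 1e-10)

  # perfect fit clamps just below 1
  dp <- d; dp$y <- 3 * dp$X[, 2] - 1
  expect_equal(r_squared(dp, 2L), 1 - 1e-12)

  # duplicated (collinear) columns are handled via the pivoted QR
  dc <- d; dc$X[, 3] <- dc$X[, 1]
  expect_equal(r_squared(dc, c(1L, 3L)), r_squared(d, 1L), tolerance = 1e-10)

  # zero-variance response
  dz <- d; dz$y <- rep(2, d$n)
  expect_warning(rz <- r_squared(dz, 1L), "zero-variance")
  expect_equal(rz, 0)
})

test_that("g-prior score algebra and guards", {
  expect_equal(g_prior_two_log_odds(0, 0, 10, 3, 0), 0)
  # n=10, d=2, g=3, r2=0, flat priors: (10-2-1)log4 - 9 log4 = -2 log 4
  expect_equal(g_prior_two_log_odds(0, 2, 10, 3, 0), -2 * log(4),
               tolerance = 1e-12)
  expect_error(g_prior_two_log_odds(0.5, 1, 10, -1), "g must be")
  expect_error(g_prior_two_log_odds(1, 1, 10, 3), "r2 must be")
  expect_error(g_prior_two_log_odds(0.5, 9, 10, 3), "n >= d \\+ 2")
  # flat pi = 0.5 gives exactly zero prior log-odds
  expect_identical(2 * sum(log(0.5 / 0.5)), 0)
})

test_that("g-prior score matches the numerically integrated marginal-likelihood ratio", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(5:8, 1L)
    d <- sample(1:2, 1L)
    dat <- random_regression_data(n, d, seed = 500 + i, signal = rnorm(d))
    g <- runif(1, 1, n)
    pl <- rnorm(d, sd = 0.5)               # nontrivial prior log-odds
    key <- seq_len(d)
    imp <- g_prior_two_log_odds(r_squared(dat, key), d, n, g, 2 * sum(pl[key]))
    ora <- oracle_two_log_odds(dat, key, g, pl)
    expect_equal(imp, ora, tolerance = 1e-6)
  }
})

test_that("BIC score algebra matches the direct BIC-difference oracle", {
  expect_equal(bic_two_log_odds(0, 0, 100, 0), 0)
  expect_equal(bic_two_log_odds(0, 1, 100, 0), -log(100), tolerance = 1e-12)

  d <- random_regression_data(25, 4, seed = 9, signal = c(2, 0, 0, 1))
  key <- c(1L, 4L)
  r2 <- r_squared(d, key)
  # oracle: BIC_0 - BIC_k from residual sums of squares directly
  rss0 <- sum((d$y - mean(d$y))^2)
  rssk <- sum(resid(lm(d$y ~ d$X[, key]))^2)
  oracle <- (d$n * log(rss0 / d$n) + 1 * log(d$n)) -
            (d$n * log(rssk / d$n) + 3 * log(d$n))
  expect_equal(bic_two_log_odds(r2, 2, d$n, 0), oracle, tolerance = 1e-8)
})

test_that("unit information prior (g = n) tracks BIC rankings", {
  d <- random_regression_data(30, 6, seed = 41, signal = c(1.5, -1, 0, 0, 0.5, 0))
  keys <- list(integer(0), 1L, c(1L, 2L), c(1L, 2L, 5L), 3L, c(3L, 4L), c(1L, 5L))
  gp <- vapply(keys, function(k)
    g_prior_two_log_odds(r_squared(d, k), length(k), d$n, d$n), numeric(1))
  bic <- vapply(keys, function(k)
    bic_two_log_odds(r_squared(d, k), length(k), d$n), numeric(1))
  # score differences stay bounded while the scores themselves span >> that
  expect_lt(max(abs(gp - bic)), 10)
  expect_gt(diff(range(gp)), 3 * max(abs(gp - bic)))
  # identical rankings on models separated by gaps > 2
  sep <- which(vapply(seq_along(gp), function(i)
    all(abs(gp[i] - gp[-i]) > 2), logical(1)))
  expect_identical(order(gp[sep]), order(bic[sep]))
  expect_identical(which.max(gp), which.max(bic))
})

test_that("model weights normalise with a numerically stable softmax", {
  expect_equal(model_weights(c(5, 5)), c(0.5, 0.5))
  # score gap of 2 log 100 is a posterior ratio of 100 (the Occam factor)
  expect_equal(model_weights(c(0, 2 * log(100))), c(1 / 101, 100 / 101),
               tolerance = 1e-12)
  w <- model_weights(rnorm(50, sd = 300))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
})

test_that("inclusion probabilities equal the brute-force weighted sums", {
  keys <- list(c(1L, 3L))
  expect_equal(inclusion_probabilities(keys, 1, 4), c(1, 0, 1, 0))
  expect_equal(inclusion_probabilities(list(1L, 2L), c(0.7, 0.3), 3),
               c(0.7, 0.3, 0))

  # all 2^4 models on a toy instance vs direct enumeration
  d <- random_regression_data(15, 4, seed = 88, signal = c(2, 0, -1, 0))
  keys <- list(integer(0))
  for (sz in 1:4)
    keys <- c(keys, lapply(asplit(combn(4, sz), 2), as.integer))
  sc <- vapply(keys, function(k)
    g_prior_two_log_odds(r_squared(d, k), length(k), d$n, d$n), numeric(1))
  w <- model_weights(sc)
  got <- inclusion_probabilities(keys, w, 4)
  want <- vapply(1:4, function(h)
    sum(w[vapply(keys, function(k) h %in% k, logical(1))]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})
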