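test_that("prescreen ranks candidates by single-model score with stated tie-breaks", {
  ts <- toy_ts(genes = 6, times = 6, reps = 3, seed = 17)
  d <- build_lagged_design(ts, "g1")
  # nvar = p returns all candidates (order only)
  expect_setequal(prescreen(d, NULL, "g1", "all"), d$candidates)
  expect_setequal(prescreen(d, NULL, "g1", 99), d$candidates)

  # a candidate equal to y plus tiny noise ranks first under flat priors
  dd <- d
  set.seed(1)
  dd$X[, "g4"] <- dd$y + rnorm(d$n, sd = 1e-4)
  expect_identical(prescreen(dd, NULL, "g1", 3)[1L], "g4")

  # matches brute-force single-model scoring on a larger instance
  d30 <- random_regression_data(25, 30, seed = 55, signal = rep(0, 30))
  g <- d30$n
  sc <- vapply(1:30, function(j)
    g_prior_two_log_odds(r_squared(d30, j), 1, d30$n, g), numeric(1))
  want <- d30$candidates[order(-sc, d30$candidates)][1:12]
  expect_identical(prescreen(d30, NULL, "y", 12, g = g), want)
})

test_that("prescreen breaks score ties by higher prior probability", {
  # two identical candidate columns: identical R^2; prior decides
  n <- 12
  set.seed(3)
  x <- rnorm(n)
  d <- structure(list(y = rnorm(n), X = cbind(a = x, b = x), n = n,
                      candidates = c("a", "b")), class = "regression_data")
  pm <- prior_matrix(matrix(c(0.2, 0.6), 2, 1,
                            dimnames = list(c("a", "b"), "tgt")))
  expect_identical(prescreen(d, pm, "tgt", 2)[1L], "b")
})

test_that("scan recovers the exact Occam's window of exhaustive enumeration", {
  opts <- scan_options(occam_c = 100, nvar = "all")
  for (seed in c(101, 202, 303, 404, 505)) {
    set.seed(seed)
    p <- sample(6:10, 1L)
    beta <- ifelse(runif(p) < 0.3, rnorm(p, sd = 1), 0)
    d <- random_regression_data(30, p, seed = seed, signal = beta)
    pl <- rnorm(p, sd = 0.3)
    g <- d$n
    win <- scan_models(d, pl, g, opts)
    ora <- enumerate_window(d, pl, g, 100)
    expect_identical(scan_ids(win), ora$ids)
    # and every returned score is within the window of the best
    expect_true(all(win$scores >= max(win$scores) - 2 * log(100)))
  }
})

test_that("scan handles degenerate and near-degenerate model spaces", {
  # p = 1, single model far better than null: null is discarded
  n <- 40
  set.seed(10)
  x <- rnorm(n)
  d <- structure(list(y = 5 * x + rnorm(n, sd = 0.1), X = cbind(a = x),
                      n = n, candidates = "a"), class = "regression_data")
  win <- scan_models(d, 0, n, scan_options())
  expect_equal(length(win$keys), 1L)
  expect_identical(win$keys[[1L]], 1L)

  # C -> 1+ keeps only models tied with the best
  d2 <- random_regression_data(30, 5, seed = 77, signal = c(3, 0, 0, 0, 0))
  win2 <- scan_models(d2, numeric(5), d2$n, scan_options(occam_c = 1 + 1e-9))
  expect_true(all(win2$scores >= max(win2$scores) - 2 * log(1 + 1e-9)))
  expect_equal(length(win2$keys), 1L)
})

test_that("enlarging the window never shrinks the returned model set", {
  d <- random_regression_data(30, 8, seed = 99, signal = c(1, -1, rep(0, 6)))
  ids_prev <- character(0)
  for (C in c(5, 20, 100, 1000)) {
    win <- scan_models(d, numeric(8), d$n, scan_options(occam_c = C))
    ids <- scan_ids(win)
    expect_true(all(ids_prev %in% ids))
    ids_prev <- ids
  }
})

test_that("scan is deterministic", {
  d <- random_regression_data(30, 7, seed = 123, signal = c(0, 2, 0, -1, 0, 0, 0))
  a <- scan_models(d, numeric(7), d$n, scan_options())
  b <- scan_models(d, numeric(7), d$n, scan_options())
  expect_identical(a, b)
})

test_that("refinement reproduces the two-model odds formulas", {
  d <- random_regression_data(25, 4, seed = 31, signal = c(2.5, 1.5, 0, 0))
  opts <- scan_options(nvar = "all")
  g <- d$n
  cache <- new.env(parent = emptyenv())
  win <- scan_models(d, numeric(4), g, opts, cache)
  w <- model_weights(win$scores)
  raw <- inclusion_probabilities(win$keys, w, 4)
  ref <- refine_inclusion(win, raw, d, numeric(4), g, opts, cache)
  expect_true(all(ref > 0 & ref < 1))

  best_key <- win$keys[[1L]]
  best_score <- win$scores[[1L]]
  score_of <- function(k)
    g_prior_two_log_odds(r_squared(d, k), length(k), d$n, g)
  for (h in 1:4) {
    if (raw[h] >= 1 - 1e-9) {
      O <- exp((best_score - score_of(setdiff(best_key, h))) / 2)
      expect_equal(ref[h], min(O / (1 + O), 1 - 1e-12), tolerance = 1e-10)
    } else if (raw[h] <= 1e-9) {
      O <- exp((best_score - score_of(sort(c(best_key, h)))) / 2)
      expect_equal(ref[h], max(1 / (1 + O), 1e-12), tolerance = 1e-10)
    } else {
      expect_equal(ref[h], raw[h], tolerance = 1e-12)
    }
  }
})

test_that("refinement algebra on constructed score gaps", {
  # equal scores -> O = 1 -> refined 0.5; gap of 2 log 99 -> 1/(1+99)
  O1 <- exp(0 / 2)
  expect_equal(O1 / (1 + O1), 0.5)
  O2 <- exp(2 * log(99) / 2)
  expect_equal(1 / (1 + O2), 0.01, tolerance = 1e-12)
})

test_that("refinement preserves ranking within each extreme group", {
  # several strong regulators all at raw probability 1, several at 0
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("c%d", 1:6)))
  y <- 0.7 * X[, 1] + 0.55 * X[, 2] + 0.45 * X[, 3] + rnorm(n, sd = 0.5)
  d <- structure(list(y = y, X = X, n = n, candidates = colnames(X)),
                 class = "regression_data")
  opts <- scan_options(nvar = "all")
  cache <- new.env(parent = emptyenv())
  win <- scan_models(d, numeric(6), d$n, opts, cache)
  w <- model_weights(win$scores)
  raw <- inclusion_probabilities(win$keys, w, 6)
  ref <- refine_inclusion(win, raw, d, numeric(6), d$n, opts, cache)
  ones <- which(raw >= 1 - 1e-9)
  if (length(ones) >= 2) {
    # stronger regulator (bigger score drop when removed) ranks higher
    best_key <- win$keys[[1L]]
    drop_gap <- vapply(ones, function(h) {
      alt <- setdiff(best_key, h)
      win$scores[[1L]] -
        g_prior_two_log_odds(r_squared(d, alt), length(alt), d$n, d$n)
    }, numeric(1))
    expect_identical(order(ref[ones]), order(drop_gap))
  }
  expect_true(all(ref > 0 & ref < 1))
})

test_that("fit_target orchestrates prescreen, EM and refinement deterministically", {
  dat <- simulate_dataset(sim_config(genes = 6, times = 10, replicates = 3,
                                     coef_scale = 0.5, self_ar = 0.3,
                                     noise_sd = 0.1, seed = 62))
  tts <- transform_pipeline(dat$ts)
  res <- fit_target(tts, "G01", NULL, scan_options(nvar = "all"))
  expect_s3_class(res, "bma_result")
  expect_true(all(res$refined_inclusion > 0 & res$refined_inclusion < 1))
  expect_true(res$g >= 1 && res$g <= 3 * 9)
  # determinism
  res2 <- fit_target(tts, "G01", NULL, scan_options(nvar = "all"))
  expect_identical(res$refined_inclusion, res2$refined_inclusion)
  expect_identical(res$g, res2$g)
  # nvar larger than p is a no-op relative to nvar = "all"
  res3 <- fit_target(tts, "G01", NULL, scan_options(nvar = 100))
  expect_identical(res$refined_inclusion, res3$refined_inclusion)

  # a strong parent gets the top refined probability (effect >> noise)
  parents <- dat$network$edges$regulator[dat$network$edges$target == "G01"]
  if (length(parents)) {
    top <- names(which.max(res$refined_inclusion))
    expect_true(top %in% parents)
  }
})

test_that("zero-variance response yields no confident regulators", {
  v <- array(0, c(3, 6, 2))
  set.seed(5)
  v[2, , ] <- rnorm(12); v[3, , ] <- rnorm(12)
  ts <- expression_ts(v, c("flat", "a", "b"), 1:6, c("r1", "r2"))
  res <- suppressWarnings(fit_target(ts, "flat", NULL, scan_options(nvar = "all")))
  expect_true(all(res$refined_inclusion < 0.5))
  expect_equal(length(res$window$keys[[1L]]), 0L)   # null model is best
})
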