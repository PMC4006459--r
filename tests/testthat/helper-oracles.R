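# Independent oracles used across the test suite.  None of these reuse the
# package's closed-form score path: marginal likelihoods are computed by
# numerical integration, window sets by exhaustive enumeration, and curve
# areas by brute-force pair counting.

# ---- Gauss-Hermite nodes/weights via Golub-Welsch (weight exp(-x^2)) ----
gauss_hermite <- function(m) {
  i <- seq_len(m - 1L)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log marginal likelihood of y under a linear model with intercept (flat
# prior), optional regressors X carrying a Zellner g-prior on the centred
# columns, and p(sigma^2) ~ 1/sigma^2, computed by numerical integration:
# Gauss-Hermite over (intercept, beta) at each node of a trapezoid grid in
# log(sigma^2).  The improper-prior constant is shared between models and
# cancels in ratios.
log_marginal_quadrature <- function(y, X = NULL, g = NULL,
                                    gh_order = 30L, n_u = 160L, u_half = 15) {
  n <- length(y)
  d <- if (is.null(X)) 0L else ncol(X)
  if (d > 0L) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    XtX <- crossprod(Xc)
    W <- cbind(1, Xc)
    D <- rbind(0, cbind(0, XtX / g))        # prior precision contribution
    ld_prior_cov <- d * log(g) + determinant(solve(XtX), logarithm = TRUE)$modulus
  } else {
    W <- matrix(1, n, 1L)
    D <- matrix(0, 1L, 1L)
    ld_prior_cov <- 0
  }
  m <- d + 1L
  M <- crossprod(W) + D
  mu <- solve(M, crossprod(W, y))
  Qmin <- sum((y - W %*% mu)^2) + as.numeric(t(mu) %*% D %*% mu)
  # quadrature transform: theta = mu + sqrt(2 v) * s * L z, deliberately
  # inflated (s > 1) so the Gauss-Hermite rule does real numerical work
  s <- 1.25
  R <- chol(solve(M))
  L <- t(R)
  ld_L <- sum(log(diag(L)))
  gh <- gauss_hermite(gh_order)
  zg <- as.matrix(do.call(expand.grid, rep(list(gh$nodes), m)))
  lw <- rowSums(log(do.call(expand.grid, rep(list(gh$weights), m))))
  z2 <- rowSums(zg^2)
  # Qtot(theta_z) = Qmin + 2 v s^2 |z|^2 (exact: Qtot has Hessian 2M)
  u0 <- log(max(Qmin, sum((y - mean(y))^2), 1e-8) / n)
  us <- seq(u0 - u_half, u0 + u_half, length.out = n_u)
  du <- us[2L] - us[1L]
  log_I <- vapply(us, function(u) {
    v <- exp(u)
    const <- -(n / 2) * log(2 * pi * v) - (d / 2) * log(2 * pi) -
      0.5 * (ld_prior_cov + d * log(v)) - log(v)
    jac <- (m / 2) * log(2 * v) + m * log(s) + ld_L
    # integrand over z: exp(const - Qmin/(2v) - s^2 z2) * e^{z2} weights
    const - Qmin / (2 * v) + jac + logsumexp(lw + z2 - s^2 * z2)
  }, numeric(1L))
  # outer integral over sigma^2 = e^u (jacobian e^u), trapezoid in u
  logsumexp(log_I + us) + log(du)
}

# 2 log marginal-likelihood ratio of model (columns `key` of data$X) vs the
# null model, plus the model-prior log-odds term
oracle_two_log_odds <- function(data, key, g, prior_lo = numeric(ncol(data$X))) {
  lk <- log_marginal_quadrature(data$y, data$X[, key, drop = FALSE], g)
  l0 <- log_marginal_quadrature(data$y)
  2 * (lk - l0) + 2 * sum(prior_lo[key])
}

# ---- exhaustive Occam's-window enumeration (oracle for scan_models) ----
enumerate_window <- function(data, prior_lo, g, occam_c, score = "gprior",
                             max_d = data$n - 2L) {
  p <- ncol(data$X)
  keys <- list(integer(0))
  for (sz in seq_len(min(p, max_d)))
    keys <- c(keys, lapply(asplit(utils::combn(p, sz), 2L), as.integer))
  scores <- vapply(keys, function(k) {
    r2 <- r_squared(data, k)
    psum <- 2 * sum(prior_lo[k])
    if (score == "bic") bic_two_log_odds(r2, length(k), data$n, psum)
    else g_prior_two_log_odds(r2, length(k), data$n, g, psum)
  }, numeric(1L))
  keep <- scores >= max(scores) - 2 * log(occam_c)
  ids <- vapply(keys[keep], paste, character(1L), collapse = ",")
  list(ids = sort(ids), scores = scores[keep][order(ids)])
}

scan_ids <- function(window) {
  sort(vapply(window$keys, paste, character(1L), collapse = ","))
}

# ---- brute-force Mann-Whitney AUROC over all true x false pairs ----
auroc_bruteforce <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# exact expectation of the step-wise AUPRC under a uniformly random ranking
# of P positives among N items with distinct scores: E[ (1/P) sum_i i/T_i ]
# where T_i, the position of the i-th positive, is negative hypergeometric.
auprc_random_expectation <- function(N, P) {
  # P(T_i = t) = choose(t-1, i-1) choose(N-t, P-i) / choose(N, P)
  tot <- 0
  for (i in seq_len(P)) {
    t <- i:(N - P + i)
    pmf <- exp(lchoose(t - 1, i - 1) + lchoose(N - t, P - i) - lchoose(N, P))
    tot <- tot + sum((i / t) * pmf)
  }
  tot / P
}

# ---- small fixture builders ----
random_regression_data <- function(n, p, seed, signal = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("C%02d", 1:p)))
  y <- if (is.null(signal)) rnorm(n) else as.vector(X %*% signal + rnorm(n))
  structure(list(y = y, X = X, n = n, candidates = colnames(X)),
            class = "regression_data")
}

toy_ts <- function(genes = 3, times = 5, reps = 2, seed = 1) {
  set.seed(seed)
  expression_ts(array(rnorm(genes * times * reps), c(genes, times, reps)),
                sprintf("g%d", seq_len(genes)), seq_len(times),
                sprintf("r%d", seq_len(reps)))
}
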