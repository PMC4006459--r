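#' Expected complete-data objective for the g-prior scale
#'
#' The E-step of the EM algorithm for g treats model membership as missing
#' data; the resulting objective is the posterior-weighted sum of the
#' g-dependent part of each window model's marginal likelihood:
#'
#'   `Q(g) = sum_k w_k [ (n - d_k - 1) log(1 + g) - (n - 1) log(1 + g (1 - R_k^2)) ]`
#'
#' For the null model alone Q is identically 0 (flat in g); for models with
#' R^2 = 0 it is strictly decreasing in g.
#'
#' @param g g-prior scale (> 0).
#' @param r2 vector of window-model R-squared values.
#' @param d vector of window-model sizes.
#' @param weights normalised model weights.
#' @param n observation count.
#' @return Q(g), a scalar.
#' @export
q_function <- function(g, r2, d, weights, n) {
  sum(weights * ((n - d - 1) * log1p(g) - (n - 1) * log1p(g * (1 - r2))))
}

#' Maximise the EM objective for g over [1, n]
#'
#' Bounded scalar optimisation of [q_function] over the recommended range
#' `1 <= g <= n` (no more spread out than the unit information prior, and
#' no tighter than the noise level).  Endpoints are checked explicitly;
#' when Q is flat (e.g. only null-equivalent models in the window) the
#' current g is returned unchanged.
#'
#' @param r2,d,weights,n as in [q_function].
#' @param g_current value returned when Q is flat (default `n`).
#' @return The maximising g in `[1, n]`.
#' @export
maximize_q <- function(r2, d, weights, n, g_current = n) {
  f <- function(g) q_function(g, r2, d, weights, n)
  probe <- vapply(c(1, (1 + n) / 2, n), f, numeric(1L))
  if (diff(range(probe)) < 1e-12 * (1 + max(abs(probe))))
    return(min(max(g_current, 1), n))
  opt <- stats::optimize(f, interval = c(1, n), maximum = TRUE, tol = 1e-8)
  cand_g <- c(1, opt$maximum, n)
  cand_q <- c(probe[1L], opt$objective, probe[3L])
  cand_g[which.max(cand_q)]
}

#' EM estimation of the g-prior scale
#'
#' Alternates (1) an Occam's-window scan at the current g, giving posterior
#' model weights, with (2) maximisation of the expected marginal-likelihood
#' objective over g.  g is initialised at `n` (the unit information prior)
#' and clamped to `[1, n]` every iteration; convergence is declared when
#' `|g' - g| <= 1e-6 * max(1, g)`, with a cap of 100 iterations (a warning
#' is issued and the last state returned if the cap is hit).  The
#' R-squared cache is shared across iterations, so each re-scan only
#' recomputes the cheap g-dependent score terms for previously visited
#' models.
#'
#' @param data a `"regression_data"` object.
#' @param prior_lo per-candidate prior log-odds vector.
#' @param opts a [scan_options] object.
#' @param cache optional shared R-squared cache environment.
#' @param g_init starting value for g (default `n`, the unit information
#'   prior).
#' @return A list with `g`, `window` (final [scan_models] output),
#'   `weights`, `converged`, `iterations`, and `history` (per-iteration
#'   data.frame of g and Q(g)).
#' @export
em_loop <- function(data, prior_lo, opts = scan_options(),
                    cache = new.env(parent = emptyenv()), g_init = NULL) {
  n <- data$n
  g <- if (is.null(g_init)) n else min(max(g_init, 1), n)
  hist_g <- numeric()
  hist_q <- numeric()
  converged <- FALSE
  it <- 0L
  window <- NULL
  w <- NULL
  repeat {
    it <- it + 1L
    window <- scan_models(data, prior_lo, g, opts, cache = cache)
    w <- model_weights(window$scores)
    g_new <- maximize_q(window$r2, window$d, w, n, g_current = g)
    g_new <- min(max(g_new, 1), n)
    hist_g <- c(hist_g, g_new)
    hist_q <- c(hist_q, q_function(g_new, window$r2, window$d, w, n))
    if (abs(g_new - g) <= 1e-6 * max(1, g)) {
      g <- g_new
      converged <- TRUE
      break
    }
    g <- g_new
    if (it >= 100L) {
      warning("EM for g did not converge within 100 iterations")
      break
    }
  }
  # final state at the converged g
  window <- scan_models(data, prior_lo, g, opts, cache = cache)
  w <- model_weights(window$scores)
  list(g = g, window = window, weights = w, converged = converged,
       iterations = it,
       history = data.frame(g = hist_g, q = hist_q))
}
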