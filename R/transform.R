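#' Time-adjust an expression series against the shared trajectory
#'
#' Subtracts, for every gene and time point, the mean expression across
#' replicates/strains.  In perturbation experiments (e.g. drug treatment)
#' most genes follow a sharp shared transient over the first few time
#' points; this common trajectory generates large spurious correlations
#' between unrelated genes.  After adjustment the replicate mean at every
#' (gene, time) is exactly zero.
#'
#' @param ts an [expression_ts].
#' @return An [expression_ts] of identical shape.
#' @export
time_adjust <- function(ts) {
  stopifnot(inherits(ts, "expression_ts"))
  v <- ts$values
  mu <- apply(v, c(1L, 2L), mean)           # genes x times
  v <- sweep(v, c(1L, 2L), mu, "-")
  expression_ts(v, ts$gene_ids, ts$times, ts$replicate_ids)
}

#' Fit a gene's first-order self-regression
#'
#' Least-squares estimate of alpha in the no-intercept model
#' `X[i,t,s] = alpha * X[i,t-1,s] + noise`, pooled over all S*(T-1)
#' lagged pairs for gene i:
#' `alpha_hat = sum(X_t * X_{t-1}) / sum(X_{t-1}^2)`.
#'
#' If the gene's lagged values are identically zero the estimate is
#' degenerate; alpha_hat is defined as 0 with a warning (the residuals then
#' equal the input).
#'
#' @param ts an [expression_ts] with at least 2 time points.
#' @param gene gene identifier or index.
#' @return A list of class `"self_trend_fit"` with elements `alpha_hat` and
#'   `sigma2` (residual variance estimate, RSS / (S*(T-1) - 1)).
#' @export
fit_self_trend <- function(ts, gene) {
  stopifnot(inherits(ts, "expression_ts"))
  if (is.character(gene)) {
    gi <- match(gene, ts$gene_ids)
    if (is.na(gi)) stop(sprintf("unknown gene '%s'", gene))
  } else gi <- as.integer(gene)
  T <- length(ts$times)
  cur <- as.vector(ts$values[gi, 2:T, , drop = FALSE])
  lag <- as.vector(ts$values[gi, 1:(T - 1L), , drop = FALSE])
  den <- sum(lag^2)
  if (den == 0) {
    warning(sprintf("gene %s has all-zero lagged values; alpha_hat set to 0",
                    ts$gene_ids[gi]))
    alpha <- 0
  } else {
    alpha <- sum(cur * lag) / den
  }
  res <- cur - alpha * lag
  n <- length(res)
  sigma2 <- if (n > 1L) sum(res^2) / (n - 1L) else 0
  structure(list(alpha_hat = alpha, sigma2 = sigma2), class = "self_trend_fit")
}

#' Remove each gene's own autoregressive effect
#'
#' Replaces the series by the residuals of the per-gene no-intercept
#' self-regression fitted by [fit_self_trend]:
#' `X*[i,t,s] = X[i,t,s] - alpha_hat_i * X[i,t-1,s]` for t = 2..T.
#' The output has one fewer time point.  By the least-squares normal
#' equation, for each gene the residuals are orthogonal to the lagged
#' values they were regressed on.
#'
#' @param ts an [expression_ts] with at least 2 time points.
#' @return An [expression_ts] with `T - 1` time points (stamps `times[2:T]`).
#' @export
self_detrend <- function(ts) {
  stopifnot(inherits(ts, "expression_ts"))
  T <- length(ts$times)
  G <- length(ts$gene_ids)
  out <- array(0, dim = c(G, T - 1L, length(ts$replicate_ids)))
  for (gi in seq_len(G)) {
    fit <- fit_self_trend(ts, gi)
    out[gi, , ] <- ts$values[gi, 2:T, ] - fit$alpha_hat * ts$values[gi, 1:(T - 1L), ]
  }
  expression_ts(out, ts$gene_ids, ts$times[2:T], ts$replicate_ids)
}

#' Apply the standard two-step transformation pipeline
#'
#' Step 1 time-adjusts the data (removes the shared perturbation
#' trajectory), step 2 removes each gene's autoregressive self-effect from
#' the adjusted values.  Since self-detrending drops one time point and the
#' downstream lagged regression drops another, at least 3 input time points
#' are required.
#'
#' @param ts an [expression_ts].
#' @param method `"time+self"` (default, both steps), `"time"` (adjustment
#'   only) or `"none"` (identity).
#' @return An [expression_ts].
#' @export
transform_pipeline <- function(ts, method = c("time+self", "time", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "expression_ts"))
  if (method == "none") return(ts)
  if (method == "time") return(time_adjust(ts))
  if (length(ts$times) < 3L)
    stop("the two-step transformation needs at least 3 time points: ",
         "self-detrending drops one and the lagged regression another")
  self_detrend(time_adjust(ts))
}
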