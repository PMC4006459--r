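#' Configuration for the network/time-series simulator
#'
#' Defaults emulate the shape of the DREAM4 10-gene in-silico time-series
#' (10 genes, 21 time points, 5 replicates) with a sparse directed network
#' whose mean in-degree matches the literature estimate of 2.76 regulators
#' per yeast gene.
#'
#' @param genes,times,replicates data dimensions.
#' @param mean_in_degree mean number of regulators per target gene
#'   (default 2.76); in-degrees are geometric, truncated at
#'   `min(13, genes - 1)` (no gene has been reported with more than 13
#'   regulators), with the geometric parameter calibrated so that the
#'   truncated mean equals `mean_in_degree`.
#' @param coef_scale absolute value of regulatory coefficients (default
#'   0.8); signs are random.
#' @param self_ar per-gene autoregressive self-coefficient in (-1, 1)
#'   (default 0.5).
#' @param noise_sd innovation noise standard deviation (default 0.25).
#' @param amplitude amplitude of the shared perturbation trajectory
#'   `m(t) = amplitude * exp(-(t - 1))` added to every gene and replicate
#'   (default 1, a modest post-perturbation transient).
#' @param seed integer RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(genes = 10, times = 21, replicates = 5,
                       mean_in_degree = 2.76, coef_scale = 0.8,
                       self_ar = 0.5, noise_sd = 0.25, amplitude = 1,
                       seed = 1) {
  stopifnot(genes >= 1, times >= 1, replicates >= 1, noise_sd > 0,
            mean_in_degree >= 0, abs(self_ar) < 1)
  structure(list(genes = as.integer(genes), times = as.integer(times),
                 replicates = as.integer(replicates),
                 mean_in_degree = mean_in_degree, coef_scale = coef_scale,
                 self_ar = self_ar, noise_sd = noise_sd,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "sim_config")
}

# geometric success probability such that the mean of the geometric law
# truncated at cap equals m (cap large relative to m => small adjustment)
.geom_prob_for_truncated_mean <- function(m, cap) {
  if (m <= 0) return(1)
  if (m >= cap) return(.Machine$double.eps)
  tmean <- function(p) {
    k <- 0:cap
    pm <- stats::dgeom(k, p)
    pm[cap + 1L] <- pm[cap + 1L] + stats::pgeom(cap, p, lower.tail = FALSE)
    sum(k * pm)
  }
  stats::uniroot(function(p) tmean(p) - m, c(1e-9, 1 - 1e-9),
                 tol = 1e-12)$root
}

#' Sample a sparse directed regulatory network
#'
#' Per-gene in-degrees are drawn from a geometric distribution truncated at
#' `min(13, genes - 1)` whose mean equals `mean_in_degree`; parents are
#' sampled uniformly without replacement; coefficients are
#' `+/- coef_scale` with random sign.  Self-edges never appear in the
#' regulator set (the self-effect is the separate `self_ar` coefficient).
#'
#' @param cfg a [sim_config]; `cfg$seed` makes the draw reproducible.
#' @return An object of class `"true_network"`: list with `edges`
#'   (data.frame `regulator`, `target`, `coef`), `self_ar` (named per-gene
#'   vector), `genes` (identifiers `G01`, `G02`, ...).
#' @export
sample_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$genes >= 2 || cfg$mean_in_degree == 0)
  set.seed(cfg$seed)
  genes <- sprintf("G%02d", seq_len(cfg$genes))
  cap <- min(13L, cfg$genes - 1L)
  if (cfg$mean_in_degree == 0 || cap == 0L) {
    indeg <- integer(cfg$genes)
  } else {
    p <- .geom_prob_for_truncated_mean(cfg$mean_in_degree, cap)
    indeg <- pmin(stats::rgeom(cfg$genes, p), cap)
  }
  reg <- tgt <- character()
  coef <- numeric()
  for (i in seq_len(cfg$genes)) {
    if (indeg[i] == 0L) next
    parents <- sample(setdiff(seq_len(cfg$genes), i), indeg[i])
    reg <- c(reg, genes[parents])
    tgt <- c(tgt, rep(genes[i], indeg[i]))
    coef <- c(coef, cfg$coef_scale * sample(c(-1, 1), indeg[i], replace = TRUE))
  }
  structure(list(edges = data.frame(regulator = reg, target = tgt,
                                    coef = coef, stringsAsFactors = FALSE),
                 self_ar = stats::setNames(rep(cfg$self_ar, cfg$genes), genes),
                 genes = genes),
            class = "true_network")
}

#' Simulate time-series expression data from a known network
#'
#' Linear-Gaussian first-order autoregressive dynamics matching the
#' inference model: `X[i,1,s] ~ N(0,1)` and, for t >= 2,
#'
#'   `X[i,t,s] = m(t) + self_ar * X[i,t-1,s] + sum_h beta_hi X[h,t-1,s] + eps`
#'
#' with `eps ~ N(0, noise_sd^2)` and the shared perturbation trajectory
#' `m(t) = amplitude * exp(-(t - 1))`.  Draws come from a single seeded
#' stream (`cfg$seed + 1`, offset so the series is decoupled from the
#' network draw); identical seeds give identical series.
#'
#' The dynamics need not be stationary: with the default coefficient
#' magnitudes the lag-1 coefficient matrix often has spectral radius
#' slightly above 1 and signals grow over the series, which mimics a
#' diverging post-perturbation response and leaves the lagged regression
#' structure intact.  Only genuinely explosive draws (any value exceeding
#' 1e12 in magnitude, or non-finite) raise an error advising smaller
#' coefficients.
#'
#' @param net a `"true_network"` from [sample_network].
#' @param cfg the matching [sim_config].
#' @return An [expression_ts] with times `1..times` and replicates
#'   `S1, S2, ...`.
#' @export
simulate_timeseries <- function(net, cfg) {
  stopifnot(inherits(net, "true_network"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  G <- cfg$genes
  T <- cfg$times
  S <- cfg$replicates
  B <- matrix(0, G, G, dimnames = list(net$genes, net$genes))  # [target, parent]
  if (nrow(net$edges))
    B[cbind(match(net$edges$target, net$genes),
            match(net$edges$regulator, net$genes))] <- net$edges$coef
  diag(B) <- diag(B) + net$self_ar
  vals <- array(NA_real_, dim = c(G, T, S))
  for (s in seq_len(S)) {
    vals[, 1L, s] <- stats::rnorm(G)
    for (t in seq.int(2L, length.out = T - 1L)) {
      m <- cfg$amplitude * exp(-(t - 1))
      vals[, t, s] <- m + B %*% vals[, t - 1L, s] +
        stats::rnorm(G, sd = cfg$noise_sd)
    }
  }
  if (!all(is.finite(vals)) || max(abs(vals)) > 1e12)
    stop("explosive dynamics: the sampled network amplifies signals ",
         "without bound; reduce coef_scale and/or self_ar")
  expression_ts(vals, net$genes, seq_len(T), sprintf("S%d", seq_len(S)))
}

#' Simulate a complete dataset (network + time series)
#'
#' @param cfg a [sim_config].
#' @return List with `network` (a `"true_network"`) and `ts` (an
#'   [expression_ts]).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  net <- sample_network(cfg)
  list(network = net, ts = simulate_timeseries(net, cfg))
}

#' Convert a true network to a gold standard
#'
#' @param net a `"true_network"`.
#' @return A [gold_standard] whose evaluable-regulator set is the genes
#'   with out-degree > 0.
#' @export
as_gold_standard <- function(net) {
  stopifnot(inherits(net, "true_network"))
  gold_standard(net$edges[c("regulator", "target")],
                regulators = unique(net$edges$regulator))
}

#' Write a true network in DREAM4 gold-standard format
#'
#' TSV triples `regulator<TAB>target<TAB>1`, one row per true edge, with a
#' header line.
#'
#' @param net a `"true_network"`.
#' @param path output path.
#' @export
write_gold_standard <- function(net, path) {
  stopifnot(inherits(net, "true_network"))
  df <- data.frame(regulator = net$edges$regulator,
                   target = net$edges$target,
                   label = rep(1L, nrow(net$edges)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(NULL)
}
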