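#' Options controlling the model search
#'
#' @param occam_c Occam's-window factor C (> 1, default 100): models whose
#'   posterior probability is more than a factor C below the best model's
#'   are discarded, i.e. scores below `best - 2 log(C)` on the 2-log-odds
#'   scale.
#' @param nvar number of candidate regulators retained by the prior/score
#'   prescreen per target, or `"all"` (default 20, leaving margin over the
#'   largest regulator counts reported for yeast).
#' @param g g-prior scale: `"em"` (default) to estimate g by the EM
#'   marginal-likelihood maximisation, or a fixed positive number.
#' @param score model-score backend, `"gprior"` (default) or `"bic"`.
#' @param max_model_size largest model size scored (default `n - 2`, the
#'   guard beyond which the g-prior score degenerates).
#' @param include_self allow self-edges as candidates (default `FALSE`).
#' @return A list of class `"scan_options"`.
#' @export
scan_options <- function(occam_c = 100, nvar = 20, g = "em",
                         score = c("gprior", "bic"), max_model_size = NULL,
                         include_self = FALSE) {
  score <- match.arg(score)
  if (!is.numeric(occam_c) || occam_c <= 1) stop("occam_c must be > 1")
  if (!(identical(nvar, "all") || (is.numeric(nvar) && nvar >= 1)))
    stop("nvar must be >= 1 or \"all\"")
  if (!(identical(g, "em") || (is.numeric(g) && g > 0)))
    stop("g must be \"em\" or a positive number")
  structure(list(occam_c = occam_c, nvar = nvar, g = g, score = score,
                 max_model_size = max_model_size, include_self = include_self),
            class = "scan_options")
}

# per-candidate prior log-odds log(pi/(1-pi)) for a given target;
# priors = NULL means a flat pi = 0.5 (zero log-odds)
.prior_log_odds <- function(priors, candidates, target) {
  if (is.null(priors)) return(numeric(length(candidates)))
  miss <- setdiff(candidates, rownames(priors))
  if (length(miss))
    stop(sprintf("candidate '%s' missing from prior matrix rows", miss[1L]))
  if (!target %in% colnames(priors))
    stop(sprintf("target '%s' missing from prior matrix columns", target))
  p <- priors[candidates, target]
  log(p / (1 - p))
}

.prior_probs <- function(priors, candidates, target) {
  if (is.null(priors)) return(rep(0.5, length(candidates)))
  priors[candidates, target]
}

#' Rank and prescreen candidate regulators
#'
#' Scores every single-regulator model with the g-prior score (R-squared of
#' the one-variable fit plus that candidate's prior log-odds) and returns
#' the top `nvar` candidates.  Ties are broken by higher prior probability,
#' then lexicographic gene identifier.
#'
#' @param data a `"regression_data"` object from [build_lagged_design].
#' @param priors a [prior_matrix] or `NULL` for a flat prior.
#' @param target target gene identifier (prior column).
#' @param nvar number of candidates to keep, or `"all"`.
#' @param g g-prior scale used for the screening scores (default `n`, the
#'   unit information prior).
#' @return Character vector of the selected candidate identifiers, ranked
#'   by decreasing single-model score.
#' @export
prescreen <- function(data, priors, target, nvar, g = data$n) {
  cand <- data$candidates
  if (identical(nvar, "all") || nvar >= length(cand)) nvar <- length(cand)
  pl <- .prior_log_odds(priors, cand, target)
  pp <- .prior_probs(priors, cand, target)
  sc <- vapply(seq_along(cand), function(j)
    g_prior_two_log_odds(r_squared(data, j), 1L, data$n, g, 2 * pl[j]),
    numeric(1L))
  o <- order(-sc, -pp, cand)
  cand[o][seq_len(nvar)]
}

#' Occam's-window model search (active-set scan)
#'
#' Explores the model space by keeping an active set of models around which
#' to search.  Starting from the null model, every model reachable by
#' adding or removing a single candidate from an active model is scored;
#' newly scored models that fall within Occam's window of the best score
#' seen so far join the next active set, and the search stops when no new
#' model enters the window.  All scored models are memoised, so nothing is
#' evaluated twice; when a better best model is found the accumulated
#' window is simply re-filtered against the new threshold.
#'
#' @param data a `"regression_data"` object.
#' @param prior_lo per-candidate prior log-odds vector
#'   (`log(pi/(1-pi))`, zero for a flat prior).
#' @param g g-prior scale.
#' @param opts a [scan_options] object.
#' @param cache optional environment memoising R-squared values across
#'   calls (shared across EM iterations; R-squared is g-independent).
#' @return A list with `keys` (list of integer index subsets), `scores`,
#'   `r2`, `d` for every model in the final window (scores within
#'   `2 log(occam_c)` of the best), ordered by decreasing score with ties
#'   broken by smaller size then lexicographic key; plus `best` (index of
#'   the best model) and `n_evaluated`.
#' @export
scan_models <- function(data, prior_lo, g, opts = scan_options(),
                        cache = new.env(parent = emptyenv())) {
  p <- ncol(data$X)
  max_d <- min(if (is.null(opts$max_model_size)) data$n - 2L else opts$max_model_size,
               data$n - 2L, p)
  width <- 2 * log(opts$occam_c)
  scores <- new.env(parent = emptyenv())   # model id -> score at current g
  eval1 <- function(key) {
    s <- .score_model(key, cache, data, prior_lo, g, opts$score)
    assign(.model_id(key), s, envir = scores)
    s
  }
  best <- eval1(integer(0))
  active <- list(integer(0))
  repeat {
    fresh_keys <- list()
    fresh_scores <- numeric()
    for (m in active) {
      nbrs <- list()
      if (length(m) < max_d)                       # single adds, ascending index
        nbrs <- c(nbrs, lapply(setdiff(seq_len(p), m), function(j) sort(c(m, j))))
      if (length(m))                               # single drops, ascending index
        nbrs <- c(nbrs, lapply(seq_along(m), function(j) m[-j]))
      for (nb in nbrs) {
        id <- .model_id(nb)
        if (!is.null(scores[[id]])) next
        s <- eval1(nb)
        fresh_keys[[length(fresh_keys) + 1L]] <- nb
        fresh_scores <- c(fresh_scores, s)
      }
    }
    if (!length(fresh_keys)) break
    best <- max(best, max(fresh_scores))
    keep <- fresh_scores >= best - width
    active <- fresh_keys[keep]
    if (!length(active)) break
  }
  ids <- ls(scores, all.names = TRUE)      # all.names: keep the "." null id
  all_scores <- vapply(ids, function(id) scores[[id]], numeric(1L))
  inwin <- all_scores >= best - width
  ids <- ids[inwin]
  all_scores <- all_scores[inwin]
  keys <- lapply(ids, function(id) cache[[id]]$key)
  d <- lengths(keys)
  r2 <- vapply(ids, function(id) cache[[id]]$r2, numeric(1L))
  o <- order(-all_scores, d, ids)
  list(keys = keys[o], scores = unname(all_scores[o]), r2 = unname(r2[o]),
       d = unname(d[o]), best = 1L,
       n_evaluated = length(ls(scores, all.names = TRUE)))
}

#' Refine extreme posterior inclusion probabilities
#'
#' Because the search does not average over the whole model space, many
#' candidates end up with raw inclusion probabilities of exactly 1 (in
#' every window model) or 0 (in none).  These extremes are refined from
#' the score gap to the best model with the candidate removed or added:
#' for a candidate at 1, with odds ratio `O = exp((score(best) -
#' score(best without h)) / 2)`, the refined probability is `O / (1 + O)`;
#' for a candidate at 0, with `O = exp((score(best) - score(best plus h)) /
#' 2)`, it is `1 / (1 + O)`.  Intermediate probabilities are left
#' unchanged.  All outputs are clamped to `(1e-12, 1 - 1e-12)`, so the
#' refinement yields a strict ordering usable for ranking edges.
#'
#' @param window result of [scan_models].
#' @param raw raw inclusion probabilities (length p).
#' @param data,prior_lo,g,opts,cache as in [scan_models]; needed to score
#'   the modified models (fresh if not cached).
#' @return Numeric vector of refined probabilities, strictly inside (0, 1).
#' @export
refine_inclusion <- function(window, raw, data, prior_lo, g,
                             opts = scan_options(),
                             cache = new.env(parent = emptyenv())) {
  p <- ncol(data$X)
  max_d <- min(if (is.null(opts$max_model_size)) data$n - 2L else opts$max_model_size,
               data$n - 2L, p)
  best_key <- window$keys[[1L]]
  best_score <- window$scores[[1L]]
  out <- raw
  for (h in seq_len(p)) {
    if (raw[h] >= 1 - 1e-9) {
      alt <- setdiff(best_key, h)
      s <- .score_model(alt, cache, data, prior_lo, g, opts$score)
      O <- exp((best_score - s) / 2)
      out[h] <- O / (1 + O)
    } else if (raw[h] <= 1e-9) {
      if (length(best_key) + 1L > max_d) next   # guard: keep raw (clamped below)
      alt <- sort(c(best_key, h))
      s <- .score_model(alt, cache, data, prior_lo, g, opts$score)
      O <- exp((best_score - s) / 2)
      out[h] <- 1 / (1 + O)
    }
  }
  pmin(pmax(out, 1e-12), 1 - 1e-12)
}

#' Fit the BMA regulator model for one target gene
#'
#' Orchestrates the per-target pipeline on an (already transformed)
#' series: build the lagged design over all candidate regulators, prescreen
#' to `nvar` candidates, estimate g by EM (or use the fixed value), run the
#' final Occam's-window scan, and compute model weights, raw inclusion
#' probabilities and refined inclusion probabilities.  Deterministic for
#' fixed inputs.
#'
#' @param ts a transformed [expression_ts] (see [transform_pipeline]).
#' @param target target gene identifier.
#' @param priors a [prior_matrix] or `NULL` for a flat prior.
#' @param opts a [scan_options] object.
#' @return An object of class `"bma_result"`: list with `target`,
#'   `candidates` (post-prescreen, in ranked order), `window` (the
#'   [scan_models] output), `weights`, `g`, `em` (EM diagnostics or NULL),
#'   `inclusion` and `refined_inclusion` (named by candidate).
#' @export
fit_target <- function(ts, target, priors = NULL, opts = scan_options()) {
  data_full <- build_lagged_design(ts, target, include_self = opts$include_self)
  g0 <- if (identical(opts$g, "em")) data_full$n else opts$g
  cand <- prescreen(data_full, priors, target, opts$nvar, g = g0)
  ci <- match(cand, data_full$candidates)
  data <- structure(list(y = data_full$y,
                         X = data_full$X[, ci, drop = FALSE],
                         n = data_full$n, candidates = cand),
                    class = "regression_data")
  prior_lo <- .prior_log_odds(priors, cand, target)
  cache <- new.env(parent = emptyenv())
  em <- NULL
  if (identical(opts$g, "em")) {
    em <- em_loop(data, prior_lo, opts, cache = cache)
    g <- em$g
    window <- em$window
  } else {
    g <- opts$g
    window <- scan_models(data, prior_lo, g, opts, cache = cache)
  }
  w <- model_weights(window$scores)
  incl <- inclusion_probabilities(window$keys, w, length(cand))
  refined <- refine_inclusion(window, incl, data, prior_lo, g, opts, cache)
  names(incl) <- names(refined) <- cand
  structure(list(target = target, candidates = cand, window = window,
                 weights = w, g = g, em = em, inclusion = incl,
                 refined_inclusion = refined),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("bma_result for target %s: %d window models, g = %.4g\n",
              x$target, length(x$window$keys), x$g))
  top <- sort(x$refined_inclusion, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  cat("  top refined inclusion probabilities:\n")
  for (i in seq_along(top))
    cat(sprintf("    %s  %.4f\n", names(top)[i], top[i]))
  invisible(x)
}
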