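#' Infer a regulatory network across target genes
#'
#' Runs the transformation pipeline once, then fits the BMA regulator model
#' for every target gene and assembles the refined posterior inclusion
#' probabilities into a directed weighted edge list.  Per-target failures
#' are caught, logged in the metadata and skipped.
#'
#' @param ts an untransformed [expression_ts].
#' @param priors a [prior_matrix] or `NULL` for a flat prior.
#' @param opts a [scan_options] object.
#' @param targets target genes to fit (default: all genes).
#' @param transform transformation method passed to [transform_pipeline].
#' @param verbose print per-gene progress (window size and estimated g).
#' @return An object of class `"inferred_network"`: list with `edges` (an
#'   [edge_list] sorted by descending probability), `results` (per-target
#'   [fit_target] outputs), and `meta` (options, transform, per-target g,
#'   failures).
#' @export
infer_network <- function(ts, priors = NULL, opts = scan_options(),
                          targets = NULL,
                          transform = c("time+self", "time", "none"),
                          verbose = FALSE) {
  transform <- match.arg(transform)
  stopifnot(inherits(ts, "expression_ts"))
  if (is.null(targets)) targets <- ts$gene_ids
  tts <- transform_pipeline(ts, transform)
  results <- list()
  failures <- character()
  reg <- tgt <- character()
  prob <- numeric()
  for (target in targets) {
    res <- tryCatch(fit_target(tts, target, priors, opts), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", target, conditionMessage(res)))
      next
    }
    results[[target]] <- res
    keep <- res$refined_inclusion > 0
    reg <- c(reg, names(res$refined_inclusion)[keep])
    tgt <- c(tgt, rep(target, sum(keep)))
    prob <- c(prob, unname(res$refined_inclusion[keep]))
    if (verbose)
      message(sprintf("%s: %d window models, g = %.3f",
                      target, length(res$window$keys), res$g))
  }
  edges <- edge_list(reg, tgt, prob, allow_self = opts$include_self)
  o <- order(-edges$probability, edges$regulator, edges$target)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("edge_list", "data.frame")
  structure(list(edges = edges, results = results,
                 meta = list(opts = opts, transform = transform,
                             g = vapply(results, `[[`, numeric(1L), "g"),
                             failures = failures)),
            class = "inferred_network")
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("inferred_network: %d targets fitted, %d candidate edges\n",
              length(x$results), nrow(x$edges)))
  cat(sprintf("  edges at the 0.95 cutoff: %d\n",
              sum(x$edges$probability >= 0.95)))
  if (length(x$meta$failures))
    cat("  failures:", length(x$meta$failures), "\n")
  invisible(x)
}

#' Threshold an inferred network's edges
#'
#' @param net an `"inferred_network"` or an [edge_list].
#' @param cutoff posterior inclusion probability cutoff in `[0, 1]`
#'   (default 0.95); edges with probability `>= cutoff` are kept.
#' @return An [edge_list].
#' @export
threshold_edges <- function(net, cutoff = 0.95) {
  edges <- if (inherits(net, "inferred_network")) net$edges else net
  stopifnot(cutoff >= 0, cutoff <= 1)
  out <- edges[edges$probability >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Restrict edges to an evaluable regulator set (partial assessment)
#'
#' Gold standards curated from the literature only document targets for a
#' subset of regulators (e.g. known transcription factors); edges from any
#' other gene cannot be assessed and are dropped before computing metrics.
#'
#' @param edges an [edge_list].
#' @param gold a [gold_standard] carrying the evaluable-regulator set.
#' @return The filtered [edge_list]; if the gold standard has no regulator
#'   set, the input is returned unchanged with a warning.
#' @export
restrict_to_regulators <- function(edges, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  if (is.null(gold$regulators) || !length(gold$regulators)) {
    warning("gold standard has no evaluable-regulator set; edges unchanged")
    return(edges)
  }
  out <- edges[edges$regulator %in% gold$regulators, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

.gold_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

#' Precision of the thresholded network
#'
#' Precision = true positives / total predicted edges, at a probability
#' cutoff.  An edge is a true positive iff it is present in the gold
#' standard; the absence of a gold edge counts as a false positive even
#' for incomplete gold standards.
#'
#' @param edges an [edge_list] (already restricted for partial assessment
#'   if applicable).
#' @param gold a [gold_standard].
#' @param cutoff probability cutoff (default 0.95).
#' @return A list with `precision` (NA if nothing is predicted), `tp`, `fp`.
#' @export
precision_at <- function(edges, gold, cutoff = 0.95) {
  stopifnot(inherits(gold, "gold_standard"))
  sel <- threshold_edges(edges, cutoff)
  if (!nrow(sel)) return(list(precision = NA_real_, tp = 0L, fp = 0L))
  truth <- .gold_key(gold$edges$regulator, gold$edges$target)
  hit <- .gold_key(sel$regulator, sel$target) %in% truth
  list(precision = mean(hit), tp = sum(hit), fp = sum(!hit))
}

#' Universe of evaluable regulator-target pairs
#'
#' @param regulators,targets identifier vectors.
#' @param exclude_self drop pairs with regulator == target (default `TRUE`;
#'   self-effects are removed by the detrending and are outside the
#'   regression's scope).
#' @return data.frame with columns `regulator`, `target`.
#' @export
edge_universe <- function(regulators, targets, exclude_self = TRUE) {
  u <- expand.grid(regulator = regulators, target = targets,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (exclude_self) u <- u[u$regulator != u$target, , drop = FALSE]
  rownames(u) <- NULL
  u
}

# scores and labels over the full evaluation universe; pairs not in the
# edge list are scored 0 (ranked below every emitted edge, tied together)
.universe_scores <- function(edges, gold, universe) {
  key_u <- .gold_key(universe$regulator, universe$target)
  sc <- numeric(nrow(universe))
  m <- match(.gold_key(edges$regulator, edges$target), key_u)
  keep <- !is.na(m)
  sc[m[keep]] <- edges$probability[keep]
  lab <- key_u %in% .gold_key(gold$edges$regulator, gold$edges$target)
  list(score = sc, label = lab)
}

#' Area under the ROC curve of a ranked edge list
#'
#' Rank-based AUROC equal to the Mann-Whitney statistic: the probability
#' that a uniformly chosen true pair outscores a uniformly chosen false
#' pair, plus half the probability of a tie (average ranks).  Pairs of the
#' universe absent from the edge list are scored 0.
#'
#' @param edges an [edge_list].
#' @param gold a [gold_standard].
#' @param universe data.frame of all evaluable (regulator, target) pairs,
#'   e.g. from [edge_universe].
#' @return AUROC in `[0, 1]`; NA if the universe has no true or no false
#'   pairs.
#' @export
auroc <- function(edges, gold, universe) {
  us <- .universe_scores(edges, gold, universe)
  n1 <- sum(us$label)
  n0 <- sum(!us$label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(us$score)
  (sum(r[us$label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve of a ranked edge list
#'
#' Step-wise PR curve over descending unique score thresholds with tied
#' scores grouped into one step; the area sums precision times the recall
#' increment at each step.  For random scores the value concentrates near
#' the prevalence of true pairs in the universe.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; NA if the universe has no true pairs.
#' @export
auprc <- function(edges, gold, universe) {
  us <- .universe_scores(edges, gold, universe)
  P <- sum(us$label)
  if (P == 0L) return(NA_real_)
  o <- order(us$score, decreasing = TRUE)
  sc <- us$score[o]
  lab <- us$label[o]
  grp_end <- cumsum(rle(sc)$lengths)        # last index of each tie group
  tp <- cumsum(lab)[grp_end]
  np <- grp_end
  prec <- tp / np
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Full evaluation report against a gold standard
#'
#' Applies partial assessment (if the gold standard carries an
#' evaluable-regulator set), computes precision/TP/FP at the cutoff, and
#' AUROC/AUPRC over the evaluable pair universe.
#'
#' @param edges an [edge_list] (e.g. `net$edges` from [infer_network]).
#' @param gold a [gold_standard].
#' @param targets target identifiers spanning the universe (default: all
#'   targets appearing in the edge list and the gold standard).
#' @param cutoff probability cutoff for precision (default 0.95).
#' @return A list of class `"eval_report"` with `precision`, `tp`, `fp`,
#'   `auroc`, `auprc`, `cutoff`, `n_universe`, `n_true`.
#' @export
evaluate_network <- function(edges, gold, targets = NULL, cutoff = 0.95) {
  stopifnot(inherits(gold, "gold_standard"))
  if (!is.null(gold$regulators) && length(gold$regulators))
    edges <- restrict_to_regulators(edges, gold)
  regs <- if (!is.null(gold$regulators) && length(gold$regulators))
    gold$regulators else sort(unique(c(edges$regulator, gold$edges$regulator)))
  if (is.null(targets))
    targets <- sort(unique(c(edges$target, gold$edges$target)))
  uni <- edge_universe(regs, targets)
  pr <- precision_at(edges, gold, cutoff)
  structure(list(precision = pr$precision, tp = pr$tp, fp = pr$fp,
                 auroc = auroc(edges, gold, uni),
                 auprc = auprc(edges, gold, uni),
                 cutoff = cutoff, n_universe = nrow(uni),
                 n_true = sum(.gold_key(uni$regulator, uni$target) %in%
                                .gold_key(gold$edges$regulator, gold$edges$target))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (cutoff %.2f): precision %.3f (tp %d, fp %d)\n",
              x$cutoff, x$precision, x$tp, x$fp))
  cat(sprintf("  AUROC %.3f  AUPRC %.3f  (universe %d pairs, %d true)\n",
              x$auroc, x$auprc, x$n_universe, x$n_true))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `"eval_report"`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(NULL)
}
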