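#' Construct an expression time-series object
#'
#' The central data container: a 3-D block of expression values indexed by
#' (gene, time point, replicate).  In multi-strain designs such as a panel of
#' yeast segregants, the "replicate" axis holds the strains.
#'
#' @param values numeric 3-D array of shape (genes, time points, replicates).
#' @param gene_ids character vector of unique gene identifiers.
#' @param times strictly increasing numeric vector of time stamps
#'   (arbitrary units).
#' @param replicate_ids character vector of replicate/strain identifiers.
#' @return An object of class `"expression_ts"`: a list with elements
#'   `values`, `gene_ids`, `times`, `replicate_ids`.
#' @examples
#' x <- array(rnorm(2 * 3 * 2), dim = c(2, 3, 2))
#' ts <- expression_ts(x, c("g1", "g2"), times = 0:2, replicate_ids = c("r1", "r2"))
#' dim(ts$values)
#' @export
expression_ts <- function(values, gene_ids, times, replicate_ids) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array (genes x times x replicates)")
  gene_ids <- as.character(gene_ids)
  replicate_ids <- as.character(replicate_ids)
  times <- as.numeric(times)
  if (anyDuplicated(gene_ids))
    stop("gene identifiers must be unique")
  if (length(times) < 2L)
    stop("at least 2 time points are required (lagged regression needs T >= 2)")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (!all(dim(values) == c(length(gene_ids), length(times), length(replicate_ids))))
    stop(sprintf("shape of 'values' %s does not match (genes=%d, times=%d, replicates=%d)",
                 paste(dim(values), collapse = "x"),
                 length(gene_ids), length(times), length(replicate_ids)))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (missing values are rejected)")
  dimnames(values) <- list(gene_ids, NULL, replicate_ids)
  structure(list(values = values, gene_ids = gene_ids, times = times,
                 replicate_ids = replicate_ids),
            class = "expression_ts")
}

#' @export
print.expression_ts <- function(x, ...) {
  cat(sprintf("expression_ts: %d genes x %d time points x %d replicates\n",
              length(x$gene_ids), length(x$times), length(x$replicate_ids)))
  cat("  times:", paste(format(x$times, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_ts <- function(x) dim(x$values)

#' Read time-series expression data in long format
#'
#' Canonical input format: a tab-separated file with header columns
#' `gene`, `replicate`, `time`, `value` and one row per observation.
#' The grid must be complete: every (gene, time, replicate) combination
#' present exactly once.
#'
#' @param path path to a TSV file.
#' @return An [expression_ts] object, with times sorted ascending.  Gene and
#'   replicate ordering follows first appearance in the file.
#' @export
read_expression_long <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("gene", "replicate", "time", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("expected header columns %s; got %s",
                 paste(need, collapse = ", "), paste(names(df), collapse = ", ")))
  tm <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tm))
    stop(sprintf("non-numeric time value at line %d", which(is.na(tm))[1L] + 1L))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- is.na(val) | !is.finite(val)
  if (any(bad))
    stop(sprintf("non-numeric or non-finite expression value at line %d",
                 which(bad)[1L] + 1L))
  genes <- unique(df$gene)
  reps  <- unique(df$replicate)
  times <- sort(unique(tm))
  gi <- match(df$gene, genes)
  ti <- match(tm, times)
  ri <- match(df$replicate, reps)
  idx <- cbind(gi, ti, ri)
  if (anyDuplicated(idx)) {
    d <- idx[duplicated(idx), , drop = FALSE][1L, ]
    stop(sprintf("duplicate row for (gene=%s, time=%s, replicate=%s)",
                 genes[d[1L]], format(times[d[2L]]), reps[d[3L]]))
  }
  full <- length(genes) * length(times) * length(reps)
  if (nrow(df) != full) {
    seen <- array(FALSE, dim = c(length(genes), length(times), length(reps)))
    seen[idx] <- TRUE
    m <- which(!seen, arr.ind = TRUE)[1L, ]
    stop(sprintf("incomplete grid: missing (gene=%s, time=%s, replicate=%s)",
                 genes[m[1L]], format(times[m[2L]]), reps[m[3L]]))
  }
  vals <- array(NA_real_, dim = c(length(genes), length(times), length(reps)))
  vals[idx] <- val
  expression_ts(vals, genes, times, reps)
}

#' Write time-series expression data in long format
#'
#' Inverse of [read_expression_long]; values are printed with full double
#' precision so a write-then-read round trip is the identity to ~1e-15.
#'
#' @param ts an [expression_ts] object.
#' @param path output file path.
#' @export
write_expression_long <- function(ts, path) {
  stopifnot(inherits(ts, "expression_ts"))
  g <- rep(ts$gene_ids, times = length(ts$times) * length(ts$replicate_ids))
  t <- rep(rep(ts$times, each = length(ts$gene_ids)), times = length(ts$replicate_ids))
  r <- rep(ts$replicate_ids, each = length(ts$gene_ids) * length(ts$times))
  df <- data.frame(gene = g, replicate = r,
                   time = format(t, digits = 17, trim = TRUE, scientific = FALSE),
                   value = format(as.vector(ts$values), digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read time-series expression data in the DREAM4 wide dialect
#'
#' The DREAM4 in-silico challenge distributes time series as a `Time`
#' column followed by one column per gene; replicate series are stacked as
#' consecutive blocks, separated either by blank lines or by the time stamp
#' resetting to its starting value.  All blocks must share an identical
#' time grid.
#'
#' @param path path to a tab-separated DREAM4-style file.
#' @return An [expression_ts] object with replicates `"R1"`, `"R2"`, ...
#' @export
read_expression_dream4 <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (tolower(header[1L]) != "time")
    stop("first column of a DREAM4 file must be 'Time'")
  genes <- header[-1L]
  body <- lines[-1L]
  blank <- !nzchar(trimws(body))
  rows <- lapply(body[!blank], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
    if (anyNA(v) || length(v) != length(header))
      stop(sprintf("malformed data row: '%s'", l))
    v
  })
  if (!length(rows)) stop("no data rows")
  tm <- vapply(rows, `[`, numeric(1L), 1L)
  # new block when a blank line intervened or the time stamp does not increase
  src <- which(!blank)
  gap <- c(TRUE, diff(src) > 1L) | c(TRUE, diff(tm) <= 0)
  block <- cumsum(gap)
  nb <- max(block)
  tgrid <- tm[block == 1L]
  for (b in seq_len(nb)) {
    tb <- tm[block == b]
    if (length(tb) != length(tgrid) || any(tb != tgrid)) {
      row <- which(block == b)[which(tb != tgrid[seq_along(tb)])[1L]]
      if (is.na(row)) row <- which(block == b)[length(tb)]
      stop(sprintf("replicate block %d has a different time grid (data row %d)", b, row))
    }
  }
  vals <- array(NA_real_, dim = c(length(genes), length(tgrid), nb))
  for (b in seq_len(nb)) {
    m <- do.call(rbind, rows[block == b])      # time x (1+genes)
    vals[, , b] <- t(m[, -1L, drop = FALSE])
  }
  expression_ts(vals, genes, tgrid, paste0("R", seq_len(nb)))
}

# shared clipping for prior probabilities; exact 0/1 would make the
# log-odds term in the model score infinite
.clip_prob <- function(p, eps = 1e-8) {
  out <- pmin(pmax(p, eps), 1 - eps)
  if (any(p <= 0 | p >= 1))
    warning(sprintf("%d prior probabilities outside (0,1) clipped to [%g, %g]",
                    sum(p <= 0 | p >= 1), eps, 1 - eps))
  out
}

#' Construct a prior edge-probability matrix
#'
#' @param probs numeric matrix, rows = regulators, columns = targets; entry
#'   (h, i) is the prior probability that gene h regulates gene i.  Entries
#'   equal to 0 or 1 are clipped to `[1e-8, 1 - 1e-8]` with a warning so the
#'   prior log-odds stay finite.
#' @param regulator_ids,target_ids row/column identifiers (default: dimnames).
#' @return A classed matrix of class `"prior_matrix"`.
#' @export
prior_matrix <- function(probs, regulator_ids = rownames(probs),
                         target_ids = colnames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(regulator_ids) || is.null(target_ids))
    stop("regulator and target identifiers are required")
  if (any(probs < 0)) stop("negative prior probability")
  if (any(probs > 1)) stop("prior probability greater than 1")
  probs[] <- .clip_prob(probs)
  dimnames(probs) <- list(as.character(regulator_ids), as.character(target_ids))
  class(probs) <- c("prior_matrix", "matrix")
  probs
}

#' Read a prior edge-probability matrix from TSV
#'
#' Format: first column holds regulator identifiers, header row holds target
#' identifiers, body holds probabilities.
#'
#' @param path path to the TSV matrix.
#' @param regulators,targets optional identifier vectors to validate the file
#'   labels against; unknown identifiers raise an error.
#' @return A [prior_matrix].
#' @export
read_prior_matrix <- function(path, regulators = NULL, targets = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric entry in prior matrix")
  if (!is.null(regulators) && !all(rownames(m) %in% regulators))
    stop(sprintf("unknown regulator identifier: %s",
                 setdiff(rownames(m), regulators)[1L]))
  if (!is.null(targets) && !all(colnames(m) %in% targets))
    stop(sprintf("unknown target identifier: %s",
                 setdiff(colnames(m), targets)[1L]))
  prior_matrix(m)
}

#' Flat prior from the expected regulator count per gene
#'
#' Literature curation of the yeast transcription network found each target
#' gene to be regulated by about 2.76 transcription factors out of roughly
#' 6000 genes, giving a flat per-edge prior probability of 2.76/6000.
#'
#' @param regulators,targets identifier vectors.
#' @param expected_regulators expected number of regulators per target
#'   (default 2.76).
#' @param n_genes size of the candidate pool the expectation refers to
#'   (default 6000).
#' @return A [prior_matrix] with every entry `expected_regulators / n_genes`.
#' @export
guelzim_prior <- function(regulators, targets, expected_regulators = 2.76,
                          n_genes = 6000) {
  p <- expected_regulators / n_genes
  m <- matrix(p, nrow = length(regulators), ncol = length(targets),
              dimnames = list(regulators, targets))
  prior_matrix(m)
}

#' Construct a directed weighted edge list
#'
#' @param regulator,target character vectors of gene identifiers.
#' @param probability numeric scores in `[0, 1]` (posterior inclusion
#'   probabilities of the edges).
#' @param allow_self allow self-edges (default `FALSE`).
#' @return A `data.frame` of class `"edge_list"` with columns `regulator`,
#'   `target`, `probability`.
#' @export
edge_list <- function(regulator = character(), target = character(),
                      probability = numeric(), allow_self = FALSE) {
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   probability = as.numeric(probability),
                   stringsAsFactors = FALSE)
  if (any(df$probability < 0 | df$probability > 1))
    stop("edge probabilities must lie in [0, 1]")
  if (anyDuplicated(df[c("regulator", "target")]))
    stop("duplicate (regulator, target) pair")
  if (!allow_self && any(df$regulator == df$target))
    stop("self-edges are not allowed (use allow_self = TRUE)")
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Write an edge list as TSV
#'
#' Rows are sorted by descending probability, ties broken by (regulator,
#' target) lexicographically, so output is reproducible across runs.
#' Probabilities are printed with 6 decimals.
#'
#' @param edges an [edge_list].
#' @param path output file path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(is.data.frame(edges))
  o <- order(-edges$probability, edges$regulator, edges$target)
  out <- edges[o, c("regulator", "target", "probability"), drop = FALSE]
  out$probability <- sprintf("%.6f", out$probability)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an edge list written by [write_edge_list]
#'
#' @param path path to a TSV with columns `regulator`, `target`, `probability`.
#' @return An [edge_list].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  edge_list(df$regulator, df$target, df$probability, allow_self = TRUE)
}

#' Construct a gold-standard network
#'
#' @param edges data.frame with character columns `regulator` and `target`
#'   listing the true directed edges.
#' @param regulators optional character vector of evaluable regulators (for
#'   example the transcription factors with documented targets); used by
#'   [restrict_to_regulators] for partial assessment.
#' @return An object of class `"gold_standard"`.
#' @export
gold_standard <- function(edges, regulators = NULL) {
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  structure(list(edges = edges,
                 regulators = if (is.null(regulators)) NULL else as.character(regulators)),
            class = "gold_standard")
}

#' Read a gold standard in DREAM4 triple format
#'
#' TSV rows `regulator<TAB>target<TAB>{0|1}`; pairs absent from the file are
#' treated as non-edges.  The evaluable-regulator set defaults to the genes
#' with at least one outgoing true edge.
#'
#' @param path path to the TSV file (a header line `regulator target label`
#'   is tolerated).
#' @param regulators optional explicit evaluable-regulator vector.
#' @return A [gold_standard].
#' @export
read_gold_standard <- function(path, regulators = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df[1L, 1L]), "regulator"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 3L && nrow(df) > 0L)
    stop("gold standard rows must be regulator<TAB>target<TAB>{0|1}")
  if (nrow(df)) {
    lab <- suppressWarnings(as.integer(df[[3L]]))
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      stop("gold standard labels must be 0 or 1")
    df <- df[lab == 1L, , drop = FALSE]
  }
  ed <- data.frame(regulator = if (nrow(df)) df[[1L]] else character(),
                   target = if (nrow(df)) df[[2L]] else character(),
                   stringsAsFactors = FALSE)
  if (is.null(regulators)) regulators <- unique(ed$regulator)
  gold_standard(ed, regulators = regulators)
}
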