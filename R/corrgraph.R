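#' Per-dimension Pearson correlations between landmarks
#'
#' Splits the ensemble into its spatial components and, for each dimension,
#' computes the `k x k` Pearson correlation matrix between landmarks.  A
#' landmark whose coordinate is constant in some dimension would give an
#' undefined correlation; such entries are set to 0 with a warning.
#'
#' @param ens a [coord_ensemble()] with at least 4 observations.
#' @return An object of class `correlation_stack`: list with `raw` (a
#'   `k x k x dims` array of correlations, unit diagonal), `n_obs`,
#'   `landmark_ids` and `dims`.
#' @export
per_dimension_correlations <- function(ens) {
  stopifnot(inherits(ens, "coord_ensemble"))
  k <- length(ens$landmark_ids)
  raw <- array(0, dim = c(k, k, ens$dims),
               dimnames = list(ens$landmark_ids, ens$landmark_ids, NULL))
  degenerate <- FALSE
  for (d in seq_len(ens$dims)) {
    m <- dimension_matrix(ens, d)
    r <- suppressWarnings(cor(m))
    if (anyNA(r)) {
      degenerate <- TRUE
      r[is.na(r)] <- 0
    }
    diag(r) <- 1
    raw[, , d] <- r
  }
  if (degenerate)
    warning("constant landmark coordinate(s): undefined correlations set to 0")
  structure(list(raw = raw, filtered = NULL, n_obs = ens$n_obs,
                 alpha = NULL, landmark_ids = ens$landmark_ids,
                 dims = ens$dims),
            class = "correlation_stack")
}

#' Fisher-z significance filtering of a correlation stack
#'
#' Tests every per-dimension entry against the null hypothesis of zero
#' correlation and zeroes the entries that fail.  An entry `r` is kept iff
#' `|atanh(r)| >= qnorm(1 - alpha/2) / sqrt(n_obs - 3)`, the standard
#' two-sided Fisher-z criterion (the sampling standard deviation of
#' `atanh(r)` is `1/sqrt(n - 3)`).  Negative correlations therefore survive
#' filtering; they are squared during aggregation anyway.  `|r| = 1` maps to
#' an infinite z and is always kept.
#'
#' @param stack a `correlation_stack` from [per_dimension_correlations()].
#' @param alpha significance level of the per-entry test (default 0.05).
#' @return The stack with its `filtered` array populated: each entry is
#'   either 0 or the corresponding raw correlation.  The diagonal is kept.
#' @export
fisher_filter <- function(stack, alpha = 0.05) {
  stopifnot(inherits(stack, "correlation_stack"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (stack$n_obs <= 3L) stop("Fisher filter requires n_obs > 3")
  thr <- qnorm(1 - alpha / 2) / sqrt(stack$n_obs - 3)
  z <- suppressWarnings(atanh(pmin(pmax(stack$raw, -1), 1)))
  filtered <- stack$raw
  filtered[abs(z) < thr] <- 0
  stack$filtered <- filtered
  stack$alpha <- alpha
  stack
}

#' Aggregate filtered correlations into the correlation-vector magnitude
#'
#' For each landmark pair the per-dimension significant correlations form a
#' vector `P`; its Euclidean magnitude `Xi = sqrt(sum_d P_d^2)` aggregates
#' the dimensions without violating the non-additivity of `r` (squares are
#' additive, `r` is not).  `Xi` is zero only when the pair is independent in
#' every dimension, and is bounded by `sqrt(dims)`.
#'
#' @param stack a filtered `correlation_stack` (see [fisher_filter()]), or a
#'   `k x k x dims` array of filtered correlations.
#' @return Symmetric `k x k` matrix of `Xi` values with zero diagonal.
#' @export
xi_aggregate <- function(stack) {
  filt <- if (inherits(stack, "correlation_stack")) {
    if (is.null(stack$filtered))
      stop("stack has not been filtered; call fisher_filter() first")
    stack$filtered
  } else stack
  stopifnot(is.array(filt), length(dim(filt)) == 3L)
  xi <- sqrt(apply(filt^2, c(1L, 2L), sum))
  diag(xi) <- 0
  xi
}

#' Build the weighted landmark graph
#'
#' An edge between landmarks `i` and `j` is assigned only if `Xi_ij > 0`
#' *and* the residues are in contact; its weight is `Xi_ij`.  The full
#' (contact-independent) `Xi` matrix is retained because the significance
#' and power layers operate in correlation space, not only on graph edges.
#' Landmarks with no edge remain as isolated nodes.
#'
#' @param xi_matrix symmetric `k x k` matrix of `Xi` values (from
#'   [xi_aggregate()]).
#' @param contacts a [compute_contacts()] result, a symmetric logical
#'   matrix, or `NULL` meaning all pairs in contact (simulation mode).
#' @param landmark_ids optional ids; defaults to the row names of
#'   `xi_matrix`.
#' @return An object of class `modular_graph`: list with `weights` (the
#'   masked adjacency matrix), `xi_matrix`, and `landmark_ids`.
#' @export
build_graph <- function(xi_matrix, contacts = NULL, landmark_ids = NULL) {
  xi_matrix <- as.matrix(xi_matrix)
  k <- nrow(xi_matrix)
  stopifnot(ncol(xi_matrix) == k)
  if (max(abs(xi_matrix - t(xi_matrix))) > 1e-8)
    stop("'xi_matrix' must be symmetric")
  landmark_ids <- landmark_ids %||% rownames(xi_matrix) %||%
    sprintf("L%03d", seq_len(k))
  mask <- if (is.null(contacts)) {
    matrix(TRUE, k, k)
  } else {
    cm <- if (inherits(contacts, "contact_map")) contacts$contacts else contacts
    stopifnot(is.matrix(cm), nrow(cm) == k, ncol(cm) == k)
    cm & t(cm)
  }
  diag(mask) <- FALSE
  weights <- xi_matrix
  weights[!mask] <- 0
  weights[weights < 0] <- 0
  dimnames(weights) <- list(landmark_ids, landmark_ids)
  dimnames(xi_matrix) <- list(landmark_ids, landmark_ids)
  structure(list(weights = weights, xi_matrix = xi_matrix,
                 landmark_ids = landmark_ids),
            class = "modular_graph")
}

#' @export
print.modular_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("modular_graph: %d nodes, %d edges, total weight %.3f\n",
              length(x$landmark_ids), ne, sum(x$weights) / 2))
  invisible(x)
}

#' Edge list of a modular graph
#'
#' @param graph a `modular_graph`.
#' @return A data.frame with columns `i`, `j` (landmark ids, `i < j` by
#'   position) and `xi` (edge weight), one row per edge.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "modular_graph"))
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  data.frame(i = graph$landmark_ids[idx[, 1L]],
             j = graph$landmark_ids[idx[, 2L]],
             xi = w[idx],
             stringsAsFactors = FALSE)
}
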