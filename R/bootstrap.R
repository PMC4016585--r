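#' Bipartition conflict between two clusters
#'
#' Viewing each cluster as a bipartition of the landmark set (members vs
#' non-members), two clusters conflict iff they partially overlap: their
#' intersection is non-empty and neither contains the other.  Disjoint or
#' nested clusters are compatible.
#'
#' @param cluster,other non-empty vectors of landmark ids from the same
#'   landmark universe.
#' @return `TRUE` when the bipartitions conflict.
#' @export
cluster_conflict <- function(cluster, other) {
  inter <- length(intersect(cluster, other))
  inter > 0L && inter < length(unique(cluster)) &&
    inter < length(unique(other))
}

#' Bootstrap support of the clusters of a partition
#'
#' Resamples the `n` observations with replacement `B_boot` times; each
#' replicate reruns the correlation graph construction, the fast-greedy
#' community detection and (by default) the significance refinement, with
#' the contact map held fixed.  The support of an original cluster is the
#' percentage of replicates in which *no* replicate cluster conflicts with
#' it in the bipartition sense of [cluster_conflict()].  Size-1 replicate
#' clusters are ignored (a singleton is nested in or disjoint from any set,
#' so it can never conflict).  A cluster equal to the full landmark set can
#' never conflict and has support 100 by construction.
#'
#' @param ens the original [coord_ensemble()].
#' @param clusters the original clusters: a named list of landmark-id
#'   vectors (e.g. from [refine_partition()]'s `clusters`), or a
#'   `landmark_partition`.
#' @param contacts contact map or `NULL` (simulation mode), as in
#'   [build_graph()].
#' @param B_boot number of bootstrap replicates (default 100).
#' @param seed integer seed; replicate draws and permutation streams are
#'   fully determined by it.
#' @param refine run the significance refinement inside each replicate
#'   (default `TRUE`).
#' @param alpha significance level used for the Fisher filter and, when
#'   `refine` is `TRUE`, the refinement.
#' @param B_perm permutations per refinement test inside replicates
#'   (default 199; the p floor of 1/200 is well below `alpha`, which is all
#'   a merge decision needs).
#' @return Named numeric vector of support percentages in `[0, 100]`, one
#'   per original cluster.  The number of usable replicates is attached as
#'   attribute `n_replicates` (degenerate resamples are skipped with a
#'   warning and shrink the denominator).
#' @export
bootstrap_support <- function(ens, clusters, contacts = NULL, B_boot = 100L,
                              seed = NULL, refine = TRUE, alpha = 0.05,
                              B_perm = 199L) {
  stopifnot(inherits(ens, "coord_ensemble"))
  if (inherits(clusters, "landmark_partition"))
    clusters <- partition_clusters(clusters)
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  if (B_boot < 1L) stop("'B_boot' must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nonconf <- setNames(numeric(length(clusters)), names(clusters))
  used <- 0L
  for (b in seq_len(B_boot)) {
    idx <- sample.int(ens$n_obs, ens$n_obs, replace = TRUE)
    rep_clusters <- tryCatch(
      replicate_clusters(resample_ensemble(ens, idx), contacts, refine,
                         alpha, B_perm),
      error = function(e) NULL)
    if (is.null(rep_clusters)) {
      warning("degenerate bootstrap replicate skipped")
      next
    }
    used <- used + 1L
    for (i in seq_along(clusters)) {
      conflict <- any(vapply(rep_clusters, cluster_conflict, TRUE,
                             other = clusters[[i]]))
      if (!conflict) nonconf[i] <- nonconf[i] + 1
    }
  }
  if (used == 0L) stop("all bootstrap replicates were degenerate")
  support <- 100 * nonconf / used
  attr(support, "n_replicates") <- used
  support
}

# One bootstrap replicate: rebuild the graph and cluster it; return the
# multi-member clusters only.
replicate_clusters <- function(ens_b, contacts, refine, alpha, B_perm) {
  stack <- suppressWarnings(
    fisher_filter(per_dimension_correlations(ens_b), alpha = alpha))
  graph <- build_graph(xi_aggregate(stack), contacts,
                       landmark_ids = ens_b$landmark_ids)
  part <- fast_greedy_partition(graph)
  cl <- if (refine) {
    refine_partition(part, stack, alpha = alpha,
                     B_perm = B_perm)$clusters
  } else partition_clusters(part)
  cl <- cl[names(cl) != "singletons"]
  cl[lengths(cl) >= 2L]
}
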