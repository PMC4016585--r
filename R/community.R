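#' Weighted modularity of a partition
#'
#' Computes `Q = (1/2m) * sum_vw [A_vw - k_v k_w / 2m] * delta(C_v, C_w)`,
#' where `A` is the weighted adjacency matrix, `k_v` the weighted degree of
#' node `v` and `m` the total edge weight.  `Q` ranges over `[-1, 1]`; a
#' graph with zero total edge weight has `Q = 0` by convention.
#'
#' @param graph a `modular_graph` (see [build_graph()]) or a symmetric
#'   weighted adjacency matrix with zero diagonal.
#' @param membership vector of community labels, one per node (any atomic
#'   type; only equality matters).
#' @return The modularity score, a single number.
#' @export
modularity_q <- function(graph, membership) {
  A <- if (inherits(graph, "modular_graph")) graph$weights else as.matrix(graph)
  n <- nrow(A)
  stopifnot(length(membership) == n)
  W <- sum(A)                      # 2m
  if (W == 0) return(0)
  deg <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(deg, deg) / W)[same]) / W
}

#' Fast-greedy community detection by modularity maximization
#'
#' Agglomerative (Clauset-Newman-Moore style) clustering on the weighted
#' landmark graph: starting from singletons, the pair of connected
#' communities whose merge yields the largest modularity gain is merged
#' repeatedly, and the partition along the merge path with maximal `Q` is
#' returned.  Only connected community pairs are ever merged, so the nodes
#' of distinct graph components never share a cluster and isolated nodes end
#' as singletons.  Ties in the modularity gain are broken by the
#' lexicographically smallest pair of community labels (a community is
#' labelled by its smallest node index), which makes the result independent
#' of node input order.
#'
#' The number of clusters is emergent: it is whatever maximizes `Q`, never
#' a parameter.
#'
#' @param graph a `modular_graph` or symmetric weighted adjacency matrix.
#' @return An object of class `landmark_partition`: list with `membership`
#'   (integer cluster labels named by landmark id, numbered by decreasing
#'   cluster size), `q` (the modularity of the returned partition,
#'   recomputed from scratch), and `clusters` (list of landmark-id vectors).
#' @export
fast_greedy_partition <- function(graph) {
  A <- if (inherits(graph, "modular_graph")) graph$weights else as.matrix(graph)
  n <- nrow(A)
  if (n < 1L) stop("graph must have at least one node")
  ids <- rownames(A) %||% sprintf("L%03d", seq_len(n))
  W <- sum(A)
  if (W == 0) {
    memb <- seq_len(n)
    names(memb) <- ids
    return(new_partition(memb, A))
  }
  # Community state: B[c, d] = total weight between communities c and d
  # (diagonal: twice the internal weight); deg = summed weighted degrees.
  B <- A
  deg <- rowSums(A)
  minlab <- seq_len(n)             # community label = smallest member index
  alive <- rep(TRUE, n)
  memb <- seq_len(n)               # current community index per node
  q_cur <- -sum((deg / W)^2)       # all-singleton modularity
  best_q <- q_cur
  best_memb <- memb
  repeat {
    live <- which(alive)
    if (length(live) < 2L) break
    Bl <- B[live, live, drop = FALSE]
    dl <- deg[live]
    gain <- 2 * (Bl / W - outer(dl, dl) / W^2)
    cand <- which(upper.tri(Bl) & Bl > 0, arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    g <- gain[cand]
    top <- which(g == max(g))
    if (length(top) > 1L) {
      l1 <- pmin(minlab[live[cand[top, 1L]]], minlab[live[cand[top, 2L]]])
      l2 <- pmax(minlab[live[cand[top, 1L]]], minlab[live[cand[top, 2L]]])
      top <- top[order(l1, l2)[1L]]
    }
    ci <- live[cand[top, 1L]]
    cj <- live[cand[top, 2L]]
    if (minlab[cj] < minlab[ci]) { tmp <- ci; ci <- cj; cj <- tmp }
    q_cur <- q_cur + max(g)
    # merge cj into ci
    B[ci, ] <- B[ci, ] + B[cj, ]
    B[, ci] <- B[, ci] + B[, cj]   # diagonal ends at twice the merged internal weight
    deg[ci] <- deg[ci] + deg[cj]
    alive[cj] <- FALSE
    memb[memb == cj] <- ci
    if (q_cur > best_q + 1e-12) {
      best_q <- q_cur
      best_memb <- memb
    }
  }
  names(best_memb) <- ids
  new_partition(best_memb, A)
}

# Canonicalize a membership vector into a landmark_partition, relabelling
# clusters 1..K by decreasing size (ties: smallest member index first) and
# recomputing q from the adjacency matrix.
new_partition <- function(membership, A) {
  ids <- names(membership) %||% sprintf("L%03d", seq_along(membership))
  grp <- split(seq_along(membership), membership)
  ord <- order(-lengths(grp), vapply(grp, min, 0L))
  grp <- grp[ord]
  memb <- integer(length(membership))
  for (i in seq_along(grp)) memb[grp[[i]]] <- i
  names(memb) <- ids
  structure(list(membership = memb,
                 q = modularity_q(A, memb),
                 clusters = lapply(grp, function(ix) ids[ix])),
            class = "landmark_partition")
}

#' @export
print.landmark_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("landmark_partition: %d clusters (sizes %s), Q = %.4f\n",
              length(sz), paste(sz, collapse = "/"), x$q))
  invisible(x)
}

#' Members of each cluster of a partition
#'
#' @param partition a `landmark_partition`.
#' @param min_size drop clusters smaller than this (default 1: keep all).
#' @return Named list of landmark-id vectors.
#' @export
partition_clusters <- function(partition, min_size = 1L) {
  stopifnot(inherits(partition, "landmark_partition"))
  cl <- partition$clusters
  cl[lengths(cl) >= min_size]
}
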