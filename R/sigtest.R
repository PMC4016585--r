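#' Intra- and inter-correlation value sets of clusters
#'
#' The significance layer works in correlation space, independent of the
#' contact mask: `intra_values` collects the entries among the `c(c-1)/2`
#' landmark pairs inside one cluster, `inter_values` the entries between
#' the `c_u * c_v` cross pairs of two disjoint clusters.  `values` may be a
#' symmetric `k x k` matrix (one value per pair, e.g. the `Xi` magnitudes
#' of [xi_aggregate()]) or a `k x k x D` array of per-dimension
#' correlations (one *signed* value per pair and dimension, e.g. the `raw`
#' array of [per_dimension_correlations()]); the pipeline tests the
#' latter.
#'
#' @param members,members_u,members_v landmark ids (or indices) of the
#'   cluster(s).
#' @param values symmetric `k x k` matrix or `k x k x D` array of
#'   correlation values.
#' @return Numeric vector of correlation values.
#' @export
intra_values <- function(members, values) {
  arr <- as_value_array(values)
  idx <- resolve_members(members, arr)
  if (length(idx) < 2L) return(numeric(0))
  ut <- upper.tri(matrix(0, length(idx), length(idx)))
  as.vector(apply(arr[idx, idx, , drop = FALSE], 3L, function(m) m[ut]))
}

#' @rdname intra_values
#' @export
inter_values <- function(members_u, members_v, values) {
  arr <- as_value_array(values)
  iu <- resolve_members(members_u, arr)
  iv <- resolve_members(members_v, arr)
  if (length(intersect(iu, iv)) > 0L)
    stop("clusters must be disjoint")
  as.vector(arr[iu, iv, , drop = FALSE])
}

as_value_array <- function(values) {
  if (inherits(values, "correlation_stack")) values <- values$raw
  if (is.matrix(values))
    values <- array(values, dim = c(dim(values), 1L),
                    dimnames = c(dimnames(values), list(NULL)))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  values
}

resolve_members <- function(members, m) {
  if (is.character(members)) {
    idx <- match(members, rownames(m))
    if (anyNA(idx)) stop("unknown landmark id(s): ",
                         paste(members[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(members)
}

# Welch t statistic from sufficient statistics; groups of size 1 contribute
# zero variance.  A zero standard error gives 0 for equal means and signed
# infinity otherwise, so the permutation distribution stays well defined.
welch_t_stat <- function(sa, qa, na, sb, qb, nb) {
  ma <- sa / na
  mb <- sb / nb
  va <- if (na > 1L) pmax((qa - na * ma^2) / (na - 1L), 0) else 0
  vb <- if (nb > 1L) pmax((qb - nb * mb^2) / (nb - 1L), 0) else 0
  se <- sqrt(va / na + vb / nb)
  d <- ma - mb
  ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
}

#' One-sided permutation t-test of two value sets
#'
#' Tests whether the values in `a` (intra-correlations) are larger on
#' average than those in `b` (inter-correlations) using the Welch two-sample
#' t statistic and its permutation distribution: the pooled values are
#' reshuffled between groups of the original sizes `B_perm` times, and
#' `p_raw = (1 + #\{t* >= t_obs\}) / (B_perm + 1)` (add-one rule, so p is
#' never 0 and is floored at `1/(B_perm + 1)`).
#'
#' @param a,b non-empty numeric vectors.
#' @param B_perm number of permutations (default 9999).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `t_obs` and `p_raw`.  When both groups are constant
#'   and equal the statistic carries no information and `p_raw = 1`.
#' @export
permutation_t_test <- function(a, b, B_perm = 9999L, seed = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("both value sets must be non-empty")
  if (!is.null(seed)) set.seed(as.integer(seed))
  na <- length(a); nb <- length(b); n <- na + nb
  x <- c(a, b)
  x2 <- x * x
  S <- sum(x); Q <- sum(x2)
  t_obs <- welch_t_stat(sum(a), sum(a^2), na, sum(b), sum(b^2), nb)
  if (is.nan(t_obs) || (t_obs == 0 && var(x) == 0))
    return(list(t_obs = 0, p_raw = 1))
  B_perm <- as.integer(B_perm)
  hits <- 0L
  for (i in seq_len(B_perm)) {
    idx <- sample.int(n, na)
    sa <- sum(x[idx]); qa <- sum(x2[idx])
    tp <- welch_t_stat(sa, qa, na, S - sa, Q - qa, nb)
    if (!is.nan(tp) && tp >= t_obs) hits <- hits + 1L
  }
  list(t_obs = t_obs, p_raw = (1 + hits) / (B_perm + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' package's single multiple-testing surface (the refinement runs
#' `K(K-1)` cluster-pair tests per iteration).
#'
#' @param p numeric vector of raw p-values (may be empty).
#' @return Adjusted p-values, capped at 1, monotone in rank.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Significance testing and refinement of a partition
#'
#' Each cluster pair `(u, v)` is tested with the one-sided permutation
#' t-test of `intra(u)` against `inter(u, v)` — the null hypothesis that the
#' mean intra-correlation of `u` equals the mean correlation between `u` and
#' `v`.  All `K(K-1)` raw p-values of an iteration are BH-adjusted; a
#' directed edge `u -> v` is drawn when the null is *not* rejected at
#' `alpha`, and every connected component of the bidirectional-edge subgraph
#' is merged simultaneously.  Testing and merging iterate until no
#' bidirectional edge remains: if the community step artificially split one
#' true module in two, neither half differs from their union and they merge
#' back; genuinely distinct modules reject in both directions and stay
#' apart.
#'
#' All size-1 clusters are pooled into one `"singletons"` pseudo-cluster
#' that participates in every test and is reported like a cluster, but is
#' never merged into a module (it is a reporting device, not a spatially
#' coherent group).
#'
#' The tested values are the *signed* raw per-dimension correlations (pass
#' a `correlation_stack` or its `raw` array).  The sign matters: community
#' detection groups landmarks with large `Xi`, so the magnitude of the
#' within-cluster correlations is elevated by selection even in pure noise
#' and a magnitude-based test would reject spuriously; signed chance
#' correlations cancel, which keeps the type-I rate of the layer at its
#' nominal level while genuinely co-moving (positively correlated) modules
#' still reject.  A `k x k` matrix of `Xi` magnitudes is also accepted for
#' comparison work.
#'
#' @param partition a `landmark_partition` from [fast_greedy_partition()].
#' @param values correlation values to test: a `correlation_stack`, its
#'   `k x k x D` raw array, or a symmetric `k x k` matrix (see
#'   [intra_values()]).
#' @param alpha FDR level for the merge decisions (default 0.05).
#' @param B_perm permutations per test (default 999).
#' @param seed optional integer seed for the permutation streams.
#' @return An object of class `refined_partition`: list with
#'   \describe{
#'     \item{clusters}{named list of landmark-id vectors, modules
#'       (`M1`, `M2`, ... by decreasing size) plus `singletons` if any;}
#'     \item{membership}{final cluster label per landmark;}
#'     \item{tests}{data.frame of every test run: `iteration`, `u`, `v`,
#'       `t_obs`, `p_raw`, `p_adj`, `reject`;}
#'     \item{significance}{per cluster, the largest adjusted p-value over
#'       its outgoing comparisons in the final iteration (a module is
#'       "significant" when every comparison rejects);}
#'     \item{n_iterations}{number of test iterations run.}
#'   }
#' @export
refine_partition <- function(partition, values, alpha = 0.05,
                             B_perm = 999L, seed = NULL) {
  stopifnot(inherits(partition, "landmark_partition"))
  values <- as_value_array(values)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cl <- partition$clusters
  singles <- unlist(cl[lengths(cl) == 1L], use.names = FALSE)
  ent <- cl[lengths(cl) >= 2L]
  names(ent) <- if (length(ent)) paste0("M", seq_along(ent)) else character(0)
  if (length(singles) > 0L) ent$singletons <- singles
  tests <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    K <- length(ent)
    if (K < 2L) break
    res <- test_all_pairs(ent, values, B_perm, iter)
    res$p_adj <- bh_adjust(res$p_raw)
    res$reject <- !is.na(res$p_adj) & res$p_adj <= alpha
    tests[[iter]] <- res
    merged <- merge_bidirectional(ent, res)
    if (length(merged) == length(ent)) break
    ent <- merged
  }
  finalize_refinement(ent, tests)
}

# Run the K(K-1) ordered pair tests for one refinement iteration.  A test
# whose "u" side has no intra values (a pool of < 2 members) is recorded
# with NA and treated as rejected, i.e. it never supports a merge.
test_all_pairs <- function(ent, values, B_perm, iter) {
  nm <- names(ent)
  K <- length(ent)
  out <- list()
  for (u in seq_len(K)) for (v in seq_len(K)) {
    if (u == v) next
    a <- intra_values(ent[[u]], values)
    b <- inter_values(ent[[u]], ent[[v]], values)
    r <- if (length(a) < 1L) list(t_obs = NA_real_, p_raw = NA_real_)
         else permutation_t_test(a, b, B_perm = B_perm)
    out[[length(out) + 1L]] <- data.frame(
      iteration = iter, u = nm[u], v = nm[v],
      t_obs = r$t_obs, p_raw = r$p_raw, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Merge the connected components of the bidirectional non-rejection graph.
# The singleton pool never takes part in a merge.
merge_bidirectional <- function(ent, res) {
  nm <- names(ent)
  mergeable <- nm[nm != "singletons"]
  if (length(mergeable) < 2L) return(ent)
  edge <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  keep <- !is.na(res$p_raw) & !res$reject
  edge[cbind(res$u[keep], res$v[keep])] <- TRUE
  bidir <- edge & t(edge)
  bidir[nm == "singletons", ] <- FALSE
  bidir[, nm == "singletons"] <- FALSE
  comp <- components_of(bidir)
  if (max(tabulate(comp)) < 2L) return(ent)
  new_ent <- lapply(split(seq_along(nm), comp),
                    function(ix) unlist(ent[ix], use.names = FALSE))
  pool <- which(vapply(split(nm, comp), function(s)
    identical(s, "singletons"), TRUE))
  names(new_ent) <- paste0("G", seq_along(new_ent))
  if (length(pool)) names(new_ent)[pool] <- "singletons"
  # stable module naming: biggest first
  mods <- new_ent[names(new_ent) != "singletons"]
  mods <- mods[order(-lengths(mods))]
  names(mods) <- paste0("M", seq_along(mods))
  c(mods, new_ent[names(new_ent) == "singletons"])
}

# Connected components of an undirected logical adjacency matrix.
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

finalize_refinement <- function(ent, tests) {
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(iteration = integer(0), u = character(0), v = character(0),
               t_obs = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
               reject = logical(0))
  mods <- ent[names(ent) != "singletons"]
  mods <- mods[order(-lengths(mods))]
  names(mods) <- if (length(mods)) paste0("M", seq_along(mods)) else character(0)
  clusters <- c(mods, ent[names(ent) == "singletons"])
  membership <- unlist(lapply(names(clusters), function(nm)
    structure(rep(nm, length(clusters[[nm]])), names = clusters[[nm]])))
  last <- tests[tests$iteration == max(c(tests$iteration, 0L)), , drop = FALSE]
  sig <- vapply(names(clusters), function(nm) {
    p <- last$p_adj[last$u == nm]
    if (length(p) == 0L || anyNA(p)) NA_real_ else max(p)
  }, 0)
  structure(list(clusters = clusters, membership = membership,
                 tests = tests, significance = sig,
                 n_iterations = max(c(tests$iteration, 0L))),
            class = "refined_partition")
}

#' @export
print.refined_partition <- function(x, ...) {
  cat(sprintf("refined_partition: %d cluster(s) after %d iteration(s)\n",
              length(x$clusters), x$n_iterations))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %-10s size %3d  max p_adj %s\n", nm,
                length(x$clusters[[nm]]),
                formatC(x$significance[[nm]], digits = 3, format = "g")))
  }
  invisible(x)
}
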