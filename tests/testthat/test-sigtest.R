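sym_matrix <- function(k, fill, ids = sprintf("L%03d", seq_len(k))) {
  m <- matrix(fill, k, k, dimnames = list(ids, ids))
  diag(m) <- 0
  m
}

test_that("intra and inter value sets have the right cardinality", {
  xi <- sym_matrix(40, 0.5)
  ids <- rownames(xi)
  expect_length(intra_values(ids[1:2], xi), 1L)
  expect_length(intra_values(ids[1:10], xi), 45L)
  expect_length(intra_values(ids[1:30], xi), 435L)
  expect_length(intra_values(ids[1], xi), 0L)
  expect_length(inter_values(ids[1:10], ids[11:20], xi), 100L)
  expect_error(inter_values(ids[1:3], ids[3:5], xi), "disjoint")
  # per-dimension arrays contribute one value per pair per dimension
  arr <- array(0.2, c(40, 40, 3), dimnames = list(ids, ids, NULL))
  expect_length(intra_values(ids[1:10], arr), 135L)
  expect_length(inter_values(ids[1:2], ids[3:4], arr), 12L)
})

test_that("permutation p-value matches exhaustive enumeration on 3+3", {
  a <- c(10, 11, 12); b <- c(0, 1, 2)
  # oracle: enumerate all C(6,3) = 20 assignments of the pooled values
  pooled <- c(a, b)
  t_for <- function(ix) {
    g1 <- pooled[ix]; g2 <- pooled[-ix]
    (mean(g1) - mean(g2)) / sqrt(var(g1) / 3 + var(g2) / 3)
  }
  t_obs <- t_for(1:3)
  t_all <- apply(combn(6, 3), 2, t_for)
  p_exact <- mean(t_all >= t_obs)
  expect_equal(p_exact, 1 / 20)
  res <- permutation_t_test(a, b, B_perm = 9999, seed = 1)
  expect_equal(res$t_obs, t_obs)
  expect_lt(abs(res$p_raw - p_exact), 0.015)
  # p is floored by the add-one rule and never 0
  expect_gte(res$p_raw, 1 / 10000)
})

test_that("degenerate and symmetric inputs give uninformative p-values", {
  expect_equal(permutation_t_test(c(.5, .5, .5), c(.5, .5, .5), 99)$p_raw, 1)
  res <- permutation_t_test(c(0, 1, 2), c(10, 11, 12), B_perm = 999, seed = 2)
  expect_gt(res$p_raw, 0.9)   # one-sided: a below b is never significant
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.5, 5)), rep(0.5, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))   # monotone in rank
})

test_that("an artificially split block is merged back", {
  ens <- sample_ensemble(list(c(20, 0.6)), n_noise = 0, dims = 2,
                         n_obs = 100, seed = 11)
  st <- fisher_filter(per_dimension_correlations(ens))
  ids <- ens$landmark_ids
  memb <- setNames(rep(1:2, each = 10), ids)   # split the true block in two
  part <- modulyzer:::new_partition(memb, build_graph(xi_aggregate(st))$weights)
  ref <- refine_partition(part, st, B_perm = 499, seed = 1)
  expect_equal(length(ref$clusters), 1L)
  expect_setequal(ref$clusters[[1]], ids)
  expect_gte(ref$n_iterations, 1L)
})

test_that("independent strongly-correlated blocks are never merged", {
  kept <- vapply(1:10, function(s) {
    ens <- sample_ensemble(list(c(15, 0.8), c(15, 0.8)), n_noise = 0,
                           dims = 2, n_obs = 85, seed = 200 + s)
    st <- fisher_filter(per_dimension_correlations(ens))
    g <- build_graph(xi_aggregate(st))
    ref <- refine_partition(fast_greedy_partition(g), st,
                            B_perm = 199, seed = s)
    length(ref$clusters)
  }, 0L)
  expect_true(all(kept >= 2L))
})

test_that("a one-directional non-rejection does not merge", {
  # u is tightly correlated while v sits below the inter level, so u -> v
  # rejects (intra >> inter) and v -> u cannot (intra < inter): exactly one
  # direction is non-rejected, which must not merge
  set.seed(8)
  k <- 12
  xi <- sym_matrix(k, 0)
  ids <- rownames(xi)
  u <- ids[1:6]; v <- ids[7:12]
  xi[u, u] <- 0.8 + rnorm(36, 0, 0.01)
  xi[v, v] <- abs(rnorm(36, 0, 0.005))
  xi[u, v] <- 0.1 + abs(rnorm(36, 0, 0.01))
  xi <- (xi + t(xi)) / 2; diag(xi) <- 0
  memb <- setNames(rep(1:2, each = 6), ids)
  part <- modulyzer:::new_partition(memb, xi)
  ref <- refine_partition(part, xi, B_perm = 499, seed = 3)
  expect_equal(length(ref$clusters), 2L)
  tests <- ref$tests
  expect_true(any(tests$reject))         # u -> v rejected
  expect_true(any(!tests$reject))        # v -> u not rejected
})

test_that("refinement output is internally consistent", {
  ens <- sample_ensemble(list(c(10, 0.5)), n_noise = 20, dims = 2,
                         n_obs = 85, seed = 21)
  st <- fisher_filter(per_dimension_correlations(ens))
  g <- build_graph(xi_aggregate(st))
  part <- fast_greedy_partition(g)
  ref <- refine_partition(part, st, B_perm = 199, seed = 5)
  # the clusters partition the landmark set
  expect_setequal(unlist(ref$clusters), ens$landmark_ids)
  expect_equal(anyDuplicated(unlist(ref$clusters)), 0L)
  # adjusted p never below raw p; iterations bounded by initial cluster count
  ok <- !is.na(ref$tests$p_raw)
  expect_true(all(ref$tests$p_adj[ok] >= ref$tests$p_raw[ok]))
  expect_lte(ref$n_iterations, length(part$clusters))
  # cluster count never increases through refinement
  expect_lte(length(ref$clusters), length(part$clusters))
})
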