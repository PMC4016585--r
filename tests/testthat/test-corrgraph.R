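# direct construction of a correlation stack for exact-value tests
manual_stack <- function(raw, n_obs) {
  k <- dim(raw)[1]
  ids <- dimnames(raw)[[1]] %||% sprintf("L%03d", seq_len(k))
  dimnames(raw) <- list(ids, ids, NULL)
  structure(list(raw = raw, filtered = NULL, n_obs = n_obs, alpha = NULL,
                 landmark_ids = ids, dims = dim(raw)[3]),
            class = "correlation_stack")
}

test_that("per-dimension correlations capture exact linear relations", {
  n <- 20
  x <- rnorm(n)
  # landmark 2 duplicates landmark 1; landmark 3 is its mirror image
  vals <- cbind(x, rnorm(n), x, rnorm(n), -x, rnorm(n))
  ens <- coord_ensemble(vals, c("a", "b", "c"), dims = 2)
  st <- per_dimension_correlations(ens)
  expect_equal(st$raw[1, 2, 1], 1)
  expect_equal(st$raw[1, 3, 1], -1)
  expect_equal(diag(st$raw[, , 1]), setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(st$raw[, , 1], t(st$raw[, , 1]))
})

test_that("constant coordinates give zero correlation with a warning", {
  vals <- cbind(rnorm(10), rnorm(10), rep(2, 10), rnorm(10))
  ens <- coord_ensemble(vals, c("a", "b"), dims = 2)
  expect_warning(st <- per_dimension_correlations(ens), "constant")
  expect_equal(st$raw[1, 2, 1], 0)
  expect_equal(st$raw[2, 2, 1], 1)
})

test_that("Fisher filter applies the two-sided z criterion", {
  # n = 85: critical |atanh r| is 1.95996/sqrt(82) = 0.21644, i.e. |r| >= 0.21312
  raw <- array(0, c(2, 2, 3))
  raw[1, 2, ] <- raw[2, 1, ] <- c(0.30, 0.10, -0.30)
  raw[1, 1, ] <- raw[2, 2, ] <- 1
  st <- fisher_filter(manual_stack(raw, n_obs = 85), alpha = 0.05)
  expect_equal(st$filtered[1, 2, 1], 0.30)   # atanh(.30)=0.3095 >= 0.2164
  expect_equal(st$filtered[1, 2, 2], 0)      # atanh(.10)=0.1003 <  0.2164
  expect_equal(st$filtered[1, 2, 3], -0.30)  # negative correlations survive
  # |r| = 1 is always kept
  raw1 <- array(1, c(2, 2, 1))
  expect_equal(fisher_filter(manual_stack(raw1, 10))$filtered[1, 2, 1], 1)
})

test_that("Fisher filter is monotone in alpha", {
  set.seed(5)
  raw <- array(0, c(6, 6, 2))
  for (d in 1:2) {
    m <- matrix(0, 6, 6)
    m[upper.tri(m)] <- runif(15, -0.6, 0.6)
    m <- m + t(m); diag(m) <- 1
    raw[, , d] <- m
  }
  st <- manual_stack(raw, n_obs = 60)
  for (pair in list(c(0.01, 0.05), c(0.05, 0.2), c(0.1, 0.5))) {
    lo <- fisher_filter(st, alpha = pair[1])$filtered != 0
    hi <- fisher_filter(st, alpha = pair[2])$filtered != 0
    expect_true(all(hi[lo]))   # raising alpha never removes a kept entry
  }
})

test_that("xi aggregation is the euclidean magnitude of the filtered vector", {
  filt <- array(0, c(2, 2, 3))
  filt[1, 2, ] <- filt[2, 1, ] <- c(0.3, 0.4, 0)
  xi <- xi_aggregate(filt)
  expect_equal(xi[1, 2], 0.5)            # 3-4-5 triple
  expect_equal(diag(xi), rep(0, 2))
  filt[1, 2, ] <- filt[2, 1, ] <- c(-0.7, 0, 0)
  expect_equal(xi_aggregate(filt)[1, 2], 0.7)   # single-dimension |r|
  filt[1, 2, ] <- filt[2, 1, ] <- c(0, 0, 0)
  expect_equal(xi_aggregate(filt)[1, 2], 0)
  # bound: Xi <= sqrt(D), equality only when every dimension has |r| = 1
  filt[1, 2, ] <- filt[2, 1, ] <- c(1, -1, 1)
  expect_equal(xi_aggregate(filt)[1, 2], sqrt(3))
})

test_that("edges require both positive xi and contact", {
  xi <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  g_all <- build_graph(xi, contacts = NULL)
  expect_equal(nrow(graph_edges(g_all)), 1L)
  contacts <- matrix(FALSE, 2, 2)
  g_masked <- build_graph(xi, contacts = contacts)
  expect_equal(nrow(graph_edges(g_masked)), 0L)
  expect_equal(g_masked$xi_matrix[1, 2], 0.5)  # xi retained contact-free
  g_zero <- build_graph(matrix(0, 2, 2), contacts = NULL,
                        landmark_ids = c("a", "b"))
  expect_equal(sum(g_zero$weights), 0)
  expect_equal(length(g_zero$landmark_ids), 2L)  # isolated nodes retained
})

test_that("on pure noise the filter survival rate is close to alpha", {
  rates <- vapply(1:5, function(s) {
    ens <- sample_ensemble(list(), n_noise = 40, dims = 2, n_obs = 200,
                           seed = 100 + s)
    st <- fisher_filter(per_dimension_correlations(ens), alpha = 0.05)
    off <- upper.tri(st$filtered[, , 1])
    mean(c(st$filtered[, , 1][off], st$filtered[, , 2][off]) != 0)
  }, 0)
  expect_lt(abs(mean(rates) - 0.05), 0.025)  # within 50% relative
})
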