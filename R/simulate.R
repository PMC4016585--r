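#' Block correlation matrix for multivariate-normal simulation
#'
#' Constructs the correlation matrix of a coordinate ensemble with planted
#' modules: each block of landmarks shares one uniform correlation `rho`
#' across *all* of its `n_landmarks * dims` variables (the X coordinate of
#' one landmark correlates with the Y coordinate of another landmark of the
#' same block just as strongly), while noise landmarks and all cross-block
#' entries are uncorrelated.  With one 30-landmark block, 70 noise landmarks
#' and `dims = 2`, the leading 60 x 60 sub-matrix carries `rho` off the
#' diagonal and the remaining 140 variables are independent.
#'
#' @param blocks list of blocks; each block is a numeric vector
#'   `c(n_landmarks, rho)` with `n_landmarks >= 1` and `rho` in `[0, 1]`.
#'   May be empty.
#' @param n_noise number of uncorrelated noise landmarks appended after the
#'   blocks.
#' @param dims spatial dimensions per landmark (default 2).
#' @return A symmetric positive semi-definite matrix with unit diagonal of
#'   size `(sum(block sizes) + n_noise) * dims`.
#' @examples
#' R <- build_correlation_matrix(list(c(2, 0.5)), n_noise = 1, dims = 1)
#' @export
build_correlation_matrix <- function(blocks = list(), n_noise = 0L, dims = 2L) {
  blocks <- validate_blocks(blocks)
  n_noise <- as.integer(n_noise)
  dims <- as.integer(dims)
  if (n_noise < 0L) stop("'n_noise' must be non-negative")
  if (dims < 1L) stop("'dims' must be a positive integer")
  sizes <- vapply(blocks, `[`, 0, 1L) * dims
  p <- as.integer(sum(sizes) + n_noise * dims)
  if (p == 0L) stop("simulation must contain at least one variable")
  R <- diag(p)
  at <- 0L
  for (b in blocks) {
    nb <- as.integer(b[1L] * dims)
    idx <- at + seq_len(nb)
    R[idx, idx] <- b[2L]
    at <- at + nb
  }
  diag(R) <- 1
  R
}

validate_blocks <- function(blocks) {
  if (is.null(blocks)) return(list())
  if (is.numeric(blocks) && length(blocks) == 2L) blocks <- list(blocks)
  if (!is.list(blocks)) stop("'blocks' must be a list of c(size, rho) pairs")
  for (b in blocks) {
    if (length(b) != 2L || !is.numeric(b))
      stop("each block must be a numeric vector c(n_landmarks, rho)")
    if (b[1L] < 1 || b[1L] != floor(b[1L]))
      stop("block size must be a positive integer")
    if (b[2L] < 0 || b[2L] > 1)
      stop("block correlation must lie in [0, 1]")
  }
  blocks
}

#' Simulate a multivariate-normal coordinate ensemble
#'
#' Draws `n_obs` observations as `L y`, where `y` is a vector of independent
#' standard normal variates and `L L^T` equals the block correlation matrix
#' of [build_correlation_matrix()].  For `rho < 1` the Cholesky factor is
#' used; a block at `rho = 1` makes the matrix singular, in which case a
#' symmetric eigendecomposition factor with negative eigenvalues clipped at
#' zero is used instead, so the degenerate case samples exactly (all block
#' variables identical).
#'
#' @inheritParams build_correlation_matrix
#' @param n_obs number of observations to draw (at least 4).
#' @param seed integer seed; identical seeds give bitwise-identical
#'   ensembles.  `NULL` uses the current RNG stream.
#' @param prefix prefix for the generated landmark ids.
#' @return A [coord_ensemble()] with block landmarks first, then noise
#'   landmarks.
#' @examples
#' ens <- sample_ensemble(list(c(5, 0.8)), n_noise = 5, n_obs = 50, seed = 1)
#' @export
sample_ensemble <- function(blocks = list(), n_noise = 0L, dims = 2L,
                            n_obs, seed = NULL, prefix = "L") {
  blocks <- validate_blocks(blocks)
  n_obs <- as.integer(n_obs)
  if (n_obs < 4L) stop("'n_obs' must be at least 4")
  R <- build_correlation_matrix(blocks, n_noise, dims)
  p <- ncol(R)
  L <- tryCatch(t(chol(R)), error = function(e) {
    eg <- eigen(R, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- matrix(rnorm(n_obs * p), n_obs, p)
  values <- y %*% t(L)
  k <- p %/% as.integer(dims)
  ids <- sprintf("%s%0*d", prefix, max(3L, nchar(k)), seq_len(k))
  coord_ensemble(values, ids, dims)
}

#' Landmark ids belonging to each simulated block
#'
#' Convenience accessor mirroring the id layout of [sample_ensemble()]:
#' block landmarks come first, in block order, followed by noise landmarks.
#'
#' @inheritParams build_correlation_matrix
#' @param prefix prefix used when the ensemble was generated.
#' @return A list with one character vector of landmark ids per block and,
#'   if `n_noise > 0`, a final element `noise`.
#' @export
block_landmarks <- function(blocks = list(), n_noise = 0L, prefix = "L") {
  blocks <- validate_blocks(blocks)
  sizes <- vapply(blocks, `[`, 0, 1L)
  k <- as.integer(sum(sizes) + n_noise)
  ids <- sprintf("%s%0*d", prefix, max(3L, nchar(k)), seq_len(k))
  out <- list()
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[paste0("block", i)]] <- ids[at + seq_len(sizes[i])]
    at <- at + sizes[i]
  }
  if (n_noise > 0L) out$noise <- ids[(at + 1L):k]
  out
}
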