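#' Minimum resolvable correlation for a given sample size
#'
#' Under the Fisher-z approximation, the smallest true correlation that a
#' two-sided level-`alpha` test detects with probability `power` from
#' `n_obs` observations is
#' `rho_res = tanh( (z_{1-alpha/2} + z_{power}) / sqrt(n_obs - 3) )`.
#' It is strictly decreasing in `n_obs`: about 0.28 at 100 observations
#' (`alpha = 0.05`, `power = 0.8`) and below 0.005 at a million.
#'
#' @param n_obs number of observations (must exceed 3).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power `1 - beta` (default 0.8).
#' @return The minimum resolvable correlation, in `(0, 1)`.
#' @export
resolvable_correlation <- function(n_obs, alpha = 0.05, power = 0.8) {
  if (any(n_obs <= 3)) stop("'n_obs' must exceed 3")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("'power' must lie in (0, 1)")
  tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n_obs - 3))
}

#' Power indicator for a correlation entry
#'
#' `gamma = 1` when the entry is resolvable at the configured power, i.e.
#' `|r| >= rho_res` (two-sided: a strong negative correlation is just as
#' resolvable as a positive one), else 0.  The boundary `|r| == rho_res`
#' counts as resolvable.
#'
#' @param r correlation value(s).
#' @param rho_res minimum resolvable correlation from
#'   [resolvable_correlation()].
#' @return Integer vector of 0/1 indicators.
#' @export
power_gamma <- function(r, rho_res) {
  as.integer(abs(r) >= rho_res)
}

#' Proportion of variables with enough power (PVP) of a cluster
#'
#' For a cluster with `c` elements, PVP is the fraction of its pairwise
#' correlation entries whose magnitude reaches `rho_res`:
#' `PVP = 2 * sum(gamma) / (c^2 - c)` over the upper triangle, averaged
#' across spatial dimensions when a per-dimension stack is supplied.  The
#' indicator is evaluated on the raw per-dimension correlations (one entry
#' per pair and dimension), the convention that reproduces both the
#' near-zero PVP of pooled noise singletons and intermediate PVP values for
#' weakly correlated modules at small sample sizes.  PVP is a post-hoc
#' diagnostic: it reports how much of the cluster the sample size had power
#' to resolve, not a test.
#'
#' @param members landmark ids (or indices) of the cluster.
#' @param correlations a `correlation_stack` (its raw array is used), a
#'   `k x k x dims` array, or a symmetric `k x k` matrix of correlations.
#' @param rho_res minimum resolvable correlation.
#' @return PVP in `[0, 1]`.  A cluster with fewer than 2 members has no
#'   pairs; 0 is returned with a warning.
#' @export
cluster_pvp <- function(members, correlations, rho_res) {
  arr <- if (inherits(correlations, "correlation_stack")) correlations$raw
         else correlations
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L),
                                   dimnames = c(dimnames(arr), list(NULL)))
  stopifnot(length(dim(arr)) == 3L)
  rn <- dimnames(arr)[[1L]]
  idx <- if (is.character(members)) {
    i <- match(members, rn)
    if (anyNA(i)) stop("unknown landmark id(s)")
    i
  } else as.integer(members)
  cc <- length(idx)
  if (cc < 2L) {
    warning("PVP is undefined for clusters with fewer than 2 members; returning 0")
    return(0)
  }
  ut <- upper.tri(matrix(0, cc, cc))
  vals <- apply(arr[idx, idx, , drop = FALSE], 3L, function(m) m[ut])
  mean(power_gamma(vals, rho_res))
}
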