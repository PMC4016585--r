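#' Coordinate ensemble container
#'
#' An ensemble of `n_obs` observations of `k` landmarks, each landmark
#' carrying `dims` spatial coordinates.  Columns of `values` are ordered
#' landmark-major (`L1_1, L1_2, ..., L2_1, ...`), so in a `dims = 2`
#' simulation a block of 30 landmarks occupies the first 60 variables.
#'
#' @param values numeric matrix, `n_obs` rows by `k * dims` columns, no
#'   missing entries.
#' @param landmark_ids character vector of `k` unique landmark labels.
#' @param dims number of spatial dimensions per landmark (2 for the planar
#'   simulations, 3 for structural data).
#' @return An object of class `coord_ensemble`: a list with elements
#'   `values`, `landmark_ids`, `dims` and `n_obs`.
#' @seealso [sample_ensemble()], [compute_landmarks()]
#' @export
coord_ensemble <- function(values, landmark_ids, dims) {
  values <- as.matrix(values)
  dims <- as.integer(dims)
  landmark_ids <- as.character(landmark_ids)
  k <- length(landmark_ids)
  if (dims < 1L) stop("'dims' must be a positive integer")
  if (ncol(values) != k * dims)
    stop("ncol(values) must equal length(landmark_ids) * dims")
  if (anyDuplicated(landmark_ids))
    stop("landmark ids must be unique")
  if (anyNA(values) || !all(is.finite(values)))
    stop("ensemble values must be finite with no missing entries")
  if (nrow(values) < 4L)
    stop("at least 4 observations are required (Fisher filter needs n - 3 > 0)")
  colnames(values) <- paste(rep(landmark_ids, each = dims),
                            rep(seq_len(dims), times = k), sep = "_")
  structure(list(values = values, landmark_ids = landmark_ids,
                 dims = dims, n_obs = nrow(values)),
            class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("coord_ensemble: %d observations x %d landmarks x %d dims\n",
              x$n_obs, length(x$landmark_ids), x$dims))
  invisible(x)
}

# n_obs x k matrix holding coordinate d of every landmark.
dimension_matrix <- function(ens, d) {
  stopifnot(inherits(ens, "coord_ensemble"), d >= 1L, d <= ens$dims)
  idx <- seq(from = d, by = ens$dims,
             length.out = length(ens$landmark_ids))
  m <- ens$values[, idx, drop = FALSE]
  colnames(m) <- ens$landmark_ids
  m
}

#' Read and write coordinate ensembles as CSV
#'
#' One row per observation; column names follow the `<landmark>_<dim>`
#' convention of [coord_ensemble()], with a header row.
#'
#' @param ens a `coord_ensemble`.
#' @param path file path.
#' @return `write_ensemble_csv` returns `path` invisibly;
#'   `read_ensemble_csv` returns a `coord_ensemble`.
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "coord_ensemble"))
  write.csv(as.data.frame(ens$values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  cols <- colnames(df)
  m <- regmatches(cols, regexec("^(.*)_([0-9]+)$", cols))
  if (any(lengths(m) != 3L))
    stop("column names must follow the '<landmark>_<dim>' convention")
  ids <- unique(vapply(m, `[`, "", 2L))
  dims <- max(as.integer(vapply(m, `[`, "", 3L)))
  expected <- paste(rep(ids, each = dims), rep(seq_len(dims), length(ids)),
                    sep = "_")
  if (!identical(cols, expected))
    stop("columns are not in landmark-major order with a complete set of dims")
  coord_ensemble(as.matrix(df), ids, dims)
}

# Resample observations with replacement (used by the bootstrap).
resample_ensemble <- function(ens, idx) {
  out <- ens
  out$values <- ens$values[idx, , drop = FALSE]
  out$n_obs <- length(idx)
  out
}
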