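#' Gaussian random-projection matrix
#'
#' Builds a d x k matrix with entries drawn i.i.d. from N(0, 1/k). With this
#' variance the projection `Y = X R` approximately preserves pairwise
#' Euclidean distances (Johnson-Lindenstrauss): for a unit-norm row x,
#' E||xR||^2 = 1.
#'
#' @param d Input dimensionality (number of genes), positive integer.
#' @param k Target dimensionality, positive integer. A warning (not an
#'   error) is raised when `k >= d`, where projection is pointless.
#' @param seed Integer seed fully determining the entries.
#' @return An object of class `rp_matrix`: the d x k matrix with `d`, `k`
#'   and `seed` attributes.
#' @export
rp_matrix <- function(d, k, seed) {
  if (!is_count(d)) stopf("`d` must be a positive integer, got %s", format(d))
  if (!is_count(k)) stopf("`k` must be a positive integer, got %s", format(k))
  if (k >= d) warnf("target dimension k = %d is not smaller than d = %d", k, d)
  entries <- with_seed(seed, matrix(stats::rnorm(d * k, mean = 0, sd = sqrt(1 / k)), d, k))
  structure(entries, d = as.integer(d), k = as.integer(k), seed = as.integer(seed),
            class = c("rp_matrix", "matrix", "array"))
}

#' Project an expression matrix with a random-projection matrix
#'
#' Exact matrix product `Y = X R`, mapping n x d data to n x k.
#'
#' @param X Numeric matrix (samples x genes), typically stage-`"log"`.
#' @param R An [rp_matrix()].
#' @return Numeric n x k matrix with `X`'s rownames.
#' @export
rp_project <- function(X, R) {
  if (ncol(X) != nrow(R))
    stopf("dimension mismatch: X is %d x %d but R is %d x %d",
          nrow(X), ncol(X), nrow(R), ncol(R))
  Y <- as_plain_matrix(X) %*% unclass(R)
  rownames(Y) <- rownames(X)
  Y
}

#' Fuse multiple independent random projections
#'
#' Generates `m` independent Gaussian projection matrices with seeds
#' `base_seed + 0, ..., base_seed + m - 1`, projects `X` with each, and
#' concatenates the m blocks of k columns in seed order.
#'
#' @param X Numeric matrix (samples x genes).
#' @param k Target dimensionality per projection.
#' @param m Number of independent projections, `m >= 1`.
#' @param base_seed Integer; seed of block i is `base_seed + i - 1`.
#' @return An object of class `fused_features`: an n x (m*k) matrix with
#'   attributes `k`, `m`, `source_seeds` and `block_boundaries` (a list of
#'   column-index ranges per source projection).
#' @export
fuse_projections <- function(X, k, m, base_seed) {
  if (!is_count(m)) stopf("`m` must be a positive integer")
  d <- ncol(X)
  seeds <- as.integer(base_seed) + seq_len(m) - 1L
  blocks <- vector("list", m)
  for (i in seq_len(m)) {
    blocks[[i]] <- rp_project(X, rp_matrix(d, k, seeds[i]))
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- paste0("rp", rep(seq_len(m), each = k), "_", rep(seq_len(k), m))
  boundaries <- lapply(seq_len(m), function(i) c(from = (i - 1L) * k + 1L, to = i * k))
  structure(out, k = as.integer(k), m = as.integer(m), source_seeds = seeds,
            block_boundaries = boundaries,
            class = c("fused_features", "matrix", "array"))
}

#' Pairwise distance preservation between two representations
#'
#' Computes all n(n-1)/2 pairwise Euclidean distances within `A` and within
#' `B` (rows paired in the same (i < j) order) and returns their Pearson
#' correlation together with the paired distance vectors for plotting the
#' distance-fitting curve. Used to quantify how faithfully a reduced
#' representation `B` preserves the sample-to-sample geometry of `A`; any
#' externally reduced matrix (PCA scores, UMAP embedding, ...) can be passed
#' as `B`.
#'
#' @param A Numeric matrix, n x p (e.g. the original data).
#' @param B Numeric matrix, n x q with the same rows (e.g. the projection).
#' @return An object of class `rps_distcheck`: list with `correlation` and a
#'   data.frame `pairs` (`pair_id`, `dist_original`, `dist_reduced`). If
#'   either distance vector has zero variance the correlation is defined as
#'   0 with a warning.
#' @export
distance_preservation <- function(A, B) {
  if (nrow(A) != nrow(B))
    stopf("A and B must have the same number of rows (%d vs %d)", nrow(A), nrow(B))
  n <- nrow(A)
  if (n < 3) stopf("need at least 3 rows to correlate pairwise distances")
  da <- as.vector(stats::dist(as_plain_matrix(A)))
  db <- as.vector(stats::dist(as_plain_matrix(B)))
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warnf("zero variance in a pairwise-distance vector; correlation defined as 0")
    r <- 0
  } else {
    r <- stats::cor(da, db)
  }
  # stats::dist emits pairs column-major: (2,1),(3,1),...,(n,1),(3,2),...
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_id <- paste0(idx[, 2], "-", idx[, 1])
  structure(list(correlation = r,
                 pairs = data.frame(pair_id = pair_id, dist_original = da,
                                    dist_reduced = db)),
            class = "rps_distcheck")
}

#' @export
print.rps_distcheck <- function(x, ...) {
  cat(sprintf("distance preservation over %d pairs: Pearson r = %.4f\n",
              nrow(x$pairs), x$correlation))
  invisible(x)
}

#' @export
plot.rps_distcheck <- function(x, ...) {
  plot(x$pairs$dist_original, x$pairs$dist_reduced,
       xlab = "pairwise distance (original)",
       ylab = "pairwise distance (reduced)",
       main = sprintf("distance-fitting curve (r = %.3f)", x$correlation),
       pch = 20, col = grDevices::adjustcolor("steelblue", 0.4), ...)
  graphics::abline(stats::lm(x$pairs$dist_reduced ~ x$pairs$dist_original),
                   col = "firebrick")
  invisible(x)
}
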