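#' Principal component analysis of reduced conformational coordinates
#'
#' Fits PCA (via [stats::prcomp()]) to a sample of reduced coordinates
#' \eqn{x \in R^5}. The returned basis holds the orthogonal loading matrix
#' `W` (columns = principal directions, ordered by decreasing variance), the
#' per-direction standard deviations \eqn{\sigma_1 \ge \dots \ge \sigma_5}
#' (square roots of covariance eigenvalues, 1/(K-1) normalization), and the
#' sample mean. Column signs are fixed so each column's largest-magnitude
#' entry is positive, making the basis reproducible across platforms.
#'
#' In low-energy docking clusters most of the variability concentrates in the
#' first three principal directions (the smooth "permissive" subspace); the
#' remaining directions are steep and "restrictive".
#'
#' @param x A data frame or matrix of reduced coordinates (rows = samples);
#'   at least 2 rows. Zero-variance directions are permitted.
#' @param scale. Optionally z-score columns before PCA (default `FALSE`).
#' @return An object of class `pca_basis` with elements `W`, `sigma`, `xbar`,
#'   `scale`, `n`.
#' @export
fit_pca <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_ssdu("PCA needs at least 2 samples")
  if (any(!is.finite(x))) stop_ssdu("reduced coordinates must be finite")
  scl <- rep(1, ncol(x))
  if (isTRUE(scale.)) {
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
  }
  p <- prcomp(x, center = TRUE, scale. = if (isTRUE(scale.)) scl else FALSE)
  W <- p$rotation
  # deterministic sign convention
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = unname(W), sigma = unname(p$sdev),
                 xbar = unname(p$center), scale = unname(scl),
                 n = nrow(x)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis> p =", length(x$sigma), " sigma =",
      paste(signif(x$sigma, 4), collapse = " "), "\n")
  invisible(x)
}

coord_matrix <- function(x, p) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.double(x), ncol = p)
  if (ncol(x) != p) stop_ssdu("expected ", p, " coordinates per row")
  x
}

#' Transform to and from principal coordinates
#'
#' `to_principal()` maps reduced coordinates to principal coordinates
#' \eqn{z = W'(x - \bar x)}; `from_principal()` is its inverse
#' \eqn{x = W z + \bar x}. Both accept single vectors or row-wise matrices /
#' data frames and return matrices with one row per sample.
#'
#' @param basis A [fit_pca()] basis.
#' @param x,z Coordinates (vector, matrix, or data frame).
#' @return A numeric matrix, rows = samples.
#' @export
to_principal <- function(basis, x) {
  x <- coord_matrix(x, length(basis$sigma))
  x <- sweep(x, 2, basis$xbar)
  x <- sweep(x, 2, basis$scale, `/`)
  x %*% basis$W
}

#' @rdname to_principal
#' @export
from_principal <- function(basis, z) {
  z <- coord_matrix(z, length(basis$sigma))
  x <- z %*% t(basis$W)
  x <- sweep(x, 2, basis$scale, `*`)
  sweep(x, 2, basis$xbar, `+`)
}

#' Permissive-subspace coordinates
#'
#' Keeps the first `dim` principal coordinates (default 3), i.e. the
#' projection of `z` onto the permissive subspace spanned by the
#' leading principal directions.
#'
#' @param z Principal coordinates (vector, matrix, or data frame).
#' @param dim Permissive dimension, 2 or 3 (default 3).
#' @return A matrix with `dim` columns.
#' @export
permissive <- function(z, dim = 3) {
  if (!dim %in% c(2, 3)) stop_ssdu("permissive dimension must be 2 or 3")
  if (is.data.frame(z)) z <- as.matrix(z)
  if (!is.matrix(z)) z <- matrix(as.double(z), nrow = 1)
  z[, seq_len(dim), drop = FALSE]
}

#' Fraction of variance explained by the leading principal directions
#'
#' \eqn{(\sum_{i \le k} \sigma_i^2) / (\sum_i \sigma_i^2)}. For docking
#' clusters with a genuine permissive subspace this exceeds 0.75 at k = 3.
#'
#' @param basis A [fit_pca()] basis.
#' @param k Number of leading directions, between 1 and the dimension.
#' @return A fraction between 0 and 1.
#' @export
explained_fraction <- function(basis, k) {
  p <- length(basis$sigma)
  if (k < 1 || k > p) stop_ssdu("`k` must be in 1..", p)
  tot <- sum(basis$sigma^2)
  if (tot == 0) stop_ssdu("all directions have zero variance")
  sum(basis$sigma[seq_len(k)]^2) / tot
}

#' Principal angles between two subspaces
#'
#' Angles (degrees) between the column spans of `U` and `V`, from the
#' singular values of \eqn{Q_U' Q_V}. Used to check that a recovered
#' permissive subspace aligns with a planted one.
#'
#' @param U,V Matrices whose columns span the subspaces.
#' @return Numeric vector of principal angles in degrees, increasing.
#' @export
principal_angles <- function(U, V) {
  qu <- qr.Q(qr(as.matrix(U)))
  qv <- qr.Q(qr(as.matrix(V)))
  s <- svd(crossprod(qu, qv))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}
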