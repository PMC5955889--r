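#' Fit an SOS-convex polynomial underestimator
#'
#' Finds the degree-`degree` polynomial \eqn{U} minimizing the total gap
#' \eqn{\sum_i [f_i - U(\phi_i)]} subject to \eqn{U(\phi_i) \le f_i} at every
#' sample and SOS-convexity of \eqn{U} (the Hessian biform
#' \eqn{y'\nabla^2 U(\phi)\,y} admits a sum-of-squares representation with a
#' positive semidefinite Gram matrix) — a tractable certificate of convexity
#' checked by semidefinite programming. The tight convex envelope of a
#' funnel's sampled local minima approximates the funnel bottom; its global
#' minimum is where sampling is subsequently concentrated.
#'
#' Data are preconditioned before the SDP (coordinates centered and scaled to
#' unit standard deviation, energies shifted to minimum zero and scaled by
#' their standard deviation) and the optimum is mapped back exactly, so the
#' returned coefficients are in the original coordinates. A small ridge
#' (`1e-9` on the squared coefficient norm) breaks ties deterministically in
#' underdetermined fits.
#'
#' @param phi Sample points: a matrix or data frame with one row per sample
#'   (typically 3 permissive coordinates).
#' @param f Energies at the samples (finite, same length).
#' @param degree Even polynomial degree, one of 2, 4, 6 (default 4).
#' @param tol Underestimation feasibility tolerance on the original scale.
#' @return An object of class `underestimator` with fields `coeffs` (original
#'   coordinates), `exponents`, `transform`, `gram` + `gram_basis` (the
#'   SOS-convexity certificate, in preconditioned coordinates), and `fit`
#'   (per-sample gaps, total gap, solver status). Supports [predict()],
#'   [tidy()], [glance()], [poly_gradient()], [poly_hessian()],
#'   [minimize_convex()].
#' @examples
#' phi <- matrix(rnorm(60), 20, 3)
#' f <- rowSums(phi^2) + 1
#' U <- fit_underestimator(phi, f, degree = 2)
#' glance(U)
#' @export
fit_underestimator <- function(phi, f, degree = 4, tol = 1e-6) {
  phi <- as.matrix(phi)
  f <- as.double(f)
  K <- nrow(phi)
  if (K == 0) stop_ssdu("no sample points")
  if (length(f) != K || any(!is.finite(f)) || any(!is.finite(phi)))
    stop_ssdu("`phi` and `f` must be finite and of matching length")
  n <- ncol(phi)
  if (!degree %in% c(2, 4, 6)) stop_ssdu("`degree` must be 2, 4 or 6")
  st <- sos_structure(n, degree)
  if (K < st$m)
    warning("fewer samples (", K, ") than coefficients (", st$m,
            "); fit is underdetermined", call. = FALSE)

  center <- colMeans(phi)
  scale <- apply(phi, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  f_shift <- min(f)
  f_scale <- sd(f)
  if (!is.finite(f_scale) || f_scale == 0) f_scale <- 1
  phi_s <- sweep(sweep(phi, 2, center), 2, scale, `/`)
  f_s <- (f - f_shift) / f_scale

  Phi <- design_matrix(phi_s, st$E_U)
  sol <- sdp_underestimate(st, Phi, f_s, relaxed = degree >= 6)

  coeffs_std <- sol$cc
  coeffs <- affine_pullback(coeffs_std, st$E_U, center, scale,
                            f_scale = f_scale, f_shift = f_shift)
  gaps <- sol$slacks * f_scale
  ev_g <- eigen(sol$G, symmetric = TRUE, only.values = TRUE)$values
  obj <- structure(list(
    n = n, degree = degree, exponents = st$E_U,
    coeffs = coeffs, coeffs_std = coeffs_std,
    transform = list(center = center, scale = scale,
                     f_shift = f_shift, f_scale = f_scale),
    gram = sol$G, gram_basis = st$Gam, gram_min_eig = min(ev_g),
    fit = list(gaps = gaps, total_gap = sum(gaps), min_gap = min(gaps),
               status = sol$status, mu_final = sol$mu, tol = tol,
               n_samples = K)
  ), class = "underestimator")
  if (min(gaps) < -tol)
    stop_ssdu("solver returned an infeasible underestimator (min gap ",
              format(min(gaps)), "); status: ", sol$status)
  obj
}

#' @export
print.underestimator <- function(x, ...) {
  cat("<underestimator> degree ", x$degree, " in ", x$n, " variables; ",
      "total gap ", signif(x$fit$total_gap, 5),
      ", min gap ", signif(x$fit$min_gap, 3),
      ", Gram min eig ", signif(x$gram_min_eig, 3), "\n", sep = "")
  invisible(x)
}

phi_rows <- function(U, phi) {
  if (is.data.frame(phi)) phi <- as.matrix(phi)
  if (!is.matrix(phi)) phi <- matrix(as.double(phi), ncol = U$n)
  if (ncol(phi) != U$n) stop_ssdu("expected ", U$n, " coordinates")
  phi
}

#' Evaluate a fitted underestimator
#'
#' Exact polynomial evaluation from the stored coefficients.
#'
#' @param object An `underestimator`.
#' @param phi Points (vector, matrix, or data frame).
#' @param ... Unused.
#' @return Numeric vector of values.
#' @export
predict.underestimator <- function(object, phi, ...) {
  drop(design_matrix(phi_rows(object, phi), object$exponents) %*% object$coeffs)
}

#' Gradient and Hessian of an underestimator
#'
#' Exact polynomial differentiation from the coefficient vector.
#'
#' @param U An `underestimator`.
#' @param phi A single point (length-`n` vector or one-row matrix).
#' @return `poly_gradient()`: length-`n` numeric; `poly_hessian()`: a
#'   symmetric `n x n` matrix.
#' @export
poly_gradient <- function(U, phi) {
  phi <- phi_rows(U, phi)
  maps <- deriv_cache(U)
  vapply(maps$first, function(M)
    drop(design_matrix(phi, U$exponents) %*% (M %*% U$coeffs)), numeric(nrow(phi)))
}

#' @rdname poly_gradient
#' @export
poly_hessian <- function(U, phi) {
  phi <- phi_rows(U, phi)
  if (nrow(phi) != 1) stop_ssdu("`phi` must be a single point")
  maps <- deriv_cache(U)
  n <- U$n
  H <- matrix(0, n, n)
  dm <- design_matrix(phi, U$exponents)
  for (u in seq_len(n)) for (v in u:n) {
    H[u, v] <- H[v, u] <- drop(dm %*% (maps$second[[u]][[v - u + 1]] %*% U$coeffs))
  }
  H
}

.deriv_cache <- new.env(parent = emptyenv())

deriv_cache <- function(U) {
  key <- paste(U$n, U$degree, sep = "_")
  if (!is.null(.deriv_cache[[key]])) return(.deriv_cache[[key]])
  first <- first_deriv_maps(U$exponents)
  second <- lapply(seq_len(U$n), function(u)
    lapply(u:U$n, function(v) second_deriv_map(U$exponents, u, v)))
  .deriv_cache[[key]] <- list(first = first, second = second)
  .deriv_cache[[key]]
}

#' Global minimum of a certified-convex underestimator
#'
#' Damped Newton descent with backtracking from `init`; by convexity any
#' stationary point is the global minimum, so the result is independent of
#' the start (up to `tol`). Errors out with a diagnosis if the polynomial is
#' unbounded below (possible for fits with a degenerate quadratic part).
#'
#' @param U An `underestimator`.
#' @param init Starting point (default: origin of the preconditioning, i.e.
#'   the sample mean).
#' @param tol Gradient-norm tolerance.
#' @param max_iter Iteration cap.
#' @return A list with `phi_star` and `value`.
#' @export
minimize_convex <- function(U, init = NULL, tol = 1e-8, max_iter = 200) {
  if (is.null(init)) init <- U$transform$center
  x <- as.double(init)
  scale_ref <- 1 + abs(predict(U, matrix(x, 1)))
  for (it in seq_len(max_iter)) {
    g <- drop(poly_gradient(U, matrix(x, 1)))
    if (sqrt(sum(g^2)) <= tol * scale_ref) break
    H <- poly_hessian(U, matrix(x, 1))
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    lam <- max(0, 1e-8 * (1 + max(abs(ev))) - min(ev))
    d <- -solve(H + diag(lam + 1e-12, U$n), g)
    f0 <- predict(U, matrix(x, 1))
    alpha <- 1
    repeat {
      f1 <- predict(U, matrix(x + alpha * d, 1))
      if (f1 <= f0 + 1e-4 * alpha * sum(g * d)) break
      alpha <- alpha / 2
      if (alpha < 1e-14) break
    }
    x <- x + alpha * d
    if (sqrt(sum(x^2)) > 1e8 * (1 + sqrt(sum(U$transform$center^2)) +
                                  sum(abs(U$transform$scale))))
      stop_ssdu("underestimator appears unbounded below (iterates diverge)")
  }
  list(phi_star = x, value = predict(U, matrix(x, 1)))
}

#' Certify (or refuse) SOS-convexity of a polynomial
#'
#' Attempts the SOS feasibility semidefinite program for the Hessian biform
#' \eqn{y'\nabla^2 U(\phi) y}: it searches the affine slice of Gram matrices
#' reproducing the biform for the one with the largest minimum eigenvalue.
#' Returns a certificate (a PSD Gram matrix within solver tolerance) on
#' success and a refusal otherwise.
#'
#' @param coeffs Either an `underestimator` (its standardized coefficients
#'   are checked) or a raw coefficient vector over [monomial_basis()].
#' @param n,degree Dimensions when `coeffs` is a raw vector.
#' @param tol Acceptance tolerance on the Gram minimum eigenvalue.
#' @return A list with `certified` (logical), `lambda_min`, `gram`, and
#'   `basis` (exponents of the phi-part of the Gram basis).
#' @export
is_sos_convex <- function(coeffs, n = NULL, degree = NULL, tol = 1e-7) {
  if (inherits(coeffs, "underestimator")) {
    n <- coeffs$n; degree <- coeffs$degree
    cc <- coeffs$coeffs_std
  } else {
    cc <- as.double(coeffs)
    if (is.null(n) || is.null(degree)) stop_ssdu("supply `n` and `degree`")
    st0 <- sos_structure(n, degree)
    if (length(cc) != st0$m) stop_ssdu("coefficient length must be ", st0$m)
  }
  st <- sos_structure(n, degree)
  res <- sdp_sos_feasibility(st, cc)
  scale_ref <- 1 + max(abs(cc))
  list(certified = res$lambda >= -tol * scale_ref,
       lambda_min = res$lambda, gram = res$G, basis = st$Gam)
}

#' Tidy an underestimator: one row per monomial
#'
#' @param x An `underestimator`.
#' @param ... Unused.
#' @return A tibble with `term`, `degree`, `estimate` (original-scale
#'   coefficient).
#' @export
#' @method tidy underestimator
tidy.underestimator <- function(x, ...) {
  E <- x$exponents
  tibble::tibble(
    term = apply(E, 1, function(e) {
      if (sum(e) == 0) return("1")
      paste0(paste0("phi", which(e > 0), ifelse(e[e > 0] > 1,
                                                paste0("^", e[e > 0]), "")),
             collapse = "*")
    }),
    degree = rowSums(E),
    estimate = x$coeffs
  )
}

#' One-row summary of an underestimator fit
#'
#' @param x An `underestimator`.
#' @param ... Unused.
#' @return A one-row tibble with sizes, total/min/mean gaps, the Gram
#'   minimum eigenvalue, and the solver status.
#' @export
#' @method glance underestimator
glance.underestimator <- function(x, ...) {
  tibble::tibble(
    n = x$n, degree = x$degree, n_samples = x$fit$n_samples,
    total_gap = x$fit$total_gap, min_gap = x$fit$min_gap,
    mean_gap = x$fit$total_gap / x$fit$n_samples,
    gram_min_eig = x$gram_min_eig, status = x$fit$status
  )
}
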