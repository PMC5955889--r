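# Dense multivariate polynomial utilities over a graded-lexicographic
# monomial basis. Polynomials are coefficient vectors aligned with an
# exponent matrix (rows = monomials, cols = variables).

#' Monomial exponent basis
#'
#' All exponent tuples in `n` variables with total degree at most `d`, in
#' graded-lexicographic order (ascending total degree; lexicographic within a
#' degree). The basis has `choose(n + d, d)` rows.
#'
#' @param n Number of variables (>= 1).
#' @param d Maximum total degree (>= 0).
#' @return An integer matrix with one row per monomial.
#' @examples
#' monomial_basis(3, 2)
#' @export
monomial_basis <- function(n, d) {
  if (n < 1 || d < 0) stop_ssdu("need n >= 1, d >= 0")
  per_degree <- function(g, nv) {
    if (nv == 1) return(matrix(g, 1, 1))
    out <- NULL
    for (e1 in g:0) {
      rest <- per_degree(g - e1, nv - 1)
      out <- rbind(out, cbind(e1, rest))
    }
    out
  }
  rows <- lapply(0:d, per_degree, nv = n)
  E <- do.call(rbind, rows)
  dimnames(E) <- NULL
  storage.mode(E) <- "integer"
  E
}

mono_key <- function(E) apply(E, 1, paste, collapse = ",")

# values of each monomial at each point: m x k matrix (points x monomials)
design_matrix <- function(points, E) {
  points <- as.matrix(points)
  k <- nrow(E)
  out <- matrix(1, nrow(points), k)
  for (j in seq_len(k)) {
    e <- E[j, ]
    for (v in which(e > 0)) out[, j] <- out[, j] * points[, v]^e[v]
  }
  out
}

# sparse linear map (as k x k matrix) taking coefficients to coefficients of
# the second partial derivative d^2/dx_u dx_v, within the same basis E
second_deriv_map <- function(E, u, v) {
  k <- nrow(E)
  keys <- mono_key(E)
  M <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- E[j, ]
    if (u == v) {
      if (e[u] < 2) next
      w <- e[u] * (e[u] - 1)
      e2 <- e; e2[u] <- e2[u] - 2L
    } else {
      if (e[u] < 1 || e[v] < 1) next
      w <- e[u] * e[v]
      e2 <- e; e2[u] <- e2[u] - 1L; e2[v] <- e2[v] - 1L
    }
    i <- match(paste(e2, collapse = ","), keys)
    M[i, j] <- w
  }
  M
}

# first-derivative coefficient maps, one k x k matrix per variable
first_deriv_maps <- function(E) {
  k <- nrow(E)
  keys <- mono_key(E)
  lapply(seq_len(ncol(E)), function(v) {
    M <- matrix(0, k, k)
    for (j in seq_len(k)) {
      e <- E[j, ]
      if (e[v] < 1) next
      e2 <- e; e2[v] <- e2[v] - 1L
      M[match(paste(e2, collapse = ","), keys), j] <- e[v]
    }
    M
  })
}

# exact re-expansion of sum_a c_a * prod_i ((x_i - m_i)/s_i)^{a_i} in the
# original coordinates; returns coefficients over the same basis E
affine_pullback <- function(coeffs, E, center, scale, f_scale = 1, f_shift = 0) {
  keys <- mono_key(E)
  out <- numeric(nrow(E))
  n <- ncol(E)
  for (j in seq_along(coeffs)) {
    if (coeffs[j] == 0) next
    # term starts as the constant coefficient, exponents built up per variable
    term_E <- matrix(0L, 1, n)
    term_c <- coeffs[j] * f_scale
    for (v in seq_len(n)) {
      p <- E[j, v]
      if (p == 0) next
      # ((x_v - m_v)/s_v)^p expanded by the binomial theorem
      kk <- 0:p
      bin_c <- choose(p, kk) * (-center[v])^(p - kk) / scale[v]^p
      newE <- term_E[rep(seq_len(nrow(term_E)), each = p + 1), , drop = FALSE]
      newE[, v] <- newE[, v] + rep(kk, nrow(term_E))
      term_c <- as.vector(outer(bin_c, term_c))
      term_E <- newE
    }
    idx <- match(apply(term_E, 1, paste, collapse = ","), keys)
    for (t in seq_along(idx)) out[idx[t]] <- out[idx[t]] + term_c[t]
  }
  out[1] <- out[1] + f_shift
  out
}
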