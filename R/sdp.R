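# SOS-convexity machinery and a small dense primal log-barrier interior-point
# solver, specialized to the underestimation program
#
#   min  sum_i [f_i - U(phi_i)]   s.t.  f_i >= U(phi_i),  U SOS-convex,
#
# and to the SOS-convexity feasibility program. SOS-convexity of a degree-2d
# polynomial U in n variables is encoded as: the biform y' Hess(U)(phi) y
# equals m(phi,y)' G m(phi,y) with G positive semidefinite, over the basis
# m = {phi-monomials of degree <= d-1} (x) {y_1..y_n}. The linear identity
# between Gram entries and Hessian-form coefficients is imposed exactly.
#
# Problem sizes are tiny (n = 3, degree 4: 35 coefficients, a 12x12 Gram),
# so dense Newton steps on the central path are fast and deterministic.

.sos_cache <- new.env(parent = emptyenv())

# Structure for (n, degree 2d): exponent bases, the Gram-to-polynomial map A,
# the coefficient-to-Hessian-form map B, a particular solution P (A P = B),
# an orthonormal null-space basis Nn of A, and stacked basis matrices for
# every free variable.
sos_structure <- function(n, degree) {
  if (degree %% 2 != 0 || degree < 2) stop_ssdu("`degree` must be even and >= 2")
  key <- paste(n, degree, sep = "_")
  if (!is.null(.sos_cache[[key]])) return(.sos_cache[[key]])
  d <- degree %/% 2
  E_U <- monomial_basis(n, degree)
  E_H <- monomial_basis(n, degree - 2)
  Gam <- monomial_basis(n, d - 1)
  m <- nrow(E_U); mh <- nrow(E_H); g <- nrow(Gam)
  Nb <- g * n                                  # Gram dimension
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]  # (u<=v)
  np <- nrow(pairs)

  # B: (mh*np) x m ; rows indexed by (beta, pair), beta fastest
  B <- matrix(0, mh * np, m)
  for (p in seq_len(np)) {
    u <- pairs[p, 1]; v <- pairs[p, 2]
    Duv <- second_deriv_map_cross(E_U, E_H, u, v)
    w <- if (u == v) 1 else 2
    B[(p - 1) * mh + seq_len(mh), ] <- w * Duv
  }

  # Gram basis entry p = (gamma_{gi}, y_i): index (gi-1)*n + i
  keysH <- mono_key(E_H)
  S <- Nb * (Nb + 1) / 2
  sym_idx <- which(upper.tri(diag(Nb), diag = TRUE), arr.ind = TRUE)
  sym_idx <- sym_idx[order(sym_idx[, 2], sym_idx[, 1]), , drop = FALSE]
  A <- matrix(0, mh * np, S)
  pair_of <- matrix(0L, n, n)
  for (p in seq_len(np)) pair_of[pairs[p, 1], pairs[p, 2]] <- p
  for (s in seq_len(S)) {
    pq <- sym_idx[s, ]
    gp <- (pq[1] - 1) %/% n + 1; ip <- (pq[1] - 1) %% n + 1
    gq <- (pq[2] - 1) %/% n + 1; iq <- (pq[2] - 1) %% n + 1
    beta <- Gam[gp, ] + Gam[gq, ]
    bi <- match(paste(beta, collapse = ","), keysH)
    pr <- pair_of[min(ip, iq), max(ip, iq)]
    w <- if (pq[1] == pq[2]) 1 else 2
    A[(pr - 1) * mh + bi, s] <- A[(pr - 1) * mh + bi, s] + w
  }

  sv <- svd(A, nu = min(dim(A)), nv = ncol(A))
  rk <- sum(sv$d > max(dim(A)) * max(sv$d) * 1e-12)
  Dinv <- c(1 / sv$d[seq_len(rk)], rep(0, length(sv$d) - rk))
  P <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (Dinv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], B))
  if (max(abs(A %*% P - B)) > 1e-8)
    stop_ssdu("internal error: Hessian-form map not in the Gram image")
  Nn <- sv$v[, -seq_len(rk), drop = FALSE]

  # stacked basis matrices: columns = vec(full symmetric matrix) per variable
  packed_to_vec <- matrix(0, Nb * Nb, S)
  for (s in seq_len(S)) {
    pq <- sym_idx[s, ]
    M <- matrix(0, Nb, Nb)
    M[pq[1], pq[2]] <- 1; M[pq[2], pq[1]] <- 1
    if (pq[1] == pq[2]) M[pq[1], pq[1]] <- 1
    packed_to_vec[, s] <- as.vector(M)
  }
  VA_c <- packed_to_vec %*% P     # per U-coefficient
  VA_t <- packed_to_vec %*% Nn    # per free Gram parameter

  out <- list(n = n, degree = degree, d = d, E_U = E_U, E_H = E_H, Gam = Gam,
              m = m, Nb = Nb, nt = ncol(Nn), A = A, B = B, P = P, Nn = Nn,
              VA_c = VA_c, VA_t = VA_t, packed_to_vec = packed_to_vec)
  .sos_cache[[key]] <- out
  out
}

# second-derivative map with distinct source/target bases
second_deriv_map_cross <- function(E_from, E_to, u, v) {
  keys <- mono_key(E_to)
  M <- matrix(0, nrow(E_to), nrow(E_from))
  for (j in seq_len(nrow(E_from))) {
    e <- E_from[j, ]
    if (u == v) {
      if (e[u] < 2) next
      w <- e[u] * (e[u] - 1); e2 <- e; e2[u] <- e2[u] - 2L
    } else {
      if (e[u] < 1 || e[v] < 1) next
      w <- e[u] * e[v]; e2 <- e; e2[u] <- e2[u] - 1L; e2[v] <- e2[v] - 1L
    }
    M[match(paste(e2, collapse = ","), keys), j] <- w
  }
  M
}

gram_from_theta <- function(st, cc, tt) {
  v <- st$VA_c %*% cc
  if (st$nt > 0 && length(tt) > 0) v <- v + st$VA_t %*% tt
  matrix(v, st$Nb, st$Nb)
}

# Strictly feasible start for degrees 2 and 4: U0 = off + delta(|phi|^2 +
# [degree 4] |phi|^4) has the explicit positive-definite Gram built here.
feasible_start <- function(st, offset, delta) {
  n <- st$n
  keys <- mono_key(st$E_U)
  cc <- numeric(st$m)
  cc[1] <- offset
  for (v in seq_len(n)) {
    e <- integer(n); e[v] <- 2L
    cc[match(paste(e, collapse = ","), keys)] <- cc[match(paste(e, collapse = ","), keys)] + delta
  }
  G <- NULL
  if (st$degree == 2) {
    G <- diag(2 * delta, st$Nb)
  } else if (st$degree == 4) {
    # add |phi|^4 = (sum phi_i^2)^2
    for (v in seq_len(n)) {
      e <- integer(n); e[v] <- 4L
      cc[match(paste(e, collapse = ","), keys)] <- cc[match(paste(e, collapse = ","), keys)] + delta
    }
    cmb <- utils::combn(n, 2)
    for (j in seq_len(ncol(cmb))) {
      e <- integer(n); e[cmb[1, j]] <- 2L; e[cmb[2, j]] <- 2L
      cc[match(paste(e, collapse = ","), keys)] <- cc[match(paste(e, collapse = ","), keys)] + 2 * delta
    }
    # Gram: y-block 2*delta I; (phi x y)-block 4*delta I + 8*delta vv'
    G <- matrix(0, st$Nb, st$Nb)
    yblk <- seq_len(n)                     # gamma = 1 entries
    G[yblk, yblk] <- diag(2 * delta, n)
    xy <- (n + 1):st$Nb
    G[xy, xy] <- diag(4 * delta, length(xy))
    vv <- numeric(st$Nb)
    for (j in seq_len(n)) {
      # basis index of (gamma = phi_j, y_j): Gam row for phi_j is 1 + j
      vv[j * n + j] <- 1
    }
    G <- G + 8 * delta * tcrossprod(vv)
  }
  list(cc = cc, G = G)
}

# Solve the underestimation SDP on preconditioned data.
# Phi: K x m design matrix at the sample points; f: energies (min 0, sd ~1).
sdp_underestimate <- function(st, Phi, f, ridge = 1e-9, mu_final = 1e-11,
                              relaxed = FALSE) {
  K <- nrow(Phi); m <- st$m; nt <- st$nt
  a <- colSums(Phi) / K

  strt <- feasible_start(st, offset = min(f) - 1, delta = 1e-3 / (1 + max(abs(f))))
  cc <- strt$cc
  tt <- numeric(nt)
  if (!relaxed && !is.null(strt$G)) {
    # free Gram parameters reproducing the explicit PD start on the slice
    resid <- as.vector(strt$G) - st$VA_c %*% cc
    if (nt > 0) tt <- drop(qr.coef(qr(st$VA_t), resid))
    G <- gram_from_theta(st, cc, tt)
    if (min(eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      relaxed <- TRUE
  } else relaxed <- TRUE

  VA <- cbind(st$VA_c, st$VA_t)
  ntheta <- m + nt
  mu <- 1
  status <- "optimal"
  for (outer in seq_len(60)) {
    nu <- if (relaxed) mu else 0
    for (inner in seq_len(60)) {
      s <- f - drop(Phi %*% cc)
      G <- gram_from_theta(st, cc, tt) + diag(nu, st$Nb)
      R <- tryCatch(chol(G), error = function(e) NULL)
      if (is.null(R) || any(s <= 0)) stop_ssdu("interior-point lost feasibility")
      Rinv <- backsolve(R, diag(st$Nb))
      Ginv <- tcrossprod(Rinv)
      # gradient
      gr <- numeric(ntheta)
      gr[1:m] <- -a + 2 * ridge * cc + mu * drop(crossprod(Phi, 1 / s))
      gr <- gr - mu * drop(crossprod(VA, as.vector(Ginv)))
      # Hessian
      H <- matrix(0, ntheta, ntheta)
      H[1:m, 1:m] <- mu * crossprod(Phi / s, Phi / s) + diag(2 * ridge, m)
      Cmat <- matrix(0, st$Nb * st$Nb, ntheta)
      for (j in seq_len(ntheta)) {
        Aj <- matrix(VA[, j], st$Nb, st$Nb)
        Cmat[, j] <- as.vector(crossprod(Rinv, Aj) %*% Rinv)
      }
      H <- H + mu * crossprod(Cmat)
      dth <- tryCatch(-solve(H, gr), error = function(e) NULL)
      if (is.null(dth)) {
        dth <- -solve(H + diag(1e-10 * max(diag(H)), ntheta), gr)
      }
      dec <- -sum(gr * dth)
      if (!is.finite(dec) || dec <= 0) break
      dc <- dth[1:m]; dt <- if (nt > 0) dth[m + 1:nt] else numeric(0)
      # step to boundary of the slack cone
      ds <- -drop(Phi %*% dc)
      neg <- ds < 0
      amax <- if (any(neg)) 0.99 * min(-s[neg] / ds[neg]) else 1
      alpha <- min(1, amax)
      F0 <- barrier_value(st, Phi, f, a, ridge, mu, nu, cc, tt)
      repeat {
        c2 <- cc + alpha * dc; t2 <- tt + alpha * dt
        F1 <- barrier_value(st, Phi, f, a, ridge, mu, nu, c2, t2)
        if (is.finite(F1) && F1 <= F0 - 1e-4 * alpha * dec) break
        alpha <- alpha / 2
        if (alpha < 1e-13) break
      }
      if (alpha < 1e-13) break
      cc <- cc + alpha * dc; tt <- tt + alpha * dt
      if (dec / 2 < 1e-11 * (1 + abs(F0))) break
    }
    if (mu <= mu_final) break
    mu <- max(mu * 0.12, mu_final)
  }
  s <- f - drop(Phi %*% cc)
  G <- gram_from_theta(st, cc, tt)
  list(cc = cc, tt = tt, G = (G + t(G)) / 2, slacks = s, mu = mu,
       status = status, relaxed = relaxed)
}

barrier_value <- function(st, Phi, f, a, ridge, mu, nu, cc, tt) {
  s <- f - drop(Phi %*% cc)
  if (any(s <= 0)) return(Inf)
  G <- gram_from_theta(st, cc, tt) + diag(nu, st$Nb)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  -sum(a * cc) + ridge * sum(cc^2) - mu * sum(log(s)) - 2 * mu * sum(log(diag(R)))
}

# Phase-I / feasibility: maximize lambda_min over the Gram slice of a fixed
# coefficient vector. Returns the best lambda and the Gram attaining it.
sdp_sos_feasibility <- function(st, cc, mu_final = 1e-9) {
  Gp <- gram_from_theta(st, cc, numeric(st$nt))
  Gp <- (Gp + t(Gp)) / 2
  if (st$nt == 0) {
    ev <- eigen(Gp, symmetric = TRUE)
    return(list(lambda = ev$values[st$Nb], G = Gp))
  }
  nt <- st$nt
  tt <- numeric(nt)
  lam <- min(eigen(Gp, symmetric = TRUE, only.values = TRUE)$values) - 1
  VA <- cbind(st$VA_t, -as.vector(diag(st$Nb)))
  mu <- 1
  val <- function(tt, lam) {
    G <- Gp + matrix(st$VA_t %*% tt, st$Nb, st$Nb) - diag(lam, st$Nb)
    R <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    -lam - 2 * mu * sum(log(diag(R)))
  }
  for (outer in seq_len(40)) {
    for (inner in seq_len(50)) {
      G <- Gp + matrix(st$VA_t %*% tt, st$Nb, st$Nb) - diag(lam, st$Nb)
      R <- tryCatch(chol((G + t(G)) / 2), error = function(e) NULL)
      if (is.null(R)) stop_ssdu("feasibility solve lost interior")
      Rinv <- backsolve(R, diag(st$Nb))
      Ginv <- tcrossprod(Rinv)
      gr <- c(numeric(nt), -1) - mu * drop(crossprod(VA, as.vector(Ginv)))
      Cmat <- matrix(0, st$Nb^2, nt + 1)
      for (j in seq_len(nt + 1)) {
        Aj <- matrix(VA[, j], st$Nb, st$Nb)
        Cmat[, j] <- as.vector(crossprod(Rinv, Aj) %*% Rinv)
      }
      H <- mu * crossprod(Cmat)
      H <- H + diag(max(diag(H)) * 1e-11 + 1e-300, nt + 1)
      dth <- tryCatch(-solve(H, gr), error = function(e)
        -solve(H + diag(max(diag(H)) * 1e-7, nt + 1), gr))
      dec <- -sum(gr * dth)
      if (!is.finite(dec) || dec <= 0) break
      alpha <- 1
      F0 <- val(tt, lam)
      repeat {
        t2 <- tt + alpha * dth[seq_len(nt)]; l2 <- lam + alpha * dth[nt + 1]
        if (val(t2, l2) <= F0 - 1e-4 * alpha * dec) break
        alpha <- alpha / 2
        if (alpha < 1e-13) break
      }
      if (alpha < 1e-13) break
      tt <- tt + alpha * dth[seq_len(nt)]; lam <- lam + alpha * dth[nt + 1]
      if (dec / 2 < 1e-12 * (1 + abs(F0))) break
    }
    if (mu <= mu_final) break
    mu <- max(mu * 0.1, mu_final)
  }
  G <- Gp + matrix(st$VA_t %*% tt, st$Nb, st$Nb)
  list(lambda = lam, G = (G + t(G)) / 2)
}
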