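# Independent oracles and fixture builders used across the test files.
# Each oracle deliberately takes a different computational route than the
# package implementation it checks.

# --- rotations -------------------------------------------------------------

# axis-angle -> rotation matrix via unit quaternions
quat_rotation <- function(y) {
  th <- sqrt(sum(y^2))
  if (th == 0) return(diag(3))
  k <- y / th
  q <- c(cos(th / 2), sin(th / 2) * k)
  w <- q[1]; x <- q[2]; yy <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (yy^2 + z^2), 2 * (x * yy + w * z), 2 * (x * z - w * yy),
           2 * (x * yy - w * z), 1 - 2 * (x^2 + z^2), 2 * (yy * z + w * x),
           2 * (x * z + w * yy), 2 * (yy * z - w * x), 1 - 2 * (x^2 + yy^2)),
         3, 3)
}

# --- DBSCAN ----------------------------------------------------------------

# Declarative density-connectivity oracle: core points, connected components
# of the core graph (igraph), clusters ordered by their smallest core index,
# border points joined to the lowest-ordered cluster among their core
# neighbours.
oracle_dbscan <- function(x, eps, n_min) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  nb <- D <= eps
  core <- which(rowSums(nb) >= n_min)
  lab <- rep(-1L, n)
  if (length(core) > 0) {
    g <- igraph::graph_from_adjacency_matrix(nb[core, core, drop = FALSE],
                                             mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    # order components by smallest original core index
    first <- vapply(seq_len(max(comp)), function(c)
      min(core[comp == c]), 0)
    rank <- match(seq_len(max(comp)), order(first))
    lab[core] <- rank[comp] - 1L
    for (i in setdiff(seq_len(n), core)) {
      cn <- core[nb[i, core]]
      if (length(cn) > 0) lab[i] <- min(lab[cn])
    }
  }
  lab
}

# partitions equal up to label renaming (outliers must match exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# --- greedy clustering -----------------------------------------------------

# plain-loop re-implementation of the greedy neighbour-count rule
oracle_greedy <- function(D, threshold = 9, max_clusters = 30, min_size = 10) {
  n <- nrow(D)
  remaining <- seq_len(n)
  out <- list()
  while (length(out) < max_clusters && length(remaining) > 0) {
    counts <- sapply(remaining, function(i)
      sum(D[i, remaining] < threshold) - 1L)
    best_pos <- which(counts == max(counts))[1]
    center <- remaining[best_pos]
    if (counts[best_pos] + 1 < min_size) break
    members <- remaining[D[center, remaining] < threshold]
    members <- c(center, setdiff(members, center))
    out[[length(out) + 1]] <- list(center = center, members = members)
    remaining <- setdiff(remaining, members)
  }
  out
}

# --- degree-2 underestimation oracle ---------------------------------------

# Explicit-PSD-Hessian quadratic underestimator fit by an increasing-penalty
# method over a Cholesky parameterization (A = LL'), entirely independent of
# the package's interior-point solver.
oracle_quadratic_fit <- function(phi, f) {
  phi <- as.matrix(phi)
  n <- ncol(phi)
  qval <- function(par, P) {
    L <- matrix(0, n, n)
    L[lower.tri(L, diag = TRUE)] <- par[1:(n * (n + 1) / 2)]
    A <- L %*% t(L)
    b <- par[n * (n + 1) / 2 + 1:n]
    c0 <- par[length(par)]
    pred <- rowSums((phi %*% A) * phi) + phi %*% b + c0
    s <- f - pred
    sum(s) + P * sum(pmax(-s, 0)^2)
  }
  # start from the unconstrained least-squares quadratic (exact when the
  # data comes from a quadratic), PSD-projected for the Cholesky factor
  mono <- cbind(1, phi, phi^2, phi[, 1] * phi[, 2], phi[, 1] * phi[, 3],
                phi[, 2] * phi[, 3])
  ls <- qr.coef(qr(mono), f)
  A0 <- diag(ls[5:7], n)
  A0[1, 2] <- A0[2, 1] <- ls[8] / 2
  A0[1, 3] <- A0[3, 1] <- ls[9] / 2
  A0[2, 3] <- A0[3, 2] <- ls[10] / 2
  ev <- eigen(A0, symmetric = TRUE)
  A0 <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
  L0 <- t(chol(A0 + diag(1e-10, n)))
  npar <- n * (n + 1) / 2 + n + 1
  par <- c(L0[lower.tri(L0, diag = TRUE)], ls[2:4], ls[1])
  for (P in 10^(2:9)) {
    par <- optim(par, qval, P = P, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))$par
  }
  L <- matrix(0, n, n)
  L[lower.tri(L, diag = TRUE)] <- par[1:(n * (n + 1) / 2)]
  polished <- list(A = L %*% t(L), b = par[n * (n + 1) / 2 + 1:n],
                   c0 = par[length(par)])
  # pick whichever feasible candidate (least-squares or polished) has the
  # smaller true objective
  cand <- list(list(A = A0, b = ls[2:4], c0 = ls[1]), polished)
  score <- vapply(cand, function(q) {
    s <- f - (rowSums((phi %*% q$A) * phi) + phi %*% q$b + q$c0)
    if (min(s) < -1e-7) Inf else sum(s)
  }, 0)
  cand[[which.min(score)]]
}

# quadratic coefficient extraction from a fitted degree-2 underestimator:
# value c0, linear b, matrix A with q(phi) = phi'A phi + b'phi + c0
quad_parts <- function(U) {
  E <- U$exponents
  co <- U$coeffs
  n <- U$n
  A <- matrix(0, n, n); b <- numeric(n); c0 <- 0
  for (j in seq_len(nrow(E))) {
    e <- E[j, ]; d <- sum(e)
    if (d == 0) c0 <- co[j]
    else if (d == 1) b[which(e == 1)] <- co[j]
    else if (d == 2 && any(e == 2)) A[which(e == 2), which(e == 2)] <- co[j]
    else { ij <- which(e == 1); A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- co[j] / 2 }
  }
  list(A = A, b = b, c0 = c0)
}

# --- misc fixtures ---------------------------------------------------------

random_ensemble <- function(n, seed = 1) {
  set.seed(seed)
  conformations(r = runif(n, 5, 15), a = rnorm(n), b = rnorm(n),
                y1 = rnorm(n, 0, .5), y2 = rnorm(n, 0, .5), y3 = rnorm(n, 0, .5),
                energy = rnorm(n))
}

# rough multi-well energy samples over a box in R^3 (for underestimator fits)
rough_energy_data <- function(K, seed) {
  set.seed(seed)
  phi <- matrix(runif(3 * K, -2, 2), K, 3)
  ctr <- matrix(runif(9, -1, 1), 3, 3)
  f <- apply(phi, 1, function(p) min(apply(ctr, 1, function(c0)
    sum((p - c0)^2)))) + 0.3 * sin(3 * phi[, 1]) * cos(2 * phi[, 2]) +
    0.2 * abs(rnorm(K))
  list(phi = phi, f = f)
}

two_funnel_landscape <- function(seed, depth2 = -50) {
  funnel_landscape(
    list(funnel(center = c(0, 0, 0, 0, 0), depth = -50),
         funnel(center = c(8, 8, 0, 0, 0), depth = depth2, r0 = 11)),
    ruggedness = 0.3, seed = seed)
}

# planted-signal cluster feature generator for ranking tests
planted_features <- function(n_complex, per = 8, margin = 6, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_complex), function(cx) {
    lab <- ifelse(runif(per) < 0.3, 1, -1)
    tibble::tibble(
      complex = cx, label = lab,
      e25 = ifelse(lab > 0, -margin, 0) + rnorm(per),
      e50 = ifelse(lab > 0, -margin, 0) + rnorm(per),
      e75 = rnorm(per), e100 = rnorm(per),
      size = sample(10:60, per, TRUE),
      d25 = abs(rnorm(per)), d50 = abs(rnorm(per)),
      d75 = abs(rnorm(per)), d100 = abs(rnorm(per)))
  })
}
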