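#' Specify one binding-energy funnel
#'
#' A funnel is an anisotropic quadratic basin in the five reduced coordinates
#' \eqn{x = (a, b, y_1, y_2, y_3)} plus a stiff quadratic term in the
#' center-to-center distance `r`. Its curvature matrix
#' \eqn{A = Q\,\mathrm{diag}(\lambda)\,Q'} has three small "permissive"
#' eigenvalues (directions along which the energy is smooth and conformations
#' spread widely) and two large "restrictive" eigenvalues (steep directions
#' confining the cluster), emulating the wide-to-narrow pattern of docking
#' energy landscapes near the native state.
#'
#' @param center Basin center in reduced coordinates (length 5).
#' @param r0 Reference center-to-center distance (Angstrom, > 0).
#' @param depth Energy at the basin bottom (the funnel's `d`).
#' @param lambda_permissive,lambda_restrictive Curvature eigenvalues; three
#'   permissive and two restrictive values (restrictive/permissive ratio must
#'   be at least 10). Scalars are recycled.
#' @param k_r Stiffness of the quadratic `r` term.
#' @param rotation Optional 5x5 orthogonal matrix `Q` orienting the basin; the
#'   default is axis-aligned (first three axes permissive).
#' @return A `funnel` list used by [funnel_landscape()].
#' @export
funnel <- function(center = rep(0, 5), r0 = 10, depth = -50,
                   lambda_permissive = 2, lambda_restrictive = 200,
                   k_r = 10, rotation = NULL) {
  center <- as.double(center)
  if (length(center) != 5 || any(!is.finite(center)))
    stop_ssdu("`center` must be a finite 5-vector")
  if (r0 <= 0) stop_ssdu("`r0` must be positive")
  lp <- rep_len(as.double(lambda_permissive), 3)
  lr <- rep_len(as.double(lambda_restrictive), 2)
  if (any(lp <= 0) || any(lr <= 0)) stop_ssdu("eigenvalues must be positive")
  if (min(lr) / max(lp) < 10)
    stop_ssdu("restrictive/permissive eigenvalue ratio must be >= 10")
  lambda <- c(lp, lr)
  if (is.null(rotation)) rotation <- diag(5)
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(5))) > 1e-8)
    stop_ssdu("`rotation` must be orthogonal")
  A <- rotation %*% diag(lambda) %*% t(rotation)
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_ssdu("curvature matrix is not positive definite")
  structure(list(center = center, r0 = r0, depth = depth, A = A,
                 lambda = lambda, rotation = rotation, k_r = k_r),
            class = "ssdu_funnel")
}

#' Random orthogonal 5x5 matrix (for oriented funnels)
#'
#' QR-based Haar draw with a deterministic sign fix; useful for building
#' funnel curvature orientations that are not axis-aligned.
#'
#' @param seed Integer seed.
#' @return A 5x5 orthogonal matrix.
#' @export
random_rotation5 <- function(seed) {
  set.seed(as.integer(seed))
  qr_ <- qr(matrix(rnorm(25), 5, 5))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))
}

#' Synthetic multi-funnel energy landscape
#'
#' Builds a deterministic energy model
#' \deqn{f(\psi) = \min_j\big[d_j + (x - c_j)' A_j (x - c_j)
#'   + k_r (r - r_j)^2\big] + \rho \sum_{i=1}^5 \sin(\omega_i x_i + \phi_i),}
#' a smooth multi-funnel surface with superimposed sinusoidal ruggedness
#' (phases \eqn{\phi} drawn once from `seed`). It stands in for the rugged,
#' anisotropic binding-energy landscapes that docking refinement operates on,
#' with a known construction usable as ground truth in tests.
#'
#' @param funnels A single [funnel()] or a list of them.
#' @param ruggedness Amplitude \eqn{\rho \ge 0} of the sinusoidal term.
#' @param omega Frequency 5-vector \eqn{\omega} (recycled from a scalar).
#' @param outlier_fraction Fraction of uniform-outlier decoys generated by
#'   [simulate_decoys()] (in [0, 1)).
#' @param seed Integer seed fixing the ruggedness phases (and decoy draws).
#' @return An object of class `funnel_landscape`; evaluate it with
#'   [energy()].
#' @examples
#' fl <- funnel_landscape(funnel(depth = -10), ruggedness = 0)
#' energy(fl, conformations(r = 10))
#' @export
funnel_landscape <- function(funnels, ruggedness = 0.3, omega = 3,
                             outlier_fraction = 0.05, seed = 1) {
  if (inherits(funnels, "ssdu_funnel")) funnels <- list(funnels)
  if (length(funnels) < 1) stop_ssdu("at least one funnel is required")
  if (!all(vapply(funnels, inherits, TRUE, "ssdu_funnel")))
    stop_ssdu("`funnels` must be funnel() objects")
  if (ruggedness < 0) stop_ssdu("`ruggedness` must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_ssdu("`outlier_fraction` must be in [0, 1)")
  omega <- rep_len(as.double(omega), 5)
  set.seed(as.integer(seed))
  phases <- runif(5, 0, 2 * pi)
  structure(list(funnels = funnels, ruggedness = ruggedness, omega = omega,
                 phases = phases, outlier_fraction = outlier_fraction,
                 seed = as.integer(seed), truth = NULL),
            class = "funnel_landscape")
}

#' @export
print.funnel_landscape <- function(x, ...) {
  cat("<funnel_landscape> ", length(x$funnels), " funnel(s), ruggedness ",
      x$ruggedness, "\n", sep = "")
  invisible(x)
}

#' Evaluate an energy model
#'
#' Energy models are deterministic maps from conformations to finite scalar
#' energies. Methods exist for the synthetic [funnel_landscape()], the
#' [toy_rigid_energy()] physical model, and bare functions (which receive a
#' numeric 6-vector per conformation).
#'
#' @param model An energy model.
#' @param psi A conformation tibble (any number of rows), or a numeric
#'   6-vector.
#' @param ... Unused.
#' @return A numeric vector of energies, one per conformation.
#' @export
energy <- function(model, psi, ...) UseMethod("energy")

psi_matrix <- function(psi) {
  if (is.data.frame(psi)) {
    validate_ensemble(psi)
    as.matrix(psi[psi_cols])
  } else if (is.matrix(psi)) {
    psi[, 1:6, drop = FALSE]
  } else {
    matrix(as.double(psi[1:6]), 1)
  }
}

#' @rdname energy
#' @export
energy.funnel_landscape <- function(model, psi, ...) {
  m <- psi_matrix(psi)
  x <- m[, 2:6, drop = FALSE]
  r <- m[, 1]
  basin <- rep(Inf, nrow(m))
  for (fn in model$funnels) {
    dx <- sweep(x, 2, fn$center)
    q <- fn$depth + rowSums((dx %*% fn$A) * dx) + fn$k_r * (r - fn$r0)^2
    basin <- pmin(basin, q)
  }
  rug <- 0
  if (model$ruggedness > 0) {
    s <- sweep(x, 2, model$omega, `*`)
    s <- sweep(s, 2, model$phases, `+`)
    rug <- model$ruggedness * rowSums(sin(s))
  }
  basin + rug
}

#' @rdname energy
#' @export
energy.function <- function(model, psi, ...) {
  m <- psi_matrix(psi)
  apply(m, 1, model)
}

# Energy restricted to reduced coordinates, with r optimized out analytically
# (the active funnel's r0); used by ground_truth.
reduced_energy_fl <- function(model, x) {
  x <- matrix(x, ncol = 5)
  basin <- rep(Inf, nrow(x))
  for (fn in model$funnels) {
    dx <- sweep(x, 2, fn$center)
    basin <- pmin(basin, fn$depth + rowSums((dx %*% fn$A) * dx))
  }
  rug <- 0
  if (model$ruggedness > 0) {
    s <- sweep(x, 2, model$omega, `*`)
    s <- sweep(s, 2, model$phases, `+`)
    rug <- model$ruggedness * rowSums(sin(s))
  }
  basin + rug
}

#' Ground-truth global minimum of a synthetic landscape
#'
#' Locates the global minimum by multi-start local minimization (starts at
#' every funnel center plus deterministic random probes in a box around the
#' centers), then refines the best hit. With zero ruggedness this is exactly
#' the lowest-depth funnel center. The result is cached on the model.
#'
#' @param model A [funnel_landscape()].
#' @param n_probes Number of additional random starts.
#' @return A list with `psi` (one-row conformation tibble), `energy`, and
#'   `x` (reduced coordinates of the minimum).
#' @export
ground_truth <- function(model, n_probes = 2000) {
  stopifnot(inherits(model, "funnel_landscape"))
  if (!is.null(model$truth)) return(model$truth)
  centers <- do.call(rbind, lapply(model$funnels, `[[`, "center"))
  if (model$ruggedness == 0) {
    depths <- vapply(model$funnels, `[[`, 0, "depth")
    j <- which.min(depths)
    fn <- model$funnels[[j]]
    psi <- conformations(r = fn$r0, a = fn$center[1], b = fn$center[2],
                         y1 = fn$center[3], y2 = fn$center[4], y3 = fn$center[5])
    psi$energy <- energy(model, psi)
    return(list(psi = psi, energy = psi$energy, x = fn$center))
  }
  # probe box: centers +- 3 permissive standard-length scales
  spread <- max(vapply(model$funnels, function(f) 1 / sqrt(min(f$lambda)), 0))
  lo <- apply(centers, 2, min) - 3 * spread
  hi <- apply(centers, 2, max) + 3 * spread
  set.seed(child_seed(model$seed, stream = 7L))
  probes <- matrix(runif(5 * n_probes, rep(lo, each = n_probes),
                         rep(hi, each = n_probes)), n_probes, 5)
  starts <- rbind(centers, probes)
  vals <- reduced_energy_fl(model, starts)
  starts <- starts[order(vals)[seq_len(min(40, nrow(starts)))], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], function(x) reduced_energy_fl(model, x),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  x <- best$par
  # r of the active funnel at x
  per_f <- vapply(model$funnels, function(fn) {
    dx <- x - fn$center
    fn$depth + drop(dx %*% fn$A %*% dx)
  }, 0)
  fn <- model$funnels[[which.min(per_f)]]
  psi <- conformations(r = fn$r0, a = x[1], b = x[2],
                       y1 = x[3], y2 = x[4], y3 = x[5])
  psi$energy <- energy(model, psi)
  list(psi = psi, energy = psi$energy, x = x)
}

#' Generate a PIPER-like decoy ensemble from a synthetic landscape
#'
#' Emulates the low-energy output of an FFT global docking stage: samples
#' concentrate in the landscape's funnels (Gaussian about each center with
#' covariance `temperature * A_j^-1`, so the spread is wide along permissive
#' and narrow along restrictive directions), with a fraction of uniform
#' outliers in the bounding box. Funnels receive samples proportionally to
#' Boltzmann-like weights `exp(-depth_j / temperature)`. The distance `r` is
#' drawn from the Boltzmann marginal of the quadratic `r` term,
#' `N(r0, temperature / (2 k_r))`, truncated to positive values.
#'
#' @param model A [funnel_landscape()].
#' @param n Ensemble size `K`.
#' @param temperature Sampling temperature (> 0) controlling cloud width.
#' @param seed Integer seed.
#' @return A conformation tibble with `n` rows and model energies; the
#'   integer attribute `origin` gives the generating funnel (0 = outlier).
#' @export
simulate_decoys <- function(model, n, temperature = 1, seed = 1) {
  stopifnot(inherits(model, "funnel_landscape"))
  if (n < 1) stop_ssdu("`n` must be >= 1")
  if (temperature <= 0) stop_ssdu("`temperature` must be positive")
  set.seed(as.integer(seed))
  nf <- length(model$funnels)
  n_out <- round(model$outlier_fraction * n)
  n_fun <- n - n_out
  depths <- vapply(model$funnels, `[[`, 0, "depth")
  w <- exp(-(depths - min(depths)) / temperature)
  w <- w / sum(w)
  counts <- floor(w * n_fun)
  rem <- n_fun - sum(counts)
  if (rem > 0) {
    top <- order(w * n_fun - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  rows <- vector("list", nf + 1)
  origin <- integer(0)
  for (j in seq_len(nf)) {
    kj <- counts[j]
    if (kj == 0) { rows[[j]] <- NULL; next }
    fn <- model$funnels[[j]]
    ev <- eigen(fn$A, symmetric = TRUE)
    # covariance = temperature * A^-1
    half <- ev$vectors %*% diag(sqrt(temperature / ev$values))
    x <- matrix(rnorm(5 * kj), kj, 5) %*% t(half)
    x <- sweep(x, 2, fn$center, `+`)
    r <- fn$r0 + rnorm(kj, 0, sqrt(temperature / (2 * fn$k_r)))
    r <- pmax(r, 0.05 * fn$r0)
    rows[[j]] <- cbind(r, x)
    origin <- c(origin, rep(j, kj))
  }
  if (n_out > 0) {
    centers <- do.call(rbind, lapply(model$funnels, `[[`, "center"))
    spread <- max(vapply(model$funnels, function(f) 1 / sqrt(min(f$lambda)), 0))
    lo <- apply(centers, 2, min) - 4 * spread * sqrt(temperature)
    hi <- apply(centers, 2, max) + 4 * spread * sqrt(temperature)
    x <- matrix(runif(5 * n_out, rep(lo, each = n_out), rep(hi, each = n_out)),
                n_out, 5)
    r0s <- vapply(model$funnels, `[[`, 0, "r0")
    r <- runif(n_out, 0.5 * min(r0s), 1.5 * max(r0s))
    rows[[nf + 1]] <- cbind(r, x)
    origin <- c(origin, rep(0L, n_out))
  }
  m <- do.call(rbind, rows)
  out <- conformations(r = m[, 1], a = m[, 2], b = m[, 3],
                       y1 = m[, 4], y2 = m[, 5], y3 = m[, 6])
  out$energy <- energy(model, out)
  attr(out, "origin") <- origin
  out
}

#' Toy rigid-body physical energy (Lennard-Jones + Coulomb)
#'
#' A minimal physical energy over two point sets:
#' \deqn{f(\psi) = w_{VDW} \sum 4\epsilon[(\sigma/r_{ij})^{12} -
#'   (\sigma/r_{ij})^6] + w_{COUL} \sum k_e q_i q_j / (\epsilon_r r_{ij}),}
#' pairs running over receptor x placed-ligand atoms. The repulsive LJ term
#' uses a soft core (`r_ij` replaced by `max(r_ij, 0.6 sigma)`) so clashes
#' stay bounded, which underestimation over sampled minima relies on.
#' `k_e = 332.0636` kcal A / (mol e^2).
#'
#' @param receptor,ligand [rigid_body()] objects (ligand centroid-relative).
#' @param w_vdw,w_coul Dimensionless weights of the two terms. Coulomb with a
#'   nonzero weight requires charges on both bodies.
#' @param epsilon,sigma LJ well depth (kcal/mol) and diameter (Angstrom).
#' @param eps_r Relative dielectric constant.
#' @return An object of class `toy_rigid_energy`; evaluate with [energy()].
#' @export
toy_rigid_energy <- function(receptor, ligand, w_vdw = 1, w_coul = 0,
                             epsilon = 0.2, sigma = 3.5, eps_r = 15) {
  stopifnot(inherits(receptor, "rigid_body"), inherits(ligand, "rigid_body"))
  if (!is.finite(w_vdw) || !is.finite(w_coul))
    stop_ssdu("energy weights must be finite")
  if (w_coul != 0 && (is.null(receptor$charges) || is.null(ligand$charges)))
    stop_ssdu("Coulomb term requires charges on both bodies")
  structure(list(receptor = receptor, ligand = ligand, w_vdw = w_vdw,
                 w_coul = w_coul, epsilon = epsilon, sigma = sigma,
                 eps_r = eps_r, ke = 332.0636),
            class = "toy_rigid_energy")
}

#' @rdname energy
#' @export
energy.toy_rigid_energy <- function(model, psi, ...) {
  m <- psi_matrix(psi)
  vapply(seq_len(nrow(m)), function(i) {
    placed <- place_ligand(model$ligand, m[i, ])
    rx <- model$receptor$coords
    lx <- placed$coords
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), `+`) - 2 * rx %*% t(lx)
    d <- sqrt(pmax(d2, 0))
    e <- 0
    if (model$w_vdw != 0) {
      dsoft <- pmax(d, 0.6 * model$sigma)
      sr6_rep <- (model$sigma / dsoft)^6
      sr6_att <- (model$sigma / pmax(d, 1e-6))^6
      sr6_att <- pmin(sr6_att, (1 / 0.6)^6)  # cap attraction at the soft core too
      e <- e + model$w_vdw * 4 * model$epsilon * sum(sr6_rep^2 - sr6_att)
    }
    if (model$w_coul != 0) {
      qq <- outer(model$receptor$charges, placed$charges)
      e <- e + model$w_coul * model$ke * sum(qq / (model$eps_r * pmax(d, 0.6 * model$sigma)))
    }
    e
  }, 0)
}
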