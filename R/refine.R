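#' Parameters of the refinement loop
#'
#' Bundles and validates all tunables of [ssdu_refine()]. Defaults follow
#' the published protocol: DBSCAN with `eps = 1.0` and `n_min = 100`, fit-set
#' fraction `eta = 0.3`, at most 3 iterations, and `k_bar` (samples per
#' cluster per iteration) defaulting to the ensemble size.
#'
#' @param eps DBSCAN neighbour radius (> 0).
#' @param n_min DBSCAN minimum cluster size (>= 1).
#' @param eta Fraction of lowest-energy cluster members used as the
#'   underestimation fit set, in (0, 1].
#' @param beta Sampling-range constant (> 0): each principal coordinate is
#'   perturbed uniformly in `(-0.5 beta sigma_i, 0.5 beta sigma_i)`.
#' @param k_bar Samples drawn per cluster per iteration; `NULL` means "the
#'   ensemble size".
#' @param max_iter Iteration cap (>= 1).
#' @param degree Underestimator degree (2, 4 or 6).
#' @param permissive_dim Dimension of the permissive subspace (2 or 3).
#' @param rel_tol Early stop when the best energy improves by less than this
#'   relative amount between iterations.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `ssdu_params`.
#' @export
ssdu_params <- function(eps = 1.0, n_min = 100, eta = 0.3, beta = 2,
                        k_bar = NULL, max_iter = 3, degree = 4,
                        permissive_dim = 3, rel_tol = 1e-4, seed = 1) {
  if (eps <= 0) stop_ssdu("`eps` must be positive")
  if (n_min < 1) stop_ssdu("`n_min` must be >= 1")
  if (eta <= 0 || eta > 1) stop_ssdu("`eta` must be in (0, 1]")
  if (beta < 0) stop_ssdu("`beta` must be >= 0")
  if (!is.null(k_bar) && k_bar < 1) stop_ssdu("`k_bar` must be >= 1")
  if (max_iter < 1) stop_ssdu("`max_iter` must be >= 1")
  if (!degree %in% c(2, 4, 6)) stop_ssdu("`degree` must be 2, 4 or 6")
  if (!permissive_dim %in% c(2, 3)) stop_ssdu("`permissive_dim` must be 2 or 3")
  structure(list(eps = eps, n_min = n_min, eta = eta, beta = beta,
                 k_bar = k_bar, max_iter = max_iter, degree = degree,
                 permissive_dim = permissive_dim, rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "ssdu_params")
}

#' Density-based clustering with outlier elimination (DBSCAN)
#'
#' Standard DBSCAN semantics on the Euclidean distance: a point is a *core*
#' point if at least `n_min` points (itself included) lie within `eps`;
#' clusters are the maximal density-connected sets of core points plus the
#' border points they reach; everything else is noise (label -1). Border
#' points reachable from several clusters join the earliest-founded one
#' (founding order = input order of each cluster's first core point), which
#' makes the partition reproducible and independent of internal scan details.
#'
#' @param x Points: matrix or data frame, one row per observation.
#' @param eps Neighbour radius (> 0).
#' @param n_min Minimum neighbourhood size (self included) for a core point.
#' @return A tibble with `point` (row index), `label` (0-based cluster id,
#'   -1 for outliers), and `core` (logical).
#' @examples
#' x <- rbind(matrix(rnorm(40, 0, .1), 20), matrix(rnorm(40, 5, .1), 20))
#' dbscan_cluster(x, eps = 1, n_min = 5)
#' @export
dbscan_cluster <- function(x, eps, n_min) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1) stop_ssdu("no points to cluster")
  D <- as.matrix(stats::dist(x))
  nb <- D <= eps
  core <- rowSums(nb) >= n_min
  label <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != -1L) next
    # found a new cluster: flood fill over core points
    label[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      reach <- which(nb[j, ] & label == -1L)
      if (length(reach) > 0) {
        label[reach] <- cl
        queue <- c(queue, reach[core[reach]])
      }
    }
    cl <- cl + 1L
  }
  tibble::tibble(point = seq_len(n), label = label, core = core)
}

#' Lowest-energy fit set of a cluster
#'
#' Returns the indices of the `ceiling(eta * n)` lowest-energy members (ties
#' broken by input order). The underestimator is fitted to the envelope of a
#' cluster's best local minima, not to its full population.
#'
#' @param energies Member energies.
#' @param eta Fraction in (0, 1].
#' @return Integer indices into `energies`.
#' @export
select_fit_set <- function(energies, eta) {
  n <- length(energies)
  if (n < 1) stop_ssdu("empty cluster")
  if (eta <= 0 || eta > 1) stop_ssdu("`eta` must be in (0, 1]")
  k <- ceiling(eta * n)
  order(energies)[seq_len(k)]
}

#' Rigid-body local minimization of a conformation
#'
#' Quasi-Newton (BFGS, finite-difference gradients) descent of the energy
#' model over the full 6D parameterization, from the given conformation. The
#' returned energy never exceeds the starting energy.
#'
#' @param model An energy model (see [energy()]).
#' @param psi A one-row conformation tibble or numeric 6-vector.
#' @param maxit Iteration cap for the quasi-Newton search.
#' @param tol Relative convergence tolerance.
#' @return A one-row conformation tibble with the minimized `energy`.
#' @export
local_minimize <- function(model, psi, maxit = 200, tol = 1e-10) {
  v <- as_psi_vector(psi)
  f0 <- energy(model, v)
  if (!is.finite(f0)) stop_ssdu("energy is not finite at the start point")
  fn <- function(p) {
    if (p[1] <= 0) return(f0 + 1e6 + 1e6 * (0 - p[1]))  # keep r positive
    e <- energy(model, p)
    if (!is.finite(e)) f0 + 1e6 else e
  }
  o <- optim(v, fn, method = "BFGS",
             control = list(maxit = maxit, reltol = tol))
  if (o$value > f0) o <- list(par = v, value = f0)  # descent contract
  conformations(r = o$par[1], a = o$par[2], b = o$par[3],
                y1 = o$par[4], y2 = o$par[5], y3 = o$par[6],
                energy = o$value)
}

#' Biased sampling around an underestimator minimum
#'
#' Builds the 5D target `z* = (phi*, mean z4, mean z5)` (restrictive
#' coordinates approximated by their cluster means), perturbs it `k_bar`
#' times with independent uniform noise in `(-0.5 beta sigma_i,
#' 0.5 beta sigma_i)` per principal coordinate, and maps the perturbed points
#' back to reduced coordinates `x = W (z* + s) + xbar`.
#'
#' @param basis A [fit_pca()] basis of the cluster.
#' @param phi_star Permissive coordinates of the underestimator minimum.
#' @param z Cluster members in principal coordinates (rows), used for the
#'   restrictive-coordinate means.
#' @param beta Range constant (>= 0); 0 collapses all draws onto `z*`.
#' @param k_bar Number of samples (>= 1).
#' @param seed Integer seed.
#' @return A tibble of reduced coordinates (columns `a b y1 y2 y3`).
#' @export
sample_around <- function(basis, phi_star, z, beta, k_bar, seed) {
  if (k_bar < 1) stop_ssdu("`k_bar` must be >= 1")
  p <- length(basis$sigma)
  phi_star <- as.double(phi_star)
  nd <- length(phi_star)
  zbar <- colMeans(coord_matrix(z, p))
  z_star <- c(phi_star, zbar[seq.int(nd + 1, p)])
  set.seed(as.integer(seed))
  s <- matrix(runif(k_bar * p, -0.5, 0.5), k_bar, p)
  s <- sweep(s, 2, beta * basis$sigma, `*`)
  xt <- from_principal(basis, sweep(s, 2, z_star, `+`))
  colnames(xt) <- red_cols
  tibble::as_tibble(xt)
}

#' Rebuild conformations from reduced coordinates
#'
#' Appends the cluster's mean center-to-center distance `r_bar` to each
#' reduced-coordinate sample, restoring full 6D conformations.
#'
#' @param x_tilde Reduced coordinates (tibble with columns `a b y1 y2 y3`).
#' @param r_bar Positive scalar distance.
#' @return A conformation tibble.
#' @export
reconstruct <- function(x_tilde, r_bar) {
  if (length(r_bar) != 1 || !is.finite(r_bar) || r_bar <= 0)
    stop_ssdu("`r_bar` must be a positive scalar")
  attach_distance(x_tilde, r_bar)
}

#' Refine a docking ensemble by subspace underestimation
#'
#' The full refinement loop. Each iteration: (1) cluster the ensemble's
#' reduced coordinates with DBSCAN (`eps`, `n_min`), dropping outliers;
#' (2) per cluster - fit PCA, take the `eta` lowest-energy members, locally
#' minimize them, fit an SOS-convex polynomial underestimator to their
#' permissive coordinates and energies, minimize it, draw `k_bar` biased
#' samples around the minimum ([sample_around()]), rebuild full conformations
#' with the cluster's mean `r`, and locally minimize each new sample;
#' (3) merge all new conformations with the current ensemble and keep the
#' `K` lowest energies. The loop stops after `max_iter` iterations or when
#' the best energy improves by less than `rel_tol` relatively.
#'
#' The output always has exactly `K` rows, its sorted energies dominate the
#' input's elementwise, and the run is fully reproducible from
#' `params$seed`. If DBSCAN finds no cluster the input is returned unchanged
#' with a warning; a cluster whose underestimation fails is skipped with a
#' warning.
#'
#' @param ensemble Input conformation tibble with finite energies (size `K`).
#' @param model An energy model (see [energy()]).
#' @param params An [ssdu_params()] object.
#' @return An object of class `ssdu_refined`: list with `ensemble` (the
#'   refined tibble), `input`, `history` (per-iteration tibble),
#'   `cluster_info` (per-iteration, per-cluster diagnostics: size, mean `r`,
#'   underestimator minimum and total gap, and the minimizer mapped back to
#'   reduced coordinates as the `x_star` list-column), and `params`.
#' @export
ssdu_refine <- function(ensemble, model, params = ssdu_params()) {
  stopifnot(inherits(params, "ssdu_params"))
  validate_ensemble(ensemble, require_energy = TRUE)
  K <- nrow(ensemble)
  k_bar <- params$k_bar %||% K
  current <- tibble::as_tibble(ensemble[ens_cols])
  history <- list()
  cluster_info <- list()
  best_prev <- Inf
  for (iter in seq_len(params$max_iter)) {
    X <- as.matrix(reduce_coords(current))
    cl <- dbscan_cluster(X, params$eps, params$n_min)
    ids <- sort(unique(cl$label[cl$label >= 0]))
    if (length(ids) == 0) {
      warning("DBSCAN found no cluster (all points are outliers); ",
              "returning the ensemble unchanged", call. = FALSE)
      if (iter == 1) {
        return(structure(list(ensemble = current, input = ensemble,
                              history = tibble::tibble(),
                              cluster_info = tibble::tibble(),
                              params = params),
                         class = "ssdu_refined"))
      }
      break
    }
    new_rows <- list()
    for (ci in ids) {
      members <- which(cl$label == ci)
      res <- tryCatch(
        refine_cluster(current[members, ], model, params, k_bar,
                       iter = iter, cluster = ci),
        error = function(e) {
          warning("cluster ", ci, " skipped at iteration ", iter, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(res)) {
        res$info$iteration <- iter
        new_rows[[length(new_rows) + 1]] <- res
      }
    }
    cluster_info[[length(cluster_info) + 1]] <-
      dplyr::bind_rows(lapply(new_rows, `[[`, "info"))
    pool <- dplyr::bind_rows(c(list(current), lapply(new_rows, `[[`, "samples")))
    pool <- dplyr::arrange(pool, .data$energy)
    current <- pool[seq_len(K), ]
    best <- current$energy[1]
    history[[iter]] <- tibble::tibble(
      iteration = iter, n_clusters = length(ids),
      n_outliers = sum(cl$label == -1L),
      n_new = sum(vapply(new_rows, function(r) nrow(r$samples), 0L)),
      best_energy = best,
      median_energy = stats::median(current$energy))
    if (is.finite(best_prev) &&
        (best_prev - best) < params$rel_tol * abs(best_prev)) {
      best_prev <- best
      break
    }
    best_prev <- best
  }
  structure(list(ensemble = current, input = ensemble,
                 history = dplyr::bind_rows(history),
                 cluster_info = dplyr::bind_rows(cluster_info),
                 params = params),
            class = "ssdu_refined")
}

# One cluster's exploration step: PCA, fit set, local minimization,
# underestimation in the permissive subspace, biased resampling.
refine_cluster <- function(members, model, params, k_bar, iter, cluster) {
  X <- as.matrix(reduce_coords(members))
  basis <- fit_pca(X)
  fit_idx <- select_fit_set(members$energy, params$eta)
  mins <- dplyr::bind_rows(lapply(fit_idx, function(i)
    local_minimize(model, members[i, ])))
  z_min <- to_principal(basis, as.matrix(reduce_coords(mins)))
  phi <- permissive(z_min, params$permissive_dim)
  U <- fit_underestimator(phi, mins$energy, degree = params$degree)
  start <- phi[which.min(mins$energy), ]
  ms <- minimize_convex(U, init = start)
  z_all <- to_principal(basis, X)
  xt <- sample_around(basis, ms$phi_star, z_all, params$beta, k_bar,
                      seed = child_seed(params$seed, iter, cluster))
  r_bar <- mean(members$r)
  fresh <- reconstruct(xt, r_bar)
  samples <- dplyr::bind_rows(lapply(seq_len(nrow(fresh)), function(i)
    local_minimize(model, fresh[i, ])))
  # underestimator minimizer mapped back to reduced coordinates (z* with the
  # restrictive coordinates at their cluster means)
  z_star <- c(ms$phi_star, colMeans(z_all)[-seq_along(ms$phi_star)])
  x_star <- drop(from_principal(basis, z_star))
  info <- tibble::tibble(cluster = cluster, size = nrow(members),
                         r_bar = r_bar, u_min_value = ms$value,
                         u_total_gap = U$fit$total_gap,
                         x_star = list(x_star))
  list(samples = samples, underestimator = U, phi_star = ms$phi_star,
       info = info)
}

#' @export
print.ssdu_refined <- function(x, ...) {
  cat("<ssdu_refined> K =", nrow(x$ensemble), "conformations;",
      nrow(x$history), "iteration(s); best energy",
      signif(min(x$ensemble$energy), 6), "\n")
  invisible(x)
}

#' Per-iteration summary of a refinement run
#'
#' @param x An `ssdu_refined` object.
#' @param ... Unused.
#' @return The history tibble: iteration, cluster/outlier counts, number of
#'   new conformations, best and median energy.
#' @export
#' @method tidy ssdu_refined
tidy.ssdu_refined <- function(x, ...) x$history

#' One-row summary of a refinement run
#'
#' @param x An `ssdu_refined` object.
#' @param ... Unused.
#' @return A one-row tibble with ensemble size, iterations run, input and
#'   output best energies.
#' @export
#' @method glance ssdu_refined
glance.ssdu_refined <- function(x, ...) {
  tibble::tibble(
    K = nrow(x$ensemble),
    iterations = nrow(x$history),
    best_input = min(x$input$energy),
    best_refined = min(x$ensemble$energy),
    median_input = stats::median(x$input$energy),
    median_refined = stats::median(x$ensemble$energy)
  )
}
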