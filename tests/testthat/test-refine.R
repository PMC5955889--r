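test_that("DBSCAN separates well-spaced blobs with no outliers", {
  set.seed(1)
  x <- rbind(matrix(rnorm(2000, 0, 0.1), 200, 10 / 2 * 2)[, 1:5],
             matrix(rnorm(1000, 100, 0.1), 200, 5))
  cl <- dbscan_cluster(x, eps = 1, n_min = 10)
  expect_identical(length(unique(cl$label[cl$label >= 0])), 2L)
  expect_identical(sum(cl$label == -1L), 0L)
  expect_true(same_partition(cl$label, oracle_dbscan(x, 1, 10)))
})

test_that("DBSCAN labels everything noise when nothing is dense", {
  x <- diag(5) * 100
  cl <- dbscan_cluster(x, eps = 1, n_min = 2)
  expect_true(all(cl$label == -1L))
  expect_true(all(!cl$core))
})

test_that("DBSCAN matches the density-connectivity oracle on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    nblob <- sample(1:4, 1)
    x <- do.call(rbind, lapply(seq_len(nblob), function(b)
      matrix(rnorm(5 * sample(20:60, 1), b * 4, runif(1, 0.2, 1.2)), ncol = 5)))
    x <- rbind(x, matrix(runif(5 * 20, -10, 10 + 4 * nblob), 20, 5))
    eps <- runif(1, 0.5, 2)
    n_min <- sample(4:12, 1)
    ours <- dbscan_cluster(x, eps, n_min)$label
    expect_true(same_partition(ours, oracle_dbscan(x, eps, n_min)))
  }
})

test_that("DBSCAN partitions are invariant to input order", {
  set.seed(2)
  x <- rbind(matrix(rnorm(500, 0, 0.3), 100, 5),
             matrix(rnorm(500, 3, 0.3), 100, 5))
  l1 <- dbscan_cluster(x, 1, 8)$label
  perm <- sample(200)
  l2 <- dbscan_cluster(x[perm, ], 1, 8)$label
  expect_true(same_partition(l1, l2[order(perm)]))
})

test_that("every DBSCAN cluster holds at least n_min points", {
  n_clustered <- 0
  for (seed in 1:5) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(5 * 60, 0, 0.5), 60, 5),
               matrix(rnorm(5 * 90, 0, 3), 90, 5))
    cl <- dbscan_cluster(x, eps = 1.2, n_min = 8)
    sizes <- table(cl$label[cl$label >= 0])
    n_clustered <- n_clustered + length(sizes)
    if (length(sizes)) expect_true(all(sizes >= 8))
  }
  expect_gt(n_clustered, 0)
})

test_that("fit sets are the lowest-energy fraction with a ceiling rule", {
  e <- c(5, 1, 4, 2, 3, 9, 0, 8, 7, 6)
  expect_identical(select_fit_set(e, 1), order(e))
  idx <- select_fit_set(e, 0.3)
  expect_identical(sort(e[idx]), c(0, 1, 2))
  expect_lte(max(e[idx]), min(e[-idx]))
  expect_identical(length(select_fit_set(e[1:4], 0.3)), 2L)  # ceiling(1.2)
})

test_that("local minimization descends to analytic minima of quadratics", {
  A6 <- diag(c(2, 1, 3, 1, 2, 1))
  ctr <- c(8, 0.2, -0.1, 0, 0.3, 0)
  model <- function(psi) sum((psi - ctr) * (A6 %*% (psi - ctr))) - 5
  for (seed in 1:5) {
    set.seed(seed)
    start <- ctr + rnorm(6, 0, 0.5)
    start[1] <- abs(start[1]) + 1
    out <- local_minimize(model, start)
    expect_equal(as.double(out[1, 1:6]), ctr, tolerance = 1e-4)
    expect_equal(out$energy, -5, tolerance = 1e-6)
  }
  # stationarity: starting at the minimum stays put
  out0 <- local_minimize(model, ctr)
  expect_equal(as.double(out0[1, 1:6]), ctr, tolerance = 1e-8)
  # descent contract on a rugged model
  fl <- funnel_landscape(funnel(), ruggedness = 0.4, seed = 5)
  st <- conformations(r = 10.3, a = 0.4, b = -0.2, y1 = 0.1, y2 = 0, y3 = 0.2)
  res <- local_minimize(fl, st)
  expect_lte(res$energy, energy(fl, st))
})

test_that("biased sampling respects the uniform ranges in principal coords", {
  set.seed(3)
  X <- matrix(rnorm(500), 100, 5) %*% diag(c(3, 2, 1, .5, .2))
  basis <- fit_pca(X)
  z <- to_principal(basis, X)
  phi_star <- c(0.5, -0.5, 0.2)
  beta <- 2

  x0 <- sample_around(basis, phi_star, z, beta = 0, k_bar = 7, seed = 1)
  expect_identical(nrow(x0), 7L)
  expect_lt(max(abs(as.matrix(x0) - matrix(as.matrix(x0)[1, ], 7, 5, byrow = TRUE))), 1e-12)

  xs <- sample_around(basis, phi_star, z, beta, k_bar = 5000, seed = 2)
  zs <- to_principal(basis, as.matrix(xs))
  z_star <- c(phi_star, colMeans(z)[4:5])
  dev <- abs(sweep(zs, 2, z_star))
  expect_true(all(sweep(dev, 2, 0.5 * beta * basis$sigma + 1e-12, `<=`)))
  # uniform moments: sd -> beta * sigma / sqrt(12)
  sds <- apply(zs, 2, sd)
  expect_lt(max(abs(sds / (beta * basis$sigma / sqrt(12)) - 1)), 0.05)
})

test_that("reconstruction appends the mean distance", {
  xt <- tibble::tibble(a = c(0, 1), b = 0, y1 = 0, y2 = 0, y3 = 0)
  out <- reconstruct(xt, r_bar = 7)
  expect_identical(out$r, c(7, 7))
  expect_identical(nrow(out), nrow(xt))
  expect_equal(mean(c(6, 8)), 7)
  expect_error(reconstruct(xt, -1), "positive")
})

small_run <- function(seed = 5, max_iter = 2) {
  fl <- funnel_landscape(funnel(center = c(0.5, -0.3, 0.2, 0, 0.1)),
                         ruggedness = 0.3, seed = 11)
  dec <- simulate_decoys(fl, 150, temperature = 1, seed = seed)
  p <- ssdu_params(n_min = 20, k_bar = 60, max_iter = max_iter, seed = seed)
  list(fl = fl, dec = dec, res = ssdu_refine(dec, fl, p))
}

test_that("refinement keeps the ensemble size and dominates input energies", {
  run <- small_run()
  expect_identical(nrow(run$res$ensemble), nrow(run$dec))
  expect_lte(min(run$res$ensemble$energy), min(run$dec$energy))
  expect_true(all(sort(run$res$ensemble$energy) <= sort(run$dec$energy)))
  expect_gt(nrow(run$res$history), 0)
  expect_true(all(diff(run$res$history$best_energy) <= 1e-12))
})

test_that("refinement is bit-for-bit reproducible from the seed", {
  r1 <- small_run(seed = 9)$res
  r2 <- small_run(seed = 9)$res
  expect_identical(as.matrix(r1$ensemble), as.matrix(r2$ensemble))
  expect_identical(r1$history, r2$history)
})

test_that("an ensemble of identical conformations passes through unchanged", {
  fl <- funnel_landscape(funnel(), ruggedness = 0, seed = 1)
  one <- conformations(r = 10, a = 0.1, b = 0.1, y1 = 0, y2 = 0, y3 = 0)
  ens <- one[rep(1, 40), ]
  ens$energy <- energy(fl, ens)
  p <- ssdu_params(n_min = 10, k_bar = 20, max_iter = 1, seed = 1)
  res <- suppressWarnings(ssdu_refine(ens, fl, p))
  expect_identical(nrow(res$ensemble), 40L)
  expect_true(all(res$ensemble$energy <= ens$energy[1] + 1e-12))
})

test_that("all-outlier ensembles return unchanged with a warning", {
  fl <- funnel_landscape(funnel(), ruggedness = 0, seed = 1)
  set.seed(4)
  ens <- conformations(r = runif(30, 5, 15), a = runif(30, -50, 50),
                       b = runif(30, -50, 50), y1 = rnorm(30), y2 = rnorm(30),
                       y3 = rnorm(30))
  ens$energy <- energy(fl, ens)
  p <- ssdu_params(n_min = 25, k_bar = 10, max_iter = 1, seed = 1)
  expect_warning(res <- ssdu_refine(ens, fl, p), "no cluster")
  expect_identical(as.matrix(res$ensemble[, 1:6]), as.matrix(ens[, 1:6]))
})

test_that("parameter validation matches the documented invariants", {
  expect_error(ssdu_params(eps = 0), "eps")
  expect_error(ssdu_params(eta = 1.5), "eta")
  expect_error(ssdu_params(max_iter = 0), "max_iter")
  expect_error(ssdu_params(degree = 3), "degree")
})
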