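test_that("a smooth single funnel bottoms out exactly at its center", {
  fn <- funnel(center = c(1, -1, 0, 0.5, 0), depth = -30)
  fl <- funnel_landscape(fn, ruggedness = 0, seed = 1)
  at_center <- conformations(r = fn$r0, a = 1, b = -1, y1 = 0, y2 = 0.5, y3 = 0)
  expect_equal(energy(fl, at_center), -30)
  set.seed(2)
  off <- random_ensemble(50, seed = 2)
  expect_true(all(energy(fl, off) > -30))
  gt <- ground_truth(fl)
  expect_equal(gt$energy, -30)
  expect_equal(gt$x, fn$center)
})

test_that("with two smooth funnels the deeper center is the global minimum", {
  fl <- funnel_landscape(list(funnel(center = rep(0, 5), depth = -50),
                              funnel(center = c(4, 4, 0, 0, 0), depth = -40)),
                         ruggedness = 0, seed = 1)
  gt <- ground_truth(fl)
  expect_equal(gt$x, rep(0, 5))
  expect_equal(gt$energy, -50)
})

test_that("rugged ground truth agrees with a dense grid oracle", {
  # variation confined to the first two coordinates so the oracle can grid
  fn <- funnel(center = c(0.3, -0.4, 0, 0, 0), depth = -20)
  fl <- funnel_landscape(fn, ruggedness = 0.5, omega = c(4, 4, 0, 0, 0),
                         seed = 13)
  gt <- ground_truth(fl)
  g <- seq(-1.2, 1.2, by = 0.005)
  grid <- as.matrix(expand.grid(a = g + 0.3, b = g - 0.4))
  X <- cbind(grid, matrix(0, nrow(grid), 3))
  vals <- energy(fl, cbind(fn$r0, X))
  expect_lt(min(vals) - gt$energy, 1e-4)       # grid never beats the truth much
  best <- X[which.min(vals), ]
  expect_lt(sqrt(sum((best - gt$x)^2)), 0.01)  # within one grid step
})

test_that("ground truth dominates probe points and random search", {
  fl <- funnel_landscape(funnel(center = c(0.5, 0, -0.5, 0, 0.2)),
                         ruggedness = 0.4, seed = 21)
  gt <- ground_truth(fl)
  for (fn in fl$funnels) {
    at <- conformations(r = fn$r0, a = fn$center[1], b = fn$center[2],
                        y1 = fn$center[3], y2 = fn$center[4], y3 = fn$center[5])
    expect_lte(gt$energy, energy(fl, at))
  }
  set.seed(4)
  n <- 1e5
  X <- cbind(runif(n, 8, 12),
             sweep(matrix(runif(5 * n, -1.5, 1.5), n, 5), 2, fl$funnels[[1]]$center, `+`))
  expect_lte(gt$energy, min(energy(fl, X)) + 1e-6)
})

test_that("decoy ensembles have the stated size, outlier count and law", {
  fl <- funnel_landscape(funnel(), ruggedness = 0.2, outlier_fraction = 0.1,
                         seed = 3)
  dec <- simulate_decoys(fl, 500, temperature = 1, seed = 5)
  expect_identical(nrow(dec), 500L)
  expect_identical(sum(attr(dec, "origin") == 0L), as.integer(round(0.1 * 500)))
  expect_true(all(is.finite(dec$energy)))

  # per-funnel sample covariance ~ temperature * A^-1 (Monte-Carlo check)
  fl0 <- funnel_landscape(funnel(), ruggedness = 0, outlier_fraction = 0,
                          seed = 3)
  big <- simulate_decoys(fl0, 1e4, temperature = 2, seed = 8)
  S <- cov(as.matrix(reduce_coords(big)))
  target <- 2 * solve(fl0$funnels[[1]]$A)
  scale_ij <- sqrt(diag(target) %o% diag(target))
  expect_lt(max(abs(S - target) / scale_ij), 0.15)
})

test_that("decoy generation is deterministic and concentrates as T -> 0", {
  fl <- funnel_landscape(funnel(), ruggedness = 0.1, seed = 2)
  d1 <- simulate_decoys(fl, 200, 1, seed = 42)
  d2 <- simulate_decoys(fl, 200, 1, seed = 42)
  expect_identical(as.matrix(d1), as.matrix(d2))

  fl0 <- funnel_landscape(funnel(), ruggedness = 0, outlier_fraction = 0,
                          seed = 2)
  cold <- simulate_decoys(fl0, 300, temperature = 1e-6, seed = 1)
  dmax <- max(sqrt(rowSums(sweep(as.matrix(reduce_coords(cold)), 2,
                                 fl0$funnels[[1]]$center)^2)))
  expect_lt(dmax, 0.01)
})

test_that("decoy clouds are much wider along permissive directions", {
  Q <- random_rotation5(6)
  fn <- funnel(lambda_permissive = 2, lambda_restrictive = 300, rotation = Q)
  fl <- funnel_landscape(fn, ruggedness = 0.2, outlier_fraction = 0, seed = 6)
  dec <- simulate_decoys(fl, 2e4, 1, seed = 7)
  Z <- sweep(as.matrix(reduce_coords(dec)), 2, fn$center) %*% Q
  spread <- apply(Z, 2, sd)
  expect_gte(min(spread[1:3]) / max(spread[4:5]), 10)
})

test_that("energy models are deterministic", {
  fl <- funnel_landscape(funnel(), ruggedness = 0.3, seed = 9)
  ens <- random_ensemble(20, seed = 3)
  expect_identical(energy(fl, ens), energy(fl, ens))
})

test_that("the toy rigid-body energy reproduces closed-form LJ values", {
  rec <- rigid_body(matrix(0, 1, 3))
  lig <- rigid_body(matrix(0, 1, 3))
  eps <- 0.25; sig <- 3.5
  model <- toy_rigid_energy(rec, lig, w_vdw = 2, epsilon = eps, sigma = sig)
  rmin <- 2^(1 / 6) * sig
  e <- energy(model, c(rmin, 0, 0, 0, 0, 0))
  expect_equal(e, 2 * (-eps), tolerance = 1e-12)
  expect_lt(abs(energy(model, c(80, 0, 0, 0, 0, 0))), 1e-6)
  # monotone decay to zero far away
  far <- energy(model, cbind(seq(20, 60, 10), 0, 0, 0, 0, 0))
  expect_true(all(abs(diff(abs(far))) < abs(far[-5]) + 1e-15))
})

test_that("the toy energy matches an explicit pairwise hand sum", {
  rec <- rigid_body(rbind(c(0, 0, 0), c(2, 0, 0)), charges = c(0.5, -0.3))
  lig <- rigid_body(rbind(c(0.5, 0, 0), c(-0.5, 0, 0)), charges = c(0.2, 0.1))
  eps <- 0.2; sig <- 2.0; ke <- 332.0636; epsr <- 4
  model <- toy_rigid_energy(rec, lig, w_vdw = 1.5, w_coul = 0.8,
                            epsilon = eps, sigma = sig, eps_r = epsr)
  psi <- c(8, 0, 0, 0, 0, 0)   # ligand centroid at (0, 0, 8)
  placed <- sweep(lig$coords, 2, c(0, 0, 8), `+`)
  e_hand <- 0
  for (i in 1:2) for (j in 1:2) {
    d <- sqrt(sum((rec$coords[i, ] - placed[j, ])^2))
    e_hand <- e_hand + 1.5 * 4 * eps * ((sig / d)^12 - (sig / d)^6) +
      0.8 * ke * rec$charges[i] * lig$charges[j] / (epsr * d)
  }
  expect_equal(energy(model, psi), e_hand, tolerance = 1e-12)
})

test_that("toy energy configuration errors are caught", {
  rec <- rigid_body(matrix(0, 1, 3))
  lig <- rigid_body(matrix(0, 1, 3))
  expect_error(toy_rigid_energy(rec, lig, w_coul = 1), "charges")
})

test_that("funnel specifications are validated", {
  expect_error(funnel(lambda_permissive = 2, lambda_restrictive = 10), ">= 10")
  expect_error(funnel(center = c(0, 0)), "5-vector")
  expect_error(funnel_landscape(list()), "at least one")
  expect_error(funnel_landscape(funnel(), outlier_fraction = 1), "outlier_fraction")
})
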