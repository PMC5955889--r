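test_that("monomial bases have the stars-and-bars sizes in graded order", {
  expect_identical(nrow(monomial_basis(1, 1)), 2L)           # 1, x
  expect_identical(nrow(monomial_basis(2, 2)), 6L)           # C(4,2)
  expect_identical(nrow(monomial_basis(3, 4)), 35L)          # C(7,4)
  E <- monomial_basis(3, 2)
  expect_true(all(diff(rowSums(E)) >= 0))                    # graded
  expect_identical(E[1, ], c(0L, 0L, 0L))
  expect_error(monomial_basis(0, 2))
})

test_that("data from a convex quadratic is recovered exactly at degree 2", {
  set.seed(10)
  phi <- matrix(rnorm(450), 150, 3)
  A <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3) * 0.5
  b <- rnorm(3); c0 <- 2.5
  f <- rowSums((phi %*% A) * phi) + phi %*% b + c0
  U <- fit_underestimator(phi, f, degree = 2)
  qp <- quad_parts(U)
  expect_lt(max(abs(qp$A - A)), 1e-4)
  expect_lt(max(abs(qp$b - b)), 1e-4)
  expect_lt(abs(qp$c0 - c0), 1e-4)
  expect_lt(U$fit$total_gap, 1e-6 * nrow(phi))
  expect_gte(U$fit$min_gap, -1e-6)
})

test_that("constant energies yield the tight constant underestimator", {
  set.seed(11)
  phi <- matrix(rnorm(90), 30, 3)
  U <- fit_underestimator(phi, rep(4.2, 30), degree = 2)
  expect_lt(max(abs(predict(U, phi) - 4.2)), 1e-5)
})

test_that("polynomial calculus is exact for closed forms", {
  phi <- matrix(rnorm(60), 20, 3)
  f <- rowSums(phi^2) + 1
  U <- fit_underestimator(phi, f, degree = 2)
  p <- c(1, 1, 1)
  expect_equal(predict(U, p), 4, tolerance = 1e-5)
  expect_equal(drop(poly_gradient(U, p)), c(2, 2, 2), tolerance = 1e-4)
  expect_equal(poly_hessian(U, p), 2 * diag(3), tolerance = 1e-4)
})

test_that("gradients match central finite differences on fitted polynomials", {
  d <- rough_energy_data(120, seed = 12)
  for (deg in c(2, 4)) {
    U <- fit_underestimator(d$phi, d$f, degree = deg)
    set.seed(13)
    for (k in 1:10) {
      p <- rnorm(3)
      g <- drop(poly_gradient(U, p))
      h <- 1e-5
      gfd <- vapply(1:3, function(v) {
        e <- numeric(3); e[v] <- h
        (predict(U, p + e) - predict(U, p - e)) / (2 * h)
      }, 0)
      expect_equal(g, gfd, tolerance = 1e-6 * (1 + max(abs(g))))
      H <- poly_hessian(U, p)
      expect_identical(H, t(H))
    }
  }
})

test_that("convex minimization reaches the closed-form quadratic minimum", {
  set.seed(14)
  phi <- matrix(rnorm(300), 100, 3)
  A <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  b <- rnorm(3)
  f <- rowSums((phi %*% A) * phi) + phi %*% b + 1
  U <- fit_underestimator(phi, f, degree = 2)
  m <- minimize_convex(U, init = c(2, -2, 2))
  expect_equal(m$phi_star, drop(-solve(A, b)) / 2, tolerance = 1e-6)
  expect_lte(m$value, min(predict(U, phi)) + 1e-9)
  m2 <- minimize_convex(U, init = c(-5, 5, 0))
  expect_equal(m$phi_star, m2$phi_star, tolerance = 1e-6)
})

test_that("SOS-convexity certification accepts convex and refuses concave forms", {
  E <- monomial_basis(3, 4)
  key <- apply(E, 1, paste, collapse = ",")
  # |phi|^4
  cc <- numeric(nrow(E))
  cc[match(c("4,0,0", "0,4,0", "0,0,4"), key)] <- 1
  cc[match(c("2,2,0", "2,0,2", "0,2,2"), key)] <- 2
  res <- is_sos_convex(cc, n = 3, degree = 4)
  expect_true(res$certified)

  E2 <- monomial_basis(3, 2)
  key2 <- apply(E2, 1, paste, collapse = ",")
  cn <- numeric(nrow(E2))
  cn[match(c("2,0,0", "0,2,0", "0,0,2"), key2)] <- -1
  res2 <- is_sos_convex(cn, n = 3, degree = 2)
  expect_false(res2$certified)
  expect_lt(res2$lambda_min, -1)

  # built to be SOS-convex: squares of affine forms plus a PSD quadratic
  set.seed(15)
  L <- matrix(rnorm(9), 3, 3)
  Apsd <- crossprod(L)
  cc3 <- numeric(nrow(E))
  for (k in 1:3) {
    l <- rnorm(3)
    # (l . phi)^2 expanded
    cc3[match(c("2,0,0", "0,2,0", "0,0,2"), key)] <-
      cc3[match(c("2,0,0", "0,2,0", "0,0,2"), key)] + l^2
    cc3[match("1,1,0", key)] <- cc3[match("1,1,0", key)] + 2 * l[1] * l[2]
    cc3[match("1,0,1", key)] <- cc3[match("1,0,1", key)] + 2 * l[1] * l[3]
    cc3[match("0,1,1", key)] <- cc3[match("0,1,1", key)] + 2 * l[2] * l[3]
  }
  cc3 <- cc3 + 0.5 * cc   # add the certified quartic
  res3 <- is_sos_convex(cc3, n = 3, degree = 4)
  expect_true(res3$certified)
  ev <- eigen(res3$gram, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-7 * (1 + max(abs(cc3))))
})

test_that("fits are feasible with certified convexity on rough data", {
  for (seed in 1:5) {
    d <- rough_energy_data(150, seed = 20 + seed)
    U <- fit_underestimator(d$phi, d$f, degree = 4)
    expect_gte(U$fit$min_gap, -1e-6)
    # spot-check Hessian PSD over the data bounding box
    set.seed(seed)
    lo <- apply(d$phi, 2, min); hi <- apply(d$phi, 2, max)
    for (k in 1:100) {
      p <- runif(3, lo, hi)
      H <- poly_hessian(U, p)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * (1 + max(abs(H))))
    }
  }
})

test_that("degree-4 fits are at least as tight as degree-2 fits", {
  for (seed in 1:5) {
    d <- rough_energy_data(120, seed = 30 + seed)
    U2 <- fit_underestimator(d$phi, d$f, degree = 2)
    U4 <- fit_underestimator(d$phi, d$f, degree = 4)
    expect_lte(U4$fit$total_gap, U2$fit$total_gap)
  }
})

test_that("fits are affinely equivariant", {
  d <- rough_energy_data(100, seed = 40)
  U <- fit_underestimator(d$phi, d$f, degree = 4)
  Us <- fit_underestimator(d$phi, d$f + 7.5, degree = 4)
  expect_lt(max(abs(Us$coeffs - U$coeffs - c(7.5, rep(0, 34)))), 1e-5)

  t <- c(1, -2, 0.5)
  Ut <- fit_underestimator(sweep(d$phi, 2, t, `+`), d$f, degree = 4)
  m <- minimize_convex(U); mt <- minimize_convex(Ut)
  expect_equal(mt$phi_star, m$phi_star + t, tolerance = 1e-4)
})

test_that("degenerate and underdetermined fits stay well defined", {
  phi1 <- matrix(0.5, 40, 3)           # all points identical
  U <- fit_underestimator(phi1, rep(2, 40), degree = 2)
  expect_lt(abs(predict(U, c(0.5, 0.5, 0.5)) - 2), 1e-5)

  set.seed(41)
  phi2 <- matrix(rnorm(30), 10, 3)     # K < number of coefficients
  expect_warning(fit_underestimator(phi2, rnorm(10) + 5, degree = 4),
                 "underdetermined")
  expect_error(fit_underestimator(matrix(0, 0, 3), numeric(0)), "no sample")
})

test_that("degree-6 fits remain feasible underestimators", {
  d <- rough_energy_data(120, seed = 50)
  U6 <- fit_underestimator(d$phi, d$f, degree = 6)
  expect_gte(U6$fit$min_gap, -1e-6)
  expect_gte(U6$gram_min_eig, -1e-6)
  U4 <- fit_underestimator(d$phi, d$f, degree = 4)
  expect_lte(U6$fit$total_gap, U4$fit$total_gap + 1e-6)
})

test_that("tidy and glance expose coefficients and fit quality", {
  d <- rough_energy_data(60, seed = 60)
  U <- fit_underestimator(d$phi, d$f, degree = 2)
  td <- tidy(U)
  expect_identical(nrow(td), 10L)
  expect_identical(td$term[1], "1")
  gl <- glance(U)
  expect_identical(gl$n_samples, 60L)
  expect_gte(gl$min_gap, -1e-6)
})
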