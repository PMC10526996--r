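test_that("eigenvalues satisfy the transcendental condition in their brackets", {
  for (ab in c(0.2, 1, 5, 31)) {
    mu <- robin_eigenvalues(ab, 200)
    n <- seq_along(mu)
    expect_true(all(mu > (n - 0.5) * pi & mu < n * pi))
    expect_true(all(diff(mu) > 0))
    expect_lt(max(abs(mu * cos(mu) + ab * sin(mu))), 1e-10)
  }
  expect_error(robin_eigenvalues(0, 3), "alpha_bar")
  expect_error(robin_eigenvalues(-1, 3), "alpha_bar")
  expect_error(robin_eigenvalues(1, 0), "n_modes")
})

test_that("eigenvalues match an independent bisection oracle", {
  # frozen oracle values for alpha_bar = 1 (roots of tan(mu) = -mu)
  expect_equal(robin_eigenvalues(1, 2), c(2.0287578381104341, 4.9131804394348837),
               tolerance = 1e-10)
  for (ab in c(0.2, 5)) {
    mu <- robin_eigenvalues(ab, 5)
    oracle <- vapply(1:5, function(n) bisect_eigenvalue(ab, n), numeric(1))
    expect_equal(mu, oracle, tolerance = 1e-10)
  }
})

test_that("the Robin eigenvalues approach the Dirichlet and Neumann modes", {
  n <- 1:10
  expect_equal(robin_eigenvalues(1e8, 10), n * pi, tolerance = 1e-6)
  expect_equal(robin_eigenvalues(1e-8, 10), (n - 0.5) * pi, tolerance = 1e-6)
})

test_that("projection coefficients match numerical quadrature", {
  for (ab in c(0.2, 1, 5)) {
    mu <- robin_eigenvalues(ab, 4)
    b <- robin_coefficients(ab, mu)
    bq <- vapply(mu, function(m) quadrature_coefficient(ab, m), numeric(1))
    expect_equal(b, bq, tolerance = 1e-10)
  }
  expect_error(robin_coefficients(1, numeric(0)), "eigenvalue")
})

test_that("eigenmodes are orthogonal under the L2 inner product", {
  mu <- robin_eigenvalues(1, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    ip <- stats::integrate(function(x) sin(mu[i] * x) * sin(mu[j] * x), 0, 1,
                           rel.tol = 1e-12, abs.tol = 1e-13)$value
    expect_lt(abs(ip), 1e-10)
  }
})

test_that("the mode expansion reconstructs the zero initial condition", {
  # The series must cancel the steady profile at t = 0. The basis vanishes at
  # the blood face while the target is -1 there, so the partial sum carries a
  # Gibbs tail ~ 1/(pi N d) at distance d from that endpoint: the error away
  # from the endpoints shrinks like 1/N and is below 1e-3 on [0.1, 0.9] by
  # N = 4000.
  for (ab in c(0.2, 1, 5)) {
    xb <- seq(0.1, 0.9, by = 0.005)
    recon_err <- function(N) {
      es <- robin_eigensystem(ab, N)
      max(abs(colSums(es$b * sin(outer(es$mu, xb))) +
                (1 - (ab / (1 + ab)) * xb)))
    }
    e200 <- recon_err(200)
    e1000 <- recon_err(1000)
    expect_lt(e1000, e200 / 3)             # ~1/N decay
    expect_lt(recon_err(4000), 1e-3)
  }
  # physically: one smoothing instant after the step the interior is still
  # analyte-free, and the evaluated series honours that
  for (ab in c(0.2, 1, 5)) {
    prof <- robin_profile(seq(0.1, 0.9, 0.01), 2e-4, ab, n_modes = 600)
    expect_lt(max(abs(prof)), 1e-3)
  }
})

test_that("Robin profile honours conventions, steady state and the Dirichlet limit", {
  expect_equal(robin_profile(0.7, 0, alpha_bar = 1), 0)
  expect_equal(robin_profile(0, 0, alpha_bar = 1), 1)
  # sensor-face steady state is 1/(1 + alpha_bar)
  expect_equal(robin_profile(1, 50, alpha_bar = 1), 0.5, tolerance = 1e-9)
  expect_equal(robin_profile(1, 50, alpha_bar = 4), 0.2, tolerance = 1e-9)
  xb <- seq(0, 1, 0.05)
  for (tb in c(0.01, 0.1, 1)) {
    expect_lt(max(abs(robin_profile(xb, tb, 1e8, n_modes = 400) -
                        conc_profile_dirichlet(xb, tb))), 1e-4)
  }
})

test_that("Robin response is normalized, monotone, and consistent dimensionally", {
  expect_identical(robin_response_normalized(0, 1), 0)
  expect_equal(robin_response_normalized(30, 1), 1, tolerance = 1e-9)
  tb <- seq(0.01, 3, by = 0.01)
  for (ab in c(0.2, 1, 5)) {
    m <- robin_response_normalized(tb, ab)
    expect_true(all(diff(m) >= -1e-12))
    expect_true(all(m >= 0 & m <= 1 + 1e-9))
  }
  # dimensional response = steady state x normalized response
  skin <- skin_kskin(C0 = 2e-5)
  alpha <- 2.45e-7
  ab <- alpha_bar(alpha, skin)
  expect_equal(robin_response(tb, skin, alpha),
               robin_steady_state(skin, alpha) *
                 robin_response_normalized(tb, ab))
  expect_equal(robin_steady_state(skin, alpha),
               skin$C0 * alpha / (1 + ab))
  expect_equal(robin_steady_state(skin_kskin(C0 = 0), alpha), 0)
})

test_that("Robin response approaches the ideal-flux and concentration envelopes", {
  tb <- seq(0.01, 3, by = 0.01)
  expect_lt(max(abs(robin_response_normalized(tb, 1e8, n_modes = 200) -
                      response_flux(tb))), 1e-4)
  expect_lt(max(abs(robin_response_normalized(tb, 1e-8, n_modes = 200) -
                      response_conc(tb))), 1e-4)
})

test_that("responses order by sensitivity between the two envelopes", {
  tb <- seq(0.02, 3, by = 0.02)
  curves <- rbind(
    response_conc(tb),
    robin_response_normalized(tb, 0.2),
    robin_response_normalized(tb, 1),
    robin_response_normalized(tb, 5),
    response_flux(tb)
  )
  for (k in 1:4) expect_true(all(curves[k + 1, ] >= curves[k, ] - 1e-12))
})

test_that("robin_eigensystem tidiers expose modes and residuals", {
  es <- robin_eigensystem(1, 12)
  td <- tidy(es)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("n", "mu", "b", "residual"))
  expect_equal(nrow(td), 12)
  expect_lt(max(abs(td$residual)), 1e-10)
  gl <- glance(es)
  expect_equal(gl$alpha_bar, 1)
  expect_equal(gl$mu_1, robin_eigenvalues(1, 1))
})

test_that("Robin profile matches the finite-difference oracle", {
  fd <- solve_pde("robin", t_out = c(0.1, 0.2), alpha_bar = 1, nx = 401)
  es <- robin_eigensystem(1, 200)
  for (j in 1:2) {
    exact <- robin_profile(fd$x_bar, fd$t_bar[j], 1, eigensystem = es)
    expect_lt(max(abs(fd$c_bar[j, ] - exact)), 1e-5)
  }
  i_mid <- which(fd$x_bar == 0.5)
  expect_lt(abs(fd$c_bar[1, i_mid] - robin_profile(0.5, 0.1, 1)), 1e-5)
})
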