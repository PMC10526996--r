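test_that("the leading-timescale ratio is exactly 4 for any skin", {
  set.seed(42)
  for (k in 1:5) {
    skin <- skin_barrier(D = 10^stats::runif(1, -11, -6),
                         L = 10^stats::runif(1, -4, -1))
    tc <- leading_timescale("concentration", skin)
    tf <- leading_timescale("ideal_flux", skin)
    expect_equal(tc / tf, 4, tolerance = 1e-14)
    expect_equal(tf, skin$L^2 / (skin$D * pi^2), tolerance = 1e-14)
  }
  expect_error(leading_timescale("robin", skin_timescale()), "robin_leading_timescale")
})

test_that("ethanol response timescales land at the published hours", {
  skin <- skin_timescale()
  expect_equal(seconds_to_hours(leading_timescale("concentration", skin)),
               8.4, tolerance = 0.1 / 8.4)
  expect_equal(seconds_to_hours(leading_timescale("ideal_flux", skin)),
               2.1, tolerance = 0.05 / 2.1)
})

test_that("the Robin timescale interpolates the two envelopes monotonically", {
  skin <- skin_timescale()
  tf <- leading_timescale("ideal_flux", skin)
  tc <- leading_timescale("concentration", skin)
  abs_grid <- c(1e-8, 0.2, 1, 5, 31, 1e8)
  taus <- vapply(abs_grid, robin_leading_timescale, numeric(1), skin = skin)
  expect_true(all(diff(taus) < 0))              # faster as sensitivity grows
  expect_true(all(taus[2:5] > tf & taus[2:5] < tc))
  expect_equal(taus[length(taus)], tf, tolerance = 1e-6)
  expect_equal(taus[1], tc, tolerance = 1e-6)
  mu1 <- 2.0287578381104341
  expect_equal(robin_leading_timescale(1, skin), skin$L^2 / (skin$D * mu1^2),
               tolerance = 1e-10)
})

test_that("integrated intercepts hit their closed-form values", {
  expect_equal(integrated_intercept("ideal_flux"), 1 / 6, tolerance = 1e-10)
  expect_equal(integrated_intercept("concentration"), 1 / 2, tolerance = 1e-10)
  expect_equal(integrated_intercept("concentration") /
                 integrated_intercept("ideal_flux"), 3, tolerance = 0.02 / 3)
})

test_that("term-wise intercepts agree with numerical quadrature", {
  quad <- function(m_bar_fun) {
    stats::integrate(function(t) 1 - m_bar_fun(t), 0, Inf,
                     rel.tol = 1e-12)$value
  }
  expect_equal(integrated_intercept("ideal_flux"), quad(response_flux),
               tolerance = 1e-8)
  expect_equal(integrated_intercept("concentration"), quad(response_conc),
               tolerance = 1e-8)
  for (ab in c(0.2, 1, 5)) {
    expect_equal(
      integrated_intercept("robin", alpha_bar = ab),
      quad(function(t) robin_response_normalized(t, ab, n_modes = 400)),
      tolerance = 1e-8)
  }
})

test_that("the Robin intercept decreases in sensitivity within its bounds", {
  abs_grid <- c(0.1, 0.5, 1, 2, 10, 100)
  vals <- vapply(abs_grid, function(ab)
    integrated_intercept("robin", alpha_bar = ab), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 1 / 6 & vals < 1 / 2))
  expect_error(integrated_intercept("robin"), "alpha_bar")
})

test_that("sensors classify by sensitivity thresholds", {
  out <- classify_sensor(c(0, 0.02, 0.75, 31, 10, 0.1))
  expect_equal(out$label, c("concentration-like", "concentration-like", "robin",
                            "ideal-flux-like", "ideal-flux-like",
                            "concentration-like"))
  expect_equal(out$alpha_bar[4], 31)
  # thresholds are configurable
  expect_equal(classify_sensor(0.75, lower = 0.8)$label, "concentration-like")
  expect_error(classify_sensor(-1), "alpha_bar")
  expect_error(classify_sensor(1, lower = 2, upper = 1), "lower")
})

test_that("timescale_report assembles both metrics with tidiers", {
  skin <- skin_timescale()
  rep <- timescale_report(skin, alpha = 2.45e-7)
  expect_equal(rep$tau_ratio, 4, tolerance = 1e-14)
  expect_equal(rep$intercept_ratio, 3, tolerance = 1e-8)
  expect_gt(rep$tau_robin_s, rep$tau_flux_s)
  expect_lt(rep$tau_robin_s, rep$tau_conc_s)
  td <- tidy(rep)
  expect_true(all(c("tau_ratio", "intercept_robin") %in% td$metric))
  gl <- glance(rep)
  expect_equal(gl$tau_ratio, 4)
  expect_equal(gl$classification, "ideal-flux-like")  # alpha >> this skin's D/L
  # without a sensor the robin rows are absent
  expect_false("alpha_bar" %in% names(glance(timescale_report(skin))))
})
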