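# Shared fixtures: the two published ethanol skin parameterizations and
# small independent oracles used to freeze expected values.

ETHANOL_MW_TEST <- 46.07

skin_timescale <- function() skin_barrier(D = 3e-11, L = um_to_cm(15))
skin_kskin <- function(C0 = 0) skin_barrier(D = 5e-10, L = um_to_cm(15), C0 = C0)

# Independent eigenvalue oracle: plain bisection on mu cos(mu) + ab sin(mu)
# over the known bracket, no shared code with robin_eigenvalues().
bisect_eigenvalue <- function(ab, n, iters = 200) {
  f <- function(mu) mu * cos(mu) + ab * sin(mu)
  lo <- (n - 0.5) * pi + 1e-12
  hi <- n * pi - 1e-12
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Quadrature projection oracle for the Robin coefficients.
quadrature_coefficient <- function(ab, mu) {
  beta <- ab / (1 + ab)
  num <- stats::integrate(function(x) (1 - beta * x) * sin(mu * x), 0, 1,
                          rel.tol = 1e-13)$value
  den <- stats::integrate(function(x) sin(mu * x)^2, 0, 1,
                          rel.tol = 1e-13)$value
  -num / den
}
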