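# Robin-boundary problem: a finite-sensitivity sensor imposes
# D dc/dx|_{x=L} = -alpha c(L,t). In dimensionless variables the separated
# modes are sin(mu_n x_bar) with eigenvalues mu_n solving the transcendental
# condition mu cos(mu) + alpha_bar sin(mu) = 0 (the boundary condition applied
# to the mode shape), one root per interval ((n-1/2) pi, n pi).

robin_eigcondition <- function(mu, alpha_bar) mu * cos(mu) + alpha_bar * sin(mu)

#' Eigenvalues of the Robin-boundary diffusion problem
#'
#' Returns the first `n_modes` positive roots mu_n of
#' \deqn{\mu \cos\mu + \bar\alpha \sin\mu = 0,}
#' each bracketed in ((n - 1/2) pi, n pi) and refined by a bracketing root
#' finder plus Newton polish. As alpha_bar -> Inf the roots approach n pi
#' (the Dirichlet modes); as alpha_bar -> 0 they approach (n - 1/2) pi (the
#' Neumann modes).
#'
#' @param alpha_bar Dimensionless sensor sensitivity alpha L / D, > 0. For
#'   the exact limits use the dedicated Neumann/Dirichlet solutions.
#' @param n_modes Number of eigenvalues to return (>= 1).
#' @return Numeric vector of increasing eigenvalues, length `n_modes`.
#' @examples
#' robin_eigenvalues(1, 3)   # 2.0288, 4.9132, 7.9787
#' @seealso [robin_eigensystem()], [robin_profile()]
#' @export
robin_eigenvalues <- function(alpha_bar, n_modes) {
  stopifnot(is.numeric(alpha_bar), length(alpha_bar) == 1,
            is.numeric(n_modes), length(n_modes) == 1)
  if (!is.finite(alpha_bar) || alpha_bar <= 0) {
    abort("`alpha_bar` must be > 0 (use the Neumann/Dirichlet solutions for the limits).")
  }
  n_modes <- as.integer(n_modes)
  if (n_modes < 1) abort("`n_modes` must be >= 1.")
  vapply(seq_len(n_modes), function(n) {
    lo <- (n - 0.5) * pi
    hi <- n * pi
    root <- uniroot(robin_eigcondition, c(lo, hi), alpha_bar = alpha_bar,
                    tol = 1e-13)$root
    # two Newton steps push the residual to rounding level
    for (k in 1:2) {
      f <- robin_eigcondition(root, alpha_bar)
      fp <- cos(root) - root * sin(root) + alpha_bar * cos(root)
      step <- f / fp
      cand <- root - step
      if (is.finite(cand) && cand > lo && cand < hi) root <- cand
    }
    root
  }, numeric(1))
}

# Dimensionless Robin steady-state profile c_ss(x_bar) = 1 - beta x_bar with
# beta = alpha_bar / (1 + alpha_bar): linear between c(0) = 1 and
# c(1) = 1/(1 + alpha_bar), balancing diffusive supply against sensor uptake.
robin_steady_profile <- function(x_bar, alpha_bar) {
  1 - (alpha_bar / (1 + alpha_bar)) * x_bar
}

#' Projection coefficients of the Robin series solution
#'
#' The transient part of the Robin step response expands the negated
#' steady-state profile on the eigenmodes sin(mu_n x_bar):
#' \deqn{b_n = -\frac{\int_0^1 (1 - \beta \bar x)\sin(\mu_n \bar x)\,
#'   d\bar x}{\int_0^1 \sin^2(\mu_n \bar x)\, d\bar x}, \qquad
#'   \beta = \frac{\bar\alpha}{1 + \bar\alpha},}
#' so that the full solution satisfies the zero initial condition. Both
#' integrals are evaluated in closed form:
#' numerator \eqn{(1-\cos\mu)/\mu - \beta(\sin\mu - \mu\cos\mu)/\mu^2},
#' denominator \eqn{1/2 - \sin(2\mu)/(4\mu)}.
#'
#' @inheritParams robin_eigenvalues
#' @param mu Eigenvalues from [robin_eigenvalues()] (same `alpha_bar`).
#' @return Numeric vector of coefficients b_n, same length as `mu`.
#' @export
robin_coefficients <- function(alpha_bar, mu) {
  stopifnot(is.numeric(mu))
  if (length(mu) == 0) abort("`mu` must contain at least one eigenvalue.")
  if (!is.numeric(alpha_bar) || length(alpha_bar) != 1 || alpha_bar <= 0) {
    abort("`alpha_bar` must be a single positive number.")
  }
  beta <- alpha_bar / (1 + alpha_bar)
  num <- (1 - cos(mu)) / mu - beta * (sin(mu) - mu * cos(mu)) / mu^2
  den <- 0.5 - sin(2 * mu) / (4 * mu)
  -num / den
}

#' Assemble the Robin eigensystem
#'
#' Bundles eigenvalues and projection coefficients for a given sensitivity,
#' for reuse across profile/response evaluations. `tidy()` returns one row
#' per mode with the eigencondition residual; `glance()` summarises the
#' system.
#'
#' @inheritParams robin_eigenvalues
#' @return An object of class `robin_eigensystem` with elements `alpha_bar`,
#'   `mu`, `b`, `n_modes`.
#' @examples
#' es <- robin_eigensystem(1, 8)
#' tidy(es)
#' glance(es)
#' @export
robin_eigensystem <- function(alpha_bar, n_modes = 200) {
  mu <- robin_eigenvalues(alpha_bar, n_modes)
  b <- robin_coefficients(alpha_bar, mu)
  structure(list(alpha_bar = alpha_bar, mu = mu, b = b,
                 n_modes = as.integer(n_modes)),
            class = "robin_eigensystem")
}

#' @export
print.robin_eigensystem <- function(x, ...) {
  cat(sprintf("<robin_eigensystem> alpha_bar = %.4g, %d modes\n",
              x$alpha_bar, x$n_modes))
  cat("  mu_1..: ", paste(sprintf("%.5f", utils::head(x$mu, 4)), collapse = ", "),
      if (x$n_modes > 4) "..." else "", "\n")
  invisible(x)
}

#' @rdname robin_eigensystem
#' @param x A `robin_eigensystem`.
#' @param ... Unused.
#' @export
tidy.robin_eigensystem <- function(x, ...) {
  tibble(
    n = seq_len(x$n_modes),
    mu = x$mu,
    b = x$b,
    residual = robin_eigcondition(x$mu, x$alpha_bar)
  )
}

#' @rdname robin_eigensystem
#' @export
glance.robin_eigensystem <- function(x, ...) {
  tibble(
    alpha_bar = x$alpha_bar,
    n_modes = x$n_modes,
    mu_1 = x$mu[1],
    max_abs_residual = max(abs(robin_eigcondition(x$mu, x$alpha_bar)))
  )
}

resolve_eigensystem <- function(alpha_bar, n_modes, eigensystem) {
  if (!is.null(eigensystem)) {
    stopifnot(inherits(eigensystem, "robin_eigensystem"))
    return(eigensystem)
  }
  robin_eigensystem(alpha_bar, n_modes)
}

#' Concentration profile under a Robin (finite-sensitivity) sensor
#'
#' Dimensionless step-response profile
#' \deqn{\bar c(\bar x, \bar t) = \sum_n b_n \sin(\mu_n \bar x)
#'   e^{-\mu_n^2 \bar t} + 1 - \frac{\bar\alpha\,\bar x}{1 + \bar\alpha}.}
#' The steady state is linear with sensor-face value 1/(1 + alpha_bar). At
#' `t_bar` below 1e-4 the exact initial values are returned.
#'
#' @inheritParams conc_profile_neumann
#' @inheritParams robin_eigenvalues
#' @param n_modes Number of eigenmodes retained (default 200 for profiles).
#' @param eigensystem Optional precomputed [robin_eigensystem()] (overrides
#'   `alpha_bar`/`n_modes`).
#' @return Dimensionless concentration(s) c/C0.
#' @examples
#' robin_profile(x_bar = 1, t_bar = 10, alpha_bar = 1)   # -> 0.5
#' @export
robin_profile <- function(x_bar, t_bar, alpha_bar, n_modes = 200,
                          eigensystem = NULL) {
  check_xbar(x_bar); check_tbar(t_bar)
  es <- resolve_eigensystem(alpha_bar, n_modes, eigensystem)
  n <- max(length(x_bar), length(t_bar))
  x_bar <- rep_len(x_bar, n); t_bar <- rep_len(t_bar, n)
  out <- ifelse(x_bar > 0, 0, 1)
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    xs <- x_bar[live]; ts <- t_bar[live]
    ex <- exp(-outer(es$mu^2, ts))
    sn <- sin(outer(es$mu, xs))
    out[live] <- colSums(es$b * ex * sn) + robin_steady_profile(xs, es$alpha_bar)
  }
  out
}

#' Step response of a Robin sensor
#'
#' A Robin sensor reads the flux alpha * c(L, t) it draws from the skin. Its
#' steady state is
#' \deqn{m_{ss} = \frac{C_0 \alpha}{1 + \bar\alpha}}
#' (flux units, mol cm^-2 s^-1), and the normalized response is
#' \deqn{\bar m_{Robin}(\bar t) = 1 + (1 + \bar\alpha) \sum_n b_n
#'   \sin(\mu_n) e^{-\mu_n^2 \bar t},}
#' rising monotonically from 0 to 1 between the concentration-type
#' (alpha_bar -> 0) and ideal flux-type (alpha_bar -> Inf) responses.
#'
#' @inheritParams robin_profile
#' @param n_modes Number of eigenmodes retained (default 50, ample for
#'   `t_bar >= 0.01`; raise it to evaluate earlier times).
#' @return `robin_response_normalized()`: dimensionless m/m_ss in \[0, 1\].
#' @examples
#' robin_response_normalized(c(0.1, 1, 3), alpha_bar = 1)
#' @export
robin_response_normalized <- function(t_bar, alpha_bar, n_modes = 50,
                                      eigensystem = NULL) {
  check_tbar(t_bar)
  es <- resolve_eigensystem(alpha_bar, n_modes, eigensystem)
  out <- numeric(length(t_bar))
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    ex <- exp(-outer(es$mu^2, t_bar[live]))
    out[live] <- 1 + (1 + es$alpha_bar) * colSums(es$b * sin(es$mu) * ex)
  }
  out
}

#' @rdname robin_response_normalized
#' @param skin A [skin_barrier()] with `C0` set.
#' @param alpha Sensor rate constant, cm/s (> 0).
#' @return `robin_steady_state()`: steady-state flux C0 alpha / (1 +
#'   alpha_bar), mol cm^-2 s^-1. `robin_response()`: dimensional response
#'   m(t_bar) = m_ss * m_bar(t_bar), same units.
#' @export
robin_steady_state <- function(skin, alpha) {
  stopifnot(inherits(skin, "skin_barrier"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a single positive rate constant (cm/s).")
  }
  skin$C0 * alpha / (1 + alpha_bar(alpha, skin))
}

#' @rdname robin_response_normalized
#' @export
robin_response <- function(t_bar, skin, alpha, n_modes = 50,
                           eigensystem = NULL) {
  ab <- alpha_bar(alpha, skin)
  robin_steady_state(skin, alpha) *
    robin_response_normalized(t_bar, ab, n_modes, eigensystem)
}
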