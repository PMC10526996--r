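# Closed-form separation-of-variables solutions for the step response of the
# skin slab, in dimensionless variables x_bar = x/L in [0,1], t_bar = tD/L^2,
# c_bar = c/C0. Two boundary conditions at the sensor face x_bar = 1:
#   Neumann  (concentration-type sensor): dc/dx = 0
#   Dirichlet (ideal flux-type sensor):   c = 0
# The Robin family lives in robin.R.

# Series are non-uniformly convergent at t_bar = 0 (Gibbs); below this floor
# the exact initial/boundary values are returned instead of summing.
T_BAR_FLOOR <- 1e-4
MAX_SERIES_TERMS <- 10000

check_tbar <- function(t_bar) {
  stopifnot(is.numeric(t_bar))
  if (any(!is.finite(t_bar)) || any(t_bar < 0)) abort("`t_bar` must be finite and >= 0.")
}

check_xbar <- function(x_bar) {
  stopifnot(is.numeric(x_bar))
  if (any(!is.finite(x_bar)) || any(x_bar < 0 | x_bar > 1)) {
    abort("`x_bar` must lie in [0, 1].")
  }
}

# Number of terms so the envelope of term i (decay exp(-a*k(i)^2*t)) drops
# below tol at the smallest summed time; cap at MAX_SERIES_TERMS.
n_terms_for <- function(t_min, a, amp = 4 / pi, tol = 1e-12) {
  kmax <- sqrt(max(log(amp / tol), 1) / (a * t_min))
  min(max(ceiling(kmax) + 2L, 8L), MAX_SERIES_TERMS)
}

# Dimensionless decay rate of series mode i for the two closed-form sensor
# classes. The leading (i = 1) rate is what sets the response timescale, so
# timescale extraction reads this table rather than a hard-coded constant.
series_mode_rate <- function(kind = c("concentration", "ideal_flux"), i) {
  kind <- match.arg(kind)
  switch(kind,
    concentration = pi^2 * (2 * i - 1)^2 / 4,
    ideal_flux    = pi^2 * i^2
  )
}

#' Concentration profile under a concentration-type (Neumann) sensor
#'
#' Dimensionless solution of the diffusion step response with a zero-flux
#' sensor boundary:
#' \deqn{\bar c(\bar x,\bar t) = 1 - \frac{4}{\pi}\sum_{i\ge 1}
#'   \frac{1}{2i-1} e^{-\pi^2(2i-1)^2\bar t/4}
#'   \sin\!\frac{\pi (2i-1)\bar x}{2}.}
#' The steady state is the uniform blood concentration, c_bar = 1.
#'
#' `x_bar` and `t_bar` are recycled against each other; at `t_bar` below
#' 1e-4 the exact initial/boundary values are returned (1 at the blood face
#' `x_bar = 0`, 0 elsewhere) since the series converges non-uniformly there.
#'
#' @param x_bar Dimensionless position(s) in \[0, 1\] (0 = blood side,
#'   1 = sensor side).
#' @param t_bar Dimensionless time(s) `t * D / L^2`, >= 0.
#' @param tol Series truncation tolerance: terms are retained until their
#'   envelope falls below `tol` (capped at 10 000 terms).
#' @return Dimensionless concentration(s) c/C0 in \[0, 1\].
#' @examples
#' conc_profile_neumann(x_bar = 1, t_bar = c(0.01, 0.1, 1, 10))
#' @seealso [response_conc()], [conc_profile_dirichlet()], [robin_profile()]
#' @export
conc_profile_neumann <- function(x_bar, t_bar, tol = 1e-12) {
  check_xbar(x_bar); check_tbar(t_bar)
  n <- max(length(x_bar), length(t_bar))
  x_bar <- rep_len(x_bar, n); t_bar <- rep_len(t_bar, n)
  out <- ifelse(x_bar > 0, 0, 1)           # initial/boundary convention
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    xs <- x_bar[live]; ts <- t_bar[live]
    N <- n_terms_for(min(ts), a = pi^2 / 4, tol = tol)
    k <- 2 * seq_len(N) - 1
    ex <- exp(-(pi^2 / 4) * outer(k^2, ts))          # N x m
    sn <- sin((pi / 2) * outer(k, xs))               # N x m
    out[live] <- 1 - (4 / pi) * colSums((1 / k) * ex * sn)
  }
  out
}

#' Normalized step response of a concentration-type sensor
#'
#' The sensor reads the interface concentration c(L, t); normalized by its
#' steady state C0 this is
#' \deqn{\bar m_{Conc}(\bar t) = 1 + \frac{4}{\pi}\sum_{i\ge 1}
#'   \frac{(-1)^i}{2i-1} e^{-\pi^2 (2i-1)^2 \bar t / 4},}
#' i.e. [conc_profile_neumann()] evaluated at `x_bar = 1` (the alternating
#' sign is `cos(pi * i)`). Rises monotonically from 0 to 1.
#'
#' @inheritParams conc_profile_neumann
#' @return Normalized response value(s) in \[0, 1\].
#' @examples
#' response_conc(c(0.1, 1, 3))
#' @export
response_conc <- function(t_bar, tol = 1e-12) {
  check_tbar(t_bar)
  out <- numeric(length(t_bar))
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    ts <- t_bar[live]
    N <- n_terms_for(min(ts), a = pi^2 / 4, tol = tol)
    i <- seq_len(N)
    k <- 2 * i - 1
    ex <- exp(-(pi^2 / 4) * outer(k^2, ts))
    out[live] <- 1 + (4 / pi) * colSums((cos(pi * i) / k) * ex)
  }
  out
}

#' Concentration profile under an ideal flux-type (Dirichlet) sensor
#'
#' Dimensionless solution with an irreversibly consuming sensor boundary
#' (c = 0 at x = L):
#' \deqn{\bar c(\bar x,\bar t) = 1 - \bar x - \frac{2}{\pi}\sum_{i\ge 1}
#'   \frac{1}{i} e^{-\pi^2 i^2 \bar t} \sin(\pi i \bar x).}
#' The steady state is the linear profile 1 - x_bar.
#'
#' @inheritParams conc_profile_neumann
#' @return Dimensionless concentration(s) c/C0 in \[0, 1\].
#' @examples
#' conc_profile_dirichlet(x_bar = 0.5, t_bar = c(0.01, 0.1, 1))
#' @export
conc_profile_dirichlet <- function(x_bar, t_bar, tol = 1e-12) {
  check_xbar(x_bar); check_tbar(t_bar)
  n <- max(length(x_bar), length(t_bar))
  x_bar <- rep_len(x_bar, n); t_bar <- rep_len(t_bar, n)
  out <- ifelse(x_bar > 0, 0, 1)
  out[x_bar == 1] <- 0                     # sensor face pinned at zero
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    xs <- x_bar[live]; ts <- t_bar[live]
    N <- n_terms_for(min(ts), a = pi^2, amp = 2 / pi, tol = tol)
    i <- seq_len(N)
    ex <- exp(-pi^2 * outer(i^2, ts))
    sn <- sin(pi * outer(i, xs))
    out[live] <- 1 - xs - (2 / pi) * colSums((1 / i) * ex * sn)
  }
  out
}

#' Normalized step response of an ideal flux-type sensor
#'
#' The sensor reads the analyte flux into it, -D dc/dx at x = L; normalized
#' by the steady-state flux C0 D / L this is
#' \deqn{\bar m_{Flux}(\bar t) = 1 + 2 \sum_{i\ge 1} (-1)^i
#'   e^{-\pi^2 i^2 \bar t}.}
#' Defined as 0 at `t_bar = 0` (no analyte has crossed the skin yet; the
#' series itself does not converge pointwise there). Rises monotonically to 1.
#'
#' @inheritParams conc_profile_neumann
#' @return Normalized response value(s) in \[0, 1\].
#' @examples
#' response_flux(c(0.1, 1, 3))
#' @export
response_flux <- function(t_bar, tol = 1e-12) {
  check_tbar(t_bar)
  out <- numeric(length(t_bar))
  live <- t_bar >= T_BAR_FLOOR
  if (any(live)) {
    ts <- t_bar[live]
    N <- n_terms_for(min(ts), a = pi^2, amp = 2, tol = tol)
    i <- seq_len(N)
    ex <- exp(-pi^2 * outer(i^2, ts))
    out[live] <- 1 + 2 * colSums(cos(pi * i) * ex)
  }
  out
}

#' Steady-state outputs of the two ideal sensor classes
#'
#' A concentration-type sensor settles at the blood concentration C0
#' (mol/cm^3); an ideal flux-type sensor settles at the trans-barrier flux
#' C0 D / L = C0 k_skin (mol cm^-2 s^-1). The two sensor classes therefore
#' report in different physical units and are compared via their normalized
#' responses.
#'
#' @param skin A [skin_barrier()] with `C0` set.
#' @return Steady-state sensor output (see units above).
#' @examples
#' skin <- skin_barrier(D = 5e-10, L = um_to_cm(15),
#'                      C0 = mg_per_dl_to_mol_per_cm3(100, 46.07))
#' steady_state_flux(skin)   # ~1.1e-11 mol cm^-2 s^-1
#' @export
steady_state_flux <- function(skin) {
  stopifnot(inherits(skin, "skin_barrier"))
  skin$C0 * skin$D / skin$L
}

#' @rdname steady_state_flux
#' @export
steady_state_conc <- function(skin) {
  stopifnot(inherits(skin, "skin_barrier"))
  skin$C0
}
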