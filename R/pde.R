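# Independent finite-difference solution of the dimensionless diffusion
# equation dc/dt = d2c/dx2 on x_bar in [0,1], used as the verification oracle
# for the analytic series. Second-order central differences in space;
# Crank-Nicolson in time with a few backward-Euler startup steps (Rannacher
# smoothing) to damp the step discontinuity at the blood face, and a fine
# initial time-step phase while the concentration front is steep.

# Tridiagonal LU (no pivoting; the CN/BE matrices are strictly diagonally
# dominant). Returns dense L and U so the per-step solves run through
# forwardsolve/backsolve at C speed.
tridiag_lu <- function(sub, dia, sup) {
  m <- length(dia)
  l <- numeric(m); u <- numeric(m)
  u[1] <- dia[1]
  for (i in seq_len(m)[-1]) {
    l[i] <- sub[i] / u[i - 1]
    u[i] <- dia[i] - l[i] * sup[i - 1]
  }
  L <- diag(m); U <- diag(u, nrow = m)
  idx <- seq_len(m - 1)
  L[cbind(idx + 1, idx)] <- l[-1]
  U[cbind(idx, idx + 1)] <- sup[-m]
  list(L = L, U = U)
}

tridiag_apply <- function(sub, dia, sup, v) {
  n <- length(v)
  dia * v + c(0, sub[-1] * v[-n]) + c(sup[-n] * v[-1], 0)
}

#' Finite-difference solution of the skin diffusion step response
#'
#' Solves the dimensionless diffusion equation with the blood face held at
#' c_bar = 1 from the first time step and the sensor face under a Neumann,
#' Dirichlet or Robin condition. Neumann/Robin boundaries are imposed through
#' a ghost node so the boundary flux is second-order accurate; Dirichlet is
#' imposed directly. The time march is Crank-Nicolson (unconditionally
#' stable) with `n_startup` backward-Euler steps at the start and a finer
#' step size `dt_init` until `t_fine`, where the solution still has a steep
#' front.
#'
#' This solver is deliberately independent of the series solutions and
#' serves as their verification oracle.
#'
#' @param boundary Sensor-face condition: `"neumann"`, `"dirichlet"` or
#'   `"robin"`.
#' @param t_out Dimensionless output times (sorted, >= 0). Times are matched
#'   to the step grid; with the default steps any multiple of `dt_bar` is hit
#'   exactly.
#' @param alpha_bar Dimensionless sensitivity (> 0); required for
#'   `boundary = "robin"`.
#' @param nx Number of spatial nodes on \[0, 1\] (>= 11; default 401).
#' @param dt_bar Main dimensionless time step (default 1e-4).
#' @param dt_init Fine time step used until `t_fine` (default 1e-5).
#' @param t_fine End of the fine-step phase (default 0.01).
#' @param n_startup Number of backward-Euler startup steps (default 4).
#' @return An object of class `fd_field`: list with `x_bar` (length `nx`),
#'   `t_bar` (the achieved output times), `c_bar` (length(t_bar) x nx
#'   matrix), and scheme metadata. `tidy()` returns it as a long tibble.
#' @examples
#' fd <- solve_pde("dirichlet", t_out = c(0.1, 1), nx = 101)
#' max(abs(fd$c_bar[2, ] - conc_profile_dirichlet(fd$x_bar, 1)))
#' @seealso [boundary_flux()], [convergence_study()]
#' @export
solve_pde <- function(boundary = c("neumann", "dirichlet", "robin"),
                      t_out, alpha_bar = NULL, nx = 401, dt_bar = 1e-4,
                      dt_init = 1e-5, t_fine = 0.01, n_startup = 4) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(t_out), length(t_out) >= 1)
  if (any(!is.finite(t_out)) || any(t_out < 0)) abort("`t_out` must be finite and >= 0.")
  t_out <- sort(t_out)
  if (nx < 11) abort("`nx` must be >= 11 for a meaningful grid.")
  if (!is.finite(dt_bar) || dt_bar <= 0 || dt_bar > 0.05) {
    abort("`dt_bar` must be in (0, 0.05]: larger steps cannot resolve the transient.")
  }
  if (!is.finite(dt_init) || dt_init <= 0 || dt_init > dt_bar) {
    abort("`dt_init` must be in (0, dt_bar].")
  }
  if (boundary == "robin") {
    if (is.null(alpha_bar) || !is.numeric(alpha_bar) || length(alpha_bar) != 1 ||
        alpha_bar <= 0) {
      abort("`alpha_bar` (> 0) is required for a robin boundary.")
    }
  } else {
    alpha_bar <- NA_real_
  }

  dx <- 1 / (nx - 1)
  # unknowns: nodes 2..nx (node 1 pinned at 1); Dirichlet drops node nx too
  m <- if (boundary == "dirichlet") nx - 2 else nx - 1
  sub <- rep(1, m); dia <- rep(-2, m); sup <- rep(1, m)
  if (boundary == "neumann") sub[m] <- 2                    # ghost: c_{nx+1} = c_{nx-1}
  if (boundary == "robin") {                                # ghost encodes dc/dx = -ab*c
    sub[m] <- 2
    dia[m] <- -2 * (1 + dx * alpha_bar)
  }

  t_end <- max(t_out)
  phase <- function(dt) {
    r <- dt / dx^2
    list(
      dt = dt, r = r,
      lu_cn = tridiag_lu(-(r / 2) * sub, 1 - (r / 2) * dia, -(r / 2) * sup),
      lu_be = tridiag_lu(-r * sub, 1 - r * dia, -r * sup)
    )
  }
  p_fine <- phase(dt_init)
  p_main <- phase(dt_bar)

  cvec <- numeric(m)
  t_now <- 0
  want <- t_out
  got_t <- numeric(0)
  got_c <- list()
  record <- function(tval) {
    prof <- if (boundary == "dirichlet") c(1, cvec, 0) else c(1, cvec)
    got_t <<- c(got_t, tval)
    got_c[[length(got_c) + 1L]] <<- prof
  }
  if (want[1] == 0) {  # initial condition: zero except the blood node
    got_t <- 0
    got_c[[1]] <- c(1, numeric(nx - 1))
    want <- want[-1]
  }

  step_count <- 0L
  advance <- function(p, t_stop) {
    nstep <- max(0L, as.integer(round((t_stop - t_now) / p$dt)))
    for (s in seq_len(nstep)) {
      step_count <<- step_count + 1L
      if (step_count <= n_startup) {
        rhs <- cvec
        rhs[1] <- rhs[1] + p$r * 1          # coupling to the fixed blood node
        cvec <<- backsolve(p$lu_be$U, forwardsolve(p$lu_be$L, rhs))
      } else {
        rhs <- cvec + (p$r / 2) * tridiag_apply(sub, dia, sup, cvec)
        rhs[1] <- rhs[1] + p$r * 1          # r/2 on each side of the step
        cvec <<- backsolve(p$lu_cn$U, forwardsolve(p$lu_cn$L, rhs))
      }
      t_now <<- t_now + p$dt
      while (length(want) > 0 && abs(t_now - want[1]) <= p$dt / 2 * (1 + 1e-9)) {
        record(want[1])
        want <<- want[-1]
      }
    }
  }
  t_switch <- min(t_fine, t_end)
  advance(p_fine, t_switch)
  if (t_end > t_now + 1e-15) advance(p_main, t_end)
  if (length(want) > 0) {
    abort(sprintf("output times not on the step grid: %s",
                  paste(signif(want, 6), collapse = ", ")))
  }

  structure(list(
    x_bar = seq(0, 1, length.out = nx),
    t_bar = got_t,
    c_bar = do.call(rbind, got_c),
    boundary = boundary, alpha_bar = alpha_bar,
    nx = nx, dt_bar = dt_bar, dt_init = dt_init,
    t_fine = t_fine, n_startup = n_startup
  ), class = "fd_field")
}

#' @export
print.fd_field <- function(x, ...) {
  cat(sprintf("<fd_field> %s boundary%s, nx = %d, %d output times (t_bar %.3g..%.3g)\n",
              x$boundary,
              if (!is.na(x$alpha_bar)) sprintf(" (alpha_bar = %.3g)", x$alpha_bar) else "",
              x$nx, length(x$t_bar), min(x$t_bar), max(x$t_bar)))
  invisible(x)
}

#' @rdname solve_pde
#' @param x An `fd_field`.
#' @param ... Unused.
#' @export
tidy.fd_field <- function(x, ...) {
  tidyr::expand_grid(t_bar = x$t_bar, x_bar = x$x_bar) |>
    dplyr::mutate(c_bar = as.vector(t(x$c_bar)))
}

#' Sensor-face flux of a finite-difference field
#'
#' Estimates the dimensionless flux into the sensor, -dc_bar/dx_bar at
#' x_bar = 1 (units of the steady trans-barrier flux C0 D / L), by a
#' one-sided third-order difference over the last four nodes.
#'
#' @param field An `fd_field` from [solve_pde()].
#' @return A tibble with columns `t_bar`, `flux_bar`.
#' @examples
#' fd <- solve_pde("dirichlet", t_out = c(0.5, 5), nx = 101)
#' boundary_flux(fd)    # approaches 1 at late time
#' @export
boundary_flux <- function(field) {
  stopifnot(inherits(field, "fd_field"))
  nx <- field$nx
  dx <- 1 / (nx - 1)
  cb <- field$c_bar
  grad <- (11 * cb[, nx] - 18 * cb[, nx - 1] + 9 * cb[, nx - 2] -
             2 * cb[, nx - 3]) / (6 * dx)
  tibble(t_bar = field$t_bar, flux_bar = -grad)
}

#' Spatial convergence study of the finite-difference scheme
#'
#' Solves the same problem on successively refined nested grids and reports
#' the Richardson-style observed order from the differences between
#' successive solutions at the probe time (restricted to the shared coarse
#' nodes). The scheme is second order in space, so the observed order should
#' be close to 2.
#'
#' @inheritParams solve_pde
#' @param nx_values At least three nested grid sizes (each `2*(nx-1)+1` of
#'   the previous), default `c(41, 81, 161)`.
#' @param t_probe Dimensionless time at which solutions are compared.
#' @param dt_bar Time step (kept small so temporal error does not pollute
#'   the spatial order).
#' @return A list of class `convergence_study`: `order` (observed order
#'   between the last grid pair), `table` (tibble of successive-difference
#'   norms and pairwise orders).
#' @examples
#' convergence_study("dirichlet", t_probe = 0.1)$order
#' @export
convergence_study <- function(boundary = c("neumann", "dirichlet", "robin"),
                              nx_values = c(41, 81, 161), t_probe = 0.1,
                              alpha_bar = NULL, dt_bar = 2e-5) {
  boundary <- match.arg(boundary)
  if (length(nx_values) < 3) abort("need at least 3 grid refinements.")
  sols <- lapply(nx_values, function(nx) {
    fd <- solve_pde(boundary, t_out = t_probe, alpha_bar = alpha_bar, nx = nx,
                    dt_bar = dt_bar, dt_init = dt_bar, t_fine = 0)
    fd$c_bar[1, ]
  })
  nref <- length(nx_values) - 1
  diffs <- vapply(seq_len(nref), function(k) {
    coarse <- sols[[k]]
    fine <- sols[[k + 1]]
    stride <- (nx_values[k + 1] - 1) / (nx_values[k] - 1)
    if (stride != round(stride)) abort("`nx_values` must be nested grids.")
    max(abs(fine[seq(1, nx_values[k + 1], by = stride)] - coarse))
  }, numeric(1))
  orders <- log2(diffs[-nref] / diffs[-1])
  structure(list(
    order = orders[length(orders)],
    table = tibble(
      nx_coarse = nx_values[-length(nx_values)],
      nx_fine = nx_values[-1],
      max_diff = diffs,
      observed_order = c(NA_real_, orders)
    )
  ), class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat(sprintf("<convergence_study> observed spatial order %.3f\n", x$order))
  print(x$table)
  invisible(x)
}
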