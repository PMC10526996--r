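# Tibble-first surface over the analytic solutions: sampled response curves
# and spatial profiles ready for dplyr/ggplot2 pipelines.

sensor_label <- function(kind, alpha_bar = NULL) {
  switch(kind,
    concentration = "concentration (Neumann)",
    ideal_flux = "ideal flux (Dirichlet)",
    robin = sprintf("robin (alpha_bar = %g)", alpha_bar)
  )
}

#' Sampled normalized step-response curve
#'
#' Evaluates the normalized response m_bar(t_bar) of one sensor class on a
#' time grid and returns it as a tibble, together with the dimensional
#' steady state when a [skin_barrier()] is supplied (mol/cm^3 for a
#' concentration sensor, mol cm^-2 s^-1 for flux-reading sensors).
#'
#' @param kind `"concentration"`, `"ideal_flux"` or `"robin"`.
#' @param t_bar Dimensionless time grid (>= 0).
#' @param alpha_bar Dimensionless sensitivity (robin only).
#' @param skin Optional [skin_barrier()] for the dimensional steady state.
#' @param n_modes Robin modes retained (default 50).
#' @return A tibble of class `response_curve` with columns `t_bar`, `m_bar`,
#'   `sensor`; attributes `kind`, `alpha_bar`, `steady_state`,
#'   `steady_state_units`.
#' @examples
#' response_curve("robin", t_bar = seq(0, 2, 0.1), alpha_bar = 1)
#' @seealso [response_curves()], [profile_curve()]
#' @export
response_curve <- function(kind = c("concentration", "ideal_flux", "robin"),
                           t_bar, alpha_bar = NULL, skin = NULL, n_modes = 50) {
  kind <- match.arg(kind)
  m_bar <- switch(kind,
    concentration = response_conc(t_bar),
    ideal_flux = response_flux(t_bar),
    robin = {
      if (is.null(alpha_bar)) abort("`alpha_bar` is required for a robin curve.")
      robin_response_normalized(t_bar, alpha_bar, n_modes = n_modes)
    }
  )
  ss <- NA_real_
  ss_units <- switch(kind, concentration = "mol/cm^3", "mol cm^-2 s^-1")
  if (!is.null(skin)) {
    ss <- switch(kind,
      concentration = steady_state_conc(skin),
      ideal_flux = steady_state_flux(skin),
      robin = robin_steady_state(skin, alpha_bar * permeability(skin))
    )
  }
  out <- tibble(t_bar = t_bar, m_bar = m_bar,
                sensor = sensor_label(kind, alpha_bar))
  class(out) <- c("response_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "alpha_bar") <- alpha_bar
  attr(out, "steady_state") <- ss
  attr(out, "steady_state_units") <- ss_units
  out
}

#' Normalized responses of all sensor classes on a common time grid
#'
#' The concentration-type and ideal flux-type envelopes plus Robin curves at
#' the requested sensitivities, stacked long for comparison plots. At every
#' time the curves are ordered concentration <= robin (increasing
#' alpha_bar) <= ideal flux: the skin-plus-sensor system gets faster as the
#' sensor sensitivity grows, up to the ideal-flux limit.
#'
#' @param t_bar Dimensionless time grid.
#' @param alpha_bars Robin sensitivities to include (default 0.2, 1, 5).
#' @param n_modes Robin modes retained per curve.
#' @return A tibble with columns `t_bar`, `m_bar`, `sensor`.
#' @examples
#' curves <- response_curves(seq(0, 1.5, 0.05))
#' if (interactive()) autoplot(curves)
#' @export
response_curves <- function(t_bar, alpha_bars = c(0.2, 1, 5), n_modes = 50) {
  pieces <- c(
    list(response_curve("concentration", t_bar)),
    purrr::map(alpha_bars,
               ~response_curve("robin", t_bar, alpha_bar = .x, n_modes = n_modes)),
    list(response_curve("ideal_flux", t_bar))
  )
  out <- dplyr::bind_rows(lapply(pieces, as_tibble))
  class(out) <- c("response_curve", class(out))
  out
}

#' Sampled concentration profiles through the skin
#'
#' Dimensionless concentration c_bar(x_bar) at selected times for one sensor
#' class, in long format (the data behind the classic family-of-curves
#' profile plots).
#'
#' @inheritParams response_curve
#' @param x_bar Spatial grid in \[0, 1\].
#' @param t_bar Times at which profiles are sampled.
#' @param n_modes Robin modes retained (default 200 for profiles).
#' @return A tibble of class `profile_curve` with columns `x_bar`, `t_bar`,
#'   `c_bar`, `sensor`.
#' @examples
#' profile_curve("ideal_flux", t_bar = c(0.01, 0.1, 1, 10))
#' @export
profile_curve <- function(kind = c("concentration", "ideal_flux", "robin"),
                          x_bar = seq(0, 1, by = 0.01),
                          t_bar = c(0.01, 0.1, 1, 10),
                          alpha_bar = NULL, n_modes = 200) {
  kind <- match.arg(kind)
  es <- if (kind == "robin") {
    if (is.null(alpha_bar)) abort("`alpha_bar` is required for a robin profile.")
    robin_eigensystem(alpha_bar, n_modes)
  }
  grid <- tidyr::expand_grid(t_bar = t_bar, x_bar = x_bar)
  grid$c_bar <- switch(kind,
    concentration = conc_profile_neumann(grid$x_bar, grid$t_bar),
    ideal_flux = conc_profile_dirichlet(grid$x_bar, grid$t_bar),
    robin = robin_profile(grid$x_bar, grid$t_bar, alpha_bar, eigensystem = es)
  )
  grid$sensor <- sensor_label(kind, alpha_bar)
  out <- grid[, c("x_bar", "t_bar", "c_bar", "sensor")]
  class(out) <- c("profile_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "alpha_bar") <- alpha_bar
  out
}

#' Plot normalized response curves
#'
#' @param object A `response_curve` tibble (possibly several stacked curves).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t_bar, y = .data$m_bar,
                               colour = .data$sensor)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = expression(bar(t) == t * D / L^2),
      y = expression(bar(m)(bar(t))),
      colour = "sensor",
      title = "Normalized step response at the skin/sensor interface"
    ) +
    ggplot2::theme_minimal()
}

#' Plot concentration profiles through the skin
#'
#' @param object A `profile_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_bar, y = .data$c_bar,
                               colour = factor(.data$t_bar))) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = expression(bar(x) == x / L),
      y = expression(bar(c) == c / C[0]),
      colour = expression(bar(t)),
      title = unique(object$sensor)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
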