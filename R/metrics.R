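# Two timescale metrics for comparing sensor classes, plus the sensitivity
# classification. Both metrics are extracted from the implemented series
# solutions rather than hard-coded formulas: the leading timescale reads the
# mode-1 decay rate, and the integrated intercept integrates the series
# term by term in closed form.

#' Leading-exponential response timescale
#'
#' The slowest decaying mode of the step response dominates the approach to
#' steady state; its reciprocal decay rate is the natural response
#' timescale. For the series solutions implemented here the mode-1
#' dimensionless rates are pi^2/4 (concentration-type) and pi^2 (ideal
#' flux-type), giving
#' \deqn{\tau_{Conc} = \frac{4 L^2}{\pi^2 D}, \qquad
#'       \tau_{Flux} = \frac{L^2}{\pi^2 D},}
#' a fixed ratio of 4: an ideal flux-type sensor is four times faster than a
#' concentration-type sensor on the same skin. The rate is read from the
#' implemented series' mode table, not hard-coded.
#'
#' @param kind `"concentration"` or `"ideal_flux"`. For a Robin sensor use
#'   [robin_leading_timescale()].
#' @param skin A [skin_barrier()].
#' @return Timescale in seconds.
#' @examples
#' skin <- skin_barrier(D = 3e-11, L = um_to_cm(15))
#' seconds_to_hours(leading_timescale("concentration", skin))  # ~8.4 h
#' seconds_to_hours(leading_timescale("ideal_flux", skin))     # ~2.1 h
#' @export
leading_timescale <- function(kind = c("concentration", "ideal_flux"), skin) {
  if (length(kind) == 1 && identical(kind, "robin")) {
    abort("use `robin_leading_timescale(alpha_bar, skin)` for a robin sensor.")
  }
  kind <- match.arg(kind)
  stopifnot(inherits(skin, "skin_barrier"))
  rate1 <- series_mode_rate(kind, 1)        # dimensionless mode-1 decay rate
  skin$L^2 / (skin$D * rate1)
}

#' @rdname leading_timescale
#' @param alpha_bar Dimensionless sensor sensitivity (> 0). The Robin
#'   timescale L^2 / (D mu_1^2) interpolates between tau_Flux (alpha_bar ->
#'   Inf, mu_1 -> pi) and tau_Conc (alpha_bar -> 0, mu_1 -> pi/2).
#' @export
robin_leading_timescale <- function(alpha_bar, skin) {
  stopifnot(inherits(skin, "skin_barrier"))
  mu1 <- robin_eigenvalues(alpha_bar, 1)
  skin$L^2 / (skin$D * mu1^2)
}

#' Integrated-intercept response timescale
#'
#' The time integral of the normalized response approaches the asymptote
#' (t_bar - t_bar*) at late times; the x-intercept
#' \deqn{\bar t^* = \int_0^\infty (1 - \bar m(\bar t))\, d\bar t}
#' is a whole-curve timescale (dimensionless; multiply by L^2/D for
#' seconds). Each exponential series term integrates in closed form, so the
#' intercept is computed by term-wise summation to `tol`:
#' ideal flux-type gives 1/6, concentration-type 1/2 (ratio 3), and the
#' Robin family interpolates, \eqn{-(1+\bar\alpha)\sum_n b_n \sin(\mu_n) /
#' \mu_n^2}, decreasing in alpha_bar within (1/6, 1/2).
#'
#' @param kind `"concentration"`, `"ideal_flux"` or `"robin"`.
#' @param alpha_bar Dimensionless sensitivity, required for `kind = "robin"`.
#' @param tol Truncation tolerance for the term-wise sum (the alternating
#'   tail bounds the error by the first omitted term).
#' @param n_modes Number of Robin eigenmodes summed (robin only).
#' @return Dimensionless intercept timescale t_bar*.
#' @examples
#' integrated_intercept("ideal_flux")              # 1/6
#' integrated_intercept("concentration")           # 1/2
#' integrated_intercept("robin", alpha_bar = 1)
#' @export
integrated_intercept <- function(kind = c("concentration", "ideal_flux", "robin"),
                                 alpha_bar = NULL, tol = 1e-12, n_modes = 4000) {
  kind <- match.arg(kind)
  if (kind == "concentration") {
    # terms (16/pi^3) (-1)^(i+1) / (2i-1)^3
    kmax <- ceiling(((16 / pi^3) / tol)^(1 / 3)) + 1
    k <- seq(1, kmax, by = 2)
    s <- (16 / pi^3) * sum(rev(((-1)^(seq_along(k) + 1)) / k^3))
    return(s)
  }
  if (kind == "ideal_flux") {
    # terms 2 (-1)^(i+1) / (pi^2 i^2)
    imax <- ceiling(sqrt((2 / pi^2) / tol)) + 1
    i <- seq_len(imax)
    s <- (2 / pi^2) * sum(rev(((-1)^(i + 1)) / i^2))
    return(s)
  }
  if (is.null(alpha_bar)) abort("`alpha_bar` is required for the robin intercept.")
  es <- robin_eigensystem(alpha_bar, n_modes)
  -(1 + alpha_bar) * sum(rev(es$b * sin(es$mu) / es$mu^2))
}

#' Classify a sensor by its dimensionless sensitivity
#'
#' A sensor whose rate constant is much larger than the skin permeability
#' responds like an ideal flux-type sensor; much smaller, like a
#' concentration-type sensor (in temporal shape, with flux-type units);
#' comparable sensitivities need the full Robin treatment. "Much" is
#' operationalized by two configurable thresholds.
#'
#' @param alpha_bar Dimensionless sensitivity value(s), >= 0; vectorized.
#' @param lower Below (or at) this threshold the response is
#'   concentration-like (default 0.1).
#' @param upper Above (or at) this threshold the response is ideal-flux-like
#'   (default 10).
#' @return A tibble with columns `alpha_bar` and `label` (one of
#'   `"concentration-like"`, `"robin"`, `"ideal-flux-like"`).
#' @examples
#' classify_sensor(c(0.02, 0.75, 31))
#' @export
classify_sensor <- function(alpha_bar, lower = 0.1, upper = 10) {
  stopifnot(is.numeric(alpha_bar))
  if (any(alpha_bar < 0, na.rm = TRUE)) abort("`alpha_bar` must be >= 0.")
  if (lower >= upper) abort("`lower` must be below `upper`.")
  label <- dplyr::case_when(
    alpha_bar >= upper ~ "ideal-flux-like",
    alpha_bar <= lower ~ "concentration-like",
    TRUE ~ "robin"
  )
  tibble(alpha_bar = alpha_bar, label = label)
}

#' Side-by-side timescale report for a skin barrier
#'
#' Computes both timescale metrics for the two ideal sensor classes on the
#' given skin (and, if `alpha` is supplied, for the Robin sensor): the
#' leading-exponential timescales in seconds with their exact ratio of 4,
#' and the dimensionless integrated intercepts with their ratio of ~3.
#' Neither metric is privileged; both are reported.
#'
#' @param skin A [skin_barrier()].
#' @param alpha Optional Robin sensor rate constant, cm/s.
#' @return An object of class `timescale_report`. `tidy()` returns one row
#'   per metric; `glance()` a one-row summary.
#' @examples
#' skin <- skin_barrier(D = 3e-11, L = um_to_cm(15))
#' glance(timescale_report(skin))
#' @export
timescale_report <- function(skin, alpha = NULL) {
  stopifnot(inherits(skin, "skin_barrier"))
  rep <- list(
    skin = skin,
    tau_flux_s = leading_timescale("ideal_flux", skin),
    tau_conc_s = leading_timescale("concentration", skin),
    intercept_flux = integrated_intercept("ideal_flux"),
    intercept_conc = integrated_intercept("concentration"),
    alpha = alpha
  )
  rep$tau_ratio <- rep$tau_conc_s / rep$tau_flux_s
  rep$intercept_ratio <- rep$intercept_conc / rep$intercept_flux
  if (!is.null(alpha)) {
    ab <- alpha_bar(alpha, skin)
    rep$alpha_bar <- ab
    rep$tau_robin_s <- robin_leading_timescale(ab, skin)
    rep$intercept_robin <- integrated_intercept("robin", alpha_bar = ab)
    rep$classification <- classify_sensor(ab)$label
  }
  structure(rep, class = "timescale_report")
}

#' @export
print.timescale_report <- function(x, ...) {
  cat("<timescale_report>\n")
  cat(sprintf("  tau_flux = %.4g s (%.3g h), tau_conc = %.4g s (%.3g h), ratio = %.4g\n",
              x$tau_flux_s, x$tau_flux_s / 3600,
              x$tau_conc_s, x$tau_conc_s / 3600, x$tau_ratio))
  cat(sprintf("  intercepts: flux = %.6f, conc = %.6f, ratio = %.4g\n",
              x$intercept_flux, x$intercept_conc, x$intercept_ratio))
  if (!is.null(x$alpha)) {
    cat(sprintf("  robin: alpha = %.4g cm/s, alpha_bar = %.4g, tau = %.4g s, label = %s\n",
                x$alpha, x$alpha_bar, x$tau_robin_s, x$classification))
  }
  invisible(x)
}

#' @rdname timescale_report
#' @param x A `timescale_report`.
#' @param ... Unused.
#' @export
tidy.timescale_report <- function(x, ...) {
  out <- tibble(
    metric = c("tau_flux", "tau_conc", "tau_ratio",
               "intercept_flux", "intercept_conc", "intercept_ratio"),
    value = c(x$tau_flux_s, x$tau_conc_s, x$tau_ratio,
              x$intercept_flux, x$intercept_conc, x$intercept_ratio),
    units = c("s", "s", "", "dimensionless t_bar", "dimensionless t_bar", "")
  )
  if (!is.null(x$alpha)) {
    out <- dplyr::bind_rows(out, tibble(
      metric = c("alpha_bar", "tau_robin", "intercept_robin"),
      value = c(x$alpha_bar, x$tau_robin_s, x$intercept_robin),
      units = c("", "s", "dimensionless t_bar")
    ))
  }
  out
}

#' @rdname timescale_report
#' @export
glance.timescale_report <- function(x, ...) {
  out <- tibble(
    D = x$skin$D, L = x$skin$L,
    tau_flux_s = x$tau_flux_s, tau_conc_s = x$tau_conc_s,
    tau_ratio = x$tau_ratio,
    intercept_flux = x$intercept_flux, intercept_conc = x$intercept_conc,
    intercept_ratio = x$intercept_ratio
  )
  if (!is.null(x$alpha)) {
    out$alpha_bar <- x$alpha_bar
    out$classification <- x$classification
  }
  out
}
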