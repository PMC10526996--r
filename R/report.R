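# Reporting: figure-data tables, series-vs-oracle verification, and a
# config-driven pipeline (the engine behind the command-line interface in
# inst/cli/dermadiff).

FIGURE_TIMES <- c(0.01, 0.1, 1, 10)   # log-spaced representative profile times

#' Tabular data behind the standard figures
#'
#' Regenerates, as tibbles, the data behind the four canonical plots of the
#' step-response analysis:
#' * `2` — concentration profiles, concentration-type (Neumann) sensor,
#'   at t_bar in \{0.01, 0.1, 1, 10\};
#' * `3` — the same for the ideal flux-type (Dirichlet) sensor;
#' * `4` — the same for a Robin sensor with alpha_bar = 1;
#' * `5` — normalized responses m_bar(t_bar) for the concentration and
#'   ideal-flux envelopes plus Robin curves at alpha_bar in \{0.2, 1, 5\}.
#'
#' @param which Figure id: 2, 3, 4 or 5.
#' @param t_bar Optional time grid override.
#' @param x_bar Optional spatial grid override (profiles only).
#' @param alpha_bars Robin sensitivities (figure 5 only).
#' @return A `profile_curve` tibble (figures 2-4) or `response_curve`
#'   tibble (figure 5).
#' @examples
#' figure_tables(5, t_bar = seq(0, 1, 0.1))
#' @export
figure_tables <- function(which, t_bar = NULL, x_bar = seq(0, 1, by = 0.01),
                          alpha_bars = c(0.2, 1, 5)) {
  if (!length(which) == 1 || !which %in% 2:5) {
    abort("`which` must be one of 2, 3, 4, 5.")
  }
  if (which == 5) {
    return(response_curves(t_bar %||% seq(0, 3, by = 0.01),
                           alpha_bars = alpha_bars))
  }
  t_bar <- t_bar %||% FIGURE_TIMES
  switch(as.character(which),
    "2" = profile_curve("concentration", x_bar, t_bar),
    "3" = profile_curve("ideal_flux", x_bar, t_bar),
    "4" = profile_curve("robin", x_bar, t_bar, alpha_bar = 1)
  )
}

#' Verify the analytic series against the finite-difference oracle
#'
#' For each sensor class, solves the PDE with [solve_pde()] and reports the
#' maximum absolute deviation of the analytic profile over the full spatial
#' grid at each requested time, and of the normalized response at the sensor
#' face. With default grids all deviations are below 1e-5.
#'
#' @param t_bar Dimensionless comparison times (kept >= 0.01 where the
#'   finite-difference transient is well resolved).
#' @param alpha_bars Robin sensitivities to verify.
#' @param nx,dt_bar Oracle grid parameters (see [solve_pde()]).
#' @return A tibble with columns `sensor`, `max_dev_profile`,
#'   `max_dev_response`.
#' @examples
#' \donttest{verify_series_vs_oracle(t_bar = c(0.05, 0.5), alpha_bars = 1)}
#' @export
verify_series_vs_oracle <- function(t_bar = c(0.01, 0.05, 0.1, 0.3, 1, 3),
                                    alpha_bars = c(0.2, 1, 5),
                                    nx = 401, dt_bar = 1e-4) {
  check_tbar(t_bar)
  one <- function(boundary, ab = NULL) {
    fd <- solve_pde(boundary, t_out = t_bar, alpha_bar = ab, nx = nx,
                    dt_bar = dt_bar)
    exact <- switch(boundary,
      neumann = sapply(fd$t_bar, function(t) conc_profile_neumann(fd$x_bar, t)),
      dirichlet = sapply(fd$t_bar, function(t) conc_profile_dirichlet(fd$x_bar, t)),
      robin = {
        es <- robin_eigensystem(ab, 200)
        sapply(fd$t_bar, function(t) robin_profile(fd$x_bar, t, ab, eigensystem = es))
      }
    )
    dev_prof <- max(abs(t(fd$c_bar) - exact))
    dev_resp <- switch(boundary,
      neumann = max(abs(fd$c_bar[, nx] - response_conc(fd$t_bar))),
      dirichlet = max(abs(boundary_flux(fd)$flux_bar - response_flux(fd$t_bar))),
      robin = max(abs((1 + ab) * fd$c_bar[, nx] -
                        robin_response_normalized(fd$t_bar, ab)))
    )
    tibble(
      sensor = sensor_label(switch(boundary, neumann = "concentration",
                                   dirichlet = "ideal_flux", robin = "robin"), ab),
      max_dev_profile = dev_prof,
      max_dev_response = dev_resp
    )
  }
  dplyr::bind_rows(
    one("neumann"),
    one("dirichlet"),
    purrr::map_dfr(alpha_bars, ~one("robin", .x))
  )
}

# CSV with fixed 9-significant-digit formatting: byte-identical across runs
# and locales.
write_curve_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 9, format = "g")
    }
  }
  utils::write.table(df, path, sep = ",", dec = ".", row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || length(cfg) == 0) abort("config is empty or not a mapping.")
  if (is.null(cfg$skin)) abort("config must have a `skin` section.")
  need <- c("D_cm2_per_s", "L_cm")
  miss <- setdiff(need, names(cfg$skin))
  if (length(miss) > 0) {
    abort(sprintf("config skin section missing: %s", paste(miss, collapse = ", ")))
  }
  cfg
}

#' Run a configured analysis end to end
#'
#' Reads a YAML or JSON configuration describing the skin barrier and
#' (optionally) the sensor, computes timescales and requested curve tables,
#' and writes them under `out_dir` as CSV plus a JSON summary report.
#'
#' Config schema:
#' ```yaml
#' skin:  {D_cm2_per_s: 3.0e-11, L_cm: 1.5e-3, C0_mol_per_cm3: 0}
#' sensor: {kind: robin, alpha_cm_per_s: 2.45e-7}   # optional
#' figures: [2, 5]                                  # optional
#' response_t_bar: [0.0, 0.01, ..., 3]              # optional grid override
#' verify: false                                    # optional oracle check
#' ```
#'
#' @param path Path to the config file.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The JSON report, invisibly, as a list.
#' @export
run_config <- function(path, out_dir = ".", quiet = FALSE) {
  cfg <- read_run_config(path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  skin <- skin_barrier(D = cfg$skin$D_cm2_per_s, L = cfg$skin$L_cm,
                       C0 = cfg$skin$C0_mol_per_cm3 %||% 0)
  alpha <- NULL
  if (!is.null(cfg$sensor)) {
    kind <- cfg$sensor$kind %||% "robin"
    if (!kind %in% c("concentration", "ideal_flux", "robin")) {
      abort(sprintf("unknown sensor kind '%s'.", kind))
    }
    if (kind == "robin") {
      alpha <- cfg$sensor$alpha_cm_per_s
      if (is.null(alpha)) abort("robin sensor needs `alpha_cm_per_s`.")
    }
  }
  say("skin: D = %g cm^2/s, L = %g cm, k_skin = %g cm/s",
      skin$D, skin$L, permeability(skin))

  ts <- timescale_report(skin, alpha = alpha)
  report <- list(
    skin = list(D_cm2_per_s = skin$D, L_cm = skin$L, C0_mol_per_cm3 = skin$C0,
                k_skin_cm_per_s = permeability(skin)),
    timescales = list(
      tau_flux_s = ts$tau_flux_s, tau_conc_s = ts$tau_conc_s,
      tau_ratio = ts$tau_ratio,
      intercept_flux = ts$intercept_flux, intercept_conc = ts$intercept_conc,
      intercept_ratio = ts$intercept_ratio
    )
  )
  if (!is.null(alpha)) {
    report$sensor <- list(
      alpha_cm_per_s = alpha, alpha_bar = ts$alpha_bar,
      tau_robin_s = ts$tau_robin_s, intercept_robin = ts$intercept_robin,
      classification = ts$classification
    )
  }

  for (fig in cfg$figures %||% integer(0)) {
    tab <- figure_tables(fig)
    f <- file.path(out_dir, sprintf("figure%d.csv", fig))
    write_curve_csv(tab, f)
    say("wrote %s", f)
  }
  if (!is.null(cfg$response_t_bar)) {
    curves <- response_curves(as.numeric(cfg$response_t_bar))
    wide <- tidyr::pivot_wider(curves, names_from = "sensor",
                               values_from = "m_bar")
    f <- file.path(out_dir, "responses.csv")
    write_curve_csv(wide, f)
    say("wrote %s", f)
  }
  if (isTRUE(cfg$verify)) {
    say("running series-vs-oracle verification (this solves the PDE)...")
    dev <- verify_series_vs_oracle()
    write_curve_csv(dev, file.path(out_dir, "verification.csv"))
    report$verification <- list(max_deviation = max(dev$max_dev_profile,
                                                    dev$max_dev_response))
    say("max series-vs-oracle deviation: %.3g", report$verification$max_deviation)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %s", file.path(out_dir, "report.json"))
  invisible(report)
}
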