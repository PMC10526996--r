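#' Describe the skin barrier as a homogeneous diffusive slab
#'
#' The stratum corneum — the rate-limiting layer of skin for passive
#' ("insensible") permeation — is modelled as a single homogeneous layer of
#' thickness `L` with Fickian diffusion coefficient `D`. The blood-side
#' boundary (x = 0) is held at the analyte concentration `C0` after a step
#' change; the sensor sits at x = L. Internal units are cgs-style throughout:
#' cm, s, mol.
#'
#' @param D Diffusion coefficient of the analyte in the barrier, cm^2/s.
#' @param L Thickness of the rate-limiting layer, cm (see [um_to_cm()]).
#' @param C0 Blood-side concentration step, mol/cm^3. May be zero (a sensor
#'   on alcohol-free skin); defaults to 0.
#' @return An object of class `skin_barrier`: a list with elements `D`, `L`,
#'   `C0`.
#' @examples
#' skin <- skin_barrier(D = 5e-10, L = um_to_cm(15))
#' permeability(skin)   # k_skin = D/L, cm/s
#' @seealso [permeability()], [nondim_time()], [sensor_spec()]
#' @export
skin_barrier <- function(D, L, C0 = 0) {
  stopifnot(is.numeric(D), is.numeric(L), is.numeric(C0),
            length(D) == 1, length(L) == 1, length(C0) == 1)
  if (!is.finite(D) || D <= 0) abort("`D` must be a positive diffusion coefficient (cm^2/s).")
  if (!is.finite(L) || L <= 0) abort("`L` must be a positive thickness (cm).")
  if (!is.finite(C0) || C0 < 0) abort("`C0` must be a nonnegative concentration (mol/cm^3).")
  structure(list(D = D, L = L, C0 = C0), class = "skin_barrier")
}

#' @export
print.skin_barrier <- function(x, ...) {
  cat("<skin_barrier>\n")
  cat(sprintf("  D      = %.4g cm^2/s\n", x$D))
  cat(sprintf("  L      = %.4g cm (%.3g um)\n", x$L, x$L * 1e4))
  cat(sprintf("  C0     = %.4g mol/cm^3\n", x$C0))
  cat(sprintf("  k_skin = %.4g cm/s\n", permeability(x)))
  invisible(x)
}

#' Skin permeability (mass-transfer coefficient)
#'
#' The permeability k_skin = D/L (cm/s) relates steady-state transdermal flux
#' to the blood-side concentration: flux_ss = k_skin * C0.
#'
#' @param skin A [skin_barrier()].
#' @return Permeability in cm/s.
#' @export
permeability <- function(skin) {
  stopifnot(inherits(skin, "skin_barrier"))
  skin$D / skin$L
}

#' Nondimensionalize and redimensionalize time
#'
#' Diffusion across a slab has the natural timescale L^2/D; dimensionless
#' time is t_bar = t * D / L^2 (the Fourier number). All series solutions and
#' the finite-difference solver work in these units.
#'
#' @param t Time(s) in seconds; vectorized. Must be nonnegative.
#' @param skin A [skin_barrier()].
#' @return `nondim_time()`: dimensionless time(s); `redim_time()`: seconds.
#' @examples
#' skin <- skin_barrier(D = 3e-11, L = 1.5e-3)
#' nondim_time(3600, skin)    # one hour is ~0.048 diffusion times
#' @export
nondim_time <- function(t, skin) {
  stopifnot(inherits(skin, "skin_barrier"), is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) abort("`t` must be nonnegative.")
  t * skin$D / skin$L^2
}

#' @param t_bar Dimensionless time(s), t * D / L^2.
#' @rdname nondim_time
#' @export
redim_time <- function(t_bar, skin) {
  stopifnot(inherits(skin, "skin_barrier"), is.numeric(t_bar))
  if (any(t_bar < 0, na.rm = TRUE)) abort("`t_bar` must be nonnegative.")
  t_bar * skin$L^2 / skin$D
}

#' Describe a sensor by its boundary-condition class
#'
#' Three idealized sensor classes set the boundary condition at the
#' skin/sensor interface (x = L):
#'
#' * `"concentration"` — a reversible, non-consuming sensor: zero flux
#'   (Neumann condition), the sensor reads the interface concentration.
#' * `"ideal_flux"` — an irreversibly consuming sensor: zero interface
#'   concentration (Dirichlet condition), the sensor reads the incoming flux.
#' * `"robin"` — a finite-sensitivity flux sensor: flux proportional to the
#'   local concentration with rate constant `alpha` (cm/s), interpolating
#'   between the two extremes.
#'
#' @param kind One of `"concentration"`, `"ideal_flux"`, `"robin"`.
#' @param alpha Sensor rate constant, cm/s. Required (and > 0) iff
#'   `kind = "robin"`; ignored otherwise.
#' @return An object of class `sensor_spec`.
#' @seealso [alpha_bar()], [classify_sensor()]
#' @export
sensor_spec <- function(kind = c("concentration", "ideal_flux", "robin"),
                        alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "robin") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1 ||
        !is.finite(alpha) || alpha <= 0) {
      abort("A robin sensor needs a single positive `alpha` (cm/s).")
    }
  } else {
    alpha <- NULL
  }
  structure(list(kind = kind, alpha = alpha), class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat("<sensor_spec>", x$kind)
  if (!is.null(x$alpha)) cat(sprintf(" (alpha = %.4g cm/s)", x$alpha))
  cat("\n")
  invisible(x)
}

#' Dimensionless sensor sensitivity relative to skin permeability
#'
#' alpha_bar = alpha / k_skin = alpha * L / D. A sensor with alpha_bar >> 1
#' behaves like an ideal flux-type sensor; alpha_bar << 1 behaves like a
#' concentration-type sensor in its time response.
#'
#' @param alpha Sensor rate constant(s), cm/s; vectorized, nonnegative.
#' @param skin A [skin_barrier()].
#' @return Dimensionless sensitivity, same length as `alpha`.
#' @examples
#' skin <- skin_barrier(D = 5e-10, L = um_to_cm(15))
#' alpha_bar(1.3e-7, skin)
#' @export
alpha_bar <- function(alpha, skin) {
  stopifnot(is.numeric(alpha))
  if (any(alpha < 0, na.rm = TRUE)) abort("`alpha` must be nonnegative.")
  alpha / permeability(skin)
}

#' Unit converters for the package's cgs-style internal units
#'
#' Everything internal is cm / s / mol. These helpers convert the units in
#' which skin and sensor parameters are usually quoted.
#'
#' `mg_per_dl_to_mol_per_cm3()` converts a mass concentration (e.g. blood
#' alcohol in mg/dL) to mol/cm^3 given the molecular weight:
#' conc * 1e-3 (g/mg) / (mw * 100 (cm^3/dL)).
#'
#' @param x Value(s) to convert; vectorized.
#' @param mw Molecular weight, g/mol (ethanol: 46.07).
#' @return Converted value(s).
#' @examples
#' mg_per_dl_to_mol_per_cm3(100, mw = 46.07)  # ~2.17e-5 mol/cm^3
#' umol_per_l_to_mol_per_cm3(200)             # 2e-7 mol/cm^3
#' @name units
NULL

#' @rdname units
#' @export
mg_per_dl_to_mol_per_cm3 <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw))
  if (any(x < 0, na.rm = TRUE)) abort("mass concentration must be nonnegative.")
  if (any(!is.finite(mw) | mw <= 0)) abort("`mw` must be a positive molecular weight (g/mol).")
  x * 1e-3 / (mw * 100)
}

#' @rdname units
#' @export
mol_per_cm3_to_mg_per_dl <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw))
  if (any(!is.finite(mw) | mw <= 0)) abort("`mw` must be a positive molecular weight (g/mol).")
  x * mw * 100 / 1e-3
}

#' @rdname units
#' @export
umol_per_l_to_mol_per_cm3 <- function(x) x * 1e-6 / 1e3

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
hours_to_seconds <- function(x) x * 3600

#' @rdname units
#' @export
seconds_to_hours <- function(x) x / 3600

#' @rdname units
#' @export
nA_to_A <- function(x) x * 1e-9

#' @rdname units
#' @export
uA_to_A <- function(x) x * 1e-6
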