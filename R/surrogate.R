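# Analytic surrogate for the Monte-Carlo-computed air-kerma field of a
# diagnostic X-ray tube. The field is modelled as a separable product of
#   * a heel-effect profile in the tangent angle phi (kerma falls towards the
#     anode side as photons traverse more target material),
#   * the inverse-square law in source-detector distance r,
#   * a power law in tube voltage V,
# anchored to the packaged reference table of simulated kerma values, with
# optional multiplicative Monte-Carlo-like noise. The polar angle theta has
# no effect (the beam is treated as azimuthally uniform).

REF_TABLE_ROWS <- 324L
# frozen column totals of the packaged fixture, used as a corruption check
REF_TABLE_CHECKSUMS <- c(phi_deg = 3180, theta_deg = 9900, r_mm = 246000,
                      v_kv = 29160, kerma = 24.2672, kerma_predicted = 24.1011)

#' Load the packaged reference table of simulated air-kerma values
#'
#' Returns the packaged table of simulated air kerma (and the reference
#' network predictions) on part of the detector grid: tangent angle phi
#' 0-20 deg, five (theta, R) detector rings, six tube voltages. Kerma columns
#' are scaled to absolute relative units (the printed 1e-5 scale is applied).
#'
#' @return a data frame with columns `phi_deg`, `theta_deg`, `r_mm`, `v_kv`,
#'   `kerma`, `kerma_predicted` (324 rows).
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "reference_air_kerma.csv",
                      package = "kermagmdh", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    abort("reference kerma table is missing from the installed package")
  df <- utils::read.csv(path)
  sums <- vapply(names(REF_TABLE_CHECKSUMS), function(nm) sum(df[[nm]]), numeric(1))
  if (nrow(df) != REF_TABLE_ROWS ||
      any(abs(sums - REF_TABLE_CHECKSUMS) > 1e-6 * pmax(1, abs(REF_TABLE_CHECKSUMS))))
    abort("reference kerma table failed its checksum: file corrupted?")
  df$kerma <- df$kerma * 1e-5
  df$kerma_predicted <- df$kerma_predicted * 1e-5
  df
}

#' Parameters of the analytic air-kerma surrogate
#'
#' Defaults are anchored to the packaged reference table: `k_ref` is the
#' kerma at the anchor point (phi = 0, r = 250 mm, V = 40 kV); `heel_knots`
#' are the anchor-block kerma ratios at phi = 0, 2, ..., 20 deg (the 20 deg
#' knot is linearly extrapolated from the last two printed values and floored
#' at `heel_floor` to keep kerma positive); `p_volt` is the log-log
#' least-squares slope of kerma against voltage over the six anchor rows.
#'
#' @param k_ref kerma at the anchor point, absolute units. Default 0.3730e-5.
#' @param r_ref reference distance in mm. Default 250.
#' @param p_volt voltage exponent; default fitted from the reference table.
#' @param heel_knots normalized heel factors at phi = 0, 2, ..., 20 deg;
#'   must start at 1 and be strictly decreasing.
#' @param noise_sigma multiplicative noise fraction in [0, 0.04] (the
#'   Monte-Carlo statistical uncertainty cap). Default 0.04.
#' @param heel_floor lower bound applied to the extrapolated 20 deg knot.
#' @return an object of class `surrogate_params`.
#' @export
surrogate_params <- function(k_ref = 0.3730e-5, r_ref = 250,
                             p_volt = NULL, heel_knots = NULL,
                             noise_sigma = 0.04, heel_floor = 0.005) {
  if (is.null(p_volt) || is.null(heel_knots)) {
    tab <- load_reference_table()
    anchor <- tab[tab$theta_deg == 0 & tab$r_mm == 250, ]
    if (is.null(p_volt)) {
      a0 <- anchor[anchor$phi_deg == 0, ]
      p_volt <- unname(stats::coef(stats::lm(log(kerma) ~ log(v_kv),
                                             data = a0))[2L])
    }
    if (is.null(heel_knots)) {
      b <- anchor[anchor$v_kv == 40, ]
      b <- b[order(b$phi_deg), ]
      knots <- b$kerma / b$kerma[1L]
      # no phi = 20 row exists in the anchor block: extrapolate linearly
      k20 <- max(heel_floor, 2 * knots[length(knots)] - knots[length(knots) - 1L])
      heel_knots <- c(knots, k20)
    }
  }
  if (noise_sigma < 0 || noise_sigma > 0.04)
    abort("noise_sigma must lie in [0, 0.04]")
  if (length(heel_knots) != 11L)
    abort("heel_knots must hold 11 values (phi = 0, 2, ..., 20 deg)")
  if (abs(heel_knots[1L] - 1) > 1e-12)
    abort("heel_knots must equal 1 at phi = 0")
  if (any(diff(heel_knots) >= 0))
    abort("heel_knots must be strictly decreasing in phi")
  structure(list(k_ref = k_ref, r_ref = r_ref, p_volt = p_volt,
                 heel_knots = heel_knots, noise_sigma = noise_sigma),
            class = "surrogate_params")
}

#' Heel-effect attenuation factor
#'
#' Piecewise-linear interpolation of the normalized heel profile: 1 at
#' phi = 0, strictly decreasing towards the anode side.
#'
#' @param phi_deg tangent angle(s) in degrees, within [0, 20].
#' @param params a [surrogate_params()] object.
#' @return factor(s) in (0, 1].
#' @export
heel_factor <- function(phi_deg, params = surrogate_params()) {
  if (any(phi_deg < 0 | phi_deg > 20))
    abort("tangent angle outside modelled cone [0, 20] degrees")
  stats::approx(seq(0, 20, by = 2), params$heel_knots, xout = phi_deg)$y
}

#' Noiseless or noisy surrogate air kerma at a field point
#'
#' Noiseless value: k_ref * heel_factor(phi) * (r_ref / r)^2 * (V / 40)^p_volt.
#' The polar angle theta has no effect (azimuthal symmetry). With a
#' `noise_seed`, each value is multiplied by (1 + eps), eps ~ Normal(0,
#' noise_sigma) truncated at +/- 3 sigma, emulating Monte-Carlo tally noise.
#'
#' @param phi_deg tangent angle(s), degrees, in [0, 20].
#' @param theta_deg polar angle(s), degrees, in [0, 360]; no effect on the value.
#' @param r_mm source-detector distance(s), mm, > 0.
#' @param v_kv tube voltage(s), kV, > 0.
#' @param params a [surrogate_params()] object.
#' @param noise_seed optional integer; when given (and noise_sigma > 0),
#'   seeded multiplicative noise is applied.
#' @return air kerma value(s) in the reference table's absolute units.
#' @export
kerma_value <- function(phi_deg, theta_deg = 0, r_mm, v_kv,
                        params = surrogate_params(), noise_seed = NULL) {
  if (any(r_mm <= 0)) abort("distance r_mm must be positive")
  if (any(v_kv <= 0)) abort("tube voltage v_kv must be positive")
  if (any(theta_deg < 0 | theta_deg > 360))
    abort("polar angle theta_deg must lie in [0, 360]")
  k <- params$k_ref * heel_factor(phi_deg, params) *
    (params$r_ref / r_mm)^2 * (v_kv / 40)^params$p_volt
  if (!is.null(noise_seed) && params$noise_sigma > 0) {
    eps <- with_local_seed(noise_seed,
                           stats::rnorm(length(k), 0, params$noise_sigma))
    eps <- pmin(pmax(eps, -3 * params$noise_sigma), 3 * params$noise_sigma)
    k <- k * (1 + eps)
  }
  k
}

#' Detector-grid specification
#'
#' Defaults reproduce the study grid: tangent angles 0-20 deg in steps of
#' 2 deg (11 values), polar angles 0-360 deg in steps of 15 deg (25 values,
#' 0 and 360 kept distinct), five distances and six tube voltages —
#' 11 x 25 x 5 = 1375 points per voltage, 8250 samples in all.
#'
#' @param tangent_angles_deg,polar_angles_deg,distances_mm,voltages_kv
#'   numeric vectors overriding the defaults.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(tangent_angles_deg = seq(0, 20, by = 2),
                      polar_angles_deg = seq(0, 360, by = 15),
                      distances_mm = c(250, 500, 750, 1000, 1250),
                      voltages_kv = c(40, 60, 80, 100, 120, 140)) {
  if (length(tangent_angles_deg) == 0L || length(polar_angles_deg) == 0L ||
      length(distances_mm) == 0L || length(voltages_kv) == 0L)
    abort("grid component lists must be non-empty")
  structure(list(tangent_angles_deg = tangent_angles_deg,
                 polar_angles_deg = polar_angles_deg,
                 distances_mm = distances_mm,
                 voltages_kv = voltages_kv),
            class = "grid_spec")
}

#' Enumerate the detector grid
#'
#' Full Cartesian product of the grid components in deterministic order:
#' tangent angle varies fastest, then polar angle, distance, voltage.
#'
#' @param spec a [grid_spec()].
#' @return data frame with columns `phi_deg`, `theta_deg`, `r_mm`, `v_kv`.
#' @export
generate_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- expand.grid(phi_deg = spec$tangent_angles_deg,
                   theta_deg = spec$polar_angles_deg,
                   r_mm = spec$distances_mm,
                   v_kv = spec$voltages_kv,
                   KEEP.OUT.ATTRS = FALSE)
  g
}

#' Generate a surrogate air-kerma dataset over the detector grid
#'
#' Evaluates the surrogate at every grid point; when `seed` is given and
#' `params$noise_sigma > 0`, applies seeded multiplicative noise. The same
#' seed always reproduces the identical dataset.
#'
#' @param spec a [grid_spec()].
#' @param params a [surrogate_params()].
#' @param seed optional integer master seed for the noise stream.
#' @return data frame with columns `phi_deg`, `theta_deg`, `r_mm`, `v_kv`,
#'   `kerma`.
#' @export
generate_dataset <- function(spec = grid_spec(), params = surrogate_params(),
                             seed = NULL) {
  g <- generate_grid(spec)
  noise_seed <- if (is.null(seed)) NULL else derive_seed(seed, "mc-noise")
  g$kerma <- kerma_value(g$phi_deg, g$theta_deg, g$r_mm, g$v_kv,
                         params = params, noise_seed = noise_seed)
  g
}
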