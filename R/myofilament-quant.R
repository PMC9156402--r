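AVOGADRO <- 6.02214076e23

#' Fluorescence calibration series
#'
#' Serial-dilution standard: mean fluorescence intensity of labelled myosin
#' monomer solutions at known concentrations, each averaged over several
#' imaged fields.
#'
#' @param conc_uM labelled-monomer concentrations (uM), non-negative, at
#'   least 3 distinct levels.
#' @param mean_intensity mean fluorescence intensities (a.u.),
#'   non-negative.
#' @param n_fields number of imaged fields per level (default 4).
#' @return A `calibration_series` data frame.
#' @export
calibration_series <- function(conc_uM, mean_intensity, n_fields = 4L) {
  stopifnot(length(conc_uM) == length(mean_intensity))
  if (any(conc_uM < 0) || any(mean_intensity < 0))
    stop("concentrations and intensities must be non-negative", call. = FALSE)
  if (length(unique(conc_uM)) < 3L)
    stop("need >= 3 distinct concentration levels", call. = FALSE)
  df <- data.frame(conc_uM = as.numeric(conc_uM),
                   mean_intensity = as.numeric(mean_intensity),
                   n_fields = as.integer(rep_len(n_fields, length(conc_uM))))
  class(df) <- c("calibration_series", "data.frame")
  df
}

#' Fit the fluorescence standard curve
#'
#' Ordinary least-squares line `intensity = slope * C + intercept` through
#' the calibration series.
#'
#' @param series a [calibration_series()].
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, their standard errors `slope_se`, `intercept_se`, the
#'   2x2 coefficient covariance `vcov`, residual `sigma`, degrees of
#'   freedom `df` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(series) {
  if (!is.data.frame(series) || !all(c("conc_uM", "mean_intensity") %in% names(series)))
    stop("series must be a calibration_series", call. = FALSE)
  if (length(unique(series$conc_uM)) < 2L)
    stop("rank-deficient calibration: need >= 2 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(mean_intensity ~ conc_uM, data = series)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  structure(list(slope = unname(cf["conc_uM"]),
                 intercept = unname(cf["(Intercept)"]),
                 slope_se = unname(se["conc_uM"]),
                 intercept_se = unname(se["(Intercept)"]),
                 vcov = V,
                 sigma = stats::sigma(fit),
                 df = stats::df.residual(fit),
                 fit = fit),
            class = "standard_curve")
}

#' Constants for myofilament counting
#'
#' @param labelling_ratio fraction of myosin monomers carrying the
#'   fluorophore (default 0.10).
#' @param volume_inner local volume of the inner region (um^3, default
#'   1055).
#' @param volume_ring local volume of the ring region (um^3, default 1225).
#' @param monomer_density myosin monomers per um of myofilament
#'   (default 560).
#' @param filament_length average myofilament length (um, default 0.56).
#' @return An object of class `quant_constants`.
#' @export
quant_constants <- function(labelling_ratio = 0.10,
                            volume_inner = 1055, volume_ring = 1225,
                            monomer_density = 560, filament_length = 0.56) {
  if (!(labelling_ratio > 0 && labelling_ratio <= 1))
    stop("labelling_ratio must be in (0, 1]", call. = FALSE)
  vals <- c(volume_inner, volume_ring, monomer_density, filament_length)
  if (any(vals <= 0)) stop("volumes, density and length must be > 0", call. = FALSE)
  structure(list(labelling_ratio = labelling_ratio,
                 volume_inner = volume_inner, volume_ring = volume_ring,
                 monomer_density = monomer_density,
                 filament_length = filament_length),
            class = "quant_constants")
}

#' Convert a measured fluorescence intensity into a myofilament count
#'
#' Inverts the standard curve to the labelled-monomer concentration,
#' corrects for the labelling ratio, converts concentration x local volume
#' to a monomer count via Avogadro's number, and divides by the average
#' monomers per filament (monomer density x filament length). Uncertainty
#' in the measured intensity and in the standard-curve coefficients is
#' propagated to the count by the first-order delta method; a two-sided
#' interval uses the t distribution with the curve's residual degrees of
#' freedom.
#'
#' @param measured_intensity mean local fluorescence intensity (a.u.).
#' @param curve a [fit_standard_curve()] result with positive slope.
#' @param constants a [quant_constants()].
#' @param intensity_sd optional standard error of `measured_intensity`
#'   (a.u.); default 0 (intensity treated as exact).
#' @param conf_level confidence level for the reported interval.
#' @return An object of class `quant_result`: list with
#'   `local_concentration_total` (uM, all monomers),
#'   `local_concentration_label` (uM, labelled), `monomer_count`,
#'   `filament_count`, per-region counts `filament_count_inner` /
#'   `filament_count_ring`, delta-method `filament_count_se`, interval
#'   `filament_count_ci`, and the curve coefficients with standard errors.
#' @examples
#' s <- calibration_series(c(0.001, 0.01, 0.1, 1), 2 * c(0.001, 0.01, 0.1, 1) + 1)
#' cv <- fit_standard_curve(s)
#' count_myofilaments(1.38, cv)$filament_count
#' @export
count_myofilaments <- function(measured_intensity, curve,
                               constants = quant_constants(),
                               intensity_sd = 0, conf_level = 0.95) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(constants, "quant_constants"))
  if (curve$slope <= 0) stop("standard-curve slope must be > 0", call. = FALSE)
  if (measured_intensity < curve$intercept)
    stop("measured intensity below the curve intercept: negative ",
         "concentration", call. = FALSE)

  m <- curve$slope; b <- curve$intercept
  C_label <- (measured_intensity - b) / m           # uM labelled monomer
  C_total <- C_label / constants$labelling_ratio    # uM all monomers

  V_L <- (constants$volume_inner + constants$volume_ring) * 1e-15  # um^3 -> L
  per_uM <- 1e-6 * AVOGADRO * V_L     # monomers per uM of total concentration
  monomers_per_filament <- constants$monomer_density * constants$filament_length
  monomer_count <- C_total * per_uM
  filament_count <- monomer_count / monomers_per_filament

  # delta method on C_label = (I - b)/m:
  # dC/dI = 1/m, dC/db = -1/m, dC/dm = -C/m; cov(b, m) from the OLS fit.
  vb <- curve$vcov["(Intercept)", "(Intercept)"]
  vm <- curve$vcov["conc_uM", "conc_uM"]
  cbm <- curve$vcov["(Intercept)", "conc_uM"]
  var_C <- (intensity_sd^2 + vb + C_label^2 * vm + 2 * C_label * cbm) / m^2
  scale_count <- per_uM / (constants$labelling_ratio * monomers_per_filament)
  count_se <- sqrt(max(var_C, 0)) * scale_count
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = max(curve$df, 1L))
  ci <- filament_count + c(-1, 1) * tq * count_se

  vol_tot <- constants$volume_inner + constants$volume_ring
  structure(list(local_concentration_total = C_total,
                 local_concentration_label = C_label,
                 monomer_count = monomer_count,
                 filament_count = filament_count,
                 filament_count_inner = filament_count * constants$volume_inner / vol_tot,
                 filament_count_ring = filament_count * constants$volume_ring / vol_tot,
                 filament_count_se = count_se,
                 filament_count_ci = ci,
                 conf_level = conf_level,
                 slope = m, intercept = b,
                 slope_se = curve$slope_se, intercept_se = curve$intercept_se),
            class = "quant_result")
}
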