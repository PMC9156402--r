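#' Parameters of the 1D pillar-ring contractility model
#'
#' Bundles the mechanical and kinetic constants of the one-dimensional
#' viscoelastic contraction model: each pillar is an elastic spring (`k_p`)
#' loaded by an actomyosin network represented by a spring (`k_am`) and a
#' dashpot (`gamma_am`), driven by an active force from `n_b` transiently
#' bound myofilaments, each contributing a force `f_s`. In the
#' `"load_dependent"` mode the unbinding rate decreases with the load per
#' bound filament (catch-bond-like), `k_off(f) = k_off0 * exp(-f / f_d)`,
#' which creates a positive feedback between stress build-up and motor
#' engagement. In the `"density_only"` control mode unbinding is
#' load-independent and the active force instead scales with the geometric
#' densification of the network, `rho(x)/rho0 = R / (R - x)`.
#'
#' Internal units are pN, micrometres and seconds throughout.
#'
#' @param k_p pillar spring constant (pN/um).
#' @param k_am actomyosin network spring constant (pN/um).
#' @param gamma_am network friction coefficient (pN s/um).
#' @param N_m available myofilament pool per pillar (dimensionless count).
#' @param f_s force generated per bound myofilament (pN).
#' @param k_on0 baseline binding rate (1/s).
#' @param k_off0 baseline unbinding rate at zero load (1/s).
#' @param f_d load scale of unbinding-rate suppression (pN).
#' @param rho0 reference actin areal density (normalised, dimensionless).
#' @param R pillar-ring radius at tip height (um).
#' @param mode force-generation law: `"load_dependent"` (default) or the
#'   `"density_only"` control variant.
#' @param n_pillars number of pillars in the ring.
#'
#' @return An object of class `model_parameters` (a validated named list).
#'
#' @details The default values form the package's reference parameter set:
#' they are a documented working point (not fitted ground truth) chosen so
#' that at `k_p = 35` pN/um the steady pillar force is of order 10^2 pN and
#' the time to peak contraction velocity is of order one minute, matching
#' the scales observed in pillar-ring assays. Every value can be
#' overridden.
#'
#' @seealso [simulate_contraction()], [steady_state()], [parameter_schedule()]
#' @examples
#' p <- model_parameters(k_p = 35)
#' steady_state(p)
#' @export
model_parameters <- function(k_p = 35, k_am = 1, gamma_am = 2000,
                             N_m = 10, f_s = 40,
                             k_on0 = 0.05, k_off0 = 1.0, f_d = 10,
                             rho0 = 1, R = 13,
                             mode = c("load_dependent", "density_only"),
                             n_pillars = 10) {
  mode <- match.arg(mode)
  p <- list(k_p = k_p, k_am = k_am, gamma_am = gamma_am, N_m = N_m,
            f_s = f_s, k_on0 = k_on0, k_off0 = k_off0, f_d = f_d,
            rho0 = rho0, R = R, mode = mode, n_pillars = n_pillars)
  validate_model_parameters(p)
  class(p) <- "model_parameters"
  p
}

validate_model_parameters <- function(p) {
  num <- setdiff(names(p), "mode")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  stopifnot_param(p$k_p > 0, "k_p must be > 0")
  stopifnot_param(p$gamma_am > 0, "gamma_am must be > 0")
  stopifnot_param(p$k_am >= 0, "k_am must be >= 0")
  stopifnot_param(p$N_m >= 0, "N_m must be >= 0")
  stopifnot_param(p$f_s >= 0, "f_s must be >= 0")
  stopifnot_param(p$k_on0 >= 0, "k_on0 must be >= 0")
  stopifnot_param(p$k_off0 >= 0, "k_off0 must be >= 0")
  stopifnot_param(p$f_d > 0, "f_d must be > 0")
  stopifnot_param(p$rho0 > 0, "rho0 must be > 0")
  stopifnot_param(p$R > 0, "R must be > 0")
  stopifnot_param(p$n_pillars >= 1, "n_pillars must be >= 1")
  if (!p$mode %in% c("load_dependent", "density_only"))
    stop("mode must be 'load_dependent' or 'density_only'", call. = FALSE)
  invisible(p)
}

stopifnot_param <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Update a parameter set with named overrides
#'
#' @param params a `model_parameters` object.
#' @param overrides named list of replacement values; names must be existing
#'   parameter names.
#' @return A validated `model_parameters` object.
#' @export
update_parameters <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  bad <- setdiff(names(overrides), names(unclass(params)))
  if (length(bad) > 0L)
    stop("unknown parameter name(s) in overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  validate_model_parameters(p)
  class(p) <- "model_parameters"
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("1D actomyosin contractility model parameters (", x$mode, " mode)\n",
      sep = "")
  cat(sprintf("  k_p = %g pN/um, k_am = %g pN/um, gamma_am = %g pN s/um\n",
              x$k_p, x$k_am, x$gamma_am))
  cat(sprintf("  N_m = %g, f_s = %g pN, k_on0 = %g /s, k_off0 = %g /s, f_d = %g pN\n",
              x$N_m, x$f_s, x$k_on0, x$k_off0, x$f_d))
  cat(sprintf("  R = %g um, rho0 = %g, n_pillars = %d\n",
              x$R, x$rho0, as.integer(x$n_pillars)))
  invisible(x)
}

#' Schedule of parameter switches during a simulation
#'
#' Describes experiment-style interventions: at each switch time the listed
#' parameters are overridden (for example `k_on0 = 0` to model ATP
#' depletion / motor detachment, or restoring `k_on0` to model ATP
#' re-addition or light-triggered release of caged ATP). The integrator is
#' restarted exactly at each switch. `initial_binding` selects the starting
#' motor engagement: `"unloaded"` uses the zero-load binding equilibrium
#' `n_b(0) = k_on0 N_m / (k_on0 + k_off0)`, `"preloaded"` starts from the
#' loaded steady state so that motors respond without the slow engagement
#' build-up.
#'
#' @param switch_times strictly increasing vector of switch times (s); may
#'   be empty.
#' @param overrides list (one element per switch time) of named lists of
#'   parameter overrides, applied cumulatively.
#' @param initial_binding `"unloaded"` (default) or `"preloaded"`.
#' @return An object of class `parameter_schedule`.
#' @export
parameter_schedule <- function(switch_times = numeric(0), overrides = list(),
                               initial_binding = c("unloaded", "preloaded")) {
  initial_binding <- match.arg(initial_binding)
  if (length(switch_times) != length(overrides))
    stop("switch_times and overrides must have the same length", call. = FALSE)
  if (length(switch_times) > 0) {
    if (any(!is.finite(switch_times)) || any(diff(switch_times) <= 0) ||
        any(switch_times <= 0))
      stop("switch_times must be positive, finite and strictly increasing",
           call. = FALSE)
    ok <- vapply(overrides, function(o) is.list(o) && length(names(o)) == length(o),
                 logical(1))
    if (!all(ok)) stop("each override must be a named list", call. = FALSE)
  }
  structure(list(switch_times = as.numeric(switch_times),
                 overrides = overrides,
                 initial_binding = initial_binding),
            class = "parameter_schedule")
}
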