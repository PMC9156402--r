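# Per-filament load; epsilon floors n_b to avoid 0/0 at full detachment.
.load_per_filament <- function(x, n_b, params, eps = 1e-6) {
  (params$k_p + params$k_am) * x / max(n_b, eps)
}

# Active force for the current mode. Densification rho(x)/rho0 = R/(R - x)
# diverges as the tips approach the ring centre.
.active_force <- function(x, n_b, params) {
  if (params$mode == "density_only") {
    if (x >= params$R)
      stop("densification factor diverges: x >= R (x = ", signif(x, 6), " um)",
           call. = FALSE)
    n_b * params$f_s * params$R / (params$R - x)
  } else {
    n_b * params$f_s
  }
}

.model_rhs <- function(t, y, params) {
  x <- y[[1L]]; n_b <- y[[2L]]
  F_A <- if (params$mode == "density_only") {
    # guard: beyond closure the model is invalid; push derivative to NaN so
    # the failure is detected and reported with its time
    if (x >= params$R) NaN else n_b * params$f_s * params$R / (params$R - x)
  } else {
    n_b * params$f_s
  }
  k_tot <- params$k_p + params$k_am
  dx <- (F_A - k_tot * x) / params$gamma_am
  f <- k_tot * x / max(n_b, 1e-6)
  k_off <- if (params$mode == "load_dependent") {
    params$k_off0 * exp(-f / params$f_d)
  } else {
    params$k_off0
  }
  dn_b <- params$k_on0 * (params$N_m - n_b) - k_off * n_b
  list(c(dx, dn_b))
}

#' Simulate pillar-ring contraction
#'
#' Integrates the governing equations of the 1D contractility model
#' \deqn{\gamma_{am}\,\dot x = F_A - (k_p + k_{am})\,x,\qquad
#'       \dot n_b = k_{on,0}(N_m - n_b) - k_{off}(f)\,n_b,}
#' with active force \eqn{F_A = n_b f_s} (load-dependent mode) or
#' \eqn{F_A = n_b f_s R/(R-x)} (density-only mode), per-filament load
#' \eqn{f = (k_p+k_{am})x/\max(n_b,\epsilon)} and catch-bond-like unbinding
#' \eqn{k_{off}(f) = k_{off,0} e^{-f/f_d}} (constant \eqn{k_{off,0}} in
#' density-only mode). Integration uses an adaptive stiff-capable solver
#' (lsoda) and restarts exactly at every schedule switch time.
#'
#' @param params a [model_parameters()] object.
#' @param schedule a [parameter_schedule()]; default: no switches, unloaded
#'   initial binding.
#' @param t_end simulation end time (s), > 0.
#' @param dt_out output sampling interval (s).
#' @param rtol,atol integrator tolerances.
#' @return A `trajectory` data frame with columns `t` (s), `x` (um),
#'   `v = dx/dt` (um/s), `n_b` (bound myofilaments), `F_A` (active force,
#'   pN), `F_pillar = k_p x` (pN) and `P` (instantaneous mechanical power of
#'   the whole ring, W). The parameter set is attached as attribute
#'   `params`.
#' @examples
#' traj <- simulate_contraction(model_parameters(), t_end = 600)
#' peak_velocity(traj)
#' @export
simulate_contraction <- function(params, schedule = parameter_schedule(),
                                 t_end, dt_out = 1,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_parameters"))
  if (!inherits(schedule, "parameter_schedule"))
    stop("schedule must be a parameter_schedule object", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("t_end must be a positive finite number", call. = FALSE)
  if (any(schedule$switch_times >= t_end))
    stop("all schedule switch times must lie strictly before t_end",
         call. = FALSE)

  t_grid <- seq(0, t_end, by = dt_out)
  if (t_grid[length(t_grid)] < t_end) t_grid <- c(t_grid, t_end)

  n_b0 <- if (schedule$initial_binding == "preloaded") {
    steady_state(params)$n_b_ss
  } else {
    if (params$k_on0 + params$k_off0 > 0)
      params$k_on0 * params$N_m / (params$k_on0 + params$k_off0)
    else 0
  }
  y <- c(x = 0, n_b = n_b0)

  seg_bounds <- c(0, schedule$switch_times, t_end)
  cur <- params
  rows <- vector("list", length(seg_bounds) - 1L)
  for (s in seq_len(length(seg_bounds) - 1L)) {
    if (s > 1L) cur <- update_parameters(cur, schedule$overrides[[s - 1L]])
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1)))
    sol <- deSolve::ode(y = y, times = times, func = .model_rhs, parms = cur,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (any(!is.finite(sol))) {
      bad <- which(apply(sol, 1L, function(r) any(!is.finite(r))))[1L]
      stop("integration failure: non-finite state at t = ",
           signif(sol[max(bad - 1L, 1L), "time"], 6), " s", call. = FALSE)
    }
    y <- c(x = unname(sol[nrow(sol), "x"]), n_b = unname(sol[nrow(sol), "n_b"]))
    keep <- sol[, "time"] %in% t_grid
    if (s > 1L) keep[1L] <- FALSE  # segment start already emitted
    sub <- sol[keep, , drop = FALSE]
    if (nrow(sub) > 0) {
      n_b <- pmin(pmax(sub[, "n_b"], 0), cur$N_m)
      x <- sub[, "x"]
      F_A <- vapply(seq_along(x), function(i) .active_force(x[i], n_b[i], cur),
                    numeric(1))
      k_tot <- cur$k_p + cur$k_am
      v <- (F_A - k_tot * x) / cur$gamma_am
      F_pillar <- cur$k_p * x
      rows[[s]] <- data.frame(t = sub[, "time"], x = x, v = v, n_b = n_b,
                              F_A = F_A, F_pillar = F_pillar,
                              P = cur$n_pillars * F_pillar * v * 1e-18)
    }
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  attr(traj, "params") <- params
  attr(traj, "schedule") <- schedule
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Steady state of the contractility model
#'
#' Finds the fixed point of the governing equations by root finding on the
#' nullcline intersection. In load-dependent mode the force balance pins the
#' per-filament load to \eqn{f_s} at any interior fixed point, and the root
#' is located on the binding nullcline. In density-only mode the bound pool
#' equilibrates at its zero-load value and the displacement solves
#' \eqn{n_b f_s R/(R-x) = (k_p+k_{am})x}; when the active amplitude exceeds
#' what the pillar can balance there is no interior fixed point and the ring
#' contracts to closure — this is reported as a collapsed state with
#' `x_ss = R` and the limiting force `k_p R`.
#'
#' @param params a [model_parameters()] object (either mode).
#' @return A list with `x_ss` (um), `n_b_ss`, `F_pillar_ss` (pN),
#'   `degenerate` (TRUE when motors cannot sustain any load and the zero
#'   state is returned) and `collapsed` (density-only runaway).
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  k_tot <- params$k_p + params$k_am
  zero <- list(x_ss = 0, n_b_ss = 0, F_pillar_ss = 0,
               degenerate = TRUE, collapsed = FALSE)
  if (params$N_m <= 0 || params$f_s <= 0 || params$k_on0 <= 0) return(zero)

  if (params$mode == "density_only") {
    n_b <- params$k_on0 * params$N_m / (params$k_on0 + params$k_off0)
    A <- n_b * params$f_s
    R <- params$R
    disc <- R^2 - 4 * A * R / k_tot
    if (disc < 0) {
      # runaway densification: no interior fixed point, tips reach the centre
      return(list(x_ss = R, n_b_ss = n_b, F_pillar_ss = params$k_p * R,
                  degenerate = FALSE, collapsed = TRUE))
    }
    x <- (R - sqrt(disc)) / 2  # stable branch
    return(list(x_ss = x, n_b_ss = n_b, F_pillar_ss = params$k_p * x,
                degenerate = FALSE, collapsed = FALSE))
  }

  # load_dependent: dx/dt = 0 forces f = f_s per filament; solve the binding
  # nullcline residual g(n_b) = k_on0 (N_m - n_b) - k_off(f_s) n_b = 0.
  # k_off(f_s) is constant in n_b, so the root is explicit, but locate it by
  # uniroot on the residual to keep the fixed-point computation generic.
  k_off_ss <- params$k_off0 * exp(-params$f_s / params$f_d)
  g <- function(n_b) params$k_on0 * (params$N_m - n_b) - k_off_ss * n_b
  if (g(params$N_m) >= 0) {
    n_b <- params$N_m
  } else {
    n_b <- stats::uniroot(g, c(0, params$N_m), tol = 1e-12)$root
  }
  if (n_b <= 0) return(zero)
  x <- n_b * params$f_s / k_tot
  list(x_ss = x, n_b_ss = n_b, F_pillar_ss = params$k_p * x,
       degenerate = FALSE, collapsed = x >= params$R)
}

#' Peak contraction velocity of a trajectory
#'
#' @param traj a `trajectory` (or any data frame with `t` and `v` columns).
#' @return list with `v_max` (um/s) and `t_at_vmax` (s); ties are broken by
#'   the earliest time.
#' @export
peak_velocity <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) == 0L)
    stop("traj must be a non-empty trajectory", call. = FALSE)
  i <- which.max(traj$v)  # which.max returns the first maximum
  list(v_max = traj$v[i], t_at_vmax = traj$t[i])
}

#' Mechanical power of the pillar ring
#'
#' Instantaneous power delivered to the pillars,
#' \eqn{P(t) = n_{pillars} F_{pillar}(t) v(t)}, converted from pN um/s to
#' SI watts (1 pN um/s = 1e-18 W).
#'
#' @param traj a `trajectory`.
#' @param n_pillars number of pillars in the ring; defaults to the value in
#'   the trajectory's parameter set.
#' @return list with `P_series` (W, one value per sample) and `P_peak` (W).
#' @export
mechanical_power <- function(traj, n_pillars = NULL) {
  stopifnot(is.data.frame(traj), nrow(traj) > 0L)
  if (is.null(n_pillars)) {
    p <- attr(traj, "params")
    n_pillars <- if (is.null(p)) 1 else p$n_pillars
  }
  P <- n_pillars * traj$F_pillar * traj$v * 1e-18
  list(P_series = P, P_peak = max(P))
}

#' Active force of the density-only control variant
#'
#' The control model drops the load dependence of unbinding and lets the
#' contractility scale only with the local actin density, which rises
#' geometrically as the network shrinks toward the ring centre:
#' \eqn{F_A = n_b f_s \rho(x)/\rho_0} with \eqn{\rho(x) = \rho_0 R/(R-x)}.
#'
#' @param params a [model_parameters()] with `mode = "density_only"`.
#' @param x pillar-tip displacement (um), must satisfy `x < R`.
#' @param n_b bound myofilament count.
#' @return Active force (pN).
#' @export
density_only_force <- function(params, x, n_b) {
  stopifnot(inherits(params, "model_parameters"))
  if (params$mode != "density_only")
    stop("density_only_force requires mode = 'density_only'", call. = FALSE)
  .active_force(x, n_b, params)
}

#' Calibrate the active amplitude to a target steady force
#'
#' Rescales the per-filament force `f_s` so that the model's steady-state
#' pillar force at a reference stiffness equals a target value — the
#' single-curve calibration protocol used to anchor both model variants to
#' the same measured force before comparing their stiffness dependence.
#' For the density-only variant the reachable steady forces are bounded
#' (the stable branch ends at `x = R/2`), so the target must lie below
#' `k_p R/2`.
#'
#' @param params a [model_parameters()] object (either mode).
#' @param F_target target steady-state pillar force (pN).
#' @param k_p_ref reference pillar stiffness (pN/um) at which to calibrate.
#' @return A `model_parameters` object with rescaled `f_s`.
#' @export
calibrate_to_force <- function(params, F_target, k_p_ref = params$k_p) {
  stopifnot(inherits(params, "model_parameters"), F_target > 0)
  base <- update_parameters(params, list(k_p = k_p_ref))
  obj <- function(f_s) {
    steady_state(update_parameters(base, list(f_s = f_s)))$F_pillar_ss - F_target
  }
  if (params$mode == "density_only") {
    k_tot <- k_p_ref + params$k_am
    n_b <- params$k_on0 * params$N_m / (params$k_on0 + params$k_off0)
    f_hi <- k_tot * params$R / (4 * n_b) * (1 - 1e-9)  # stable-branch limit
    if (obj(f_hi) < 0)
      stop("F_target exceeds the maximum stably sustainable density-only ",
           "force at k_p_ref (", signif(k_p_ref * params$R / 2, 4), " pN)",
           call. = FALSE)
  } else {
    f_hi <- 1
    while (obj(f_hi) < 0 && f_hi < 1e8) f_hi <- f_hi * 2
  }
  f_s <- stats::uniroot(obj, c(1e-9, f_hi), tol = 1e-10)$root
  update_parameters(params, list(f_s = f_s))
}
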