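#' Specification of a model calibration
#'
#' Declares which contractility-model parameters are free in the fit, their
#' bounds, the fixed values for the rest, the loss, and the multistart
#' budget. The default free set is `gamma_am`, `f_d` and `f_s`, with the
#' kinetic rates and `N_m` held fixed from the literature block: the model
#' is invariant under rescaling `N_m` with `f_s` and `f_d` adjusted
#' accordingly, so only the lumped amplitudes `N_m f_s` and `N_m f_d` are
#' identifiable from a single displacement curve (`f_s` acts as the lumped
#' amplitude per unit pool), and freeing `k_off0` as well leaves the loss
#' surface too sloppy to pin any kinetic parameter at realistic noise.
#'
#' @param free character vector of free parameter names, a subset of
#'   `gamma_am`, `k_am`, `N_m`, `f_s`, `f_d`, `k_on0`, `k_off0`.
#' @param lower,upper named numeric vectors of finite bounds for every free
#'   parameter.
#' @param fixed a [model_parameters()] object providing all non-free
#'   values (and the geometry/ring constants).
#' @param loss `"sse_displacement"` (default) or
#'   `"sse_displacement_plus_velocity"`.
#' @param n_starts number of Latin-hypercube multistart points.
#' @param seed RNG seed for the start design (fits are deterministic given
#'   the seed).
#' @return A `fit_spec`.
#' @export
fit_spec <- function(free = c("gamma_am", "f_d", "f_s"),
                     lower = c(gamma_am = 100, f_d = 1, f_s = 5, k_off0 = 0.05),
                     upper = c(gamma_am = 2e4, f_d = 100, f_s = 200, k_off0 = 10),
                     fixed = model_parameters(),
                     loss = c("sse_displacement", "sse_displacement_plus_velocity"),
                     n_starts = 8, seed = 1) {
  loss <- match.arg(loss)
  allowed <- c("gamma_am", "k_am", "N_m", "f_s", "f_d", "k_on0", "k_off0")
  if (length(free) == 0L || !all(free %in% allowed))
    stop("free must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("lower and upper must name every free parameter", call. = FALSE)
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  stopifnot(inherits(fixed, "model_parameters"))
  structure(list(free = free, lower = lower, upper = upper, fixed = fixed,
                 loss = loss, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "fit_spec")
}

.loss_residuals <- function(theta, spec, observed, k_p, dt_out) {
  p <- update_parameters(spec$fixed, c(as.list(theta), list(k_p = k_p)))
  traj <- try(simulate_contraction(p, t_end = max(observed$t), dt_out = dt_out,
                                   rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(traj, "try-error"))
    return(rep(1e6, nrow(observed) * (1L + (spec$loss != "sse_displacement"))))
  x_mod <- stats::approx(traj$t, traj$x, xout = observed$t, rule = 2)$y
  r <- x_mod - observed$x
  if (spec$loss == "sse_displacement_plus_velocity" && !is.null(observed$v)) {
    v_mod <- stats::approx(traj$t, traj$v, xout = observed$t, rule = 2)$y
    # velocity residuals rescaled to the displacement scale
    sc <- max(abs(observed$x)) / max(max(abs(observed$v)), 1e-12)
    r <- c(r, (v_mod - observed$v) * sc)
  }
  r
}

#' Calibrate the contractility model to one contraction curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) on the free parameters, started from a seeded
#' Latin-hypercube design over the bounds; the best local optimum is
#' returned. This is the "fit once at one stiffness" protocol: all
#' remaining behaviour across stiffnesses is then prediction, see
#' [predict_across_stiffness()].
#'
#' @param observed data frame with columns `t` (s) and `x` (um) spanning
#'   both the acceleration and the deceleration phase (>= 10 samples).
#' @param spec a [fit_spec()].
#' @param k_p pillar stiffness of the observed curve (pN/um), typically
#'   from [pillar_stiffness()].
#' @param include_truth_start optional named vector added to the start
#'   list (e.g. a known truth in self-consistency checks).
#' @return A `fit_result`: list with `params` (best-fit
#'   [model_parameters()]), `estimates` (named free-parameter vector),
#'   `loss`, `se` (approximate standard errors from the local quadratic
#'   expansion; `NA` when the Hessian is ill-conditioned), `convergence`
#'   (TRUE if any start converged), `n_evals`, `at_boundary` (names of
#'   parameters within 0.1% of a bound), and `hessian_condition`.
#' @export
fit_model_to_trajectory <- function(observed, spec, k_p,
                                    include_truth_start = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  if (!is.data.frame(observed) || !all(c("t", "x") %in% names(observed)))
    stop("observed must have columns t and x", call. = FALSE)
  if (nrow(observed) < 10L)
    stop("need >= 10 observed samples", call. = FALSE)

  dt_out <- max(diff(observed$t)[1L], max(observed$t) / 2000)
  k <- length(spec$free)
  starts <- .with_seed(spec$seed, lhs::randomLHS(spec$n_starts, k))
  starts <- sweep(sweep(starts, 2L, spec$upper - spec$lower, "*"),
                  2L, spec$lower, "+")
  colnames(starts) <- spec$free
  if (!is.null(include_truth_start))
    starts <- rbind(starts, include_truth_start[spec$free])

  best <- NULL
  n_evals <- 0L
  converged_any <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = spec$lower, upper = spec$upper,
      fn = .loss_residuals, spec = spec, observed = observed,
      k_p = k_p, dt_out = dt_out,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    n_evals <- n_evals + fit$niter
    ok <- fit$info %in% 1:4
    converged_any <- converged_any || ok
    loss <- sum(fit$fvec^2)
    if (ok && (is.null(best) || loss < best$loss_val)) {
      best <- list(fit = fit, loss_val = loss)
    }
  }
  if (!converged_any || is.null(best))
    stop("non-convergence: no multistart point reached a local optimum",
         call. = FALSE)

  est <- best$fit$par
  J <- best$fit$hessian  # nls.lm stores J'J (Gauss-Newton Hessian)
  cond <- tryCatch(kappa(J, exact = TRUE), error = function(e) Inf)
  dof <- max(length(best$fit$fvec) - k, 1L)
  sigma2 <- best$loss_val / dof
  se <- rep(NA_real_, k); names(se) <- spec$free
  Jinv <- if (is.finite(cond) && cond < 1e8) {
    tryCatch(solve(J), error = function(e) NULL)
  } else NULL
  if (!is.null(Jinv)) {
    se <- sqrt(pmax(diag(Jinv), 0) * sigma2)
    names(se) <- spec$free
  } else {
    warning("loss Hessian condition number ", signif(cond, 3),
            " exceeds 1e8: sloppy parameter directions, standard errors ",
            "not reported", call. = FALSE)
  }
  span <- spec$upper - spec$lower
  at_b <- spec$free[est <= spec$lower + 1e-3 * span |
                    est >= spec$upper - 1e-3 * span]

  params <- update_parameters(spec$fixed, c(as.list(est), list(k_p = k_p)))
  structure(list(params = params, estimates = est, loss = best$loss_val,
                 se = se, convergence = TRUE, n_evals = n_evals,
                 at_boundary = at_b, hessian_condition = cond,
                 spec = spec, k_p = k_p),
            class = "fit_result")
}

#' Predict contraction behaviour across pillar stiffnesses
#'
#' Runs the calibrated model at each stiffness on the grid and tabulates
#' the steady-state pillar force and the peak velocity with its time —
#' the quantities a stiffness sweep of the assay measures.
#'
#' @param fit a `fit_result` (or a bare [model_parameters()] object).
#' @param k_p_grid pillar stiffnesses to evaluate (pN/um).
#' @param t_end,dt_out simulation window passed to
#'   [simulate_contraction()]. The default end time scales with the
#'   slowest relaxation on the grid so the steady state is reached.
#' @return data frame with columns `k_p`, `F_pillar_ss`, `v_max`,
#'   `t_at_vmax`.
#' @export
predict_across_stiffness <- function(fit, k_p_grid, t_end = NULL, dt_out = 1) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "model_parameters"))
  if (inherits(fit, "fit_result") && !isTRUE(fit$convergence))
    stop("fit did not converge", call. = FALSE)
  if (is.null(t_end))
    t_end <- 20 * params$gamma_am / (min(k_p_grid) + params$k_am)
  rows <- lapply(k_p_grid, function(kp) {
    p <- update_parameters(params, list(k_p = kp))
    ss <- steady_state(p)
    traj <- simulate_contraction(p, t_end = t_end, dt_out = dt_out)
    pk <- peak_velocity(traj)
    data.frame(k_p = kp, F_pillar_ss = ss$F_pillar_ss,
               v_max = pk$v_max, t_at_vmax = pk$t_at_vmax)
  })
  do.call(rbind, rows)
}
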