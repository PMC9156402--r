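test_that("parameter validation rejects nonphysical values", {
  expect_error(model_parameters(k_p = 0), "k_p")
  expect_error(model_parameters(gamma_am = -1), "gamma_am")
  expect_error(model_parameters(f_d = 0), "f_d")
  expect_error(model_parameters(n_pillars = 0), "n_pillars")
  expect_error(update_parameters(model_parameters(), list(nope = 1)),
               "unknown parameter")
})

test_that("no motors means no force and no motion", {
  p <- ref_params(N_m = 0)
  traj <- simulate_contraction(p, t_end = 300, dt_out = 10)
  expect_true(all(traj$x == 0))
  expect_true(all(traj$F_pillar == 0))
})

test_that("load-independent, non-detaching limit saturates at the closed form", {
  # f_d -> Inf removes the load dependence; k_off0 = 0 lets every filament
  # stay bound, so n_b -> N_m and x -> N_m f_s / (k_p + k_am).
  p <- ref_params(f_d = 1e12, k_off0 = 0)
  traj <- simulate_contraction(p, t_end = 3000, dt_out = 10)
  x_inf <- p$N_m * p$f_s / (p$k_p + p$k_am)
  expect_lt(abs(tail(traj$x, 1) - x_inf) / x_inf, 1e-6)
  expect_true(all(diff(traj$x) >= -1e-9))
  expect_true(all(diff(traj$n_b) >= -1e-9))
})

test_that("reference contraction shows an acceleration then a deceleration phase", {
  traj <- simulate_contraction(ref_params(k_p = 35), t_end = 900, dt_out = 1)
  i <- which.max(traj$v)
  expect_gt(i, 1)
  expect_lt(i, nrow(traj))
  # velocity rises up to the single interior maximum, then decays
  expect_true(all(diff(traj$v[1:i]) > 0))
  expect_true(all(diff(traj$v[i:nrow(traj)]) < 0))
})

test_that("motor detachment relaxes the pillar on the viscoelastic timescale", {
  p <- ref_params(k_p = 35)
  sched <- parameter_schedule(switch_times = 300,
                              overrides = list(list(k_on0 = 0, f_d = 1e12)))
  # after the switch binding stops and (with load dependence disabled)
  # n_b decays at k_off0 while x relaxes with tau = gamma_am/(k_p + k_am)
  traj <- simulate_contraction(p, sched, t_end = 1200, dt_out = 1)
  x_pre <- traj$x[traj$t == 300]
  expect_lt(tail(traj$x, 1), 0.05 * x_pre)
  # linear relaxation oracle: after detachment the active force decays as
  # n_b(t300) f_s e^{-k_off0 s}; solve the linear ODE in closed form
  tau <- p$gamma_am / (p$k_p + p$k_am)
  nb0 <- traj$n_b[traj$t == 300]
  s <- traj$t[traj$t >= 300] - 300
  a <- 1 / tau; b <- p$k_off0
  x_closed <- x_pre * exp(-a * s) +
    (nb0 * p$f_s / p$gamma_am) * (exp(-b * s) - exp(-a * s)) / (a - b)
  expect_lt(max(abs(traj$x[traj$t >= 300] - x_closed)), 1e-4 * x_pre)
})

test_that("trajectory invariants hold along the solution", {
  p <- ref_params(k_p = 60)
  traj <- simulate_contraction(p, t_end = 600, dt_out = 2)
  expect_true(all(diff(traj$t) > 0))
  expect_equal(traj$F_pillar, p$k_p * traj$x)
  expect_true(all(traj$n_b >= 0 & traj$n_b <= p$N_m))
  # force balance residual: gamma v = F_A - (k_p + k_am) x
  res <- p$gamma_am * traj$v - (traj$F_A - (p$k_p + p$k_am) * traj$x)
  expect_lt(max(abs(res)), 1e-8)
})

test_that("trajectories match an independent RK4 reference integration", {
  for (mode in c("load_dependent", "density_only")) {
    p <- ref_params(k_p = 35, mode = mode)
    traj <- simulate_contraction(p, t_end = 600, dt_out = 10)
    ref <- rk4_reference(p, t_end = 600, dt = 0.05)
    x_ref <- ref$x[match(traj$t, ref$t)]
    expect_lt(max(abs(traj$x - x_ref)) / max(abs(x_ref)), 1e-4)
  }
})

test_that("steady state agrees with long-time integration to 1e-6 relative", {
  p <- ref_params(k_p = 35)
  ss <- steady_state(p)
  t_long <- 200 * p$gamma_am / p$k_p
  traj <- simulate_contraction(p, t_end = t_long, dt_out = t_long / 50,
                               rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(tail(traj$F_pillar, 1) - ss$F_pillar_ss) / ss$F_pillar_ss,
            1e-6)
  expect_lt(abs(tail(traj$n_b, 1) - ss$n_b_ss) / ss$n_b_ss, 1e-6)
})

test_that("with k_am = 0 the pillar bears the whole active force at steady state", {
  p <- ref_params(k_am = 0)
  ss <- steady_state(p)
  expect_equal(ss$F_pillar_ss, ss$n_b_ss * p$f_s, tolerance = 1e-12)
})

test_that("degenerate parameter sets return the flagged zero state", {
  expect_true(steady_state(ref_params(N_m = 0))$degenerate)
  expect_true(steady_state(ref_params(k_on0 = 0))$degenerate)
  expect_equal(steady_state(ref_params(f_s = 0))$F_pillar_ss, 0)
})

test_that("steady-state force is insensitive to stiffness in load-dependent mode", {
  kps <- c(20, 50, 100, 200, 350, 500)
  F <- vapply(kps, function(kp)
    steady_state(ref_params(k_p = kp, k_am = 1))$F_pillar_ss, numeric(1))
  expect_lte(max(F) / min(F), 1.2)
})

test_that("peak velocity reports the first maximum", {
  traj <- data.frame(t = 0:10, v = rep(0.1, 11))
  pk <- peak_velocity(traj)
  expect_equal(pk$v_max, 0.1)
  expect_equal(pk$t_at_vmax, 0)
  expect_error(peak_velocity(data.frame()), "non-empty")
})

test_that("peak velocity is stable under 10x finer output sampling", {
  p <- ref_params(k_p = 35)
  coarse <- simulate_contraction(p, t_end = 600, dt_out = 5)
  fine <- simulate_contraction(p, t_end = 600, dt_out = 0.5)
  pc <- peak_velocity(coarse); pf <- peak_velocity(fine)
  expect_lt(abs(pc$t_at_vmax - pf$t_at_vmax), 5)
  expect_lt(abs(pc$v_max - pf$v_max) / pf$v_max, 0.01)
})

test_that("softer pillars reach higher peak velocities", {
  v <- vapply(c(35, 300), function(kp) {
    traj <- simulate_contraction(ref_params(k_p = kp), t_end = 900, dt_out = 2)
    peak_velocity(traj)$v_max
  }, numeric(1))
  expect_gt(v[1], v[2])
})

test_that("mechanical power follows n_pillars * F * v with pN um/s -> W units", {
  traj <- data.frame(t = 0:4, v = rep(0.05, 5), F_pillar = rep(100, 5))
  pw <- mechanical_power(traj, n_pillars = 10)
  expect_equal(pw$P_peak, 5.0e-17)
  expect_equal(pw$P_series, rep(5.0e-17, 5))
  # at steady state v = 0 so P = 0
  still <- data.frame(t = 0:4, v = rep(0, 5), F_pillar = rep(100, 5))
  expect_equal(mechanical_power(still, 10)$P_peak, 0)
})

test_that("cumulative work dominates the stored elastic energy", {
  p <- ref_params(k_p = 35)
  traj <- simulate_contraction(p, t_end = 900, dt_out = 1)
  work <- cumsum(c(0, diff(traj$t)) * traj$P) / 1e-18  # back to pN um
  elastic <- p$n_pillars * 0.5 * p$k_p * traj$x^2
  expect_true(all(work - elastic >= -1e-6 * max(elastic)))
})

test_that("density-only force law densifies geometrically", {
  p <- ref_params(mode = "density_only")
  expect_equal(density_only_force(p, x = 0, n_b = 3), 3 * p$f_s)
  expect_equal(density_only_force(p, x = p$R / 2, n_b = 3), 2 * 3 * p$f_s)
  expect_error(density_only_force(p, x = p$R, n_b = 3), "diverges")
  expect_error(density_only_force(ref_params(), x = 1, n_b = 3),
               "density_only")
})

test_that("density-only variant mispredicts the stiffness dependence", {
  # both variants anchored to the same measured force at the reference
  # stiffness, then swept: the load-dependent force stays flat while the
  # density-only force varies strongly (soft pillars run away to closure)
  kps <- c(20, 50, 100, 200, 500)
  p_ld <- calibrate_to_force(ref_params(), 126, k_p_ref = 35)
  p_do <- calibrate_to_force(ref_params(mode = "density_only"), 126,
                             k_p_ref = 35)
  F_ld <- vapply(kps, function(kp)
    steady_state(update_parameters(p_ld, list(k_p = kp)))$F_pillar_ss,
    numeric(1))
  F_do <- vapply(kps, function(kp)
    steady_state(update_parameters(p_do, list(k_p = kp)))$F_pillar_ss,
    numeric(1))
  expect_lte(max(F_ld) / min(F_ld), 1.2)
  expect_gt(max(F_do) / min(F_do), max(F_ld) / min(F_ld))
})

test_that("calibration hits the target steady force in both modes", {
  for (mode in c("load_dependent", "density_only")) {
    p <- calibrate_to_force(ref_params(mode = mode), 115, k_p_ref = 35)
    ss <- steady_state(update_parameters(p, list(k_p = 35)))
    expect_equal(ss$F_pillar_ss, 115, tolerance = 1e-6)
  }
  expect_error(calibrate_to_force(ref_params(mode = "density_only"),
                                  5000, k_p_ref = 35), "exceeds")
})

test_that("preloaded motors respond faster than unloaded ones", {
  p <- ref_params(k_p = 35)
  half_time <- function(init) {
    sched <- parameter_schedule(initial_binding = init)
    traj <- simulate_contraction(p, sched, t_end = 900, dt_out = 0.5)
    x_half <- 0.5 * max(traj$x)
    traj$t[which(traj$x >= x_half)[1]]
  }
  expect_lt(half_time("preloaded"), half_time("unloaded"))
})

test_that("schedule switches restart integration exactly and are validated", {
  expect_error(parameter_schedule(switch_times = c(5, 5),
                                  overrides = list(list(), list())),
               "strictly increasing")
  expect_error(parameter_schedule(switch_times = 10, overrides = list()),
               "same length")
  p <- ref_params()
  sched <- parameter_schedule(switch_times = 100,
                              overrides = list(list(k_on0 = 0.2)))
  traj <- simulate_contraction(p, sched, t_end = 200, dt_out = 1)
  expect_equal(traj$t, 0:200)
  expect_error(simulate_contraction(p, parameter_schedule(
    switch_times = 300, overrides = list(list(k_on0 = 0))), t_end = 200),
    "before t_end")
})

test_that("ATP-switch schedule closes and reopens the ring reversibly", {
  # deplete ATP at 400 s (motors detach), restore it at 800 s
  p <- ref_params(k_p = 35)
  sched <- parameter_schedule(
    switch_times = c(400, 800),
    overrides = list(list(k_on0 = 0), list(k_on0 = 0.05)))
  traj <- simulate_contraction(p, sched, t_end = 1600, dt_out = 2)
  x400 <- traj$x[traj$t == 400]
  x800 <- traj$x[traj$t == 800]
  expect_lt(x800, 0.35 * x400)           # relaxed most of the way back
  expect_gt(tail(traj$x, 1), 0.8 * x400) # re-contracted after ATP return
})
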