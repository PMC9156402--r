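# Shared fixtures: the reference parameter set and a small pillar geometry
# whose stiffness matches the soft-pillar assay scale (~35-40 pN/um).

ref_params <- function(...) model_parameters(...)

ref_geom <- function(...) pillar_geometry(L = 15, d = 2, E = 57, ...)

# Independent fixed-step RK4 integrator for the governing equations; kept
# deliberately separate from the deSolve-based implementation so trajectory
# tests have an external oracle.
rk4_reference <- function(params, t_end, dt, n_b0 = NULL) {
  rhs <- function(x, n_b) {
    k_tot <- params$k_p + params$k_am
    F_A <- if (params$mode == "density_only") {
      n_b * params$f_s * params$R / (params$R - x)
    } else {
      n_b * params$f_s
    }
    f <- k_tot * x / max(n_b, 1e-6)
    k_off <- if (params$mode == "load_dependent") {
      params$k_off0 * exp(-f / params$f_d)
    } else params$k_off0
    c((F_A - k_tot * x) / params$gamma_am,
      params$k_on0 * (params$N_m - n_b) - k_off * n_b)
  }
  if (is.null(n_b0))
    n_b0 <- params$k_on0 * params$N_m / (params$k_on0 + params$k_off0)
  n <- ceiling(t_end / dt)
  t <- numeric(n + 1); x <- numeric(n + 1); nb <- numeric(n + 1)
  x[1] <- 0; nb[1] <- n_b0
  for (i in seq_len(n)) {
    y <- c(x[i], nb[i])
    k1 <- rhs(y[1], y[2])
    k2 <- rhs(y[1] + dt / 2 * k1[1], y[2] + dt / 2 * k1[2])
    k3 <- rhs(y[1] + dt / 2 * k2[1], y[2] + dt / 2 * k2[2])
    k4 <- rhs(y[1] + dt * k3[1], y[2] + dt * k3[2])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t[i + 1] <- i * dt; x[i + 1] <- y[1]; nb[i + 1] <- y[2]
  }
  data.frame(t = t, x = x, n_b = nb)
}
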