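# Seeded RNG scope: generators perturb only a local RNG state so that
# callers' random streams are unaffected.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite seed is required for stochastic output", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Measurement-noise description for synthetic trajectories
#'
#' @param sigma Gaussian measurement noise on the tip position x (um).
#' @param interval sampling interval (s).
#' @param duration recording duration (s).
#' @param seed RNG seed (mandatory; the generator is seeded-deterministic).
#' @return A `trajectory_noise_spec`.
#' @export
trajectory_noise_spec <- function(sigma = 0.05, interval = 5, duration = 600,
                                  seed) {
  stopifnot(sigma >= 0, interval > 0, duration > 0)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(sigma = sigma, interval = interval, duration = duration,
                 seed = as.integer(seed)),
            class = "trajectory_noise_spec")
}

#' Generate a noisy contraction trajectory with ground truth
#'
#' Simulates the contractility model, then emulates a measured tip-position
#' time series by adding i.i.d. Gaussian noise to x and recomputing the
#' velocity from the noisy positions by central differences (one-sided at
#' the ends), as one would from tracked image data.
#'
#' @param params a [model_parameters()] object.
#' @param noise a [trajectory_noise_spec()].
#' @param schedule optional [parameter_schedule()].
#' @return list with `observed` (data frame `t`, `x`, `v`), `truth` (the
#'   noise-free `trajectory`) and `seed`.
#' @export
gen_trajectory <- function(params, noise, schedule = parameter_schedule()) {
  stopifnot(inherits(noise, "trajectory_noise_spec"))
  truth <- simulate_contraction(params, schedule = schedule,
                                t_end = noise$duration,
                                dt_out = noise$interval)
  x_obs <- .with_seed(noise$seed,
                      truth$x + stats::rnorm(nrow(truth), 0, noise$sigma))
  n <- length(x_obs)
  v_obs <- numeric(n)
  dt <- noise$interval
  if (n >= 3L) v_obs[2:(n - 1L)] <- (x_obs[3:n] - x_obs[1:(n - 2L)]) / (2 * dt)
  if (n >= 2L) {
    v_obs[1L] <- (x_obs[2L] - x_obs[1L]) / dt
    v_obs[n] <- (x_obs[n] - x_obs[n - 1L]) / dt
  }
  list(observed = data.frame(t = truth$t, x = x_obs, v = v_obs),
       truth = truth,
       seed = noise$seed)
}

#' Generate a fluorescence calibration series with ground truth
#'
#' Emulates a serial-dilution standard: intensities follow the line
#' `slope * C + intercept` plus additive Gaussian noise. The default levels
#' span the 0.001-1 uM dilution range used for labelled myosin standards.
#'
#' @param slope,intercept ground-truth line coefficients (a.u. per uM,
#'   a.u.).
#' @param levels concentration levels (uM), >= 3.
#' @param sigma additive Gaussian noise on each mean intensity (a.u.).
#' @param n_fields imaged fields per level (recorded, not simulated
#'   individually).
#' @param seed RNG seed (mandatory).
#' @return list with `series` (a [calibration_series()]), `truth` (list
#'   with slope and intercept) and `seed`.
#' @export
gen_calibration_series <- function(slope, intercept,
                                   levels = c(0.001, 0.01, 0.1, 1),
                                   sigma = 0, n_fields = 4L, seed) {
  if (length(levels) < 3L) stop("need >= 3 concentration levels", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  ints <- .with_seed(seed,
                     slope * levels + intercept +
                       stats::rnorm(length(levels), 0, sigma))
  list(series = calibration_series(levels, pmax(ints, 0), n_fields),
       truth = list(slope = slope, intercept = intercept, sigma = sigma),
       seed = as.integer(seed))
}

#' Rendering description for a synthetic pillar-ring z-stack
#'
#' @param n_pillars pillars on the ring.
#' @param ring_diameter ring diameter D at the pillar bases (um).
#' @param geom a [pillar_geometry()] shared by all pillars.
#' @param forces per-pillar applied force (pN); recycled to `n_pillars`.
#' @param voxel_size `(dz, dy, dx)` in um; the lateral default matches a
#'   0.099 um confocal pixel, the axial default a typical 0.5 um z-step.
#' @param psf_sigma `(axial, lateral)` Gaussian PSF standard deviations
#'   (um).
#' @param background background intensity level (counts).
#' @param amplitude in-pillar signal amplitude above background (counts).
#' @param noise_model `"mixed"` (Poisson shot noise + Gaussian read noise,
#'   default), `"gaussian"` or `"poisson"`.
#' @param read_sigma Gaussian read-noise SD (counts), used by `"mixed"` and
#'   `"gaussian"`.
#' @param margin lateral margin beyond the ring (um).
#' @param seed RNG seed (mandatory).
#' @return A `render_spec`.
#' @export
render_spec <- function(n_pillars = 10, ring_diameter = 26,
                        geom = pillar_geometry(L = 15, d = 2, E = 57),
                        forces = 126,
                        voxel_size = c(0.5, 0.099, 0.099),
                        psf_sigma = c(0.3, 0.15),
                        background = 20, amplitude = 400,
                        noise_model = c("mixed", "gaussian", "poisson"),
                        read_sigma = 5, margin = 3, seed) {
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(geom, "pillar_geometry"),
            n_pillars >= 1, length(voxel_size) == 3L, all(voxel_size > 0),
            length(psf_sigma) == 2L, all(psf_sigma > 0),
            background >= 0, amplitude > 0, read_sigma >= 0)
  if (ring_diameter <= geom$d * n_pillars / pi)
    stop("pillars overlap on the ring: need D > d * n_pillars / pi",
         call. = FALSE)
  structure(list(n_pillars = as.integer(n_pillars),
                 ring_diameter = ring_diameter, geom = geom,
                 forces = rep_len(forces, n_pillars),
                 voxel_size = voxel_size, psf_sigma = psf_sigma,
                 background = background, amplitude = amplitude,
                 noise_model = noise_model, read_sigma = read_sigma,
                 margin = margin, seed = as.integer(seed)),
            class = "render_spec")
}

# 1D Gaussian convolution along the z axis of a (z, y, x) array, reflecting
# at the boundaries; kernel truncated at 3 sigma.
.axial_blur <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  nz <- dim(arr)[1L]
  out <- array(0, dim = dim(arr))
  for (j in seq_along(k)) {
    shift <- j - half - 1L
    idx <- seq_len(nz) + shift
    idx[idx < 1L] <- 1L - (idx[idx < 1L] - 1L)   # reflect
    idx[idx > nz] <- 2L * nz - idx[idx > nz] + 1L
    out <- out + k[j] * arr[idx, , , drop = FALSE]
  }
  out
}

#' Render before/after pillar-ring z-stacks with ground truth
#'
#' Renders each pillar as a circular cross-section of diameter `d` along a
#' straight centreline (before) or along the Euler-beam deflected
#' centreline under its applied force (after, via [predict_profile()]),
#' with all deflections pointing toward the ring centre. The ideal image is
#' blurred with an anisotropic Gaussian PSF (lateral blur per slice, axial
#' blur along z), scaled to `background + amplitude`, and corrupted with
#' the chosen noise model. Ground-truth centrelines and forces are returned
#' alongside the stacks.
#'
#' @param spec a [render_spec()].
#' @return list with `before`/`after` ([voxel_stack()]s), `truth` (list of
#'   per-pillar data frames `z`, `cx`, `cy` for both states, the forces,
#'   the ring centre and tip deflections) and `seed`.
#' @export
render_pillar_ring <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  g <- spec$geom
  dz <- spec$voxel_size[1L]; dy <- spec$voxel_size[2L]; dx <- spec$voxel_size[3L]
  R_ring <- spec$ring_diameter / 2
  half <- R_ring + g$d / 2 + spec$margin
  centre <- c(half, half)  # (cy, cx): ring centre in physical um

  nz <- floor(g$L / dz) + 1L
  ny <- floor(2 * half / dy) + 1L
  nx <- floor(2 * half / dx) + 1L
  zs <- (seq_len(nz) - 1L) * dz
  ys <- (seq_len(ny) - 1L) * dy
  xs <- (seq_len(nx) - 1L) * dx

  ang <- 2 * pi * (seq_len(spec$n_pillars) - 1L) / spec$n_pillars
  base_cx <- centre[2L] + R_ring * cos(ang)
  base_cy <- centre[1L] + R_ring * sin(ang)
  # minimal gap between adjacent pillar footprints before blurring
  chord <- 2 * R_ring * sin(pi / spec$n_pillars)
  if (chord <= g$d)
    stop("overlapping pillar footprints: chord spacing ", signif(chord, 4),
         " um <= diameter ", g$d, " um", call. = FALSE)

  defl <- lapply(seq_len(spec$n_pillars), function(i)
    predict_profile(g, spec$forces[i], z = zs)$w)

  render_state <- function(deflected) {
    arr <- array(0, dim = c(nz, ny, nx))
    r2 <- (g$d / 2)^2
    for (s in seq_len(nz)) {
      sl <- matrix(0, ny, nx)
      for (i in seq_len(spec$n_pillars)) {
        w <- if (deflected) defl[[i]][s] else 0
        # unit vector from base toward ring centre
        ux <- (centre[2L] - base_cx[i]) / R_ring
        uy <- (centre[1L] - base_cy[i]) / R_ring
        cx <- base_cx[i] + w * ux
        cy <- base_cy[i] + w * uy
        ix <- which(abs(xs - cx) <= g$d / 2 + dx)
        iy <- which(abs(ys - cy) <= g$d / 2 + dy)
        if (length(ix) == 0L || length(iy) == 0L) next
        dd <- outer((ys[iy] - cy)^2, (xs[ix] - cx)^2, "+")
        sl[iy, ix] <- pmax(sl[iy, ix], (dd <= r2) * 1)
      }
      arr[s, , ] <- sl
    }
    # PSF: lateral per-slice Gaussian blur, then axial 1D blur
    sig_lat_px <- spec$psf_sigma[2L] / dx
    for (s in seq_len(nz)) {
      arr[s, , ] <- as.matrix(EBImage::gblur(arr[s, , ], sigma = sig_lat_px))
    }
    arr <- .axial_blur(arr, spec$psf_sigma[1L] / dz)
    spec$background + spec$amplitude * arr
  }

  ideal_before <- render_state(FALSE)
  ideal_after <- render_state(TRUE)

  add_noise <- function(ideal) {
    n <- length(ideal)
    noisy <- switch(spec$noise_model,
      gaussian = ideal + stats::rnorm(n, 0, spec$read_sigma),
      poisson = stats::rpois(n, lambda = pmax(ideal, 0)),
      mixed = stats::rpois(n, lambda = pmax(ideal, 0)) +
        stats::rnorm(n, 0, spec$read_sigma))
    array(pmax(round(noisy), 0), dim = dim(ideal))
  }
  noisy <- .with_seed(spec$seed,
                      list(before = add_noise(ideal_before),
                           after = add_noise(ideal_after)))

  truth <- list(
    ring_centre = c(cx = centre[2L], cy = centre[1L]),
    forces = spec$forces,
    tip_deflection = vapply(defl, function(w) w[length(w)], numeric(1)),
    centerlines_before = lapply(seq_len(spec$n_pillars), function(i)
      data.frame(z = zs, cx = base_cx[i], cy = base_cy[i])),
    centerlines_after = lapply(seq_len(spec$n_pillars), function(i) {
      ux <- (centre[2L] - base_cx[i]) / R_ring
      uy <- (centre[1L] - base_cy[i]) / R_ring
      data.frame(z = zs, cx = base_cx[i] + defl[[i]] * ux,
                 cy = base_cy[i] + defl[[i]] * uy)
    }))

  list(before = voxel_stack(noisy$before, spec$voxel_size),
       after = voxel_stack(noisy$after, spec$voxel_size),
       truth = truth, seed = spec$seed)
}
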