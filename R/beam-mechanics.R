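#' Pillar geometry and material
#'
#' Describes a cylindrical hydrogel micropillar treated as a linear
#' Euler-Bernoulli cantilever: clamped at the substrate, loaded laterally by
#' the actomyosin network at height `attach_height` (default: the tip).
#' Profile data below `foot_cutoff` are excluded from force fits because
#' printed pillars have a stiffer, hardly deflected foot.
#'
#' @param L pillar length (um).
#' @param d cross-section diameter (um, circular).
#' @param E Young's modulus (kPa); 1 kPa = 1000 pN/um^2.
#' @param foot_cutoff height below which profile samples are ignored in
#'   fits (um, default 2).
#' @param attach_height height of network attachment (um, default `L`).
#' @return An object of class `pillar_geometry`.
#' @examples
#' g <- pillar_geometry(L = 15, d = 2, E = 57)
#' pillar_stiffness(g)
#' @export
pillar_geometry <- function(L, d, E, foot_cutoff = 2, attach_height = L) {
  stopifnot(is.numeric(L), is.numeric(d), is.numeric(E))
  if (!(d > 0 && d < L)) stop("need 0 < d < L", call. = FALSE)
  if (E <= 0) stop("E must be > 0", call. = FALSE)
  if (!(foot_cutoff >= 0 && foot_cutoff < attach_height && attach_height <= L))
    stop("need 0 <= foot_cutoff < attach_height <= L", call. = FALSE)
  structure(list(L = L, d = d, E = E, foot_cutoff = foot_cutoff,
                 attach_height = attach_height),
            class = "pillar_geometry")
}

#' Second moment of area of a circular cross-section
#'
#' @param geom a [pillar_geometry()].
#' @return I = pi d^4 / 64 (um^4).
#' @export
second_moment <- function(geom) {
  stopifnot(inherits(geom, "pillar_geometry"))
  pi * geom$d^4 / 64
}

#' Cantilever tip stiffness
#'
#' @param geom a [pillar_geometry()].
#' @return k_p = 3 E I / L^3 in pN/um (E converted from kPa to pN/um^2).
#' @export
pillar_stiffness <- function(geom) {
  stopifnot(inherits(geom, "pillar_geometry"))
  E_pN <- geom$E * 1000  # kPa -> pN/um^2
  3 * E_pN * second_moment(geom) / geom$L^3
}

#' Deflection profile container
#'
#' @param z heights above the substrate (um), strictly increasing, within
#'   `[0, L]` of the geometry they describe.
#' @param w lateral displacement toward the ring centre (um, signed;
#'   positive = toward the centre).
#' @param sigma optional per-sample measurement uncertainty (um).
#' @return A `deflection_profile` data frame.
#' @export
deflection_profile <- function(z, w, sigma = NULL) {
  stopifnot(length(z) == length(w))
  if (any(diff(z) <= 0)) stop("z must be strictly increasing", call. = FALSE)
  if (any(z < 0)) stop("z must be non-negative", call. = FALSE)
  df <- data.frame(z = as.numeric(z), w = as.numeric(w))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(z), all(sigma > 0))
    df$sigma <- as.numeric(sigma)
  }
  class(df) <- c("deflection_profile", "data.frame")
  df
}

# Unit-force deflection shape of a clamped cantilever with a point load at
# height a: the basis function of the one-parameter force fit.
.unit_profile <- function(z, geom) {
  EI <- geom$E * 1000 * second_moment(geom)
  a <- geom$attach_height
  ifelse(z <= a,
         z^2 * (3 * a - z) / (6 * EI),
         a^2 * (3 * z - a) / (6 * EI))
}

#' Predict a cantilever deflection profile under a point load
#'
#' Linear Euler-Bernoulli solution for a clamped cantilever with a lateral
#' point load `F` at `attach_height` a:
#' \deqn{w(z) = F z^2 (3a - z)/(6EI)\ (z \le a),\qquad
#'       w(z) = F a^2 (3z - a)/(6EI)\ (z > a).}
#'
#' @param geom a [pillar_geometry()].
#' @param F applied force (pN); positive = toward the ring centre.
#' @param z heights at which to evaluate (um); default 101 evenly spaced
#'   points spanning `[0, L]`.
#' @return A [deflection_profile()].
#' @export
predict_profile <- function(geom, F, z = seq(0, geom$L, length.out = 101)) {
  stopifnot(inherits(geom, "pillar_geometry"), is.finite(F))
  deflection_profile(z, F * .unit_profile(z, geom))
}

#' Infer the active force from a measured deflection profile
#'
#' One-parameter least-squares fit of the Euler-Bernoulli profile shape to
#' the measured displacements, restricted to heights at or above the foot
#' cutoff. Because the predicted profile is linear in `F`, the solution is
#' closed-form. When an initial (pre-contraction) profile is supplied, a
#' force `F0` is first fitted to it and its predicted shape is subtracted
#' from the measurement, correcting for pillars that were not perfectly
#' straight before myosin activation; `initial_correction = "raw"` subtracts
#' the initial samples directly instead (requires matching heights). If the
#' measured profile carries per-sample uncertainties the fit is weighted by
#' `1/sigma^2`.
#'
#' @param measured a [deflection_profile()] of the contracted pillar.
#' @param geom a [pillar_geometry()].
#' @param initial optional [deflection_profile()] of the pillar before
#'   contraction.
#' @param initial_correction `"fitted"` (default) or `"raw"`.
#' @return list with `F_hat` (pN), `residual_rms` (um), `F_se` (pN,
#'   standard error from the residual scatter), `n_used`, and `F0` (the
#'   fitted initial force, `NA` when no initial profile was given).
#' @examples
#' g <- pillar_geometry(L = 15, d = 2, E = 57)
#' prof <- predict_profile(g, F = 126)
#' fit_force(prof, g)$F_hat
#' @export
fit_force <- function(measured, geom, initial = NULL,
                      initial_correction = c("fitted", "raw")) {
  stopifnot(inherits(geom, "pillar_geometry"))
  initial_correction <- match.arg(initial_correction)
  if (!is.data.frame(measured) || !all(c("z", "w") %in% names(measured)))
    stop("measured must be a deflection_profile with z and w", call. = FALSE)

  keep <- measured$z >= geom$foot_cutoff
  if (sum(keep) < 3L)
    stop("insufficient data: need >= 3 samples at z >= foot_cutoff (",
         geom$foot_cutoff, " um)", call. = FALSE)

  w <- measured$w
  F0 <- NA_real_
  if (!is.null(initial)) {
    if (initial_correction == "fitted") {
      fit0 <- fit_force(initial, geom)
      F0 <- fit0$F_hat
      w <- w - F0 * .unit_profile(measured$z, geom)
    } else {
      if (length(initial$w) != length(w) ||
          max(abs(initial$z - measured$z)) > 1e-9)
        stop("raw initial correction requires matching sample heights",
             call. = FALSE)
      w <- w - initial$w
    }
  }

  z <- measured$z[keep]
  w <- w[keep]
  phi <- .unit_profile(z, geom)
  wt <- if (!is.null(measured$sigma)) 1 / measured$sigma[keep]^2 else rep(1, length(z))
  denom <- sum(wt * phi^2)
  if (denom <= 0) stop("degenerate profile basis (all phi = 0)", call. = FALSE)
  F_hat <- sum(wt * phi * w) / denom
  res <- w - F_hat * phi
  dof <- max(length(z) - 1L, 1L)
  sigma2 <- sum(wt * res^2) / dof
  list(F_hat = F_hat,
       residual_rms = sqrt(mean(res^2)),
       F_se = sqrt(sigma2 / denom),
       n_used = length(z),
       F0 = F0)
}

#' Pillar shear strain
#'
#' @param delta_x tip displacement (um).
#' @param L pillar length (um), > 0.
#' @return delta_x / L (dimensionless).
#' @export
shear_strain <- function(delta_x, L) {
  if (!is.numeric(L) || any(L <= 0)) stop("L must be > 0", call. = FALSE)
  delta_x / L
}
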