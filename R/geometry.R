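## Limb geometry and trunk equations of motion. Each limb is a massless
## telescoping strut between a fixed footfall on the ground and its attachment
## point on the trunk (hip for hindlimbs, shoulder for forelimbs); actuator
## force acts along the strut axis and is reflected instantaneously in the
## ground reaction force.

## Vectorized geometry over n trunk states x K footfalls. All inputs are
## length-n vectors except px (n x K footfall positions) and d, lmax
## (length K). For the point-mass variant the trunk is permanently level:
## theta and omega are treated as identically zero. Dm is the n x K matrix of
## attachment offsets used throughout the hot adjoint path.
.geom <- function(x, y, th, vx, vy, om, px, d, lmax, pointmass = FALSE) {
  if (pointmass) {
    th <- th * 0
    om <- om * 0
  }
  n <- length(x); K <- length(d)
  Dm <- matrix(d, n, K, byrow = TRUE)
  ct <- cos(th); st <- sin(th)
  beta <- (x + Dm * ct) - px  # attachment - foot, horizontal
  gamma <- y + Dm * st        # attachment height (foot at ground)
  l <- pmax(sqrt(beta^2 + gamma^2), 1e-12)  # guard foot/attachment overlap
  ux <- beta / l
  uy <- gamma / l
  adx <- vx - Dm * (om * st)  # attachment velocity
  ady <- vy + Dm * (om * ct)
  ld <- (beta * adx + gamma * ady) / l
  list(beta = beta, gamma = gamma, l = l, ux = ux, uy = uy,
       adx = adx, ady = ady, ld = ld, ct = ct, st = st,
       d = d, Dm = Dm, lmax = lmax, pointmass = pointmass)
}

#' Limb geometry
#'
#' Length, axis direction and length rate of one limb strut, from the trunk
#' state and a footfall. The strut runs from the foot to the attachment point:
#' hips for hindlimbs (\code{LH}, \code{RH}), shoulders for forelimbs
#' (\code{LFt}, \code{LFl}, \code{RF}). For the point-mass variant the
#' attachment points are the fixed hip/shoulder offsets of a permanently level
#' trunk (theta treated as 0).
#'
#' @param state a [trunk_state()].
#' @param body a [body_model()].
#' @param foot a [footfall()].
#' @return list with \code{length}, \code{unit_vector} (pointing from foot to
#'   attachment), \code{length_rate} and \code{attachment} (x, y).
#' @export
limb_geometry <- function(state, body, foot) {
  stopifnot(inherits(state, "trunk_state"), inherits(body, "body_model"),
            inherits(foot, "footfall"))
  off <- .limb_offsets(body)
  i <- match(foot$limb, off$id)
  g <- .geom(state$x, state$y, state$theta, state$vx, state$vy, state$omega,
             px = matrix(foot$x_foot, 1, 5), d = off$d, lmax = off$lmax,
             pointmass = body$variant == "point_mass")
  if (g$gamma[1, i] < -1e-12)
    .stopf("attachment point of %s is below ground", foot$limb)
  if (g$l[1, i] < 1e-10)
    .stopf("degenerate geometry: attachment coincides with foot for %s",
           foot$limb)
  list(length = g$l[1, i],
       unit_vector = c(g$ux[1, i], g$uy[1, i]),
       length_rate = g$ld[1, i],
       attachment = c(g$beta[1, i] + foot$x_foot, g$gamma[1, i]))
}

#' Trunk dynamics
#'
#' Accelerations of the planar trunk under a set of axial limb forces and
#' gravity. Limb forces act along the foot-to-attachment axis and are applied
#' at the attachment point; the moment about the COM drives pitch for the
#' distributed-mass variant. The point-mass variant ignores moments and
#' returns zero pitch acceleration.
#'
#' @param state a [trunk_state()].
#' @param forces nonnegative axial force magnitudes, one per footfall in
#'   \code{feet} (units of body weight internally).
#' @param body a [body_model()].
#' @param feet list of [footfall()] objects matching \code{forces}.
#' @return numeric vector \code{c(ax, ay, alpha)}.
#' @export
trunk_dynamics <- function(state, forces, body, feet) {
  stopifnot(inherits(state, "trunk_state"), inherits(body, "body_model"))
  if (any(forces < 0)) .stopf("limb forces must be nonnegative")
  if (length(forces) != length(feet))
    .stopf("forces and feet must have equal length")
  ax <- 0; ay <- -body$g; al <- 0
  I <- .pitch_inertia(body)
  for (k in seq_along(feet)) {
    lg <- limb_geometry(state, body, feet[[k]])
    f <- forces[k] * lg$unit_vector
    ax <- ax + f[1] / body$mass
    ay <- ay + f[2] / body$mass
    if (body$variant != "point_mass") {
      r <- lg$attachment - c(state$x, state$y)
      al <- al + (r[1] * f[2] - r[2] * f[1]) / I
    }
  }
  c(ax = ax, ay = ay, alpha = al)
}

## Vectorized trunk accelerations from a geometry cache and force matrix
## (n x K). Returns list(ax, ay, al) of length-n vectors.
.accel <- function(gc, Fm, I, m = 1, g = 1) {
  ax <- rowSums(Fm * gc$ux) / m
  ay <- rowSums(Fm * gc$uy) / m - g
  if (gc$pointmass) {
    al <- numeric(length(ax))
  } else {
    ## torque_i = (a - c) x F u = F d (cos(th) uy - sin(th) ux)
    s <- gc$gamma * gc$ct - gc$beta * gc$st
    al <- rowSums(gc$Dm * Fm * s / gc$l) / I
  }
  list(ax = ax, ay = ay, al = al)
}

## Vector-Jacobian product of the accelerations: given adjoint weights w4
## (for ax), w5 (ay), w6 (alpha), each length n, accumulate gradients with
## respect to x, y, theta, F (n x K) and the footfall positions px (n x K).
## Returns list(gx, gy, gth, gF, gpx). Velocities do not enter.
.accel_vjp <- function(gc, Fm, I, w4, w5, w6) {
  l <- gc$l; beta <- gc$beta; gamma <- gc$gamma
  il3 <- 1 / l^3
  dbeta <- Fm * (w4 * gamma^2 - w5 * beta * gamma) * il3
  dgamma <- Fm * (w5 * beta^2 - w4 * beta * gamma) * il3
  gF <- (w4 * beta + w5 * gamma) / l
  gth_exp <- 0
  if (!gc$pointmass && any(w6 != 0)) {
    s <- gamma * gc$ct - beta * gc$st
    w6I <- w6 / I
    Fd <- Fm * gc$Dm
    dbeta <- dbeta + Fd * w6I * (-l^2 * gc$st - s * beta) * il3
    dgamma <- dgamma + Fd * w6I * (l^2 * gc$ct - s * gamma) * il3
    gF <- gF + gc$Dm * (s / l) * w6I
    gth_exp <- rowSums(Fd * (-gamma * gc$st - beta * gc$ct) / l) * w6I
  }
  .chain_bg(gc, dbeta, dgamma, gF = gF, gth_extra = gth_exp)
}

## Chain gradients through beta = x + d cos(th) - px, gamma = y + d sin(th):
## given dbeta, dgamma (n x K) accumulate into trunk-state and footfall
## gradients. gth_extra holds any explicit theta-dependence already summed.
.chain_bg <- function(gc, dbeta, dgamma, gF = NULL, gth_extra = 0,
                      gvx = NULL, gvy = NULL, gom = NULL) {
  gx <- rowSums(dbeta)
  gy <- rowSums(dgamma)
  if (gc$pointmass) {
    gth <- numeric(length(gx))
  } else {
    gth <- rowSums(gc$Dm * (dgamma * gc$ct - dbeta * gc$st)) + gth_extra
  }
  list(gx = gx, gy = gy, gth = gth, gF = gF, gpx = -dbeta,
       gvx = gvx, gvy = gvy, gom = gom)
}
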