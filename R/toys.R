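## Conservative toy systems used as analytic oracles for the energy and
## recovery code: systems with perfect pendular recovery (point pendulum,
## bead on a frictionless wire, parallelogram four-bar vaulting) and systems
## with low recovery because energy passes through rotational kinetic energy
## (physical pendulum, rolling ball, staggered four-bar).

#' Conservative toy system
#'
#' @param kind one of \code{"point_pendulum"}, \code{"physical_pendulum"},
#'   \code{"bead_on_wire"}, \code{"rolling_ball"}, \code{"passive_4bar"}.
#' @param ... parameter overrides. Common: \code{m}, \code{g}. Per kind:
#'   pendula take \code{L} and release angle \code{theta0}; the bead slides on
#'   the parabola y = x^2/2 from \code{x0}; the ball (uniform sphere, radius
#'   \code{r}) rolls without slipping inside a circular valley of radius
#'   \code{R} from angle \code{phi0}; the four-bar has hind/fore leg lengths
#'   \code{l_h}, \code{l_f}, trunk length \code{gad}, COM fraction
#'   \code{com_fraction}, Murphy number \code{murphy}, foot separation
#'   \code{sep} and contact pattern \code{contact} (\code{"walking_trot"}
#'   for the parallelogram geometry, \code{"four_beat"} for staggered feet),
#'   plus initial hind-leg angle \code{phi0} and rate \code{w0}.
#' @return object of class \code{toy_system}.
#' @export
toy_system <- function(kind = c("point_pendulum", "physical_pendulum",
                                "bead_on_wire", "rolling_ball",
                                "passive_4bar"), ...) {
  kind <- match.arg(kind)
  p <- switch(kind,
    point_pendulum = list(m = 1, g = 1, L = 1, theta0 = 0.6),
    physical_pendulum = list(m = 1, g = 1, L = 1, theta0 = 0.6),
    bead_on_wire = list(m = 1, g = 1, x0 = 1),
    rolling_ball = list(m = 1, g = 1, R = 1, r = 0.2, phi0 = 0.5),
    passive_4bar = list(m = 1, g = 1, l_h = 1, l_f = 1, gad = 1,
                        com_fraction = 0.57, murphy = 0.82,
                        contact = "walking_trot", sep = NULL,
                        phi0 = -0.35, w0 = 0.8))
  dots <- list(...)
  p[names(dots)] <- dots
  if (kind == "passive_4bar" && is.null(p$sep))
    p$sep <- if (identical(p$contact, "four_beat")) p$gad + 0.3 else p$gad
  structure(c(list(kind = kind), p), class = "toy_system")
}

## Four-bar closure: hind foot at origin, fore foot at (sep, 0); the hind leg
## angle phi (from vertical, forward positive) is the generalized coordinate.
## Returns hip, shoulder, COM and trunk angle psi.
.fourbar_geometry <- function(phi, p) {
  hip <- c(p$l_h * sin(phi), p$l_h * cos(phi))
  b <- c(p$sep, 0)
  dv <- b - hip
  dd <- sqrt(sum(dv^2))
  along <- (p$gad^2 - p$l_f^2 + dd^2) / (2 * dd)
  perp2 <- p$gad^2 - along^2
  if (perp2 < 0) .stopf("four-bar linkage cannot close at phi = %.3f", phi)
  dhat <- dv / dd
  nhat <- c(-dhat[2], dhat[1])
  s1 <- hip + along * dhat + sqrt(perp2) * nhat
  s2 <- hip + along * dhat - sqrt(perp2) * nhat
  s <- if (s1[2] >= s2[2]) s1 else s2
  com <- hip + p$com_fraction * (s - hip)
  list(hip = hip, shoulder = s, com = com,
       psi = atan2(s[2] - hip[2], s[1] - hip[1]))
}

## Energy coefficients of the one-DOF four-bar: kinetic energy
## 0.5 * A(phi) * phidot^2 and potential V(phi), by central differencing of
## the closure map.
.fourbar_coeffs <- function(phi, p, dphi = 1e-5) {
  gp <- .fourbar_geometry(phi + dphi, p)
  gm <- .fourbar_geometry(phi - dphi, p)
  dc <- (gp$com - gm$com) / (2 * dphi)
  dpsi <- (gp$psi - gm$psi) / (2 * dphi)
  I <- p$murphy * p$m * p$gad^2 / 4
  g0 <- .fourbar_geometry(phi, p)
  list(A = p$m * sum(dc^2) + I * dpsi^2, V = p$m * p$g * g0$com[2],
       dc = dc, dpsi = dpsi, geom = g0)
}

#' Simulate a conservative toy system
#'
#' Forward-integrates the toy system and evaluates the COM energy series and
#' pendular recovery. For oscillating systems released from rest the recovery
#' is computed over whole half-oscillations (between turning points) so that
#' the positive-work accounting closes; for the vaulting four-bar it is
#' computed over the simulated passage.
#'
#' @param system a [toy_system()].
#' @param duration simulated time.
#' @param n number of output samples.
#' @return object of class \code{toy_simulation}: time, COM kinetic/potential
#'   and rotational energy series, total energy, and \code{recovery} (percent).
#' @export
simulate_toy <- function(system, duration = 6, n = 1201) {
  stopifnot(inherits(system, "toy_system"))
  p <- system
  times <- seq(0, duration, length.out = n)
  tolset <- list(rtol = 1e-10, atol = 1e-10)
  out <- switch(p$kind,
    point_pendulum = {
      de <- function(t, y, parms)
        list(c(y[2], -(p$g / p$L) * sin(y[1])))
      s <- deSolve::ode(c(p$theta0, 0), times, de, NULL,
                        rtol = tolset$rtol, atol = tolset$atol)
      th <- s[, 2]; w <- s[, 3]
      list(v = w,
           Ek = 0.5 * p$m * (p$L * w)^2,
           Ep = -p$m * p$g * p$L * cos(th),
           Erot = 0 * w)
    },
    physical_pendulum = {
      ## uniform rod pivoted at one end, COM at L/2
      Ipiv <- p$m * p$L^2 / 3
      de <- function(t, y, parms)
        list(c(y[2], -(p$m * p$g * p$L / 2) * sin(y[1]) / Ipiv))
      s <- deSolve::ode(c(p$theta0, 0), times, de, NULL,
                        rtol = tolset$rtol, atol = tolset$atol)
      th <- s[, 2]; w <- s[, 3]
      list(v = w,
           Ek = 0.5 * p$m * (p$L / 2 * w)^2,
           Ep = -p$m * p$g * (p$L / 2) * cos(th),
           Erot = 0.5 * (p$m * p$L^2 / 12) * w^2)
    },
    bead_on_wire = {
      ## frictionless wire y = x^2 / 2
      de <- function(t, y, parms) {
        x <- y[1]; v <- y[2]
        a <- -(p$g * x + x * v^2) / (1 + x^2)
        list(c(v, a))
      }
      s <- deSolve::ode(c(p$x0, 0), times, de, NULL,
                        rtol = tolset$rtol, atol = tolset$atol)
      x <- s[, 2]; v <- s[, 3]
      list(v = v,
           Ek = 0.5 * p$m * (1 + x^2) * v^2,
           Ep = p$m * p$g * x^2 / 2,
           Erot = 0 * v)
    },
    rolling_ball = {
      ## uniform sphere rolling without slipping inside a circular valley
      Re <- p$R - p$r
      de <- function(t, y, parms)
        list(c(y[2], -(5 / 7) * p$g * sin(y[1]) / Re))
      s <- deSolve::ode(c(p$phi0, 0), times, de, NULL,
                        rtol = tolset$rtol, atol = tolset$atol)
      phi <- s[, 2]; w <- s[, 3]
      v <- Re * w
      list(v = w,
           Ek = 0.5 * p$m * v^2,
           Ep = -p$m * p$g * Re * cos(phi),
           Erot = 0.5 * (2 / 5) * p$m * p$r^2 * (v / p$r)^2)
    },
    passive_4bar = {
      de <- function(t, y, parms) {
        cf <- .fourbar_coeffs(y[1], p)
        dA <- (.fourbar_coeffs(y[1] + 1e-5, p)$A -
                 .fourbar_coeffs(y[1] - 1e-5, p)$A) / 2e-5
        dV <- (.fourbar_coeffs(y[1] + 1e-5, p)$V -
                 .fourbar_coeffs(y[1] - 1e-5, p)$V) / 2e-5
        list(c(y[2], (-dV - 0.5 * dA * y[2]^2) / cf$A))
      }
      s <- deSolve::ode(c(p$phi0, p$w0), times, de, NULL,
                        rtol = 1e-8, atol = 1e-8)
      phi <- s[, 2]; w <- s[, 3]
      I <- p$murphy * p$m * p$gad^2 / 4
      Ek <- Ep <- Erot <- numeric(length(phi))
      for (i in seq_along(phi)) {
        cf <- .fourbar_coeffs(phi[i], p)
        vc <- cf$dc * w[i]
        Ek[i] <- 0.5 * p$m * sum(vc^2)
        Ep[i] <- p$m * p$g * cf$geom$com[2]
        Erot[i] <- 0.5 * I * (cf$dpsi * w[i])^2
      }
      list(v = w, Ek = Ek, Ep = Ep, Erot = Erot)
    })
  Ek <- out$Ek; Ep <- out$Ep; Erot <- out$Erot
  ## segment between turning points for cyclic accounting
  v <- out$v
  sg <- sign(v)
  sg[abs(v) < 1e-10] <- 0
  turns <- which(diff(sg[sg != 0]) != 0)
  idx_nz <- which(sg != 0)
  seg <- seq_along(v)
  if (length(turns) >= 1L && abs(v[1]) < 1e-8) {
    seg <- 1:idx_nz[turns[length(turns)] + 1L]
  }
  recovery <- percent_recovery(Ek[seg], ep = Ep[seg])
  structure(list(time = times, Ek = Ek, Ep = Ep, Erot = Erot,
                 Etot = Ek + Ep + Erot, v = v, segment = seg,
                 recovery = recovery, system = system),
            class = "toy_simulation")
}

#' @export
print.toy_simulation <- function(x, ...) {
  drift <- max(abs(x$Etot - x$Etot[1]))
  cat(sprintf("Toy simulation (%s): recovery %.2f%%, energy drift %.2e\n",
              x$system$kind, x$recovery, drift))
  invisible(x)
}
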