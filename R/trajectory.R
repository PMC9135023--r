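## Trajectory container: time-sampled trunk kinematics, per-footfall axial
## forces and footfall positions, either over the solved half cycle or over a
## full stride obtained by mirroring under gait symmetry.

#' Gait trajectory
#'
#' Time-sampled solution of the trunk and limb forces. Time is normalized to
#' the stride period (t' = t / T); a half-cycle trajectory spans t' in
#' [0, 0.5] and a full-stride one [0, 1]. All quantities are in internal
#' units (mass = g = l_H_max = 1), so forces are body weights and the stride
#' period is in units of sqrt(l_H_max / g).
#'
#' @param tp increasing vector of stride fractions.
#' @param states n x 6 matrix with columns x, y, theta, vx, vy, omega.
#' @param forces n x K matrix of nonnegative axial footfall forces.
#' @param feet data.frame with one row per force column: \code{id},
#'   \code{limb} (LH/RH/LF/RF), \code{x} (footfall position), \code{d}
#'   (signed attachment offset from the COM along the trunk axis) and
#'   \code{lmax}.
#' @param body a [body_model()] in internal units.
#' @param task a [gait_task()].
#' @param half logical; \code{TRUE} for a half-cycle trajectory.
#' @param controls optional n x K matrix of force rates dF/dt'.
#' @param params optional footfall decision parameters (x_LH, x_LFt).
#' @return object of class \code{gait_trajectory}.
#' @export
gait_trajectory <- function(tp, states, forces, feet, body, task,
                            half = TRUE, controls = NULL, params = NULL) {
  states <- as.matrix(states); forces <- as.matrix(forces)
  stopifnot(length(tp) == nrow(states), nrow(states) == nrow(forces),
            ncol(states) == 6L, nrow(feet) == ncol(forces))
  colnames(states) <- c("x", "y", "theta", "vx", "vy", "omega")
  structure(list(tp = tp, states = states, forces = forces, feet = feet,
                 body = body, task = task, half = half,
                 controls = controls, params = params),
            class = "gait_trajectory")
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf("Gait trajectory (%s): %d nodes, %s, stride %.3g, period %.3g\n",
              if (x$half) "half cycle" else "full stride",
              length(x$tp), x$body$variant, x$task$stride, x$task$period))
  invisible(x)
}

## Geometry cache for all footfall columns of a trajectory.
.traj_geom <- function(traj) {
  s <- traj$states
  .geom(s[, "x"], s[, "y"], s[, "theta"], s[, "vx"], s[, "vy"], s[, "omega"],
        px = matrix(traj$feet$x, nrow(s), nrow(traj$feet), byrow = TRUE),
        d = traj$feet$d, lmax = traj$feet$lmax,
        pointmass = traj$body$variant == "point_mass")
}

## Symmetry residual of a half-cycle trajectory: kinematic periodicity
## (y, theta, velocities equal at both ends; x advances by D/2), reference
## limb force conventions and the left/right force hand-off.
.symmetry_residual <- function(traj) {
  stopifnot(traj$half)
  s <- traj$states; f <- traj$forces; n <- nrow(s)
  D <- traj$task$stride
  ids <- traj$feet$id
  c(s[n, c("y", "theta", "vx", "vy", "omega")] -
      s[1L, c("y", "theta", "vx", "vy", "omega")],
    x_advance = s[n, "x"] - s[1L, "x"] - D / 2,
    F_LH_0 = f[1L, ids == "LH"],
    F_RH_half = f[n, ids == "RH"],
    F_LFt_half = f[n, ids == "LFt"],
    F_LFl_0 = f[1L, ids == "LFl"],
    hand_RH = f[1L, ids == "RH"] - f[n, ids == "LH"],
    hand_RF = f[1L, ids == "RF"] - f[n, ids == "LFl"],
    hand_LFt = f[1L, ids == "LFt"] - f[n, ids == "RF"])
}

#' Mirror a half cycle to a full stride
#'
#' Under gait symmetry the right-limb histories equal the left-limb histories
#' delayed by half a stride and translated by D/2. This expands a solved half
#' cycle into a periodic full-stride trajectory; each limb's stance is carried
#' by the appropriate footfall (translated by D/2 for the opposite side, by D
#' across stride boundaries).
#'
#' @param half a half-cycle [gait_trajectory()].
#' @param tol maximum allowed symmetry boundary residual.
#' @return a full-stride \code{gait_trajectory}.
#' @export
mirror_half_cycle <- function(half, tol = 1e-5) {
  stopifnot(inherits(half, "gait_trajectory"))
  if (!half$half) return(half)
  res <- .symmetry_residual(half)
  if (max(abs(res)) > tol)
    .stopf("half cycle violates symmetry boundary conditions (max residual %.3g > %.3g)",
           max(abs(res)), tol)
  n <- nrow(half$states)
  D <- half$task$stride
  tp <- c(half$tp, 0.5 + half$tp[-1L])
  s2 <- half$states[-1L, , drop = FALSE]
  s2[, "x"] <- s2[, "x"] + D / 2
  states <- rbind(half$states, s2)
  f <- half$forces
  ids <- half$feet$id
  gf <- function(id) f[, ids == id]
  z <- numeric(n)
  tail1 <- function(v) v[-1L]
  ## Seven distinct footfalls carry the four limbs over one full stride.
  ## The LH stance continues across the seam as the mirrored RH tail through
  ## the same contact; RH and RF contacts from the previous half stride sit
  ## D/2 behind the corresponding left touchdowns.
  x5 <- stats::setNames(half$feet$x, ids)
  src <- c("LH", "RH", "RH", "LFt", "LFl", "RF", "RF")
  feet <- data.frame(
    id = c("LH", "RH.a", "RH.b", "LF.t", "LF.l", "RF.a", "RF.b"),
    limb = c("LH", "RH", "RH", "LF", "LF", "RF", "RF"),
    x = c(x5["LH"], x5["LH"] - D / 2, x5["LH"] + D / 2, x5["LFt"],
          x5["LFl"], x5["LFt"] + D / 2, x5["LFt"] + 3 * D / 2),
    d = half$feet$d[match(src, ids)],
    lmax = half$feet$lmax[match(src, ids)],
    row.names = NULL)
  col <- function(a, b) c(a, tail1(b))
  forces <- cbind(
    col(gf("LH"), gf("RH")),     # LH stance spans the seam at its own foot
    col(gf("RH"), z),            # RH finishing the previous stance
    col(z, gf("LH")),            # RH touchdown in the second half
    col(gf("LFt"), z),           # trailing fore contact
    col(gf("LFl"), gf("RF")),    # leading fore contact, continued
    col(gf("RF"), gf("LFt")),    # right fore footfall spans the seam
    col(z, gf("LFl")))           # next leading contact of RF
  colnames(forces) <- feet$id
  controls <- NULL
  if (!is.null(half$controls)) {
    u <- half$controls
    gu <- function(id) u[, ids == id]
    controls <- cbind(col(gu("LH"), gu("RH")), col(gu("RH"), z),
                      col(z, gu("LH")), col(gu("LFt"), z),
                      col(gu("LFl"), gu("RF")), col(gu("RF"), gu("LFt")),
                      col(z, gu("LFl")))
    colnames(controls) <- feet$id
  }
  gait_trajectory(tp, states, forces, feet, half$body, half$task,
                  half = FALSE, controls = controls, params = half$params)
}

## Coerce to a full-stride trajectory for metric evaluation.
.as_full <- function(traj, tol = 1e-4) {
  if (traj$half) mirror_half_cycle(traj, tol = tol) else traj
}
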