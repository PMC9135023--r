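## Body model, task definition and nondimensionalization for the planar
## quadruped: a rigid trunk (or point mass) carried on four massless
## telescoping limb actuators, hindlimbs at the hips and forelimbs at the
## shoulders.

#' Planar quadruped body model
#'
#' Constructs the geometric and inertial description of the model: a single
#' rigid trunk with massless prismatic (telescoping) legs. Hindlimbs attach at
#' the hips, forelimbs at the shoulders, separated by the glenoacetabular
#' distance (GAD). Pitch inertia is parameterized by the dimensionless Murphy
#' number, 4 I / (m GAD^2).
#'
#' Internally the package works in units where \code{mass = g = l_H_max = 1},
#' so forces are in body weights, lengths in hindlimb lengths and works in
#' m g l_H. Use [nondimensionalize()] to convert an SI description.
#'
#' @param mass trunk mass (kg in SI, 1 internally).
#' @param g gravitational acceleration (9.81 m s^-2 in SI, 1 internally).
#' @param l_H_max maximum hindlimb length, hip to pes in standing (reference
#'   length).
#' @param l_F_max maximum forelimb length (same units as \code{l_H_max}).
#' @param gad glenoacetabular distance, hips to shoulders.
#' @param com_fraction centre-of-mass position along the hip-to-shoulder axis
#'   as a fraction of \code{gad}, measured from the hips.
#' @param murphy Murphy number, 4 I / (m gad^2); ignored for the point-mass
#'   variant.
#' @param variant \code{"distributed_mass"} (trunk with pitch inertia) or
#'   \code{"point_mass"} (no rotational state; the trunk stays level and limb
#'   forces produce no moments, but limb length constraints are kept).
#' @return an object of class \code{body_model}.
#' @seealso [horse_preset()], [murphy_number()], [trunk_dynamics()]
#' @export
body_model <- function(mass = 1, g = 1, l_H_max = 1, l_F_max = 1, gad = 1,
                       com_fraction = 0.57, murphy = 0.82,
                       variant = c("distributed_mass", "point_mass")) {
  variant <- match.arg(variant)
  if (!all(c(mass, g, l_H_max, l_F_max, gad) > 0))
    .stopf("mass, g and all lengths must be strictly positive")
  if (com_fraction < 0 || com_fraction > 1)
    .stopf("com_fraction must lie in [0, 1]")
  if (murphy < 0) .stopf("murphy must be nonnegative")
  structure(list(mass = mass, g = g, l_H_max = l_H_max, l_F_max = l_F_max,
                 gad = gad, com_fraction = com_fraction, murphy = murphy,
                 variant = variant),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat("Planar quadruped body model (", x$variant, ")\n", sep = "")
  cat(sprintf("  mass %.4g, g %.4g, l_H_max %.4g, l_F_max %.4g\n",
              x$mass, x$g, x$l_H_max, x$l_F_max))
  cat(sprintf("  GAD %.4g, COM at %.2f GAD from hips, Murphy number %.3g\n",
              x$gad, x$com_fraction, x$murphy))
  invisible(x)
}

#' Murphy number
#'
#' Dimensionless pitch inertia, 4 I / (m gad^2). A value below one means a
#' vertical contact impulse at one end of the trunk pitches the other end
#' downward.
#'
#' @param I pitch moment of inertia about the COM.
#' @param m body mass.
#' @param gad glenoacetabular distance.
#' @return the dimensionless Murphy number.
#' @export
murphy_number <- function(I, m, gad) {
  if (!all(c(I, m, gad) > 0)) .stopf("murphy_number: arguments must be positive")
  4 * I / (m * gad^2)
}

## Pitch moment of inertia implied by the Murphy number (internal units).
.pitch_inertia <- function(body) body$murphy * body$mass * body$gad^2 / 4

#' Gait task
#'
#' A single optimization problem: nondimensional forward speed and stride
#' length. The stride period is derived, T' = D'/U', and is not a free
#' parameter. Speed is normalized by sqrt(g l_H_max) and stride length by
#' l_H_max.
#'
#' @param speed nondimensional average forward speed U'.
#' @param stride nondimensional stride length D'.
#' @return an object of class \code{gait_task} with fields \code{speed},
#'   \code{stride} and \code{period} (in units of sqrt(l_H_max / g)).
#' @export
gait_task <- function(speed, stride) {
  if (speed <= 0 || stride <= 0) .stopf("speed and stride must be positive")
  structure(list(speed = speed, stride = stride, period = stride / speed),
            class = "gait_task")
}

#' @export
print.gait_task <- function(x, ...) {
  cat(sprintf("Gait task: U' = %.4g, D' = %.4g, T' = %.4g\n",
              x$speed, x$stride, x$period))
  invisible(x)
}

#' Nondimensionalize an SI body model and task
#'
#' Maps an SI description to internal units with mass = g = l_H_max = 1.
#' Speed maps to U' = U / sqrt(g l_H_max) and stride length to D' = D /
#' l_H_max; all work metrics are then natively in units of m g l_H.
#'
#' @param body_SI a [body_model()] in SI units.
#' @param speed_SI average forward speed (m s^-1).
#' @param stride_SI stride length (m).
#' @return list with elements \code{body} (internal units) and \code{task}.
#' @examples
#' horse <- body_model(mass = 500, g = 9.81, l_H_max = 1.38, l_F_max = 1.38,
#'                     gad = 1.38, com_fraction = 0.57, murphy = 0.82)
#' nondimensionalize(horse, speed_SI = 1.6, stride_SI = 1.856)$task
#' @export
nondimensionalize <- function(body_SI, speed_SI, stride_SI) {
  stopifnot(inherits(body_SI, "body_model"))
  if (speed_SI < 0 || stride_SI <= 0)
    .stopf("speed must be nonnegative and stride positive")
  l <- body_SI$l_H_max
  body <- body_model(mass = 1, g = 1, l_H_max = 1,
                     l_F_max = body_SI$l_F_max / l,
                     gad = body_SI$gad / l,
                     com_fraction = body_SI$com_fraction,
                     murphy = body_SI$murphy,
                     variant = body_SI$variant)
  u_prime <- speed_SI / sqrt(body_SI$g * l)
  d_prime <- stride_SI / l
  if (u_prime == 0)
    return(list(body = body, task = structure(
      list(speed = 0, stride = d_prime, period = Inf), class = "gait_task")))
  list(body = body, task = gait_task(speed = u_prime, stride = d_prime))
}

#' Trunk state
#'
#' Planar trunk kinematics: COM position (x forward, y up), pitch angle theta
#' (radians, counterclockwise positive, 0 = hip-shoulder axis horizontal) and
#' their time derivatives.
#'
#' @param x,y COM position. @param theta pitch angle.
#' @param vx,vy,omega time derivatives of x, y, theta.
#' @return object of class \code{trunk_state}.
#' @export
trunk_state <- function(x = 0, y = 1, theta = 0, vx = 0, vy = 0, omega = 0) {
  if (abs(theta) > pi / 2) .stopf("pitch must lie within [-pi/2, pi/2]")
  structure(list(x = x, y = y, theta = theta, vx = vx, vy = vy, omega = omega),
            class = "trunk_state")
}

#' Footfall
#'
#' A ground contact for one limb: feet are fixed in place while producing
#' force. The left forelimb acts through a trailing (\code{LFt}) and a leading
#' (\code{LFl}) footfall separated by one stride length.
#'
#' @param limb one of \code{"LH"}, \code{"RH"}, \code{"LFt"}, \code{"LFl"},
#'   \code{"RF"}.
#' @param x_foot horizontal position of the contact point (ground height 0).
#' @return object of class \code{footfall}.
#' @export
footfall <- function(limb = c("LH", "RH", "LFt", "LFl", "RF"), x_foot = 0) {
  limb <- match.arg(limb)
  structure(list(limb = limb, x_foot = x_foot), class = "footfall")
}

## Signed offset (along the trunk axis, from the COM) and maximum length of
## the attachment for each footfall id.
.limb_offsets <- function(body) {
  d_hip <- -body$com_fraction * body$gad
  d_sh <- (1 - body$com_fraction) * body$gad
  list(
    id = c("LH", "RH", "LFt", "LFl", "RF"),
    limb = c("LH", "RH", "LF", "LF", "RF"),
    d = c(d_hip, d_hip, d_sh, d_sh, d_sh),
    lmax = c(body$l_H_max, body$l_H_max, body$l_F_max, body$l_F_max,
             body$l_F_max)
  )
}

## Footfall x positions of the five half-cycle footfalls from the two free
## parameters q = (x_LH, x_LFt). Right-limb footfalls are the left ones
## translated by D/2 under gait symmetry; within the half-cycle window the
## right limbs are always finishing a stance begun half a stride earlier, so
## their contacts sit half a stride BEHIND the corresponding left touchdown
## (x_RH = x_LH - D/2; x_RF = x_LFl - D/2 = x_LFt + D/2). The leading
## left-fore contact is a full stride ahead of the trailing one.
.footfall_x <- function(q, task) {
  D <- task$stride
  c(LH = q[1L], RH = q[1L] - D / 2, LFt = q[2L], LFl = q[2L] + D,
    RF = q[2L] + D / 2)
}
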