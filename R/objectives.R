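## Work metrics and auxiliary costs. Exact (quadrature) evaluation for
## reporting lives here; the smoothed slack-variable form used inside the
## nonlinear program is described by smooth_objective() and realized by the
## transcription module.
##
## All works are per full stride in units of m g l_H. Positive-part integrals
## use the trapezoidal rule on the trajectory grid; physical time is the
## stride fraction times the stride period.

## Per-footfall power series on a full-stride trajectory.
## com: F_i u_i . V_COM; ext: F_i * ldot_i (axial actuator power).
.powers <- function(traj) {
  gc <- .traj_geom(traj)
  s <- traj$states
  Fm <- traj$forces
  p_com <- Fm * (gc$ux * s[, "vx"] + gc$uy * s[, "vy"])
  p_ext <- Fm * gc$ld
  I <- .pitch_inertia(traj$body)
  acc <- .accel(gc, Fm, I)
  ek_dot <- s[, "vx"] * acc$ax + s[, "vy"] * acc$ay
  ep_dot <- s[, "vy"]
  erot_dot <- if (traj$body$variant == "point_mass") 0 * ep_dot else
    I * s[, "omega"] * acc$al
  list(gc = gc, p_com = p_com, p_ext = p_ext,
       ek_dot = ek_dot, ep_dot = ep_dot, erot_dot = erot_dot,
       t_phys = traj$tp * traj$task$period)
}

.check_periodic <- function(traj) {
  s <- traj$states; n <- nrow(s)
  res <- max(abs(s[n, c("y", "theta", "vx", "vy", "omega")] -
                   s[1L, c("y", "theta", "vx", "vy", "omega")]))
  if (res > 1e-3)
    warning(sprintf(
      "trajectory is not periodic (kinematic end mismatch %.3g); stride-normalized works are ambiguous",
      res), call. = FALSE)
  invisible(res)
}

#' Net COM Work
#'
#' Positive-part integral over one stride of the net ground reaction force
#' dotted with the COM velocity, equivalently of the rate of COM kinetic plus
#' gravitational potential energy.
#'
#' @param traj a [gait_trajectory()]; a half cycle is mirrored to a full
#'   stride first.
#' @return work in m g l_H per stride.
#' @export
ncw <- function(traj) {
  traj <- .as_full(traj); .check_periodic(traj)
  pw <- .powers(traj)
  .pos_work(pw$t_phys, rowSums(pw$p_com))
}

#' Individual Limbs COM Work
#'
#' Sum over footfalls of the positive-part integral of each limb force dotted
#' with the COM velocity. Captures simultaneous positive and negative work
#' that cancels in [ncw()].
#'
#' @inheritParams ncw
#' @return work in m g l_H per stride.
#' @export
ilcw <- function(traj) {
  traj <- .as_full(traj); .check_periodic(traj)
  pw <- .powers(traj)
  sum(apply(pw$p_com, 2L, function(p) .pos_work(pw$t_phys, p)))
}

#' Limb Extension Work
#'
#' Sum over footfalls of the positive-part integral of axial leg force times
#' leg length rate: the positive work of extending and contracting each limb
#' strut, which also accounts for the work of body pitching.
#'
#' @inheritParams ncw
#' @return work in m g l_H per stride.
#' @export
lew <- function(traj) {
  traj <- .as_full(traj); .check_periodic(traj)
  pw <- .powers(traj)
  sum(apply(pw$p_ext, 2L, function(p) .pos_work(pw$t_phys, p)))
}

#' Net System Work
#'
#' Positive-part integral of the rate of total mechanical energy:
#' gravitational potential plus translational plus rotational kinetic energy.
#' For the point-mass variant this equals [ncw()] identically.
#'
#' @inheritParams ncw
#' @return work in m g l_H per stride.
#' @export
nsw <- function(traj) {
  traj <- .as_full(traj); .check_periodic(traj)
  pw <- .powers(traj)
  .pos_work(pw$t_phys, pw$ek_dot + pw$ep_dot + pw$erot_dot)
}

#' Pendular (Cavagna) percent recovery
#'
#' Fraction of COM kinetic and gravitational potential energy fluctuation
#' recovered by out-of-phase exchange rather than by muscular work:
#' 100 (W+_Ek + W+_Ep - W+_{Ek+Ep}) / (W+_Ek + W+_Ep), where W+ is the
#' positive-part integral of the named energy rate over one stride. Computed
#' from COM energies only (no rotational term).
#'
#' @param traj a [gait_trajectory()], or a numeric vector of COM kinetic
#'   energies (with \code{ep} and \code{time} supplied).
#' @param ep,time COM gravitational potential energy series and time grid,
#'   used when \code{traj} is a plain kinetic-energy series.
#' @return percentage in [0, 100]; \code{NA} when the COM energies do not
#'   fluctuate.
#' @export
percent_recovery <- function(traj, ep = NULL, time = NULL) {
  if (inherits(traj, "gait_trajectory")) {
    traj <- .as_full(traj)
    pw <- .powers(traj)
    w_ek <- .pos_work(pw$t_phys, pw$ek_dot)
    w_ep <- .pos_work(pw$t_phys, pw$ep_dot)
    w_sum <- .pos_work(pw$t_phys, pw$ek_dot + pw$ep_dot)
  } else {
    ek <- traj
    stopifnot(!is.null(ep), length(ek) == length(ep))
    ## rates by first differences of the sampled energy series
    w_ek <- sum(.pos(diff(ek)))
    w_ep <- sum(.pos(diff(ep)))
    w_sum <- sum(.pos(diff(ek + ep)))
  }
  den <- w_ek + w_ep
  if (den <= .Machine$double.eps) return(NA_real_)
  ## clamp tiny quadrature overshoots outside [0, 100]
  min(100, max(0, 100 * (den - w_sum) / den))
}

#' Force-rate penalty
#'
#' Regularization term c1 * sum_i integral of (dF_i/dt')^2 over one stride,
#' with forces in body weights and time normalized to the stride period
#' (t' = t / T). It penalizes rapid force development and avoids the
#' non-smooth force profiles typical of work-minimizing solutions.
#'
#' @inheritParams ncw
#' @param c1 penalty coefficient (default 3e-5).
#' @return dimensionless penalty value.
#' @export
force_rate_penalty <- function(traj, c1 = 3e-5) {
  if (c1 == 0) return(0)
  traj <- .as_full(traj)
  rates <- traj$controls
  if (is.null(rates)) {
    ## central-difference force rates with respect to stride fraction
    rates <- apply(traj$forces, 2L, function(f) {
      n <- length(f)
      d <- numeric(n)
      d[1L] <- (f[2L] - f[1L]) / (traj$tp[2L] - traj$tp[1L])
      d[n] <- (f[n] - f[n - 1L]) / (traj$tp[n] - traj$tp[n - 1L])
      d[2:(n - 1L)] <- (f[3:n] - f[1:(n - 2L)]) / (traj$tp[3:n] - traj$tp[1:(n - 2L)])
      d
    })
  }
  c1 * sum(apply(rates^2, 2L, function(r2) .trapz(traj$tp, r2)))
}

#' Work breakdown of a trajectory
#'
#' Evaluates all four work metrics, pendular recovery, the force-rate penalty
#' and per-limb positive/negative work decompositions on one trajectory.
#'
#' @inheritParams force_rate_penalty
#' @return object of class \code{work_breakdown}.
#' @export
work_breakdown <- function(traj, c1 = 3e-5) {
  full <- .as_full(traj)
  pw <- .powers(full)
  per_foot <- function(P) {
    pos <- apply(P, 2L, function(p) .pos_work(pw$t_phys, p))
    neg <- apply(-P, 2L, function(p) .pos_work(pw$t_phys, p))
    limb <- full$feet$limb
    list(positive = tapply(pos, limb, sum), negative = tapply(neg, limb, sum))
  }
  out <- list(
    ncw = .pos_work(pw$t_phys, rowSums(pw$p_com)),
    nsw = .pos_work(pw$t_phys, pw$ek_dot + pw$ep_dot + pw$erot_dot),
    ilcw = sum(apply(pw$p_com, 2L, function(p) .pos_work(pw$t_phys, p))),
    lew = sum(apply(pw$p_ext, 2L, function(p) .pos_work(pw$t_phys, p))),
    percent_recovery = percent_recovery(full),
    force_rate_penalty = force_rate_penalty(full, c1),
    per_limb_com = per_foot(pw$p_com),
    per_limb_ext = per_foot(pw$p_ext))
  class(out) <- "work_breakdown"
  out
}

#' @export
print.work_breakdown <- function(x, ...) {
  cat("Work breakdown (m g l_H per stride)\n")
  cat(sprintf("  NCW  %.4f   NSW %.4f\n  ILCW %.4f   LEW %.4f\n",
              x$ncw, x$nsw, x$ilcw, x$lew))
  cat(sprintf("  Percent recovery %.1f%%   force-rate penalty %.3g\n",
              x$percent_recovery, x$force_rate_penalty))
  invisible(x)
}

#' Smoothed work objective for the nonlinear program
#'
#' Describes the slack-variable transform of the positive-part work integrand
#' used inside the transcription: each (per-limb or net) power term p is split
#' as p = s_plus - s_minus with s_plus, s_minus >= 0, the integrand is linear
#' in s_plus, and the complementarity s_plus * s_minus = 0 is driven to zero
#' by the relaxation penalty schedule, so the exact metric is recovered from
#' the solution to relaxation tolerance.
#'
#' @param metric one of \code{"ncw"}, \code{"ilcw"}, \code{"lew"}.
#' @param slack_scheme relaxation scheme; only \code{"penalty"} (linear
#'   penalty on the slack products, weight on the relaxation schedule) is
#'   implemented.
#' @return list describing the slack layout: number of slack pairs per node,
#'   the power terms they split and the integrand weight.
#' @export
smooth_objective <- function(metric = c("ncw", "ilcw", "lew"),
                             slack_scheme = "penalty") {
  metric <- match.arg(metric)
  if (!identical(slack_scheme, "penalty"))
    .stopf("unknown slack scheme: %s", slack_scheme)
  list(metric = metric,
       n_slack_pairs = if (metric == "ncw") 1L else 5L,
       power = switch(metric,
                      ncw = "net COM power, sum_i F_i u_i . V_COM",
                      ilcw = "per-footfall COM power, F_i u_i . V_COM",
                      lew = "per-footfall extension power, F_i ldot_i"),
       integrand = "2 T' * sum(s_plus) per unit stride fraction",
       complementarity = "s_plus * s_minus = 0 via relaxation penalty")
}
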