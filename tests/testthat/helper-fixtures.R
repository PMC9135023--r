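## Shared fixtures: small bodies/tasks, synthetic trajectories and numerical
## oracles used across the test files.

fd_gradient <- function(f, z, h = 1e-6) {
  vapply(seq_along(z), function(i) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + h
    zm[i] <- zm[i] - h
    (f(zp) - f(zm)) / (2 * h)
  }, numeric(1))
}

internal_horse <- function(variant = "distributed_mass")
  horse_preset(variant)

## A full-stride synthetic trajectory with smooth periodic kinematics and
## nonnegative bump forces through four footfalls (one per limb). Not
## dynamics-consistent; used for metric property tests.
random_full_trajectory <- function(seed, variant = "distributed_mass",
                                   n = 81) {
  set.seed(seed)
  hp <- horse_preset(variant)
  body <- hp$body; task <- hp$task
  tp <- seq(0, 1, length.out = n)
  four <- function(amp) {
    ph <- stats::runif(3, 0, 2 * pi)
    amp[1] * sin(2 * pi * tp + ph[1]) + amp[2] * sin(4 * pi * tp + ph[2]) +
      amp[3] * sin(6 * pi * tp + ph[3])
  }
  y <- 0.9 + four(c(0.03, 0.015, 0.005))
  th <- if (variant == "point_mass") numeric(n) else four(c(0.05, 0.02, 0.01))
  vx <- task$speed + four(c(0.05, 0.02, 0.01))
  vy <- four(c(0.08, 0.04, 0.01))
  om <- if (variant == "point_mass") numeric(n) else four(c(0.2, 0.1, 0.02))
  x <- task$stride * tp
  states <- cbind(x, y, th, vx, vy, om)
  bump <- function(td, duty) {
    u <- (tp - td) %% 1
    ifelse(u < duty, sin(pi * u / duty)^2, 0)
  }
  off <- quadgait:::.limb_offsets(body)
  feet <- data.frame(id = c("LH", "RH", "LF", "RF"),
                     limb = c("LH", "RH", "LF", "RF"),
                     x = stats::runif(4, 0, task$stride),
                     d = off$d[c(1, 2, 3, 5)],
                     lmax = off$lmax[c(1, 2, 3, 5)])
  forces <- sapply(1:4, function(k)
    stats::runif(1, 0.2, 1.2) * bump(stats::runif(1), stats::runif(1, 0.3, 0.9)))
  gait_trajectory(tp, states, forces, feet, body, task, half = FALSE)
}

## Forward-integrate the trunk under smooth prescribed footfall forces with a
## classical RK4 scheme: a dynamics-consistent (but non-periodic) trajectory
## for work-energy checks.
rk4_trajectory <- function(seed, variant = "distributed_mass", n = 601,
                           t_end = 1.5) {
  set.seed(seed)
  hp <- horse_preset(variant)
  body <- hp$body; task <- hp$task
  off <- quadgait:::.limb_offsets(body)
  feet <- data.frame(id = off$id, limb = off$limb,
                     x = c(-0.2, 0.5, 0.4, 1.0, 0.8) +
                       stats::runif(5, -0.1, 0.1),
                     d = off$d, lmax = off$lmax)
  ph <- stats::runif(5, 0, 2 * pi)
  amp <- stats::runif(5, 0.1, 0.5)
  ffun <- function(t) amp * (1 + sin(2 * pi * t / t_end + ph)) / 2
  I <- quadgait:::.pitch_inertia(body)
  pm <- variant == "point_mass"
  deriv <- function(t, s) {
    gc <- quadgait:::.geom(s[1], s[2], s[3], s[4], s[5], s[6],
                           px = matrix(feet$x, 1, 5), d = off$d,
                           lmax = off$lmax, pointmass = pm)
    acc <- quadgait:::.accel(gc, matrix(ffun(t), 1, 5), I)
    c(s[4], s[5], if (pm) 0 else s[6], acc$ax, acc$ay, if (pm) 0 else acc$al)
  }
  ts <- seq(0, t_end, length.out = n)
  hstep <- ts[2] - ts[1]
  S <- matrix(0, n, 6)
  S[1, ] <- c(0, 0.9, 0, task$speed, 0, 0)
  for (i in 1:(n - 1)) {
    s <- S[i, ]; t <- ts[i]
    k1 <- deriv(t, s)
    k2 <- deriv(t + hstep / 2, s + hstep / 2 * k1)
    k3 <- deriv(t + hstep / 2, s + hstep / 2 * k2)
    k4 <- deriv(t + hstep, s + hstep * k3)
    S[i + 1, ] <- s + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  forces <- t(vapply(ts, ffun, numeric(5)))
  Tper <- t_end  # map physical time to one "stride" for bookkeeping
  task2 <- structure(list(speed = task$stride / t_end, stride = task$stride,
                          period = t_end), class = "gait_task")
  gait_trajectory(ts / t_end, S, forces, feet, body, task2, half = FALSE)
}

## Total mechanical energy series of a trajectory (internal units).
energy_series <- function(traj) {
  s <- traj$states
  I <- quadgait:::.pitch_inertia(traj$body)
  Ek <- 0.5 * (s[, "vx"]^2 + s[, "vy"]^2)
  Ep <- s[, "y"]
  Erot <- 0.5 * I * s[, "omega"]^2
  list(Ek = Ek, Ep = Ep, Erot = Erot, Etot = Ek + Ep + Erot)
}
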