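test_that("limb geometry matches trivial strut configurations", {
  hp <- internal_horse()
  body <- hp$body
  off <- quadgait:::.limb_offsets(body)
  ## vertical strut: trunk level at height 1, foot directly below the hip
  st <- trunk_state(x = 0, y = 1, theta = 0)
  lg <- limb_geometry(st, body, footfall("LH", x_foot = off$d[1]))
  expect_equal(lg$length, 1, tolerance = 1e-12)
  expect_equal(lg$unit_vector, c(0, 1), tolerance = 1e-12)
  ## horizontal motion perpendicular to a vertical strut: zero length rate
  st2 <- trunk_state(x = 0, y = 1, theta = 0, vx = 0.7)
  lg2 <- limb_geometry(st2, body, footfall("LH", x_foot = off$d[1]))
  expect_equal(lg2$length_rate, 0, tolerance = 1e-12)
  ## degenerate geometry is refused
  st3 <- trunk_state(x = 0, y = 0, theta = 0)
  expect_error(limb_geometry(st3, body, footfall("LH", x_foot = off$d[1])),
               "degenerate|below ground")
})

test_that("limb length and rate agree with symbolic differentiation", {
  hp <- internal_horse()
  body <- hp$body
  off <- quadgait:::.limb_offsets(body)
  dL <- off$d[3]  # shoulder attachment (forelimb)
  ## symbolic oracle: R's deriv() on the closed-form distance
  len_expr <- deriv(~ sqrt((x + d * cos(th) - px)^2 + (y + d * sin(th))^2),
                    c("x", "y", "th"))
  st <- trunk_state(x = 0.3, y = 0.92, theta = 0.1,
                    vx = 0.5, vy = -0.2, omega = 0.4)
  px <- 0.8
  x <- st$x; y <- st$y; th <- st$theta; d <- dL
  ev <- eval(len_expr)
  g <- attr(ev, "gradient")
  rate_sym <- g[1, "x"] * st$vx + g[1, "y"] * st$vy + g[1, "th"] * st$omega
  lg <- limb_geometry(st, body, footfall("LFt", x_foot = px))
  expect_equal(lg$length, as.numeric(ev), tolerance = 1e-10)
  expect_equal(lg$length_rate, as.numeric(rate_sym), tolerance = 1e-10)
})

test_that("trunk dynamics reproduces ballistic flight and static equilibrium", {
  hp <- internal_horse()
  body <- hp$body
  st <- trunk_state(x = 0, y = 1, theta = 0.2, vx = 0.3, omega = 0.1)
  acc <- trunk_dynamics(st, forces = numeric(0), body, feet = list())
  expect_equal(unname(acc), c(0, -1, 0), tolerance = 1e-12)
  ## hind attachment at the COM (com_fraction 0): a vertical leg through the
  ## COM loaded with body weight is in static equilibrium
  b0 <- body_model(com_fraction = 0, murphy = 0.82)
  st0 <- trunk_state(x = 0, y = 0.9, theta = 0)
  acc0 <- trunk_dynamics(st0, forces = 1, b0, feet = list(footfall("LH", 0)))
  expect_equal(unname(acc0), c(0, 0, 0), tolerance = 1e-12)
  expect_error(trunk_dynamics(st0, forces = -0.1, b0,
                              feet = list(footfall("LH", 0))),
               "nonnegative")
})

test_that("pitch moment equals force times perpendicular distance to the leg line", {
  hp <- internal_horse()
  body <- hp$body
  st <- trunk_state(x = 0.1, y = 0.85, theta = 0.15, vx = 0.4)
  foot <- footfall("LH", x_foot = -0.45)
  Fv <- 0.8
  acc <- trunk_dynamics(st, forces = Fv, body, feet = list(foot))
  lg <- limb_geometry(st, body, foot)
  ## independent route: |torque| = F * (perpendicular distance from COM to
  ## the leg's line of action)
  r <- lg$attachment - c(st$x, st$y)
  dist <- abs(r[1] * lg$unit_vector[2] - r[2] * lg$unit_vector[1])
  I <- quadgait:::.pitch_inertia(body)
  expect_equal(abs(acc["alpha"]) * I, Fv * dist, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("murphy number matches closed forms", {
  expect_equal(internal_horse()$body$murphy, 0.82)
  m <- 3.2; gad <- 1.7
  expect_equal(murphy_number(m * gad^2 / 12, m, gad), 1 / 3)  # uniform rod
  expect_equal(murphy_number(m * gad^2 / 4, m, gad), 1)       # end masses
  expect_error(murphy_number(-1, 1, 1), "positive")
})

test_that("nondimensionalization reproduces the horse task scales", {
  horse <- body_model(mass = 540, g = 9.81, l_H_max = 1.38, l_F_max = 1.38,
                      gad = 1.38, com_fraction = 0.57, murphy = 0.82)
  nd <- nondimensionalize(horse, speed_SI = 1.6, stride_SI = 1.6 * 1.16)
  expect_equal(round(nd$task$speed, 2), 0.43)
  expect_equal(round(nd$task$stride, 2), 1.34)
  expect_equal(nd$body$l_H_max, 1)
  expect_equal(nd$body$gad, 1)
  nd0 <- nondimensionalize(horse, speed_SI = 0, stride_SI = 1)
  expect_equal(nd0$task$speed, 0)
  expect_error(nondimensionalize(horse, 1, -2), "positive")
})

test_that("work-energy theorem holds on forward-integrated force histories", {
  for (seed in 1:4) {
    traj <- rk4_trajectory(seed)
    es <- energy_series(traj)
    ## actuator power is the only energy input (massless legs, rigid ground)
    gc <- quadgait:::.traj_geom(traj)
    p_act <- rowSums(traj$forces * gc$ld)
    t_phys <- traj$tp * traj$task$period
    dE <- quadgait:::.trapz(t_phys, p_act)
    expect_equal(tail(es$Etot, 1) - es$Etot[1], dE, tolerance = 1e-4)
  }
})

test_that("point-mass variant conserves zero pitch under any force history", {
  traj <- rk4_trajectory(9, variant = "point_mass")
  expect_true(all(abs(traj$states[, "theta"]) < 1e-14))
  expect_true(all(abs(traj$states[, "omega"]) < 1e-14))
})

test_that("type constructors enforce their invariants", {
  expect_error(body_model(l_H_max = -1), "positive")
  expect_error(body_model(com_fraction = 1.4), "com_fraction")
  expect_error(body_model(murphy = -0.1), "murphy")
  expect_error(trunk_state(theta = 2), "pitch")
  expect_error(gait_task(-1, 1), "positive")
  b <- internal_horse()$body
  expect_equal(quadgait:::.pitch_inertia(b), 0.82 * b$gad^2 / 4)
})
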