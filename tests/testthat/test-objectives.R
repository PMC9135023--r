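test_that("work metrics vanish in the canonical degenerate cases", {
  hp <- internal_horse("point_mass")
  body <- hp$body; task <- hp$task
  off <- quadgait:::.limb_offsets(body)
  ## point-mass vault: hip circles a fixed foot, velocity always
  ## perpendicular to the leg, leg length constant
  n <- 101
  tp <- seq(0, 1, length.out = n)
  L <- 0.95
  phi <- seq(-0.5, 0.5, length.out = n)
  px <- 0.3
  dh <- off$d[1]
  x <- px + L * sin(phi) - dh   # COM position placing the hip on the arc
  y <- L * cos(phi)
  dphi <- (phi[2] - phi[1]) / (tp[2] - tp[1]) / task$period
  vx <- L * cos(phi) * dphi
  vy <- -L * sin(phi) * dphi
  states <- cbind(x, y, 0, vx, vy, 0)
  feet <- data.frame(id = "LH", limb = "LH", x = px, d = dh, lmax = 1)
  forces <- matrix(0.8 + 0.2 * sin(2 * pi * tp), n, 1)
  traj <- gait_trajectory(tp, states, forces, feet, body, task, half = FALSE)
  expect_lt(suppressWarnings(ilcw(traj)), 1e-10)
  expect_lt(suppressWarnings(ncw(traj)), 1e-10)
  ## rigid-strut vaulting does no extension work regardless of force
  expect_lt(suppressWarnings(lew(traj)), 1e-10)
  ## zero velocity: no COM work at all
  states0 <- cbind(x, y, 0, 0, 0, 0)
  traj0 <- gait_trajectory(tp, states0, forces, feet, body, task, half = FALSE)
  expect_equal(suppressWarnings(ncw(traj0)), 0)
})

test_that("NCW equals the positive part of the COM energy fluctuations", {
  for (seed in 1:3) {
    traj <- rk4_trajectory(seed)
    ## independent oracle: finite differences of the COM energy series
    es <- energy_series(traj)
    t_phys <- traj$tp * traj$task$period
    e_com <- es$Ek + es$Ep
    oracle <- sum(pmax(diff(e_com), 0))
    expect_equal(suppressWarnings(ncw(traj)), oracle, tolerance = 5e-3)
  }
})

test_that("NCW never exceeds ILCW and doubling forces doubles all works", {
  for (seed in 1:25) {
    traj <- random_full_trajectory(seed)
    w_n <- suppressWarnings(ncw(traj))
    w_i <- suppressWarnings(ilcw(traj))
    expect_lte(w_n, w_i + 1e-12)
    traj2 <- traj
    traj2$forces <- 2 * traj$forces
    expect_equal(suppressWarnings(ncw(traj2)), 2 * w_n, tolerance = 1e-10)
    expect_equal(suppressWarnings(lew(traj2)), 2 * suppressWarnings(lew(traj)),
                 tolerance = 1e-10)
  }
})

test_that("work metrics are invariant to horizontal translation", {
  traj <- random_full_trajectory(7)
  shifted <- traj
  shifted$states[, "x"] <- shifted$states[, "x"] + 3.7
  shifted$feet$x <- shifted$feet$x + 3.7
  for (f in list(ncw, ilcw, lew, nsw))
    expect_equal(suppressWarnings(f(shifted)), suppressWarnings(f(traj)),
                 tolerance = 1e-12)
})

test_that("point-mass trajectories have ILCW identical to LEW and NSW to NCW", {
  for (seed in 1:10) {
    traj <- random_full_trajectory(seed, variant = "point_mass")
    expect_lt(abs(suppressWarnings(ilcw(traj)) - suppressWarnings(lew(traj))),
              1e-6)
    expect_lt(abs(suppressWarnings(nsw(traj)) - suppressWarnings(ncw(traj))),
              1e-12)
  }
})

test_that("percent recovery matches the canonical exchange patterns", {
  t <- seq(0, 1, length.out = 201)
  ## perfect out-of-phase exchange (point pendulum): 100%
  ek <- 1 + 0.3 * cos(2 * pi * t)
  expect_equal(percent_recovery(ek, ep = 2 - 0.3 * cos(2 * pi * t)), 100)
  ## in-phase fluctuation: no exchange possible
  expect_equal(percent_recovery(ek, ep = ek), 0)
  ## no fluctuation at all: undefined
  expect_true(is.na(percent_recovery(rep(1, 201), ep = rep(2, 201))))
})

test_that("force-rate penalty matches the closed-form sinusoid integral", {
  hp <- internal_horse()
  n <- 401
  tp <- seq(0, 1, length.out = n)
  states <- cbind(tp, 0.9, 0, 0.4, 0, 0)
  feet <- data.frame(id = "LH", limb = "LH", x = 0.5,
                     d = quadgait:::.limb_offsets(hp$body)$d[1], lmax = 1)
  forces <- matrix(1, n, 1)
  traj <- gait_trajectory(tp, states, forces, feet, hp$body, hp$task,
                          half = FALSE, controls = matrix(sin(2 * pi * tp)))
  c1 <- 3e-5
  ## integral of sin^2 over one period is 1/2
  expect_equal(force_rate_penalty(traj, c1), c1 / 2, tolerance = 1e-6)
  expect_equal(force_rate_penalty(traj, 0), 0)
  ## constant force: zero penalty (finite-difference route)
  traj$controls <- NULL
  expect_equal(force_rate_penalty(traj, c1), 0)
})

test_that("work_breakdown is self-consistent and ordered", {
  traj <- random_full_trajectory(3)
  wb <- suppressWarnings(work_breakdown(traj))
  expect_s3_class(wb, "work_breakdown")
  expect_equal(wb$ncw, suppressWarnings(ncw(traj)), tolerance = 1e-12)
  expect_equal(wb$ilcw, sum(wb$per_limb_com$positive), tolerance = 1e-12)
  expect_equal(wb$lew, sum(wb$per_limb_ext$positive), tolerance = 1e-12)
  expect_true(all(c(wb$ncw, wb$nsw, wb$ilcw, wb$lew) >= 0))
  expect_true(wb$percent_recovery >= 0 && wb$percent_recovery <= 100)
})

test_that("smoothed objective describes the slack split", {
  so <- smooth_objective("ncw")
  expect_equal(so$n_slack_pairs, 1L)
  expect_equal(smooth_objective("lew")$n_slack_pairs, 5L)
  expect_error(smooth_objective("ncw", slack_scheme = "epsilon"), "scheme")
})
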