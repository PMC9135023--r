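test_that("NLP dimensions match the closed-form variable count", {
  hp <- internal_horse()
  for (metric in c("ncw", "lew")) {
    spec <- transcription_spec(n_nodes = 16)
    nlp <- build_nlp(hp$body, hp$task, metric, spec)
    n <- 16L
    ns <- if (metric == "ncw") 1L else 5L
    ## 12 states + 5 rate controls + 2 ns slacks per node, 2 footfall params
    expect_equal(nlp$nz, n * (17L + 2L * ns) + 2L)
    ## 12 defects per interval, ns slack splits per node, 15 boundary rows
    expect_equal(nlp$neq, 12L * (n - 1L) + ns * n + 15L)
    ## 5 force-length rows + 2 attachment heights per node
    expect_equal(nlp$nin, 7L * n)
    expect_equal(length(nlp$lower), nlp$nz)
    ## forces are bounded below by zero (pushing only)
    v <- nlp$unpack(nlp$lower)
    expect_true(all(v$X[, 7:11] == 0))
  }
})

test_that("collocation defects vanish on an exactly integrable ballistic arc", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 12)
  for (rule in c("trapezoidal", "hermite_simpson")) {
    spec$collocation_rule <- rule
    nlp <- build_nlp(hp$body, hp$task, "lew", spec)
    n <- nlp$n
    tp <- nlp$tp
    Tq <- hp$task$period
    t_phys <- tp * Tq
    ## unforced flight: polynomial states solve the dynamics exactly
    X <- cbind(0.2 + 0.4 * t_phys, 1.5 - 0.5 * t_phys^2 / 2 - 0 * t_phys,
               0.1, 0.4, -0.5 * t_phys, 0,
               matrix(0, n, 5), 0)
    X[, 5] <- -t_phys  # vy = -g t
    X[, 2] <- 1.5 - t_phys^2 / 2
    z <- nlp$pack(list(X = X, U = matrix(0, n, 5),
                       SP = matrix(0, n, nlp$ns), SM = matrix(0, n, nlp$ns),
                       q = c(0, 0.5)))
    ce <- nlp$constraints(z)$ceq
    defects <- ce[seq_len(12 * (n - 1))]
    expect_lt(max(abs(defects)), 1e-10)
  }
})

test_that("compiled and reference merit evaluations agree", {
  hp <- internal_horse()
  set.seed(33)
  for (metric in c("ncw", "ilcw", "lew")) {
    spec <- transcription_spec(n_nodes = 9)
    nc <- build_nlp(hp$body, hp$task, metric, spec, rho = 0.7, backend = "cpp")
    nr <- build_nlp(hp$body, hp$task, metric, spec, rho = 0.7, backend = "r")
    z <- random_guess(1, hp$body, hp$task, spec, metric)
    z <- pmin(pmax(z + runif(nc$nz, -0.02, 0.02), nc$lower), nc$upper)
    al <- list(lam = runif(nc$neq, -1, 1), sig = runif(nc$nin, 0, 1), mu = 7)
    ec <- nc$eval_core(z, al)
    er <- nr$eval_core(z, al)
    expect_equal(ec$merit, er$merit, tolerance = 1e-12)
    expect_equal(ec$grad, er$grad, tolerance = 1e-10)
    expect_equal(ec$ceq, er$ceq, tolerance = 1e-12)
    expect_equal(ec$cineq, er$cineq, tolerance = 1e-12)
  }
})

test_that("analytic merit gradient matches finite differences", {
  hp <- internal_horse("point_mass")
  spec <- transcription_spec(n_nodes = 8)
  nlp <- build_nlp(hp$body, hp$task, "ilcw", spec, rho = 0.3)
  set.seed(4)
  z <- random_guess(2, hp$body, hp$task, spec, "ilcw")
  z <- pmin(pmax(z + runif(nlp$nz, -0.01, 0.01), nlp$lower), nlp$upper)
  al <- list(lam = runif(nlp$neq, -0.5, 0.5), sig = runif(nlp$nin, 0, 0.5),
             mu = 3)
  ga <- nlp$merit_grad(z, al)
  gf <- fd_gradient(function(zz) nlp$merit(zz, al), z)
  expect_lt(max(abs(ga - gf)) / max(1, max(abs(gf))), 1e-6)
})

test_that("relaxation penalties follow the tenfold schedule", {
  expect_equal(relaxation_schedule(0, 0.3), 0.3)
  expect_equal(relaxation_schedule(1, 0.3), 3)
  expect_equal(relaxation_schedule(3, 0.3), 300)
  expect_error(relaxation_schedule(-1), "nonnegative")
})

test_that("mirroring produces a periodic full stride with shifted right limbs", {
  hp <- internal_horse()
  n <- 31
  tp <- seq(0, 0.5, length.out = n)
  D <- hp$task$stride
  off <- quadgait:::.limb_offsets(hp$body)
  ## a half cycle satisfying all symmetry conventions: the reference hind limb
  ## touches down at t' = 0, the fore limb at 0.25; right-limb forces are the
  ## tails of stances begun half a stride earlier
  bump <- quadgait:::.bump
  forces <- cbind(bump(tp, 0, 0.6), bump(tp + 0.5, 0, 0.6), 0 * tp,
                  bump(tp, 0.25, 0.5), bump(tp + 0.5, 0.25, 0.5))
  colnames(forces) <- off$id
  states <- cbind(D * tp, 0.9, 0, hp$task$speed, 0, 0)
  feet <- data.frame(id = off$id, limb = off$limb,
                     x = as.numeric(quadgait:::.footfall_x(c(0.2, 0.9), hp$task)),
                     d = off$d, lmax = off$lmax)
  half <- gait_trajectory(tp, states, forces, feet, hp$body, hp$task,
                          half = TRUE)
  full <- mirror_half_cycle(half)
  expect_false(full$half)
  expect_equal(nrow(full$states), 2 * n - 1)
  expect_equal(unname(full$states[2 * n - 1, "x"]), D, tolerance = 1e-12)
  ## each limb's stance recurs half a stride later on the opposite side
  lf <- quadgait:::.limb_forces(full)
  i_half <- n  # sample index of t' = 0.5
  expect_equal(lf[1:(n - 1), "LH"], lf[i_half:(2 * n - 2), "RH"],
               ignore_attr = TRUE, tolerance = 1e-12)
  ## hind-hind phase difference is exactly half a stride
  gd <- gait_diagram(full)
  expect_equal(abs(gd$phase["RH"] - gd$phase["LH"]), 0.5, tolerance = 0.02,
               ignore_attr = TRUE)
  ## an asymmetric half cycle is refused
  bad <- half
  bad$forces[1, 1] <- 0.5  # reference limb must be unloaded at t' = 0
  expect_error(mirror_half_cycle(bad), "symmetry")
})

test_that("random decision vectors violating force positivity sit outside bounds", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 8)
  nlp <- build_nlp(hp$body, hp$task, "lew", spec)
  z <- random_guess(5, hp$body, hp$task, spec, "lew")
  v <- nlp$unpack(z)
  v$X[3, 8] <- -0.2
  z_bad <- nlp$pack(v)
  expect_true(any(z_bad < nlp$lower))
})
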