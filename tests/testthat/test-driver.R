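test_that("random guesses are deterministic and physically scaled", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 12)
  z1 <- random_guess(77, hp$body, hp$task, spec, "lew")
  z2 <- random_guess(77, hp$body, hp$task, spec, "lew")
  expect_identical(z1, z2)
  z3 <- random_guess(78, hp$body, hp$task, spec, "lew")
  expect_false(identical(z1, z3))
})

test_that("guessed forces are nonnegative and support body weight on average", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 12)
  nlp <- build_nlp(hp$body, hp$task, "lew", spec)
  wq <- nlp$wq
  ok_pos <- TRUE
  mean_vert <- numeric(1000)
  for (seed in 1:1000) {
    z <- random_guess(seed, hp$body, hp$task, spec, "lew")
    v <- nlp$unpack(z)
    Fm <- v$X[, 7:11]
    if (any(Fm < 0)) ok_pos <- FALSE
    tr <- nlp$as_trajectory(z)
    gc <- quadgait:::.traj_geom(tr)
    mean_vert[seed] <- sum(wq * rowSums(Fm * gc$uy)) / 0.5
  }
  expect_true(ok_pos)
  expect_true(all(mean_vert > 0.5 & mean_vert < 1.5))
})

test_that("staged solve reports failure instead of raising", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 8)
  nlp <- build_nlp(hp$body, hp$task, "lew", spec)
  bad <- rep(NaN, nlp$nz)
  rep <- staged_solve(bad, hp$body, hp$task, "lew", spec,
                      solver_control(inner_maxit = 10, max_outer = 1,
                                     refine = FALSE))
  expect_s3_class(rep, "solve_report")
  expect_false(rep$converged)
  expect_false(rep$accepted)
})

test_that("staged protocol increases relaxation penalties tenfold per round", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 8)
  g <- random_guess(3, hp$body, hp$task, spec, "lew")
  rep <- staged_solve(g, hp$body, hp$task, "lew", spec,
                      solver_control(inner_maxit = 15, max_outer = 1,
                                     rounds = 3, refine = TRUE, n_coarse = 8),
                      seed = 3)
  rhos <- vapply(rep$log, function(l) l$rho, numeric(1))
  expect_equal(rhos[-1] / rhos[-length(rhos)], rep(10, length(rhos) - 1))
  ## the refinement round interpolates midpoints
  ns <- vapply(rep$log, function(l) l$n, numeric(1))
  expect_equal(ns[length(ns)], 2 * ns[length(ns) - 1] - 1)
})

test_that("multistart returns an explicit no-solution result when all fail", {
  hp <- internal_horse()
  spec <- transcription_spec(n_nodes = 8)
  ## a convergence tolerance of zero is unattainable, so every restart is
  ## rejected and the no-solution branch must engage
  ctl <- solver_control(inner_maxit = 5, max_outer = 1, rounds = 1,
                        refine = FALSE, finish_top = 0, newton_steps = 0,
                        converge_tol = 0)
  expect_warning(
    ms <- multistart(2, 10, hp$body, hp$task, "lew", spec, ctl),
    "no restart")
  expect_null(ms$best)
  expect_length(ms$reports, 2)
  expect_equal(vapply(ms$reports, function(r) r$seed, numeric(1)), c(11, 12))
})
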