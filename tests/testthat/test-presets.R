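test_that("horse preset reproduces the published model dimensions", {
  hp <- horse_preset()
  expect_equal(round(hp$task$speed, 2), 0.43)
  expect_equal(round(hp$task$stride, 2), 1.34)
  expect_equal(hp$body$murphy, 0.82)
  expect_equal(hp$body$com_fraction, 0.57)
  expect_equal(hp$body$l_F_max, 1)
  expect_equal(hp$body$gad, 1)
  expect_equal(hp$c1, 3e-5)
  expect_equal(hp$body_SI$l_H_max, 1.38)
  ## stride length from speed and stride time
  expect_equal(round(hp$stride_SI, 2), 1.86)
  alt <- horse_preset(alternate = TRUE)
  expect_equal(alt$body_SI$l_F_max, 1.14)
  expect_equal(alt$body_SI$gad, 1.63)
  expect_equal(round(alt$body$gad, 3), round(1.63 / 1.38, 3))
})

test_that("packaged configuration files round-trip through the reader", {
  cfg <- read_gait_config(system.file("extdata", "horse.yaml",
                                      package = "quadgait"))
  hp <- horse_preset()
  expect_equal(cfg$task$speed, hp$task$speed, tolerance = 1e-3)
  expect_equal(cfg$body$murphy, 0.82)
  expect_equal(cfg$metric, "lew")
  expect_equal(cfg$spec$c1, 3e-5)
  expect_s3_class(cfg$spec, "transcription_spec")
  expect_equal(cfg$n_restarts, 10L)
  alt <- read_gait_config(system.file("extdata", "horse_alternate.yaml",
                                      package = "quadgait"))
  expect_equal(alt$body$gad, 1.63 / 1.38, tolerance = 1e-12)
})

test_that("pendular toys have perfect recovery and conserve energy", {
  for (kind in c("point_pendulum", "bead_on_wire")) {
    sim <- simulate_toy(toy_system(kind), duration = 8)
    expect_lt(max(abs(sim$Etot - sim$Etot[1])), 1e-6)
    expect_equal(sim$recovery, 100, tolerance = 0.1)
  }
})

test_that("rotational-energy toys lose recovery by the closed-form share", {
  ## rolling uniform sphere: translational share of kinetic energy is 5/7,
  ## so recovery = (1 + 5/7 - 2/7) / (1 + 5/7) = 5/6
  sim <- simulate_toy(toy_system("rolling_ball"), duration = 8)
  expect_lt(max(abs(sim$Etot - sim$Etot[1])), 1e-6)
  expect_equal(sim$recovery, 100 * 5 / 6, tolerance = 0.5)
  ## rod pivoted at its end: COM share is (L/2)^2 / ((L/2)^2 + L^2/12) = 3/4,
  ## recovery = (1 + 3/4 - 1/4) / (1 + 3/4) = 6/7
  simp <- simulate_toy(toy_system("physical_pendulum"), duration = 8)
  expect_equal(simp$recovery, 100 * 6 / 7, tolerance = 0.5)
  ## finite NCW arises passively although no work is performed
  seg <- simp$segment
  w_sum <- sum(pmax(diff(simp$Ek[seg] + simp$Ep[seg]), 0))
  expect_gt(w_sum, 1e-4)
})

test_that("passive four-bar vaulting: walking trot recovers fully, four-beat does not", {
  trot <- simulate_toy(toy_system("passive_4bar", contact = "walking_trot"),
                       duration = 0.8, n = 801)
  expect_lt(max(abs(trot$Etot - trot$Etot[1])), 1e-4)
  expect_equal(trot$recovery, 100, tolerance = 0.2)
  ## the parallelogram keeps the trunk level: no rotational energy
  expect_lt(max(trot$Erot), 1e-10)
  fb <- simulate_toy(toy_system("passive_4bar", contact = "four_beat"),
                     duration = 0.8, n = 801)
  expect_lt(max(abs(fb$Etot - fb$Etot[1])), 1e-4)
  expect_gt(max(fb$Erot), 1e-4)
  expect_lt(fb$recovery, 99.5)
})
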