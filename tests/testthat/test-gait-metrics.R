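## Synthetic full-stride trajectory with prescribed per-limb force profiles.
synthetic_gait <- function(profiles, n = 201) {
  hp <- internal_horse()
  tp <- seq(0, 1, length.out = n)
  off <- quadgait:::.limb_offsets(hp$body)
  feet <- data.frame(id = names(profiles), limb = names(profiles),
                     x = seq_along(profiles) * 0.3,
                     d = off$d[c(1, 2, 3, 5)][seq_along(profiles)],
                     lmax = 1)
  forces <- sapply(profiles, function(f) f(tp))
  states <- cbind(hp$task$stride * tp, 0.9, 0, hp$task$speed, 0, 0)
  gait_trajectory(tp, states, forces, feet, hp$body, hp$task, half = FALSE)
}

test_that("duty factors recover prescribed stance fractions", {
  sq <- function(duty) function(t) ifelse((t - 0.2) %% 1 < duty, 1, 0)
  traj <- synthetic_gait(list(LH = sq(0.6), RH = function(t) rep(1, length(t)),
                              LF = sq(0.35), RF = function(t) rep(0, length(t))))
  gd <- gait_diagram(traj)
  expect_equal(unname(gd$duty["LH"]), 0.6, tolerance = 0.01)
  expect_equal(unname(gd$duty["RH"]), 1)
  expect_equal(unname(gd$duty["LF"]), 0.35, tolerance = 0.02)
  expect_equal(unname(gd$duty["RF"]), 0)
  expect_true(is.na(gd$touchdown["RF"]))
  ## phase is relative to LH touchdown
  expect_equal(unname(gd$phase["LH"]), 0)
})

test_that("stance intervals match a brute-force level set, including two-hump dips", {
  n <- 401
  tp <- seq(0, 1, length.out = n)
  thr <- 0.02
  ## two humps separated by a sub-threshold gap wider than one grid step
  f <- pmax(sin(2 * pi * tp)^2 - 0.35, 0) + pmax(sin(2 * pi * (tp - 0.25))^2 - 0.6, 0)
  iv <- quadgait:::.stance_intervals(tp, f, thr)
  ## brute force: runs of the indicator
  up <- f > thr
  runs <- rle(up)
  expect_equal(nrow(iv), sum(runs$values))
  measure <- sum(pmin(iv[, 2], iv[, 1] + 1) - iv[, 1])
  expect_equal(measure, mean(up), tolerance = 0.02)
})

test_that("hump counting distinguishes single from double humps", {
  tp <- seq(0, 1, length.out = 201)
  single <- sin(pi * pmin(tp / 0.6, 1))^2 * (tp < 0.6)
  ## piecewise-linear M profile: peaks at 0.15 and 0.45, trough 0.4 between
  double <- stats::approx(c(0, 0.15, 0.3, 0.45, 0.6, 1),
                          c(0, 1, 0.4, 1, 0, 0), xout = tp)$y
  expect_equal(quadgait:::.hump_count(single, 0.02), 1L)
  expect_equal(quadgait:::.hump_count(double, 0.02), 2L)
  expect_equal(quadgait:::.hump_count(rep(0, 201), 0.02), 0L)
})

test_that("gait classification separates the three canonical patterns", {
  bump <- function(td, duty, amp = 1) function(t)
    amp * quadgait:::.bump(t, td, duty)
  ## compliant: all limbs nearly always loaded, single hump
  compliant <- synthetic_gait(list(LH = bump(0.00, 0.97), RH = bump(0.50, 0.97),
                                   LF = bump(0.25, 0.97), RF = bump(0.75, 0.97)))
  cg <- classify_gait(gait_diagram(compliant), compliant)
  expect_equal(cg$label, "compliant_high_duty")
  ## single-stance vaulting: sequential lone supports with brief overlaps
  vault <- synthetic_gait(list(LH = bump(0.00, 0.30), RF = bump(0.25, 0.30),
                               RH = bump(0.50, 0.30), LF = bump(0.75, 0.30)))
  cv <- classify_gait(gait_diagram(vault), vault)
  expect_equal(cv$label, "single_stance_vaulting")
  ## four-beat singlefoot: evenly spaced touchdowns, duty 0.6
  fb <- synthetic_gait(list(LH = bump(0.00, 0.60), RH = bump(0.50, 0.60),
                            LF = bump(0.25, 0.60), RF = bump(0.75, 0.60)))
  cf <- classify_gait(gait_diagram(fb), fb)
  expect_equal(cf$label, "four_beat_singlefoot")
  expect_true(all(cf$features$support_range >= 2) &&
                all(cf$features$support_range <= 3))
})

test_that("power traces integrate back to the work breakdown", {
  traj <- random_full_trajectory(12)
  pt <- power_traces(traj)
  wb <- suppressWarnings(work_breakdown(traj))
  tr <- function(p) quadgait:::.pos_work(pt$t, p)
  expect_equal(tr(pt$ncp), wb$ncw, tolerance = 1e-10)
  expect_equal(tr(pt$nsp), wb$nsw, tolerance = 1e-10)
  ext_cols <- grep("^extP_", names(pt))
  com_cols <- grep("^comP_", names(pt))
  expect_equal(sum(vapply(pt[ext_cols], tr, numeric(1))), wb$lew,
               tolerance = 1e-10)
  ## per-limb aggregation loses the footfall split, so per-limb positive COM
  ## work integrates limb totals
  expect_equal(sum(vapply(pt[com_cols], tr, numeric(1))),
               sum(wb$per_limb_com$positive), tolerance = 1e-6)
})

test_that("work table lays out metrics by optimized objective", {
  traj <- random_full_trajectory(5)
  wt <- suppressWarnings(work_table(list(ncw = traj, ilcw = NULL, lew = traj)))
  expect_equal(dim(wt), c(5L, 3L))
  expect_true(all(is.na(wt[, "ILCW"])))
  wb <- suppressWarnings(work_breakdown(traj))
  expect_equal(wt["LEW", "NCW"], wb$lew)
  expect_equal(wt["Percent Recovery", "LEW"], wb$percent_recovery)
})

test_that("duty and phase are invariant to left-right relabeling", {
  traj <- random_full_trajectory(8)
  gd <- gait_diagram(traj)
  swapped <- traj
  swapped$feet$limb <- c(LH = "RH", RH = "LH", LF = "RF", RF = "LF")[traj$feet$limb]
  gs <- gait_diagram(swapped)
  expect_equal(sort(unname(gd$duty)), sort(unname(gs$duty)))
})
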