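## Multi-start global search driver: random initial guesses, the staged
## relaxation protocol (loose penalties first, tenfold increases, midpoint
## mesh refinement, final polish) and selection of the "pseudoglobal"
## optimum among accepted restarts.

#' Solver control settings
#'
#' @param rounds number of penalty rounds before mesh refinement (each round
#'   multiplies the relaxation penalty tenfold).
#' @param inner_maxit L-BFGS-B iteration caps, one per round plus one for the
#'   refined-mesh polish round (recycled if shorter).
#' @param max_outer augmented-Lagrangian outer iteration caps (recycled).
#' @param newton_steps exact-Hessian Newton steps on the merit after each
#'   inner solve (recycled per round); these second-order steps carry the
#'   iterate through the flat, ill-conditioned valleys of the collocation
#'   problem.
#' @param feas_tol feasibility target of the augmented-Lagrangian rounds
#'   (defects are scaled by the grid step, so this is an O(1) measure).
#' @param converge_tol equality residual (including the symmetry boundary
#'   conditions) required of an accepted solution after the Gauss-Newton
#'   feasibility polish.
#' @param comp_tol acceptance threshold on complementarity residuals at the
#'   nodes.
#' @param mesh_tol acceptance threshold on the change of the optimized work
#'   metric under midpoint mesh refinement (m g l_H).
#' @param refine logical; perform midpoint mesh-refinement polish rounds.
#' @param refinements number of successive midpoint refinements (each doubles
#'   the interval count); the mesh-acceptance flag compares the optimized work
#'   metric across the last refinement.
#' @param n_coarse grid size that round-one output is downsampled to.
#' @param finish_top number of lowest-objective restarts that receive a
#'   deep-finish stage (extra heavy outer iterations at the final mesh and
#'   relaxation penalty) before pseudoglobal selection.
#' @return list of class \code{solver_control}.
#' @export
solver_control <- function(rounds = 3, inner_maxit = c(500, 300, 300, 400),
                           max_outer = c(6, 8, 8, 4),
                           newton_steps = c(20, 30, 30, 12),
                           feas_tol = 1e-5, converge_tol = 1e-6,
                           comp_tol = 1e-4,
                           mesh_tol = 0.01, refine = TRUE, refinements = 1,
                           n_coarse = 16, finish_top = 3) {
  structure(list(rounds = rounds, inner_maxit = inner_maxit,
                 max_outer = max_outer, newton_steps = newton_steps,
                 feas_tol = feas_tol, converge_tol = converge_tol,
                 comp_tol = comp_tol, mesh_tol = mesh_tol, refine = refine,
                 refinements = refinements, n_coarse = n_coarse,
                 finish_top = finish_top),
            class = "solver_control")
}

## Smooth raised-sine stance bump on the periodic stride, touchdown at td,
## stance duration duty (stride fractions).
.bump <- function(t, td, duty) {
  u <- (t - td) %% 1
  ifelse(u < duty, sin(pi * u / duty)^2, 0)
}

#' Random initial guess
#'
#' Draws one feasible-bounds initial guess for the half-cycle NLP:
#' trunk height near standing height with a small periodic fluctuation,
#' linear horizontal progression from 0 to D/2, small random pitch, smooth
#' nonnegative stance-bump force profiles with random touchdown phases and
#' duty factors scaled to support body weight on average, and footfall
#' positions near the attachment position at mid-stance. Deterministic given
#' the seed.
#'
#' @param seed integer seed.
#' @param body,task internal-unit [body_model()] and [gait_task()].
#' @param spec a [transcription_spec()].
#' @param metric objective the guess is built for (sets the slack layout).
#' @return decision vector \code{z} for the matching [build_nlp()] problem.
#' @export
random_guess <- function(seed, body, task, spec = transcription_spec(),
                         metric = "lew") {
  nlp <- build_nlp(body, task, metric, spec)
  set.seed(seed)
  n <- nlp$n; tp <- nlp$tp
  D <- task$stride; Tper <- task$period; U0 <- task$speed
  off <- .limb_offsets(body)
  pointmass <- body$variant == "point_mass"
  ## trunk kinematics: near-standing height, linear progression
  h0 <- stats::runif(1, 0.75, 0.95)
  a_y <- stats::runif(1, 0, 0.04); ph_y <- stats::runif(1, 0, 2 * pi)
  y <- h0 + a_y * cos(4 * pi * tp + ph_y)
  vy <- -a_y * 4 * pi * sin(4 * pi * tp + ph_y) / Tper
  x <- D * tp
  a_v <- stats::runif(1, 0, 0.05); ph_v <- stats::runif(1, 0, 2 * pi)
  vx <- U0 + a_v * cos(4 * pi * tp + ph_v)
  if (pointmass) {
    th <- om <- numeric(n)
  } else {
    a_t <- stats::runif(1, 0, 0.08); ph_t <- stats::runif(1, 0, 2 * pi)
    th <- a_t * cos(4 * pi * tp + ph_t)
    om <- -a_t * 4 * pi * sin(4 * pi * tp + ph_t) / Tper
  }
  ## stance-bump force profiles (full-stride periodic, sampled on the half
  ## cycle). The left hind is the reference limb: it touches down within the
  ## first half cycle; the trailing fore and right-limb forces are tails of
  ## stances begun half a stride earlier.
  td_h <- stats::runif(1, 0, 0.45)
  duty_h <- stats::runif(1, 0.35, min(0.95, 0.97 - td_h))
  td_f <- stats::runif(1, 0, 0.5)
  duty_f <- stats::runif(1, 0.35, 0.95)
  fore_share <- stats::runif(1, 0.45, 0.70)
  F_LH <- .bump(tp, td_h, duty_h)
  F_RH <- .bump(tp + 0.5, td_h, duty_h)
  fore <- .bump(tp, td_f, duty_f)
  F_LFl <- fore * (tp >= td_f)
  F_LFt <- fore * (tp < td_f)
  F_RF <- .bump(tp + 0.5, td_f, duty_f)
  wq <- nlp$wq
  m_h <- sum(wq * (F_LH + F_RH)) / 0.5
  m_f <- sum(wq * (F_LFt + F_LFl + F_RF)) / 0.5
  amp_h <- if (m_h > 0) (1 - fore_share) / m_h else 0
  amp_f <- if (m_f > 0) fore_share / m_f else 0
  Fm <- cbind(amp_h * F_LH, amp_h * F_RH, amp_f * F_LFt, amp_f * F_LFl,
              amp_f * F_RF)
  ## footfalls near the attachment at mid-stance
  mid_h <- (td_h + duty_h / 2) %% 1
  mid_f <- (td_f + duty_f / 2) %% 1
  q1 <- D * mid_h + off$d[1] + stats::runif(1, -D / 4, D / 4)
  q2 <- (D * mid_f + off$d[3] - D) + stats::runif(1, -D / 4, D / 4)
  q <- pmin(pmax(c(q1, q2), nlp$lower[nlp$nz - 1:0]), nlp$upper[nlp$nz - 1:0])
  ## force-rate controls from finite differences of the profiles
  U <- apply(Fm, 2L, function(f) c(diff(f) / diff(tp), 0))
  J <- .cumtrapz(tp, Fm[, 4])
  X <- cbind(x, y, th, vx, vy, om, Fm, J)
  z <- nlp$pack(list(X = X, U = U, SP = matrix(0, n, nlp$ns),
                     SM = matrix(0, n, nlp$ns), q = q))
  ## initialize slacks at the exact positive/negative power split
  P <- nlp$eval_core(z)$P
  z <- nlp$pack(list(X = X, U = U, SP = .pos(P), SM = .pos(-P), q = q))
  pmin(pmax(z, nlp$lower), nlp$upper)
}

#' Staged solve of one initial guess
#'
#' Runs the staged optimization protocol on one guess: an initial round with
#' a low relaxation penalty and an iteration cap, downsampling to an evenly
#' spaced coarse grid, further rounds with tenfold-increased penalties, then
#' a mesh-refinement step interpolating collocation points midway between
#' existing points followed by a final polish round. Solver failure at any
#' round yields a report with the convergence flag set to \code{FALSE}
#' rather than an error.
#'
#' @param guess decision vector from [random_guess()] (or a compatible one).
#' @param body,task,metric,spec problem definition as in [build_nlp()].
#' @param control a [solver_control()].
#' @param seed seed recorded in the report.
#' @return object of class \code{solve_report} with acceptance flags
#'   (\code{converged}, \code{mesh_ok}, \code{comp_ok}, \code{accepted}), the
#'   final objective decomposition and the solution trajectory.
#' @export
staged_solve <- function(guess, body, task, metric = "lew",
                         spec = transcription_spec(),
                         control = solver_control(), seed = NA_integer_) {
  w0 <- spec$relaxation_w0
  nr <- control$rounds
  caps <- rep_len(control$inner_maxit, nr + 1L)
  outers <- rep_len(control$max_outer, nr + 1L)
  newts <- rep_len(control$newton_steps %||% 20, nr + 1L)
  nlp <- build_nlp(body, task, metric, spec, rho = relaxation_schedule(0, w0))
  z <- guess
  ok <- TRUE
  log <- list()
  for (r in seq_len(nr)) {
    rho_r <- relaxation_schedule(r - 1L, w0)
    nlp_r <- build_nlp(body, task, metric, spec, rho = rho_r)
    if (r == 2L && control$n_coarse != nlp_r$n) {
      spec_c <- spec; spec_c$n_nodes <- as.integer(control$n_coarse)
      nlp_c <- build_nlp(body, task, metric, spec_c, rho = rho_r)
      z <- .resample_z(z, nlp_r, nlp_c)
      nlp_r <- nlp_c
    } else if (r > 2L) {
      nlp_r <- build_nlp(body, task, metric,
                         if (exists("spec_c", inherits = FALSE)) spec_c else spec,
                         rho = rho_r)
    }
    sol <- .auglag(nlp_r, z, inner_maxit = caps[r], max_outer = outers[r],
                   feas_tol = control$feas_tol, newton_steps = newts[r])
    z <- sol$z
    log[[r]] <- list(round = r, rho = rho_r, viol = sol$viol,
                     feasible = sol$feasible, n = nlp_r$n,
                     objective = nlp_r$objective(z))
    if (!is.null(sol$error)) { ok <- FALSE; break }
    nlp <- nlp_r
  }
  if (ok) z <- .polish_eq(nlp, z)
  mesh_ok <- FALSE
  n_ref <- if (isTRUE(control$refine)) control$refinements %||% 1L
           else if (is.numeric(control$refine)) as.integer(control$refine)
           else 0L
  for (j in seq_len(n_ref)) {
    if (!ok) break
    spec_f <- spec
    spec_f$n_nodes <- 2L * nlp$n - 1L
    rho_f <- relaxation_schedule(nr + j - 1L, w0)
    nlp_f <- build_nlp(body, task, metric, spec_f, rho = rho_f)
    zf <- .resample_z(z, nlp, nlp_f)
    sol <- .auglag(nlp_f, zf, inner_maxit = caps[nr + 1L],
                   max_outer = outers[nr + 1L], feas_tol = control$feas_tol,
                   newton_steps = newts[nr + 1L])
    if (is.null(sol$error)) {
      z <- .polish_eq(nlp_f, sol$z)
      nlp <- nlp_f
      log[[nr + j]] <- list(round = nr + j, rho = rho_f, viol = sol$viol,
                            feasible = sol$feasible, n = nlp_f$n,
                            objective = nlp_f$objective(z))
    } else ok <- FALSE
  }
  .assess_solution(nlp, z, body, task, metric, spec, control, seed, log, ok)
}

## Evaluate acceptance flags and assemble a solve_report for a final iterate.
.assess_solution <- function(nlp, z, body, task, metric, spec, control,
                             seed, log, ok) {
  if (ok) {
    cr <- tryCatch(nlp$comp_residuals(z), error = function(e) NULL)
    bad6 <- !is.null(cr) && cr["eq6"] > control$comp_tol
    bad7 <- !is.null(cr) && "eq7" %in% names(cr) && cr["eq7"] > control$comp_tol
    if (isTRUE(bad6) || isTRUE(bad7))
      z <- tryCatch(.enforce_exclusion(nlp, z), error = function(e) z)
  }
  cc_fin <- nlp$constraints(z)
  eq_res <- max(abs(cc_fin$ceq))
  in_res <- max(.pos(cc_fin$cineq), 0)
  converged <- ok && eq_res <= control$converge_tol && in_res <= control$comp_tol
  traj <- tryCatch(nlp$as_trajectory(z), error = function(e) NULL)
  works <- tryCatch(work_breakdown(traj, c1 = spec$c1),
                    error = function(e) NULL)
  ## discretization-error estimate: re-collocate the solution on a doubled
  ## mesh (feasibility polish only, no re-optimization) and compare the
  ## optimized work metric
  mesh_ok <- FALSE
  if (ok && !is.null(works)) {
    spec_m <- spec
    spec_m$n_nodes <- 2L * nlp$n - 1L
    mesh_ok <- tryCatch({
      nlp_m <- build_nlp(body, task, metric, spec_m, rho = nlp$rho)
      zm <- .polish_eq(nlp_m, .resample_z(z, nlp, nlp_m))
      wm <- work_breakdown(nlp_m$as_trajectory(zm), c1 = spec$c1)
      vm <- max(abs(nlp_m$constraints(zm)$ceq))
      is.finite(wm[[metric]]) && vm < 1e-5 &&
        abs(wm[[metric]] - works[[metric]]) < control$mesh_tol
    }, error = function(e) FALSE)
  }
  comp <- tryCatch(nlp$comp_residuals(z), error = function(e) Inf)
  comp_ok <- all(is.finite(comp)) && max(comp) <= control$comp_tol
  sym <- tryCatch(max(abs(.symmetry_residual(traj))), error = function(e) Inf)
  obj <- nlp$objective(z)
  accepted <- converged && mesh_ok && comp_ok
  structure(list(seed = seed, converged = converged, mesh_ok = mesh_ok,
                 comp_ok = comp_ok, accepted = accepted,
                 objective = obj, works = works, comp = comp,
                 eq_residual = eq_res, ineq_residual = in_res,
                 symmetry_residual = sym, trajectory = traj, z = z,
                 metric = metric, n_final = nlp$n, log = log),
            class = "solve_report")
}

## Deep-finish a restart at its final mesh: extra augmented-Lagrangian outer
## iterations with heavy Newton refinement at the final relaxation penalty,
## then the feasibility polish and a fresh assessment. Rescues restarts whose
## round budgets left them short of the convergence flags or of a fully
## resolved optimum.
.deep_finish <- function(rep, body, task, metric, spec, control) {
  w0 <- spec$relaxation_w0
  log <- rep$log
  ## stage A: heavy outer iterations at the restart's final mesh, penalty
  ## one decade up
  spec_a <- spec
  spec_a$n_nodes <- rep$n_final
  rho_a <- relaxation_schedule(control$rounds, w0)
  nlp_a <- build_nlp(body, task, metric, spec_a, rho = rho_a)
  sol <- .auglag(nlp_a, rep$z, inner_maxit = 400, max_outer = 6,
                 feas_tol = control$feas_tol, newton_steps = 30)
  if (!is.null(sol$error)) return(rep)
  z <- .polish_eq(nlp_a, sol$z)
  log <- c(log, list(list(round = length(log) + 1L, rho = rho_a,
                          viol = sol$viol, feasible = sol$feasible,
                          n = nlp_a$n, objective = nlp_a$objective(z))))
  ## stage B: midpoint mesh refinement with another tenfold penalty increase
  spec_b <- spec
  spec_b$n_nodes <- 2L * nlp_a$n - 1L
  rho_b <- relaxation_schedule(control$rounds + 1L, w0)
  nlp_b <- build_nlp(body, task, metric, spec_b, rho = rho_b)
  z <- .resample_z(z, nlp_a, nlp_b)
  sol <- .auglag(nlp_b, z, inner_maxit = 500, max_outer = 8,
                 feas_tol = control$feas_tol, newton_steps = 30)
  if (!is.null(sol$error)) return(rep)
  z <- .polish_eq(nlp_b, sol$z)
  log <- c(log, list(list(round = length(log) + 1L, rho = rho_b,
                          viol = sol$viol, feasible = sol$feasible,
                          n = nlp_b$n, objective = nlp_b$objective(z))))
  .assess_solution(nlp_b, z, body, task, metric, spec, control, rep$seed,
                   log, ok = TRUE)
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf(
    "Solve report (seed %s, %s): %s  [converged %s, mesh %s, complementarity %s]\n",
    x$seed, toupper(x$metric),
    if (x$accepted) "accepted" else "rejected",
    x$converged, x$mesh_ok, x$comp_ok))
  if (!is.null(x$objective))
    cat(sprintf("  objective %.5f = work %.5f + rate %.5f + relax %.5f\n",
                x$objective$total, x$objective$work, x$objective$rate_penalty,
                x$objective$relax_penalty))
  invisible(x)
}

#' Multi-start search for the pseudoglobal optimum
#'
#' Runs [staged_solve()] from \code{n_guesses} independent random initial
#' guesses (seeds \code{base_seed + 1, ..., base_seed + n_guesses}), filters
#' restarts by the acceptance flags (convergence, mesh tolerance,
#' complementarity satisfaction) and selects the accepted solution minimizing
#' the total objective (work, force-rate penalty and relaxation penalties) as
#' the pseudoglobal optimum.
#'
#' @param n_guesses number of restarts (>= 1).
#' @param base_seed base integer seed; restart k uses seed
#'   \code{base_seed + k}.
#' @param body,task,metric,spec problem definition as in [build_nlp()].
#' @param control a [solver_control()].
#' @param verbose print a one-line summary per restart.
#' @return object of class \code{multistart_result}: list with \code{best}
#'   (the pseudoglobal [staged_solve()] report, or \code{NULL} if no restart
#'   was accepted) and \code{reports} (all restarts).
#' @export
multistart <- function(n_guesses, base_seed, body, task, metric = "lew",
                       spec = transcription_spec(),
                       control = solver_control(), verbose = FALSE) {
  stopifnot(n_guesses >= 1)
  ## screening pass: full penalty rounds per restart; the mesh-refinement
  ## stage is reserved for the most promising restarts (refinement follows
  ## success, it does not precede it)
  ctl_screen <- control
  if ((control$finish_top %||% 0L) > 0L) ctl_screen$refine <- FALSE
  reports <- vector("list", n_guesses)
  for (k in seq_len(n_guesses)) {
    seed <- base_seed + k
    g <- random_guess(seed, body, task, spec, metric)
    reports[[k]] <- staged_solve(g, body, task, metric, spec, ctl_screen,
                                 seed = seed)
    if (verbose) print(reports[[k]])
  }
  ## deep-finish the most promising restarts: extra heavy outer iterations
  ## at the final mesh rescue near-misses and sharpen the eventual optimum
  k_top <- min(control$finish_top %||% 0L, n_guesses)
  if (k_top > 0L) {
    objs <- vapply(reports, function(r)
      if (is.finite(r$objective$total) && !is.null(r$works))
        r$objective$total else Inf, numeric(1))
    for (i in order(objs)[seq_len(k_top)]) {
      if (!is.finite(objs[i])) next
      r2 <- tryCatch(
        .deep_finish(reports[[i]], body, task, metric, spec, control),
        error = function(e) NULL)
      if (!is.null(r2) &&
          (r2$objective$total <= reports[[i]]$objective$total + 1e-9 ||
             (isTRUE(r2$accepted) && !isTRUE(reports[[i]]$accepted))))
        reports[[i]] <- r2
      if (verbose) print(reports[[i]])
    }
  }
  acc <- Filter(function(r) isTRUE(r$accepted), reports)
  best <- NULL
  if (length(acc)) {
    objs <- vapply(acc, function(r) r$objective$total, numeric(1))
    best <- acc[[which.min(objs)]]
  } else {
    warning("no restart satisfied all acceptance criteria", call. = FALSE)
  }
  structure(list(best = best, reports = reports, metric = metric,
                 n_guesses = n_guesses, base_seed = base_seed),
            class = "multistart_result")
}

#' @export
print.multistart_result <- function(x, ...) {
  n_acc <- sum(vapply(x$reports, function(r) isTRUE(r$accepted), logical(1)))
  cat(sprintf("Multistart (%s): %d/%d restarts accepted\n",
              toupper(x$metric), n_acc, x$n_guesses))
  if (!is.null(x$best)) {
    cat("Pseudoglobal optimum:\n")
    print(x$best)
    if (!is.null(x$best$works)) print(x$best$works)
  }
  invisible(x)
}
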