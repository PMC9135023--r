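## Direct-collocation transcription of the half-cycle, symmetry-reduced
## optimal-control problem. States are the planar trunk kinematics, the five
## footfall actuator forces and the running integral of the leading left-fore
## force; controls are the force rates; slack variables split the signed work
## integrand into positive and negative parts. Footfall positions of the left
## limbs are static decision parameters. Complementarity path conditions
## (force only below maximum limb length; leading/trailing fore exclusion) are
## relaxed with penalty weights on a tenfold schedule.
##
## The transcription exposes the objective, constraint residuals and an
## augmented-Lagrangian merit function with a hand-coded analytic gradient
## (adjoint accumulation); it is solved by the bound-constrained
## augmented-Lagrangian loop in auglag.R.

#' Transcription settings
#'
#' @param n_nodes collocation grid size over the half cycle (>= 8).
#' @param collocation_rule \code{"hermite_simpson"} (default) or
#'   \code{"trapezoidal"}.
#' @param relaxation_w0 initial relaxation-parameter penalty weight; each
#'   optimization round multiplies it tenfold (see [relaxation_schedule()]).
#' @param c1 force-rate penalty coefficient (default 3e-5).
#' @param bounds optional named list overriding default variable bounds
#'   (elements \code{y}, \code{vx}, \code{vy}, \code{omega}, \code{force},
#'   \code{rate}, \code{slack}, \code{x_pad}, \code{q_pad}; each a range).
#' @return object of class \code{transcription_spec}.
#' @export
transcription_spec <- function(n_nodes = 16,
                               collocation_rule = c("hermite_simpson",
                                                    "trapezoidal"),
                               relaxation_w0 = 0.1, c1 = 3e-5,
                               bounds = list()) {
  collocation_rule <- match.arg(collocation_rule)
  if (n_nodes < 8) .stopf("n_nodes must be at least 8")
  if (relaxation_w0 <= 0) .stopf("relaxation_w0 must be positive")
  if (c1 < 0) .stopf("c1 must be nonnegative")
  b <- list(y = c(0.05, 2.5), vx = c(-1.5, 2.5), vy = c(-3, 3),
            omega = c(-8, 8), force = c(0, 12), rate = c(-300, 300),
            slack = c(0, 80), x_pad = 1, q_pad = 1.5)
  b[names(bounds)] <- bounds
  structure(list(n_nodes = as.integer(n_nodes),
                 collocation_rule = collocation_rule,
                 relaxation_w0 = relaxation_w0, c1 = c1, bounds = b),
            class = "transcription_spec")
}

#' Relaxation-penalty schedule
#'
#' Geometric schedule for the relaxation-parameter penalty weight: each round
#' of the staged optimization increases the penalty tenfold.
#'
#' @param round_index nonnegative round number (0 = first round).
#' @param w0 initial weight.
#' @return penalty weight \code{w0 * 10^round_index}.
#' @export
relaxation_schedule <- function(round_index, w0 = 0.1) {
  if (any(round_index < 0)) .stopf("round_index must be nonnegative")
  w0 * 10^round_index
}

## ---------------------------------------------------------------------------
## NLP construction

#' Build the half-cycle nonlinear program
#'
#' Transcribes one gait optimization problem by direct collocation on a
#' uniform grid over the half cycle t' in [0, 0.5]. Constraints encode the
#' trunk dynamics defects, the slack split of the work integrand, symmetry
#' and periodicity boundary conditions, reference-limb force conventions,
#' force-only-below-maximum-length complementarity, the leading/trailing
#' fore-contact exclusion, attachment heights above ground and the pitch
#' bound. The objective is the smoothed work metric plus the force-rate
#' penalty and the relaxation penalties.
#'
#' @param body a [body_model()] in internal units.
#' @param task a [gait_task()].
#' @param metric objective to minimize: \code{"ncw"}, \code{"ilcw"} or
#'   \code{"lew"}.
#' @param spec a [transcription_spec()].
#' @param rho relaxation penalty weight for this round.
#' @param eq7 logical; add the extra trailing-fore/leading-fore-rate
#'   complementarity used to prevent brief five-contact intervals between
#'   nodes. Defaults to \code{TRUE} for the NCW metric only.
#' @param backend \code{"cpp"} (compiled merit/gradient kernel, default) or
#'   \code{"r"} (reference implementation; used as a cross-check in tests).
#' @return an object of class \code{gait_nlp}: a list of dimensions, bounds
#'   and closures (\code{objective}, \code{constraints}, \code{merit},
#'   \code{merit_grad}, \code{comp_residuals}, \code{pack}, \code{unpack},
#'   \code{as_trajectory}).
#' @export
build_nlp <- function(body, task, metric = c("lew", "ncw", "ilcw"),
                      spec = transcription_spec(), rho = spec$relaxation_w0,
                      eq7 = NULL, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  metric <- match.arg(metric)
  stopifnot(inherits(body, "body_model"), inherits(task, "gait_task"),
            inherits(spec, "transcription_spec"))
  if (is.null(eq7)) eq7 <- metric == "ncw"
  n <- spec$n_nodes
  ns <- if (metric == "ncw") 1L else 5L
  K <- 5L
  tp <- seq(0, 0.5, length.out = n)
  h <- tp[2L] - tp[1L]
  wq <- .trapz_weights(tp)
  Tper <- task$period
  D <- task$stride
  off <- .limb_offsets(body)
  pointmass <- body$variant == "point_mass"
  I <- if (pointmass) 1 else .pitch_inertia(body)
  hs <- spec$collocation_rule == "hermite_simpson"
  c1 <- spec$c1

  ## variable layout ---------------------------------------------------------
  nX <- 12L * n; nU <- K * n; nS <- ns * n
  oX <- 0L; oU <- nX; oSP <- nX + nU; oSM <- oSP + nS; oq <- oSM + nS
  nz <- oq + 2L
  iX <- matrix(seq_len(nX), n, 12L)
  iU <- matrix(oU + seq_len(nU), n, K)
  iSP <- matrix(oSP + seq_len(nS), n, ns)
  iSM <- matrix(oSM + seq_len(nS), n, ns)
  iq <- oq + 1:2
  unpack <- function(z)
    list(X = matrix(z[1:nX], n, 12L), U = matrix(z[iU], n, K),
         SP = matrix(z[iSP], n, ns), SM = matrix(z[iSM], n, ns), q = z[iq])
  pack <- function(v) c(v$X, v$U, v$SP, v$SM, v$q)

  ## bounds ------------------------------------------------------------------
  b <- spec$bounds
  lowX <- matrix(rep(c(-b$x_pad, b$y[1], -pi / 2, b$vx[1], b$vy[1], b$omega[1],
                       rep(b$force[1], 5), 0), each = n), n, 12L)
  uppX <- matrix(rep(c(D / 2 + b$x_pad, b$y[2], pi / 2, b$vx[2], b$vy[2],
                       b$omega[2], rep(b$force[2], 5), b$force[2] * Tper),
                     each = n), n, 12L)
  if (pointmass) {
    lowX[, 3] <- uppX[, 3] <- 0
    lowX[, 6] <- uppX[, 6] <- 0
  }
  lower <- c(lowX, matrix(b$rate[1], n, K), rep(b$slack[1], 2L * nS),
             rep(-b$q_pad, 2L))
  upper <- c(uppX, matrix(b$rate[2], n, K), rep(b$slack[2], 2L * nS),
             rep(D + b$q_pad, 2L))

  neq <- 12L * (n - 1L) + nS + 15L
  nin <- 7L * n

  px_of <- function(q) cbind(q[1], q[1] - D / 2, q[2], q[2] + D, q[2] + D / 2)
  geom_at <- function(X, q)
    .geom(X[, 1], X[, 2], X[, 3], X[, 4], X[, 5], X[, 6],
          px = px_of(q)[rep(1, nrow(X)), , drop = FALSE],
          d = off$d, lmax = off$lmax, pointmass = pointmass)

  ## state derivative wrt stride fraction t'
  dyn_G <- function(X, U, gc) {
    Fm <- X[, 7:11, drop = FALSE]
    acc <- .accel(gc, Fm, I)
    cbind(Tper * X[, 4], Tper * X[, 5], Tper * X[, 6],
          Tper * acc$ax, Tper * acc$ay, Tper * acc$al,
          U, X[, 10])
  }

  ## adjoint of dyn_G: weights W (m x 12) -> gradients wrt X, U, q
  dyn_vjp <- function(X, gc, W) {
    Fm <- X[, 7:11, drop = FALSE]
    gX <- matrix(0, nrow(X), 12L)
    av <- .accel_vjp(gc, Fm, I, Tper * W[, 4], Tper * W[, 5], Tper * W[, 6])
    gX[, 1] <- av$gx; gX[, 2] <- av$gy; gX[, 3] <- av$gth
    gX[, 7:11] <- av$gF
    gX[, 4] <- gX[, 4] + Tper * W[, 1]
    gX[, 5] <- gX[, 5] + Tper * W[, 2]
    gX[, 6] <- gX[, 6] + Tper * W[, 3]
    gX[, 10] <- gX[, 10] + W[, 12]
    gU <- W[, 7:11, drop = FALSE]
    gq <- c(sum(av$gpx[, 1:2]), sum(av$gpx[, 3:5]))
    list(gX = gX, gU = gU, gq = gq)
  }

  ## power terms split by the slacks (physical-time power at nodes, m x ns)
  power_P <- function(X, gc) {
    Fm <- X[, 7:11, drop = FALSE]
    if (metric == "lew") return(Fm * gc$ld)
    pc <- Fm * (gc$ux * X[, 4] + gc$uy * X[, 5])
    if (metric == "ilcw") pc else rowSums(pc)
  }

  ## adjoint of power terms: Wp (m x ns) -> gradients
  power_vjp <- function(X, gc, Wp) {
    Fm <- X[, 7:11, drop = FALSE]
    m <- nrow(X)
    Wl <- if (metric == "ncw") matrix(Wp, m, 5L) else Wp
    if (metric == "lew") {
      w <- Wl * Fm
      dbeta <- w * (gc$adx - gc$ld * gc$ux) / gc$l
      dgamma <- w * (gc$ady - gc$ld * gc$uy) / gc$l
      dadx <- w * gc$ux
      dady <- w * gc$uy
      gvx <- rowSums(dadx); gvy <- rowSums(dady)
      if (pointmass) {
        gom <- numeric(m); gth_e <- 0
      } else {
        gom <- rowSums(gc$Dm * (dady * gc$ct - dadx * gc$st))
        gth_e <- rowSums(gc$Dm * (-dadx * gc$ct - dady * gc$st)) * X[, 6]
      }
      ch <- .chain_bg(gc, dbeta, dgamma, gth_extra = gth_e)
      gF <- Wl * gc$ld
    } else {
      cd <- gc$ux * X[, 4] + gc$uy * X[, 5]
      w <- Wl * Fm
      dbeta <- w * (X[, 4] - cd * gc$ux) / gc$l
      dgamma <- w * (X[, 5] - cd * gc$uy) / gc$l
      gvx <- rowSums(w * gc$ux); gvy <- rowSums(w * gc$uy)
      gom <- numeric(m)
      ch <- .chain_bg(gc, dbeta, dgamma)
      gF <- Wl * cd
    }
    gX <- matrix(0, m, 12L)
    gX[, 1] <- ch$gx; gX[, 2] <- ch$gy; gX[, 3] <- ch$gth
    gX[, 4] <- gvx; gX[, 5] <- gvy; gX[, 6] <- gom
    gX[, 7:11] <- gF
    list(gX = gX, gq = c(sum(ch$gpx[, 1:2]), sum(ch$gpx[, 3:5])))
  }

  ## boundary-condition residuals (15) and their adjoint
  bc_eval <- function(X) {
    c(X[1, 1],
      X[n, 1] - D / 2,
      X[n, 2] - X[1, 2], X[n, 3] - X[1, 3], X[n, 4] - X[1, 4],
      X[n, 5] - X[1, 5], X[n, 6] - X[1, 6],
      X[1, 7], X[n, 8], X[n, 9], X[1, 10],
      X[1, 8] - X[n, 7],
      X[1, 11] - X[n, 10],
      X[1, 9] - X[n, 11],
      X[1, 12])
  }
  bc_vjp <- function(w, gX) {
    gX[1, 1] <- gX[1, 1] + w[1]
    gX[n, 1] <- gX[n, 1] + w[2]
    for (j in 2:6) {
      gX[n, j] <- gX[n, j] + w[j + 1]
      gX[1, j] <- gX[1, j] - w[j + 1]
    }
    gX[1, 7] <- gX[1, 7] + w[8]
    gX[n, 8] <- gX[n, 8] + w[9]
    gX[n, 9] <- gX[n, 9] + w[10]
    gX[1, 10] <- gX[1, 10] + w[11]
    gX[1, 8] <- gX[1, 8] + w[12]; gX[n, 7] <- gX[n, 7] - w[12]
    gX[1, 11] <- gX[1, 11] + w[13]; gX[n, 10] <- gX[n, 10] - w[13]
    gX[1, 9] <- gX[1, 9] + w[14]; gX[n, 11] <- gX[n, 11] - w[14]
    gX[1, 12] <- gX[1, 12] + w[15]
    gX
  }

  ## parameter block for the compiled kernel
  par_cpp <- list(n = n, ns = ns,
                  metric_code = match(metric, c("ncw", "ilcw", "lew")) - 1L,
                  hs = hs, pointmass = pointmass, eq7 = eq7, Tper = Tper,
                  D = D, h = h, c1 = c1, I = I, wq = wq, d = off$d,
                  lmax = off$lmax)

  ## full evaluation; gradient assembled when al (lam, sig, mu) is given -----
  eval_core_r <- function(z, al = NULL, rho_now = rho) {
    v <- unpack(z)
    X <- v$X; U <- v$U; SP <- v$SP; SM <- v$SM; q <- v$q
    gc <- geom_at(X, q)
    G <- dyn_G(X, U, gc)
    Fm <- X[, 7:11, drop = FALSE]
    i1 <- 1:(n - 1L); i2 <- 2:n
    if (hs) {
      Xm <- 0.5 * (X[i1, ] + X[i2, ]) + (h / 8) * (G[i1, ] - G[i2, ])
      Um <- 0.5 * (U[i1, , drop = FALSE] + U[i2, , drop = FALSE])
      gcm <- geom_at(Xm, q)
      Gm <- dyn_G(Xm, Um, gcm)
      Dd <- (X[i2, ] - X[i1, ]) / h - (G[i1, ] + 4 * Gm + G[i2, ]) / 6
    } else {
      Dd <- (X[i2, ] - X[i1, ]) / h - (G[i1, ] + G[i2, ]) / 2
    }
    P <- power_P(X, gc)
    ceq_s <- SP - SM - P
    bc <- bc_eval(X)
    ceq <- c(Dd, ceq_s, bc)
    ## inequalities: force only below maximum limb length; attachments above
    ## ground
    eq5 <- Fm * (gc$l - matrix(off$lmax, n, K, byrow = TRUE))
    hip_h <- -(X[, 2] + off$d[1] * gc$st)
    sh_h <- -(X[, 2] + off$d[3] * gc$st)
    cineq <- c(eq5, hip_h, sh_h)
    ## objective
    work <- 2 * Tper * sum(wq * rowSums(SP))
    rate_pen <- 2 * c1 * sum(wq * rowSums(U^2))
    p6 <- Fm[, 3] * X[, 12]
    relax <- 2 * sum(wq * rowSums(SP * SM)) + 2 * sum(wq * p6)
    if (eq7) {
      p7 <- Fm[, 3] * U[, 4]
      relax <- relax + 2 * sum(wq * p7^2)
    }
    obj <- work + rate_pen + rho_now * relax
    out <- list(obj = obj, work = work, rate_pen = rate_pen,
                relax_pen = rho_now * relax, ceq = ceq, cineq = cineq,
                P = P, eq5 = eq5, p6 = p6)
    if (is.null(al)) return(out)
    ## augmented-Lagrangian merit and gradient -------------------------------
    mu <- al$mu
    weq <- al$lam + mu * ceq
    win <- .pos(al$sig + mu * cineq)
    merit <- obj + sum(al$lam * ceq) + (mu / 2) * sum(ceq^2) +
      sum(win^2 - al$sig^2) / (2 * mu)
    gX <- matrix(0, n, 12L); gU <- matrix(0, n, K)
    gSP <- matrix(0, n, ns); gSM <- matrix(0, n, ns); gq <- c(0, 0)
    ## objective terms
    gSP <- gSP + 2 * Tper * wq
    gU <- gU + 4 * c1 * wq * U
    gSP <- gSP + rho_now * 2 * wq * SM
    gSM <- gSM + rho_now * 2 * wq * SP
    gX[, 9] <- gX[, 9] + rho_now * 2 * wq * X[, 12]
    gX[, 12] <- gX[, 12] + rho_now * 2 * wq * Fm[, 3]
    if (eq7) {
      p7 <- Fm[, 3] * U[, 4]
      gX[, 9] <- gX[, 9] + rho_now * 4 * wq * p7 * U[, 4]
      gU[, 4] <- gU[, 4] + rho_now * 4 * wq * p7 * Fm[, 3]
    }
    ## defect adjoint
    Wd <- matrix(weq[1:(12L * (n - 1L))], n - 1L, 12L)
    gX[i2, ] <- gX[i2, ] + Wd / h
    gX[i1, ] <- gX[i1, ] - Wd / h
    WG <- matrix(0, n, 12L)
    if (hs) {
      vm <- -(4 / 6) * Wd
      vj_m <- dyn_vjp(Xm, gcm, vm)
      gXm <- vj_m$gX
      gX[i1, ] <- gX[i1, ] + 0.5 * gXm
      gX[i2, ] <- gX[i2, ] + 0.5 * gXm
      gU[i1, ] <- gU[i1, ] + 0.5 * vj_m$gU
      gU[i2, ] <- gU[i2, ] + 0.5 * vj_m$gU
      gq <- gq + vj_m$gq
      WG[i1, ] <- WG[i1, ] - Wd / 6 + (h / 8) * gXm
      WG[i2, ] <- WG[i2, ] - Wd / 6 - (h / 8) * gXm
    } else {
      WG[i1, ] <- WG[i1, ] - Wd / 2
      WG[i2, ] <- WG[i2, ] - Wd / 2
    }
    vj_n <- dyn_vjp(X, gc, WG)
    gX <- gX + vj_n$gX; gU <- gU + vj_n$gU; gq <- gq + vj_n$gq
    ## slack equality adjoint
    Ws <- matrix(weq[12L * (n - 1L) + seq_len(nS)], n, ns)
    gSP <- gSP + Ws; gSM <- gSM - Ws
    pv <- power_vjp(X, gc, -Ws)
    gX <- gX + pv$gX; gq <- gq + pv$gq
    ## boundary conditions
    gX <- bc_vjp(weq[(neq - 14L):neq], gX)
    ## inequality adjoint
    W5 <- matrix(win[seq_len(5L * n)], n, K)
    gX[, 7:11] <- gX[, 7:11] + W5 * (gc$l - matrix(off$lmax, n, K, byrow = TRUE))
    wF5 <- W5 * Fm
    ch5 <- .chain_bg(gc, wF5 * gc$ux, wF5 * gc$uy)
    gX[, 1] <- gX[, 1] + ch5$gx; gX[, 2] <- gX[, 2] + ch5$gy
    gX[, 3] <- gX[, 3] + ch5$gth
    gq <- gq + c(sum(ch5$gpx[, 1:2]), sum(ch5$gpx[, 3:5]))
    w_hip <- win[5L * n + 1:n]; w_sh <- win[6L * n + 1:n]
    gX[, 2] <- gX[, 2] - w_hip - w_sh
    if (!pointmass)
      gX[, 3] <- gX[, 3] - (w_hip * off$d[1] + w_sh * off$d[3]) * gc$ct
    out$merit <- merit
    out$grad <- c(gX, gU, gSP, gSM, gq)
    out
  }

  eval_core <- if (backend == "cpp") {
    function(z, al = NULL, rho_now = rho) .eval_core_cpp(z, par_cpp, al, rho_now)
  } else eval_core_r

  ## residuals of the complementarity conditions at the nodes (post hoc)
  comp_residuals <- function(z) {
    e <- eval_core(z)
    v <- unpack(z)
    out <- c(eq5 = max(.pos(e$eq5)), eq6 = max(.pos(e$p6)),
             slack = max(v$SP * v$SM))
    if (eq7) out["eq7"] <- max(abs(v$X[, 9] * v$U[, 4]))
    out
  }

  as_trajectory <- function(z) {
    v <- unpack(z)
    feet <- data.frame(id = off$id, limb = off$limb,
                       x = as.numeric(px_of(v$q)), d = off$d,
                       lmax = off$lmax, row.names = NULL)
    gait_trajectory(tp, v$X[, 1:6], v$X[, 7:11], feet, body, task,
                    half = TRUE, controls = v$U, params = v$q)
  }

  ## diagonal curvature of the smooth objective (force-rate penalty); the
  ## work term is linear in the slacks and the relaxation terms are handled
  ## by Levenberg damping in the Newton step
  hobj_diag <- numeric(nz)
  hobj_diag[oU + seq_len(nU)] <- rep(4 * c1 * wq, K)

  structure(list(
    n = n, ns = ns, nz = nz, neq = neq, nin = nin, metric = metric,
    body = body, task = task, spec = spec, rho = rho, eq7 = eq7,
    tp = tp, h = h, wq = wq, lower = lower, upper = upper,
    hobj_diag = hobj_diag,
    pack = pack, unpack = unpack,
    objective = function(z) {
      e <- eval_core(z)
      list(total = e$obj, work = e$work, rate_penalty = e$rate_pen,
           relax_penalty = e$relax_pen)
    },
    constraints = function(z) {
      e <- eval_core(z)
      list(ceq = e$ceq, cineq = e$cineq)
    },
    merit = function(z, al) eval_core(z, al)$merit,
    merit_grad = function(z, al) eval_core(z, al)$grad,
    eval_core = eval_core,
    eval_core_r = eval_core_r,
    comp_residuals = comp_residuals,
    as_trajectory = as_trajectory),
    class = "gait_nlp")
}

#' @export
print.gait_nlp <- function(x, ...) {
  cat(sprintf(
    "Gait NLP: metric %s, %s, %d nodes (%s), %d variables, %d eq / %d ineq constraints\n",
    toupper(x$metric), x$body$variant, x$n, x$spec$collocation_rule, x$nz,
    x$neq, x$nin))
  invisible(x)
}
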