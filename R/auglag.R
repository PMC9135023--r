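## Bound-constrained augmented-Lagrangian loop used to solve one relaxation
## round of the gait NLP. Equality constraints (collocation defects, slack
## splits, boundary conditions) carry explicit multiplier estimates;
## inequality constraints (force-length complementarity, attachment heights)
## use the standard one-sided shifted quadratic. The inner bound-constrained
## subproblems are solved with L-BFGS-B on the analytic merit gradient.

## fn/gr pair sharing one evaluation of the merit core per iterate.
.make_fg <- function(nlp, al) {
  cache <- new.env(parent = emptyenv())
  ev <- function(z) {
    if (is.null(cache$z) || !identical(z, cache$z)) {
      cache$e <- nlp$eval_core(z, al)
      cache$z <- z
    }
    cache$e
  }
  list(fn = function(z) ev(z)$merit, gr = function(z) ev(z)$grad)
}

## One augmented-Lagrangian solve at the nlp's relaxation weight.
## Returns the iterate, feasibility measure and convergence information.
.auglag <- function(nlp, z0, al = NULL,
                    inner_maxit = 2000, max_outer = 8,
                    feas_tol = 1e-4, mu0 = 50, mu_max = 1e6,
                    factr = 1e3, newton_steps = 6) {
  if (is.null(al))
    al <- list(lam = numeric(nlp$neq), sig = numeric(nlp$nin), mu = mu0)
  z <- pmin(pmax(z0, nlp$lower), nlp$upper)
  viol_prev <- Inf
  inner_conv <- 1L
  viol <- Inf
  lm <- 1e-4
  for (it in seq_len(max_outer)) {
    fg <- .make_fg(nlp, al)
    res <- tryCatch(
      stats::optim(z, fn = fg$fn, gr = fg$gr, method = "L-BFGS-B",
                   lower = nlp$lower, upper = nlp$upper,
                   control = list(maxit = inner_maxit, factr = factr,
                                  lmm = 20)),
      error = function(e) e)
    if (inherits(res, "error"))
      return(list(z = z, al = al, feasible = FALSE, viol = viol,
                  inner_convergence = 99L, outer_iters = it,
                  error = conditionMessage(res)))
    z <- res$par
    if (newton_steps > 0) {
      nm <- tryCatch(.newton_merit(nlp, z, al, max_steps = newton_steps,
                                   lm = lm),
                     error = function(e) NULL)
      if (!is.null(nm)) {
        z <- nm$z
        lm <- nm$lm
      }
    }
    inner_conv <- res$convergence
    cc <- nlp$constraints(z)
    viol <- max(abs(cc$ceq), .pos(cc$cineq), 0)
    if (viol <= feas_tol) break
    al$lam <- al$lam + al$mu * cc$ceq
    al$sig <- .pos(al$sig + al$mu * cc$cineq)
    if (viol > 0.3 * viol_prev) al$mu <- min(al$mu * 5, mu_max)
    viol_prev <- min(viol_prev, viol)
  }
  list(z = z, al = al, feasible = viol <= feas_tol, viol = viol,
       inner_convergence = inner_conv, outer_iters = it, error = NULL)
}

## Damped Newton descent on the augmented-Lagrangian merit. The merit
## gradient is analytic and cheap, so the exact Hessian on the free
## coordinates is built by forward-differencing the gradient; indefiniteness
## and the C1 kinks of the one-sided penalty terms are handled by adaptive
## Levenberg damping. Variables pinned at a bound with an inward-pointing
## gradient stay fixed. Second-order steps traverse the long, ill-conditioned
## valleys of the collocation problem that defeat first-order inner solvers.
.merit_hessian <- function(nlp, z, al, free, g0, h = 1e-6) {
  idx <- which(free)
  H <- matrix(0, length(idx), length(idx))
  for (j in seq_along(idx)) {
    zp <- z
    zp[idx[j]] <- zp[idx[j]] + h
    H[, j] <- (nlp$merit_grad(zp, al)[idx] - g0[idx]) / h
  }
  (H + t(H)) / 2
}

.newton_merit <- function(nlp, z, al, max_steps = 6, lm = 1e-5,
                          gtol = 1e-7) {
  e <- nlp$eval_core(z, al)
  for (st in seq_len(max_steps)) {
    g <- e$grad
    at_lo <- z <= nlp$lower + 1e-12
    at_up <- z >= nlp$upper - 1e-12
    free <- !(at_lo & g > 0) & !(at_up & g < 0) & (nlp$upper > nlp$lower)
    gf <- g[free]
    if (max(abs(gf)) < gtol) break
    H <- .merit_hessian(nlp, z, al, free, g)
    improved <- FALSE
    for (try in 1:12) {
      d <- tryCatch(solve(H + diag(lm, nrow(H)), -gf),
                    error = function(err) NULL)
      if (!is.null(d) && sum(d * gf) < 0) {
        z_new <- z
        z_new[free] <- z_new[free] + d
        z_new <- pmin(pmax(z_new, nlp$lower), nlp$upper)
        e_new <- nlp$eval_core(z_new, al)
        if (is.finite(e_new$merit) && e_new$merit < e$merit - 1e-14) {
          z <- z_new
          e <- e_new
          lm <- max(lm / 5, 1e-10)
          improved <- TRUE
          break
        }
      }
      lm <- lm * 8
      if (lm > 1e10) break
    }
    if (!improved) break
  }
  list(z = z, lm = lm)
}

## Five-contact exclusion cleanup for the extra trailing/leading fore
## complementarity: where the trailing fore contact is loaded, the leading
## contact must be inactive, so its force and force rate are pinned to zero
## and the equality residuals re-polished on the remaining coordinates.
.enforce_exclusion <- function(nlp, z, f_tol = 1e-3) {
  n <- nlp$n
  v <- nlp$unpack(z)
  i_bad <- which(v$X[, 9] > f_tol & v$X[, 10] < 1e-2)
  if (!length(i_bad)) return(z)
  iF <- 9L * n + i_bad          # X column 10 (leading fore force)
  iU <- 12L * n + 3L * n + i_bad  # control column 4 (its rate)
  z[c(iF, iU)] <- 0
  nlp2 <- nlp
  nlp2$lower[c(iF, iU)] <- 0
  nlp2$upper[c(iF, iU)] <- 0
  z <- .polish_eq(nlp2, z)
  z
}

## Equality-constraint Jacobian products for the feasibility polish.
## J^T w via the adjoint (the merit gradient is linear in the equality
## multipliers); J v by central differencing of the residual vector.
.jac_ops <- function(nlp, z) {
  g0 <- nlp$merit_grad(z, list(lam = numeric(nlp$neq),
                               sig = numeric(nlp$nin), mu = 1e-30))
  list(
    jtw = function(w)
      nlp$merit_grad(z, list(lam = w, sig = numeric(nlp$nin),
                             mu = 1e-30)) - g0,
    jv = function(v) {
      eps <- 1e-5 / max(max(abs(v)), 1e-12)
      (nlp$constraints(z + eps * v)$ceq -
         nlp$constraints(z - eps * v)$ceq) / (2 * eps)
    })
}

## Explicit Jacobian rows of the equality constraints and a selected set of
## inequality rows, one adjoint evaluation per row (the merit gradient is
## linear in the multipliers for vanishing penalty weight).
.con_jacobian <- function(nlp, z, act = integer(0)) {
  zero_al <- list(lam = numeric(nlp$neq), sig = numeric(nlp$nin), mu = 1e-30)
  g0 <- nlp$merit_grad(z, zero_al)
  J <- matrix(0, nlp$neq + length(act), nlp$nz)
  for (i in seq_len(nlp$neq)) {
    al <- zero_al; al$lam[i] <- 1
    J[i, ] <- nlp$merit_grad(z, al) - g0
  }
  for (k in seq_along(act)) {
    al <- zero_al; al$sig[act[k]] <- 1
    J[nlp$neq + k, ] <- nlp$merit_grad(z, al) - g0
  }
  J
}

## One Gauss-Newton pass: minimum-norm correction (restricted to coordinates
## away from their bounds) driving the stacked residual rows to their targets.
## extra_rows is a matrix of additional Jacobian rows with residuals
## extra_res; row_fun recomputes the full residual at trial points.
.gn_step <- function(nlp, z, J, res, row_fun, max_gn = 6, tol = 1e-10) {
  for (gn in seq_len(max_gn)) {
    v0 <- max(abs(res))
    if (v0 <= tol) break
    free <- (z > nlp$lower + 1e-12 & z < nlp$upper - 1e-12) |
      (nlp$lower == nlp$upper)
    Jf <- J[, free, drop = FALSE]
    JJt <- tcrossprod(Jf)
    ridge <- 1e-12 * max(diag(JJt))
    w <- NULL
    for (tries in 1:6) {
      w <- tryCatch(solve(JJt + diag(ridge, nrow(JJt)), -res),
                    error = function(e) NULL)
      if (!is.null(w)) break
      ridge <- ridge * 100
    }
    if (is.null(w)) break
    x <- numeric(nlp$nz)
    x[free] <- crossprod(Jf, w)
    step <- 1
    repeat {
      z_new <- pmin(pmax(z + step * x, nlp$lower), nlp$upper)
      v1 <- max(abs(row_fun(z_new)))
      if (v1 < v0 || step < 1 / 16) break
      step <- step / 2
    }
    if (v1 >= v0) break
    z <- z_new
    res <- row_fun(z)
    J <- attr(res, "J")
  }
  z
}

## Feasibility polish. Phase one drives the equality residuals (collocation
## defects, slack splits, boundary conditions) to near round-off by exact
## minimum-norm Newton steps. Phase two repairs violated inequality rows:
## force-length complementarity violations are converted to well-conditioned
## limb-overextension rows (l - lmax, for loaded limbs) or resolved by
## clamping a negligible force to zero; attachment-height violations are
## corrected directly. Phases alternate until all residuals pass.
.polish_eq <- function(nlp, z, tol = 1e-10, tol_in = 1e-8, cycles = 3) {
  n <- nlp$n
  score <- function(zz) {
    cc <- nlp$constraints(zz)
    max(abs(cc$ceq), .pos(cc$cineq), 0)
  }
  eq_pass <- function(z) {
    row_fun <- function(zz) {
      r <- nlp$constraints(zz)$ceq
      attr(r, "J") <- .con_jacobian(nlp, zz)
      r
    }
    res <- row_fun(z)
    .gn_step(nlp, z, attr(res, "J"), as.numeric(res), row_fun, tol = tol)
  }
  z_in <- z
  z <- eq_pass(z)
  z_eq_only <- z
  for (cyc in seq_len(cycles)) {
    cc <- nlp$constraints(z)
    bad5 <- which(cc$cineq[seq_len(5L * n)] > tol_in)
    badh <- 5L * n + which(cc$cineq[(5L * n + 1L):(7L * n)] > tol_in)
    if (!length(bad5) && !length(badh)) break
    ## a limb far out of reach cannot be in contact: clamp its force to zero;
    ## a loaded limb marginally beyond maximum length keeps its force and has
    ## its geometry corrected instead
    if (length(bad5)) {
      k <- ceiling(bad5 / n); i <- bad5 - (k - 1L) * n
      zF <- (5L + k) * n + i
      lex <- cc$cineq[bad5] / pmax(z[zF], 1e-12)
      clamp <- lex > 5e-3 | z[zF] < 1e-4
      z[zF[clamp]] <- 0
      bad5 <- bad5[!clamp]
    }
    cc <- nlp$constraints(z)
    bad5 <- bad5[cc$cineq[bad5] > tol_in]
    if (length(bad5) || length(badh)) {
      act <- c(bad5, badh)
      Jall <- .con_jacobian(nlp, z, act)
      Jx <- Jall[nlp$neq + seq_along(act), , drop = FALSE]
      res_x <- cc$cineq[act] + 1e-9
      if (length(bad5)) {
        ## replace product rows by geometry rows (l - lmax) for loaded limbs
        k <- ceiling(bad5 / n); i <- bad5 - (k - 1L) * n
        zF <- (5L + k) * n + i
        for (j in seq_along(bad5)) {
          Fv <- z[zF[j]]
          lex <- cc$cineq[bad5[j]] / Fv  # l - lmax
          row <- Jx[j, ]
          row[zF[j]] <- row[zF[j]] - lex
          Jx[j, ] <- row / Fv
          res_x[j] <- lex + 1e-9
        }
      }
      row_fun <- function(zz) {
        r <- nlp$constraints(zz)$ceq
        attr(r, "J") <- NULL
        r
      }
      ## one combined correction round, then re-polish equalities
      Jc <- rbind(Jall[seq_len(nlp$neq), , drop = FALSE], Jx)
      resc <- c(cc$ceq, res_x)
      combined_fun <- function(zz) {
        c1 <- nlp$constraints(zz)
        r <- c(c1$ceq, .pos(c1$cineq[act]))
        attr(r, "J") <- Jc
        r
      }
      z <- .gn_step(nlp, z, Jc, resc, combined_fun, max_gn = 2, tol = tol)
    }
    z <- eq_pass(z)
  }
  ## never hand back something worse than the plain equality polish
  cand <- list(z, z_eq_only, z_in)
  cand[[which.min(vapply(cand, score, numeric(1)))]]
}

## Resample a decision vector onto the grid of another transcription of the
## same problem (linear interpolation of states, controls and slacks).
.resample_z <- function(z, nlp_from, nlp_to) {
  v <- nlp_from$unpack(z)
  t0 <- nlp_from$tp; t1 <- nlp_to$tp
  nlp_to$pack(list(X = .interp_cols(t0, v$X, t1),
                   U = .interp_cols(t0, v$U, t1),
                   SP = as.matrix(.interp_cols(t0, v$SP, t1)),
                   SM = as.matrix(.interp_cols(t0, v$SM, t1)),
                   q = v$q))
}
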