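## Post-processing of solved trajectories into reported quantities: gait
## diagrams (stance intervals, duty factors, phases), footfall-sequence
## classification, power traces and the cross-evaluated work table.

## Per-limb GRF magnitude series (LH, RH, LF, RF) of a full-stride trajectory.
.limb_forces <- function(traj) {
  traj <- .as_full(traj)
  limbs <- c("LH", "RH", "LF", "RF")
  out <- sapply(limbs, function(lb)
    rowSums(traj$forces[, traj$feet$limb == lb, drop = FALSE]))
  colnames(out) <- limbs
  out
}

## Stance intervals of one periodic force trace: closure of {t : F > thr},
## with gaps shorter than one grid step merged. Returns a matrix with columns
## on/off (stride fractions; off may exceed 1 for intervals wrapping the
## stride boundary).
.stance_intervals <- function(tp, f, threshold, merge_gap = NULL) {
  n <- length(tp)
  if (is.null(merge_gap)) merge_gap <- 1.5 * max(diff(tp))
  up <- f > threshold
  if (!any(up)) return(matrix(numeric(0), 0, 2))
  if (all(up)) return(matrix(c(0, 1), 1, 2))
  r <- rle(up)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(tp[starts[r$values]], tp[ends[r$values]])
  ## wrap: join a final interval touching t=1 with an initial one at t=0
  wrap <- nrow(iv) > 1L && iv[1L, 1L] <= tp[1L] + 1e-12 &&
    iv[nrow(iv), 2L] >= tp[n] - 1e-12
  if (wrap) {
    iv[nrow(iv), 2L] <- iv[1L, 2L] + 1
    iv <- iv[-1L, , drop = FALSE]
  }
  ## merge gaps shorter than one grid step
  if (nrow(iv) > 1L) {
    keep <- iv[1L, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1L] - keep[nrow(keep), 2L] < merge_gap)
        keep[nrow(keep), 2L] <- iv[i, 2L]
      else keep <- rbind(keep, iv[i, ])
    }
    iv <- keep
  }
  iv
}

#' Gait diagram
#'
#' Stance intervals, duty factors and touchdown phases of the four limbs.
#' A limb is in stance when its ground reaction force exceeds the threshold
#' (default 0.02 body weights). The left hind limb is the phase reference.
#'
#' @param traj a [gait_trajectory()] (a half cycle is mirrored first).
#' @param threshold stance threshold in body weights.
#' @return object of class \code{gait_diagram}: per-limb stance intervals,
#'   duty factors, touchdown phases relative to LH, and the support-count
#'   sequence over the stride.
#' @export
gait_diagram <- function(traj, threshold = 0.02) {
  traj <- .as_full(traj)
  lf <- .limb_forces(traj)
  tp <- traj$tp
  limbs <- colnames(lf)
  intervals <- lapply(limbs, function(lb)
    .stance_intervals(tp, lf[, lb], threshold))
  names(intervals) <- limbs
  duty <- vapply(intervals, function(iv)
    min(1, if (nrow(iv)) sum(pmin(iv[, 2], iv[, 1] + 1) - iv[, 1]) else 0),
    numeric(1))
  touchdown <- vapply(intervals, function(iv) {
    if (!nrow(iv)) return(NA_real_)
    if (nrow(iv) == 1L && iv[1, 1] <= tp[1] + 1e-12 && iv[1, 2] >= 1 - 1e-12)
      return(0)  # always in stance
    iv[which.max(iv[, 2] - iv[, 1]), 1L] %% 1
  }, numeric(1))
  phase <- (touchdown - touchdown["LH"]) %% 1
  support <- rowSums(lf > threshold)
  structure(list(intervals = intervals, duty = duty, phase = phase,
                 touchdown = touchdown, support = support, tp = tp,
                 threshold = threshold),
            class = "gait_diagram")
}

#' @export
print.gait_diagram <- function(x, ...) {
  cat("Gait diagram (stance threshold", x$threshold, "body weights)\n")
  for (lb in names(x$duty))
    cat(sprintf("  %-3s duty %.3f  phase %.3f\n", lb, x$duty[lb], x$phase[lb]))
  cat("  support counts:", paste(sort(unique(x$support)), collapse = "/"), "\n")
  invisible(x)
}

## Count force humps within stance: strict local maxima of the 3-point
## moving-average-smoothed trace above threshold, separated by a trough at
## least 5 percent of the peak below the smaller adjacent maximum.
.hump_count <- function(f, threshold) {
  n <- length(f)
  if (n < 3L || max(f) <= threshold) return(0L)
  fs <- stats::filter(f, rep(1 / 3, 3), sides = 2, circular = TRUE)
  fs <- as.numeric(fs)
  pk <- which(diff(sign(diff(fs))) < 0) + 1L
  pk <- pk[fs[pk] > threshold]
  if (!length(pk)) return(if (max(fs) > threshold) 1L else 0L)
  ## merge peaks not separated by a sufficient trough
  keep <- pk[1L]
  for (i in seq_along(pk)[-1L]) {
    seg <- fs[keep[length(keep)]:pk[i]]
    lo <- min(seg)
    if (lo < (1 - 0.05) * min(fs[keep[length(keep)]], fs[pk[i]]))
      keep <- c(keep, pk[i])
    else if (fs[pk[i]] > fs[keep[length(keep)]])
      keep[length(keep)] <- pk[i]
  }
  length(keep)
}

#' Classify the footfall pattern
#'
#' Labels a solved gait by its stance structure: \code{compliant_high_duty}
#' (duty factors above 0.8 on all limbs with single-hump GRFs),
#' \code{single_stance_vaulting} (periods with exactly one limb in stance),
#' \code{four_beat_singlefoot} (four distinct touchdowns, support counts
#' alternating between 2 and 3, duty factors in [0.45, 0.75]), or
#' \code{other}. The planar model cannot distinguish lateral- from
#' diagonal-sequence walks, so the label is left/right agnostic.
#'
#' @param diagram a [gait_diagram()].
#' @param traj the trajectory the diagram came from (for hump counting).
#' @return list with \code{label}, per-limb \code{humps} and the feature set
#'   used.
#' @export
classify_gait <- function(diagram, traj) {
  stopifnot(inherits(diagram, "gait_diagram"))
  lf <- .limb_forces(traj)
  humps <- vapply(colnames(lf), function(lb)
    .hump_count(lf[, lb], diagram$threshold), integer(1))
  duty <- diagram$duty
  sup <- diagram$support
  n_touch <- length(unique(round(diagram$touchdown[!is.na(diagram$touchdown)], 3)))
  features <- list(duty = duty, humps = humps,
                   support_range = range(sup), n_touchdowns = n_touch)
  label <-
    if (all(duty > 0.8) && all(humps <= 1)) "compliant_high_duty"
    else if (any(sup == 1L)) "single_stance_vaulting"
    else if (n_touch == 4L && min(sup) >= 2L && max(sup) <= 3L &&
             all(duty >= 0.45 & duty <= 0.75)) "four_beat_singlefoot"
    else "other"
  list(label = label, humps = humps, features = features)
}

#' Power traces
#'
#' Time series of Net COM Power, Net System Power and the per-limb COM and
#' extension powers over one full stride. Integrating the positive parts of
#' these traces reproduces the [work_breakdown()] entries.
#'
#' @inheritParams gait_diagram
#' @return data.frame with stride fraction \code{tp}, physical time \code{t},
#'   \code{ncp}, \code{nsp} and per-limb \code{comP_*} and \code{extP_*}
#'   columns.
#' @export
power_traces <- function(traj) {
  traj <- .as_full(traj)
  pw <- .powers(traj)
  limbs <- unique(traj$feet$limb)
  agg <- function(P) sapply(limbs, function(lb)
    rowSums(P[, traj$feet$limb == lb, drop = FALSE]))
  com <- agg(pw$p_com); ext <- agg(pw$p_ext)
  colnames(com) <- paste0("comP_", limbs)
  colnames(ext) <- paste0("extP_", limbs)
  data.frame(tp = traj$tp, t = pw$t_phys,
             ncp = rowSums(pw$p_com),
             nsp = pw$ek_dot + pw$ep_dot + pw$erot_dot,
             com, ext)
}

#' Cross-evaluated work table
#'
#' Evaluates all four work metrics and percent recovery on one solution per
#' objective, mirroring the layout of the positive-work comparison table:
#' rows NCW, NSW, ILCW, LEW and Percent Recovery; one column per optimized
#' objective. Missing solutions yield NA columns.
#'
#' @param solutions named list with elements \code{ncw}, \code{ilcw},
#'   \code{lew}, each a [gait_trajectory()] or \code{solve_report} (or
#'   \code{NULL}).
#' @param c1 force-rate coefficient for the penalty row bookkeeping.
#' @return 5 x 3 numeric matrix.
#' @export
work_table <- function(solutions, c1 = 3e-5) {
  cols <- c("ncw", "ilcw", "lew")
  out <- matrix(NA_real_, 5, 3,
                dimnames = list(c("NCW", "NSW", "ILCW", "LEW",
                                  "Percent Recovery"), toupper(cols)))
  for (j in seq_along(cols)) {
    s <- solutions[[cols[j]]]
    if (is.null(s)) next
    if (inherits(s, "solve_report")) s <- s$trajectory
    if (is.null(s)) next
    wb <- work_breakdown(s, c1 = c1)
    out[, j] <- c(wb$ncw, wb$nsw, wb$ilcw, wb$lew, wb$percent_recovery)
  }
  out
}
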