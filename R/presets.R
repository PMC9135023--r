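## Parameter presets and structured-text (YAML) configuration files.

#' Warmblood horse preset
#'
#' The adult Warmblood horse model: maximum hindlimb length 1.38 m (pes to
#' hips in standing), forelimb length and glenoacetabular distance equal to
#' the hindlimb length for the main model (an alternate preset uses the
#' empirical 1.14 m forelimb and 1.63 m GAD), COM at 0.57 GAD from the hips,
#' Murphy number 0.82, walking speed 1.6 m/s and stride time 1.16 s (stride
#' length 1.856 m). Nondimensionally U' = 0.43 and D' = 1.34.
#'
#' @param variant \code{"distributed_mass"} or \code{"point_mass"}.
#' @param alternate use the empirical forelimb length and GAD instead of the
#'   equal-lengths simplification.
#' @return list with \code{body} and \code{task} in internal units, the SI
#'   inputs (\code{body_SI}, \code{speed_SI}, \code{stride_SI}) and the
#'   force-rate coefficient \code{c1 = 3e-5}.
#' @export
horse_preset <- function(variant = c("distributed_mass", "point_mass"),
                         alternate = FALSE) {
  variant <- match.arg(variant)
  body_SI <- body_model(mass = 540, g = 9.81, l_H_max = 1.38,
                        l_F_max = if (alternate) 1.14 else 1.38,
                        gad = if (alternate) 1.63 else 1.38,
                        com_fraction = 0.57, murphy = 0.82, variant = variant)
  speed_SI <- 1.6
  stride_SI <- 1.6 * 1.16
  nd <- nondimensionalize(body_SI, speed_SI, stride_SI)
  c(nd, list(body_SI = body_SI, speed_SI = speed_SI, stride_SI = stride_SI,
             c1 = 3e-5))
}

#' Read a gait configuration file
#'
#' Reads a structured-text (YAML) configuration with sections \code{body}
#' (model parameters plus \code{units: SI} or \code{units: internal}),
#' \code{task} (\code{speed}, \code{stride}, in the body's units),
#' \code{objective}, \code{transcription} and \code{solver}.
#'
#' @param path path to the YAML file.
#' @return list with \code{body}, \code{task} (internal units),
#'   \code{metric}, \code{spec} (a [transcription_spec()]) and \code{solver}
#'   (a [solver_control()] plus \code{n_restarts} and \code{base_seed}).
#' @export
read_gait_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- cfg$body
  units <- b$units %||% "internal"
  b$units <- NULL
  body <- do.call(body_model, b)
  tk <- cfg$task
  if (identical(units, "SI")) {
    nd <- nondimensionalize(body, tk$speed, tk$stride)
    body <- nd$body; task <- nd$task
  } else {
    task <- gait_task(tk$speed, tk$stride)
  }
  metric <- cfg$objective %||% "lew"
  tr <- cfg$transcription %||% list()
  spec <- do.call(transcription_spec, tr)
  sv <- cfg$solver %||% list()
  n_restarts <- sv$n_restarts %||% 10L
  base_seed <- sv$base_seed %||% 1L
  sv$n_restarts <- NULL; sv$base_seed <- NULL
  control <- do.call(solver_control, sv)
  list(body = body, task = task, metric = metric, spec = spec,
       control = control, n_restarts = n_restarts, base_seed = base_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
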