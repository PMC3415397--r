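#' @title Arbitrary-precision zero-crossing detection
#' @description
#' Events are scalar guard functions of state, parameters and time. On every
#' accepted solver step the guard is sampled on `M` equispaced points of the
#' dense-output interpolant; each sign change whose direction matches the
#' event declaration yields a bracket, refined to the event's time tolerance
#' by safeguarded root finding (Brent). Non-terminal events are pure
#' observations and never alter the trajectory.
#' @name events
NULL

event_g_fun <- function(ev, compiled) {
  fn <- compiled$event_funs[[ev$name]]
  if (is.null(fn)) {
    # event not declared on the model (e.g. standalone use): compile now
    md <- compiled$model
    md$events <- list(ev)
    fn <- compile_model(md)$event_funs[[ev$name]]
  }
  fn
}

#' Scan one solver step for guard sign changes
#'
#' @param ev An [event_definition()].
#' @param step A step record with dense-output data.
#' @param model A [compile_model()] result (or model definition).
#' @param M Number of equispaced sub-intervals to scan (default 20).
#' @param suppress_left Drop a crossing beginning at the step's initial
#'   sub-sample (used for first-step suppression after a reset lands exactly
#'   on a guard).
#' @return List of brackets, each `list(t_lo, t_hi, g_lo, g_hi, direction)`,
#'   in time order. Multiple crossings in one step are all returned.
#' @export
detect_crossings <- function(ev, step, model, M = 20L, suppress_left = FALSE) {
  compiled <- if (inherits(model, "compiled_model")) model else compile_model(model)
  gf <- event_g_fun(ev, compiled)
  ts <- seq(step$t0, step$t1, length.out = M + 1L)
  gs <- vapply(ts, function(tt) gf(tt, dense_eval(step, tt)), numeric(1))
  if (any(!is.finite(gs)))
    stop("detect_crossings: event '", ev$name,
         "' evaluated non-finite within step [", step$t0, ", ", step$t1, "]")
  out <- list()
  for (i in seq_len(M)) {
    gl <- gs[i]; gr <- gs[i + 1L]
    if (gl == 0 && gr == 0) next
    if (gl == 0) {
      # exact root at a sub-sample: degenerate bracket; a root exactly at
      # the step's start belongs to the previous step and is not reported
      dir <- sign(gr)
      if (ev$direction != 0 && dir != ev$direction) next
      if (i == 1L) next
      out[[length(out) + 1L]] <- list(t_lo = ts[i], t_hi = ts[i],
                                      g_lo = 0, g_hi = 0, direction = dir)
      next
    }
    if (gr == 0 && i == M) {
      # exact root at the step's end
      dir <- sign(-gl)
      if (ev$direction != 0 && dir != ev$direction) next
      out[[length(out) + 1L]] <- list(t_lo = ts[i + 1L], t_hi = ts[i + 1L],
                                      g_lo = 0, g_hi = 0, direction = dir)
      next
    }
    if (gl * gr < 0) {
      dir <- if (gr > gl) 1 else -1
      if (ev$direction != 0 && dir != ev$direction) next
      if (i == 1L && suppress_left) next
      out[[length(out) + 1L]] <- list(t_lo = ts[i], t_hi = ts[i + 1L],
                                      g_lo = gl, g_hi = gr, direction = dir)
    }
  }
  out
}

#' Refine a bracketed event crossing to its time tolerance
#'
#' @param ev The [event_definition()].
#' @param bracket A bracket from [detect_crossings()] (guard signs must
#'   differ at its ends).
#' @param step The step record that produced it.
#' @param model Compiled model (or model definition).
#' @return An event occurrence: `event_name`, `t_star`, `state_at` (full
#'   named state from dense output), `gval` (guard residual at `t_star`),
#'   `direction_observed`.
#' @export
refine_event_time <- function(ev, bracket, step, model) {
  compiled <- if (inherits(model, "compiled_model")) model else compile_model(model)
  gf <- event_g_fun(ev, compiled)
  f <- function(tt) gf(tt, dense_eval(step, tt))
  if (bracket$t_lo == bracket$t_hi) {
    t_star <- bracket$t_lo
  } else {
    if (sign(bracket$g_lo) * sign(bracket$g_hi) >= 0)
      stop("refine_event_time: bracket for '", ev$name,
           "' has no sign change")
    t_star <- stats::uniroot(f, c(bracket$t_lo, bracket$t_hi),
                             f.lower = bracket$g_lo, f.upper = bracket$g_hi,
                             tol = ev$tol_t / 2, maxiter = 1000L)$root
  }
  y_star <- dense_eval(step, t_star)
  structure(list(event_name = ev$name, t_star = t_star,
                 state_at = full_state(compiled, t_star, y_star),
                 gval = f(t_star), direction_observed = bracket$direction),
            class = "event_occurrence")
}
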