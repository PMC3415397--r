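#' @title Adaptive ODE integration with dense output
#' @description
#' A Dormand-Prince 5(4) embedded Runge-Kutta integrator with
#' proportional-integral step-size control. Each accepted step stores the
#' endpoint states and derivatives, giving a cubic Hermite dense-output
#' interpolant used both for trajectory evaluation and for
#' arbitrary-precision event localization. Algebraic variables are computed
#' by substitution at every evaluation; frozen (dummy) variables are carried
#' as constants so every trajectory reports the model's full state.
#' @name integrate
NULL

# Dormand-Prince 5(4) tableau
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_a <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_e <- c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40)

default_ode_opts <- function(span) {
  list(rtol = 1e-8, atol = 1e-10, h0 = 1e-4 * span, max_steps = 1e6,
       safety = 0.9, fac_min = 0.2, fac_max = 5, subsamples = 20L,
       event_residual_tol = 1e-9)
}

step_record <- function(t0, t1, y0, y1, f0, f1) {
  structure(list(t0 = t0, t1 = t1, y0 = y0, y1 = y1, f0 = f0, f1 = f1),
            class = "step_record")
}

#' Dense-output evaluation inside one accepted step
#'
#' Cubic Hermite interpolant from the step's endpoint states and
#' derivatives; exact at the endpoints, O(h^4) accurate in between for
#' smooth solutions.
#'
#' @param step A step record from [integrate_ode()] (`$steps`).
#' @param t Time within `[step$t0, step$t1]`.
#' @return Numeric state vector at `t`.
#' @export
dense_eval <- function(step, t) {
  if (t < step$t0 - 1e-12 || t > step$t1 + 1e-12)
    stop("dense_eval: t=", t, " outside step [", step$t0, ", ", step$t1, "]")
  if (t <= step$t0) return(step$y0)
  if (t >= step$t1) return(step$y1)
  hermite_interp(t, step$t0, step$t1, step$y0, step$y1, step$f0, step$f1)
}

# growable sample accumulator
new_accum <- function(n_cols) {
  env <- new.env(parent = emptyenv())
  env$t <- numeric(256L); env$v <- matrix(0, 256L, n_cols)
  env$d <- matrix(0, 256L, n_cols); env$n <- 0L
  env
}
accum_push <- function(acc, t, v, d) {
  n <- acc$n + 1L
  if (n > length(acc$t)) {
    acc$t <- c(acc$t, numeric(length(acc$t)))
    acc$v <- rbind(acc$v, matrix(0, nrow(acc$v), ncol(acc$v)))
    acc$d <- rbind(acc$d, matrix(0, nrow(acc$d), ncol(acc$d)))
  }
  acc$t[n] <- t; acc$v[n, ] <- v; acc$d[n, ] <- d; acc$n <- n
  invisible(acc)
}

# full state row + its derivative row at (t, y, f)
state_row <- function(compiled, t, y, f) {
  md <- compiled$model
  v <- as.numeric(y); d <- as.numeric(f)
  if (!is.null(compiled$alg)) {
    v <- c(v, as.numeric(compiled$alg(t, y)))
    d <- c(d, as.numeric(compiled$alg_deriv(t, y, f)))
  }
  if (length(md$frozen)) {
    v <- c(v, vapply(md$frozen, function(fz) get(fz, envir = compiled$env),
                     numeric(1)))
    d <- c(d, rep(0, length(md$frozen)))
  }
  list(v = v, d = d)
}

#' Integrate a model's ODEs over a time span
#'
#' Adaptive embedded Runge-Kutta of order 5(4) with PI step control. All
#' declared events are checked on every accepted step over the dense-output
#' interpolant; a terminal event stops integration at the localized event
#' time. State-domain membership is checked at accepted steps; violation
#' raises an error naming the variable. Step-size underflow raises a
#' stiffness error.
#'
#' @param model A [model_definition()] or [compile_model()] result.
#' @param ic Named numeric / [point()] binding every dynamic (and frozen)
#'   state variable.
#' @param tspan An [interval()] or numeric `c(t0, t1)`.
#' @param opts List of options: `rtol` (1e-8), `atol` (1e-10), `h0`
#'   (1e-4 x span), `max_steps` (1e6), `safety` (0.9), `fac_min`/`fac_max`
#'   (0.2/5), `subsamples` (20, event-scan resolution per step),
#'   `event_residual_tol` (1e-9, initial-time suppression threshold).
#' @return Object of class `"integration_result"`: `trajectory` (full state,
#'   Hermite-interpolable, with event labels), `steps` (step records),
#'   `events_hit` (list of event occurrences), `terminated_by` (`"none"`,
#'   an event name, `"t_end"`, or `"step-limit"`).
#' @export
integrate_ode <- function(model, ic, tspan, opts = list()) {
  compiled <- if (inherits(model, "compiled_model")) model else compile_model(model)
  md <- compiled$model
  if (is_interval(tspan)) tspan <- c(tspan$lo, tspan$hi)
  t0 <- tspan[1L]; t_end <- tspan[2L]
  span <- t_end - t0
  stopifnot(span > 0)
  o <- utils::modifyList(default_ode_opts(span), opts)

  ic <- unclass(ic)
  missing_ic <- setdiff(c(md$vars, md$frozen), names(ic))
  if (length(missing_ic))
    stop("integrate_ode: initial condition missing variable(s): ",
         paste(missing_ic, collapse = ", "))
  if (length(md$frozen)) set_frozen(compiled, ic[md$frozen])
  y <- as.numeric(ic[md$vars])
  check_domains <- function(t, y) {
    for (i in seq_along(md$vars)) {
      dv <- md$domains[[md$vars[i]]]
      if (!is.null(dv) && !interval_query(dv, y[i], "contains"))
        stop("integrate_ode: variable '", md$vars[i], "' left its domain [",
             dv$lo, ", ", dv$hi, "] at t=", t, " (value ", y[i], ")")
    }
  }
  check_domains(t0, y)

  all_names <- model_state_names(md)
  acc <- new_accum(length(all_names))
  f <- compiled$deriv(t0, y)
  if (!all(is.finite(f)))
    stop("integrate_ode: non-finite right-hand side at initial condition")
  sr0 <- state_row(compiled, t0, y, f)
  accum_push(acc, t0, sr0$v, sr0$d)

  events <- md$events
  n_ev <- length(events)
  ev_funs <- compiled$event_funs
  # initial-time suppression: an event already at its guard (within residual
  # tolerance) is ignored for the first accepted step
  suppress <- logical(n_ev)
  if (n_ev) {
    for (j in seq_len(n_ev)) {
      g0 <- ev_funs[[j]](t0, y)
      if (!is.finite(g0))
        stop("integrate_ode: event '", events[[j]]$name,
             "' non-finite at initial state")
      suppress[j] <- abs(g0) <= o$event_residual_tol
    }
  }

  steps <- vector("list", 256L); n_steps <- 0L
  events_hit <- list()
  labels <- list()
  terminated_by <- "t_end"
  t <- t0
  h <- min(o$h0, span)
  errold <- 1e-4
  n_acc <- 0L

  push_sample <- function(tt, yy, ff) {
    sr <- state_row(compiled, tt, yy, ff)
    accum_push(acc, tt, sr$v, sr$d)
  }

  while (t < t_end - 1e-14 * max(1, abs(t_end))) {
    if (n_steps >= o$max_steps) { terminated_by <- "step-limit"; break }
    h <- min(h, t_end - t)
    if (h < 1e-14 * max(1, abs(t)))
      stop("integrate_ode: stiffness error: step size underflow at t=", t)
    k <- matrix(0, length(y), 7L)
    k[, 1L] <- f
    ok <- TRUE
    for (s in 2L:6L) {
      ys <- y + h * as.numeric(k[, seq_len(s - 1L), drop = FALSE] %*% .dp_a[[s - 1L]])
      ks <- compiled$deriv(t + .dp_c[s] * h, ys)
      if (!all(is.finite(ks))) { ok <- FALSE; break }
      k[, s] <- ks
    }
    if (ok) {
      ynew <- y + h * as.numeric(k[, 1L:6L, drop = FALSE] %*% .dp_a[[6L]])
      fnew <- compiled$deriv(t + h, ynew)
      ok <- all(is.finite(fnew)) && all(is.finite(ynew))
      k[, 7L] <- fnew
    }
    if (!ok) { h <- h / 2; n_steps <- n_steps + 1L; next }
    sc <- o$atol + o$rtol * pmax(abs(y), abs(ynew))
    err_vec <- h * as.numeric(k %*% .dp_e)
    err <- sqrt(mean((err_vec / sc)^2))
    n_steps <- n_steps + 1L
    if (!is.finite(err)) { h <- h / 2; next }
    if (err > 1) {
      h <- h * max(o$fac_min, min(1, o$safety * err^(-0.2)))
      next
    }
    # accepted
    step <- step_record(t, t + h, y, ynew, f, fnew)
    stop_here <- FALSE
    if (n_ev) {
      occs <- list()
      for (j in seq_len(n_ev)) {
        brs <- detect_crossings(events[[j]], step, compiled,
                                M = o$subsamples,
                                suppress_left = (n_acc == 0L && suppress[j]))
        for (br in brs) {
          occ <- refine_event_time(events[[j]], br, step, compiled)
          occ$index <- j
          occs[[length(occs) + 1L]] <- occ
        }
      }
      if (length(occs)) {
        ord <- order(vapply(occs, `[[`, numeric(1), "t_star"),
                     vapply(occs, `[[`, numeric(1), "index"))
        occs <- occs[ord]
        term_i <- which(vapply(occs, function(oc)
          events[[oc$index]]$terminal, logical(1)))
        t_cut <- if (length(term_i)) occs[[term_i[1L]]]$t_star else Inf
        for (oc in occs) {
          if (oc$t_star > t_cut) break
          is_term <- events[[oc$index]]$terminal && oc$t_star == t_cut
          # non-terminal events are pure observations: the trajectory is not
          # altered, labels map to the nearest stored sample row
          labels[[oc$event_name]] <- c(labels[[oc$event_name]], oc$t_star)
          events_hit[[length(events_hit) + 1L]] <- oc
          if (is_term) {
            y_star <- dense_eval(step, oc$t_star)
            f_star <- compiled$deriv(oc$t_star, y_star)
            step$t1 <- oc$t_star; step$y1 <- y_star; step$f1 <- f_star
            if (oc$t_star > acc$t[acc$n]) push_sample(oc$t_star, y_star, f_star)
            terminated_by <- oc$event_name
            stop_here <- TRUE
            break
          }
        }
      }
    }
    n_acc <- n_acc + 1L
    if (n_acc > length(steps)) steps <- c(steps, vector("list", length(steps)))
    steps[[n_acc]] <- step
    if (!stop_here && step$t1 > acc$t[acc$n])
      push_sample(step$t1, step$y1, step$f1)
    check_domains(step$t1, step$y1)
    if (stop_here) break
    t <- step$t1; y <- step$y1; f <- step$f1
    fac <- o$safety * err^(-0.17) * errold^(0.04)
    h <- h * max(o$fac_min, min(o$fac_max, fac))
    errold <- max(err, 1e-10)
  }

  times <- acc$t[seq_len(acc$n)]
  vals <- acc$v[seq_len(acc$n), , drop = FALSE]
  dvs <- acc$d[seq_len(acc$n), , drop = FALSE]
  colnames(vals) <- colnames(dvs) <- all_names
  # de-duplicate exactly-equal consecutive times (event at step end)
  keep <- c(TRUE, diff(times) > 0)
  times_k <- times[keep]
  # event labels: map recorded occurrence times to sample rows
  row_labels <- lapply(labels, function(tt)
    vapply(tt, function(t1) which.min(abs(times_k - t1)), integer(1)))
  traj <- trajectory(times_k, vals[keep, , drop = FALSE], all_names,
                     derivs = dvs[keep, , drop = FALSE], interp = "hermite",
                     labels = row_labels)
  structure(list(trajectory = traj, steps = steps[seq_len(n_acc)],
                 events_hit = events_hit, terminated_by = terminated_by,
                 n_steps = n_steps, opts = o),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat("Integration result: ", length(x$steps), " steps on [",
      x$trajectory$domain$lo, ", ", x$trajectory$domain$hi,
      "], terminated by ", x$terminated_by, ", ",
      length(x$events_hit), " event occurrence(s)\n", sep = "")
  invisible(x)
}

#' Write the event log of an integration or hybrid run to CSV
#' @param events_hit List of event occurrences.
#' @param path CSV path (columns: name, t, then state variables).
#' @export
write_event_log <- function(events_hit, path) {
  if (!length(events_hit)) {
    utils::write.csv(data.frame(name = character(0), t = numeric(0)), path,
                     row.names = FALSE)
    return(invisible(path))
  }
  states <- do.call(rbind, lapply(events_hit, function(oc)
    as.data.frame(t(oc$state_at))))
  df <- cbind(data.frame(
    name = vapply(events_hit, `[[`, character(1), "event_name"),
    t = vapply(events_hit, `[[`, numeric(1), "t_star")), states)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
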