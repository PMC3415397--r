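#' Parameterized evaluable curves
#'
#' A trajectory wraps time-stamped samples (and, when available, their time
#' derivatives) behind a transparent layer of domain checking and
#' interpolation, so that numerically computed data can be treated as a
#' continuous curve. Interpolation is cubic Hermite when derivatives are
#' stored (always true for ODE output), linear otherwise.
#'
#' @param times Strictly increasing numeric vector of sample times.
#' @param values Numeric matrix, one row per time, named columns.
#' @param names Optional column names (defaults to `colnames(values)`).
#' @param derivs Optional matrix of time derivatives matching `values`.
#' @param interp `"hermite"` or `"linear"`; default picks Hermite iff
#'   `derivs` is supplied.
#' @param labels Optional labels, as in [pointset()].
#' @param tol Endpoint tolerance for the time domain.
#' @return Object of class `"trajectory"` with fields `domain` (an
#'   [interval()]), `names`, `samples` (a [pointset()]), `deriv_samples`,
#'   `interp_kind`.
#' @export
trajectory <- function(times, values, names = NULL, derivs = NULL,
                       interp = NULL, labels = list(), tol = 1e-12) {
  values <- as.matrix(values)
  ps <- pointset(values, names, indep = times, labels = labels)
  if (!is.null(derivs)) {
    derivs <- as.matrix(derivs)
    if (!all(dim(derivs) == dim(ps$values)))
      stop("trajectory: derivs dimensions must match values")
  }
  if (is.null(interp)) interp <- if (is.null(derivs)) "linear" else "hermite"
  interp <- match.arg(interp, c("linear", "hermite"))
  if (interp == "hermite" && is.null(derivs))
    stop("trajectory: hermite interpolation requires derivs")
  structure(list(domain = interval(times[1L], times[length(times)], tol = tol),
                 names = ps$names, samples = ps, deriv_samples = derivs,
                 interp_kind = interp),
            class = "trajectory")
}

is_trajectory <- function(x) inherits(x, "trajectory")

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory on [", x$domain$lo, ", ", x$domain$hi, "]: ",
      nrow(x$samples$values), " samples of (",
      paste(x$names, collapse = ", "), "), ", x$interp_kind,
      " interpolation\n", sep = "")
  invisible(x)
}

# scalar cubic Hermite over [t0,t1] for row vectors y0,y1 and slopes f0,f1
hermite_interp <- function(t, t0, t1, y0, y1, f0, f1) {
  h <- t1 - t0
  s <- (t - t0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y0 + h * h10 * f0 + h01 * y1 + h * h11 * f1
}

#' Evaluate a trajectory at one or more times
#'
#' Returns exact stored values at sample times; interpolates between them.
#' Times outside the domain (beyond its endpoint tolerance) raise a domain
#' error reporting the bounds.
#'
#' @param traj A [trajectory()].
#' @param t Numeric vector of times.
#' @param names Optional subset of variable names to return.
#' @return For a single time, a [point()]; for several, a matrix with one row
#'   per time.
#' @export
traj_eval <- function(traj, t, names = NULL) {
  stopifnot(is_trajectory(traj))
  sel <- traj$names
  if (!is.null(names)) {
    missing_n <- setdiff(names, traj$names)
    if (length(missing_n))
      stop("traj_eval: unknown variable(s): ", paste(missing_n, collapse = ", "))
    sel <- names
  }
  tt <- traj$samples$indep
  dom <- traj$domain
  bad <- t < dom$lo - dom$tol | t > dom$hi + dom$tol
  if (any(bad))
    stop("traj_eval: t=", t[which(bad)[1L]], " outside domain [",
         dom$lo, ", ", dom$hi, "]")
  t <- pmin(pmax(t, dom$lo), dom$hi)
  vals <- traj$samples$values[, sel, drop = FALSE]
  out <- matrix(NA_real_, length(t), length(sel), dimnames = list(NULL, sel))
  idx <- findInterval(t, tt, rightmost.closed = TRUE)
  exact <- t == tt[idx]
  if (any(exact)) out[exact, ] <- vals[idx[exact], , drop = FALSE]
  rest <- which(!exact)
  if (length(rest)) {
    if (traj$interp_kind == "hermite") {
      dv <- traj$deriv_samples[, sel, drop = FALSE]
      for (k in rest) {
        i <- idx[k]
        out[k, ] <- hermite_interp(t[k], tt[i], tt[i + 1L],
                                   vals[i, ], vals[i + 1L, ],
                                   dv[i, ], dv[i + 1L, ])
      }
    } else {
      for (k in rest) {
        i <- idx[k]
        s <- (t[k] - tt[i]) / (tt[i + 1L] - tt[i])
        out[k, ] <- (1 - s) * vals[i, ] + s * vals[i + 1L, ]
      }
    }
  }
  if (length(t) == 1L) point(stats::setNames(out[1L, ], sel)) else out
}

#' Serialize a trajectory to CSV (with labels sidecar)
#' @param traj A trajectory.
#' @param path CSV path; derivative columns are not serialized.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_pointset_csv(traj$samples, path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  ps <- read_pointset_csv(path)
  if (is.null(ps$indep)) stop("read_trajectory_csv: no 't' column in ", path)
  trajectory(ps$indep, ps$values, ps$names, labels = ps$labels)
}
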