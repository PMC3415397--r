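#' @title Model interfaces: validation features, conditions, recovery
#' @description
#' A model interface wraps a (hybrid or non-hybrid) model with optional
#' pre-simulation hooks (input validation / transformation of the request),
#' post-simulation hooks (filtering or transforming the output), a condition
#' (a set of features with target truth values) evaluated against the run,
#' and failure recovery: if the simulation raises (stiffness, domain
#' violation, dead end), a sentinel objective value is returned instead of an
#' error, which makes models safe to embed in optimization loops. Hooks are
#' pure transformations of copies; the wrapped model is never mutated. A
#' neutral interface (no hooks, no condition) is observationally equivalent
#' to the bare model.
#' @name interfaces
NULL

#' Define a validation feature
#'
#' @param name Feature name.
#' @param measure Function `(traj, ref) -> value` (pure; must not mutate its
#'   inputs).
#' @param compare Predicate `(value) -> logical` turning the measurement into
#'   a truth value. Default: `isTRUE(value)`.
#' @return Object of class `"mi_feature"`.
#' @export
feature <- function(name, measure, compare = NULL) {
  if (is.null(compare)) compare <- function(v) isTRUE(v)
  structure(list(name = name, measure = measure, compare = compare),
            class = "mi_feature")
}

#' Define a condition: features plus target truth values
#' @param features List of [feature()]s.
#' @param targets Logical vector (recycled) of required truth values, one per
#'   feature; the condition is satisfied iff every feature's comparison
#'   equals its target.
#' @return Object of class `"mi_condition"`.
#' @export
condition <- function(features, targets = TRUE) {
  targets <- rep_len(as.logical(targets), length(features))
  structure(list(features = features, targets = targets),
            class = "mi_condition")
}

#' Evaluate a condition against a trajectory
#'
#' Every feature is evaluated independently and reported even after a
#' failure (no short-circuit), so diagnostics are complete; a feature raising
#' an internal error is marked failed with an error note rather than
#' aborting the report.
#'
#' @param cond A [condition()].
#' @param traj A trajectory or hybrid trajectory.
#' @param ref Optional reference data passed to each feature's measure.
#' @return A `"condition_report"`: data frame `table` (feature, value, truth,
#'   target, pass, note), `overall`, `recovery_invoked`, `sentinel`.
#' @export
evaluate_condition <- function(cond, traj, ref = NULL) {
  rows <- lapply(seq_along(cond$features), function(i) {
    ft <- cond$features[[i]]
    target <- cond$targets[[i]]
    val <- NA_real_; truth <- NA; note <- ""
    ok <- tryCatch({
      val <- ft$measure(traj, ref)
      truth <- isTRUE(ft$compare(val))
      TRUE
    }, error = function(e) { note <<- conditionMessage(e); FALSE })
    pass <- ok && identical(truth, target)
    data.frame(feature = ft$name,
               value = if (is.numeric(val)) as.numeric(val) else NA_real_,
               truth = if (ok) truth else NA, target = target, pass = pass,
               note = note, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  structure(list(table = table, overall = all(table$pass),
                 recovery_invoked = FALSE, sentinel = NULL),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat("Condition report: overall ", if (x$overall) "PASS" else "FAIL",
      if (x$recovery_invoked) " (recovery invoked)", "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize a condition report to CSV (truth table) or text
#' @param report A condition report.
#' @param path Output path.
#' @export
write_condition_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}

#' Wrap a model in a model interface
#'
#' @param model A [model_definition()] or [hybrid_model()].
#' @param pre Optional function `(request) -> request` run before
#'   simulation; `request` has fields `ic`, `t_end`, `opts`.
#' @param post Optional function `(traj) -> traj` run on a copy of the
#'   output.
#' @param cond Optional [condition()].
#' @param sentinel Objective value returned on failure recovery (default
#'   `1e10`; set negative for maximization problems).
#' @param recover If `TRUE` (default), simulation errors are caught and the
#'   sentinel is returned instead.
#' @return Object of class `"model_interface"`.
#' @export
model_interface <- function(model, pre = NULL, post = NULL, cond = NULL,
                            sentinel = 1e10, recover = TRUE) {
  structure(list(model = model, pre = pre, post = post, cond = cond,
                 sentinel = sentinel, recover = isTRUE(recover)),
            class = "model_interface")
}

#' Run a wrapped model with validation and failure recovery
#'
#' @param mi A [model_interface()].
#' @param ic Initial condition (full state).
#' @param t_end End time.
#' @param opts Integration options.
#' @param objective Optional [feature()] whose measured value is returned as
#'   the objective.
#' @param ref Reference data for condition/objective features.
#' @return `list(result, report, objective_value)`. On recovery, `result` is
#'   `NULL`, `objective_value` is the sentinel and
#'   `report$recovery_invoked` is `TRUE` (the sentinel is returned iff
#'   recovery was invoked).
#' @export
run_with_validation <- function(mi, ic, t_end, opts = list(),
                                objective = NULL, ref = NULL) {
  request <- list(ic = ic, t_end = t_end, opts = opts)
  if (!is.null(mi$pre)) request <- mi$pre(request)
  run_one <- function() {
    if (is_hybrid_model(mi$model)) {
      simulate_hybrid(mi$model, request$ic, request$t_end, opts = request$opts)
    } else {
      integrate_ode(mi$model, request$ic,
                    c(0, request$t_end), request$opts)$trajectory
    }
  }
  result <- if (mi$recover) {
    tryCatch(run_one(), error = function(e) structure(
      list(message = conditionMessage(e)), class = "mi_failure"))
  } else run_one()
  if (inherits(result, "mi_failure")) {
    report <- structure(list(
      table = data.frame(feature = character(0), value = numeric(0),
                         truth = logical(0), target = logical(0),
                         pass = logical(0), note = character(0)),
      overall = FALSE, recovery_invoked = TRUE, sentinel = mi$sentinel,
      failure = result$message), class = "condition_report")
    return(list(result = NULL, report = report,
                objective_value = mi$sentinel))
  }
  if (!is.null(mi$post)) result <- mi$post(result)
  report <- if (!is.null(mi$cond)) evaluate_condition(mi$cond, result, ref)
            else structure(list(table = NULL, overall = TRUE,
                                recovery_invoked = FALSE, sentinel = NULL),
                           class = "condition_report")
  obj <- if (!is.null(objective)) objective$measure(result, ref) else NULL
  list(result = result, report = report, objective_value = obj)
}

## ---- built-in feature library -------------------------------------------

# upward (direction=+1) or downward crossings of `level` by variable `var`,
# refined on the trajectory interpolant
trajectory_crossings <- function(traj, var, level, direction = 1) {
  if (is_hybrid_trajectory(traj)) {
    out <- numeric(0)
    for (sg in traj$segments)
      out <- c(out, trajectory_crossings(sg$traj, var, level, direction))
    return(sort(out))
  }
  tt <- traj$samples$indep
  x <- as.numeric(traj$samples$values[, var])
  g <- x - level
  out <- numeric(0)
  for (i in seq_len(length(g) - 1L)) {
    if (g[i] == 0) next
    if (g[i] * g[i + 1L] < 0) {
      dir <- if (g[i + 1L] > g[i]) 1 else -1
      if (direction != 0 && dir != direction) next
      root <- stats::uniroot(function(s)
        as.numeric(traj_eval(traj, s, var)) - level,
        c(tt[i], tt[i + 1L]), tol = 1e-10)$root
      out <- c(out, root)
    }
  }
  out
}

#' Built-in feature: threshold-crossing spike count
#' @param var Variable name (default `"V"`).
#' @param level Crossing level (default `-10`).
#' @param min_count Comparison threshold: truth value is
#'   `count >= min_count`.
#' @return A [feature()].
#' @export
feature_spike_count <- function(var = "V", level = -10, min_count = 1) {
  feature(paste0("spike_count(", var, ">", level, ")"),
          measure = function(traj, ref)
            length(trajectory_crossings(traj, var, level, 1)),
          compare = function(v) v >= min_count)
}

#' Built-in feature: period of regular firing
#' @param var,level Spike-detection crossing.
#' @param settle_fraction Fraction of the record discarded as transient.
#' @param target_period,rel_tol Comparison: truth is
#'   `|period - target_period| <= rel_tol * target_period` (skipped if
#'   `target_period` is `NULL`, then truth is `period > 0`).
#' @return A [feature()].
#' @export
feature_period_estimate <- function(var = "V", level = -10,
                                    settle_fraction = 0.3,
                                    target_period = NULL, rel_tol = 0.05) {
  feature("period_estimate",
          measure = function(traj, ref) {
            times <- trajectory_crossings(traj, var, level, 1)
            measure_period(times, settle_fraction)$period
          },
          compare = function(v) {
            if (is.null(target_period)) v > 0
            else abs(v - target_period) <= rel_tol * target_period
          })
}

#' Built-in feature: max absolute difference vs a reference trajectory
#' @param var Variable compared.
#' @param grid Common evaluation grid (numeric times); defaults to 200
#'   points over the overlap of the two domains.
#' @param tol Comparison threshold.
#' @return A [feature()]; its `ref` argument must be a trajectory.
#' @export
feature_max_abs_difference <- function(var = "V", grid = NULL, tol = 1) {
  feature(paste0("max_abs_difference(", var, ")"),
          measure = function(traj, ref) {
            stopifnot(!is.null(ref))
            ev <- function(tr, tt) {
              if (is_hybrid_trajectory(tr))
                vapply(tt, function(s) hybrid_traj_eval(tr, s)$state[[var]],
                       numeric(1))
              else as.numeric(traj_eval(tr, tt, var))
            }
            dom_lo <- max(if (is_hybrid_trajectory(traj)) traj$domain$lo else traj$domain$lo,
                          if (is_hybrid_trajectory(ref)) ref$domain$lo else ref$domain$lo)
            dom_hi <- min(if (is_hybrid_trajectory(traj)) traj$domain$hi else traj$domain$hi,
                          if (is_hybrid_trajectory(ref)) ref$domain$hi else ref$domain$hi)
            tt <- if (is.null(grid)) seq(dom_lo, dom_hi, length.out = 200L) else grid
            max(abs(ev(traj, tt) - ev(ref, tt)))
          },
          compare = function(v) v <= tol)
}

#' Built-in feature: regime sequence matches a template cycle
#' @param template A [regime_template()].
#' @return A [feature()] measuring TRUE/FALSE cyclic agreement of the
#'   hybrid trajectory's regime visit sequence with the template.
#' @export
feature_regime_sequence_match <- function(template) {
  feature("regime_sequence_match",
          measure = function(traj, ref) {
            stopifnot(is_hybrid_trajectory(traj))
            seq_ids <- vapply(traj$segments, function(sg)
              as.character(sg$regime), character(1))
            seq_ids <- seq_ids[c(TRUE, seq_ids[-1L] != seq_ids[-length(seq_ids)])]
            k <- length(template$active_sets)
            if (length(seq_ids) < k) return(FALSE)
            ids <- template$regime_ids %||%
              paste0("R", seq_len(k))
            # compare consecutive windows against rotations of the template
            win <- seq_ids[seq_len(min(length(seq_ids), 2L * k))]
            any(vapply(seq_len(k), function(r) {
              rot <- ids[((seq_len(k) + r - 2L) %% k) + 1L]
              all(win == rep_len(rot, length(win)))
            }, logical(1)))
          },
          compare = isTRUE)
}
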