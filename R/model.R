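#' Zero-crossing event declaration
#'
#' @param name Event name.
#' @param g Guard expression (tree or string) of state, parameters and `t`;
#'   the event fires when `g` crosses zero.
#' @param direction `+1` (upward), `-1` (downward) or `0` (either).
#' @param terminal If `TRUE`, the event stops trajectory generation.
#' @param tol_t Time-localization tolerance (> 0), default `1e-10`.
#' @return Object of class `"event_definition"`.
#' @export
event_definition <- function(name, g, direction = 0, terminal = FALSE,
                             tol_t = 1e-10) {
  if (is.character(g)) g <- parse_expression(g)
  stopifnot(direction %in% c(-1, 0, 1), tol_t > 0)
  structure(list(name = name, gfun = g, direction = direction,
                 terminal = isTRUE(terminal), tol_t = tol_t),
            class = "event_definition")
}

#' Auxiliary function declaration
#' @param args Character vector of formal argument names.
#' @param body Expression tree or string.
#' @return Object of class `"aux_fn"`.
#' @export
aux_fn <- function(args, body) {
  if (is.character(body)) body <- parse_expression(body)
  structure(list(args = as.character(args), body = body), class = "aux_fn")
}

#' Define a non-hybrid sub-model
#'
#' A model definition holds dynamic state variables with optional domain
#' intervals, parameters, symbolic right-hand sides, algebraic variables
#' (defined by substitution — the DAE-by-substitution mechanism), frozen
#' (dummy-constant) variables, auxiliary functions, events, and external
#' input time series. Every symbol appearing in any expression must be a
#' state name, parameter, auxiliary function, external input, or time `t`;
#' unhoused symbols are a validation error.
#'
#' @param name Model name.
#' @param vars Character vector of dynamic state names (order defines the
#'   state vector).
#' @param rhs Named list of expressions (one per element of `vars`).
#' @param params Named numeric vector of parameters.
#' @param algebraic Named list of expressions for algebraic variables.
#' @param frozen Character vector of dummy-constant variable names (values
#'   supplied with the initial condition and held fixed).
#' @param aux_fns Named list of [aux_fn()] objects.
#' @param events List of [event_definition()] objects.
#' @param domains Named list of [interval()] domains for state variables.
#' @param external_inputs Named list of two-column (t, value) matrices or
#'   data frames, played back with linear interpolation.
#' @return Object of class `"model_definition"`.
#' @export
model_definition <- function(name, vars, rhs, params = numeric(0),
                             algebraic = list(), frozen = character(0),
                             aux_fns = list(), events = list(),
                             domains = list(), external_inputs = list()) {
  vars <- as.character(vars)
  rhs <- lapply(rhs, function(e) if (is.character(e)) parse_expression(e) else e)
  algebraic <- lapply(algebraic, function(e) if (is.character(e)) parse_expression(e) else e)
  md <- structure(list(name = name, vars = vars, rhs = rhs,
                       params = unlist(params) %||% numeric(0),
                       algebraic = algebraic, frozen = as.character(frozen),
                       aux_fns = aux_fns, events = events, domains = domains,
                       external_inputs = external_inputs),
                  class = "model_definition")
  validate_model(md)
  md
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_model <- function(x) inherits(x, "model_definition")

#' @export
print.model_definition <- function(x, ...) {
  cat("Model '", x$name, "': ", length(x$vars), " dynamic (",
      paste(x$vars, collapse = ", "), ")", sep = "")
  if (length(x$algebraic)) cat(", algebraic:", paste(names(x$algebraic), collapse = ", "))
  if (length(x$frozen)) cat(", frozen:", paste(x$frozen, collapse = ", "))
  cat("; ", length(x$events), " events\n", sep = "")
  invisible(x)
}

#' All state names formally exposed by a model
#' @param model A model definition.
#' @return Character vector: dynamic, algebraic, then frozen names.
#' @export
model_state_names <- function(model) {
  c(model$vars, names(model$algebraic), model$frozen)
}

validate_model <- function(md) {
  if (!setequal(names(md$rhs), md$vars) || length(md$rhs) != length(md$vars))
    stop("model '", md$name, "': rhs must be given for exactly the dynamic vars")
  all_names <- model_state_names(md)
  if (anyDuplicated(all_names))
    stop("model '", md$name, "': dynamic/algebraic/frozen name sets overlap")
  housed <- c(all_names, names(md$params), names(md$external_inputs), "t")
  fun_ok <- c(.expr_binops, .expr_funs, "(", names(md$aux_fns))
  check_expr <- function(e, where, extra_syms = character(0)) {
    bad <- setdiff(expr_symbols(e), c(housed, extra_syms))
    if (length(bad))
      stop("model '", md$name, "': unhoused symbol(s) ",
           paste(bad, collapse = ", "), " in ", where)
    badf <- setdiff(expr_functions(e), fun_ok)
    if (length(badf))
      stop("model '", md$name, "': unknown function(s) ",
           paste(badf, collapse = ", "), " in ", where)
  }
  for (v in md$vars) check_expr(md$rhs[[v]], paste0("rhs of ", v))
  for (a in names(md$algebraic)) check_expr(md$algebraic[[a]], paste0("algebraic ", a))
  for (f in names(md$aux_fns))
    check_expr(md$aux_fns[[f]]$body, paste0("aux ", f), md$aux_fns[[f]]$args)
  for (ev in md$events) check_expr(ev$gfun, paste0("event ", ev$name))
  for (nm in names(md$domains))
    if (!is_interval(md$domains[[nm]]))
      stop("model '", md$name, "': domain for ", nm, " is not an interval")
  for (nm in names(md$external_inputs)) {
    xi <- as.matrix(md$external_inputs[[nm]])
    if (ncol(xi) != 2L || (nrow(xi) > 1L && any(diff(xi[, 1L]) <= 0)))
      stop("model '", md$name, "': external input '", nm,
           "' must be a two-column series with increasing times")
  }
  invisible(TRUE)
}

# topological order of algebraic definitions (they may reference each other)
alg_topo_order <- function(md) {
  anames <- names(md$algebraic)
  if (!length(anames)) return(character(0))
  deps <- lapply(md$algebraic, function(e) intersect(expr_symbols(e), anames))
  order <- character(0)
  remaining <- anames
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(a)
      !length(setdiff(deps[[a]], order)), logical(1))]
    if (!length(ready))
      stop("model '", md$name, "': cyclic algebraic definitions among ",
           paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

# inline auxiliary function calls (beta-reduction), recursively
inline_aux <- function(e, aux_fns) {
  if (!length(aux_fns)) return(e)
  walk <- function(x) {
    if (is.call(x)) {
      head <- as.character(x[[1L]])
      args <- lapply(as.list(x)[-1L], walk)
      if (head %in% names(aux_fns)) {
        af <- aux_fns[[head]]
        if (length(args) != length(af$args))
          stop("aux call '", head, "' arity mismatch")
        return(walk(substitute_expression(af$body,
                                          stats::setNames(args, af$args))))
      }
      for (i in seq_along(args)) x[[i + 1L]] <- args[[i]]
      return(x)
    }
    x
  }
  walk(e)
}

# Build a fast function(t, y) evaluating `result_expr` after assigning state,
# external inputs and algebraic variables. `env` must contain params, aux
# closures and frozen values.
build_eval_fun <- function(md, result_expr, env) {
  prologue <- list()
  for (i in seq_along(md$vars))
    prologue[[length(prologue) + 1L]] <-
      call("<-", as.symbol(md$vars[i]), call("[[", quote(y), i))
  for (nm in names(md$external_inputs))
    prologue[[length(prologue) + 1L]] <-
      call("<-", as.symbol(nm), call(paste0(".ext_", nm), quote(t)))
  for (a in alg_topo_order(md))
    prologue[[length(prologue) + 1L]] <-
      call("<-", as.symbol(a), md$algebraic[[a]])
  f <- function(t, y) NULL
  body(f) <- as.call(c(quote(`{`), prologue, list(result_expr)))
  environment(f) <- env
  f
}

#' Compile a model definition for fast evaluation
#'
#' Builds closures for the derivative vector, the full named state (dynamic +
#' algebraic + frozen), event guard functions and algebraic-derivative
#' evaluation. Frozen variable values are set with [set_frozen()].
#'
#' @param model A model definition.
#' @return Object of class `"compiled_model"`.
#' @export
compile_model <- function(model) {
  stopifnot(is_model(model))
  env <- new.env(parent = make_math_env())
  for (p in names(model$params)) assign(p, model$params[[p]], envir = env)
  # aux closures evaluate in env so they see params and each other
  for (f in names(model$aux_fns)) {
    af <- model$aux_fns[[f]]
    fn <- function() NULL
    formals(fn) <- stats::setNames(rep(list(quote(expr = )), length(af$args)),
                                   af$args)
    body(fn) <- af$body
    environment(fn) <- env
    assign(f, fn, envir = env)
  }
  for (nm in names(model$external_inputs)) {
    xi <- as.matrix(model$external_inputs[[nm]])
    assign(paste0(".ext_", nm),
           stats::approxfun(xi[, 1L], xi[, 2L], rule = 2), envir = env)
  }
  for (fz in model$frozen) assign(fz, NA_real_, envir = env)

  n <- length(model$vars)
  deriv_expr <- as.call(c(quote(c), unname(model$rhs[model$vars])))
  deriv_fun <- build_eval_fun(model, deriv_expr, env)

  anames <- names(model$algebraic)
  alg_fun <- NULL
  alg_deriv_fun <- NULL
  if (length(anames)) {
    alg_expr <- as.call(c(quote(c), lapply(anames, as.symbol)))
    alg_fun <- build_eval_fun(model, alg_expr, env)
    # symbolic d(alg)/dt along the flow: sum_v dA/dv * f_v + dA/dt;
    # falls back to a small central difference along the flow direction
    alg_deriv_fun <- tryCatch({
      grads <- list()
      for (a in anames) {
        inl <- inline_aux(model$algebraic[[a]], model$aux_fns)
        # express in dynamic vars only: substitute other algebraic defs
        for (b in rev(alg_topo_order(model))) {
          if (b != a)
            inl <- substitute_expression(inl, stats::setNames(
              list(inline_aux(model$algebraic[[b]], model$aux_fns)), b))
        }
        grads[[a]] <- c(lapply(model$vars, function(v)
          differentiate_expression(inl, v)),
          list(differentiate_expression(inl, "t")))
      }
      grad_exprs <- as.call(c(quote(c), unlist(grads, recursive = FALSE)))
      grad_fun <- build_eval_fun(model, grad_exprs, env)
      local({
        nv <- n
        function(t, y, f) {
          g <- grad_fun(t, y)
          vapply(seq_along(anames), function(k) {
            off <- (k - 1L) * (nv + 1L)
            sum(g[off + seq_len(nv)] * f) + g[off + nv + 1L]
          }, numeric(1))
        }
      })
    }, error = function(e) {
      function(t, y, f) {
        h <- 1e-6 * max(1, abs(t))
        (alg_fun(t + h, y + h * f) - alg_fun(t - h, y - h * f)) / (2 * h)
      }
    })
  }

  event_funs <- lapply(model$events, function(ev)
    build_eval_fun(model, ev$gfun, env))
  names(event_funs) <- vapply(model$events, `[[`, character(1), "name")

  structure(list(model = model, env = env, n = n,
                 deriv = deriv_fun, alg = alg_fun, alg_deriv = alg_deriv_fun,
                 event_funs = event_funs),
            class = "compiled_model")
}

#' Set frozen (dummy-constant) variable values on a compiled model
#' @param compiled A compiled model.
#' @param values Named numeric vector covering the model's frozen names.
#' @export
set_frozen <- function(compiled, values) {
  for (fz in compiled$model$frozen) {
    if (!fz %in% names(values))
      stop("set_frozen: no value for frozen variable '", fz, "'")
    assign(fz, as.numeric(values[[fz]]), envir = compiled$env)
  }
  invisible(compiled)
}

# full named state (dynamic, algebraic, frozen) at (t, y)
full_state <- function(compiled, t, y) {
  md <- compiled$model
  out <- stats::setNames(as.numeric(y), md$vars)
  if (!is.null(compiled$alg)) {
    av <- compiled$alg(t, y)
    out <- c(out, stats::setNames(as.numeric(av), names(md$algebraic)))
  }
  if (length(md$frozen))
    out <- c(out, stats::setNames(
      vapply(md$frozen, function(fz) get(fz, envir = compiled$env), numeric(1)),
      md$frozen))
  out
}
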