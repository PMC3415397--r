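#' @title Dominant-scale analysis and hybrid reduction
#' @description
#' Dominant-scale analysis treats a conductance-based model as a hub
#' equation (the membrane potential V) fed by input terms (gated
#' conductances, a leak, an applied current). The quasi-static resting
#' potential V_qs is the instantaneous fixed point of the hub equation with
#' the gating variables frozen; the influence Psi of each input source is
#' the sensitivity of V_qs to that source (in mV), available in explicit
#' algebraic form by symbolic differentiation. For a scale tolerance
#' gamma > 1 the active set is A = { i : Psi_i >= Psi_max / gamma }.
#' Maximal intervals of constant active set (epochs) tile a trajectory;
#' each epoch yields a reduced sub-model in which inactive terms are
#' dropped from the hub equation (their 0/1 inclusion flags s, c set to 0),
#' fast active gating variables are replaced by their voltage asymptote
#' (DAE by substitution), inactive gating variables are simulated as
#' shadow variables slaved to V, and join/leave events guard the regime's
#' validity. The cyclic sequence of active sets is the template; wiring
#' the reduced regimes along it gives a hybrid model whose behavior is a
#' testable mechanistic hypothesis for the full dynamics.
#' @name dssrt
NULL

#' Declare input terms of a conductance target
#'
#' @param name Source/term name.
#' @param conductance Conductance expression in gating variables and
#'   parameters (e.g. `"gna*m^3*h"`).
#' @param E Reversal potential: parameter symbol or number.
#' @param gating Character vector of gating variable names (defaults to the
#'   expression's free symbols that are state variables, resolved when the
#'   target is built).
#' @return A term object for [conductance_target()].
#' @export
gated_term <- function(name, conductance, E, gating = NULL) {
  if (is.character(conductance)) conductance <- parse_expression(conductance)
  if (is.character(E)) E <- parse_expression(E)
  structure(list(name = name, kind = "gated", conductance = conductance,
                 E = E, gating = gating), class = "input_term")
}

#' @rdname gated_term
#' @param flag Inclusion-flag symbol name: `"s"` (leak) / `"c"` (current).
#' @export
leak_term <- function(name = "leak", conductance, E, flag = "s") {
  if (is.character(conductance)) conductance <- parse_expression(conductance)
  if (is.character(E)) E <- parse_expression(E)
  structure(list(name = name, kind = "leak", conductance = conductance,
                 E = E, flag = flag), class = "input_term")
}

#' @rdname gated_term
#' @param current Applied-current expression or parameter symbol.
#' @export
applied_current_term <- function(name = "Iapp", current, flag = "c") {
  if (is.character(current)) current <- parse_expression(current)
  structure(list(name = name, kind = "applied_current", current = current,
                 flag = flag), class = "input_term")
}

sum_exprs <- function(es) {
  es <- Filter(function(e) !is_zero_expr(e), es)
  if (!length(es)) return(0)
  Reduce(function(a, b) call("+", a, b), es)
}

#' Declare the hub structure of a conductance-based model
#'
#' Builds the symbolic quasi-static potential, influence (Psi) expressions,
#' per-gating-variable timescales and voltage asymptotes, all compiled
#' against the model for fast evaluation. The hub invariant — that the hub's
#' right-hand side equals the summed term currents over C — is validated at
#' `n_check` random states (relative error <= 1e-10).
#'
#' @param model The full [model_definition()].
#' @param C Membrane capacitance (same units as the model's hub equation).
#' @param terms List of [gated_term()] / [leak_term()] /
#'   [applied_current_term()] objects.
#' @param target Hub variable name (default `"V"`).
#' @param n_check Random states used to validate the hub invariant (0 skips).
#' @param seed Seed for the validation states.
#' @return Object of class `"conductance_target"`.
#' @export
conductance_target <- function(model, C, terms, target = "V",
                               n_check = 100L, seed = 1L) {
  stopifnot(is_model(model))
  flags <- list(s = 1, c = 1)
  gating_all <- character(0)
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    if (tm$kind == "gated") {
      if (is.null(tm$gating))
        terms[[i]]$gating <- intersect(expr_symbols(tm$conductance), model$vars)
      gating_all <- c(gating_all, terms[[i]]$gating)
    }
  }
  gating_all <- unique(gating_all)
  if (!target %in% model$vars)
    stop("conductance_target: hub '", target, "' is not a dynamic variable")

  # symbolic V_qs with inclusion-flag symbols s (leak), c (current)
  num_parts <- list(); den_parts <- list(); cur_parts <- list()
  for (tm in terms) {
    if (tm$kind == "gated") {
      num_parts[[length(num_parts) + 1L]] <- call("*", tm$conductance, tm$E)
      den_parts[[length(den_parts) + 1L]] <- tm$conductance
      cur_parts[[length(cur_parts) + 1L]] <-
        call("*", tm$conductance,
             call("-", tm$E, as.symbol(target)))
    } else if (tm$kind == "leak") {
      fs <- as.symbol(tm$flag)
      num_parts[[length(num_parts) + 1L]] <-
        call("*", fs, call("*", tm$conductance, tm$E))
      den_parts[[length(den_parts) + 1L]] <- call("*", fs, tm$conductance)
      cur_parts[[length(cur_parts) + 1L]] <-
        call("*", fs, call("*", tm$conductance,
                           call("-", tm$E, as.symbol(target))))
    } else {
      fs <- as.symbol(tm$flag)
      num_parts[[length(num_parts) + 1L]] <- call("*", fs, tm$current)
      cur_parts[[length(cur_parts) + 1L]] <- call("*", fs, tm$current)
    }
  }
  num_expr <- sum_exprs(num_parts)
  den_expr <- sum_exprs(den_parts)
  vqs <- call("/", num_expr, den_expr)

  # Psi expressions: gating sensitivities |dV_qs/dx|; leak and current as
  # the V_qs shift from removing the term
  psi <- list()
  for (x in gating_all)
    psi[[x]] <- call("abs", differentiate_expression(vqs, x))
  for (tm in terms) {
    if (tm$kind == "leak")
      psi[[tm$name]] <- call("/", call("*", tm$conductance,
                                       call("abs", call("-", tm$E, vqs))),
                             den_expr)
    if (tm$kind == "applied_current")
      psi[[tm$name]] <- call("/", call("abs", tm$current), den_expr)
  }
  sources <- names(psi)

  # first-order gating kinetics: rhs_x = a(V) - b(V) x; b = -d rhs/dx
  tau_b <- list(); xinf <- list()
  for (x in gating_all) {
    inl <- inline_aux(model$rhs[[x]], model$aux_fns)
    dx <- differentiate_expression(inl, x)
    if (x %in% expr_symbols(dx))
      stop("conductance_target: analysis not applicable: rhs of '", x,
           "' is not first-order (kinetic rate depends on ", x, ")")
    b <- if (is.numeric(dx)) -dx else call("-", call("(", dx))
    a <- substitute_expression(inl, stats::setNames(list(0), x))
    tau_b[[x]] <- b
    xinf[[x]] <- call("/", call("(", a), call("(", b))
  }

  compiled <- compile_model(model)
  flag_env <- new.env(parent = compiled$env)
  flag_env$s <- 1; flag_env$c <- 1
  psi_fun <- build_eval_fun(model, as.call(c(quote(c), unname(psi))), flag_env)
  den_fun <- build_eval_fun(model, den_expr, flag_env)
  vqs_fun <- build_eval_fun(model, vqs, flag_env)
  taub_fun <- if (length(tau_b))
    build_eval_fun(model, as.call(c(quote(c), unname(tau_b))), flag_env)
  else NULL

  ct <- structure(list(target = target, C = C, terms = terms,
                       gating = gating_all, sources = sources,
                       model = model, vqs_expr = vqs, den_expr = den_expr,
                       cur_exprs = cur_parts, psi_exprs = psi,
                       tau_b_exprs = tau_b, xinf_exprs = xinf,
                       compiled = compiled, flag_env = flag_env,
                       psi_fun = psi_fun, den_fun = den_fun,
                       vqs_fun = vqs_fun, taub_fun = taub_fun),
                  class = "conductance_target")
  if (n_check > 0L) validate_conductance_target(ct, n_check, seed)
  ct
}

is_conductance_target <- function(x) inherits(x, "conductance_target")

random_hub_states <- function(ct, n, seed) {
  md <- ct$model
  set.seed(seed)
  states <- matrix(NA_real_, n, length(md$vars), dimnames = list(NULL, md$vars))
  for (v in md$vars) {
    dv <- md$domains[[v]]
    if (v == ct$target) {
      lo <- if (!is.null(dv)) max(dv$lo, -100) else -100
      hi <- if (!is.null(dv)) min(dv$hi, 50) else 50
    } else { lo <- 0.01; hi <- 0.99 }
    states[, v] <- stats::runif(n, lo, hi)
  }
  states
}

validate_conductance_target <- function(ct, n = 100L, seed = 1L) {
  md <- ct$model
  states <- random_hub_states(ct, n, seed)
  cur_fun <- build_eval_fun(md, sum_exprs(ct$cur_exprs), ct$flag_env)
  iv <- match(ct$target, md$vars)
  for (i in seq_len(n)) {
    y <- states[i, ]
    rhs_v <- ct$compiled$deriv(0, y)[iv]
    tot <- cur_fun(0, y) / ct$C
    if (abs(rhs_v - tot) > 1e-10 * max(1, abs(tot)))
      stop("conductance_target: hub invariant violated: rhs(V) != sum of ",
           "term currents / C (difference ", rhs_v - tot, ")")
  }
  invisible(TRUE)
}

ct_flags <- function(ct, inclusions) {
  s <- if ("s" %in% names(inclusions)) inclusions[["s"]] else 1
  c_ <- if ("c" %in% names(inclusions)) inclusions[["c"]] else 1
  c(s = s, c = c_)
}

with_flags <- function(ct, inclusions, fn) {
  fl <- ct_flags(ct, inclusions)
  old_s <- ct$flag_env$s; old_c <- ct$flag_env$c
  on.exit({ ct$flag_env$s <- old_s; ct$flag_env$c <- old_c })
  ct$flag_env$s <- fl[["s"]]; ct$flag_env$c <- fl[["c"]]
  fn()
}

state_y <- function(ct, state) as.numeric(unlist(state)[ct$model$vars])

#' Quasi-static resting potential of the hub
#'
#' The instantaneous fixed point of the hub equation with gating variables
#' frozen at the given state:
#' `V_qs = (sum G_k E_k + s g_L E_L + c I_app) / (sum G_k + s g_L)`.
#' Satisfies `rhs_V(V = V_qs) = 0` exactly.
#'
#' @param ct A [conductance_target()].
#' @param state Named state (gating variables required).
#' @param inclusions Named 0/1 values for the inclusion flags `s`, `c`
#'   (default both 1).
#' @return V_qs in mV.
#' @export
quasi_static_potential <- function(ct, state, inclusions = c(s = 1, c = 1)) {
  y <- state_y(ct, state)
  with_flags(ct, inclusions, function() {
    den <- ct$den_fun(0, y)
    if (!is.finite(den) || abs(den) < 1e-300)
      stop("quasi_static_potential: degenerate: zero total conductance")
    ct$vqs_fun(0, y)
  })
}

#' Influence sensitivities Psi of each input source
#'
#' Gating sensitivities are `|dV_qs/dx|` (mV per unit of the dimensionless
#' gating variable), obtained symbolically; the leak and applied-current
#' influences are the V_qs shift caused by removing the term
#' (`g_L |E_L - V_qs| / G_total` and `|I| / G_total`), so all Psi are
#' commensurable in mV.
#'
#' @inheritParams quasi_static_potential
#' @return Named numeric vector of Psi values (>= 0) over the sources.
#' @export
compute_psi <- function(ct, state, inclusions = c(s = 1, c = 1)) {
  y <- state_y(ct, state)
  with_flags(ct, inclusions, function()
    stats::setNames(as.numeric(ct$psi_fun(0, y)), ct$sources))
}

#' Timescales of the gating variables and of the hub
#'
#' For first-order kinetics `dx/dt = (x_inf(V) - x)/tau_x(V)` (equivalently
#' `alpha (1-x) - beta x`), `tau_x = -1 / (d rhs_x / dx)`; the hub timescale
#' is `tau_hub = C / G_total`.
#'
#' @inheritParams quasi_static_potential
#' @return `list(taus, tau_hub)` in the model's time units.
#' @export
compute_timescales <- function(ct, state, inclusions = c(s = 1, c = 1)) {
  y <- state_y(ct, state)
  with_flags(ct, inclusions, function() {
    b <- as.numeric(ct$taub_fun(0, y))
    taus <- stats::setNames(1 / b, ct$gating)
    list(taus = taus, tau_hub = ct$C / ct$den_fun(0, y))
  })
}

#' Active set under a scale tolerance
#'
#' `A = { i : Psi_i >= Psi_max / gamma }` (inclusive at equality); the
#' maximal source is always a member. Monotone in gamma.
#'
#' @param psi Named non-negative Psi values.
#' @param gamma Scale tolerance, > 1.
#' @return Character vector of active source names (in `psi` order).
#' @export
active_set <- function(psi, gamma) {
  if (!is.numeric(gamma) || gamma <= 1)
    stop("active_set: gamma must be > 1")
  if (!length(psi) || any(psi < 0))
    stop("active_set: psi must be non-empty and non-negative")
  names(psi)[psi >= max(psi) / gamma]
}
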