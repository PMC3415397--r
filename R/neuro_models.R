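#' @title Worked model fixtures: integrate-and-fire and Hodgkin-Huxley
#' @description
#' Bundled fixtures used throughout the package: a two-regime
#' integrate-and-fire neuron whose action potential is a square spike of
#' configured height and duration, and the space-clamped Hodgkin-Huxley
#' membrane with its conductance-target declaration for dominant-scale
#' analysis. All fixtures are generated programmatically from canonical
#' parameter sets; no external data.
#' @name neuro_models
NULL

#' Integrate-and-fire neuron with a square spike (two-regime hybrid model)
#'
#' Leaky regime: `tau dV/dt = -V + drive` with a terminal upward threshold
#' event at `V = V_th`; on firing, V is reset to `spike_height` and held
#' there for exactly `spike_duration` (a timer state u runs `du/dt = 1`
#' from 0 against a terminal guard `u - spike_duration`), after which V
#' resets to `V_reset` and the leaky regime resumes. From `V(0) = 0`, the
#' first threshold time is `-tau log(1 - V_th/drive)` and the full cycle
#' period adds exactly the plateau duration. A sub-threshold drive
#' (`drive <= V_th`) never fires (period 0).
#'
#' @param tau Membrane time constant (ms), default 10.
#' @param drive Normalized drive `R I` (threshold units), default 2.
#' @param V_th Threshold, default 1.
#' @param V_reset Post-spike reset value, default 0.
#' @param spike_height Plateau height, default 2.
#' @param spike_duration Plateau duration (ms), default 1.
#' @return A [hybrid_model()] with states `V`, `u`.
#' @export
make_lif_squarespike <- function(tau = 10, drive = 2, V_th = 1, V_reset = 0,
                                 spike_height = 2, spike_duration = 1) {
  leaky <- model_definition(
    "leaky", c("V", "u"),
    rhs = list(V = "(-V + drive)/tau", u = "0"),
    params = c(tau = tau, drive = drive, Vth = V_th),
    events = list(event_definition("spike", "V - Vth", direction = 1,
                                   terminal = TRUE)))
  spike <- model_definition(
    "spike", c("V", "u"),
    rhs = list(V = "0", u = "1"),
    params = c(dur = spike_duration),
    events = list(event_definition("spike_end", "u - dur", direction = 1,
                                   terminal = TRUE)))
  hybrid_model(
    regimes = list(regime("leaky", leaky), regime("spike", spike)),
    transitions = list(
      transition("leaky", "spike", "spike",
                 reset = list(V = fmt_num(spike_height), u = "0")),
      transition("spike", "spike_end", "leaky",
                 reset = list(V = fmt_num(V_reset)))),
    state_names = c("V", "u"), initial = "leaky", name = "lif_squarespike")
}

hh_rate_aux <- function(phi = 1) {
  p <- fmt_num(phi)
  pre <- if (phi == 1) "" else paste0(p, "*")
  list(
    am = aux_fn("v", paste0(pre, "0.1*(v + 40)/(1 - exp(-(v + 40)/10))")),
    bm = aux_fn("v", paste0(pre, "4*exp(-(v + 65)/18)")),
    ah = aux_fn("v", paste0(pre, "0.07*exp(-(v + 65)/20)")),
    bh = aux_fn("v", paste0(pre, "1/(1 + exp(-(v + 35)/10))")),
    an = aux_fn("v", paste0(pre, "0.01*(v + 55)/(1 - exp(-(v + 55)/10))")),
    bn = aux_fn("v", paste0(pre, "0.125*exp(-(v + 65)/80)")))
}

#' The Hodgkin-Huxley membrane model and its conductance target
#'
#' Builds the standard four-variable space-clamped membrane equations
#' `C dV/dt = gna m^3 h (ena - V) + gk n^4 (ek - V) + gl (el - V) + Iapp`
#' with first-order alpha/beta kinetics for m, h, n, plus the matching
#' conductance-target declaration (hub V; sodium and potassium gated terms;
#' leak and applied current carrying the inclusion flags s, c).
#'
#' Parameter sets: `"hh1952"` is the canonical modern-convention squid axon
#' set (C = 1 uF/cm^2, gna = 120, gk = 36, gl = 0.3 mS/cm^2, ena = 50,
#' ek = -77, el = -54.4 mV). `"interneuron"` is a clearly synthetic
#' fast-spiking stand-in: the same conductances with all rate functions sped
#' up uniformly twofold (a temperature-like rescaling). It reproduces no
#' published parameterization and carries no literature-numeric claims.
#'
#' @param paramset `"hh1952"` or `"interneuron"`.
#' @param I_app Applied current (uA/cm^2), default 10.
#' @return `list(model, ct)` — the [model_definition()] and its validated
#'   [conductance_target()].
#' @export
make_hh_model <- function(paramset = c("hh1952", "interneuron"), I_app = 10) {
  paramset <- match.arg(paramset)
  phi <- if (paramset == "interneuron") 2 else 1
  params <- c(C = 1, gna = 120, gk = 36, gl = 0.3,
              ena = 50, ek = -77, el = -54.4, Iapp = I_app)
  model <- model_definition(
    paste0("hh_", paramset), c("V", "m", "h", "n"),
    rhs = list(
      V = "(gna*m^3*h*(ena - V) + gk*n^4*(ek - V) + gl*(el - V) + Iapp)/C",
      m = "am(V)*(1 - m) - bm(V)*m",
      h = "ah(V)*(1 - h) - bh(V)*h",
      n = "an(V)*(1 - n) - bn(V)*n"),
    params = params,
    aux_fns = hh_rate_aux(phi),
    domains = list(V = interval(-120, 80),
                   m = interval(-0.001, 1.001),
                   h = interval(-0.001, 1.001),
                   n = interval(-0.001, 1.001)))
  ct <- conductance_target(
    model, C = params[["C"]],
    terms = list(
      gated_term("Na", "gna*m^3*h", "ena"),
      gated_term("K", "gk*n^4", "ek"),
      leak_term("leak", "gl", "el"),
      applied_current_term("Iapp", "Iapp")))
  list(model = model, ct = ct)
}

#' Resting-state initial condition of an HH model
#'
#' Gating variables at their voltage asymptotes for the given V.
#' @param hh Result of [make_hh_model()].
#' @param V Membrane potential (default -65 mV).
#' @return Named state vector.
#' @export
hh_initial_state <- function(hh, V = -65) {
  env <- new.env(parent = hh$ct$compiled$env)
  assign(hh$ct$target, V, envir = env)
  xinf <- vapply(hh$ct$gating, function(x)
    eval(hh$ct$xinf_exprs[[x]], env), numeric(1))
  c(stats::setNames(V, hh$ct$target), stats::setNames(xinf, hh$ct$gating))
}

#' Period of regular firing from an ordered list of event times
#'
#' The first `settle_fraction` of the record (by time) is discarded as
#' transient; the period is the mean of the remaining consecutive
#' inter-event intervals, with `steady` true when their coefficient of
#' variation is at most 0.001. With fewer than two remaining events the
#' period is exactly 0 (the "no APs / steady state" convention).
#'
#' @param event_times Ordered numeric event times.
#' @param settle_fraction Fraction in [0, 1), default 0.3.
#' @return `list(period, n_intervals, cv, steady)`.
#' @export
measure_period <- function(event_times, settle_fraction = 0.3) {
  event_times <- sort(as.numeric(event_times))
  if (length(event_times) >= 2L) {
    t_cut <- event_times[1L] +
      settle_fraction * (event_times[length(event_times)] - event_times[1L])
    event_times <- event_times[event_times >= t_cut]
  }
  if (length(event_times) < 2L)
    return(list(period = 0, n_intervals = 0L, cv = NA_real_, steady = FALSE))
  iv <- diff(event_times)
  cv <- if (length(iv) > 1L) stats::sd(iv) / mean(iv) else 0
  list(period = mean(iv), n_intervals = length(iv), cv = cv,
       steady = cv <= 0.001)
}

#' Spike times of a simulated model run
#'
#' Upward crossings of the detection level by the voltage, refined on the
#' trajectory interpolant.
#' @param traj A trajectory or hybrid trajectory.
#' @param var Voltage variable name.
#' @param level Detection level (default -10 mV).
#' @return Numeric vector of crossing times.
#' @export
spike_times <- function(traj, var = "V", level = -10) {
  trajectory_crossings(traj, var, level, direction = 1)
}

#' Current sweep: full vs hybrid-reduced firing period
#'
#' Derives a template from the full model at a reference current, assembles
#' the hybrid reduction, and for each requested current simulates both the
#' full model and the reduction (with the applied current updated), measures
#' both firing periods (0 for steady state), and tabulates the comparison.
#' Individual-run failures are recorded per row via the recovery path and
#' the sweep continues, so the table always has one row per current.
#'
#' @param I_values Applied currents to sweep.
#' @param paramset Parameter set tag for [make_hh_model()].
#' @param gamma,rho Dominant-scale settings.
#' @param run_length Simulated time per run (ms), default 300.
#' @param settle_fraction Transient fraction discarded by [measure_period()].
#' @param I_ref Reference current for template derivation (default: median
#'   of `I_values`).
#' @param level Spike-detection level (mV), default -10.
#' @param opts Integration options.
#' @param template Optionally, a precomputed [regime_template()] (skips the
#'   derivation step).
#' @return `data.frame(I, period_full, period_reduced, rel_diff,
#'   both_steady, note)`; `rel_diff` is `NA` when either period is 0.
#' @export
sweep_current <- function(I_values, paramset = "hh1952", gamma = 3, rho = 2,
                          run_length = 300, settle_fraction = 0.3,
                          I_ref = NULL, level = -10, opts = list(),
                          template = NULL) {
  if (is.null(I_ref)) I_ref <- stats::median(I_values)
  if (is.null(template)) {
    template <- derive_hh_template(paramset, I_ref, gamma = gamma, rho = rho,
                                   opts = opts)$template
  }
  rows <- lapply(I_values, function(I) {
    out <- tryCatch({
      hh <- make_hh_model(paramset, I_app = I)
      ic <- hh_initial_state(hh)
      full <- integrate_ode(hh$model, ic, c(0, run_length), opts)
      st_full <- spike_times(full$trajectory, level = level)
      pf <- measure_period(st_full, settle_fraction)
      pr <- list(period = 0, steady = FALSE)
      if (pf$period > 0) {
        red <- simulate_reduction(hh, template, full$trajectory,
                                  run_length, gamma = gamma, opts = opts)
        st_red <- spike_times(red, level = level)
        pr <- measure_period(st_red, settle_fraction)
      }
      rel <- if (pf$period > 0 && pr$period > 0)
        abs(pr$period - pf$period) / pf$period else NA_real_
      data.frame(I = I, period_full = pf$period, period_reduced = pr$period,
                 rel_diff = rel,
                 both_steady = isTRUE(pf$steady) && isTRUE(pr$steady),
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(I = I, period_full = NA_real_, period_reduced = NA_real_,
                 rel_diff = NA_real_, both_steady = FALSE,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  do.call(rbind, rows)
}

#' Derive the dominant-scale template of an HH model at one current
#'
#' Simulates the full model with the package's standard run protocol
#' (300 ms, discarding the first 30% as transient), extracts epochs over
#' the post-transient window, and builds the cyclic template from the last
#' complete firing cycle. The epoch merge threshold is the default 0.5% of
#' the analysis window.
#'
#' @param paramset Parameter set tag.
#' @param I_app Applied current (must be in the repetitive-firing range).
#' @param gamma,rho Dominant-scale settings.
#' @param run_length Simulation length (default 300 ms).
#' @param settle_fraction Transient fraction discarded (default 0.3).
#' @param opts Integration options.
#' @return `list(hh, template, epochs, traj, window)`.
#' @export
derive_hh_template <- function(paramset = "hh1952", I_app = 10, gamma = 3,
                               rho = 2, run_length = 300,
                               settle_fraction = 0.3, opts = list()) {
  hh <- make_hh_model(paramset, I_app = I_app)
  ic <- hh_initial_state(hh)
  full <- integrate_ode(hh$model, ic, c(0, run_length), opts)
  st <- spike_times(full$trajectory)
  if (length(st) < 4L)
    stop("derive_hh_template: too few spikes at I=", I_app,
         " (", length(st), "); not in the repetitive-firing range?")
  window <- c(settle_fraction * run_length, run_length)
  ep <- extract_epochs(full$trajectory, hh$ct, gamma = gamma, window = window)
  template <- template_from_epochs(ep, hh$ct, rho = rho)
  list(hh = hh, template = template, epochs = ep, traj = full$trajectory,
       window = window)
}

#' Epoch counts per firing cycle
#'
#' Groups extracted epochs into cycles keyed on the recurrence of a
#' reference entry change (the entry of the last epoch's active set) and
#' counts epochs per complete cycle — the stability diagnostic for the
#' dominant-scale analysis of a periodic orbit.
#'
#' @param ep Result of [extract_epochs()].
#' @return Integer vector of epoch counts for each complete cycle.
#' @export
epochs_per_cycle <- function(ep) {
  epochs <- ep$epochs
  if (length(epochs) < 2L) return(integer(0))
  keys <- vapply(epochs, function(e)
    paste(sort(e$active), collapse = ","), character(1))
  occ <- which(keys == keys[length(keys)])
  if (length(occ) < 2L) return(integer(0))
  diff(occ)
}

#' Simulate the hybrid reduction alongside a full-model trajectory
#'
#' Starts the reduction from matched initial conditions: the full-model
#' state at an entry into the template's first active set. When the epoch
#' extraction (`ep`) is supplied, the exact crossing time of a mid-window
#' epoch matching the template's first element is used; otherwise the entry
#' is re-detected by scanning the trajectory.
#'
#' @param hh Result of [make_hh_model()].
#' @param template A [regime_template()].
#' @param full_traj Full-model trajectory at the same current.
#' @param t_end End time for the reduced simulation.
#' @param gamma Scale tolerance for guards.
#' @param ep Optional result of [extract_epochs()] on `full_traj`.
#' @param opts Integration options.
#' @return A hybrid trajectory.
#' @export
simulate_reduction <- function(hh, template, full_traj, t_end, gamma = 3,
                               ep = NULL, opts = list()) {
  ct <- hh$ct
  hm <- assemble_hybrid_reduction(ct, template, gamma = gamma)
  target_set <- template$active_sets[[1L]]
  t_start <- NA_real_
  if (!is.null(ep)) {
    cand <- Filter(function(e)
      setequal(e$active, target_set) &&
        !identical(e$entry_change, "initial"), ep$epochs)
    if (length(cand)) {
      # earliest full entry, leaving maximal room to t_end
      t_start <- cand[[1L]]$interval$lo
    }
  }
  if (is.na(t_start)) {
    lo <- full_traj$domain$lo + 0.25 * (full_traj$domain$hi - full_traj$domain$lo)
    ts <- seq(lo, full_traj$domain$hi, length.out = 600L)
    prev_match <- TRUE
    for (tt in ts) {
      st <- traj_eval(full_traj, tt, ct$model$vars)
      a <- active_set(compute_psi(ct, st), gamma)
      m <- setequal(a, target_set)
      if (m && !prev_match) { t_start <- tt; break }
      prev_match <- m
    }
  }
  if (is.na(t_start))
    stop("simulate_reduction: full trajectory never enters the template's ",
         "first active set")
  ic <- traj_eval(full_traj, t_start, ct$model$vars)
  simulate_hybrid(hm, ic, t_end, t0 = t_start, opts = opts)
}
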