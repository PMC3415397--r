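# two-input toy hub: one gated term g1*x with reversal E1 = 0, one leak
# g2 with reversal E2 = -80; closed forms are hand-derived
toy_target <- function(I = 0) {
  md <- model_definition(
    "toy_hub", c("V", "x"),
    rhs = list(V = "(g1*x*(e1 - V) + g2*(e2 - V) + Iapp)/C",
               x = "(0.5 - x)/2"),
    params = c(g1 = 1, g2 = 1, e1 = 0, e2 = -80, C = 1, Iapp = I),
    domains = list(V = interval(-120, 60)))
  conductance_target(md, C = 1,
                     terms = list(gated_term("xterm", "g1*x", "e1"),
                                  leak_term("leak", "g2", "e2"),
                                  applied_current_term("Iapp", "Iapp")),
                     n_check = 50)
}

test_that("quasi-static potential matches hand-derived values", {
  ct <- toy_target(I = 0)
  expect_equal(quasi_static_potential(ct, c(V = -50, x = 1)), -40)
  # all inclusions off except leak: V_qs = E_L
  expect_equal(quasi_static_potential(ct, c(V = -50, x = 0),
                                      inclusions = c(s = 1, c = 0)), -80)
  expect_error(quasi_static_potential(ct, c(V = 0, x = 0),
                                      inclusions = c(s = 0, c = 0)),
               "degenerate")
})

test_that("Psi values match hand differentiation of V_qs", {
  ct <- toy_target(I = 2)
  psi <- compute_psi(ct, c(V = -50, x = 1), inclusions = c(s = 1, c = 0))
  # Psi_x = |g1 (E1 - V_qs)| / G_total = 40/2 = 20 at x = 1, I off
  expect_equal(psi[["x"]], 20, tolerance = 1e-12)
  # Psi_I = |I| / G_total = 2/2 = 1
  psi_on <- compute_psi(ct, c(V = -50, x = 1))
  expect_equal(psi_on[["Iapp"]], 1, tolerance = 1e-12)
  expect_true(all(psi_on >= 0))
})

test_that("V_qs is the exact fixed point of the hub equation (HH)", {
  hh <- hh_fix()
  compiled <- hh$ct$compiled
  states <- random_hh_states(100)
  for (i in seq_len(nrow(states))) {
    st <- unlist(states[i, ])
    vqs <- quasi_static_potential(hh$ct, st)
    y <- st; y[["V"]] <- vqs
    rhs_v <- compiled$deriv(0, as.numeric(y[c("V", "m", "h", "n")]))[1L]
    scale <- max(1, abs(vqs))
    expect_lt(abs(rhs_v), 1e-10 * scale)
  }
})

test_that("symbolic Psi agrees with finite differences of V_qs (HH)", {
  hh <- hh_fix()
  states <- random_hh_states(100, seed = 99)
  h <- 1e-6
  for (i in seq_len(nrow(states))) {
    st <- unlist(states[i, ])
    psi <- compute_psi(hh$ct, st)
    for (x in c("m", "h", "n")) {
      up <- st; up[[x]] <- up[[x]] + h
      dn <- st; dn[[x]] <- dn[[x]] - h
      fd <- abs((quasi_static_potential(hh$ct, up) -
                 quasi_static_potential(hh$ct, dn)) / (2 * h))
      expect_equal(psi[[x]], fd, tolerance = 1e-6)
    }
  }
})

test_that("timescales: tau_hub division, canonical tau_m, form equivalence", {
  ct <- toy_target()
  ts <- compute_timescales(ct, c(V = -50, x = 0.25))
  expect_equal(ts$tau_hub, 1 / (0.25 + 1))  # C / (g1 x + g2)
  expect_equal(ts$taus[["x"]], 2)           # rhs x = (0.5 - x)/2

  hh <- hh_fix()
  ts2 <- compute_timescales(hh$ct, c(V = -65, m = 0.05, h = 0.6, n = 0.3))
  # oracle: tau_m = 1/(alpha_m + beta_m) from the canonical rate formulas
  am <- 0.1 * (-65 + 40) / (1 - exp(-(-65 + 40) / 10))
  bm <- 4 * exp(-(-65 + 65) / 18)
  expect_equal(ts2$taus[["m"]], 1 / (am + bm), tolerance = 1e-12)
  expect_equal(round(ts2$taus[["m"]], 4), 0.2368)

  # alpha/beta and xinf/tau forms of the same kinetics agree
  md_ab <- model_definition("ab", c("V", "x"),
    rhs = list(V = "(gx*x*(0 - V))/C", x = "a*(1 - x) - b*x"),
    params = c(gx = 1, C = 1, a = 0.3, b = 0.7))
  ct_ab <- conductance_target(md_ab, C = 1,
    terms = list(gated_term("xt", "gx*x", "0")), n_check = 10)
  md_it <- model_definition("it", c("V", "x"),
    rhs = list(V = "(gx*x*(0 - V))/C", x = "(xinf - x)/taux"),
    params = c(gx = 1, C = 1, xinf = 0.3, taux = 1))
  ct_it <- conductance_target(md_it, C = 1,
    terms = list(gated_term("xt", "gx*x", "0")), n_check = 10)
  s <- c(V = -10, x = 0.5)
  expect_equal(compute_timescales(ct_ab, s)$taus[["x"]],
               compute_timescales(ct_it, s)$taus[["x"]], tolerance = 1e-12)

  # non-first-order kinetics are rejected
  md_bad <- model_definition("bad", c("V", "x"),
    rhs = list(V = "(gx*x*(0 - V))/C", x = "-x^2"),
    params = c(gx = 1, C = 1))
  expect_error(conductance_target(md_bad, C = 1,
    terms = list(gated_term("xt", "gx*x", "0")), n_check = 0),
    "not first-order")
})

test_that("active set thresholding is inclusive and monotone in gamma", {
  psi <- c(m = 10, h = 1, L = 0.5)
  expect_identical(active_set(psi, 4), "m")
  expect_setequal(active_set(psi, 20), c("m", "h", "L"))
  expect_error(active_set(psi, 1), "gamma must be > 1")
  set.seed(3)
  for (k in 1:20) {
    p <- stats::setNames(stats::runif(5), letters[1:5])
    g1 <- stats::runif(1, 1.1, 5); g2 <- g1 * stats::runif(1, 1, 4)
    expect_true(all(active_set(p, g1) %in% active_set(p, g2)))
    expect_true(names(p)[which.max(p)] %in% active_set(p, g1))
  }
})

# a hand-built target whose influences are exactly Psi_a = 1, Psi_b = t,
# exercising crossing detection and epoch bookkeeping in isolation
synthetic_ct <- function() {
  md <- model_definition("synth", "V", list(V = "0"))
  env <- new.env(parent = make_math_env())
  structure(list(target = "V", C = 1, terms = list(),
                 gating = character(0), sources = c("a", "b"),
                 model = md,
                 psi_fun = function(t, y) c(1, t),
                 den_fun = function(t, y) 1,
                 taub_fun = NULL),
            class = "conductance_target")
}

test_that("epoch extraction solves the two-signal crossing problem", {
  tt <- seq(0, 3, by = 0.01)
  tr <- trajectory(tt, cbind(V = rep(0, length(tt))),
                   derivs = cbind(V = rep(0, length(tt))))
  ep <- extract_epochs(tr, synthetic_ct(), gamma = 2, n_grid = 500)
  expect_length(ep$epochs, 3L)
  expect_setequal(ep$epochs[[1L]]$active, "a")
  expect_setequal(ep$epochs[[2L]]$active, c("a", "b"))
  expect_setequal(ep$epochs[[3L]]$active, "b")
  expect_equal(ep$epochs[[1L]]$interval$hi, 0.5, tolerance = 1e-6)
  expect_equal(ep$epochs[[2L]]$interval$hi, 2.0, tolerance = 1e-6)
  expect_identical(ep$epochs[[1L]]$entry_change, "initial")
  expect_identical(ep$epochs[[2L]]$entry_change,
                   list(kind = "joined", source = "b"))
  expect_identical(ep$epochs[[3L]]$entry_change,
                   list(kind = "left", source = "a"))
  # epochs tile the window
  expect_equal(ep$epochs[[1L]]$interval$lo, 0)
  expect_equal(ep$epochs[[3L]]$interval$hi, 3)
})

test_that("constant influences give a single initial epoch", {
  cts <- synthetic_ct()
  cts$psi_fun <- function(t, y) c(1, 0.3)
  tt <- seq(0, 3, by = 0.05)
  tr <- trajectory(tt, cbind(V = rep(0, length(tt))),
                   derivs = cbind(V = rep(0, length(tt))))
  ep <- extract_epochs(tr, cts, gamma = 2, n_grid = 200)
  expect_length(ep$epochs, 1L)
  expect_identical(ep$epochs[[1L]]$entry_change, "initial")
})

test_that("reduced regimes keep active terms, substitute fast gates, shadow the rest", {
  hh <- hh_fix()
  md <- build_reduced_regime(hh$ct, active = c("m", "Iapp"),
                             algebraic_vars = "m", gamma = 3,
                             name = "upstroke")
  # full state exposure: V dynamic; m algebraic; h, n shadows; s, c frozen
  expect_setequal(model_state_names(md), c("V", "m", "h", "n", "s", "c"))
  expect_identical(names(md$algebraic), "m")
  expect_true(all(c("h", "n") %in% md$vars))
  # structural oracle: rhs V equals the full rhs with leak and K zeroed and
  # m at its asymptote
  cmp <- compile_model(md)
  set_frozen(cmp, c(s = 0, c = 1))
  p <- as.list(hh$model$params)
  minf <- function(v) {
    am <- 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
    bm <- 4 * exp(-(v + 65) / 18)
    am / (am + bm)
  }
  for (V in c(-70, -55, -30, 10)) {
    y <- c(V = V, h = 0.55, n = 0.35)
    got <- cmp$deriv(0, as.numeric(y[md$vars]))[1L]
    want <- (p$gna * minf(V)^3 * 0.55 * (p$ena - V) + p$Iapp) / p$C
    expect_equal(got, want, tolerance = 1e-10)
  }
  # shadow kinetics are the full kinetics (driven by V, no hub feedback)
  expect_identical(md$rhs[["h"]], hh$model$rhs[["h"]])
  expect_identical(md$rhs[["n"]], hh$model$rhs[["n"]])
  # guard events for every source, join for outsiders, leave for members
  ev_names <- vapply(md$events, `[[`, character(1), "name")
  expect_setequal(ev_names, c("leave_m", "join_h", "join_n", "join_leak",
                              "leave_Iapp"))
})

test_that("a passive-only regime follows its linear closed form", {
  hh <- hh_fix()
  md <- build_reduced_regime(hh$ct, active = c("leak", "Iapp"),
                             name = "passive")
  md$events <- list()  # pure flow for the closed-form comparison
  p <- as.list(hh$model$params)
  ic <- c(V = -70, m = 0.05, h = 0.6, n = 0.3, s = 1, c = 1)
  r <- integrate_ode(md, ic, c(0, 5), list(rtol = 1e-10))
  # dV/dt = (gl (el - V) + I)/C -> exponential approach to el + I/gl
  v_inf <- p$el + p$Iapp / p$gl
  tau <- p$C / p$gl
  v_expected <- v_inf + (-70 - v_inf) * exp(-5 / tau)
  expect_equal(as.numeric(traj_eval(r$trajectory, 5, "V")), v_expected,
               tolerance = 1e-6)
  expect_error(build_reduced_regime(hh$ct, active = character(0)),
               "zero conductance and no current")
})

test_that("template comparison is cyclic and template files round-trip", {
  tpl <- structure(list(
    active_sets = list(c("m", "n"), c("m", "h", "n"), c("h", "n"), "n"),
    entries = list(list(kind = "joined", source = "m"),
                   list(kind = "joined", source = "h"),
                   list(kind = "left", source = "m"),
                   list(kind = "left", source = "h")),
    dynamic = list(c("V", "h", "n"), c("V", "m", "h", "n"),
                   c("V", "m", "h", "n"), c("V", "m", "h", "n")),
    algebraic = list("m", character(0), character(0), character(0)),
    regime_ids = paste0("R", 1:4), gamma = 3, rho = 2, n_regimes = 4L),
    class = "regime_template")
  expect_true(compare_templates(tpl, tpl)$match)
  rot <- tpl
  idx <- c(3, 4, 1, 2)
  rot$active_sets <- tpl$active_sets[idx]
  rot$entries <- tpl$entries[idx]
  rot$dynamic <- tpl$dynamic[idx]; rot$algebraic <- tpl$algebraic[idx]
  cmp <- compare_templates(tpl, rot)
  expect_true(cmp$match)
  expect_identical(cmp$rotation, 2L)
  diff1 <- tpl
  diff1$active_sets[[2L]] <- c("m", "h")
  bad <- compare_templates(tpl, diff1)
  expect_false(bad$match)
  expect_match(bad$first_mismatch, "position 2")

  path <- tempfile(fileext = ".txt")
  write_template_file(tpl, path)
  back <- read_template_file(path)
  expect_identical(lapply(back$active_sets, sort),
                   lapply(tpl$active_sets, sort))
  expect_identical(back$entries, tpl$entries)
  expect_true(compare_templates(tpl, back)$match)
})

test_that("a single-element template assembles to a degenerate hybrid model", {
  hh <- hh_fix()
  tpl1 <- structure(list(
    active_sets = list(c("m", "h", "n", "leak", "Iapp")),
    entries = list("initial"),
    dynamic = list(c("V", "m", "h", "n")), algebraic = list(character(0)),
    regime_ids = "R1", gamma = 3, rho = 2, n_regimes = 1L),
    class = "regime_template")
  hm <- assemble_hybrid_reduction(hh$ct, tpl1)
  expect_length(hm$regimes, 1L)
  expect_length(hm$transitions, 0L)
  ic <- c(hh_initial_state(hh))
  ht <- simulate_hybrid(hm, ic, 10)
  expect_length(ht$segments, 1L)
  # with every term active this is the full model: compare against it
  direct <- integrate_ode(hh$model, ic, c(0, 10))
  v_end_red <- hybrid_traj_eval(ht, 10)$state[["V"]]
  v_end_full <- as.numeric(traj_eval(direct$trajectory, 10, "V"))
  expect_equal(v_end_red, v_end_full, tolerance = 1e-4)
})

test_that("epoch reports and influence records serialize", {
  tt <- seq(0, 3, by = 0.01)
  tr <- trajectory(tt, cbind(V = rep(0, length(tt))),
                   derivs = cbind(V = rep(0, length(tt))))
  ep <- extract_epochs(tr, synthetic_ct(), gamma = 2, n_grid = 300)
  rp <- tempfile(fileext = ".txt"); ip <- tempfile(fileext = ".csv")
  write_epochs_report(ep, rp, ip)
  expect_match(readLines(rp)[1L], "gamma")
  infl <- utils::read.csv(ip)
  expect_true(all(c("t", "psi_a", "psi_b", "psi_max") %in% colnames(infl)))
})
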