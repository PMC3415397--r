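test_that("self-transition LIF yields the closed-form spike train", {
  ht <- simulate_hybrid(lif_selfreset(), c(V = 0), 70)
  times <- vapply(ht$transitions_taken, `[[`, numeric(1), "time")
  expect_length(times, 10L)
  expect_equal(times, (1:10) * 10 * log(2), tolerance = 1e-5)
  # segments abut exactly
  los <- vapply(ht$segments, function(sg) sg$traj$domain$lo, numeric(1))
  his <- vapply(ht$segments, function(sg) sg$traj$domain$hi, numeric(1))
  expect_identical(los[-1L], his[-length(his)])
})

test_that("degenerate one-regime hybrid is bit-identical to the plain ODE run", {
  md <- decay_model()
  hm <- hybrid_model(list(regime("only", md)), list(), "V", "only")
  ht <- simulate_hybrid(hm, c(V = 1), 2)
  direct <- integrate_ode(md, c(V = 1), c(0, 2))
  expect_length(ht$segments, 1L)
  expect_identical(ht$segments[[1L]]$traj$samples$values,
                   direct$trajectory$samples$values)
  expect_identical(ht$segments[[1L]]$traj$samples$indep,
                   direct$trajectory$samples$indep)
  expect_length(ht$transitions_taken, 0L)
})

test_that("square-spike model alternates regimes with exact plateaus", {
  hm <- make_lif_squarespike(spike_height = 2, spike_duration = 1)
  ht <- simulate_hybrid(hm, c(V = 0, u = 0), 40)
  regs <- vapply(ht$segments, function(sg) as.character(sg$regime),
                 character(1))
  expect_identical(regs[1:4], c("leaky", "spike", "leaky", "spike"))
  durs <- vapply(ht$segments, function(sg)
    sg$traj$domain$hi - sg$traj$domain$lo, numeric(1))
  plateau <- durs[regs == "spike"]
  plateau <- plateau[seq_len(length(plateau) - 1L)]  # last may be clipped
  expect_equal(plateau, rep(1, length(plateau)), tolerance = 1e-6)
  # plateau value is the configured spike height
  expect_equal(as.numeric(traj_eval(ht$segments[[2L]]$traj,
                                    ht$segments[[2L]]$traj$domain$lo, "V")),
               2)
})

test_that("reset maps: pass-through, simultaneous semantics, config errors", {
  md <- model_definition("two", c("V", "h"), list(V = "0", h = "0"),
    events = list(event_definition("go", "t - 1", 1, TRUE)))
  hm <- hybrid_model(
    list(regime("a", md)),
    list(transition("a", "go", "a", reset = list(V = "0"))),
    c("V", "h"), "a")
  out <- choose_next_regime_and_reset(hm, "a", "go", c(V = 1, h = 0.3))
  expect_identical(out$post_state[["V"]], 0)
  expect_identical(out$post_state[["h"]], 0.3)  # bit-identical pass-through

  hm_swap <- hybrid_model(
    list(regime("a", model_definition("sw", c("a1", "b1"),
      list(a1 = "0", b1 = "0"),
      events = list(event_definition("go", "t - 1", 1, TRUE))))),
    list(transition("a", "go", "a", reset = list(a1 = "b1", b1 = "a1"))),
    c("a1", "b1"), "a")
  sw <- choose_next_regime_and_reset(hm_swap, "a", "go", c(a1 = 1, b1 = 2))
  expect_equal(unclass(sw$post_state)[c("a1", "b1")], c(a1 = 2, b1 = 1))

  hm_dup <- hybrid_model(
    list(regime("a", md)),
    list(transition("a", "go", "a"), transition("a", "go", "a")),
    c("V", "h"), "a")
  expect_error(choose_next_regime_and_reset(hm_dup, "a", "go",
                                            c(V = 1, h = 0)),
               "configuration error")
  expect_error(choose_next_regime_and_reset(hm, "a", "nope",
                                            c(V = 1, h = 0)),
               "dead end")
})

test_that("reset consistency: recorded post-states equal an oracle recomputation", {
  hm <- make_lif_squarespike()
  ht <- simulate_hybrid(hm, c(V = 0, u = 0), 40)
  for (tr in ht$transitions_taken) {
    redo <- choose_next_regime_and_reset(hm, tr$from, tr$trigger,
                                         tr$pre_state)
    expect_identical(redo$post_state, tr$post_state)
  }
})

test_that("embed_state: frozen carried, algebraic recomputed, errors", {
  hh <- hh_fix()
  # frozen n: reduced sub-model exposing n as a dummy constant
  md <- model_definition("frozen_n", c("V"),
                         list(V = "-(V + 60) + n"), frozen = c("n", "m", "h"))
  rg <- regime("r", md)
  ic <- embed_state(rg, c(V = -60, n = 0.4, m = 0.1, h = 0.6))
  r <- integrate_ode(md, ic, c(0, 5))
  expect_true(all(r$trajectory$samples$values[, "n"] == 0.4))

  # algebraic m is recomputed on entry, not inherited
  minf_expr <- hh$ct$xinf_exprs[["m"]]
  md2 <- model_definition("alg_m", c("V"),
    list(V = "0"), algebraic = list(m = expr_text(minf_expr)),
    frozen = c("h", "n"),
    params = hh$model$params, aux_fns = hh$model$aux_fns)
  rg2 <- regime("r2", md2)
  ic2 <- embed_state(rg2, c(V = -60, m = 0.9, h = 0.5, n = 0.4))
  r2 <- integrate_ode(md2, ic2, c(0, 1))
  m_expected <- eval_expression(minf_expr,
                                c(list(V = -60), as.list(hh$model$params)))
  expect_equal(as.numeric(r2$trajectory$samples$values[1, "m"]), m_expected,
               tolerance = 1e-12)
  expect_error(embed_state(rg, c(V = -60)), "missing variable")
})

test_that("hybrid trajectory evaluation uses half-open post-reset semantics", {
  hm <- make_lif_squarespike(spike_height = 2)
  ht <- simulate_hybrid(hm, c(V = 0, u = 0), 20)
  t_reset <- ht$transitions_taken[[1L]]$time
  at <- hybrid_traj_eval(ht, t_reset)
  expect_identical(at$regime, "spike")
  expect_equal(at$state[["V"]], 2)   # post-reset value, not the pre-reset 1
  inside <- hybrid_traj_eval(ht, t_reset / 2)
  expect_identical(inside$regime, "leaky")
  end <- hybrid_traj_eval(ht, ht$domain$hi)
  expect_true(is.finite(end$state[["V"]]))
  expect_error(hybrid_traj_eval(ht, 25), "outside domain")
})

test_that("interpolant derivative matches the vector field along segments", {
  r <- hh_run(10, 120)
  tr <- r$trajectory
  compiled <- compile_model(hh_fix()$model)
  set.seed(7)
  probes <- stats::runif(100, tr$domain$lo + 1, tr$domain$hi - 1)
  h <- 1e-5
  for (tp in probes) {
    y0 <- as.numeric(traj_eval(tr, tp, c("V", "m", "h", "n")))
    fd <- (as.numeric(traj_eval(tr, tp + h, c("V", "m", "h", "n"))) -
           as.numeric(traj_eval(tr, tp - h, c("V", "m", "h", "n")))) / (2 * h)
    f <- compiled$deriv(tp, y0)
    expect_equal(fd, f, tolerance = 1e-4)
  }
})

test_that("nested hybrid models surface unhandled terminal events to the parent", {
  leaky <- model_definition(
    "leaky", c("V", "u"), rhs = list(V = "(-V + drive)/tau", u = "0"),
    params = c(tau = 10, drive = 2, Vth = 1),
    events = list(event_definition("spike", "V - Vth", 1, TRUE)))
  inner <- hybrid_model(list(regime("leaky", leaky)), list(),
                        c("V", "u"), "leaky", name = "inner")
  rest <- model_definition("rest", c("V", "u"),
                           rhs = list(V = "0", u = "1"),
                           params = c(dur = 2),
                           events = list(event_definition("wake", "u - dur",
                                                          1, TRUE)))
  outer <- hybrid_model(
    list(regime("charge", inner), regime("rest", rest)),
    list(transition("charge", "spike", "rest", reset = list(u = "0")),
         transition("rest", "wake", "charge", reset = list(V = "0"))),
    c("V", "u"), "charge", name = "outer")
  ht <- simulate_hybrid(outer, c(V = 0, u = 0), 25)
  trigs <- vapply(ht$transitions_taken, `[[`, character(1), "trigger")
  expect_identical(trigs[1:3], c("spike", "wake", "spike"))
  expect_equal(ht$transitions_taken[[1L]]$time, 10 * log(2),
               tolerance = 1e-5)
  # second charge phase starts from the reset V = 0 and takes as long
  expect_equal(ht$transitions_taken[[3L]]$time -
                 ht$transitions_taken[[2L]]$time, 10 * log(2),
               tolerance = 1e-4)
  regs <- vapply(ht$segments, function(sg) as.character(sg$regime),
                 character(1))
  expect_identical(regs[1:2], c("charge:leaky", "rest"))
})

test_that("hybrid model files round-trip bit-exactly", {
  hm <- make_lif_squarespike()
  p1 <- tempfile(fileext = ".txt"); p2 <- tempfile(fileext = ".txt")
  write_hybrid_model_file(hm, p1)
  back <- read_hybrid_model_file(p1)
  write_hybrid_model_file(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # behavioral equivalence of the reloaded model
  a <- simulate_hybrid(hm, c(V = 0, u = 0), 20)
  b <- simulate_hybrid(back, c(V = 0, u = 0), 20)
  expect_equal(vapply(a$transitions_taken, `[[`, numeric(1), "time"),
               vapply(b$transitions_taken, `[[`, numeric(1), "time"))
})

test_that("stitched CSV output carries a regime column", {
  hm <- make_lif_squarespike()
  ht <- simulate_hybrid(hm, c(V = 0, u = 0), 20)
  path <- tempfile(fileext = ".csv")
  write_hybrid_trajectory_csv(ht, path)
  df <- utils::read.csv(path)
  expect_true(all(c("t", "V", "u", "regime") %in% colnames(df)))
  expect_setequal(unique(df$regime), c("leaky", "spike"))
})
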