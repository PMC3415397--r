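test_that("linear decay integrates to its closed form", {
  r <- integrate_ode(decay_model(), c(V = 1), c(0, 1),
                     list(rtol = 1e-10, atol = 1e-12))
  expect_equal(as.numeric(traj_eval(r$trajectory, 1, "V")), exp(-1),
               tolerance = 1e-8)
  expect_identical(r$terminated_by, "t_end")
})

test_that("tightening tolerances never worsens the endpoint error", {
  errs <- vapply(c(1e-6, 1e-8, 1e-10), function(rt) {
    r <- integrate_ode(decay_model(), c(V = 1), c(0, 1),
                       list(rtol = rt, atol = rt * 1e-2))
    abs(as.numeric(traj_eval(r$trajectory, 1, "V")) - exp(-1))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("a constant field stays constant to machine precision", {
  md <- model_definition("flat", "V", list(V = "0"))
  r <- integrate_ode(md, c(V = 3.25), c(0, 100))
  expect_true(all(r$trajectory$samples$values[, "V"] == 3.25))
})

test_that("dense output: endpoint identity, closed form, cubic exactness", {
  r <- integrate_ode(decay_model(), c(V = 1), c(0, 0.1))
  st <- r$steps[[1L]]
  expect_identical(dense_eval(st, st$t0), st$y0)
  expect_identical(dense_eval(st, st$t1), st$y1)
  # step containing t = 0.05: dense output vs the closed form
  mid <- Find(function(s) s$t0 <= 0.05 && 0.05 <= s$t1, r$steps)
  expect_lt(abs(as.numeric(dense_eval(mid, 0.05)) - exp(-0.05)), 1e-7)
  # exact endpoint data of y = t^3 reproduces the cubic at interior points
  cube <- hybridsys:::step_record(1, 2, y0 = 1, y1 = 8, f0 = 3, f1 = 12)
  for (s in seq(1.1, 1.9, by = 0.2))
    expect_equal(as.numeric(dense_eval(cube, s)), s^3, tolerance = 1e-12)
  expect_error(dense_eval(cube, 2.5), "outside step")
})

test_that("non-terminal events are side-effect-free observations", {
  md_plain <- decay_model()
  md_obs <- model_definition("decay_obs", "V", list(V = "-V"),
    events = list(event_definition("half", "V - 0.5", direction = -1,
                                   terminal = FALSE)))
  a <- integrate_ode(md_plain, c(V = 1), c(0, 2))
  b <- integrate_ode(md_obs, c(V = 1), c(0, 2))
  expect_identical(a$trajectory$samples$values, b$trajectory$samples$values)
  expect_identical(a$trajectory$samples$indep, b$trajectory$samples$indep)
  expect_length(b$events_hit, 1L)
  expect_equal(b$events_hit[[1L]]$t_star, log(2), tolerance = 1e-6)
  expect_true("half" %in% names(b$trajectory$samples$labels))
})

test_that("state leaving its domain raises an error naming the variable", {
  md <- model_definition("grow", "x", list(x = "x"),
                         domains = list(x = interval(0, 2)))
  expect_error(integrate_ode(md, c(x = 1), c(0, 3)), "'x' left its domain")
})

test_that("algebraic variables are computed by substitution", {
  md <- model_definition("alg", "x", list(x = "-x"),
                         algebraic = list(y = "2*x", z = "y + 1"))
  r <- integrate_ode(md, c(x = 1), c(0, 1))
  vals <- r$trajectory$samples$values
  expect_equal(as.numeric(vals[, "y"]), 2 * as.numeric(vals[, "x"]),
               tolerance = 1e-12)
  expect_equal(as.numeric(vals[, "z"]), as.numeric(vals[, "y"]) + 1,
               tolerance = 1e-12)
  # interpolation of algebraic columns is consistent too
  mid <- traj_eval(r$trajectory, 0.37)
  expect_equal(mid[["y"]], 2 * mid[["x"]], tolerance = 1e-6)
})

test_that("unhoused symbols are a validation error", {
  expect_error(model_definition("bad", "x", list(x = "-k*x")),
               "unhoused symbol.*k")
  expect_error(model_definition("bad2", "x", list(x = "foo(x)")),
               "unknown function.*foo")
})

test_that("auxiliary generators: explicit, map, playback", {
  tr <- generate_aux("explicit", list(x = "sin(t)"), tspan = c(0, 2 * pi),
                     n = 101L)
  expect_equal(as.numeric(traj_eval(tr, pi / 2, "x")), 1.0, tolerance = 1e-9)
  ps <- generate_aux("map", list(update = list(x = "x/2"),
                                 init = c(x = 8)), n = 3)
  expect_equal(as.numeric(ps$values[, "x"]), c(8, 4, 2, 1))
  expect_equal(ps$indep, 0:3)
  pb <- generate_aux("playback", data.frame(t = c(0, 2), v = c(0, 4)))
  expect_equal(as.numeric(traj_eval(pb, 1)), 2.0)
  expect_error(generate_aux("playback",
                            data.frame(t = c(0, 0), v = c(1, 2))),
               "strictly increasing")
})

test_that("external-input playback drives a model", {
  md <- model_definition("driven", "x", list(x = "J"),
                         external_inputs = list(J = cbind(c(0, 10),
                                                          c(2, 2))))
  r <- integrate_ode(md, c(x = 0), c(0, 5))
  expect_equal(as.numeric(traj_eval(r$trajectory, 5, "x")), 10,
               tolerance = 1e-8)
})

test_that("model files round-trip bit-exactly", {
  hh <- hh_fix()$model
  p1 <- tempfile(fileext = ".txt"); p2 <- tempfile(fileext = ".txt")
  write_model_file(hh, p1)
  back <- read_model_file(p1)
  write_model_file(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(model_state_names(back), model_state_names(hh))
  expect_identical(back$params, hh$params)
  # model with events, frozen vars and an external input
  md <- model_definition(
    "toy", c("x"), list(x = "-a*x + J"), params = c(a = 0.5),
    frozen = "s", algebraic = list(y = "s*x^2"),
    aux_fns = list(f = aux_fn("u", "tanh(u)")),
    events = list(event_definition("cross", "x - 0.25", -1, TRUE, 1e-9)),
    domains = list(x = interval(-10, 10)),
    external_inputs = list(J = cbind(c(0, 1, 3), c(0, 0.5, 0.5))))
  write_model_file(md, p1)
  b2 <- read_model_file(p1)
  write_model_file(b2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(b2$rhs, md$rhs)
  expect_identical(b2$events[[1L]]$tol_t, md$events[[1L]]$tol_t)
})

test_that("trajectory CSV serialization round-trips values", {
  r <- integrate_ode(decay_model(), c(V = 1), c(0, 1))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(r$trajectory, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$samples$values[, "V"],
               r$trajectory$samples$values[, "V"], ignore_attr = TRUE)
})
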