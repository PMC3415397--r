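test_that("a neutral model interface is observationally equivalent", {
  mi <- model_interface(decay_model())
  out <- run_with_validation(mi, ic = c(V = 1), t_end = 2)
  direct <- integrate_ode(decay_model(), c(V = 1), c(0, 2))
  expect_identical(out$result$samples$values,
                   direct$trajectory$samples$values)
  expect_false(out$report$recovery_invoked)
  expect_true(out$report$overall)

  mi_h <- model_interface(lif_selfreset())
  out_h <- run_with_validation(mi_h, ic = c(V = 0), t_end = 30)
  direct_h <- simulate_hybrid(lif_selfreset(), c(V = 0), 30)
  expect_identical(
    vapply(out_h$result$transitions_taken, `[[`, numeric(1), "time"),
    vapply(direct_h$transitions_taken, `[[`, numeric(1), "time"))
})

test_that("failure recovery returns the sentinel instead of an error", {
  hh <- hh_fix()
  broken <- hh$model
  broken$params[["C"]] <- -1  # absurd negative capacitance
  mi <- model_interface(broken, sentinel = 1e10)
  out <- run_with_validation(mi, ic = hh_initial_state(hh), t_end = 50)
  expect_null(out$result)
  expect_true(out$report$recovery_invoked)
  expect_identical(out$objective_value, 1e10)
  # sentinel iff recovery: a successful run does not return it
  ok <- run_with_validation(model_interface(decay_model()),
                            ic = c(V = 1), t_end = 1,
                            objective = feature("endpoint",
                              function(traj, ref)
                                as.numeric(traj_eval(traj, 1, "V"))))
  expect_false(ok$report$recovery_invoked)
  expect_lt(abs(ok$objective_value - exp(-1)), 1e-6)
})

test_that("spike-count conditions pass and fail as the drive dictates", {
  cond <- condition(list(feature_spike_count(var = "V", level = 0.9,
                                             min_count = 1)))
  supra <- simulate_hybrid(lif_selfreset(), c(V = 0), 70)
  rep1 <- evaluate_condition(cond, supra)
  expect_true(rep1$overall)
  expect_gte(rep1$table$value[1L], 10)

  # sub-threshold drive: V -> 0.5 < 1, no crossings of 0.9
  sub_md <- lif_model(drive = 0.5)
  sub_run <- integrate_ode(sub_md, c(V = 0), c(0, 200))
  expect_identical(sub_run$terminated_by, "t_end")
  rep2 <- evaluate_condition(cond, sub_run$trajectory)
  expect_false(rep2$overall)
  expect_identical(rep2$table$value[1L], 0)
})

test_that("condition reports list every feature without short-circuiting", {
  boom <- feature("boom", function(traj, ref) stop("internal failure"))
  count <- feature_spike_count(level = 0.9)
  cond <- condition(list(boom, count, boom), targets = c(TRUE, TRUE, FALSE))
  run <- simulate_hybrid(lif_selfreset(), c(V = 0), 30)
  rep <- evaluate_condition(cond, run)
  expect_identical(nrow(rep$table), 3L)
  expect_false(rep$table$pass[1L])
  expect_match(rep$table$note[1L], "internal failure")
  expect_true(rep$table$pass[2L])
  expect_false(rep$overall)
  # evaluation order does not affect the report contents
  rep_rev <- evaluate_condition(condition(list(count, boom, boom),
                                          targets = c(TRUE, TRUE, FALSE)),
                                run)
  expect_setequal(rep_rev$table$feature, rep$table$feature)
  expect_identical(sort(rep_rev$table$pass), sort(rep$table$pass))
})

test_that("post-hooks transform a copy of the output", {
  # subsample to a fixed 1 ms grid: t_end + 1 rows for integer t_end
  t_end <- 20
  mi <- model_interface(decay_model(), post = function(traj) {
    grid <- seq(0, t_end, by = 1)
    pointset(traj_eval(traj, grid, "V"), "V", indep = grid)
  })
  out <- run_with_validation(mi, ic = c(V = 1), t_end = t_end)
  expect_identical(nrow(out$result$values), as.integer(t_end) + 1L)
})

test_that("reference-comparison feature and report serialization", {
  a <- integrate_ode(decay_model(), c(V = 1), c(0, 1))$trajectory
  b <- integrate_ode(decay_model(), c(V = 1.01), c(0, 1))$trajectory
  f <- feature_max_abs_difference("V", tol = 0.02)
  expect_lt(f$measure(a, b), 0.011)
  expect_true(f$compare(f$measure(a, b)))

  rep_path <- tempfile(fileext = ".csv")
  run <- simulate_hybrid(lif_selfreset(), c(V = 0), 30)
  cond <- condition(list(feature_spike_count(level = 0.9)))
  write_condition_report_csv(evaluate_condition(cond, run), rep_path)
  expect_true(file.exists(rep_path))
  expect_identical(nrow(utils::read.csv(rep_path)), 1L)
})
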