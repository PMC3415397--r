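test_that("parsing: arithmetic, symbols, malformed input", {
  expect_equal(eval_expression(parse_expression("2*3+1")), 7)
  e <- parse_expression("gna*m^3*h*(ena - v)")
  expect_setequal(expr_symbols(e), c("gna", "m", "h", "ena", "v"))
  expect_error(parse_expression("exp("), "syntax error")
  expect_error(parse_expression("x %% 2"), "syntax error")
  expect_error(parse_expression("if (x) 1 else 2"), "syntax error")
})

test_that("parse-print-parse round trip preserves structure", {
  texts <- c("2*3+1", "gna*m^3*h*(ena - v)", "exp(-(v + 40)/10)",
             "max(min(a, b), heaviside(x - 1))", "-x^2",
             "0.1*(v+40)/(1-exp(-(v+40)/10))")
  for (tx in texts) {
    e <- parse_expression(tx)
    expect_identical(parse_expression(expr_text(e)), e)
  }
})

test_that("evaluation: bindings, numeric-domain errors, heaviside", {
  expect_equal(eval_expression("exp(0)"), 1.0)
  # standard HH alpha_m rate at -65 mV against a direct closed-form oracle
  alpha_m <- function(v) 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  got <- eval_expression("0.1*(v+40)/(1-exp(-(v+40)/10))", list(v = -65))
  expect_equal(got, alpha_m(-65), tolerance = 1e-12)
  expect_equal(round(got, 5), 0.22356)
  expect_error(eval_expression("log(x)", list(x = -1)), "numeric-domain")
  expect_error(eval_expression("sqrt(x)", list(x = -4)), "numeric-domain")
  expect_error(eval_expression("a + b", list(a = 1)), "unbound symbol.*b")
  expect_equal(eval_expression("heaviside(x)", list(x = 0)), 0.5)
  expect_equal(eval_expression("heaviside(x)", list(x = 2)), 1)
  expect_equal(eval_expression("pow(x, 3)", list(x = 2)), 8)
})

test_that("substitution is structural and simultaneous", {
  got <- substitute_expression(parse_expression("m^3"),
                               list(m = parse_expression("minf(v)")))
  expect_identical(expr_text(got), "minf(v)^3")
  swap <- substitute_expression(parse_expression("a + b"),
                                list(a = quote(b), b = quote(a)))
  expect_identical(expr_text(swap), "b + a")
  # substitute-then-eval equals eval with composed bindings
  r <- make_rng(101)
  for (k in 1:20) {
    e <- random_expr(3L, c("x", "y"), r)
    repl <- random_expr(2L, c("y"), r)
    sub <- substitute_expression(e, list(x = repl))
    y0 <- stats::runif(1, 0.4, 1.6)
    direct <- eval_expression(sub, list(y = y0))
    composed <- eval_expression(e, list(x = eval_expression(repl, list(y = y0)),
                                        y = y0))
    expect_equal(direct, composed, tolerance = 1e-12)
  }
})

test_that("symbolic differentiation: rules and linearity", {
  d <- differentiate_expression("x^3", "x")
  expect_equal(eval_expression(d, list(x = 2)), 12)
  d2 <- differentiate_expression("g*x*(e - v)", "v")
  for (k in 1:5) {
    b <- list(g = stats::runif(1), x = stats::runif(1), e = stats::runif(1),
              v = stats::runif(1))
    expect_equal(eval_expression(d2, b), -b$g * b$x, tolerance = 1e-12)
  }
  expect_error(differentiate_expression("heaviside(x)", "x"),
               "non-differentiable")
  expect_error(differentiate_expression("min(x, 1)", "x"),
               "non-differentiable")
  # an auxiliary call not involving the symbol differentiates to zero
  expect_equal(differentiate_expression("am(v)*(1 - m) - bm(v)*m", "m") |>
                 eval_expression(list(v = 0, m = 0.5,
                                      am = function(v) 2, bm = function(v) 3)),
               -5)
})

test_that("differentiation agrees with central finite differences on a corpus", {
  r <- make_rng(202)
  n_checked <- 0L
  k <- 0L
  while (n_checked < 50L && k < 500L) {
    k <- k + 1L
    e <- random_expr(3L, c("x", "y"), r)
    if (!("x" %in% expr_symbols(e))) next
    de <- differentiate_expression(e, "x")
    x0 <- stats::runif(1, 0.4, 1.6); y0 <- stats::runif(1, 0.4, 1.6)
    h <- 1e-6
    fd <- (eval_expression(e, list(x = x0 + h, y = y0)) -
           eval_expression(e, list(x = x0 - h, y = y0))) / (2 * h)
    an <- eval_expression(de, list(x = x0, y = y0))
    if (abs(fd) < 1e-8) next  # skip degenerate points
    expect_equal(an, fd, tolerance = 1e-6)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 50L)
})
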