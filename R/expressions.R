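#' @title Expression language for right-hand sides, guards and auxiliaries
#' @description
#' Model right-hand sides, guard functions and auxiliary definitions are
#' small arithmetic expressions over named symbols: numbers, `+ - * / ^`,
#' parentheses, and the functions `exp, log, sin, cos, tanh, sqrt, abs, pow,
#' min, max, heaviside`, plus calls to user-declared auxiliary functions.
#' Expressions are stored as R language objects; correctness is defined by
#' evaluation, not by any normal form (no algebraic simplification is
#' attempted). `heaviside(0)` evaluates to `0.5` (symmetric convention).
#' Symbol names are case-sensitive.
#' @name expressions
NULL

.expr_binops <- c("+", "-", "*", "/", "^")
.expr_funs <- c("exp", "log", "sin", "cos", "tanh", "sqrt", "abs",
                "pow", "min", "max", "heaviside")

# shared evaluation environment with the grammar's function set;
# log/sqrt raise numeric-domain errors instead of returning NaN
make_math_env <- function(parent = baseenv()) {
  e <- new.env(parent = parent)
  e$exp <- exp; e$sin <- sin; e$cos <- cos; e$tanh <- tanh; e$abs <- abs
  e$log <- function(x) {
    if (any(x <= 0)) stop("numeric-domain error: log of non-positive value")
    base::log(x)
  }
  e$sqrt <- function(x) {
    if (any(x < 0)) stop("numeric-domain error: sqrt of negative value")
    base::sqrt(x)
  }
  e$pow <- function(a, b) a^b
  e$min <- function(...) base::min(...)
  e$max <- function(...) base::max(...)
  e$heaviside <- function(x) ifelse(x > 0, 1, ifelse(x < 0, 0, 0.5))
  e$pi <- pi
  e
}

#' Parse an expression string
#'
#' @param text A single string in the expression grammar.
#' @param allow_aux_calls If `TRUE` (default) calls to functions outside the
#'   built-in set are allowed (they must resolve to auxiliary functions at
#'   evaluation time).
#' @return An expression tree (R language object).
#' @export
parse_expression <- function(text, allow_aux_calls = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text),
                error = function(err) {
                  stop("syntax error in expression \"", text, "\": ",
                       conditionMessage(err), call. = FALSE)
                })
  validate_expr(e, text, allow_aux_calls)
  e
}

validate_expr <- function(e, text, allow_aux_calls = TRUE) {
  if (is.numeric(e) || is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    head <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    reserved <- c("if", "else", "for", "while", "repeat", "function",
                  "return", "break", "next")
    is_identifier <- grepl("^[A-Za-z][A-Za-z0-9_.]*$", head) &&
      !(head %in% reserved)
    ok <- head %in% c(.expr_binops, .expr_funs, "(") ||
      (allow_aux_calls && is_identifier)
    if (!ok || is.call(e[[1L]]))
      stop("syntax error in expression \"", text, "\": operator or construct '",
           head, "' is not in the grammar", call. = FALSE)
    for (a in args) validate_expr(a, text, allow_aux_calls)
    return(invisible(TRUE))
  }
  stop("syntax error in expression \"", text, "\": unsupported element",
       call. = FALSE)
}

#' Free symbols of an expression
#' @param e Expression tree.
#' @return Character vector of symbol names (call heads and `pi` excluded).
#' @export
expr_symbols <- function(e) {
  syms <- character(0)
  walk <- function(x) {
    if (is.symbol(x)) {
      syms[[length(syms) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      for (a in as.list(x)[-1L]) walk(a)
    }
  }
  walk(e)
  setdiff(unique(syms), "pi")
}

#' Function names called by an expression
#' @param e Expression tree.
#' @return Character vector of call heads (including operators).
#' @export
expr_functions <- function(e) {
  fns <- character(0)
  walk <- function(x) {
    if (is.call(x)) {
      fns[[length(fns) + 1L]] <<- as.character(x[[1L]])
      for (a in as.list(x)[-1L]) walk(a)
    }
  }
  walk(e)
  unique(fns)
}

#' Deparse an expression tree back to text
#' @param e Expression tree.
#' @return A single string; `parse_expression(expr_text(e))` reproduces `e`.
#' @export
expr_text <- function(e) {
  paste(deparse(e, width.cutoff = 500L), collapse = " ")
}

#' Evaluate an expression under symbol bindings
#'
#' @param e Expression tree (or string, parsed on the fly).
#' @param bindings Named list/vector: numerics for symbols, functions for
#'   auxiliary calls.
#' @return Numeric scalar.
#' @export
eval_expression <- function(e, bindings = list()) {
  if (is.character(e)) e <- parse_expression(e)
  bindings <- as.list(bindings)
  free <- expr_symbols(e)
  unbound <- setdiff(free, names(bindings))
  if (length(unbound))
    stop("eval_expression: unbound symbol(s): ", paste(unbound, collapse = ", "))
  env <- list2env(bindings, parent = make_math_env())
  eval(e, env)
}

#' Simultaneous structural substitution
#'
#' Every occurrence of each mapped symbol is replaced by a copy of its
#' replacement tree; substitution is simultaneous (replacement trees are not
#' re-scanned), so `{a -> b, b -> a}` swaps without cascading.
#'
#' @param e Expression tree.
#' @param mapping Named list: symbol name -> replacement tree (or string).
#' @return New expression tree.
#' @export
substitute_expression <- function(e, mapping) {
  mapping <- lapply(mapping, function(m) if (is.character(m)) parse_expression(m) else m)
  walk <- function(x) {
    if (is.symbol(x)) {
      nm <- as.character(x)
      if (nm %in% names(mapping)) return(mapping[[nm]])
      return(x)
    }
    if (is.call(x)) {
      # call heads are not substituted
      for (i in seq_along(x)[-1L]) x[[i]] <- walk(x[[i]])
      return(x)
    }
    x
  }
  walk(e)
}

is_zero_expr <- function(e) is.numeric(e) && length(e) == 1L && e == 0
is_one_expr <- function(e) is.numeric(e) && length(e) == 1L && e == 1

# minimal constructors that fold the trivial identities so derivatives stay
# readable; no further simplification guarantees
mk_add <- function(a, b) {
  if (is_zero_expr(a)) return(b)
  if (is_zero_expr(b)) return(a)
  call("+", a, b)
}
mk_sub <- function(a, b) {
  if (is_zero_expr(b)) return(a)
  if (is_zero_expr(a)) return(call("-", b))
  call("-", a, b)
}
mk_mul <- function(a, b) {
  if (is_zero_expr(a) || is_zero_expr(b)) return(0)
  if (is_one_expr(a)) return(b)
  if (is_one_expr(b)) return(a)
  call("*", a, b)
}
mk_div <- function(a, b) {
  if (is_zero_expr(a)) return(0)
  if (is_one_expr(b)) return(a)
  call("/", a, b)
}

#' Exact symbolic differentiation
#'
#' Differentiates an expression with respect to one symbol. `heaviside`,
#' `min` and `max` are non-differentiable and raise an error; `abs` is
#' differentiated as `u/abs(u) * u'` (valid away from `u = 0`). A call to an
#' auxiliary function not containing the differentiation symbol contributes
#' zero; one that does contain it raises an error (auxiliary definitions must
#' be substituted in first).
#'
#' @param e Expression tree (or string).
#' @param sym Symbol name to differentiate with respect to.
#' @return Expression tree of the derivative.
#' @export
differentiate_expression <- function(e, sym) {
  if (is.character(e)) e <- parse_expression(e)
  stopifnot(is.character(sym), length(sym) == 1L)
  d <- function(x) {
    if (is.numeric(x)) return(0)
    if (is.symbol(x)) return(if (as.character(x) == sym) 1 else 0)
    head <- as.character(x[[1L]])
    args <- as.list(x)[-1L]
    if (head == "(") return(d(args[[1L]]))
    if (head == "+") {
      if (length(args) == 1L) return(d(args[[1L]]))
      return(mk_add(d(args[[1L]]), d(args[[2L]])))
    }
    if (head == "-") {
      if (length(args) == 1L) {
        du <- d(args[[1L]])
        return(if (is_zero_expr(du)) 0 else call("-", du))
      }
      return(mk_sub(d(args[[1L]]), d(args[[2L]])))
    }
    if (head == "*")
      return(mk_add(mk_mul(d(args[[1L]]), args[[2L]]),
                    mk_mul(args[[1L]], d(args[[2L]]))))
    if (head == "/") {
      u <- args[[1L]]; v <- args[[2L]]
      return(mk_sub(mk_div(d(u), v),
                    mk_div(mk_mul(u, d(v)), call("^", v, 2))))
    }
    if (head == "^" || head == "pow") {
      u <- args[[1L]]; v <- args[[2L]]
      du <- d(u); dv <- d(v)
      if (is_zero_expr(dv)) {
        # power rule with constant exponent: v * u^(v-1) * du
        vm1 <- if (is.numeric(v)) v - 1 else call("-", v, 1)
        return(mk_mul(mk_mul(v, call("^", u, vm1)), du))
      }
      # general: u^v * (dv*log(u) + v*du/u)
      return(mk_mul(call("^", u, v),
                    mk_add(mk_mul(dv, call("log", u)),
                           mk_div(mk_mul(v, du), u))))
    }
    if (head %in% c("heaviside", "min", "max"))
      stop("differentiate_expression: non-differentiable node '", head, "'")
    if (head %in% .expr_funs) {
      u <- args[[1L]]
      du <- d(u)
      outer <- switch(head,
        exp = call("exp", u),
        log = mk_div(1, u),
        sin = call("cos", u),
        cos = call("-", call("sin", u)),
        tanh = mk_sub(1, call("^", call("tanh", u), 2)),
        sqrt = mk_div(1, mk_mul(2, call("sqrt", u))),
        abs = mk_div(u, call("abs", u)),
        stop("differentiate_expression: unhandled function '", head, "'"))
      return(mk_mul(outer, du))
    }
    # auxiliary call: zero unless the symbol occurs inside
    if (!(sym %in% expr_symbols(x))) return(0)
    stop("differentiate_expression: cannot differentiate through auxiliary ",
         "call '", head, "' containing '", sym, "'")
  }
  d(e)
}
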