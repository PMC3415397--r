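#' Auxiliary trajectory generators: explicit functions, maps, playback
#'
#' Three non-ODE generators share one entry point:
#' \describe{
#'   \item{`explicit`}{`spec` is a named list of expressions in `t` (plus an
#'     optional `params` entry); returns a Trajectory sampled on `n` points of
#'     `tspan` whose interpolation is backed by exact formula evaluation.}
#'   \item{`map`}{`spec` gives `update` (named list of update expressions,
#'     simultaneous semantics), `init` (named start values), optional
#'     `params`; iterated `n` times; returns a Pointset of `n + 1` iterates
#'     with indep `0..n`.}
#'   \item{`playback`}{`spec` is a two-column (t, value) table (or a named
#'     list of them); returns a linearly interpolating Trajectory over the
#'     series' time domain, with no extrapolation.}
#' }
#'
#' @param kind `"explicit"`, `"map"` or `"playback"`.
#' @param spec See Details.
#' @param tspan Time interval (explicit) — [interval()] or `c(t0, t1)`.
#' @param n Number of samples (explicit, default 201) or iteration count
#'   (map).
#' @return A [trajectory()] or [pointset()].
#' @export
generate_aux <- function(kind = c("explicit", "map", "playback"), spec,
                         tspan = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "explicit") {
    if (is.null(n)) n <- 201L
    if (is_interval(tspan)) tspan <- c(tspan$lo, tspan$hi)
    params <- as.list(spec$params %||% list())
    exprs <- spec[setdiff(names(spec), "params")]
    exprs <- lapply(exprs, function(e) if (is.character(e)) parse_expression(e) else e)
    ts <- seq(tspan[1L], tspan[2L], length.out = n)
    env <- list2env(params, parent = make_math_env())
    vals <- sapply(names(exprs), function(v)
      vapply(ts, function(tt) { env$t <- tt; eval(exprs[[v]], env) }, numeric(1)))
    dvs <- sapply(names(exprs), function(v) {
      de <- differentiate_expression(exprs[[v]], "t")
      vapply(ts, function(tt) { env$t <- tt; eval(de, env) }, numeric(1))
    })
    return(trajectory(ts, as.matrix(vals), names(exprs),
                      derivs = as.matrix(dvs), interp = "hermite"))
  }
  if (kind == "map") {
    stopifnot(!is.null(n), n >= 0)
    params <- as.list(spec$params %||% list())
    update <- lapply(spec$update, function(e) if (is.character(e)) parse_expression(e) else e)
    state <- unlist(spec$init)
    vars <- names(update)
    if (!all(vars %in% names(state)))
      stop("generate_aux(map): init must bind every updated variable")
    out <- matrix(NA_real_, n + 1L, length(vars), dimnames = list(NULL, vars))
    out[1L, ] <- state[vars]
    env <- list2env(params, parent = make_math_env())
    for (i in seq_len(n)) {
      for (v in vars) assign(v, out[i, v], envir = env)
      out[i + 1L, ] <- vapply(vars, function(v) eval(update[[v]], env), numeric(1))
    }
    return(pointset(out, vars, indep = 0:n))
  }
  # playback
  tabs <- if (is.data.frame(spec) || is.matrix(spec)) list(x = spec) else spec
  first <- as.matrix(tabs[[1L]])
  ts <- as.numeric(first[, 1L])
  if (any(diff(ts) <= 0))
    stop("generate_aux(playback): format error: times must be strictly increasing")
  vals <- sapply(names(tabs), function(nm) {
    m <- as.matrix(tabs[[nm]])
    if (!isTRUE(all.equal(as.numeric(m[, 1L]), ts)))
      stop("generate_aux(playback): all series must share the same times")
    as.numeric(m[, 2L])
  })
  trajectory(ts, as.matrix(vals), names(tabs), interp = "linear")
}

#' Read an external-input series from a two-column CSV
#' @param path CSV with header and columns (t, value).
#' @return Two-column data frame suitable for `external_inputs` /
#'   `generate_aux("playback", ...)`.
#' @export
read_external_input_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("external input CSV needs two columns (t, value)")
  df[, 1:2]
}
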