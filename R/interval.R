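#' Numeric interval with endpoint tolerance
#'
#' Intervals represent variable domains and time spans. Membership of an
#' endpoint is true iff the endpoint is closed *or* the probe lies within
#' `tol` of it; this guarantees that event-located times sitting exactly on a
#' regime boundary test as in-domain for both adjacent segments.
#'
#' @param lo,hi Numeric endpoints, `lo <= hi`.
#' @param closed_lo,closed_hi Logical; whether each endpoint belongs to the
#'   interval. Closed by default.
#' @param tol Non-negative absolute endpoint tolerance (same units as
#'   `lo`/`hi`). Default `1e-12`.
#' @return An object of class `"interval"`.
#' @examples
#' iv <- interval(0, 1)
#' interval_query(iv, 0.5, "contains")
#' @export
interval <- function(lo, hi, closed_lo = TRUE, closed_hi = TRUE, tol = 1e-12) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (is.na(lo) || is.na(hi) || lo > hi)
    stop("interval: need lo <= hi (got [", lo, ", ", hi, "])")
  if (tol < 0) stop("interval: tol must be >= 0")
  structure(list(lo = lo, hi = hi,
                 closed_lo = isTRUE(closed_lo), closed_hi = isTRUE(closed_hi),
                 tol = tol, empty = FALSE),
            class = "interval")
}

empty_interval <- function(tol = 1e-12) {
  iv <- interval(0, 0, FALSE, FALSE, tol)
  iv$empty <- TRUE
  iv
}

#' @export
print.interval <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<empty interval>\n")
  } else {
    cat(if (x$closed_lo) "[" else "(", x$lo, ", ", x$hi,
        if (x$closed_hi) "]" else ")", "  tol=", x$tol, "\n", sep = "")
  }
  invisible(x)
}

is_interval <- function(x) inherits(x, "interval")

#' Query an interval: membership, intersection, endpoint testing
#'
#' @param iv An [interval()].
#' @param probe A single numeric (`mode = "contains"` / `"at_endpoint"`) or a
#'   second interval (`mode = "intersect"`).
#' @param mode One of `"contains"`, `"intersect"`, `"at_endpoint"`.
#' @return `contains`/`at_endpoint`: a logical scalar. `intersect`: the
#'   intersection interval; an empty intersection is flagged via its `empty`
#'   field.
#' @details Endpoint membership follows the `tol` rule documented in
#'   [interval()]. Intersection is commutative and idempotent; intersecting an
#'   interval with itself returns an interval equal to itself.
#' @export
interval_query <- function(iv, probe, mode = c("contains", "intersect", "at_endpoint")) {
  mode <- match.arg(mode)
  stopifnot(is_interval(iv))
  if (mode == "intersect") {
    if (!is_interval(probe))
      stop("interval_query: mode 'intersect' requires an interval probe")
    if (isTRUE(iv$empty) || isTRUE(probe$empty)) return(empty_interval(iv$tol))
    if (iv$lo > probe$lo) { lo <- iv$lo; clo <- iv$closed_lo }
    else if (iv$lo < probe$lo) { lo <- probe$lo; clo <- probe$closed_lo }
    else { lo <- iv$lo; clo <- iv$closed_lo && probe$closed_lo }
    if (iv$hi < probe$hi) { hi <- iv$hi; chi <- iv$closed_hi }
    else if (iv$hi > probe$hi) { hi <- probe$hi; chi <- probe$closed_hi }
    else { hi <- iv$hi; chi <- iv$closed_hi && probe$closed_hi }
    tol <- min(iv$tol, probe$tol)
    if (lo > hi || (lo == hi && !(clo && chi))) return(empty_interval(tol))
    return(interval(lo, hi, clo, chi, tol))
  }
  if (!is.numeric(probe) || length(probe) != 1L)
    stop("interval_query: mode '", mode, "' requires a single numeric probe")
  if (isTRUE(iv$empty)) return(FALSE)
  at_lo <- abs(probe - iv$lo) <= iv$tol
  at_hi <- abs(probe - iv$hi) <= iv$tol
  if (mode == "at_endpoint") return(at_lo || at_hi)
  # contains
  if (probe > iv$lo && probe < iv$hi) return(TRUE)
  if (probe == iv$lo && iv$closed_lo) return(TRUE)
  if (probe == iv$hi && iv$closed_hi) return(TRUE)
  at_lo || at_hi
}
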