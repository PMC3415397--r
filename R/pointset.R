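#' Labelled point collections
#'
#' A pointset is an N x d numeric array with named columns, an optional
#' strictly increasing independent variable parameterizing the rows, and
#' metadata labels mapping a label string to a *set* of row indices (so that
#' repeated events, e.g. several spikes, share one label).
#'
#' @param values Numeric matrix (or vector for a single row/column).
#' @param names Character vector of variable names; defaults to
#'   `colnames(values)`.
#' @param indep Optional numeric vector of length `nrow(values)`, strictly
#'   increasing.
#' @param labels Named list mapping label -> integer row indices (1-based).
#' @return An object of class `"pointset"`.
#' @export
pointset <- function(values, names = NULL, indep = NULL, labels = list()) {
  values <- as.matrix(values)
  if (is.null(names)) names <- colnames(values)
  if (is.null(names)) stop("pointset: variable names required")
  names <- as.character(names)
  if (length(names) != ncol(values))
    stop("pointset: ", length(names), " names for ", ncol(values), " columns")
  if (anyDuplicated(names)) stop("pointset: duplicate variable names")
  colnames(values) <- names
  if (!is.null(indep)) {
    indep <- as.numeric(indep)
    if (length(indep) != nrow(values))
      stop("pointset: indep length != number of rows")
    if (length(indep) > 1L && any(diff(indep) <= 0))
      stop("pointset: independent variable must be strictly increasing")
    if ("t" %in% names)
      stop("pointset: variable name 't' collides with the independent variable")
  }
  if (length(labels)) {
    if (is.null(base::names(labels)) || any(base::names(labels) == ""))
      stop("pointset: labels must be a named list")
    for (lb in base::names(labels)) {
      idx <- as.integer(labels[[lb]])
      if (any(idx < 1L) || any(idx > nrow(values)))
        stop("pointset: label '", lb, "' has out-of-range row index")
      labels[[lb]] <- sort(unique(idx))
    }
  }
  structure(list(names = names, values = values, indep = indep, labels = labels),
            class = "pointset")
}

is_pointset <- function(x) inherits(x, "pointset")

#' @export
print.pointset <- function(x, ...) {
  cat("Pointset: ", nrow(x$values), " rows x ", length(x$names), " vars (",
      paste(x$names, collapse = ", "), ")",
      if (!is.null(x$indep)) " with indep", "\n", sep = "")
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a named point
#'
#' A point is a named numeric vector mapping variable name to value.
#' @param ... Named numeric values, or a single named numeric vector.
#' @return Named numeric vector of class `"point"`.
#' @export
point <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1L]]) && length(args[[1L]]) > 0L &&
      !is.null(names(args[[1L]]))) {
    v <- args[[1L]]
  } else {
    v <- unlist(args)
  }
  if (is.null(names(v)) || any(names(v) == "") || anyDuplicated(names(v)))
    stop("point: values must have unique names")
  structure(as.numeric(stats::setNames(v, names(v))), names = names(v),
            class = "point")
}

#' Access a pointset by name, row index, or label
#'
#' @param ps A [pointset()].
#' @param selector A variable name (returns that column), a row index
#'   (returns a [point()]), or a label string (returns the sub-pointset of the
#'   label's rows, preserving order, indep and any labels restricted to those
#'   rows).
#' @return A numeric column, a point, or a pointset.
#' @export
pointset_access <- function(ps, selector) {
  stopifnot(is_pointset(ps))
  if (is.numeric(selector)) {
    i <- as.integer(selector)
    if (length(i) != 1L || i < 1L || i > nrow(ps$values))
      stop("pointset_access: row index ", selector, " out of range")
    return(point(stats::setNames(ps$values[i, ], ps$names)))
  }
  if (!is.character(selector) || length(selector) != 1L)
    stop("pointset_access: selector must be a name, index or label")
  if (selector %in% ps$names)
    return(as.numeric(ps$values[, selector]))
  if (selector %in% names(ps$labels)) {
    idx <- ps$labels[[selector]]
    sub_labels <- lapply(ps$labels, function(j) match(intersect(j, idx), idx))
    sub_labels <- Filter(length, sub_labels)
    return(pointset(ps$values[idx, , drop = FALSE], ps$names,
                    indep = if (!is.null(ps$indep)) ps$indep[idx],
                    labels = sub_labels))
  }
  stop("pointset_access: key error: '", selector,
       "' is neither a variable name nor a label")
}

#' Add rows to a label of a pointset
#' @noRd
pointset_add_label <- function(ps, label, rows) {
  rows <- as.integer(rows)
  ps$labels[[label]] <- sort(unique(c(ps$labels[[label]], rows)))
  ps
}

#' Write / read a pointset as CSV with a JSON label sidecar
#'
#' The CSV has the independent variable first (header `"t"`) when present,
#' then one column per variable. Labels go to `<path>.labels.json`.
#'
#' @param ps A pointset.
#' @param path CSV file path.
#' @return `read_pointset_csv` returns a pointset.
#' @export
write_pointset_csv <- function(ps, path) {
  stopifnot(is_pointset(ps))
  df <- as.data.frame(ps$values)
  if (!is.null(ps$indep)) df <- cbind(t = ps$indep, df)
  utils::write.csv(df, path, row.names = FALSE)
  if (length(ps$labels))
    jsonlite::write_json(ps$labels, paste0(path, ".labels.json"))
  invisible(path)
}

#' @rdname write_pointset_csv
#' @export
read_pointset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  indep <- NULL
  if (identical(colnames(df)[1L], "t")) {
    indep <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  labels <- list()
  side <- paste0(path, ".labels.json")
  if (file.exists(side)) {
    labels <- lapply(jsonlite::read_json(side), function(v) unlist(v))
  }
  pointset(as.matrix(df), colnames(df), indep = indep, labels = labels)
}
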