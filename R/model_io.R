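#' @title Model definition files
#' @description
#' Models serialize to a line-oriented structured text format. Each line is
#' `keyword args... [: expression]`; expressions appear verbatim in the
#' expression grammar; `#` starts a comment. The writer is canonical
#' (deterministic ordering and number formatting), so load -> save -> load is
#' bit-exact.
#'
#' Keywords: `model <name>`; `state <var>`; `domain <var> <lo> <hi>`;
#' `frozen <var>`; `param <name> <value>`; `rhs <var> : <expr>`;
#' `algebraic <var> : <expr>`; `aux <name> <args...> : <expr>`;
#' `event <name> <direction> <terminal01> <tol_t> : <expr>`;
#' `extinput <name> : t1 v1 t2 v2 ...`.
#' @name model_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

model_to_lines <- function(md) {
  lines <- paste("model", md$name)
  for (v in md$vars) lines <- c(lines, paste("state", v))
  for (v in names(md$domains)) {
    dv <- md$domains[[v]]
    lines <- c(lines, paste("domain", v, fmt_num(dv$lo), fmt_num(dv$hi)))
  }
  for (v in md$frozen) lines <- c(lines, paste("frozen", v))
  for (p in names(md$params))
    lines <- c(lines, paste("param", p, fmt_num(md$params[[p]])))
  for (v in md$vars)
    lines <- c(lines, paste("rhs", v, ":", expr_text(md$rhs[[v]])))
  for (a in names(md$algebraic))
    lines <- c(lines, paste("algebraic", a, ":", expr_text(md$algebraic[[a]])))
  for (f in names(md$aux_fns)) {
    af <- md$aux_fns[[f]]
    lines <- c(lines, paste("aux", f, paste(af$args, collapse = " "), ":",
                            expr_text(af$body)))
  }
  for (ev in md$events)
    lines <- c(lines, paste("event", ev$name, fmt_num(ev$direction),
                            if (ev$terminal) "1" else "0", fmt_num(ev$tol_t),
                            ":", expr_text(ev$gfun)))
  for (nm in names(md$external_inputs)) {
    xi <- as.matrix(md$external_inputs[[nm]])
    lines <- c(lines, paste("extinput", nm, ":",
                            paste(fmt_num(t(xi)), collapse = " ")))
  }
  lines
}

lines_to_model <- function(lines) {
  name <- NULL; vars <- character(0); frozen <- character(0)
  params <- numeric(0); rhs <- list(); algebraic <- list()
  aux_fns <- list(); events <- list(); domains <- list(); ext <- list()
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    colon <- regexpr(" : ", line, fixed = TRUE)
    head_part <- if (colon > 0) substr(line, 1L, colon - 1L) else line
    expr_part <- if (colon > 0) substr(line, colon + 3L, nchar(line)) else NULL
    tok <- strsplit(trimws(head_part), "[[:space:]]+")[[1L]]
    kw <- tok[1L]
    if (kw == "model") { name <- tok[2L]
    } else if (kw == "state") { vars <- c(vars, tok[2L])
    } else if (kw == "domain") {
      domains[[tok[2L]]] <- interval(as.numeric(tok[3L]), as.numeric(tok[4L]))
    } else if (kw == "frozen") { frozen <- c(frozen, tok[2L])
    } else if (kw == "param") {
      params[tok[2L]] <- as.numeric(tok[3L])
    } else if (kw == "rhs") {
      rhs[[tok[2L]]] <- parse_expression(expr_part)
    } else if (kw == "algebraic") {
      algebraic[[tok[2L]]] <- parse_expression(expr_part)
    } else if (kw == "aux") {
      aux_fns[[tok[2L]]] <- aux_fn(tok[-(1:2)], parse_expression(expr_part))
    } else if (kw == "event") {
      events[[length(events) + 1L]] <-
        event_definition(tok[2L], parse_expression(expr_part),
                         direction = as.numeric(tok[3L]),
                         terminal = tok[4L] == "1",
                         tol_t = as.numeric(tok[5L]))
    } else if (kw == "extinput") {
      nums <- as.numeric(strsplit(trimws(expr_part), "[[:space:]]+")[[1L]])
      ext[[tok[2L]]] <- matrix(nums, ncol = 2L, byrow = TRUE)
    } else {
      stop("model file: unknown keyword '", kw, "'")
    }
  }
  if (is.null(name)) stop("model file: missing 'model' line")
  model_definition(name, vars, rhs, params = params, algebraic = algebraic,
                   frozen = frozen, aux_fns = aux_fns, events = events,
                   domains = domains, external_inputs = ext)
}

#' Write / read a model definition file
#' @param md A [model_definition()].
#' @param path File path.
#' @return `read_model_file` returns a model definition.
#' @export
write_model_file <- function(md, path) {
  writeLines(model_to_lines(md), path)
  invisible(path)
}

#' @rdname write_model_file
#' @export
read_model_file <- function(path) {
  lines_to_model(readLines(path))
}

#' Write / read a hybrid model file
#'
#' Sub-models are stored inline in `begin submodel` / `end submodel` blocks
#' (recursively, `begin hybrid` / `end hybrid` for nested hybrid models),
#' followed by `states`, `initial`, `regime <id> <submodel-name>
#' [<ind>=<val> ...]` and `transition <from> <trigger> <to> [:
#' <var>=<expr>, ...]` lines.
#'
#' @param hm A [hybrid_model()].
#' @param path File path.
#' @export
write_hybrid_model_file <- function(hm, path) {
  writeLines(hybrid_to_lines(hm), path)
  invisible(path)
}

hybrid_to_lines <- function(hm) {
  lines <- c(paste("hybrid", hm$name),
             paste("states", paste(hm$state_names, collapse = " ")),
             paste("initial", hm$initial))
  for (rg in hm$regimes) {
    sub <- rg$submodel
    if (is_model(sub)) {
      lines <- c(lines, "begin submodel", model_to_lines(sub), "end submodel")
    } else {
      lines <- c(lines, "begin hybrid_submodel", hybrid_to_lines(sub),
                 "end hybrid_submodel")
    }
    ind <- if (length(rg$indicators))
      paste(names(rg$indicators), fmt_num(rg$indicators), sep = "=")
    else character(0)
    sub_name <- if (is_model(sub)) sub$name else sub$name
    lines <- c(lines, paste(c("regime", rg$id, sub_name, ind), collapse = " "))
  }
  for (tr in hm$transitions) {
    resets <- if (length(tr$reset))
      paste(" :", paste(names(tr$reset),
                        vapply(tr$reset, expr_text, character(1)),
                        sep = "=", collapse = ", "))
    else ""
    lines <- c(lines, paste0("transition ", tr$from, " ", tr$trigger, " ",
                             tr$to, resets))
  }
  lines
}

#' @rdname write_hybrid_model_file
#' @export
read_hybrid_model_file <- function(path) {
  lines_to_hybrid(readLines(path))
}

lines_to_hybrid <- function(lines) {
  name <- NULL; state_names <- NULL; initial <- NULL
  submodels <- list(); regimes <- list(); transitions <- list()
  i <- 1L
  n <- length(lines)
  take_block <- function(start, open, close) {
    depth <- 1L
    j <- start
    while (depth > 0L) {
      j <- j + 1L
      if (j > n) stop("hybrid model file: unterminated ", open)
      lt <- trimws(lines[j])
      if (lt == open) depth <- depth + 1L
      if (lt == close) depth <- depth - 1L
    }
    j
  }
  while (i <= n) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(line)) { i <- i + 1L; next }
    if (line == "begin submodel") {
      j <- take_block(i, "begin submodel", "end submodel")
      sm <- lines_to_model(lines[(i + 1L):(j - 1L)])
      submodels[[sm$name]] <- sm
      i <- j + 1L; next
    }
    if (line == "begin hybrid_submodel") {
      j <- take_block(i, "begin hybrid_submodel", "end hybrid_submodel")
      sm <- lines_to_hybrid(lines[(i + 1L):(j - 1L)])
      submodels[[sm$name]] <- sm
      i <- j + 1L; next
    }
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    kw <- tok[1L]
    if (kw == "hybrid") { name <- tok[2L]
    } else if (kw == "states") { state_names <- tok[-1L]
    } else if (kw == "initial") { initial <- tok[2L]
    } else if (kw == "regime") {
      ind <- numeric(0)
      if (length(tok) > 3L) {
        kv <- strsplit(tok[-(1:3)], "=", fixed = TRUE)
        ind <- stats::setNames(vapply(kv, function(p) as.numeric(p[2L]),
                                      numeric(1)),
                               vapply(kv, `[[`, character(1), 1L))
      }
      if (is.null(submodels[[tok[3L]]]))
        stop("hybrid model file: regime '", tok[2L],
             "' references unknown sub-model '", tok[3L], "'")
      regimes[[length(regimes) + 1L]] <-
        regime(tok[2L], submodels[[tok[3L]]], indicators = ind)
    } else if (kw == "transition") {
      colon <- regexpr(" : ", line, fixed = TRUE)
      reset <- list()
      if (colon > 0) {
        body <- substr(line, colon + 3L, nchar(line))
        parts <- strsplit(body, ",", fixed = TRUE)[[1L]]
        for (p in parts) {
          eq <- regexpr("=", p, fixed = TRUE)
          reset[[trimws(substr(p, 1L, eq - 1L))]] <-
            parse_expression(trimws(substr(p, eq + 1L, nchar(p))))
        }
        tok <- strsplit(trimws(substr(line, 1L, colon - 1L)),
                        "[[:space:]]+")[[1L]]
      }
      transitions[[length(transitions) + 1L]] <-
        transition(tok[2L], tok[3L], tok[4L], reset = reset)
    } else {
      stop("hybrid model file: unknown keyword '", kw, "'")
    }
    i <- i + 1L
  }
  hybrid_model(regimes, transitions, state_names, initial, name = name)
}
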