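#' Extract epochs of constant active set from a trajectory
#'
#' Computes Psi along the trajectory on a uniform grid, locates zero
#' crossings of `gamma * Psi_i - Psi_max` for every source with root
#' refinement on the trajectory interpolant, names the joining/leaving
#' source by comparing active sets just before and after each crossing,
#' merges epochs shorter than `min_duration`, and returns ordered epochs
#' tiling the analysis window.
#'
#' @param traj Trajectory of the full model (Hermite-interpolable).
#' @param ct The [conductance_target()].
#' @param gamma Scale tolerance (> 1), default 3.
#' @param window Optional `c(lo, hi)` sub-window (default: full domain).
#' @param n_grid Uniform resampling points for the Psi signals (default
#'   2000; Psi is a derived signal without solver dense output).
#' @param min_duration Epochs shorter than this are merged into their
#'   neighbor (default 0.5% of the window).
#' @param delta Offset used to compare active sets across a crossing
#'   (default `1e-9`, ten times the default event tolerance).
#' @return `list(epochs, influence, gamma)`. `epochs` is a list of
#'   `list(interval, active, entry_change, flagged)`; `entry_change` is
#'   `"initial"` or `list(kind = "joined"|"left", source)`. `influence` is a
#'   data frame of t, Psi per source, tau per gating variable and tau_hub.
#' @export
extract_epochs <- function(traj, ct, gamma = 3, window = NULL,
                           n_grid = 2000L, min_duration = NULL,
                           delta = 1e-9) {
  if (gamma <= 1) stop("extract_epochs: gamma must be > 1")
  if (is.null(window)) window <- c(traj$domain$lo, traj$domain$hi)
  if (is_interval(window)) window <- c(window$lo, window$hi)
  span <- window[2L] - window[1L]
  if (is.null(min_duration)) min_duration <- 0.005 * span

  ts <- seq(window[1L], window[2L], length.out = n_grid)
  vars <- ct$model$vars
  Y <- traj_eval(traj, ts, vars)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  n_src <- length(ct$sources)
  P <- matrix(NA_real_, n_grid, n_src, dimnames = list(NULL, ct$sources))
  TB <- matrix(NA_real_, n_grid, length(ct$gating),
               dimnames = list(NULL, ct$gating))
  den <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    yi <- Y[i, ]
    P[i, ] <- ct$psi_fun(ts[i], yi)
    if (!is.null(ct$taub_fun)) TB[i, ] <- ct$taub_fun(ts[i], yi)
    den[i] <- ct$den_fun(ts[i], yi)
  }
  pmaxv <- apply(P, 1L, max)

  psi_at <- function(tt) {
    y <- as.numeric(traj_eval(traj, tt, vars))
    ct$psi_fun(tt, y)
  }
  g_at <- function(tt, j) {
    p <- psi_at(tt)
    gamma * p[j] - max(p)
  }
  active_at <- function(tt) {
    p <- stats::setNames(as.numeric(psi_at(tt)), ct$sources)
    active_set(p, gamma)
  }

  # locate crossings of gamma*Psi_j - Psi_max for each source; an upward
  # crossing is a join, a downward crossing a leave
  crossings <- data.frame(t = numeric(0), source = character(0),
                          direction = integer(0))
  for (j in seq_len(n_src)) {
    g <- gamma * P[, j] - pmaxv
    sgn <- sign(g)
    for (i in seq_len(n_grid - 1L)) {
      if (sgn[i] != 0 && sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L]) {
        root <- tryCatch(
          stats::uniroot(g_at, c(ts[i], ts[i + 1L]), j = j,
                         tol = delta / 10)$root,
          error = function(e) (ts[i] + ts[i + 1L]) / 2)
        crossings <- rbind(crossings,
                           data.frame(t = root, source = ct$sources[j],
                                      direction = as.integer(sgn[i + 1L])))
      }
    }
  }
  crossings <- crossings[order(crossings$t), , drop = FALSE]

  # non-generic simultaneous crossings within delta: flag, keep declaration
  # order (already ordered by source within equal times via stable sort)
  flagged_times <- numeric(0)
  if (nrow(crossings) > 1L) {
    close_pairs <- diff(crossings$t) <= delta
    if (any(close_pairs))
      flagged_times <- crossings$t[which(close_pairs)]
  }

  bounds <- c(window[1L], crossings$t, window[2L])
  bounds <- bounds[!duplicated(round(bounds / (delta / 2)))]
  bounds <- sort(bounds)
  epochs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    mid <- (bounds[k] + bounds[k + 1L]) / 2
    epochs[[length(epochs) + 1L]] <-
      list(lo = bounds[k], hi = bounds[k + 1L], active = active_at(mid))
  }

  merge_equal <- function(eps) {
    out <- list()
    for (e in eps) {
      n <- length(out)
      if (n && setequal(out[[n]]$active, e$active)) {
        out[[n]]$hi <- e$hi
      } else out[[length(out) + 1L]] <- e
    }
    out
  }
  epochs <- merge_equal(epochs)
  # drop epochs shorter than min_duration (absorbed into the previous epoch,
  # or the next one for a leading sliver), then re-merge equals
  repeat {
    if (length(epochs) <= 1L) break
    durs <- vapply(epochs, function(e) e$hi - e$lo, numeric(1))
    short <- which(durs < min_duration)
    if (!length(short)) break
    k <- short[which.min(durs[short])]
    if (k > 1L) {
      epochs[[k - 1L]]$hi <- epochs[[k]]$hi
    } else {
      epochs[[2L]]$lo <- epochs[[1L]]$lo
    }
    epochs <- merge_equal(epochs[-k])
  }

  grid_h <- ts[2L] - ts[1L]
  out <- list()
  for (k in seq_along(epochs)) {
    e <- epochs[[k]]
    flagged <- any(flagged_times >= e$lo - delta & flagged_times <= e$lo + delta)
    if (k == 1L) {
      entry <- "initial"
    } else {
      prev <- epochs[[k - 1L]]$active
      added <- setdiff(e$active, prev)
      removed <- setdiff(prev, e$active)
      if (length(added) + length(removed) != 1L) flagged <- TRUE
      # name the change (the post-processing step): prefer the refined
      # crossing at this boundary, provided it is realizable as a guard of
      # the preceding (merged) epoch — a join of a source outside its set or
      # a leave of a member; otherwise fall back to the set difference
      compatible <- function(kind, src)
        if (kind == "joined") !(src %in% prev) else src %in% prev
      entry <- NULL
      hit <- which(abs(crossings$t - e$lo) <= grid_h / 2)
      if (length(hit)) {
        cr <- crossings[hit[1L], ]
        kind <- if (cr$direction > 0) "joined" else "left"
        if (compatible(kind, cr$source))
          entry <- list(kind = kind, source = cr$source)
      }
      if (is.null(entry)) {
        if (length(removed)) {
          entry <- list(kind = "left",
                        source = removed[order(match(removed, ct$sources))][1L])
        } else {
          entry <- list(kind = "joined",
                        source = added[order(match(added, ct$sources))][1L])
        }
      }
    }
    out[[k]] <- list(interval = interval(e$lo, e$hi), active = e$active,
                     entry_change = entry, flagged = flagged)
  }

  influence <- data.frame(t = ts)
  for (j in seq_len(n_src)) influence[[paste0("psi_", ct$sources[j])]] <- P[, j]
  influence$psi_max <- pmaxv
  for (x in ct$gating) influence[[paste0("tau_", x)]] <- 1 / TB[, x]
  influence$tau_hub <- ct$C / den

  list(epochs = out, influence = influence, gamma = gamma)
}

#' Write an epochs report (structured text) and influence records CSV
#' @param ep Result of [extract_epochs()].
#' @param report_path,influence_path Output paths (either may be `NULL`).
#' @export
write_epochs_report <- function(ep, report_path = NULL, influence_path = NULL) {
  if (!is.null(report_path)) {
    lines <- sprintf("gamma %s", fmt_num(ep$gamma))
    for (e in ep$epochs) {
      ec <- if (identical(e$entry_change, "initial")) "initial"
            else paste(e$entry_change$kind, e$entry_change$source)
      lines <- c(lines, sprintf("epoch [%.9g, %.9g] active={%s} entry=%s%s",
                                e$interval$lo, e$interval$hi,
                                paste(e$active, collapse = ","), ec,
                                if (e$flagged) " FLAGGED" else ""))
    }
    writeLines(lines, report_path)
  }
  if (!is.null(influence_path))
    utils::write.csv(ep$influence, influence_path, row.names = FALSE)
  invisible(ep)
}

entry_event_name <- function(entry) {
  paste0(if (entry$kind == "joined") "join_" else "leave_", entry$source)
}

#' Build the cyclic regime template from extracted epochs
#'
#' The template is the cyclic sequence of active sets — with each epoch's
#' dynamic and algebraic (fast, substituted) gating-variable roles — that
#' summarizes one period of the analyzed behavior. Fast classification uses
#' `tau_x < tau_hub / rho` throughout the epoch. The sequence must close
#' consistently: consecutive elements (including last -> first) differ by
#' exactly one joining or leaving source.
#'
#' @param ep Result of [extract_epochs()] covering at least one full cycle.
#' @param ct The conductance target.
#' @param rho Fast-variable timescale ratio (default 2).
#' @return Object of class `"regime_template"`.
#' @export
template_from_epochs <- function(ep, ct, rho = 2) {
  all_epochs <- ep$epochs
  L <- length(all_epochs)
  if (L < 1L) stop("template_from_epochs: no epochs")
  if (L == 1L) {
    epochs <- all_epochs
  } else {
    # the epoch sequence of a periodic orbit is eventually periodic: find
    # the cycle length p as the gap between the last two occurrences of the
    # final epoch's active set, then take the last p epochs
    keys <- vapply(all_epochs, function(e)
      paste(sort(e$active), collapse = ","), character(1))
    occ <- which(keys == keys[L])
    if (length(occ) < 2L)
      stop("template_from_epochs: no repeated cycle found (window too short?)")
    p <- occ[length(occ)] - occ[length(occ) - 1L]
    if (p > L - 1L)
      stop("template_from_epochs: inconsistent cycle length")
    epochs <- all_epochs[(L - p + 1L):L]
    # verify the preceding cycle has the same set sequence (stability)
    if (L - 2L * p >= 0L) {
      prev_keys <- keys[(L - 2L * p + 1L):(L - p)]
      if (!identical(prev_keys, keys[(L - p + 1L):L]))
        warning("template_from_epochs: consecutive cycles differ; using the ",
                "last one")
    }
  }
  k <- length(epochs)
  active_sets <- lapply(epochs, `[[`, "active")
  entries <- lapply(epochs, `[[`, "entry_change")
  # cyclic consistency: each element's entry must be realizable as a guard
  # event of the preceding element (a join of a source outside its active
  # set, or a leave of a member)
  if (k > 1L) {
    for (i in seq_len(k)) {
      prev <- active_sets[[if (i == 1L) k else i - 1L]]
      en <- entries[[i]]
      if (is.character(en))
        stop("template_from_epochs: element ", i, " has no recorded entry ",
             "change; window too short for a full cycle")
      ok <- if (en$kind == "joined") !(en$source %in% prev)
            else en$source %in% prev
      if (!ok)
        stop("template_from_epochs: cycle does not close consistently at ",
             "element ", i, ": entry '", en$kind, " ", en$source,
             "' is incompatible with preceding active set {",
             paste(prev, collapse = ","), "}")
    }
  }
  # dynamic / algebraic roles per epoch from the influence grid
  infl <- ep$influence
  dynamic <- list(); algebraic <- list()
  for (i in seq_len(k)) {
    e <- epochs[[i]]
    rows <- infl$t >= e$interval$lo & infl$t <= e$interval$hi
    if (!any(rows)) rows <- which.min(abs(infl$t - (e$interval$lo + e$interval$hi) / 2))
    act_g <- intersect(e$active, ct$gating)
    alg <- character(0)
    for (x in act_g) {
      if (all(infl[[paste0("tau_", x)]][rows] <
              infl$tau_hub[rows] / rho, na.rm = TRUE))
        alg <- c(alg, x)
    }
    algebraic[[i]] <- alg
    dynamic[[i]] <- c(ct$target, setdiff(ct$gating, alg))
  }
  structure(list(active_sets = active_sets, entries = entries,
                 dynamic = dynamic, algebraic = algebraic,
                 regime_ids = paste0("R", seq_len(k)),
                 gamma = ep$gamma, rho = rho, n_regimes = k),
            class = "regime_template")
}

#' @export
print.regime_template <- function(x, ...) {
  cat("Regime template:", x$n_regimes, "regimes (gamma =", x$gamma, ")\n")
  for (i in seq_len(x$n_regimes)) {
    en <- x$entries[[i]]
    en_txt <- if (is.character(en)) en else paste(en$kind, en$source)
    cat("  ", x$regime_ids[i], ": active={",
        paste(x$active_sets[[i]], collapse = ","), "} entry=", en_txt,
        " algebraic={", paste(x$algebraic[[i]], collapse = ","),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Serialize / load a regime template
#' @param template A [regime_template()].
#' @param path File path.
#' @export
write_template_file <- function(template, path) {
  lines <- c(paste("template", template$n_regimes, fmt_num(template$gamma),
                   fmt_num(template$rho)))
  for (i in seq_len(template$n_regimes)) {
    en <- template$entries[[i]]
    if (is.character(en)) en <- list(kind = "initial", source = "none")
    lines <- c(lines, paste("element", template$regime_ids[i],
                            paste0("active=", paste(template$active_sets[[i]], collapse = ",")),
                            paste0("algebraic=", paste(template$algebraic[[i]], collapse = ",")),
                            paste0("dynamic=", paste(template$dynamic[[i]], collapse = ",")),
                            paste0("entry=", en$kind, ":", en$source)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_template_file
#' @export
read_template_file <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  active_sets <- list(); entries <- list(); dynamic <- list()
  algebraic <- list(); ids <- character(0)
  split_set <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character(0)
  for (line in lines[-1L]) {
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (tok[1L] != "element") next
    ids <- c(ids, tok[2L])
    kv <- sub("^[a-z]+=", "", tok[3:6])
    active_sets[[length(active_sets) + 1L]] <- split_set(kv[1L])
    algebraic[[length(algebraic) + 1L]] <- split_set(kv[2L])
    dynamic[[length(dynamic) + 1L]] <- split_set(kv[3L])
    en <- strsplit(kv[4L], ":", fixed = TRUE)[[1L]]
    entries[[length(entries) + 1L]] <- list(kind = en[1L], source = en[2L])
  }
  structure(list(active_sets = active_sets, entries = entries,
                 dynamic = dynamic, algebraic = algebraic, regime_ids = ids,
                 gamma = as.numeric(hd[3L]), rho = as.numeric(hd[4L]),
                 n_regimes = length(ids)),
            class = "regime_template")
}

#' Compare two templates up to cyclic rotation
#'
#' @param a,b [regime_template()] objects (or results of
#'   [template_from_epochs()]).
#' @return `list(match, rotation, first_mismatch)`; `rotation` is the offset
#'   of `b` aligning it to `a` when matched.
#' @export
compare_templates <- function(a, b) {
  sa <- lapply(a$active_sets, function(s) sort(s))
  sb <- lapply(b$active_sets, function(s) sort(s))
  if (length(sa) != length(sb))
    return(list(match = FALSE, rotation = NA_integer_,
                first_mismatch = paste0("lengths differ: ", length(sa),
                                        " vs ", length(sb))))
  k <- length(sa)
  for (r in 0:(k - 1L)) {
    rot <- sb[((seq_len(k) + r - 1L) %% k) + 1L]
    if (all(vapply(seq_len(k), function(i)
      identical(sa[[i]], rot[[i]]), logical(1))))
      return(list(match = TRUE, rotation = r, first_mismatch = NULL))
  }
  # report first mismatch at rotation 0
  fm <- which(!vapply(seq_len(k), function(i)
    identical(sa[[i]], sb[[i]]), logical(1)))[1L]
  list(match = FALSE, rotation = NA_integer_,
       first_mismatch = paste0("position ", fm, ": {",
                               paste(sa[[fm]], collapse = ","), "} vs {",
                               paste(sb[[fm]], collapse = ","), "}"))
}

#' Build the reduced sub-model for one epoch
#'
#' The hub equation keeps only the active terms (inactive inclusion flags
#' set to 0); active gating variables classified fast become algebraic
#' `x = x_inf(V)` (DAE by substitution); the remaining active gating
#' variables keep their ODEs; every inactive gating variable is retained as
#' a shadow variable — full kinetics driven by V with no feedback into the
#' hub equation beyond its (shadow) appearance inside an active term's
#' conductance. Join/leave guard events (`gamma Psi_j - Psi_max` crossing
#' zero upward for j outside A, downward for j inside) are installed for
#' every source, evaluated with all inclusion flags at 1 so they track the
#' full model's dominance criteria. The sub-model exposes the full state
#' (dynamic / algebraic / shadow roles) plus frozen inclusion flags `s`, `c`.
#'
#' @param ct The [conductance_target()].
#' @param active Character vector: the epoch's active source set.
#' @param algebraic_vars Gating variables to replace by their asymptote.
#' @param gamma Scale tolerance used in the guard events.
#' @param name Sub-model name.
#' @param events_terminal Logical: install join/leave events as terminal
#'   (default TRUE).
#' @return A [model_definition()].
#' @export
build_reduced_regime <- function(ct, active, algebraic_vars = character(0),
                                 gamma = 3, name = "reduced",
                                 events_terminal = TRUE) {
  md <- ct$model
  target <- ct$target
  bad <- setdiff(active, ct$sources)
  if (length(bad))
    stop("build_reduced_regime: unknown source(s): ", paste(bad, collapse = ", "))
  has_cond <- FALSE; has_cur <- FALSE
  cur_parts <- list()
  for (tm in ct$terms) {
    if (tm$kind == "gated") {
      if (any(tm$gating %in% active)) {
        cur_parts[[length(cur_parts) + 1L]] <-
          call("*", tm$conductance, call("-", tm$E, as.symbol(target)))
        has_cond <- TRUE
      }
    } else if (tm$kind == "leak") {
      if (tm$name %in% active) has_cond <- TRUE
      cur_parts[[length(cur_parts) + 1L]] <-
        call("*", as.symbol(tm$flag),
             call("*", tm$conductance, call("-", tm$E, as.symbol(target))))
    } else {
      if (tm$name %in% active) has_cur <- TRUE
      cur_parts[[length(cur_parts) + 1L]] <-
        call("*", as.symbol(tm$flag), tm$current)
    }
  }
  if (!has_cond && !has_cur)
    stop("build_reduced_regime: degenerate regime: active set {",
         paste(active, collapse = ","),
         "} leaves zero conductance and no current on the hub")
  hub_rhs <- call("/", call("(", sum_exprs(cur_parts)), ct$C)

  act_g <- intersect(ct$gating, active)
  alg_g <- intersect(algebraic_vars, act_g)
  dyn_g <- setdiff(ct$gating, alg_g)  # active-slow + all shadows
  vars <- c(target, dyn_g)
  rhs <- c(stats::setNames(list(hub_rhs), target), md$rhs[dyn_g])
  algebraic <- ct$xinf_exprs[alg_g]

  # guard events on the full-model dominance criteria (flags at 1)
  psi1 <- lapply(ct$psi_exprs, function(e)
    substitute_expression(e, list(s = 1, c = 1)))
  psi_max1 <- Reduce(function(a, b) call("max", a, b), unname(psi1))
  events <- list()
  for (src in ct$sources) {
    g <- call("-", call("*", gamma, call("(", psi1[[src]])),
              call("(", psi_max1))
    if (src %in% active) {
      events[[length(events) + 1L]] <-
        event_definition(paste0("leave_", src), g, direction = -1,
                         terminal = events_terminal)
    } else {
      events[[length(events) + 1L]] <-
        event_definition(paste0("join_", src), g, direction = 1,
                         terminal = events_terminal)
    }
  }

  fl <- unique(vapply(Filter(function(tm) tm$kind != "gated", ct$terms),
                      `[[`, character(1), "flag"))
  model_definition(name, vars, rhs,
                   params = md$params,
                   algebraic = algebraic,
                   frozen = fl,
                   aux_fns = md$aux_fns,
                   events = events,
                   domains = md$domains[intersect(names(md$domains), vars)])
}

#' Assemble the hybrid reduction from a template
#'
#' One reduced regime per template element, wired along the cycle: each
#' regime's terminal guard is the join/leave event that ends its epoch (the
#' next element's entry change); the other guard events are kept as
#' non-terminal diagnostics. Resets are identity on retained variables —
#' there are no discrete jumps in the reduction; algebraic variables are
#' re-initialized by substitution on regime entry, and the inclusion flags
#' `s`, `c` are set per regime as indicator values.
#'
#' @param ct The [conductance_target()].
#' @param template A [regime_template()].
#' @param gamma Scale tolerance for the guard events (default: the
#'   template's).
#' @return A [hybrid_model()] over the full model's state names.
#' @export
assemble_hybrid_reduction <- function(ct, template, gamma = NULL) {
  if (is.null(gamma)) gamma <- template$gamma
  k <- template$n_regimes
  ids <- template$regime_ids
  regimes <- vector("list", k)
  transitions <- vector("list", k)
  leak_names <- vapply(Filter(function(tm) tm$kind == "leak", ct$terms),
                       `[[`, character(1), "name")
  cur_names <- vapply(Filter(function(tm) tm$kind == "applied_current",
                             ct$terms), `[[`, character(1), "name")
  degenerate <- k == 1L && is.character(template$entries[[1L]])
  for (i in seq_len(k)) {
    nxt <- if (i == k) 1L else i + 1L
    sub <- build_reduced_regime(ct, template$active_sets[[i]],
                                template$algebraic[[i]], gamma = gamma,
                                name = ids[i], events_terminal = FALSE)
    if (!degenerate) {
      exit_event <- entry_event_name(template$entries[[nxt]])
      sub$events <- lapply(sub$events, function(ev) {
        if (ev$name == exit_event) ev$terminal <- TRUE
        ev
      })
      if (!exit_event %in% vapply(sub$events, `[[`, character(1), "name"))
        stop("assemble_hybrid_reduction: template cycle inconsistent: regime ",
             ids[i], " has no guard '", exit_event, "'")
      transitions[[i]] <- transition(ids[i], exit_event, ids[nxt])
    }
    ind <- c(s = as.numeric(any(leak_names %in% template$active_sets[[i]])),
             c = as.numeric(any(cur_names %in% template$active_sets[[i]])))
    regimes[[i]] <- regime(ids[i], sub, indicators = ind)
  }
  hybrid_model(regimes, Filter(Negate(is.null), transitions),
               model_state_names(ct$model),
               initial = ids[1L], name = paste0(ct$model$name, "_reduced"))
}
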