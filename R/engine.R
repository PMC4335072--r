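#' Regeneration run configuration
#'
#' Bundles every tunable of the greedy placement engine.
#'
#' @param rule greedy selection rule: `"3a"` picks the admissible
#'   candidate adding the largest total signal to the control cells
#'   (minimizes S* - S(t)); `"3b"` picks the candidate receiving the
#'   largest deficit-weighted signal z from the control cells.
#' @param enforce_condition2 if `TRUE` (default), a candidate is
#'   admissible only if placing it leaves every control cell's relative
#'   overshoot below `epsilon`; if `FALSE` the admissibility filter is
#'   off and overshoot is only detected after placement (the run then
#'   stops with status `"violation"`).
#' @param epsilon positive relative overshoot tolerance: placement must
#'   keep \eqn{(u_i - u_i^*)/u_i^* < \epsilon} at every control cell.
#'   Default `1e-14`.
#' @param stop_deficit nonnegative relative undershoot threshold: the run
#'   ends with status `"exact"` once
#'   \eqn{\max_i (u_i^* - u_i(t))/u_i^* \le} `stop_deficit`.
#'   Default `1e-9`. Kept separate from `epsilon`: overshoot tolerance is
#'   a model parameter, undershoot is only a float-equality surrogate for
#'   "the two signals coincide".
#' @param max_steps maximum number of placed cells.
#' @param search_margin candidates may lie in the bounding box of the
#'   original structure expanded by this many lattice units on every
#'   side (default 5). Must exceed 0 so that wrong cells *can* appear
#'   outside the original shape.
#' @return an object of class `regen_config`.
#' @export
regen_config <- function(rule = c("3b", "3a"),
                         enforce_condition2 = TRUE,
                         epsilon = 1e-14,
                         stop_deficit = 1e-9,
                         max_steps = 10000L,
                         search_margin = 5L) {
  rule <- match.arg(rule)
  stopifnot(is.logical(enforce_condition2), length(enforce_condition2) == 1L)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be positive", call. = FALSE)
  }
  if (!is.numeric(stop_deficit) || stop_deficit < 0) {
    stop("stop_deficit must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(max_steps) || max_steps < 1) {
    stop("max_steps must be at least 1", call. = FALSE)
  }
  if (!is.numeric(search_margin) || search_margin < 0) {
    stop("search_margin must be nonnegative", call. = FALSE)
  }
  structure(list(rule = rule,
                 enforce_condition2 = isTRUE(enforce_condition2),
                 epsilon = as.numeric(epsilon),
                 stop_deficit = as.numeric(stop_deficit),
                 max_steps = as.integer(max_steps),
                 search_margin = as.integer(search_margin)),
            class = "regen_config")
}

#' @export
print.regen_config <- function(x, ...) {
  cat(sprintf(
    "<regen_config> rule %s, condition 2 %s, epsilon %g, stop_deficit %g, max_steps %d, margin %d\n",
    x$rule, if (x$enforce_condition2) "on" else "off",
    x$epsilon, x$stop_deficit, x$max_steps, x$search_margin))
  invisible(x)
}

# deterministic tie-break: lexicographic (y, then x), smallest first
tie_order <- function(x, y) order(y, x)

# search window: bounding box of reference nodes expanded by margin
search_window <- function(ref_nodes, margin) {
  list(xmin = min(ref_nodes$x) - margin, xmax = max(ref_nodes$x) + margin,
       ymin = min(ref_nodes$y) - margin, ymax = max(ref_nodes$y) + margin)
}

in_window <- function(x, y, w) {
  x >= w$xmin & x <= w$xmax & y >= w$ymin & y <= w$ymax
}

#' Candidate nodes for the next cell (condition 1)
#'
#' Empty lattice nodes (not occupied by a control or new cell) inside
#' the search window that are 8-adjacent to a blastema cell or to a new
#' cell. Growth is thereby continuous, starting from the cut.
#' Admissibility (condition 2) is deliberately *not* applied here.
#'
#' @param structure an amputated `cell_structure` (possibly mid-run,
#'   with new cells).
#' @param config a [regen_config()] (for the search margin).
#' @param seeds optional data frame of seed nodes whose neighborhoods
#'   may host candidates; defaults to blastema plus new cells.
#' @param window optional precomputed window (internal use).
#' @return data frame of candidate nodes (columns `x`, `y`), in
#'   tie-break order; may have zero rows.
#' @export
candidate_set <- function(structure, config = regen_config(),
                          seeds = NULL, window = NULL) {
  df <- structure_nodes(structure)
  if (is.null(seeds)) {
    seeds <- rbind(blastema(structure),
                   df[df$role == "new", c("x", "y")])
  }
  if (nrow(seeds) == 0L) {
    return(data.frame(x = integer(0), y = integer(0)))
  }
  if (is.null(window)) {
    ref <- df[df$role %in% c("control", "removed", "original"), , drop = FALSE]
    window <- search_window(ref, config$search_margin)
  }
  nb <- neighbors8_keys(seeds$x, seeds$y)
  keep <- !duplicated(nb$key)
  cx <- nb$x[keep]; cy <- nb$y[keep]; ck <- nb$key[keep]
  occ <- node_key(df$x[df$role != "removed"], df$y[df$role != "removed"])
  free <- !(ck %in% occ) & in_window(cx, cy, window)
  cx <- cx[free]; cy <- cy[free]
  o <- tie_order(cx, cy)
  data.frame(x = cx[o], y = cy[o])
}

#' Admissibility of candidates under condition 2
#'
#' A candidate k is admissible when tentatively adding it as a source
#' keeps \eqn{(u_i - u_i^*)/u_i^* < \epsilon} for every control cell i,
#' i.e. the new signal never (beyond tolerance) exceeds the remembered
#' one. With the filter disabled every candidate is admissible.
#'
#' @param candidates data frame of candidate nodes (`x`, `y`).
#' @param old,new [signal_field]s (u*, u(t)) over the control cells.
#' @param kernel a [signal_kernel()].
#' @param epsilon relative tolerance.
#' @param enforce if `FALSE`, returns all `TRUE` (toggle semantics).
#' @return logical vector, one entry per candidate.
#' @export
admissible <- function(candidates, old, new, kernel, epsilon = 1e-14,
                       enforce = TRUE) {
  if (nrow(candidates) == 0L) return(logical(0))
  if (!enforce) return(rep(TRUE, nrow(candidates)))
  check_same_nodes(old, new)
  ov <- old$values; nv <- new$values
  # candidate k admissible <=> u_i(t) + f(d_ik) < u*_i (1 + eps) for all i
  slack <- ov$value * (1 + epsilon) - nv$value
  d <- cross_dist(candidates$x, candidates$y, ov$x, ov$y)
  f <- kernel_eval(kernel, d)
  dim(f) <- dim(d)
  apply(f < rep(slack, each = nrow(f)), 1L, all)
}

# per-candidate scores; fmat is the candidates x control kernel matrix
score_3a <- function(fmat) rowSums(fmat)
score_3b <- function(fmat, deficit) as.numeric(fmat %*% deficit)

#' Greedy candidate selection (rules 3a / 3b)
#'
#' `select_3a()` returns the admissible candidate whose placement adds
#' the largest total signal to the control cells (equivalently,
#' minimizes the remaining gap S* - S(t)). `select_3b()` returns the
#' admissible candidate receiving the maximal deficit-weighted signal
#' z. Ties are broken by the fixed lexicographic (y, then x) order, so
#' runs are fully deterministic.
#'
#' @param candidates data frame of *admissible* candidate nodes.
#' @param old,new [signal_field]s (u*, u(t)) over the control cells
#'   (`old` is unused by rule 3a but kept for a uniform signature).
#' @param kernel a [signal_kernel()].
#' @return a one-row data frame (`x`, `y`), or `NULL` when no candidate
#'   is available (stall).
#' @export
select_3a <- function(candidates, old, new, kernel) {
  if (nrow(candidates) == 0L) return(NULL)
  nv <- new$values
  d <- cross_dist(candidates$x, candidates$y, nv$x, nv$y)
  f <- kernel_eval(kernel, d); dim(f) <- dim(d)
  pick_best(candidates, score_3a(f))
}

#' @rdname select_3a
#' @export
select_3b <- function(candidates, old, new, kernel) {
  if (nrow(candidates) == 0L) return(NULL)
  check_same_nodes(old, new)
  ov <- old$values; nv <- new$values
  d <- cross_dist(candidates$x, candidates$y, ov$x, ov$y)
  f <- kernel_eval(kernel, d); dim(f) <- dim(d)
  pick_best(candidates, score_3b(f, ov$value - nv$value))
}

# argmax; candidates arrive in tie-break order and which.max returns the
# first maximum, so ties resolve lexicographically (y, then x)
pick_best <- function(candidates, scores) {
  i <- which.max(scores)
  candidates[i, c("x", "y"), drop = FALSE]
}

#' Detect condition-2 violations
#'
#' Control cells whose relative overshoot \eqn{(u_i - u_i^*)/u_i^*}
#' reaches `epsilon` (the "yellow" cells); the worst violator (the
#' "blue" cell) is the one maximizing the absolute difference
#' \eqn{u_i - u_i^*}.
#'
#' @param old,new [signal_field]s over the identical control node set.
#' @param epsilon relative tolerance.
#' @return list with `violations` (data frame `x`, `y`, `rel_excess`)
#'   and `worst` (one-row data frame or `NULL`).
#' @export
detect_violations <- function(old, new, epsilon = 1e-14) {
  check_same_nodes(old, new)
  ov <- old$values; nv <- new$values
  rel <- (nv$value - ov$value) / ov$value
  bad <- rel >= epsilon
  viol <- data.frame(x = ov$x[bad], y = ov$y[bad], rel_excess = rel[bad])
  worst <- NULL
  if (any(bad)) {
    diffs <- nv$value - ov$value
    diffs[!bad] <- -Inf
    o <- tie_order(ov$x, ov$y)
    i <- o[which.max(diffs[o])]
    worst <- data.frame(x = ov$x[i], y = ov$y[i], rel_excess = rel[i])
  }
  list(violations = viol, worst = worst)
}

#' Run the regeneration algorithm
#'
#' The greedy loop: at each discrete time step recompute the current
#' field u(t) in the control cells, enumerate candidate nodes
#' (condition 1), filter by admissibility (condition 2), choose one cell
#' by rule 3a or 3b, place it, and repeat. One cell is added per step.
#' Termination:
#' \describe{
#'   \item{`"exact"`}{every control cell's relative deficit is at most
#'     `stop_deficit` (the new signal coincides with the old one), or the
#'     run stalls after having exactly rebuilt the removed node set}
#'   \item{`"stalled"`}{no admissible candidate while a deficit remains}
#'   \item{`"violation"`}{a control cell exceeds the overshoot tolerance
#'     after a placement (only reachable with the condition-2 filter
#'     off)}
#'   \item{`"step_limit"`}{`max_steps` placements without convergence}
#' }
#'
#' @param structure an amputated `cell_structure` with nonempty blastema.
#' @param kernel a [signal_kernel()].
#' @param config a [regen_config()].
#' @param target optional [signal_field] to use as the remembered u*
#'   instead of the structure's own pre-amputation field (morphogenesis
#'   mode uses this; see [grow_from_organizer()]).
#' @return an object of class `regen_result`: list with `structure`
#'   (final `cell_structure`), `status`, `steps` (cells placed), `trace`
#'   (one row per step: `step`, `x`, `y`, `S_t`, `max_rel_deficit`),
#'   `violations` and `worst_violation` (see [detect_violations()]),
#'   `S_star`, `old` and `final_field` (u* and u(T)), and `new_nodes`
#'   (placed cells in placement order).
#' @examples
#' s <- amputate(make_rectangle(8, 6), function(x, y) y >= 4)
#' r <- regenerate(s, signal_kernel("poly", 2), regen_config("3b"))
#' r$status   # "exact"
#' @export
regenerate <- function(structure, kernel = signal_kernel("poly", 2),
                       config = regen_config(), target = NULL) {
  df <- structure_nodes(structure)
  if (!any(df$role == "control")) {
    stop("regenerate() needs an amputated structure", call. = FALSE)
  }
  ctrl <- df[df$role == "control", c("x", "y")]
  old <- if (is.null(target)) old_field(structure, kernel) else target
  fv <- field_values(old)
  if (nrow(fv) != nrow(ctrl) || !all(fv$x == ctrl$x) || !all(fv$y == ctrl$y)) {
    stop("target field must be defined exactly on the control cells",
         call. = FALSE)
  }
  ref <- df[df$role %in% c("control", "removed"), , drop = FALSE]
  window <- search_window(ref, config$search_margin)
  seeds <- rbind(blastema(structure), df[df$role == "new", c("x", "y")])
  if (nrow(seeds) == 0L) {
    stop("invalid state: empty blastema, regeneration cannot start",
         call. = FALSE)
  }
  removed_keys <- node_key(df$x[df$role == "removed"], df$y[df$role == "removed"])
  grow_run(structure, seeds, old, kernel, config, window, removed_keys)
}

# shared greedy loop for regeneration and organizer growth.
# removed_keys: node keys of the amputated cells (character(0) for
# morphogenesis); a stall that has exactly rebuilt them counts as exact.
grow_run <- function(state, seeds, old, kernel, config, window,
                     removed_keys = character(0)) {
  df <- structure_nodes(state)
  ctrl <- df[df$role == "control", c("x", "y")]
  occ <- df[df$role %in% c("control", "new"), c("x", "y")]
  cur <- compute_field(occ, ctrl, kernel)
  S_star <- total_signal(old)
  ustar <- old$values$value
  trace <- vector("list", config$max_steps)
  steps <- 0L
  status <- NULL

  repeat {
    rel_deficit <- (ustar - cur$values$value) / ustar
    if (max(rel_deficit) <= config$stop_deficit) { status <- "exact"; break }
    if (steps >= config$max_steps) { status <- "step_limit"; break }

    cand <- candidate_set(state, config, seeds = seeds, window = window)
    ok <- admissible(cand, old, cur, kernel, config$epsilon,
                     enforce = config$enforce_condition2)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) {
      nn <- structure_nodes(state, "new")
      rebuilt <- length(removed_keys) > 0L &&
        nrow(nn) == length(removed_keys) &&
        setequal(node_key(nn$x, nn$y), removed_keys)
      status <- if (rebuilt) "exact" else "stalled"
      break
    }

    pick <- if (config$rule == "3a") select_3a(cand, old, cur, kernel)
            else select_3b(cand, old, cur, kernel)

    # place the cell; update u(t) incrementally
    state$nodes <- rbind(state$nodes,
                         data.frame(x = pick$x, y = pick$y, role = "new"))
    d <- sqrt((cur$values$x - pick$x)^2 + (cur$values$y - pick$y)^2)
    cur$values$value <- cur$values$value + kernel_eval(kernel, d)
    seeds <- rbind(seeds, pick)
    steps <- steps + 1L
    trace[[steps]] <- data.frame(
      step = steps, x = pick$x, y = pick$y,
      S_t = total_signal(cur),
      max_rel_deficit = max((ustar - cur$values$value) / ustar))

    v <- detect_violations(old, cur, config$epsilon)
    if (!is.null(v$worst)) { status <- "violation"; break }
  }

  v <- detect_violations(old, cur, config$epsilon)
  trace <- if (steps > 0L) do.call(rbind, trace[seq_len(steps)])
           else data.frame(step = integer(0), x = integer(0), y = integer(0),
                           S_t = numeric(0), max_rel_deficit = numeric(0))
  # a removed node regrown by a new cell is no longer "removed": keep the
  # removed role only for nodes still missing (one node, one cell)
  nk <- node_key(state$nodes$x, state$nodes$y)
  newkey <- nk[state$nodes$role == "new"]
  drop <- state$nodes$role == "removed" & nk %in% newkey
  state$nodes <- state$nodes[!drop, , drop = FALSE]
  structure(list(structure = state, status = status, steps = steps,
                 trace = trace, violations = v$violations,
                 worst_violation = v$worst, S_star = S_star, old = old,
                 final_field = cur,
                 new_nodes = structure_nodes(state, "new")[c("x", "y")]),
            class = "regen_result")
}

#' @export
print.regen_result <- function(x, ...) {
  cat(sprintf("<regen_result> status %s after %d steps; S* = %.6g, S(T) = %.6g\n",
              x$status, x$steps, x$S_star, total_signal(x$final_field)))
  if (nrow(x$violations) > 0L) {
    cat("  condition-2 violations at", nrow(x$violations), "control cell(s)\n")
  }
  invisible(x)
}

#' Grow a structure from an organizing center (morphogenesis mode)
#'
#' The regeneration engine reused for initial tissue growth: an
#' organizer domain carries a *prescribed* signal u* per cell (appearing
#' during embryogenesis, e.g. a morphogen distribution) instead of a
#' remembered one. New cells are placed around the organizer until the
#' signal they produce inside it coincides with the prescription. All
#' organizer cells act as control cells and every organizer boundary
#' cell (having an empty 8-neighbor) seeds growth.
#'
#' @param organizer a `cell_structure` (roles ignored; all cells become
#'   control cells).
#' @param target a [signal_field] over exactly the organizer cells: the
#'   prescribed u*. Must be at least the organizer's self-generated
#'   field everywhere, otherwise no growth can realize it (infeasible
#'   target). A target equal to the self-field yields zero growth with
#'   status `"exact"`.
#' @param kernel a [signal_kernel()].
#' @param config a [regen_config()].
#' @return a `regen_result` (see [regenerate()]).
#' @export
grow_from_organizer <- function(organizer, target,
                                kernel = signal_kernel("poly", 2),
                                config = regen_config()) {
  df <- structure_nodes(organizer)
  o2 <- tie_order(df$x, df$y)
  org <- organizer
  org$nodes <- data.frame(x = df$x[o2], y = df$y[o2], role = "control",
                          stringsAsFactors = FALSE)
  ctrl <- org$nodes[c("x", "y")]

  tv <- field_values(target)
  o1 <- tie_order(tv$x, tv$y)
  if (nrow(tv) != nrow(ctrl) ||
      !all(tv$x[o1] == ctrl$x) || !all(tv$y[o1] == ctrl$y)) {
    stop("target field must be defined exactly on the organizer cells",
         call. = FALSE)
  }
  target <- new_signal_field(tv$x[o1], tv$y[o1], tv$value[o1])

  self <- compute_field(ctrl, ctrl, kernel)
  if (any(target$values$value < self$values$value * (1 - 1e-12))) {
    stop("infeasible target: prescribed signal is below the organizer's ",
         "self-generated field at some cell", call. = FALSE)
  }

  # blastema = all boundary cells of the organizer (any empty 8-neighbor)
  occ <- node_key(ctrl$x, ctrl$y)
  nb <- neighbors8_keys(ctrl$x, ctrl$y)
  empty_nb <- matrix(!(nb$key %in% occ), nrow = 8L)
  boundary <- ctrl[colSums(empty_nb) > 0L, , drop = FALSE]

  window <- search_window(ctrl, config$search_margin)
  grow_run(org, boundary, target, kernel, config, window)
}
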