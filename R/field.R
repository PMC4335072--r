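#' Signal fields
#'
#' A `signal_field` maps lattice nodes to the nonnegative total signal
#' they receive. It is a data frame with columns `x`, `y`, `value`,
#' defined exactly on the requested evaluation node set. The central
#' quantity of the model: the total signal received by cell i is
#' \deqn{u_i = \sum_{j \ne i} f(d_{ij})}
#' summed over all source cells j, with f the decay kernel and d the
#' straight-line Euclidean distance between lattice nodes. Signals cross
#' empty space unimpeded (path-distance along tissue is out of scope).
#'
#' @name signal_field
NULL

new_signal_field <- function(x, y, value) {
  df <- data.frame(x = as.integer(x), y = as.integer(y),
                   value = as.numeric(value))
  structure(list(values = df), class = "signal_field")
}

#' @export
print.signal_field <- function(x, ...) {
  v <- x$values$value
  cat("<signal_field> ", nrow(x$values), " nodes, value range [",
      format(min(v)), ", ", format(max(v)), "]\n", sep = "")
  invisible(x)
}

#' @rdname signal_field
#' @param field a `signal_field`.
#' @return `field_values()` returns the underlying data frame
#'   (columns `x`, `y`, `value`).
#' @export
field_values <- function(field) {
  stopifnot(inherits(field, "signal_field"))
  field$values
}

# distance matrix between two coordinate sets (rows: a, cols: b)
cross_dist <- function(ax, ay, bx, by) {
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  sqrt(dx * dx + dy * dy)
}

#' Compute the signal field received from a source set
#'
#' For each evaluation node i, sums the kernel over all source cells j
#' with \eqn{d_{ij} > 0}; a source located at an evaluation node never
#' contributes to itself.
#'
#' @param sources data frame (columns `x`, `y`) of emitting cells, or a
#'   `cell_structure` (its occupied nodes are used).
#' @param eval_points data frame (columns `x`, `y`) of receiving nodes,
#'   or a `cell_structure`.
#' @param kernel a [signal_kernel()].
#' @return a [signal_field] over `eval_points`.
#' @export
compute_field <- function(sources, eval_points, kernel) {
  src <- as_nodes(sources)
  ev <- as_nodes(eval_points)
  if (nrow(src) == 0L) stop("source set must be nonempty", call. = FALSE)
  if (nrow(ev) == 0L) stop("evaluation set must be nonempty", call. = FALSE)
  d <- cross_dist(ev$x, ev$y, src$x, src$y)
  f <- matrix(0, nrow(d), ncol(d))
  pos <- d > 0
  f[pos] <- kernel_eval(kernel, d[pos])
  new_signal_field(ev$x, ev$y, rowSums(f))
}

# coerce structures / data frames to an x,y node table
as_nodes <- function(obj) {
  if (inherits(obj, "cell_structure")) return(occupied_nodes(obj)[c("x", "y")])
  df <- as.data.frame(obj)
  if (!all(c("x", "y") %in% names(df))) {
    stop("node sets need columns x and y", call. = FALSE)
  }
  df[c("x", "y")]
}

#' Old (remembered) signal field u*
#'
#' The old signal is measured in the control cells from all cells of the
#' original structure before the amputation: sources are control plus
#' removed cells, evaluation points are the control cells. This is the
#' distribution the control cells remember and that regeneration tries
#' to restore.
#'
#' @param structure an amputated `cell_structure`.
#' @param kernel a [signal_kernel()].
#' @return a [signal_field] over the control cells.
#' @export
old_field <- function(structure, kernel) {
  df <- structure_nodes(structure)
  if (!any(df$role == "removed") || !any(df$role == "control")) {
    stop("old_field() requires an amputated structure (control and removed cells)",
         call. = FALSE)
  }
  orig <- df[df$role %in% c("control", "removed"), c("x", "y")]
  ctrl <- df[df$role == "control", c("x", "y")]
  compute_field(orig, ctrl, kernel)
}

#' Current signal field u(t) in the control cells
#'
#' Total signal the control cells receive from all currently occupied
#' cells: control plus any new cells placed so far. Immediately after
#' amputation (no new cells) this is the reduced-structure field.
#'
#' @inheritParams old_field
#' @return a [signal_field] over the control cells.
#' @export
new_field <- function(structure, kernel) {
  df <- structure_nodes(structure)
  if (!any(df$role == "control")) {
    stop("new_field() requires an amputated structure", call. = FALSE)
  }
  occ <- df[df$role %in% c("control", "new"), c("x", "y")]
  ctrl <- df[df$role == "control", c("x", "y")]
  compute_field(occ, ctrl, kernel)
}

# assert two fields share the same node set in the same order
check_same_nodes <- function(a, b) {
  av <- a$values; bv <- b$values
  if (nrow(av) != nrow(bv) ||
      !all(av$x == bv$x) || !all(av$y == bv$y)) {
    stop("signal fields are defined on different node sets", call. = FALSE)
  }
}

#' Deficit-weighted signal z received by a candidate node
#'
#' Each control cell emits a signal proportional to its deficit
#' \eqn{u_i^* - u_i(t)}; the candidate at node k receives
#' \deqn{z_k = \sum_{i \in I_c} f(d_{ik}) (u_i^* - u_i(t)).}
#' This is the score maximized by selection rule 3b.
#'
#' @param candidate length-2 numeric (x, y) of the candidate node.
#' @param old,new [signal_field]s over the identical control node set
#'   (u* and u(t)).
#' @param kernel a [signal_kernel()].
#' @return the nonnegative scalar z.
#' @export
deficit_signal <- function(candidate, old, new, kernel) {
  check_same_nodes(old, new)
  ov <- old$values; nv <- new$values
  d <- sqrt((ov$x - candidate[1])^2 + (ov$y - candidate[2])^2)
  if (any(d == 0)) stop("candidate coincides with a control cell", call. = FALSE)
  sum(kernel_eval(kernel, d) * (ov$value - nv$value))
}

#' Total signal S of a field
#'
#' The sum over all nodes, \eqn{S = \sum_i u_i}; the quantity whose gap
#' to S* rule 3a closes greedily.
#'
#' @param field a [signal_field].
#' @return nonnegative scalar.
#' @export
total_signal <- function(field) {
  sum(field_values(field)$value)
}
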