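#' Cell structures on the integer lattice
#'
#' A `cell_structure` is a finite, nonempty set of occupied nodes of the
#' 2D integer lattice (unit spacing), each carrying a role label:
#' \describe{
#'   \item{`original`}{cell of the intact structure (before amputation)}
#'   \item{`control`}{cell remaining after amputation; remembers its old
#'     signal and measures the current one}
#'   \item{`removed`}{cell deleted by the amputation (its node stays in the
#'     table so the original node set is never lost)}
#'   \item{`new`}{cell placed by the regeneration engine}
#' }
#' Internally it is a data frame with integer columns `x`, `y` and a
#' character column `role`; no bounding grid is stored, so irregular
#' shapes (letters, composites) cost nothing extra.
#'
#' @name cell_structure
NULL

.roles <- c("original", "control", "removed", "new")

node_key <- function(x, y) paste(x, y, sep = ",")

#' Construct a cell structure from coordinates
#'
#' @param x,y integer lattice coordinates (equal length).
#' @param role role label(s), recycled; see [cell_structure].
#' @param name optional structure name (kept through serialization).
#' @return a `cell_structure`.
#' @export
cell_structure <- function(x, y, role = "original", name = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("a cell structure must contain at least one cell", call. = FALSE)
  if (any(x != round(x)) || any(y != round(y))) {
    stop("cell coordinates must be integers (cells sit on lattice nodes)", call. = FALSE)
  }
  role <- rep_len(as.character(role), length(x))
  if (!all(role %in% .roles)) {
    stop("unknown role(s): ", paste(setdiff(role, .roles), collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(x = as.integer(round(x)), y = as.integer(round(y)),
                   role = role, stringsAsFactors = FALSE)
  if (anyDuplicated(node_key(df$x, df$y))) {
    stop("two distinct cells never share a lattice node", call. = FALSE)
  }
  structure(list(nodes = df, name = name), class = "cell_structure")
}

#' @export
print.cell_structure <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = .roles))
  cat("<cell_structure>", if (!is.null(x$name)) paste0(" '", x$name, "'"),
      " ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s: %d", names(tab)[tab > 0], tab[tab > 0]), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Extract node subsets by role
#'
#' `structure_nodes()` returns the coordinate data frame of nodes whose
#' role is in `roles` (all nodes if `NULL`). `original_nodes()` returns
#' the pre-amputation node set (original, or control + removed once
#' amputated). `occupied_nodes()` returns the currently occupied set
#' (everything except `removed`).
#'
#' @param structure a `cell_structure`.
#' @param roles character vector of roles or `NULL`.
#' @return data frame with columns `x`, `y` (and `role`).
#' @export
structure_nodes <- function(structure, roles = NULL) {
  stopifnot(inherits(structure, "cell_structure"))
  df <- structure$nodes
  if (is.null(roles)) df else df[df$role %in% roles, , drop = FALSE]
}

#' @rdname structure_nodes
#' @export
original_nodes <- function(structure) {
  structure_nodes(structure, c("original", "control", "removed"))
}

#' @rdname structure_nodes
#' @export
occupied_nodes <- function(structure) {
  structure_nodes(structure, c("original", "control", "new"))
}

#' Moore neighborhood of a lattice node
#'
#' Every cell has 8 neighbors: 4 sharing a side and 4 sharing a corner.
#'
#' @param x,y integer coordinates of one node.
#' @return an 8-row data frame of neighbor coordinates.
#' @export
neighbors8 <- function(x, y) {
  stopifnot(length(x) == 1L, length(y) == 1L)
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  data.frame(x = as.integer(x) + dx, y = as.integer(y) + dy)
}

# vectorized Moore-neighborhood keys of several nodes (with duplicates)
neighbors8_keys <- function(x, y) {
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nx <- rep(x, each = 8L) + dx
  ny <- rep(y, each = 8L) + dy
  list(x = nx, y = ny, key = node_key(nx, ny))
}

#' Generate a filled rectangle of cells
#'
#' @param width,height positive integer dimensions.
#' @param origin length-2 integer vector, the lower-left node.
#' @return a `cell_structure` of `width * height` cells, all `original`.
#' @examples
#' make_rectangle(3, 2)            # 6 cells, (0,0)..(2,1)
#' @export
make_rectangle <- function(width, height, origin = c(0L, 0L)) {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1L || length(height) != 1L ||
      width < 1 || height < 1 ||
      width != round(width) || height != round(height)) {
    stop("width and height must be positive integers", call. = FALSE)
  }
  g <- expand.grid(x = seq.int(origin[1], length.out = width),
                   y = seq.int(origin[2], length.out = height))
  cell_structure(g$x, g$y,
                 name = sprintf("rect_%dx%d", as.integer(width), as.integer(height)))
}

#' Generate a lattice-filled ellipse
#'
#' All lattice nodes strictly inside the ellipse
#' \eqn{((x-cx)/a)^2 + ((y-cy)/b)^2 < 1}. Boundary-exact nodes are
#' excluded so membership never depends on floating-point ties.
#'
#' @param a,b positive semi-axes (x and y).
#' @param center length-2 numeric center.
#' @return a `cell_structure`; error if the ellipse contains no node.
#' @export
make_ellipse <- function(a, b, center = c(0, 0)) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0) {
    stop("semi-axes must be positive", call. = FALSE)
  }
  xs <- seq.int(ceiling(center[1] - a), floor(center[1] + a))
  ys <- seq.int(ceiling(center[2] - b), floor(center[2] + b))
  if (length(xs) == 0L || length(ys) == 0L) {
    stop("ellipse contains no lattice node", call. = FALSE)
  }
  g <- expand.grid(x = xs, y = ys)
  inside <- ((g$x - center[1]) / a)^2 + ((g$y - center[2]) / b)^2 < 1
  if (!any(inside)) stop("ellipse contains no lattice node", call. = FALSE)
  cell_structure(g$x[inside], g$y[inside],
                 name = sprintf("ellipse_%gx%g", a, b))
}

#' Glyph and composite fixtures
#'
#' Deterministic nonconvex shapes defined by explicit coordinate
#' rectangles (not font rasterization), for bit-exact reproducibility.
#' Strokes are 4-5 cells thick: thinner arms sit at the edge of the
#' model's validity range, where signals from the two sides of a stroke
#' mask each other and regeneration of a cut arm end becomes unreliable.
#' \describe{
#'   \item{`"L"`}{union of a vertical bar and a horizontal foot}
#'   \item{`"T"`}{mirror-symmetric shape with two arms}
#'   \item{`"H"`}{two vertical bars joined by a crossbar}
#'   \item{`"two_headed"`}{a trunk with two head rectangles, the
#'     multi-armed composite demonstrating that the same trunk can carry
#'     several remembered heads}
#' }
#'
#' @param glyph_id one of `"L"`, `"T"`, `"H"`, `"two_headed"`.
#' @return a `cell_structure`.
#' @export
make_glyph <- function(glyph_id) {
  rect_df <- function(x0, y0, w, h) {
    expand.grid(x = seq.int(x0, length.out = w), y = seq.int(y0, length.out = h))
  }
  parts <- switch(as.character(glyph_id),
    "L" = list(rect_df(0, 0, 4, 12), rect_df(4, 0, 5, 4)),
    "T" = list(rect_df(0, 8, 10, 4), rect_df(3, 0, 4, 8)),
    "H" = list(rect_df(0, 0, 4, 12), rect_df(8, 0, 4, 12), rect_df(4, 4, 4, 4)),
    "two_headed" = list(rect_df(0, 0, 4, 10),      # trunk
                        rect_df(-4, 10, 5, 4),     # left head
                        rect_df(3, 10, 5, 4)),     # right head
    stop("unknown glyph id: ", glyph_id, call. = FALSE)
  )
  g <- do.call(rbind, parts)
  g <- g[!duplicated(node_key(g$x, g$y)), , drop = FALSE]
  cell_structure(g$x, g$y, name = paste0("glyph_", glyph_id))
}

#' Amputate part of a cell structure
#'
#' Cells selected by the mask get role `removed`; every remaining cell
#' becomes a `control` cell. The blastema is the set of control cells
#' 8-adjacent to at least one removed cell: the front from which
#' regeneration may start.
#'
#' @param structure a `cell_structure` whose cells are all `original`.
#' @param mask the cells to remove: either a data frame / matrix with
#'   columns `x`, `y`, or a predicate `function(x, y)` returning a logical
#'   vector over the structure's nodes.
#' @return the amputated `cell_structure`; the blastema is available via
#'   [blastema()]. An empty mask yields a warning and the structure with
#'   all roles set to `control` (a no-op amputation).
#' @export
amputate <- function(structure, mask) {
  stopifnot(inherits(structure, "cell_structure"))
  df <- structure$nodes
  if (!all(df$role == "original")) {
    stop("amputate() expects an intact structure (all roles 'original')",
         call. = FALSE)
  }
  if (is.function(mask)) {
    sel <- mask(df$x, df$y)
    if (!is.logical(sel) || length(sel) != nrow(df)) {
      stop("mask predicate must return one logical per cell", call. = FALSE)
    }
  } else {
    m <- as.data.frame(mask)
    if (!all(c("x", "y") %in% names(m))) {
      stop("mask must have columns x and y", call. = FALSE)
    }
    mkey <- node_key(m$x, m$y)
    extra <- setdiff(mkey, node_key(df$x, df$y))
    if (length(extra) > 0L) {
      stop("mask contains nodes outside the structure: ",
           paste(utils::head(extra, 5L), collapse = "; "), call. = FALSE)
    }
    sel <- node_key(df$x, df$y) %in% mkey
  }
  if (!any(sel)) {
    warning("empty amputation mask: nothing removed")
    df$role <- "control"
    out <- structure; out$nodes <- df
    return(out)
  }
  if (all(sel)) {
    stop("invalid amputation: at least one cell must remain", call. = FALSE)
  }
  df$role <- ifelse(sel, "removed", "control")
  out <- structure
  out$nodes <- df
  out
}

#' Blastema of an amputated structure
#'
#' Control cells having at least one removed cell among their 8
#' neighbors. For an organizer (morphogenesis mode) pass the boundary
#' definition instead; see [grow_from_organizer()].
#'
#' @param structure an amputated `cell_structure`.
#' @return data frame of blastema node coordinates (possibly 0 rows).
#' @export
blastema <- function(structure) {
  df <- structure_nodes(structure)
  ctrl <- df[df$role == "control", , drop = FALSE]
  rem <- df[df$role == "removed", , drop = FALSE]
  if (nrow(ctrl) == 0L || nrow(rem) == 0L) {
    return(data.frame(x = integer(0), y = integer(0)))
  }
  remkey <- node_key(rem$x, rem$y)
  nb <- neighbors8_keys(ctrl$x, ctrl$y)
  hit <- matrix(nb$key %in% remkey, nrow = 8L)
  ctrl[colSums(hit) > 0L, c("x", "y"), drop = FALSE]
}

# 8-connected components of a node set; returns an integer label per row
connected_components8 <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  key <- node_key(df$x, df$y)
  idx <- seq_len(n)
  names(idx) <- key
  label <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    label[s] <- comp
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      nb <- neighbors8_keys(df$x[cur], df$y[cur])
      hits <- idx[nb$key[nb$key %in% key]]
      hits <- hits[label[hits] == 0L]
      label[hits] <- comp
      queue <- c(queue, hits)
    }
  }
  label
}
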