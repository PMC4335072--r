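#' Render a cell structure to a PNG image
#'
#' One fixed-size square per lattice node, using the conventional
#' colors: green for remaining (control/original) cells, red for new
#' cells, white for removed-but-not-regenerated nodes, yellow for
#' control cells violating the overshoot condition and blue for the
#' worst violator. Output is a raster of exactly
#' `bbox_width * cell_px` by `bbox_height * cell_px` pixels and is
#' deterministic for fixed inputs. The PNG is a convenience view only;
#' the CSV forms are the canonical, parse-back-able outputs.
#'
#' @param structure a `cell_structure`.
#' @param path output PNG path.
#' @param violations optional data frame (`x`, `y`) of violating cells.
#' @param worst optional one-row data frame (`x`, `y`), the worst
#'   violator.
#' @param cell_px pixels per lattice cell (default 10).
#' @return `path`, invisibly.
#' @export
render_structure <- function(structure, path, violations = NULL,
                             worst = NULL, cell_px = 10L) {
  df <- structure_nodes(structure)
  if (nrow(df) == 0L) stop("cannot render an empty structure", call. = FALSE)
  xr <- range(df$x); yr <- range(df$y)
  wpx <- (xr[2] - xr[1] + 1L) * cell_px
  hpx <- (yr[2] - yr[1] + 1L) * cell_px

  col <- ifelse(df$role == "new", "red",
         ifelse(df$role == "removed", "white", "green3"))
  key <- node_key(df$x, df$y)
  if (!is.null(violations) && nrow(violations) > 0L) {
    col[key %in% node_key(violations$x, violations$y)] <- "yellow"
  }
  if (!is.null(worst) && nrow(worst) > 0L) {
    col[key %in% node_key(worst$x, worst$y)] <- "blue"
  }

  grDevices::png(path, width = wpx, height = hpx)
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(xr[1] - 0.5, xr[2] + 0.5),
                        ylim = c(yr[1] - 0.5, yr[2] + 0.5))
  graphics::rect(xr[1] - 0.5, yr[1] - 0.5, xr[2] + 0.5, yr[2] + 0.5,
                 col = "grey90", border = NA)
  graphics::rect(df$x - 0.5, df$y - 0.5, df$x + 0.5, df$y + 0.5,
                 col = col, border = "grey40", lwd = 0.5)
  invisible(path)
}

# width/height of a PNG file from its IHDR chunk (used by tests; avoids
# needing a PNG reader package)
png_dim <- function(path) {
  bytes <- readBin(path, "raw", n = 33L)
  w <- sum(as.integer(bytes[17:20]) * 256^(3:0))
  h <- sum(as.integer(bytes[21:24]) * 256^(3:0))
  c(width = w, height = h)
}
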