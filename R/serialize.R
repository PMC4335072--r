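#' Read and write cell structures and fields as text
#'
#' Canonical on-disk formats (no domain standard exists for lattice cell
#' structures, so plain CSV/JSON is used):
#' \itemize{
#'   \item structure CSV: header `x,y,role`, one node per line;
#'   \item structure JSON: `{"name": ..., "nodes": [[x, y, "role"], ...]}`;
#'   \item field CSV: header `x,y,value`, values printed with 17
#'     significant digits so doubles round-trip exactly;
#'   \item trace CSV: `step,x,y,S_t,max_rel_deficit,status` (final
#'     status repeated on every row).
#' }
#' All files UTF-8 with LF line endings.
#'
#' @param structure a `cell_structure`.
#' @param path file path.
#' @name structure_io
NULL

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' @rdname structure_io
#' @export
write_structure_csv <- function(structure, path) {
  df <- structure_nodes(structure)
  write_lines_lf(c("x,y,role",
                   sprintf("%d,%d,%s", df$x, df$y, df$role)), path)
  invisible(path)
}

#' @rdname structure_io
#' @export
read_structure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "role") %in% names(df))) {
    stop("structure CSV needs columns x,y,role", call. = FALSE)
  }
  cell_structure(df$x, df$y, df$role)
}

#' @rdname structure_io
#' @export
write_structure_json <- function(structure, path) {
  df <- structure_nodes(structure)
  nodes <- lapply(seq_len(nrow(df)),
                  function(i) list(df$x[i], df$y[i], df$role[i]))
  doc <- list(name = if (is.null(structure$name)) "structure" else structure$name,
              nodes = nodes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname structure_io
#' @export
read_structure_json <- function(path) {
  doc <- jsonlite::read_json(path)
  x <- vapply(doc$nodes, function(n) as.numeric(n[[1]]), numeric(1))
  y <- vapply(doc$nodes, function(n) as.numeric(n[[2]]), numeric(1))
  role <- vapply(doc$nodes, function(n) as.character(n[[3]]), character(1))
  cell_structure(x, y, role, name = doc$name)
}

#' @rdname structure_io
#' @param field a `signal_field`.
#' @export
write_field_csv <- function(field, path) {
  fv <- field_values(field)
  write_lines_lf(c("x,y,value",
                   sprintf("%d,%d,%s", fv$x, fv$y, fmt17(fv$value))), path)
  invisible(path)
}

#' @rdname structure_io
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "integer", "numeric"))
  if (!all(c("x", "y", "value") %in% names(df))) {
    stop("field CSV needs columns x,y,value", call. = FALSE)
  }
  new_signal_field(df$x, df$y, df$value)
}

#' @rdname structure_io
#' @param result a `regen_result`.
#' @export
write_trace_csv <- function(result, path) {
  tr <- result$trace
  write_lines_lf(c("step,x,y,S_t,max_rel_deficit,status",
                   sprintf("%d,%d,%d,%s,%s,%s", tr$step, tr$x, tr$y,
                           fmt17(tr$S_t), fmt17(tr$max_rel_deficit),
                           result$status)), path)
  invisible(path)
}
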