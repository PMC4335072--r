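#' Run specifications
#'
#' A run spec captures everything needed to reproduce a simulation:
#' the shape generator and its parameters, the amputation, the kernel,
#' the engine configuration, and output options. It round-trips
#' losslessly through a JSON document; unknown keys are rejected so
#' typos fail loudly instead of silently using defaults.
#'
#' Schema (JSON object):
#' \preformatted{
#' {
#'   "name":       "run name",
#'   "shape":      {"generator": "rectangle"|"ellipse"|"glyph", ...params},
#'   "amputation": {"type": "rows_above"|"rows_below"|"cols_left"|
#'                          "cols_right"|"nodes", ...params},
#'   "kernel":     {"family": "poly"|"exp", "n": number},
#'   "config":     {"rule": "3a"|"3b", "enforce_condition2": bool,
#'                  "epsilon": number, "stop_deficit": number,
#'                  "max_steps": int, "search_margin": int},
#'   "output_dir": "runs/out",
#'   "render":     true
#' }
#' }
#' Shape parameters: rectangle `width`, `height`, optional `origin`
#' (pair); ellipse `a`, `b`, optional `center`; glyph `id`. Amputation
#' parameters: `rows_above`/`rows_below` need `y`; `cols_left`/
#' `cols_right` need `x` (cells with coordinate beyond the threshold,
#' inclusive, are removed); `nodes` needs `nodes`, a list of [x, y]
#' pairs.
#'
#' @param path file path of a JSON run spec.
#' @return `load_spec()` returns a validated `run_spec` object.
#' @name run_spec
NULL

.spec_keys <- c("name", "shape", "amputation", "kernel", "config",
                "output_dir", "render")

#' @rdname run_spec
#' @export
load_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_spec(doc)
}

#' @rdname run_spec
#' @param spec a `run_spec` (or plain list matching the schema).
#' @export
save_spec <- function(spec, path) {
  spec <- validate_spec(unclass(spec))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

validate_spec <- function(doc) {
  if (!is.list(doc)) stop("run spec must be a JSON object", call. = FALSE)
  unknown <- setdiff(names(doc), .spec_keys)
  if (length(unknown) > 0L) {
    stop("unknown run-spec key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  need <- function(key) {
    if (is.null(doc[[key]])) stop("run spec is missing '", key, "'", call. = FALSE)
    doc[[key]]
  }
  shape <- need("shape")
  if (is.null(shape$generator) ||
      !shape$generator %in% c("rectangle", "ellipse", "glyph")) {
    stop("shape.generator must be one of rectangle, ellipse, glyph",
         call. = FALSE)
  }
  amp <- need("amputation")
  if (is.null(amp$type) ||
      !amp$type %in% c("rows_above", "rows_below", "cols_left",
                       "cols_right", "nodes")) {
    stop("amputation.type must be one of rows_above, rows_below, ",
         "cols_left, cols_right, nodes", call. = FALSE)
  }
  kern <- need("kernel")
  if (is.null(kern$family) || !kern$family %in% c("poly", "exp")) {
    stop("kernel.family must be 'poly' or 'exp'", call. = FALSE)
  }
  if (is.null(kern$n) || kern$n <= 0) {
    stop("kernel.n must be positive", call. = FALSE)
  }
  cfg <- doc$config
  if (!is.null(cfg)) {
    extra <- setdiff(names(cfg),
                     c("rule", "enforce_condition2", "epsilon",
                       "stop_deficit", "max_steps", "search_margin"))
    if (length(extra) > 0L) {
      stop("unknown config key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(cfg$rule) && !cfg$rule %in% c("3a", "3b")) {
      stop("config.rule must be '3a' or '3b', got '", cfg$rule, "'",
           call. = FALSE)
    }
  }
  structure(doc, class = "run_spec")
}

#' Materialize the pieces of a run spec
#'
#' `spec_structure()` builds and amputates the shape; `spec_kernel()`
#' and `spec_config()` build the kernel and engine configuration.
#'
#' @param spec a `run_spec`.
#' @return respectively an amputated `cell_structure`, a
#'   [signal_kernel()], a [regen_config()].
#' @export
spec_structure <- function(spec) {
  sh <- spec$shape
  shape <- switch(sh$generator,
    rectangle = make_rectangle(sh$width, sh$height,
                               origin = if (is.null(sh$origin)) c(0L, 0L)
                                        else unlist(sh$origin)),
    ellipse = make_ellipse(sh$a, sh$b,
                           center = if (is.null(sh$center)) c(0, 0)
                                    else unlist(sh$center)),
    glyph = make_glyph(sh$id)
  )
  amp <- spec$amputation
  mask <- switch(amp$type,
    rows_above = local({ y0 <- amp$y; function(x, y) y >= y0 }),
    rows_below = local({ y0 <- amp$y; function(x, y) y <= y0 }),
    cols_left  = local({ x0 <- amp$x; function(x, y) x <= x0 }),
    cols_right = local({ x0 <- amp$x; function(x, y) x >= x0 }),
    nodes = {
      m <- do.call(rbind, lapply(amp$nodes, function(n)
        c(as.numeric(n[[1]]), as.numeric(n[[2]]))))
      data.frame(x = m[, 1], y = m[, 2])
    }
  )
  amputate(shape, mask)
}

#' @rdname spec_structure
#' @export
spec_kernel <- function(spec) {
  signal_kernel(spec$kernel$family, spec$kernel$n)
}

#' @rdname spec_structure
#' @export
spec_config <- function(spec) {
  cfg <- spec$config
  if (is.null(cfg)) cfg <- list()
  defaults <- regen_config()
  pick <- function(key) if (is.null(cfg[[key]])) defaults[[key]] else cfg[[key]]
  regen_config(rule = pick("rule"),
               enforce_condition2 = pick("enforce_condition2"),
               epsilon = pick("epsilon"),
               stop_deficit = pick("stop_deficit"),
               max_steps = pick("max_steps"),
               search_margin = pick("search_margin"))
}

#' Execute a run spec end to end
#'
#' Builds the structure, runs the engine, and writes the outputs
#' (trace CSV, final structure CSV, and a PNG render if requested)
#' under the spec's output directory.
#'
#' @param spec a `run_spec` (or path to one).
#' @param output_dir overrides the spec's output directory.
#' @param quiet suppress per-step log lines.
#' @return the `regen_result`, invisibly.
#' @export
run_spec <- function(spec, output_dir = NULL, quiet = FALSE) {
  if (is.character(spec)) spec <- load_spec(spec)
  spec <- validate_spec(unclass(spec))
  st <- spec_structure(spec)
  kern <- spec_kernel(spec)
  cfg <- spec_config(spec)
  res <- regenerate(st, kern, cfg)

  if (!quiet && nrow(res$trace) > 0L) {
    apply(res$trace, 1L, function(r) {
      cat(sprintf("step %d: place (%d, %d)  S(t) = %.10g  max rel deficit = %.3e\n",
                  as.integer(r[["step"]]), as.integer(r[["x"]]),
                  as.integer(r[["y"]]), r[["S_t"]], r[["max_rel_deficit"]]))
    })
  }
  out <- if (!is.null(output_dir)) output_dir
         else if (!is.null(spec$output_dir)) spec$output_dir
         else "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  name <- if (is.null(spec$name)) "run" else spec$name
  write_trace_csv(res, file.path(out, paste0(name, "_trace.csv")))
  write_structure_csv(res$structure, file.path(out, paste0(name, "_final.csv")))
  if (isTRUE(spec$render)) {
    render_structure(res$structure, file.path(out, paste0(name, ".png")),
                     violations = res$violations, worst = res$worst_violation)
  }
  if (!quiet) {
    cat(sprintf("status: %s after %d steps (S* = %.10g, S(T) = %.10g)\n",
                res$status, res$steps, res$S_star,
                total_signal(res$final_field)))
  }
  invisible(res)
}
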