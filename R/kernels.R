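#' Signal-decay kernels
#'
#' A kernel describes how the intensity of the signal emitted by one cell
#' decays with the Euclidean distance `d` to the receiving cell. Two
#' families are supported:
#' \describe{
#'   \item{`"poly"`}{polynomial decay, \eqn{f(d) = d^{-n}}}
#'   \item{`"exp"`}{exponential decay, \eqn{f(d) = e^{-n d}}}
#' }
#' with decay parameter `n > 0`. Both are strictly positive and strictly
#' decreasing for `d > 0`, which the engine relies on (a monotone kernel
#' makes signal equality equivalent to distance equality).
#'
#' @param family kernel family, `"poly"` or `"exp"` (aliases
#'   `"polynomial"`, `"exponential"` accepted).
#' @param n positive decay parameter.
#' @return an object of class `signal_kernel` with elements `family` and `n`.
#' @examples
#' k <- signal_kernel("poly", 2)
#' kernel_eval(k, 1)   # 1
#' kernel_eval(k, 2)   # 0.25
#' @export
signal_kernel <- function(family = c("poly", "exp", "polynomial", "exponential"),
                          n = 2) {
  family <- match.arg(family)
  family <- switch(family,
    polynomial = "poly",
    exponential = "exp",
    family
  )
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("kernel parameter `n` must be a single positive finite number",
         call. = FALSE)
  }
  structure(list(family = family, n = as.numeric(n)),
            class = "signal_kernel")
}

#' @export
print.signal_kernel <- function(x, ...) {
  form <- if (x$family == "poly") sprintf("f(d) = d^-%g", x$n)
          else sprintf("f(d) = exp(-%g d)", x$n)
  cat("<signal_kernel> ", form, "\n", sep = "")
  invisible(x)
}

#' Evaluate a kernel at given distances
#'
#' @param kernel a [signal_kernel()].
#' @param d vector of strictly positive distances. Cells never share a
#'   lattice node, so `d = 0` is a caller error, not a value to smooth over.
#' @return numeric vector of positive signal intensities.
#' @export
kernel_eval <- function(kernel, d) {
  stopifnot(inherits(kernel, "signal_kernel"))
  if (length(d) == 0L) return(numeric(0))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("kernel distances must be strictly positive and finite", call. = FALSE)
  }
  if (kernel$family == "poly") d^(-kernel$n) else exp(-kernel$n * d)
}
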