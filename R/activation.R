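#' Activation specification
#'
#' Bundles an activation kind with its parameters.  `tanhrelu` is the piecewise
#' fusion of the hyperbolic tangent (used for `|x| <= a`) with a half-slope
#' linear tail `0.5 * x` (used for `|x| > a`); `a` is the segmentation
#' parameter separating the two branches.  The remaining kinds are the usual
#' baselines used in ablations.
#'
#' As printed, the fused activation is discontinuous at `|x| = a` whenever
#' `tanh(a) != 0.5 * a` (see [discontinuity_gap()]).  The definition is kept
#' literal by default; `continuity_correction = TRUE` replaces the linear
#' branch by `tanh(a) * sign(x) + 0.5 * (x - a * sign(x))`, which shifts the
#' tail so the function is continuous while keeping its slope 0.5.
#'
#' @param kind One of `"tanhrelu"`, `"tanh"`, `"relu"`, `"sigmoid"`.
#' @param a Positive segmentation parameter (only used by `tanhrelu`);
#'   default 0.25.
#' @param continuity_correction Logical; use the continuity-corrected tail for
#'   `tanhrelu`.  Default `FALSE` (the literal definition).
#' @return An object of class `activation_spec`.
#' @examples
#' spec <- activation_spec("tanhrelu", a = 0.25)
#' activation_forward(spec, c(0, 1, -1))
#' @export
activation_spec <- function(kind = c("tanhrelu", "tanh", "relu", "sigmoid"),
                            a = 0.25, continuity_correction = FALSE) {
  kind <- match.arg(kind)
  check_scalar_pos(a, "segmentation parameter a")
  structure(list(kind = kind, a = a,
                 continuity_correction = isTRUE(continuity_correction)),
            class = "activation_spec")
}

#' @export
print.activation_spec <- function(x, ...) {
  cat(sprintf("<activation_spec: %s%s%s>\n", x$kind,
              if (x$kind == "tanhrelu") sprintf(", a = %g", x$a) else "",
              if (x$continuity_correction) ", continuity-corrected" else ""))
  invisible(x)
}

#' TanhReLU activation
#'
#' Computes `tanh(x)` where `|x| <= a` and `0.5 * x` where `|x| > a`.  The
#' boundary `|x| = a` takes the tanh branch.  Vectorised over `x`.  The
#' linear tail makes overflow impossible for large `|x|`; the tanh branch only
#' ever sees `|x| <= a`.
#'
#' @param x Numeric vector of finite pre-activations.
#' @param a Positive segmentation parameter.
#' @param continuity_correction Logical; shift the tail to remove the jump at
#'   `|x| = a` (see [activation_spec()]).
#' @return Numeric vector, same shape as `x`.
#' @seealso [tanhrelu_grad()], [discontinuity_gap()]
#' @export
tanhrelu <- function(x, a = 0.25, continuity_correction = FALSE) {
  check_scalar_pos(a, "segmentation parameter a")
  check_finite(x, "x")
  tanhrelu_eval(x, a, isTRUE(continuity_correction))
}

#' Derivative of the TanhReLU activation
#'
#' `1 - tanh(x)^2` where `|x| <= a` (boundary included) and `0.5` elsewhere.
#' For `a <= 1.2` (in particular the default 0.25) the derivative is bounded
#' in `[0.5, 1]` everywhere, so gradients can neither vanish nor explode
#' through this nonlinearity.
#'
#' @inheritParams tanhrelu
#' @return Numeric vector of derivative values.
#' @export
tanhrelu_grad <- function(x, a = 0.25) {
  check_scalar_pos(a, "segmentation parameter a")
  check_finite(x, "x")
  tanhrelu_grad_eval(x, a)
}

#' Jump height of TanhReLU at the branch point
#'
#' The literal piecewise definition is discontinuous at `x = a`: the tanh
#' branch ends at `tanh(a)` while the linear branch starts at `0.5 * a`.  This
#' returns `tanh(a) - 0.5 * a`, the (signed) jump at `x = a`; by oddness the
#' jump at `-a` is its negation.  The gap is positive for `0 < a < ~1.915`,
#' e.g. ~0.12 at the default `a = 0.25`.
#'
#' @param a Positive segmentation parameter.
#' @return The jump height, a single number.
#' @export
discontinuity_gap <- function(a) {
  check_scalar_pos(a, "segmentation parameter a")
  tanh(a) - 0.5 * a
}

#' Apply an activation elementwise
#'
#' Elementwise lift of the scalar activations over a vector, matrix or array;
#' the shape of `x` is preserved.  Dispatches on `spec$kind` so a whole
#' network can be re-run with a different activation by swapping the spec.
#'
#' @param spec An [activation_spec()].
#' @param x Numeric vector/array of finite values.
#' @return Activated values, same shape as `x`.
#' @export
activation_forward <- function(spec, x) {
  stopifnot(inherits(spec, "activation_spec"))
  check_finite(x, "x")
  out <- switch(spec$kind,
    tanhrelu = tanhrelu(x, spec$a, spec$continuity_correction),
    tanh     = tanh(x),
    relu     = pmax(x, 0),
    sigmoid  = sigmoid(x))
  attributes(out) <- attributes(x)
  out
}

#' Elementwise activation derivative
#'
#' Derivative of [activation_forward()] with respect to its input, evaluated
#' elementwise.  Conventions where the derivative is not classically defined:
#' ReLU at 0 returns 0 (subgradient choice); TanhReLU at `|x| = a` returns the
#' tanh-branch derivative.
#'
#' @inheritParams activation_forward
#' @return Derivative values, same shape as `x`.
#' @export
activation_deriv <- function(spec, x) {
  stopifnot(inherits(spec, "activation_spec"))
  check_finite(x, "x")
  out <- switch(spec$kind,
    tanhrelu = tanhrelu_grad(x, spec$a),
    tanh     = 1 - tanh(x)^2,
    relu     = as.numeric(x > 0),
    sigmoid  = { s <- sigmoid(x); s * (1 - s) })
  attributes(out) <- attributes(x)
  out
}

#' Numerically stable logistic function
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  attributes(out) <- attributes(x)
  out
}
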