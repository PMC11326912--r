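#' Two-sigmoid tachometric model
#'
#' The tachometric curve — proportion of correct antisaccades as a function of
#' raw processing time (rPT) — is summarised by the piecewise model
#' \deqn{v(x) = \max(L(x), R(x), 0)}
#' where \eqn{L(x) = B + (A_L - B) / (1 + e^{(x - C_L)/D_L})} tracks the early
#' fall from chance (\eqn{A_L}, fixed at 0.5) to the capture minimum \eqn{B},
#' and \eqn{R(x) = B + (A_R - B) / (1 + e^{-(x - C_R)/D_R})} tracks the later
#' rise to the lapse-limited asymptote \eqn{A_R}. \eqn{C_L} (\eqn{C_R}) is the
#' rPT at which the curve is halfway between chance and minimum (minimum and
#' asymptote); \eqn{D_L}, \eqn{D_R} set how abrupt each transition is (ms).
#'
#' @param b Minimum fraction correct at the capture dip, in `[0, 1]`.
#'   Fitting constrains it to `[0, al]`; the constructor accepts any
#'   probability so that hypothetical curves (e.g. one never dipping below
#'   chance) can be evaluated.
#' @param ar Asymptotic fraction correct, in `[0, 1]` (constrained to
#'   `[al, 1]` during fitting).
#' @param cl,cr Midpoints of the falling and rising branches (ms).
#' @param dl,dr Slope constants of the two branches (ms, > 0).
#' @param al Chance level; fixed at 0.5 for all fitting.
#'
#' @return An object of class `sigmoid_fit`.
#' @examples
#' f <- sigmoid_fit(b = 0.2, ar = 0.9, cl = 95, dl = 8, cr = 150, dr = 12)
#' eval_sigmoid(f, c(0, 120, 300))
#' @export
sigmoid_fit <- function(b, ar, cl, dl, cr, dr, al = 0.5) {
  check_number(al, "al", 0, 1)
  check_number(b, "b", 0, 1)
  check_number(ar, "ar", 0, 1)
  check_number(cl, "cl"); check_number(cr, "cr")
  if (!is.numeric(dl) || dl <= 0 || !is.numeric(dr) || dr <= 0) {
    abort("`dl` and `dr` must be positive.")
  }
  structure(
    list(b = b, al = al, ar = ar, cl = cl, dl = dl, cr = cr, dr = dr,
         mae = NA_real_, converged = NA, n_bins = NA_integer_),
    class = "sigmoid_fit"
  )
}

fit_par <- function(fit) c(fit$b, fit$ar, fit$cl, fit$dl, fit$cr, fit$dr)

#' Evaluate a tachometric model
#'
#' @param fit A [sigmoid_fit()] object.
#' @param x_ms rPT values (ms) at which to evaluate the curve.
#' @return Numeric vector of predicted fractions correct, in `[0, 1]`.
#' @export
eval_sigmoid <- function(fit, x_ms) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  sigmoid_eval_cpp(as.numeric(x_ms), fit_par(fit), fit$al)
}

#' @export
predict.sigmoid_fit <- function(object, x_ms, ...) eval_sigmoid(object, x_ms)

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Two-sigmoid tachometric fit (AL fixed at", x$al, ")\n")
  cat(sprintf("  B = %.3f  AR = %.3f\n", x$b, x$ar))
  cat(sprintf("  CL = %.1f ms (DL = %.1f)   CR = %.1f ms (DR = %.1f)\n",
              x$cl, x$dl, x$cr, x$dr))
  if (!is.na(x$mae)) {
    cat(sprintf("  MAE = %.4f over %d bins; converged: %s\n",
                x$mae, x$n_bins, x$converged))
  }
  invisible(x)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "al", "ar", "cl", "dl", "cr", "dr"),
    estimate = c(x$b, x$al, x$ar, x$cl, x$dl, x$cr, x$dr),
    fixed = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    mae = x$mae, converged = x$converged, n_bins = x$n_bins,
    asymptote = x$ar,
    rpt_at_75 = rpt_at_criterion(x, 0.75),
    p_capture = capture_probability(x)$p_capture
  )
}

#' rPT at which a criterion accuracy is reached
#'
#' Reads the smallest rPT on the rising branch of the fitted curve at which
#' accuracy reaches `level`, by scanning a 0.1-ms grid starting at the location
#' of the curve minimum. Returns `NA` when the criterion is unattainable
#' (asymptote at or below `level`).
#'
#' @inheritParams eval_sigmoid
#' @param level Criterion accuracy (default 0.75).
#' @param grid_ms Search grid resolution (ms).
#' @return rPT in ms, or `NA_real_` if the criterion is never reached.
#' @export
rpt_at_criterion <- function(fit, level = 0.75, grid_ms = 0.1) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  check_number(level, "level", 0, 1)
  if (fit$ar <= level) return(NA_real_)
  # locate the curve minimum, then scan the rising branch only
  span <- range(fit$cl - 10 * fit$dl, fit$cr + 10 * fit$dr)
  coarse <- seq(span[1], span[2], by = 1)
  x_min <- coarse[which.min(eval_sigmoid(fit, coarse))]
  upper <- fit$cr + 60 * fit$dr
  xs <- seq(x_min, upper, by = grid_ms)
  v <- eval_sigmoid(fit, xs)
  hit <- which(v >= level)
  if (length(hit) == 0) return(NA_real_)
  xs[hit[1]]
}

#' Probability of exogenous capture
#'
#' Measures how much of the fitted tachometric curve lies below chance within
#' an rPT window. The areas between the curve and the chance line (0.5) are
#' integrated on a 1-ms trapezoidal grid, separately where the curve is below
#' chance (`a_under`) and above chance (`a_over`); the capture probability is
#' `a_under / (a_under + a_over)`. It equals 0 for a curve that never drops
#' below chance and 1 for one that never rises above it; when the curve sits
#' exactly at chance everywhere (both areas zero) it is defined as 0.
#'
#' @inheritParams eval_sigmoid
#' @param rpt_range Integration window in ms (default 0–300).
#' @param step_ms Integration grid step (ms).
#' @return A one-row tibble with `a_under`, `a_over` (fraction·ms),
#'   `p_capture`, `rpt_min`, `rpt_max`.
#' @export
capture_probability <- function(fit, rpt_range = c(0, 300), step_ms = 1) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (length(rpt_range) != 2 || diff(rpt_range) <= 0) {
    abort("`rpt_range` must be an increasing pair of rPT values.")
  }
  a <- capture_areas(fit, rpt_range, step_ms)
  p <- if (a[1] + a[2] == 0) 0 else a[1] / (a[1] + a[2])
  tibble::tibble(a_under = a[1], a_over = a[2], p_capture = p,
                 rpt_min = rpt_range[1], rpt_max = rpt_range[2])
}

# c(a_under, a_over) on a trapezoidal grid; numeric fast path
capture_areas <- function(fit, rpt_range, step_ms = 1) {
  xs <- seq(rpt_range[1], rpt_range[2], by = step_ms)
  v <- eval_sigmoid(fit, xs)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * step_ms
  c(trap(pmax(0.5 - v, 0)), trap(pmax(v - 0.5, 0)))
}

p_capture_value <- function(fit, rpt_range = c(0, 300), step_ms = 1) {
  a <- capture_areas(fit, rpt_range, step_ms)
  if (a[1] + a[2] == 0) 0 else a[1] / (a[1] + a[2])
}
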