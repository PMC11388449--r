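#' pH grid
#'
#' Uniform pH grid on which titration curves are evaluated. The default
#' mirrors the wide scan used for continuum-electrostatics titration of
#' buried residues: pH -10 to +20 in 0.25 pH steps.
#'
#' @param ph_min,ph_max grid limits (pH units), `ph_min < ph_max`.
#' @param step grid increment (pH units), > 0. The upper limit is included
#'   when `ph_min + k*step` reaches it exactly (within 1e-9).
#' @return An object of class `ph_grid` with elements `ph_min`, `ph_max`,
#'   `step` and the evaluated `points`.
#' @examples
#' g <- ph_grid(0, 14, 0.5)
#' length(g$points)
#' @export
ph_grid <- function(ph_min = -10, ph_max = 20, step = 0.25) {
  stopifnot(is.numeric(ph_min), is.numeric(ph_max), is.numeric(step))
  if (!is.finite(ph_min) || !is.finite(ph_max) || !is.finite(step))
    stop("ph_grid: limits and step must be finite")
  if (ph_min >= ph_max) stop("ph_grid: ph_min must be < ph_max")
  if (step <= 0) stop("ph_grid: step must be > 0")
  k <- floor((ph_max - ph_min) / step + 1e-9)
  points <- ph_min + (0:k) * step
  structure(list(ph_min = ph_min, ph_max = ph_max, step = step,
                 points = points),
            class = "ph_grid")
}

#' @export
print.ph_grid <- function(x, ...) {
  cat(sprintf("<ph_grid> %g .. %g step %g (%d points)\n",
              x$ph_min, x$ph_max, x$step, length(x$points)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$points) == length(b$points) &&
    max(abs(a$points - b$points)) <= tol
}
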