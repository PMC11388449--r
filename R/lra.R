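#' Pool per-frame protonation curves
#'
#' Grand mean over frames (equal frame weights) of one site's average
#' protonation at each pH — the "average of averages" that feeds the
#' Henderson-Hasselbalch ensemble transform. For equal-length replicates
#' this equals the mean of replicate means.
#'
#' @param curves list of `titration_curve` objects sharing one grid.
#' @param site site id (or column index) present in every curve.
#' @return A list with `protonation` (vector over the grid), `grid` and
#'   `n_frames`.
#' @export
pool_protonation <- function(curves, site) {
  if (!length(curves)) stop("pool_protonation: empty curve list")
  grid <- curves[[1L]]$grid
  cols <- vapply(curves, function(cv) {
    stopifnot(inherits(cv, "titration_curve"))
    if (!same_grid(cv$grid, grid))
      stop("pool_protonation: curves do not share one pH grid")
    j <- if (is.character(site)) match(site, colnames(cv$protonation))
         else as.integer(site)
    if (is.na(j) || j < 1L || j > ncol(cv$protonation))
      stop("pool_protonation: site '", site, "' not found in a curve")
    cv$protonation[, j]
  }, numeric(length(grid$points)))
  list(protonation = rowMeans(cols), grid = grid, n_frames = length(curves))
}

new_ensemble_curve <- function(grid, pka, label, n_frames) {
  stopifnot(label %in% c("P", "D", "LRA"), n_frames > 0)
  structure(list(grid = grid, pka_values = pka, ensemble_label = label,
                 n_frames = n_frames),
            class = "ensemble_curve")
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve> %s, %d frames, %d/%d pH points defined\n",
              x$ensemble_label, x$n_frames, sum(!is.na(x$pka_values)),
              length(x$pka_values)))
  invisible(x)
}

#' Henderson-Hasselbalch ensemble transform
#'
#' Converts pooled average protonation into pH-dependent ensemble pKa
#' values: `pKa(pH) = pH + log10(p / (1 - p))`. Points where the pooled
#' protonation is within `epsilon` of 0 or 1 are left undefined (`NA`)
#' rather than clamped — the log term diverges there and clamping would
#' bias the downstream LRA average.
#'
#' @param protonation pooled protonation values in `[0, 1]`, one per grid
#'   point (or the list returned by [pool_protonation()]).
#' @param grid the [ph_grid()] (ignored when a pooled list is given).
#' @param epsilon protonation clamp boundary (default 1e-6).
#' @param label ensemble label, `"P"` or `"D"`.
#' @param n_frames frames pooled (taken from a pooled list when given).
#' @return An `ensemble_curve`.
#' @examples
#' hh_transform(10 / 11, ph_grid(6, 7, 1), label = "P",
#'              n_frames = 1)$pka_values[1]  # 7
#' @export
hh_transform <- function(protonation, grid = NULL, epsilon = 1e-6,
                         label = "P", n_frames = NULL) {
  if (is.list(protonation) && !is.null(protonation$protonation)) {
    if (is.null(grid)) grid <- protonation$grid
    if (is.null(n_frames)) n_frames <- protonation$n_frames
    protonation <- protonation$protonation
  }
  stopifnot(inherits(grid, "ph_grid"))
  if (is.null(n_frames)) n_frames <- 1L
  p <- protonation
  if (length(p) != length(grid$points))
    stop("hh_transform: protonation length does not match the grid")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("hh_transform: protonation values must lie in [0, 1]")
  pka <- ifelse(is.na(p) | p < epsilon | p > 1 - epsilon,
                NA_real_, grid$points + log10(p / (1 - p)))
  new_ensemble_curve(grid, pka, label, n_frames)
}

#' Two-endpoint linear response average
#'
#' The LRA estimate of the conformation-resolved pKa curve: the pointwise
#' mean of the ensemble pKa curves obtained with the target site fixed
#' protonated (P) and fixed deprotonated (D). Undefined wherever either
#' endpoint curve is undefined.
#'
#' @param curve_P,curve_D `ensemble_curve` objects labelled `"P"` and `"D"`
#'   on one grid (order-insensitive: labels are checked, not positions).
#' @return An `ensemble_curve` labelled `"LRA"`.
#' @export
lra_average <- function(curve_P, curve_D) {
  stopifnot(inherits(curve_P, "ensemble_curve"),
            inherits(curve_D, "ensemble_curve"))
  labs <- sort(c(curve_P$ensemble_label, curve_D$ensemble_label))
  if (!identical(labs, c("D", "P")))
    stop("lra_average: need one 'P' and one 'D' curve")
  if (!same_grid(curve_P$grid, curve_D$grid))
    stop("lra_average: curves are on different grids")
  new_ensemble_curve(curve_P$grid,
                     (curve_P$pka_values + curve_D$pka_values) / 2,
                     "LRA", curve_P$n_frames + curve_D$n_frames)
}

#' Macroscopic pKa: intersection with y = x
#'
#' The macroscopic pKa is read off where the ensemble pKa curve meets the
#' identity line (pKa = pH). A sign change of `f(pH) = pKa(pH) - pH`
#' between consecutive defined grid points is located by linear
#' interpolation; with no sign change the defined grid point minimizing
#' `|f|` is returned with `boundary_flag` set; with several sign changes
#' the root whose bracket has the smallest `|f|` is returned and
#' `multiple` is set.
#'
#' @param curve an `ensemble_curve` with at least two defined points.
#' @return A list with `pka_macro`, `ph_star`, `boundary_flag`, `multiple`.
#' @export
macroscopic_pka <- function(curve) {
  stopifnot(inherits(curve, "ensemble_curve"))
  ph <- curve$grid$points
  def <- which(!is.na(curve$pka_values))
  if (length(def) < 2L)
    stop("macroscopic_pka: fewer than 2 defined points")
  x <- ph[def]
  f <- curve$pka_values[def] - x
  roots <- x[f == 0]
  score <- rep(0, length(roots))
  i <- which(f[-length(f)] * f[-1L] < 0)
  if (length(i)) {
    roots <- c(roots, x[i] + (x[i + 1L] - x[i]) * f[i] / (f[i] - f[i + 1L]))
    score <- c(score, pmin(abs(f[i]), abs(f[i + 1L])))
  }
  if (!length(roots)) {
    k <- which.min(abs(f))
    return(list(pka_macro = curve$pka_values[def[k]], ph_star = x[k],
                boundary_flag = TRUE, multiple = FALSE))
  }
  best <- which.min(score)
  list(pka_macro = unname(roots[best]), ph_star = unname(roots[best]),
       boundary_flag = FALSE, multiple = length(roots) > 1L)
}

#' Delete-one jackknife standard error
#'
#' Re-estimates the macroscopic pKa with each partition (by default each MD
#' replicate) left out in turn and returns the jackknife standard error
#' `sqrt((n-1)/n * sum((theta_i - mean)^2))` together with the
#' leave-one-out values.
#'
#' @param partitions named list of frame groups; each element is passed as
#'   the *retained* complement to `estimator`.
#' @param estimator function taking a list of frames (the concatenation of
#'   the retained partitions) and returning a numeric scalar.
#' @return A list with `se` and `leave_one_out` (data.frame of partition id
#'   and estimate).
#' @examples
#' jackknife_se(list(a = 1, b = 2, c = 3),
#'              function(x) mean(unlist(x)))$se
#' @export
jackknife_se <- function(partitions, estimator) {
  n <- length(partitions)
  if (n < 2L) stop("jackknife_se: need at least 2 partitions")
  ids <- names(partitions)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  theta <- vapply(seq_len(n), function(i) {
    out <- tryCatch(estimator(do.call(c, unname(partitions[-i]))),
                    error = function(e)
                      stop("jackknife_se: estimator failed leaving out '",
                           ids[i], "': ", conditionMessage(e)))
    as.numeric(out)
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
  list(se = se,
       leave_one_out = data.frame(partition = ids, pka = theta,
                                  stringsAsFactors = FALSE))
}

# exact 1-D two-cluster split minimizing within-cluster sum of squares:
# clusters are contiguous in sorted order, so scan all split points with
# prefix sums. Returns the low-cluster size in sorted order.
kmeans2_1d <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_low <- cs2[k] - cs[k]^2 / k
  ss_high <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  k_best <- which.min(ss_low + ss_high)
  list(order = o, n_low = k_best,
       mean_low = cs[k_best] / k_best,
       mean_high = (cs[n] - cs[k_best]) / (n - k_best))
}

#' Split a pKhalf series into high and low populations
#'
#' Conformational substates can leave a per-frame pKhalf time series
#' bimodal (a sustained level shift in some replicates). This partitions
#' the defined pKhalf values into high and low populations either by an
#' exact 1-D two-cluster (2-means) split, with the threshold at the
#' midpoint of the cluster means, or by a fixed user threshold
#' (`pkhalf >= threshold` is high). A separation below 1 pK unit triggers
#' a likely-unimodal warning.
#'
#' @param records data.frame with columns `frame_id`, `replicate_id`,
#'   `time_ps`, `pkhalf` (`NA` = undefined; undefined records are excluded
#'   and counted).
#' @param method `"kmeans2"` or `"fixed"`.
#' @param fixed_threshold threshold in pK units, required for
#'   `method = "fixed"`.
#' @return An object of class `population_split`: `threshold`,
#'   `high_frames`, `low_frames` (frame-id vectors), `method`,
#'   `separation`, `n_undefined`.
#' @export
split_pkhalf_populations <- function(records,
                                     method = c("kmeans2", "fixed"),
                                     fixed_threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("frame_id", "pkhalf") %in% names(records)))
  def <- records[!is.na(records$pkhalf), , drop = FALSE]
  n_undef <- nrow(records) - nrow(def)
  if (nrow(def) < 10L)
    stop("split_pkhalf_populations: need >= 10 defined pkhalf records")
  x <- def$pkhalf
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("split_pkhalf_populations: fixed method requires fixed_threshold")
    thr <- fixed_threshold
    hi <- x >= thr
    sep <- if (any(hi) && any(!hi)) mean(x[hi]) - mean(x[!hi]) else 0
  } else {
    if (diff(range(x)) == 0) {
      warning("split_pkhalf_populations: values identical; ",
              "single population (separation 0)")
      return(structure(list(threshold = x[1], high_frames = def$frame_id,
                            low_frames = character(0), method = method,
                            separation = 0, n_undefined = n_undef),
                       class = "population_split"))
    }
    km <- kmeans2_1d(x)
    thr <- (km$mean_low + km$mean_high) / 2
    hi <- x >= thr
    sep <- km$mean_high - km$mean_low
  }
  if (sep < 1)
    warning("split_pkhalf_populations: separation ", signif(sep, 3),
            " pK < 1; populations are likely unimodal")
  structure(list(threshold = thr,
                 high_frames = def$frame_id[hi],
                 low_frames = def$frame_id[!hi],
                 method = method, separation = sep,
                 n_undefined = n_undef),
            class = "population_split")
}

#' @export
print.population_split <- function(x, ...) {
  cat(sprintf(
    "<population_split> %s: %d high / %d low at threshold %.3f (sep %.3f)\n",
    x$method, length(x$high_frames), length(x$low_frames), x$threshold,
    x$separation))
  invisible(x)
}
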