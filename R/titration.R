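#' Interacting-site titration model for one conformation
#'
#' One conformation's electrostatic summary: a set of titratable sites with
#' intrinsic pKa values plus a symmetric matrix of pairwise charge-charge
#' couplings, everything in pK units (energy / kT ln 10). This is the output
#' contract of a per-frame Poisson-Boltzmann calculation; the PB solve itself
#' is upstream of this package.
#'
#' @param sites a `data.frame` with columns `id` (character, unique),
#'   `pkint` (numeric, finite) and `polarity` (`"anionic"` or `"cationic"`).
#'   Anionic sites carry charge -1 when deprotonated; cationic sites carry
#'   +1 when protonated.
#' @param w symmetric numeric matrix (pK units) of pairwise couplings with
#'   zero diagonal; dimension = number of sites. Defaults to no coupling.
#' @return An object of class `titration_model`.
#' @examples
#' m <- titration_model(data.frame(id = "Asp2.50", pkint = 6.1,
#'                                 polarity = "anionic"))
#' @export
titration_model <- function(sites, w = NULL) {
  if (!is.data.frame(sites) ||
      !all(c("id", "pkint", "polarity") %in% names(sites)))
    stop("titration_model: sites must have columns id, pkint, polarity")
  n <- nrow(sites)
  if (n < 1L) stop("titration_model: need at least one site")
  sites$id <- as.character(sites$id)
  if (anyDuplicated(sites$id)) stop("titration_model: duplicate site ids")
  if (!all(is.finite(sites$pkint)))
    stop("titration_model: pkint must be finite")
  if (!all(sites$polarity %in% c("anionic", "cationic")))
    stop("titration_model: polarity must be 'anionic' or 'cationic'")
  if (is.null(w)) w <- matrix(0, n, n)
  w <- as.matrix(w)
  if (!is.numeric(w) || nrow(w) != n || ncol(w) != n)
    stop("titration_model: w must be a ", n, "x", n, " numeric matrix")
  if (any(diag(w) != 0)) stop("titration_model: w must have zero diagonal")
  if (max(abs(w - t(w))) > 1e-9) stop("titration_model: w must be symmetric")
  w <- (w + t(w)) / 2
  dimnames(w) <- list(sites$id, sites$id)
  structure(list(sites = sites, w = w), class = "titration_model")
}

#' @export
print.titration_model <- function(x, ...) {
  cat(sprintf("<titration_model> %d site(s): %s\n", nrow(x$sites),
              paste(x$sites$id, collapse = ", ")))
  invisible(x)
}

n_sites <- function(model) nrow(model$sites)

# charge vector of a protonation state: q_i = s_i - 1 (anionic), s_i (cationic)
state_charges <- function(state, model) {
  state - as.numeric(model$sites$polarity == "anionic")
}

#' Free energy of a protonation microstate
#'
#' `G(state; pH) = sum_i s_i (pH - pkint_i) + sum_{i<j} w_ij q_i q_j` in pK
#' units, with `q_i` the site charge implied by its polarity. The Boltzmann
#' weight of the microstate is `10^(-G)`; the all-deprotonated state of an
#' all-cationic model is the zero of energy at every pH.
#'
#' @param state integer/numeric vector of 0 (deprotonated) / 1 (protonated),
#'   one per site.
#' @param model a [titration_model()].
#' @param ph pH value.
#' @return Energy in pK units.
#' @examples
#' m <- titration_model(data.frame(id = c("a", "b"), pkint = c(4, 5),
#'                                 polarity = "anionic"),
#'                      w = matrix(c(0, .5, .5, 0), 2))
#' microstate_energy(c(0, 0), m, ph = 7)  # 0.5 = w12 * (-1)(-1)
#' @export
microstate_energy <- function(state, model, ph) {
  stopifnot(inherits(model, "titration_model"))
  if (length(state) != n_sites(model))
    stop("microstate_energy: state length must equal site count")
  if (!all(state %in% c(0, 1)))
    stop("microstate_energy: state entries must be 0 or 1")
  q <- state_charges(state, model)
  sum(state * (ph - model$sites$pkint)) +
    as.numeric(crossprod(q, model$w %*% q)) / 2
}

# all 2^n protonation states as a (2^n x n) 0/1 matrix, n >= 1
enumerate_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

new_titration_curve <- function(grid, protonation, method, mc_error = NULL) {
  structure(list(grid = grid, protonation = protonation, method = method,
                 mc_error = mc_error),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> method=%s, %d site(s) x %d pH points\n",
              x$method, ncol(x$protonation), nrow(x$protonation)))
  invisible(x)
}

#' Exact equilibrium titration by microstate enumeration
#'
#' Boltzmann-weighted average protonation of every site at every pH point,
#' summing over all `2^n` protonation microstates. Exact but exponential in
#' the site count; refuses models above `cap` sites (use [mc_titration()]
#' there). Log-sum-exp is used so the wide default pH range cannot overflow.
#'
#' @param model a [titration_model()].
#' @param grid a [ph_grid()].
#' @param cap enumeration cap on the number of sites (default 20).
#' @return A `titration_curve` (method `"exact"`): `protonation` is a
#'   `length(grid$points) x n_sites` matrix with site ids as column names.
#' @examples
#' m <- titration_model(data.frame(id = "s", pkint = 4, polarity = "anionic"))
#' curve <- exact_titration(m, ph_grid(0, 8, 1))
#' curve$protonation[5, ]  # 0.5 at pH 4
#' @export
exact_titration <- function(model, grid, cap = 20L) {
  stopifnot(inherits(model, "titration_model"), inherits(grid, "ph_grid"))
  n <- n_sites(model)
  if (n > cap)
    stop("exact_titration: ", n, " sites exceeds the enumeration cap (",
         cap, "); use mc_titration()")
  S <- enumerate_states(n)
  Q <- sweep(S, 2L, as.numeric(model$sites$polarity == "anionic"))
  pair_e <- rowSums((Q %*% model$w) * Q) / 2
  a <- rowSums(S)                               # pH-linear coefficient
  b <- pair_e - as.vector(S %*% model$sites$pkint)
  ph <- grid$points
  ln10 <- log(10)
  prot <- matrix(NA_real_, length(ph), n,
                 dimnames = list(NULL, model$sites$id))
  # chunk over pH so the 2^n x n_ph weight matrix stays modest
  chunk <- max(1L, floor(2e7 / nrow(S)))
  for (start in seq(1L, length(ph), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(ph))
    logw <- -ln10 * (outer(a, ph[idx]) + b)     # states x pH
    logw <- sweep(logw, 2L, apply(logw, 2L, max))
    wgt <- exp(logw)
    prot[idx, ] <- t(wgt) %*% S / colSums(wgt)
  }
  new_titration_curve(grid, pmin(pmax(prot, 0), 1), "exact")
}

#' Metropolis Monte Carlo titration
#'
#' Samples protonation microstates with a Metropolis chain run independently
#' at each pH point. One step is a random-scan sweep of `n_sites` proposals
#' (the usual step convention in titration Monte Carlo). Proposals are
#' single-site flips; with probability `pair_move_fraction` a simultaneous
#' two-site flip of the chosen site and its most strongly coupled partner is
#' proposed instead, which rescues mixing for strongly anti-correlated site
#' pairs. Standard errors are batch means over `n_batches` post-burn-in
#' blocks. Identical seeds give identical curves.
#'
#' @inheritParams exact_titration
#' @param steps Metropolis sweeps per pH point (must exceed `burn_in`).
#' @param burn_in discarded initial sweeps per pH (default 10% of
#'   `steps`).
#' @param pair_move_fraction probability of a pair flip proposal in `[0, 1]`.
#' @param seed integer RNG seed (required: the contract is deterministic).
#' @param n_batches batches for the batch-mean standard error (default 20).
#' @return A `titration_curve` (method `"mc"`) with an `mc_error` matrix of
#'   per-point standard errors alongside `protonation`.
#' @export
mc_titration <- function(model, grid, steps = 1e5, burn_in = floor(steps / 10),
                         pair_move_fraction = 0.1, seed, n_batches = 20L) {
  stopifnot(inherits(model, "titration_model"), inherits(grid, "ph_grid"))
  if (missing(seed)) stop("mc_titration: seed is required")
  steps <- as.integer(steps); burn_in <- as.integer(burn_in)
  if (steps <= 0L) stop("mc_titration: steps must be positive")
  if (burn_in < 0L || burn_in >= steps)
    stop("mc_titration: need steps > burn_in >= 0")
  if (pair_move_fraction < 0 || pair_move_fraction > 1)
    stop("mc_titration: pair_move_fraction must be in [0, 1]")
  n <- n_sites(model)
  aw <- abs(model$w)
  partner <- if (n > 1L) apply(aw, 1L, which.max) - 1L else 0L
  # a site with no couplings has no meaningful partner: fall back to single
  has_partner <- if (n > 1L) apply(aw, 1L, max) > 0 else FALSE
  set.seed(as.integer(seed))
  res <- mc_titrate_cpp(model$sites$pkint,
                        as.integer(model$sites$polarity == "anionic"),
                        model$w, grid$points, steps, burn_in,
                        pair_move_fraction,
                        as.integer(partner), as.integer(has_partner),
                        as.integer(n_batches))
  dimnames(res$protonation) <- list(NULL, model$sites$id)
  dimnames(res$se) <- list(NULL, model$sites$id)
  new_titration_curve(grid, res$protonation, "mc", mc_error = res$se)
}

#' Half-titration pH (pKhalf) of one site
#'
#' The pH at which a site's average protonation crosses 0.5, located by
#' linear interpolation between the bracketing grid points. For interacting
#' sites the curve need not be monotone: with several crossings the median
#' crossing is returned and `multiple = TRUE`; with none the value is `NA`
#' and `boundary = TRUE` (the site stays on one side of 0.5 over the whole
#' grid).
#'
#' @param curve a `titration_curve`.
#' @param site_index site column index (or site id) within the curve.
#' @return A list with `value` (pH, or `NA`), `multiple`, `boundary` and
#'   `n_crossings`.
#' @examples
#' m <- titration_model(data.frame(id = "s", pkint = 6.1,
#'                                 polarity = "anionic"))
#' pkhalf(exact_titration(m, ph_grid()), "s")$value  # 6.1
#' @export
pkhalf <- function(curve, site_index) {
  stopifnot(inherits(curve, "titration_curve"))
  if (is.character(site_index))
    site_index <- match(site_index, colnames(curve$protonation))
  if (is.na(site_index) || site_index < 1 ||
      site_index > ncol(curve$protonation))
    stop("pkhalf: site_index out of range")
  ph <- curve$grid$points
  d <- curve$protonation[, site_index] - 0.5
  crossings <- ph[d == 0]
  i <- which(d[-length(d)] * d[-1L] < 0)
  if (length(i))
    crossings <- c(crossings,
                   ph[i] + (ph[i + 1L] - ph[i]) * d[i] / (d[i] - d[i + 1L]))
  crossings <- sort(crossings)
  if (!length(crossings))
    return(list(value = NA_real_, multiple = FALSE, boundary = TRUE,
                n_crossings = 0L))
  list(value = unname(stats::median(crossings)),
       multiple = length(crossings) > 1L,
       boundary = FALSE,
       n_crossings = length(crossings))
}
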