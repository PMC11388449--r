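#' Specification of a synthetic conformational-titration ensemble
#'
#' Describes the statistical structure of per-frame titration output from
#' fixed-protonation MD: a few conformational substates with Markov
#' persistence along each replicate, a per-substate mean intrinsic pKa for
#' the target site with Gaussian within-substate spread, and optional
#' neighbor sites coupled to the target (shared across substates, as in a
#' rigid binding pocket).
#'
#' The deprotonated-ensemble substate occupancies are given; by default the
#' protonated-ensemble occupancies are derived by equilibrium reweighting,
#' `occ_P(k) proportional to occ_D(k) * 10^pkint_k` — the thermodynamically
#' consistent occupancies of a single conformational energy surface.
#' Supplying `occupancy_P` explicitly overrides this and emulates
#' kinetically trapped sampling (e.g. a substate flip that occurred in only
#' some replicates), at the cost of consistency with the equilibrium
#' oracle.
#'
#' @param states list of substates, each `list(label =, pkint_mean =,
#'   sigma =)` (sigma >= 0, pK units).
#' @param occupancy_D substate probabilities in the deprotonated ensemble
#'   (sums to 1).
#' @param occupancy_P optional explicit protonated-ensemble occupancies.
#' @param neighbors optional data.frame of fixed neighbor sites: columns
#'   `id`, `pkint`, `polarity`, `coupling` (coupling of each neighbor to
#'   the target, pK units).
#' @param markov_persistence probability of staying in the current substate
#'   between consecutive frames, in `[0, 1]`.
#' @param n_replicates,frames_per_replicate ensemble size (defaults 3 x
#'   1001, i.e. 100 ns sampled every 100 ps including t = 0).
#' @param interval_ps snapshot spacing in ps (default 100).
#' @param target_id label of the titrating target site (default
#'   `"Asp2.50"`, anionic).
#' @param seed integer RNG seed for [simulate_ensemble()].
#' @return An object of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(states,
                                    occupancy_D = rep(1 / length(states),
                                                      length(states)),
                                    occupancy_P = NULL,
                                    neighbors = NULL,
                                    markov_persistence = 0.99,
                                    n_replicates = 3L,
                                    frames_per_replicate = 1001L,
                                    interval_ps = 100,
                                    target_id = "Asp2.50",
                                    seed = 1L) {
  stopifnot(is.list(states), length(states) >= 1L)
  for (st in states)
    stopifnot(!is.null(st$label), is.finite(st$pkint_mean),
              st$sigma >= 0)
  if (abs(sum(occupancy_D) - 1) > 1e-9 || any(occupancy_D < 0))
    stop("synthetic_ensemble_spec: occupancy_D must be a probability vector")
  pk_means <- vapply(states, `[[`, 0, "pkint_mean")
  if (is.null(occupancy_P)) {
    w <- occupancy_D * 10^(pk_means - max(pk_means))
    occupancy_P <- w / sum(w)
  } else if (abs(sum(occupancy_P) - 1) > 1e-9 || any(occupancy_P < 0)) {
    stop("synthetic_ensemble_spec: occupancy_P must be a probability vector")
  }
  if (markov_persistence < 0 || markov_persistence > 1)
    stop("synthetic_ensemble_spec: markov_persistence must be in [0, 1]")
  if (!is.null(neighbors))
    stopifnot(all(c("id", "pkint", "polarity", "coupling") %in%
                    names(neighbors)))
  structure(list(states = states, occupancy_D = occupancy_D,
                 occupancy_P = occupancy_P, neighbors = neighbors,
                 markov_persistence = markov_persistence,
                 n_replicates = as.integer(n_replicates),
                 frames_per_replicate = as.integer(frames_per_replicate),
                 interval_ps = interval_ps,
                 target_id = target_id, seed = as.integer(seed)),
            class = "synthetic_ensemble_spec")
}

# titration_model for one frame: target site first, then fixed neighbors
frame_model <- function(spec, pkint_target) {
  if (is.null(spec$neighbors)) {
    sites <- data.frame(id = spec$target_id, pkint = pkint_target,
                        polarity = "anionic", stringsAsFactors = FALSE)
    return(titration_model(sites))
  }
  nb <- spec$neighbors
  sites <- data.frame(id = c(spec$target_id, nb$id),
                      pkint = c(pkint_target, nb$pkint),
                      polarity = c("anionic", nb$polarity),
                      stringsAsFactors = FALSE)
  n <- nrow(sites)
  w <- matrix(0, n, n)
  w[1, -1] <- nb$coupling
  w[-1, 1] <- nb$coupling
  titration_model(sites, w)
}

sample_markov_chain <- function(n, occupancy, persistence) {
  k <- length(occupancy)
  out <- integer(n)
  out[1] <- sample.int(k, 1L, prob = occupancy)
  if (n > 1L) for (t in 2:n) {
    out[t] <- if (stats::runif(1) < persistence) out[t - 1L]
              else sample.int(k, 1L, prob = occupancy)
  }
  out
}

#' Simulate P and D conformational-titration ensembles
#'
#' Emulates the per-frame titration output of fixed-protonation MD plus
#' continuum electrostatics: for each ensemble (target protonated, P;
#' deprotonated, D) and each replicate, a Markov chain over conformational
#' substates with the spec's persistence, and per frame a target-site
#' intrinsic pKa drawn from the substate's Normal law. Neighbor sites and
#' couplings are fixed. Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @param out_dir optional directory: writes `frames_P.jsonl`,
#'   `frames_D.jsonl` (the titration module's JSON-lines format) and a
#'   `truth.json` sidecar with per-frame substate labels and the oracle
#'   parameters.
#' @return List with `frames_P`, `frames_D` (lists of frame records, each
#'   `list(frame_id, replicate, time_ps, ensemble, model)`), `truth` and
#'   (when written) `paths`.
#' @export
simulate_ensemble <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  set.seed(spec$seed)
  pk_means <- vapply(spec$states, `[[`, 0, "pkint_mean")
  sigmas <- vapply(spec$states, `[[`, 0, "sigma")
  labels <- vapply(spec$states, `[[`, "", "label")
  gen <- function(ens_label, occupancy) {
    frames <- list()
    substates <- list()
    for (r in seq_len(spec$n_replicates)) {
      chain <- sample_markov_chain(spec$frames_per_replicate, occupancy,
                                   spec$markov_persistence)
      pk <- stats::rnorm(spec$frames_per_replicate, pk_means[chain],
                         sigmas[chain])
      for (t in seq_len(spec$frames_per_replicate)) {
        fid <- sprintf("%s_r%d_f%04d", ens_label, r, t)
        frames[[fid]] <- list(frame_id = fid, replicate = r,
                              time_ps = (t - 1) * spec$interval_ps,
                              ensemble = ens_label,
                              model = frame_model(spec, pk[t]))
      }
      substates[[r]] <- labels[chain]
    }
    list(frames = frames, substates = substates)
  }
  P <- gen("P", spec$occupancy_P)
  D <- gen("D", spec$occupancy_D)
  truth <- list(
    target_id = spec$target_id,
    state_labels = labels,
    pkint_means = pk_means,
    sigmas = sigmas,
    occupancy_D = spec$occupancy_D,
    occupancy_P = spec$occupancy_P,
    markov_persistence = spec$markov_persistence,
    neighbors = spec$neighbors,
    substates_P = P$substates,
    substates_D = D$substates,
    seed = spec$seed)
  out <- list(frames_P = P$frames, frames_D = D$frames, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(P = file.path(out_dir, "frames_P.jsonl"),
                  D = file.path(out_dir, "frames_D.jsonl"),
                  truth = file.path(out_dir, "truth.json"))
    write_frames(P$frames, paths$P)
    write_frames(D$frames, paths$D)
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               paths$truth)
    out$paths <- paths
  }
  out
}

#' Exact joint-model oracle for the macroscopic pKa
#'
#' Ground-truth construct: a small set of conformational substates, each
#' with a conformational free energy when the target is protonated and
#' when it is deprotonated (pK units) and a target intrinsic pKa, plus
#' optional shared neighbor sites. The macroscopic pKa of this model is
#' computable exactly by enumeration and serves as the reference the LRA
#' pipeline is validated against.
#'
#' @param pkints target-site intrinsic pKa per substate.
#' @param energies_D,energies_P conformational free energies per substate
#'   (pK units) with the target deprotonated / protonated. Equal vectors =
#'   a single conformational surface.
#' @param neighbors optional neighbor data.frame as in
#'   [synthetic_ensemble_spec()].
#' @param target_id target site label.
#' @return An object of class `joint_model_oracle`.
#' @export
joint_model_oracle <- function(pkints, energies_D, energies_P = energies_D,
                               neighbors = NULL, target_id = "Asp2.50") {
  k <- length(pkints)
  stopifnot(k >= 1L, length(energies_D) == k, length(energies_P) == k,
            all(is.finite(c(pkints, energies_D, energies_P))))
  structure(list(pkints = pkints, energies_D = energies_D,
                 energies_P = energies_P, neighbors = neighbors,
                 target_id = target_id),
            class = "joint_model_oracle")
}

#' Oracle from a synthetic ensemble spec
#'
#' Builds the [joint_model_oracle()] matching a
#' [synthetic_ensemble_spec()]: substate energies are
#' `-log10(occupancy_D)` on both protonation surfaces (the single-surface
#' equilibrium model whose conditional ensembles the generator samples by
#' default), target pkints are the substate means.
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @return A `joint_model_oracle`.
#' @export
oracle_from_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  occ <- pmax(spec$occupancy_D, 1e-300)
  joint_model_oracle(vapply(spec$states, `[[`, 0, "pkint_mean"),
                     energies_D = -log10(occ),
                     neighbors = spec$neighbors,
                     target_id = spec$target_id)
}

#' Exact macroscopic pKa of a joint substate/titration model
#'
#' Builds the joint partition function over (substate, protonation
#' microstate) at each grid pH — weight
#' `10^-(E_k(s_target) + G_k(state; pH))` — computes the exact ensemble
#' average protonation of the target site, and returns the pH where it
#' crosses 0.5 (linear interpolation).
#'
#' @param oracle a [joint_model_oracle()] (<= 4 substates).
#' @param grid a [ph_grid()].
#' @param cap per-substate enumeration cap (default 20 sites).
#' @return Macroscopic pKa in pK units.
#' @export
oracle_macroscopic_pka <- function(oracle, grid, cap = 20L) {
  stopifnot(inherits(oracle, "joint_model_oracle"),
            inherits(grid, "ph_grid"))
  k <- length(oracle$pkints)
  if (k > 4L) stop("oracle_macroscopic_pka: more than 4 substates")
  ph <- grid$points
  ln10 <- log(10)
  # accumulate log-weights over all (substate, microstate) per pH
  logw_all <- NULL
  s_all <- NULL
  for (j in seq_len(k)) {
    spec_like <- list(neighbors = oracle$neighbors,
                      target_id = oracle$target_id)
    model <- frame_model(spec_like, oracle$pkints[j])
    n <- n_sites(model)
    if (n > cap) stop("oracle_macroscopic_pka: enumeration cap exceeded")
    S <- enumerate_states(n)
    Q <- sweep(S, 2L, as.numeric(model$sites$polarity == "anionic"))
    pair_e <- rowSums((Q %*% model$w) * Q) / 2
    a <- rowSums(S)
    b <- pair_e - as.vector(S %*% model$sites$pkint) +
      ifelse(S[, 1L] == 1, oracle$energies_P[j], oracle$energies_D[j])
    logw_all <- rbind(logw_all, -ln10 * (outer(a, ph) + b))
    s_all <- c(s_all, S[, 1L])
  }
  logw_all <- sweep(logw_all, 2L, apply(logw_all, 2L, max))
  wgt <- exp(logw_all)
  prot <- as.vector(crossprod(wgt, s_all)) / colSums(wgt)
  d <- prot - 0.5
  hit <- ph[d == 0]
  i <- which(d[-length(d)] * d[-1L] < 0)
  crossings <- sort(c(hit, ph[i] + (ph[i + 1L] - ph[i]) * d[i] /
                             (d[i] - d[i + 1L])))
  if (!length(crossings))
    stop("oracle_macroscopic_pka: no 0.5 crossing inside the grid")
  unname(stats::median(crossings))
}

#' Simulate a bimodal pKhalf time series
#'
#' Per-replicate pKhalf time series with a sustained level shift at a
#' switch frame in a chosen subset of replicates plus Gaussian noise —
#' the phenomenology of a conformational substate flip that depresses the
#' target's microscopic pKa in some replicates only.
#'
#' @param base_pkhalf level before the switch (pK units).
#' @param shift sustained level change applied from `switch_frame` on in
#'   `shifted_replicates` (pK units; negative = decrease).
#' @param switch_frame 1-based frame index at which the shift starts.
#' @param shifted_replicates replicate indices that undergo the shift.
#' @param sigma Gaussian noise SD (pK units).
#' @param n_replicates,frames_per_replicate series size (defaults 3 x
#'   1001).
#' @param interval_ps frame spacing (ps).
#' @param seed integer RNG seed.
#' @param system system label for the output table.
#' @return data.frame with columns `system`, `replicate_id`, `frame_id`,
#'   `time_ps`, `pkhalf` and the generator label `true_pop`
#'   (`"base"`/`"shifted"`).
#' @export
simulate_pkhalf_series <- function(base_pkhalf = 7.5, shift = -2.0,
                                   switch_frame = 501L,
                                   shifted_replicates = c(2L, 3L),
                                   sigma = 0.2,
                                   n_replicates = 3L,
                                   frames_per_replicate = 1001L,
                                   interval_ps = 100,
                                   seed = 1L,
                                   system = "synthetic") {
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    level <- rep(base_pkhalf, frames_per_replicate)
    shifted <- rep(FALSE, frames_per_replicate)
    if (r %in% shifted_replicates && switch_frame <= frames_per_replicate) {
      idx <- switch_frame:frames_per_replicate
      level[idx] <- base_pkhalf + shift
      shifted[idx] <- TRUE
    }
    data.frame(system = system, replicate_id = r,
               frame_id = sprintf("r%d_f%04d", r,
                                  seq_len(frames_per_replicate)),
               time_ps = (seq_len(frames_per_replicate) - 1) * interval_ps,
               pkhalf = stats::rnorm(frames_per_replicate, level, sigma),
               true_pop = ifelse(shifted, "shifted", "base"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Toy structure fixtures with analytically known metrics
#'
#' Small constructed structures for exercising the geometry module:
#' \describe{
#'   \item{`"triangle345"`}{three residues whose side-chain COMs sit at
#'     (0,0,0), (3,0,0), (0,4,0); pocket area over codes
#'     2.50/3.39/7.49 is 6.}
#'   \item{`"ca_pair_5A"`}{two residues with Calpha at (0,0,0) and
#'     (3,4,0); the 3.50-6.34 distance is 5.}
#'   \item{`"dihedral_cis"`, `"dihedral_trans"`, `"dihedral_90"`}{an Asp
#'     whose CA/CB/CG/OD1 dihedral is 0, 180 or +90 degrees; code 2.50.}
#'   \item{`"npxxy_shift_1A"`}{a reference plus a frame whose NPxxY motif
#'     (7.49-7.53) backbone is rigidly displaced 1 Angstrom along x while
#'     anchor residues are untouched; with a fit on the anchors the motif
#'     RMSD is exactly 1.}
#'   \item{`"toy_receptor"`}{an Asp-only mini receptor mapping every BW
#'     code used by [activation_metrics()] (distances, pocket areas,
#'     NPxxY motif, chi2 target), plus an identical reference; not a real
#'     fold, but geometrically complete.}
#' }
#'
#' @param name fixture name.
#' @return List with `frame`, `map`, and for `"npxxy_shift_1A"` also
#'   `reference` and `anchor_codes` (the non-motif fit selection).
#' @export
generate_toy_structure <- function(name) {
  res_df <- function(chain, num, resname, names, elements, coords) {
    data.frame(atom_name = names, res_name = resname, chain = chain,
               res_num = num,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               element = elements, stringsAsFactors = FALSE)
  }
  # alanine-like residue: backbone around `base`, CB (the whole side
  # chain) exactly at `cb`
  ala <- function(chain, num, base, cb) {
    res_df(chain, num, "ALA",
           c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
           rbind(base + c(-1.2, 0.8, 0), base, base + c(1.3, 0.6, 0),
                 base + c(1.4, 1.8, 0), cb))
  }
  switch(
    name,
    triangle345 = {
      atoms <- rbind(ala("A", 10, c(-5, -5, 2), c(0, 0, 0)),
                     ala("A", 20, c(8, -5, 2), c(3, 0, 0)),
                     ala("A", 30, c(-5, 9, 2), c(0, 4, 0)))
      list(frame = structure_frame(atoms, "triangle345"),
           map = bw_map(list("2.50" = list(chain = "A", res_num = 10),
                             "3.39" = list(chain = "A", res_num = 20),
                             "7.49" = list(chain = "A", res_num = 30))))
    },
    ca_pair_5A = {
      atoms <- rbind(ala("A", 10, c(0, 0, 0), c(0.5, -1, 0)),
                     ala("A", 20, c(3, 4, 0), c(3.5, 5, 0)))
      list(frame = structure_frame(atoms, "ca_pair_5A"),
           map = bw_map(list("3.50" = list(chain = "A", res_num = 10),
                             "6.34" = list(chain = "A", res_num = 20))))
    },
    dihedral_cis = toy_dihedral(c(1, 1, 0)),
    dihedral_trans = toy_dihedral(c(1, -1, 0)),
    dihedral_90 = toy_dihedral(c(1, 0, 1)),
    npxxy_shift_1A = {
      anchors <- list(c("1.50", 10), c("2.50", 20), c("3.50", 30),
                      c("4.50", 40), c("5.50", 50), c("6.30", 60))
      motif <- list(c("7.49", 70), c("7.50", 71), c("7.51", 72),
                    c("7.52", 73), c("7.53", 74))
      base_of <- function(i) c(4 * cos(i), 4 * sin(i), 1.5 * i)
      build <- function(motif_shift) {
        rows <- lapply(seq_along(c(anchors, motif)), function(i) {
          e <- c(anchors, motif)[[i]]
          shift <- if (i > length(anchors)) motif_shift else c(0, 0, 0)
          b <- base_of(i)
          res_df("A", as.integer(e[2]), "ALA",
                 c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
                 sweep(rbind(b + c(-1.2, 0.8, 0.3), b,
                             b + c(1.3, 0.6, -0.2), b + c(1.4, 1.8, 0.5)),
                       2L, shift, "+"))
        })
        structure_frame(do.call(rbind, rows), "npxxy")
      }
      entries <- lapply(c(anchors, motif), function(e)
        list(chain = "A", res_num = as.integer(e[2])))
      names(entries) <- vapply(c(anchors, motif), `[`, "", 1)
      list(frame = build(c(1, 0, 0)), reference = build(c(0, 0, 0)),
           map = bw_map(entries),
           anchor_codes = vapply(anchors, `[`, "", 1))
    },
    toy_receptor = toy_receptor(),
    stop("generate_toy_structure: unknown fixture '", name, "'")
  )
}

# geometrically complete Asp-only mini receptor: every BW code used by
# activation_metrics resolves, each residue has backbone + full Asp side
# chain. Positions are an arbitrary non-degenerate helix-ish spiral.
toy_receptor <- function() {
  codes <- c("1.50", "2.50", "3.39", "3.40", "3.43", "3.50", "5.51",
             "6.30", "6.34", "6.40", "6.41", "6.44", "6.48", "7.49",
             "7.50", "7.51", "7.52", "7.53")
  asp <- function(num, b) {
    data.frame(
      atom_name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
      res_name = "ASP", chain = "A", res_num = num,
      x = b[1] + c(-1.2, 0, 1.3, 1.4, 0.2, 1.2, 1.9, 1.8),
      y = b[2] + c(0.8, 0, 0.6, 1.8, 1.1, 1.6, 1.1, 2.8),
      z = b[3] + c(0.3, 0, -0.2, 0.5, 0.8, 1.4, 2.3, 1.2),
      element = c("N", "C", "C", "O", "C", "C", "O", "O"),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_along(codes), function(i)
    asp(100L + i, c(8 * cos(0.9 * i), 8 * sin(0.9 * i), 1.7 * i))))
  entries <- stats::setNames(lapply(seq_along(codes), function(i)
    list(chain = "A", res_num = 100L + i)), codes)
  frame <- structure_frame(atoms, "toy_receptor")
  list(frame = frame, reference = frame, map = bw_map(entries))
}

toy_dihedral <- function(od1) {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    res_name = "ASP", chain = "A", res_num = 25,
    x = c(-1.0, 0, -1.2, -1.1, 0, 1, od1[1], 2),
    y = c(1.8, 1, 0.4, -0.8, 0, 0, od1[2], -0.7),
    z = c(0.2, 0, 0, 0.1, 0, 0, od1[3], 0),
    element = c("N", "C", "C", "O", "C", "C", "O", "O"),
    stringsAsFactors = FALSE)
  list(frame = structure_frame(atoms, "dihedral"),
       map = bw_map(list("2.50" = list(chain = "A", res_num = 25))))
}
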