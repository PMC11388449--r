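two_state_spec <- function(seed, frames = 150, dpk = 2, sigma = 0.3,
                           persistence = 0.99, neighbors = NULL) {
  synthetic_ensemble_spec(
    states = list(list(label = "low", pkint_mean = 6, sigma = sigma),
                  list(label = "high", pkint_mean = 6 + dpk,
                       sigma = sigma)),
    occupancy_D = c(0.5, 0.5), neighbors = neighbors,
    markov_persistence = persistence,
    n_replicates = 3L, frames_per_replicate = frames, seed = seed)
}

test_that("simulate_ensemble degenerates correctly and is deterministic", {
  # single substate, sigma 0: every frame identical at the state mean
  spec <- synthetic_ensemble_spec(
    states = list(list(label = "only", pkint_mean = 6.1, sigma = 0)),
    n_replicates = 2L, frames_per_replicate = 5L, seed = 4)
  sim <- simulate_ensemble(spec)
  expect_length(sim$frames_P, 10L)
  pk <- vapply(sim$frames_D, function(f) f$model$sites$pkint[1], 0)
  expect_true(all(pk == 6.1))

  # persistence 1: each replicate stays in its initial substate
  spec2 <- two_state_spec(seed = 8, frames = 40, persistence = 1)
  sim2 <- simulate_ensemble(spec2)
  for (r in 1:3)
    expect_length(unique(sim2$truth$substates_D[[r]]), 1L)

  # byte-identical files under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec3 <- two_state_spec(seed = 15, frames = 10)
  simulate_ensemble(spec3, out_dir = d1)
  simulate_ensemble(spec3, out_dir = d2)
  for (f in c("frames_P.jsonl", "frames_D.jsonl", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("protonated-ensemble occupancy is reweighted toward high-pK substates", {
  spec <- two_state_spec(seed = 1)
  # pi_P proportional to pi_D * 10^pk: the 8-unit substate dominates P
  expect_equal(spec$occupancy_P,
               c(0.5 * 1e6, 0.5 * 1e8) / (0.5 * 1e6 + 0.5 * 1e8))
  expect_equal(sum(spec$occupancy_P), 1)
})

test_that("oracle_macroscopic_pka matches closed forms and direct enumeration", {
  g <- ph_grid()
  # one substate, one site: the pkint itself
  expect_equal(oracle_macroscopic_pka(joint_model_oracle(6.1, 0), g),
               6.1, tolerance = 1e-3)
  # two substates, equal conformational energies on both surfaces:
  # closed form log10(mean(10^pk)) for a fast-exchange ensemble
  o2 <- joint_model_oracle(c(6, 8), energies_D = c(log10(2), log10(2)))
  expect_equal(oracle_macroscopic_pka(o2, g), log10((1e6 + 1e8) / 2),
               tolerance = 1e-3)
  # against an independent direct enumeration over (substate, state)
  o3 <- joint_model_oracle(c(5.5, 7.2), energies_D = -log10(c(0.3, 0.7)),
                           energies_P = -log10(c(0.1, 0.9)))
  direct <- function(ph) {
    num <- den <- 0
    for (k in 1:2) for (s in 0:1) {
      E <- if (s == 1) o3$energies_P[k] else o3$energies_D[k]
      wgt <- 10^(-(E + s * (ph - o3$pkints[k])))
      num <- num + s * wgt; den <- den + wgt
    }
    num / den
  }
  root <- uniroot(function(ph) direct(ph) - 0.5, c(-10, 20),
                  tol = 1e-12)$root
  expect_equal(oracle_macroscopic_pka(o3, g), root, tolerance = 1e-3)
  expect_error(oracle_macroscopic_pka(joint_model_oracle(30, 0),
                                      ph_grid(0, 14, 0.25)),
               "no 0.5 crossing")
})

test_that("pipeline recovers the oracle on two-substate ensembles", {
  # flagship recovery property, scaled down for the test budget
  # (3 x 150 frames, 8 seeds; the acceptance suite runs 20 seeds)
  g <- ph_grid()
  hits <- vapply(1:8, function(seed) {
    spec <- two_state_spec(seed = seed)
    sim <- simulate_ensemble(spec)
    res <- run_pipeline(pipeline_config(sim$frames_P, sim$frames_D))
    abs(res$pka_macro - oracle_macroscopic_pka(oracle_from_spec(spec), g))
  }, numeric(1))
  expect_gte(mean(hits <= 0.3), 0.9)
})

test_that("zero-spread single-substate pipeline returns pkint exactly", {
  spec <- synthetic_ensemble_spec(
    states = list(list(label = "only", pkint_mean = 7.3, sigma = 0)),
    n_replicates = 3L, frames_per_replicate = 20L, seed = 2)
  sim <- simulate_ensemble(spec)
  res <- run_pipeline(pipeline_config(sim$frames_P, sim$frames_D))
  expect_equal(res$pka_macro, 7.3, tolerance = 0.05)
  expect_equal(res$se, 0, tolerance = 1e-9)
})

test_that("jackknife SE shrinks with sampling", {
  ses <- sapply(1:10, function(seed) {
    one <- function(frames) {
      spec <- two_state_spec(seed = seed, frames = frames, sigma = 0.3,
                             persistence = 0.9)
      sim <- simulate_ensemble(spec)
      run_pipeline(pipeline_config(sim$frames_P, sim$frames_D))$se
    }
    c(small = one(30), large = one(240))
  })
  expect_lt(median(ses["large", ]), median(ses["small", ]))
})

test_that("simulate_pkhalf_series produces the stated level-shift structure", {
  # deterministic under seed
  a <- simulate_pkhalf_series(frames_per_replicate = 50, seed = 5)
  b <- simulate_pkhalf_series(frames_per_replicate = 50, seed = 5)
  expect_identical(a, b)
  # shift 0: indistinguishable from one population
  flat <- simulate_pkhalf_series(shift = 0, frames_per_replicate = 100,
                                 seed = 6)
  rec <- data.frame(frame_id = flat$frame_id,
                    replicate_id = flat$replicate_id,
                    time_ps = flat$time_ps, pkhalf = flat$pkhalf)
  expect_warning(split_pkhalf_populations(rec), "unimodal")
  # shifted replicates change level at the switch frame only
  s <- simulate_pkhalf_series(base_pkhalf = 7.5, shift = -2,
                              switch_frame = 26,
                              shifted_replicates = c(2, 3),
                              frames_per_replicate = 50, sigma = 0.1,
                              seed = 7)
  r1 <- s[s$replicate_id == 1, ]
  expect_true(all(r1$true_pop == "base"))
  r2 <- s[s$replicate_id == 2, ]
  expect_true(all(r2$true_pop[26:50] == "shifted"))
  expect_lt(mean(r2$pkhalf[26:50]), mean(r2$pkhalf[1:25]) - 1)
})

test_that("kmeans2 threshold lands between the two population means", {
  # 2 pK shift in 2 of 3 replicates: over 50 seeds the data-driven
  # threshold should separate the generator means in >= 95% of runs
  ok <- vapply(1:50, function(seed) {
    s <- simulate_pkhalf_series(base_pkhalf = 7.5, shift = -2,
                                switch_frame = 51,
                                frames_per_replicate = 100,
                                sigma = 0.2, seed = seed)
    sp <- split_pkhalf_populations(
      data.frame(frame_id = s$frame_id, replicate_id = s$replicate_id,
                 time_ps = s$time_ps, pkhalf = s$pkhalf))
    sp$threshold > 5.5 && sp$threshold < 7.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("population splitting moves the LRA estimate toward the high substate", {
  # bimodal world: the P ensemble is trapped half-and-half between the
  # substates (emulating a flip in some replicates); restricting to the
  # high-pKhalf population must push the estimate toward the
  # high-substate oracle value
  spec <- synthetic_ensemble_spec(
    states = list(list(label = "low", pkint_mean = 5.5, sigma = 0.2),
                  list(label = "high", pkint_mean = 7.5, sigma = 0.2)),
    occupancy_D = c(0.5, 0.5), occupancy_P = c(0.5, 0.5),
    markov_persistence = 0.995,
    n_replicates = 3L, frames_per_replicate = 200L, seed = 21)
  sim <- simulate_ensemble(spec)
  all_res <- run_pipeline(pipeline_config(sim$frames_P, sim$frames_D))
  high_res <- run_pipeline(pipeline_config(sim$frames_P, sim$frames_D,
                                           population = "high",
                                           jackknife = "thirds"))
  high_oracle <- oracle_macroscopic_pka(
    joint_model_oracle(7.5, 0), ph_grid())
  expect_lt(abs(high_res$pka_macro - high_oracle),
            abs(all_res$pka_macro - high_oracle))
  expect_lt(high_res$n_frames_P + high_res$n_frames_D,
            all_res$n_frames_P + all_res$n_frames_D)
})

test_that("toy structure generator rejects unknown fixtures", {
  expect_error(generate_toy_structure("nope"), "unknown fixture")
})
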