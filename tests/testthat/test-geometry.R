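test_that("resolve_bw finds residues and fails loudly", {
  fx <- generate_toy_structure("ca_pair_5A")
  res <- resolve_bw(fx$map, fx$frame, "3.50")
  expect_equal(unique(res$res_num), 10L)
  expect_error(resolve_bw(fx$map, fx$frame, "9.99"), "not in map")
  bad <- bw_map(list("2.50" = list(chain = "B", res_num = 999)))
  expect_error(resolve_bw(bad, fx$frame, "2.50"), "B/999")
})

test_that("ca_distance is Euclidean, symmetric and rigid-invariant", {
  fx <- generate_toy_structure("ca_pair_5A")
  expect_equal(ca_distance(fx$frame, "3.50", "6.34", fx$map), 5)
  expect_equal(ca_distance(fx$frame, "6.34", "3.50", fx$map), 5)
  for (seed in 1:5) {
    moved <- rigid_transform(fx$frame, seed)
    expect_equal(ca_distance(moved, "3.50", "6.34", fx$map), 5,
                 tolerance = 1e-9)
  }
})

test_that("sidechain_com is the mass-weighted heavy side-chain mean", {
  fx <- generate_toy_structure("triangle345")
  # alanine: CB is the whole heavy side chain
  expect_equal(sidechain_com(fx$frame, resolve_bw(fx$map, fx$frame, "2.50")),
               c(0, 0, 0))
  expect_equal(sidechain_com(fx$frame, resolve_bw(fx$map, fx$frame, "3.39")),
               c(3, 0, 0))
  # two equal-mass atoms average to the midpoint
  res <- data.frame(atom_name = c("CB", "CG"), res_name = "XXX",
                    chain = "A", res_num = 1, x = c(0, 2), y = 0, z = 0,
                    element = "C", mass = 12.011)
  expect_equal(sidechain_com(NULL, res), c(1, 0, 0))
  # glycine has no heavy side-chain atom
  gly <- data.frame(atom_name = c("N", "CA", "C", "O"), res_name = "GLY",
                    chain = "A", res_num = 2, x = 0:3, y = 0, z = 0,
                    element = c("N", "C", "C", "O"),
                    mass = c(14, 12, 12, 16))
  expect_error(sidechain_com(NULL, gly), "side-chain")
})

test_that("heron_area handles right, degenerate and invalid triangles", {
  expect_equal(heron_area(3, 4, 5), 6)
  expect_equal(heron_area(1, 2, 3), 0)
  expect_error(heron_area(1, 1, 3), "triangle inequality")
  expect_error(heron_area(-1, 2, 2), ">= 0")
})

test_that("pocket_area composes COMs with Heron and is permutation-invariant", {
  fx <- generate_toy_structure("triangle345")
  codes <- c("2.50", "3.39", "7.49")
  expect_equal(pocket_area(fx$frame, codes, fx$map), 6)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(pocket_area(fx$frame, codes[perm], fx$map), 6)
  for (seed in 1:3)
    expect_equal(pocket_area(rigid_transform(fx$frame, seed), codes,
                             fx$map), 6, tolerance = 1e-9)
  expect_error(pocket_area(fx$frame, codes[1:2], fx$map), "three")
})

test_that("chi2_torsion matches constructed angles and the reference dihedral", {
  for (case in list(list("dihedral_cis", 0), list("dihedral_trans", 180),
                    list("dihedral_90", 90))) {
    fx <- generate_toy_structure(case[[1]])
    res <- resolve_bw(fx$map, fx$frame, "2.50")
    ang <- chi2_torsion(fx$frame, res)
    expect_equal(ang, case[[2]], tolerance = 1e-9)
    # independent implementation agrees (up to the 180 == -180 seam)
    p <- lapply(c("CA", "CB", "CG", "OD1"), function(nm)
      protolra:::atom_xyz(res, nm))
    ref <- ref_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(ang %% 360, ref %% 360, tolerance = 1e-6)
  }
  # sign flips under mirror reflection
  fx <- generate_toy_structure("dihedral_90")
  mirrored <- fx$frame
  mirrored$atoms$z <- -mirrored$atoms$z
  expect_equal(chi2_torsion(mirrored, resolve_bw(fx$map, mirrored, "2.50")),
               -90, tolerance = 1e-9)
  # rigid-transform invariance
  for (seed in 4:6) {
    moved <- rigid_transform(fx$frame, seed)
    expect_equal(chi2_torsion(moved, resolve_bw(fx$map, moved, "2.50")),
                 90, tolerance = 1e-6)
  }
})

test_that("npxxy_rmsd is zero on self and rigid copies, 1 on the 1A fixture", {
  fx <- generate_toy_structure("npxxy_shift_1A")
  expect_equal(npxxy_rmsd(fx$reference, fx$reference, fx$map), 0,
               tolerance = 1e-9)
  for (seed in 7:9) {
    moved <- rigid_transform(fx$reference, seed)
    expect_equal(npxxy_rmsd(moved, fx$reference, fx$map), 0,
                 tolerance = 1e-6)
  }
  # motif displaced 1 A, fit on the untouched anchors
  expect_equal(npxxy_rmsd(fx$frame, fx$reference, fx$map,
                          fit_selection = fx$anchor_codes), 1,
               tolerance = 1e-9)
  # rigid motion of the whole shifted frame changes nothing after the fit
  moved <- rigid_transform(fx$frame, 11)
  expect_equal(npxxy_rmsd(moved, fx$reference, fx$map,
                          fit_selection = fx$anchor_codes), 1,
               tolerance = 1e-6)
  small <- bw_map(list("7.49" = list(chain = "A", res_num = 70)))
  expect_error(npxxy_rmsd(fx$frame, fx$reference, small), "motif codes")
})

test_that("a100_index applies the 0/55 thresholds with closed boundaries", {
  fx <- generate_toy_structure("ca_pair_5A")
  cfg_at <- function(intercept)
    a100_config(rep(list(c("3.50", "6.34")), 5), rep(0, 5),
                intercept = intercept)
  cases <- list(list(60, "active"), list(-1, "inactive"),
                list(30, "intermediate"),
                # boundary values belong to the intermediate band
                list(0, "intermediate"), list(55, "intermediate"))
  for (cs in cases) {
    r <- a100_index(fx$frame, cfg_at(cs[[1]]), fx$map)
    expect_equal(r$value, cs[[1]])
    expect_identical(r$state, cs[[2]])
  }
  # distances enter through the coefficients
  cfg <- a100_config(rep(list(c("3.50", "6.34")), 5), rep(2, 5),
                     intercept = 5)
  expect_equal(a100_index(fx$frame, cfg, fx$map)$value, 5 + 2 * 5 * 5)
  expect_error(a100_config(rep(list(c("3.50", "6.34")), 4), rep(0, 4)),
               "five")
})

test_that("frame_count reproduces standard sampling protocols", {
  expect_identical(frame_count(100000, 100, 1), 1001L)
  expect_identical(frame_count(100000, 100, 3), 3003L)
  expect_identical(frame_count(0, 100, 1), 1L)
  expect_identical(frame_count(100000, 100, 2, include_t0 = FALSE), 2000L)
  expect_error(frame_count(1000, 300, 1), "divide")
})

test_that("activation_metrics assembles a full per-frame record", {
  fx <- generate_toy_structure("toy_receptor")
  cfg <- a100_config(rep(list(c("3.50", "6.34")), 5), rep(0, 5),
                     intercept = 60)
  met <- activation_metrics(fx$frame, fx$reference, fx$map, a100 = cfg)
  expect_s3_class(met, "activation_metrics")
  num <- unlist(met[c("tm3_tm6_A", "tm3_tm7_ca_A", "ts_d1_A", "ts_d2_A",
                      "na_pocket_area_A2", "hlock_area_A2",
                      "tm3_tm7_sc_A")])
  expect_true(all(is.finite(num)) && all(num > 0))
  expect_equal(met$npxxy_rmsd_A, 0, tolerance = 1e-9)  # self-reference
  expect_identical(met$state, "active")
  expect_true(met$chi2_deg > -180 && met$chi2_deg <= 180)
  # cross-check one distance against the raw coordinates
  a <- protolra:::atom_xyz(resolve_bw(fx$map, fx$frame, "3.50"), "CA")
  b <- protolra:::atom_xyz(resolve_bw(fx$map, fx$frame, "6.34"), "CA")
  expect_equal(met$tm3_tm6_A, sqrt(sum((a - b)^2)))
})
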