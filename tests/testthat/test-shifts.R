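spec_sh <- fixture_spec(20L, 4L, sigma = 0.05, seed = 31L,
                        aromatic_at = 10L)
ens_sh <- make_ensemble(spec_sh)

test_that("Shrake-Rupley agrees with the closed-form single-sphere area", {
  r_exp <- nmrvalid:::vdw_radius("C") + 1.4
  asa <- shrake_rupley_sasa(matrix(c(0, 0, 0), 1L), "C")
  expect_equal(asa, 4 * pi * r_exp^2, tolerance = 1e-9)
  # two distant atoms: both fully exposed
  asa2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(50, 0, 0)), c("C", "C"))
  expect_equal(asa2[1L], 4 * pi * r_exp^2, tolerance = 1e-9)
  # hydrogens carry no area and do not occlude
  asa3 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(1.0, 0, 0)), c("C", "H"))
  expect_equal(asa3, c(4 * pi * r_exp^2, 0), tolerance = 1e-9)
})

test_that("Shrake-Rupley matches a dense Monte Carlo oracle on two spheres", {
  coords <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  el <- c("C", "N")
  asa <- shrake_rupley_sasa(coords, el, n_points = 1024L)
  set.seed(99)
  oracle <- vapply(1:2, function(i) {
    r <- nmrvalid:::vdw_radius(el[i]) + 1.4
    n <- 20000L
    z <- matrix(rnorm(3L * n), n, 3L)
    z <- z / sqrt(rowSums(z^2)) * r
    pts <- sweep(z, 2L, coords[i, ], `+`)
    j <- 3L - i
    rj <- nmrvalid:::vdw_radius(el[j]) + 1.4
    acc <- rowSums(sweep(pts, 2L, coords[j, ])^2) > rj^2
    4 * pi * r^2 * mean(acc)
  }, 0)
  expect_equal(asa, oracle, tolerance = 0.02)
})

test_that("a buried atom at the core of a dense cluster has zero accessibility", {
  shell <- nmrvalid:::sphere_points(40L) * 3.0
  coords <- rbind(c(0, 0, 0), shell)
  asa <- shrake_rupley_sasa(coords, rep("C", nrow(coords)))
  expect_equal(asa[1L], 0)
})

test_that("residue environments classify helix interiors and isolated residues", {
  env <- residue_environments(ens_sh)
  interior <- env$resno %in% 3:18
  expect_true(all(env$ss[interior] == "H"))
  expect_true(all(env$ss[env$resno %in% c(1L, 20L)] == "C"))
  expect_true(all(env$rel_acc >= 0 & env$rel_acc <= 1))
  expect_true(all(env$acc_bin %in% c("buried", "exposed")))
  # an isolated single residue is fully exposed
  one <- nmrvalid:::build_ensemble(list(
    nmrvalid:::build_ideal_chain(5L)[1:7, ]))
  env1 <- residue_environments(one)
  expect_gt(env1$rel_acc[1L], 0.8)
  expect_equal(env1$acc_bin[1L], "exposed")
})

test_that("planted per-class offsets are recovered exactly on noiseless draws", {
  sim <- simulate_shifts(ens_sh, spec_sh,
                         offsets = c(`13C_aliphatic` = 1.7),
                         noise_frac = 0)
  env <- residue_environments(ens_sh)
  off <- suppressWarnings(
    referencing_offset(sim$shifts, sim$reference, env))
  expect_equal(off[["13C_aliphatic"]], 1.7, tolerance = 1e-9)
  expect_equal(off[["1H"]], 0, tolerance = 1e-9)
  expect_equal(off[["15N"]], 0, tolerance = 1e-9)
  expect_equal(off[["13C'"]], 0, tolerance = 1e-9)
})

test_that("classes below the atom-count threshold fall back to offset 0", {
  sim <- simulate_shifts(ens_sh, spec_sh, noise_frac = 0)
  env <- residue_environments(ens_sh)
  few <- sim$shifts[sim$shifts$nucleus_class != "15N" |
                      sim$shifts$resno <= 9L, ]
  few$value[few$nucleus_class == "15N"] <-
    few$value[few$nucleus_class == "15N"] + 3
  expect_warning(
    off <- referencing_offset(few, sim$reference, env),
    "referencing offset set to 0")
  expect_equal(off[["15N"]], 0)
})

test_that("Z-scores flag planted outliers under the strict |z| > 3 rule", {
  sim <- simulate_shifts(ens_sh, spec_sh, n_outliers = 4L,
                         outlier_sd = 6, noise_frac = 0)
  env <- residue_environments(ens_sh)
  off <- suppressWarnings(
    referencing_offset(sim$shifts, sim$reference, env))
  z <- shift_zscores(sim$shifts, sim$reference, env, off)
  flagged <- nmrvalid:::atom_key(z$chain[z$outlier], z$resno[z$outlier],
                                 z$atom[z$outlier])
  expect_setequal(flagged, sim$truth$outliers)
  expect_equal(sum(z$outlier), 4L)
  # non-outliers sit exactly at z = 0 for a noiseless draw
  expect_equal(max(abs(z$z[!z$outlier]), na.rm = TRUE), 0,
               tolerance = 1e-9)
  # z exactly 3 is NOT an outlier (strict inequality)
  sim3 <- simulate_shifts(ens_sh, spec_sh, n_outliers = 1L,
                          outlier_sd = 3, noise_frac = 0)
  z3 <- shift_zscores(sim3$shifts, sim3$reference, env,
                      suppressWarnings(referencing_offset(
                        sim3$shifts, sim3$reference, env)))
  expect_equal(sum(z3$outlier), 0L)
  expect_equal(max(abs(z3$z), na.rm = TRUE), 3, tolerance = 1e-9)
})

test_that("a constant added to one nucleus class leaves Z-scores invariant", {
  sim <- simulate_shifts(ens_sh, spec_sh, n_outliers = 3L,
                         noise_frac = 1)
  env <- residue_environments(ens_sh)
  run <- function(shifts) {
    off <- suppressWarnings(referencing_offset(shifts, sim$reference, env))
    shift_zscores(shifts, sim$reference, env, off)
  }
  z0 <- run(sim$shifts)
  shifted <- sim$shifts
  sel <- shifted$nucleus_class == "1H"
  shifted$value[sel] <- shifted$value[sel] + 2.5
  z1 <- run(shifted)
  expect_equal(z1$z, z0$z, tolerance = 1e-9)
  expect_identical(z1$outlier, z0$outlier)
})

test_that("the color ramp hits its anchors and is monotone toward red", {
  expect_equal(zscore_color(1), c(0L, 255L, 0L))
  expect_equal(zscore_color(2), c(0L, 255L, 0L))
  expect_equal(zscore_color(3.5), c(255L, 255L, 0L))
  expect_equal(zscore_color(5), c(255L, 0L, 0L))
  expect_equal(zscore_color(-6), c(255L, 0L, 0L))
  expect_equal(zscore_color(2.75), c(128L, 255L, 0L))
  zs <- seq(0, 6, by = 0.05)
  cols <- t(vapply(zs, zscore_color, integer(3L)))
  expect_true(all(diff(cols[, 1L]) >= 0))   # red channel never decreases
  expect_true(all(diff(cols[, 2L]) <= 0))   # green channel never increases
  # continuity: neighbouring z differ by at most a few counts
  expect_lt(max(abs(diff(cols[, 1L]))), 15L)
  expect_lt(max(abs(diff(cols[, 2L]))), 15L)
})

test_that("residues near a planted aromatic ring are marked", {
  arom <- aromatic_proximity(ens_sh)
  expect_true(any(arom$near_aromatic))
  near <- arom$resno[arom$near_aromatic]
  expect_true(all(abs(near - 10L) <= 4L))
  # no rings in a pure poly-ALA fixture
  plain <- make_ensemble(fixture_spec(10L, 1L, sigma = 0, seed = 1L))
  expect_false(any(aromatic_proximity(plain)$near_aromatic))
})
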