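spec_rdc <- fixture_spec(20L, 3L, sigma = 0.02, seed = 17L)
ens_rdc <- make_ensemble(spec_rdc)
S_true <- nmrvalid:::random_saupe(Da = 10, R = 0.3, seed = 101L)

test_that("RDC normalisation is identity for N-HN and invertible", {
  expect_equal(normalize_rdc(12.3, "N-HN"), 12.3, tolerance = 1e-12)
  tab <- default_bond_table()
  sc <- tab$scale[tab$type == "CA-HA"]
  expect_equal(normalize_rdc(5, "CA-HA") / sc, 5, tolerance = 1e-12)
  # independent hand calculation of the CA-HA factor
  gH <- 26.7522128; gC <- 6.728284; gN <- -2.7126
  expect_equal(sc, (gN * gH / 1.02^3) / (gC * gH / 1.09^3),
               tolerance = 1e-12)
  expect_error(normalize_rdc(1, "XX-YY"), "unknown RDC type")
})

test_that("noiseless synthetic RDCs recover the tensor exactly", {
  rdc <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0)
  fit <- fit_alignment_tensor(rdc, ens_rdc, 1L)
  expect_lt(max(abs(fit$matrix - S_true)), 1e-8)
  expect_lt(fit$q_value, 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(fit$Da, 10, tolerance = 1e-8)
  expect_equal(fit$R, 0.3, tolerance = 1e-8)
  expect_lt(abs(sum(diag(fit$matrix))), 1e-9)
  expect_gte(fit$R, 0); expect_lte(fit$R, 2 / 3 + 1e-12)
})

test_that("five constraints interpolate exactly and fewer are an error", {
  rdc <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0.5)
  five <- rdc[c(2L, 9L, 16L, 25L, 33L), ]
  fit <- fit_alignment_tensor(five, ens_rdc, 1L)
  expect_lt(fit$rmsd_hz, 1e-9)
  expect_error(fit_alignment_tensor(rdc[1:4, ], ens_rdc, 1L),
               "at least 5")
})

test_that("parallel bond vectors flag a degenerate design matrix", {
  # synthetic straight chain: all N-CA vectors parallel to x
  atoms <- do.call(rbind, lapply(1:6, function(r) data.frame(
    chain = "A", resno = r, atom = c("N", "CA"), resname = "ALA",
    element = c("N", "C"), x = c(0, 1.02) + 3 * r, y = 0, z = 0,
    stringsAsFactors = FALSE)))
  ens <- nmrvalid:::build_ensemble(list(atoms))
  rdc <- data.frame(id = paste0("r", 1:6),
                    atom1 = sprintf("A/%d/N", 1:6),
                    atom2 = sprintf("A/%d/CA", 1:6),
                    type = "N-HN", medium = "m1",
                    observed_hz = rnorm(6), stringsAsFactors = FALSE)
  expect_warning(fit <- fit_alignment_tensor(rdc, ens, 1L), "degenerate")
  expect_true(fit$degenerate)
})

test_that("goodness of fit matches hand arithmetic and edge conventions", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$rmsd_hz, 0); expect_equal(g$pearson_r, 1)
  expect_equal(g$q_value, 0)
  g <- goodness_of_fit(c(1, -2, 3), -c(1, -2, 3))
  expect_equal(g$pearson_r, -1)
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$rmsd_hz, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(g$q_value, sqrt(1 / 3) / sqrt(14 / 3), tolerance = 1e-12)
  g <- goodness_of_fit(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(g$pearson_r))
  expect_false(is.na(g$q_value))
  g <- goodness_of_fit(c(0, 0), c(1, -1))
  expect_true(is.na(g$q_value))
})

test_that("rotating the model rotates the axes but leaves Da, R, Q fixed", {
  rdc <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0.8)
  fit0 <- fit_alignment_tensor(rdc, ens_rdc, 1L)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3L,
              byrow = TRUE)
  ens2 <- ens_rdc
  for (m in seq_along(ens2$model_ids))
    ens2$coords[, , m] <- ens2$coords[, , m] %*% t(R)
  fit1 <- fit_alignment_tensor(rdc, ens2, 1L)
  expect_equal(fit1$Da, fit0$Da, tolerance = 1e-9)
  expect_equal(fit1$R, fit0$R, tolerance = 1e-9)
  expect_equal(fit1$q_value, fit0$q_value, tolerance = 1e-9)
  expect_equal(fit1$eigenvalues, fit0$eigenvalues, tolerance = 1e-9)
  for (k in 1:3) {
    v <- R %*% fit0$axes[, k]
    # eigenvectors are sign-normalised; compare up to sign
    expect_lt(min(max(abs(fit1$axes[, k] - v)),
                  max(abs(fit1$axes[, k] + v))), 1e-6)
  }
})

test_that("adding a zero-residual constraint never worsens Q or rmsd", {
  rdc <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 1)
  fit <- fit_alignment_tensor(rdc, ens_rdc, 1L)
  # append one coupling computed exactly from the fitted tensor
  u <- nmrvalid:::rdc_unit_vectors(rdc[1L, ], ens_rdc, 1L)
  extra <- rdc[1L, ]
  extra$id <- "perfect"
  s <- coef(fit)
  extra$observed_hz <- as.numeric(nmrvalid:::rdc_design(u) %*% s)
  fit2 <- fit_alignment_tensor(rbind(rdc, extra), ens_rdc, 1L)
  expect_lte(fit2$rmsd_hz, fit$rmsd_hz + 1e-12)
  expect_lte(fit2$q_value, fit$q_value + 1e-12)
})

test_that("ensemble statistics equal brute-force recomputation", {
  rdc <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0.5)
  fits <- lapply(1:3, function(m)
    fit_alignment_tensor(rdc, ens_rdc, m))
  st <- ensemble_rdc_stats(fits)
  calc <- sapply(fits, `[[`, "calculated")
  for (i in c(1L, 10L, nrow(rdc))) {
    expect_equal(st$per_constraint$mean[i], mean(calc[i, ]))
    expect_equal(st$per_constraint$sd[i], sd(calc[i, ]))
    expect_equal(st$per_constraint$min[i], min(calc[i, ]))
    expect_equal(st$per_constraint$max[i], max(calc[i, ]))
  }
  one <- ensemble_rdc_stats(fits[1L])
  expect_true(all(one$per_constraint$sd == 0))
  expect_equal(one$per_constraint$mean, one$per_constraint$min)
})

test_that("the deposition unit convention is detected from the better fit", {
  rdc_raw <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0,
                           prescaled = FALSE)
  expect_equal(detect_rdc_unit_convention(rdc_raw, ens_rdc, 1L)$convention,
               "raw")
  rdc_pre <- simulate_rdcs(ens_rdc, S_true, spec_rdc, noise_hz = 0,
                           prescaled = TRUE)
  expect_equal(detect_rdc_unit_convention(rdc_pre, ens_rdc, 1L)$convention,
               "prescaled")
  # single-type medium falls back to raw
  single <- rdc_raw[rdc_raw$type == "N-HN", ]
  expect_equal(detect_rdc_unit_convention(single, ens_rdc, 1L)$convention,
               "raw")
})

test_that("noise degrades Q monotonically on average", {
  qs <- vapply(c(0, 0.5, 2), function(noise) {
    sp <- fixture_spec(20L, 1L, sigma = 0, seed = 23L)
    rdc <- simulate_rdcs(ens_rdc, S_true, sp, noise_hz = noise)
    fit_alignment_tensor(rdc, ens_rdc, 1L)$q_value
  }, 0)
  expect_true(all(diff(qs) > 0))
})
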