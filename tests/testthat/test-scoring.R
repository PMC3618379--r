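test_that("ROG triggers follow the rule table", {
  none <- residue_rog(list(dist = list(), dih = list(), z = numeric(0)))
  expect_equal(none$rog, "green")
  expect_length(none$rationale, 0L)
  sev <- residue_rog(list(z = 6))
  expect_equal(sev$rog, "red")
  expect_equal(sev$rationale, "shift_outlier_severe")
  mid <- residue_rog(list(z = 4))
  expect_equal(mid$rog, "orange")
  expect_equal(mid$rationale, "shift_outlier")
  # 0.4 A violation in all models, nothing else -> orange
  expect_equal(residue_rog(list(dist = list(rep(0.4, 10L))))$rog, "orange")
  expect_equal(residue_rog(list(dist = list(rep(0.6, 10L))))$rog, "red")
  # violated in fewer than half the models: no trigger
  expect_equal(residue_rog(list(dist = list(c(0.6, rep(0, 9L)))))$rog,
               "green")
  # dihedral thresholds in degrees
  expect_equal(residue_rog(list(dih = list(rep(15, 4L))))$rog, "orange")
  expect_equal(residue_rog(list(dih = list(rep(25, 4L))))$rog, "red")
})

test_that("worsening evidence never moves ROG toward green", {
  rank <- c(green = 1L, orange = 2L, red = 3L)
  set.seed(5)
  for (i in 1:30) {
    mags <- runif(6L, 0, 0.7)
    z <- runif(1L, 0, 6)
    base <- residue_rog(list(dist = list(mags), z = z))
    worse <- residue_rog(list(dist = list(mags + runif(1L, 0, 0.3)),
                              z = z + runif(1L, 0, 2)))
    expect_gte(rank[[worse$rog]], rank[[base$rog]])
  }
})

test_that("a coordinates-only run scores every residue green", {
  ens <- make_ensemble(fixture_spec(10L, 4L, sigma = 0.05, seed = 3L))
  v <- validate_ensemble(ens)
  expect_s3_class(v, "nmr_validation")
  expect_true(all(v$residues$rog == "green"))
  expect_equal(length(v$report$residues), 10L)
  expect_equal(v$report$rog$summary$n_green, 10L)
  expect_length(v$report$distance_constraints, 0L)
})

test_that("report summary counts equal a brute-force recount", {
  dir <- withr::local_tempdir()
  files <- simulate_fixture_set(dir, seed = 19L, preset = "violations")
  v <- validate_ensemble(files$coordinates, distance = files$distance,
                         dihedral = files$dihedral)
  r <- v$report
  expect_equal(r$rog$summary$n_red + r$rog$summary$n_orange +
                 r$rog$summary$n_green, length(r$residues))
  expect_equal(r$rog$summary$n_red,
               sum(vapply(r$residues, function(x) x$rog == "red", TRUE)))
  # every residue appears exactly once
  tags <- vapply(r$residues, function(x) paste(x$chain, x$resno), "")
  expect_false(anyDuplicated(tags) > 0L)
  expect_equal(length(r$residues), r$ensemble$n_residues)
  # distance section matches the input table and class recount
  dist <- read_constraint_table(files$distance, "distance")
  expect_equal(length(r$distance_constraints), nrow(dist))
  ens <- read_ensemble(files$coordinates)
  recount <- table(vapply(seq_len(nrow(dist)), function(i)
    classify_distance_constraint(dist[i, ], ens), ""))
  got <- table(vapply(r$distance_constraints, `[[`, "", "range_class"))
  expect_equal(as.list(got), as.list(recount))
})

test_that("reports round-trip through JSON and satisfy the shipped schema", {
  dir <- withr::local_tempdir()
  files <- simulate_fixture_set(dir, seed = 7L, preset = "shifts")
  v <- validate_ensemble(files$coordinates, shifts = files$shifts,
                         shift_reference = files$shift_reference)
  out <- file.path(dir, "report.json")
  write_report(v, out)
  back <- read_report(out)
  expect_invisible(check_report_schema(back))
  expect_true(file.exists(report_schema_path()))
  # strict JSON: jsonlite round trip implies no NaN/Inf literals
  expect_silent(jsonlite::fromJSON(out))
  expect_equal(back$ensemble$n_models, 10L)
  expect_equal(length(back$residues), 20L)
  # re-serialising the parsed report reproduces the file byte for byte
  out2 <- file.path(dir, "report2.json")
  write_report(v, out2)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("schema violations are reported with their location", {
  ens <- make_ensemble(fixture_spec(6L, 2L, sigma = 0, seed = 1L))
  v <- validate_ensemble(ens)
  bad <- v$report
  bad$residues[[2L]]$rog <- "purple"
  probs <- check_report_schema(bad, error = FALSE)
  expect_true(any(grepl("residues\\[2\\]", probs)))
  bad$ensemble <- NULL
  expect_error(check_report_schema(bad), "ensemble")
})

test_that("per-model detail appears only behind the per-model flag", {
  dir <- withr::local_tempdir()
  files <- simulate_fixture_set(dir, seed = 2L, preset = "violations")
  v0 <- validate_ensemble(files$coordinates, distance = files$distance)
  v1 <- validate_ensemble(files$coordinates, distance = files$distance,
                          per_model = TRUE)
  expect_null(v0$report$distance_constraints[[1L]]$models)
  expect_length(v1$report$distance_constraints[[1L]]$models, 10L)
})

test_that("the CLI validates fixtures and reports input errors with status 2", {
  dir <- withr::local_tempdir()
  simulate_fixture_set(dir, seed = 4L, preset = "violations")
  out <- file.path(dir, "report.json")
  status <- suppressMessages(nmr_validate_cli(c(
    "--coordinates", file.path(dir, "ensemble.pdb"),
    "--distance-restraints", file.path(dir, "distance.tsv"),
    "--dihedral-restraints", file.path(dir, "dihedral.tsv"),
    "--out", out, "--log-level", "error")))
  expect_equal(status, 0L)
  expect_true(file.exists(out))
  expect_invisible(check_report_schema(read_report(out)))
  expect_equal(suppressMessages(nmr_validate_cli(
    c("--coordinates", "missing.pdb", "--out", out))), 2L)
  expect_equal(suppressMessages(nmr_validate_cli(
    c("--out", out))), 2L)
  expect_equal(suppressMessages(nmrvalid_main(c("frobnicate"))), 2L)
  # simulate subcommand writes a loadable fixture set
  dir2 <- file.path(dir, "sim")
  expect_equal(suppressMessages(nmrvalid_main(
    c("simulate", "--out-dir", dir2, "--seed", "9", "--preset",
      "basic"))), 0L)
  expect_true(file.exists(file.path(dir2, "ensemble.pdb")))
})
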