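test_that("ideal-helix dihedrals are recovered to high precision", {
  ens <- make_ensemble(fixture_spec(10L, 2L, sigma = 0, seed = 1L))
  dh <- compute_backbone_dihedrals(ens)
  interior <- dh$index$resno %in% 3:8
  phi <- dh$values[interior & dh$index$angle == "phi", ]
  psi <- dh$values[interior & dh$index$angle == "psi", ]
  expect_equal(as.numeric(phi), rep(-57, length(phi)), tolerance = 1e-6)
  expect_equal(as.numeric(psi), rep(-47, length(psi)), tolerance = 1e-6)
})

test_that("terminal residues omit the angle lacking a flanking atom", {
  ens <- make_ensemble(fixture_spec(6L, 1L, sigma = 0, seed = 1L))
  dh <- compute_backbone_dihedrals(ens)
  first <- dh$index[dh$index$resno == 1L, ]
  last <- dh$index[dh$index$resno == 6L, ]
  expect_false("phi" %in% first$angle)
  expect_true("psi" %in% first$angle)
  expect_false("psi" %in% last$angle)
  expect_true("phi" %in% last$angle)
})

test_that("collinear backbone atoms give an undefined dihedral with warning", {
  expect_warning(
    v <- dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "degenerate")
  expect_true(is.na(v))
})

test_that("nucleic backbone torsions are computed on hand-built coordinates", {
  # two-nucleotide chain: atoms placed so each torsion is well defined
  atoms <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  set.seed(42)
  base <- matrix(rnorm(18, sd = 0.2), 6L, 3L) +
    cbind(seq(0, 7.5, length.out = 6L), 0, 0)
  mk <- function(resno, offset) data.frame(
    chain = "B", resno = resno, atom = atoms, resname = "A",
    element = substr(atoms, 1L, 1L),
    x = base[, 1L] + offset, y = base[, 2L], z = base[, 3L],
    stringsAsFactors = FALSE)
  ens <- nmrvalid:::build_ensemble(list(rbind(mk(1L, 0), mk(2L, 9))))
  expect_equal(ens$polymer_type[["B"]], "nucleic")
  dh <- compute_backbone_dihedrals(ens)
  r1 <- dh$index[dh$index$resno == 1L, "angle"]
  # residue 1 has no alpha (needs O3' of residue 0) but has beta..zeta
  expect_false("alpha" %in% r1)
  expect_setequal(r1, c("beta", "gamma", "delta", "epsilon", "zeta"))
  expect_true(all(is.finite(dh$values[dh$index$resno == 1L, ])))
  # epsilon(1) must equal the direct 4-point dihedral C4'-C3'-O3'-P(2)
  keys <- c("B/1/C4'", "B/1/C3'", "B/1/O3'", "B/2/P")
  idx <- match(keys, ens$atoms$key)
  direct <- dihedral_angle(ens$coords[idx[1L], , 1L],
                           ens$coords[idx[2L], , 1L],
                           ens$coords[idx[3L], , 1L],
                           ens$coords[idx[4L], , 1L])
  eps <- dh$values[dh$index$resno == 1L & dh$index$angle == "epsilon", 1L]
  expect_equal(eps, direct, tolerance = 1e-9)
})

test_that("S^2 anchors: identical models, 4-fold symmetry, two-model closed form", {
  expect_equal(angular_order_parameter(
    manual_dihedrals(rep(42, 5L)), "A", 1L), 1, tolerance = 1e-12)
  expect_equal(angular_order_parameter(
    manual_dihedrals(c(0, 90, 180, -90)), "A", 1L), 0, tolerance = 1e-12)
  expect_equal(angular_order_parameter(
    manual_dihedrals(c(-10, 10)), "A", 1L),
    cos(10 * pi / 180)^2, tolerance = 1e-12)
})

test_that("S^2 averages per-angle order parameters over available angle types", {
  dh <- structure(list(
    index = data.frame(chain = "A", resno = 1L,
                       angle = c("phi", "psi"),
                       stringsAsFactors = FALSE),
    values = rbind(c(-10, 10), c(NA, 20)),
    n_models = 2L), class = "nmr_dihedrals")
  # psi is incomplete -> only phi contributes
  expect_equal(angular_order_parameter(dh, "A", 1L), cos(10 * pi / 180)^2)
  dh$values[2L, ] <- c(-90, 90)
  expect_equal(angular_order_parameter(dh, "A", 1L),
               (cos(10 * pi / 180)^2 + cos(90 * pi / 180)^2) / 2)
})

test_that("S^2 properties: range, rotation invariance, copy invariance", {
  set.seed(7)
  for (rep in 1:20) {
    v <- runif(6L, -180, 180)
    s2 <- angular_order_parameter(manual_dihedrals(v), "A", 1L)
    expect_gte(s2, 0); expect_lte(s2, 1)
    # duplicating a model never changes S^2 if the mean resultant is kept:
    # appending an exact copy of the whole set leaves the means unchanged
    expect_equal(angular_order_parameter(manual_dihedrals(c(v, v)), "A", 1L),
                 s2, tolerance = 1e-12)
  }
  # global rigid rotation of all models leaves internal dihedrals intact
  ens <- make_ensemble(fixture_spec(8L, 4L, sigma = 0.1, seed = 5L))
  s2_before <- order_parameters(compute_backbone_dihedrals(ens))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L,
              byrow = TRUE)
  for (m in seq_along(ens$model_ids))
    ens$coords[, , m] <- ens$coords[, , m] %*% t(R)
  s2_after <- order_parameters(compute_backbone_dihedrals(ens))
  expect_equal(s2_after$s2, s2_before$s2, tolerance = 1e-9)
})

test_that("single-conformer ensembles give S^2 = 1 with a warning", {
  expect_warning(s2 <- angular_order_parameter(
    manual_dihedrals(123), "A", 1L), "single")
  expect_equal(s2, 1)
})

test_that("Kabsch superposition handles identity, rigid motion and noise", {
  set.seed(11)
  a <- matrix(rnorm(30), 10L, 3L)
  fit <- kabsch_superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # rigid motion: rotate 90 deg about z and translate
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, byrow = TRUE)
  b <- sweep(a %*% t(R90), 2L, c(3, -2, 5), `+`)
  fit <- kabsch_superpose(a, b)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # noisy case: matches brute-force minimisation over Euler angles
  b <- sweep(a %*% t(R90), 2L, c(1, 2, 3), `+`) +
    matrix(rnorm(30, sd = 0.1), 10L, 3L)
  fit <- kabsch_superpose(a, b)
  euler <- function(p) {
    cz <- cos(p[1L]); sz <- sin(p[1L]); cy <- cos(p[2L]); sy <- sin(p[2L])
    cx <- cos(p[3L]); sx <- sin(p[3L])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
  }
  obj <- function(p) {
    Bc <- sweep(b, 2L, colMeans(b)); Ac <- sweep(a, 2L, colMeans(a))
    sqrt(mean(rowSums((Bc %*% t(euler(p)) - Ac)^2)))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(1.5, 0.5, -0.5), c(-1.5, 1, 2)))
    best <- min(best, stats::optim(start, obj,
                                   method = "BFGS")$value)
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected for superposition", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|rank")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2L, 3L),
                                matrix(rnorm(6), 2L, 3L)), "3 points")
})

test_that("the RMSD matrix is symmetric, zero-diagonal and matches brute force", {
  ens <- make_ensemble(fixture_spec(8L, 3L, sigma = 0.3, seed = 9L))
  m <- rmsd_matrix(ens)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 3L))
  sel <- c("N", "CA", "C", "O")
  keep <- ens$atoms$atom %in% sel
  for (i in 1:2) for (j in (i + 1L):3L) {
    expect_equal(m[i, j],
                 kabsch_superpose(ens$coords[keep, , i],
                                  ens$coords[keep, , j])$rmsd,
                 tolerance = 1e-12)
  }
})

test_that("identical models collapse to one cluster with model 1 representative", {
  ens <- make_ensemble(fixture_spec(8L, 5L, sigma = 0, seed = 1L))
  cl <- cluster_and_represent(ens)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$overall_representative, 1L)
})

test_that("a planted conformational split yields two clusters with medoids", {
  ens <- make_ensemble(fixture_spec(20L, 20L, sigma = 0.05, seed = 13L,
                                    hinge_deg = 60))
  cl <- cluster_and_represent(ens)
  expect_length(cl$clusters, 2L)
  expect_setequal(lengths(cl$clusters), c(10L, 10L))
  for (k in seq_along(cl$clusters)) {
    members <- cl$clusters[[k]]
    ssum <- rowSums(cl$rmsd[members, members, drop = FALSE])
    expect_equal(cl$representatives[k], members[which.min(ssum)])
    expect_true(cl$representatives[k] %in% members)
  }
  # clustering is invariant to model relabeling (permutation of models)
  perm <- c(20:1)
  ens2 <- ens
  ens2$coords <- ens$coords[, , perm]
  cl2 <- cluster_and_represent(ens2)
  sizes1 <- sort(lengths(cl$clusters))
  sizes2 <- sort(lengths(cl2$clusters))
  expect_equal(sizes1, sizes2)
})
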