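# Deterministic synthetic fixtures: toy poly-alanine ensembles built
# from ideal helix internal coordinates, with matching restraint, RDC
# and chemical-shift tables whose ground truth (planted violations,
# offsets, outliers, alignment tensor, cluster split) is known exactly.
# Everything is reproducible from (spec, seed); no downloads.

# Ideal internal coordinates (Angstrom / degrees) for backbone building.
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521, b_n_h = 1.01, b_ca_ha = 1.09,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.1, a_c_n_h = 119.0,
  a_n_ca_ha = 109.0, omega = 180
)

#' Specification of a synthetic fixture
#'
#' @param n_residues chain length (>= 5).
#' @param n_models ensemble size.
#' @param sigma per-atom Gaussian coordinate jitter (Angstrom).
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @param phi,psi backbone dihedrals of the ideal conformation (degrees;
#'   defaults are the alpha-helix values -57/-47).
#' @param hinge_deg if nonzero, the C-terminal half of the chain is
#'   rotated by this angle about the hinge CA in the second half of the
#'   models, planting a two-conformation split.
#' @param aromatic_at residue indices built as PHE instead of ALA (ring
#'   planted for aromatic-proximity marking).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 20L, n_models = 10L, sigma = 0.05,
                         seed = 1L, phi = -57, psi = -47, hinge_deg = 0,
                         aromatic_at = integer(0)) {
  stopifnot(n_residues >= 5L, n_models >= 1L, sigma >= 0)
  structure(list(n_residues = as.integer(n_residues),
                 n_models = as.integer(n_models), sigma = sigma,
                 seed = as.integer(seed), phi = phi, psi = psi,
                 hinge_deg = hinge_deg,
                 aromatic_at = as.integer(aromatic_at)),
            class = "fixture_spec")
}

# Single-conformer poly-ALA (optionally PHE) backbone as an atom table.
build_ideal_chain <- function(n_res, phi = -57, psi = -47,
                              aromatic_at = integer(0)) {
  g <- BB_GEOM
  rows <- list()
  add <- function(resno, resname, atom, el, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = "A", resno = resno, atom = atom, resname = resname,
      element = el, x = xyz[1L], y = xyz[2L], z = xyz[3L],
      stringsAsFactors = FALSE)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n_res)) {
    resname <- if (i %in% aromatic_at) "PHE" else "ALA"
    if (i > 1L) {
      N <- place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi)
      CA <- place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, phi)
    }
    add(i, resname, "N", "N", N)
    add(i, resname, "CA", "C", CA)
    add(i, resname, "C", "C", C)
    # carbonyl O anti to the next N (psi + 180 about CA-C)
    add(i, resname, "O", "O",
        place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180))
    CB <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, 122.6)
    add(i, resname, "CB", "C", CB)
    add(i, resname, "HA", "H",
        place_atom(C, N, CA, g$b_ca_ha, g$a_n_ca_ha, -118))
    if (i > 1L) {
      add(i, resname, "H", "H",
          place_atom(prevCA, prevC, N, g$b_n_h, g$a_c_n_h, 180))
    }
    if (resname == "PHE") {
      CG <- place_atom(N, CA, CB, 1.51, 114, 180)
      CD1 <- place_atom(CA, CB, CG, 1.39, 120, 90)
      CD2 <- place_atom(CA, CB, CG, 1.39, 120, -90)
      CE1 <- place_atom(CB, CG, CD1, 1.39, 120, 180)
      CE2 <- place_atom(CB, CG, CD2, 1.39, 120, 180)
      CZ <- place_atom(CG, CD1, CE1, 1.39, 120, 0)
      for (nm in c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
        add(i, resname, nm, "C", get(nm))
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, rows)
}

# Rotate the tail (residues > hinge) about the z axis through the hinge
# CA by `deg`; a crude but well-defined hinge motion.
apply_hinge <- function(atoms, hinge_res, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3L, 3L, byrow = TRUE)
  pivot_idx <- which(atoms$resno == hinge_res & atoms$atom == "CA")
  pivot <- as.numeric(atoms[pivot_idx, c("x", "y", "z")])
  tail <- atoms$resno > hinge_res
  xyz <- as.matrix(atoms[tail, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2L, pivot) %*% t(R), 2L, pivot, `+`)
  atoms[tail, c("x", "y", "z")] <- xyz
  atoms
}

#' Build a synthetic ensemble
#'
#' Poly-alanine chain from ideal helix internal coordinates, replicated
#' into `n_models` models with Gaussian coordinate jitter `sigma`; an
#' optional hinge rotation of the C-terminal half in the second half of
#' the models plants a two-conformation split.
#'
#' @param spec a [fixture_spec()].
#' @return an `nmr_ensemble`.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  base <- build_ideal_chain(spec$n_residues, spec$phi, spec$psi,
                            spec$aromatic_at)
  hinge_res <- spec$n_residues %/% 2L
  set.seed(spec$seed)
  models <- lapply(seq_len(spec$n_models), function(m) {
    at <- base
    if (spec$hinge_deg != 0 && m > spec$n_models %/% 2L)
      at <- apply_hinge(at, hinge_res, spec$hinge_deg)
    n <- nrow(at)
    at$x <- at$x + rnorm(n, sd = spec$sigma)
    at$y <- at$y + rnorm(n, sd = spec$sigma)
    at$z <- at$z + rnorm(n, sd = spec$sigma)
    at
  })
  build_ensemble(models, source = sprintf("fixture(seed=%d)", spec$seed))
}

#' Derive restraints from a reference model, with planted violations
#'
#' Distance restraints are generated for every heavy-atom pair closer
#' than 5 Angstrom in the reference model, with bounds
#' `[d - 0.5, d + 0.5]`; dihedral restraints bracket the true phi/psi by
#' +/-20 degrees. Planted distance violations tighten the upper bound to
#' `d - magnitude`; planted dihedral violations shift the allowed arc to
#' `[true + magnitude, true + magnitude + 40]`, so the nearer endpoint
#' sits `magnitude` degrees from the true angle. A few ambiguous
#' two-member restraints are created by merging neighbouring pairs.
#'
#' @param ensemble an `nmr_ensemble` from [make_ensemble()].
#' @param spec the generating [fixture_spec()] (its seed namespaces the
#'   random choices).
#' @param model reference model index (default 1).
#' @param planted_distance,planted_dihedral numbers of planted
#'   violations.
#' @param violation_A,violation_deg planted violation magnitudes.
#' @param n_ambiguous number of merged two-member restraints.
#' @return list `distance` and `dihedral` data.frames (the
#'   [read_constraint_table()] shapes) and `truth` (planted ids and
#'   magnitudes).
#' @export
derive_restraints <- function(ensemble, spec, model = 1L,
                              planted_distance = 0L, planted_dihedral = 0L,
                              violation_A = 1.0, violation_deg = 20,
                              n_ambiguous = 3L) {
  set.seed(spec$seed + 1000L)
  heavy <- which(ensemble$atoms$element != "H")
  xyz <- ensemble$coords[heavy, , model]
  keys <- ensemble$atoms$key[heavy]
  d <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(d) & d < 5, arr.ind = TRUE)
  dist_df <- data.frame(
    id = sprintf("d%04d", seq_len(nrow(pair))),
    lower = pmax(0, d[pair] - 0.5), upper = d[pair] + 0.5,
    stringsAsFactors = FALSE)
  dist_df$members <- lapply(seq_len(nrow(pair)), function(i)
    matrix(c(keys[pair[i, 1L]], keys[pair[i, 2L]]), 1L, 2L))
  truth <- list(distance_violations = list(),
                dihedral_violations = list())
  # merge a few neighbouring pairs into ambiguous restraints
  if (n_ambiguous > 0L && nrow(dist_df) > 2L * n_ambiguous + 2L) {
    merge_at <- sort(sample(seq_len(nrow(dist_df) - 1L), n_ambiguous))
    merge_at <- merge_at[c(TRUE, diff(merge_at) > 1L)]
    for (k in rev(merge_at)) {
      m <- rbind(dist_df$members[[k]], dist_df$members[[k + 1L]])
      d_eff <- effective_distance(d[pair[c(k, k + 1L), , drop = FALSE]])
      dist_df$members[[k]] <- m
      dist_df$lower[k] <- max(0, d_eff - 0.5)
      dist_df$upper[k] <- d_eff + 0.5
      dist_df <- dist_df[-(k + 1L), ]
    }
    rownames(dist_df) <- NULL
  }
  # plant distance violations on well-separated single-member restraints
  if (planted_distance > 0L) {
    single <- which(vapply(dist_df$members, nrow, 1L) == 1L)
    sep <- vapply(single, function(i) {
      m <- dist_df$members[[i]][1L, ]
      abs(parse_atom_key(m[1L])$resno - parse_atom_key(m[2L])$resno)
    }, 1L)
    dtrue <- (dist_df$lower + dist_df$upper)[single] / 2
    cand <- single[sep >= 3L & dtrue > violation_A + 1.0]
    pick <- sample(cand, planted_distance)
    for (i in pick) {
      dtrue_i <- (dist_df$lower[i] + dist_df$upper[i]) / 2
      dist_df$upper[i] <- dtrue_i - violation_A
      dist_df$lower[i] <- max(0, dist_df$upper[i] - 1.0)
      truth$distance_violations[[length(truth$distance_violations) + 1L]] <-
        list(id = dist_df$id[i], magnitude = violation_A)
    }
  }
  # dihedral restraints bracketing the true angles
  dih <- suppressWarnings(compute_backbone_dihedrals(ensemble))
  ok <- !is.na(dih$values[, model])
  dih_df <- data.frame(
    id = sprintf("t%04d", seq_len(sum(ok))),
    chain = dih$index$chain[ok], resno = dih$index$resno[ok],
    angle = dih$index$angle[ok], stringsAsFactors = FALSE)
  wrap180 <- function(a) {
    a <- (a + 180) %% 360 - 180
    ifelse(a == -180, 180, a)
  }
  true_ang <- dih$values[ok, model]
  dih_df$lower <- wrap180(true_ang - 20)
  dih_df$upper <- wrap180(true_ang + 20)
  if (planted_dihedral > 0L) {
    pick <- sample(seq_len(nrow(dih_df)), planted_dihedral)
    for (i in pick) {
      dih_df$lower[i] <- wrap180(true_ang[i] + violation_deg)
      dih_df$upper[i] <- wrap180(true_ang[i] + violation_deg + 40)
      truth$dihedral_violations[[length(truth$dihedral_violations) + 1L]] <-
        list(id = dih_df$id[i], magnitude = violation_deg)
    }
  }
  list(distance = dist_df, dihedral = dih_df, truth = truth)
}

# Alignment tensor with magnitude Da (Hz), rhombicity R and a seeded
# random orientation: eigenvalues (l1, l2, l3) with l3 = 2 Da,
# l1 - l2 = 1.5 R l3, l1 + l2 = -l3.
random_saupe <- function(Da = 10, R = 0.3, seed = 1L) {
  set.seed(seed)
  l3 <- 2 * Da
  l1 <- (-l3 + 1.5 * R * l3) / 2
  l2 <- (-l3 - 1.5 * R * l3) / 2
  M <- matrix(rnorm(9), 3L)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q %*% diag(c(l1, l2, l3)) %*% t(Q)
}

#' Simulate RDCs from a known alignment tensor
#'
#' Observed couplings are generated from the model's unit internuclear
#' vectors and a given traceless symmetric tensor (N-HN-normalised Hz),
#' optionally with Gaussian noise, and written either raw (divided by
#' the per-type normalisation factor) or prescaled.
#'
#' @param ensemble an `nmr_ensemble` carrying H/HA atoms.
#' @param tensor 3x3 traceless symmetric matrix (N-HN-normalised Hz).
#' @param spec the generating [fixture_spec()].
#' @param model model index providing the geometry (default 1).
#' @param types RDC types to emit (default N-HN and CA-HA).
#' @param noise_hz Gaussian noise sd added on the normalised scale.
#' @param prescaled write values on the N-HN scale (`TRUE`) or as raw
#'   couplings (`FALSE`).
#' @param medium medium id label.
#' @param bond_table as from [default_bond_table()].
#' @return rdc data.frame in the [read_constraint_table()] shape.
#' @export
simulate_rdcs <- function(ensemble, tensor, spec, model = 1L,
                          types = c("N-HN", "CA-HA"), noise_hz = 0,
                          prescaled = FALSE, medium = "m1",
                          bond_table = default_bond_table()) {
  stopifnot(max(abs(tensor - t(tensor))) < 1e-9,
            abs(sum(diag(tensor))) < 1e-6)
  set.seed(spec$seed + 2000L)
  pairs <- list(`N-HN` = c("N", "H"), `CA-HA` = c("CA", "HA"))
  rows <- list()
  for (ty in types) {
    at <- pairs[[ty]]
    if (is.null(at)) stop("no fixture geometry for RDC type ", ty)
    for (i in seq_len(nrow(ensemble$sequence))) {
      ch <- ensemble$sequence$chain[i]; rn <- ensemble$sequence$resno[i]
      k1 <- atom_key(ch, rn, at[1L]); k2 <- atom_key(ch, rn, at[2L])
      if (!(k1 %in% ensemble$atoms$key) || !(k2 %in% ensemble$atoms$key))
        next
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("r_%s_%d", gsub("[^A-Za-z]", "", ty), rn),
        atom1 = k1, atom2 = k2, type = ty, medium = medium,
        observed_hz = NA_real_, stringsAsFactors = FALSE)
    }
  }
  rdc <- do.call(rbind, rows)
  u <- rdc_unit_vectors(rdc, ensemble, model)
  d_norm <- as.numeric(rdc_design(u) %*%
                         c(tensor[1, 1], tensor[2, 2], tensor[1, 2],
                           tensor[1, 3], tensor[2, 3]))
  d_norm <- d_norm + rnorm(length(d_norm), sd = noise_hz)
  scale <- bond_table$scale[match(rdc$type, bond_table$type)]
  rdc$observed_hz <- if (prescaled) d_norm else d_norm / scale
  rdc
}

#' Simulate chemical shifts and a matching reference table
#'
#' Builds a reference table covering the fixture's (residue, atom,
#' secondary structure, accessibility) combinations, then draws observed
#' shifts at `mean(environment) + offset(class) + noise_frac * sd * e`,
#' `e ~ N(0,1)`, with outliers planted at `outlier_sd` reference
#' standard deviations above the mean.
#'
#' @param ensemble an `nmr_ensemble`.
#' @param spec the generating [fixture_spec()].
#' @param offsets named per-class referencing offsets to plant (ppm).
#' @param n_outliers number of planted outliers.
#' @param outlier_sd planted outlier size in reference sds (default 6).
#' @param noise_frac noise sd as a fraction of the reference sd
#'   (0 = exact draws).
#' @param config validation configuration (environment computation).
#' @return list `shifts`, `reference` (data.frames) and `truth`
#'   (planted offsets and outlier atom keys).
#' @export
simulate_shifts <- function(ensemble, spec,
                            offsets = c(`13C_aliphatic` = 0),
                            n_outliers = 0L, outlier_sd = 6,
                            noise_frac = 1, config = nmr_config()) {
  set.seed(spec$seed + 3000L)
  env <- residue_environments(ensemble, model = 1L, config = config)
  base_mean <- c(N = 121.5, H = 8.25, CA = 52.8, HA = 4.25, CB = 19.0,
                 C = 177.7)
  base_sd <- c(N = 2.5, H = 0.45, CA = 1.1, HA = 0.35, CB = 1.0, C = 1.2)
  ss_adj <- c(H = -0.8, E = 0.9, C = 0)
  acc_adj <- c(buried = -0.3, exposed = 0.3)
  resnames <- unique(ensemble$sequence$resname)
  ref <- expand.grid(resname = resnames, atom = names(base_mean),
                     ss = c("H", "E", "C"),
                     acc_bin = c("buried", "exposed"),
                     stringsAsFactors = FALSE)
  ref$mean_ppm <- base_mean[ref$atom] + ss_adj[ref$ss] + acc_adj[ref$acc_bin]
  ref$sd_ppm <- base_sd[ref$atom]
  ref$n <- 250L
  ref$key <- paste(ref$resname, ref$atom, ref$ss, ref$acc_bin, sep = "|")
  class(ref) <- c("shift_reference", "data.frame")
  # observed shifts for every reference-covered atom actually present
  rows <- list()
  for (i in seq_len(nrow(env))) {
    for (at in names(base_mean)) {
      key <- atom_key(env$chain[i], env$resno[i], at)
      if (!(key %in% ensemble$atoms$key)) next
      cl <- nucleus_class(env$resname[i], at)
      mu <- base_mean[[at]] + ss_adj[[env$ss[i]]] + acc_adj[[env$acc_bin[i]]]
      off <- if (cl %in% names(offsets)) offsets[[cl]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chain = env$chain[i], resno = env$resno[i],
        resname = env$resname[i], atom = at, nucleus_class = cl,
        value = mu + off + noise_frac * base_sd[[at]] * rnorm(1L),
        stringsAsFactors = FALSE)
    }
  }
  shifts <- do.call(rbind, rows)
  outlier_keys <- character(0)
  if (n_outliers > 0L) {
    pick <- sample(seq_len(nrow(shifts)), n_outliers)
    for (i in pick) {
      mu <- base_mean[[shifts$atom[i]]] +
        ss_adj[[env$ss[match(paste(shifts$chain[i], shifts$resno[i]),
                             paste(env$chain, env$resno))]]] +
        acc_adj[[env$acc_bin[match(paste(shifts$chain[i], shifts$resno[i]),
                                   paste(env$chain, env$resno))]]]
      cl <- shifts$nucleus_class[i]
      off <- if (cl %in% names(offsets)) offsets[[cl]] else 0
      shifts$value[i] <- mu + off + outlier_sd * base_sd[[shifts$atom[i]]]
      outlier_keys <- c(outlier_keys,
                        atom_key(shifts$chain[i], shifts$resno[i],
                                 shifts$atom[i]))
    }
  }
  list(shifts = shifts, reference = ref,
       truth = list(offsets = as.list(offsets),
                    outliers = outlier_keys))
}

# ---------------------------------------------------------------------------
# TSV writers matching the read_constraint_table dialects.

write_tsv <- function(header, rows, path, comment = NULL) {
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             paste(header, collapse = "\t"), rows)
  writeLines(lines, path)
  invisible(path)
}

#' Write restraint/shift tables in the package TSV dialects
#'
#' @param x a data.frame in the corresponding [read_constraint_table()]
#'   (or [read_shift_reference()]) shape.
#' @param path output file.
#' @param kind one of "distance", "dihedral", "rdc", "shift",
#'   "shift_reference".
#' @param comment optional comment line written at the top.
#' @return `path`, invisibly.
#' @export
write_constraint_table <- function(x, path,
                                   kind = c("distance", "dihedral", "rdc",
                                            "shift", "shift_reference"),
                                   comment = NULL) {
  kind <- match.arg(kind)
  fmt <- function(v) formatC(v, format = "fg", digits = 10)
  rows <- switch(kind,
    distance = vapply(seq_len(nrow(x)), function(i) {
      mem <- paste(apply(x$members[[i]], 1L, paste, collapse = "-"),
                   collapse = "|")
      paste(x$id[i], mem, fmt(x$lower[i]), fmt(x$upper[i]), sep = "\t")
    }, ""),
    dihedral = sprintf("%s\t%s\t%d\t%s\t%s\t%s", x$id, x$chain, x$resno,
                       x$angle, fmt(x$lower), fmt(x$upper)),
    rdc = sprintf("%s\t%s\t%s\t%s\t%s\t%s", x$id, x$atom1, x$atom2,
                  x$type, x$medium, fmt(x$observed_hz)),
    shift = sprintf("%s\t%d\t%s\t%s\t%s\t%s", x$chain, x$resno, x$resname,
                    x$atom, x$nucleus_class, fmt(x$value)),
    shift_reference = sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d", x$resname,
                              x$atom, x$ss, x$acc_bin, fmt(x$mean_ppm),
                              fmt(x$sd_ppm), x$n))
  header <- switch(kind,
    shift_reference = c("resname", "atom", "ss", "acc_bin", "mean_ppm",
                        "sd_ppm", "n"),
    TSV_HEADERS[[if (kind == "shift") "shift" else kind]])
  write_tsv(header, rows, path, comment)
}

#' Generate a complete fixture set on disk
#'
#' Writes a synthetic ensemble (PDB) plus whatever restraint/shift/RDC
#' tables the preset calls for, together with `ground_truth.json`
#' recording every planted feature. Presets:
#' * `basic`: 20 residues, 10 models, jitter 0.05 Angstrom.
#' * `clustered`: two conformations (60 degree hinge), 10 + 10 models.
#' * `violations`: 20 residues, 10 models, small jitter (0.02 Angstrom),
#'   one planted 1.0 Angstrom distance violation and one 20 degree
#'   dihedral violation.
#' * `rdc`: noiseless couplings from a Da = 10 Hz, R = 0.3 tensor
#'   (N-HN + CA-HA), written raw.
#' * `shifts`: planted 1.7 ppm offset on 13C_aliphatic, five +6 sd
#'   outliers, unit noise; a PHE at residue 10 for aromatic marking.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param preset fixture preset name.
#' @return named list of the file paths written, invisibly; the list
#'   also carries the `truth` attribute with the planted ground truth.
#' @export
simulate_fixture_set <- function(out_dir, seed = 1L,
                                 preset = c("basic", "clustered",
                                            "violations", "rdc",
                                            "shifts")) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- list()
  truth <- list(preset = preset, seed = seed)
  hdr <- sprintf("fixture preset=%s seed=%d", preset, seed)
  spec <- switch(preset,
    basic      = fixture_spec(20L, 10L, sigma = 0.05, seed = seed),
    clustered  = fixture_spec(20L, 20L, sigma = 0.05, seed = seed,
                              hinge_deg = 60),
    violations = fixture_spec(20L, 10L, sigma = 0.02, seed = seed),
    rdc        = fixture_spec(20L, 10L, sigma = 0.02, seed = seed),
    shifts     = fixture_spec(20L, 10L, sigma = 0.05, seed = seed,
                              aromatic_at = 10L))
  ens <- make_ensemble(spec)
  files$coordinates <- write_ensemble(ens, p("ensemble.pdb"), header = hdr)
  if (preset == "violations") {
    r <- derive_restraints(ens, spec, planted_distance = 1L,
                           planted_dihedral = 1L, violation_A = 1.0,
                           violation_deg = 20)
    files$distance <- write_constraint_table(r$distance, p("distance.tsv"),
                                             "distance", comment = hdr)
    files$dihedral <- write_constraint_table(r$dihedral, p("dihedral.tsv"),
                                             "dihedral", comment = hdr)
    truth <- c(truth, r$truth)
  }
  if (preset == "rdc") {
    tensor <- random_saupe(Da = 10, R = 0.3, seed = seed + 4000L)
    rdc <- simulate_rdcs(ens, tensor, spec, noise_hz = 0,
                         prescaled = FALSE)
    files$rdc <- write_constraint_table(rdc, p("rdc.tsv"), "rdc",
                                        comment = hdr)
    truth$tensor <- tensor
    truth$Da <- 10; truth$R <- 0.3
  }
  if (preset == "shifts") {
    sim <- simulate_shifts(ens, spec,
                           offsets = c(`13C_aliphatic` = 1.7),
                           n_outliers = 5L, outlier_sd = 6,
                           noise_frac = 1)
    files$shifts <- write_constraint_table(sim$shifts, p("shifts.tsv"),
                                           "shift", comment = hdr)
    files$shift_reference <- write_constraint_table(
      sim$reference, p("shift_reference.tsv"), "shift_reference",
      comment = hdr)
    truth <- c(truth, sim$truth)
  }
  truth_json <- jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                 na = "null")
  writeLines(truth_json, p("ground_truth.json"))
  files$ground_truth <- p("ground_truth.json")
  attr(files, "truth") <- truth
  invisible(files)
}
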