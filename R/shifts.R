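# Chemical-shift validation in two steps: (1) a robust per-nucleus-class
# re-referencing offset (median deviation from environment-matched
# reference means), then (2) Z-scores of the offset-corrected shifts
# against the reference table, with |Z| > 3 flagged as outliers and a
# green/yellow/red color ramp for display.
#
# The residue environment conditioning the reference lookup combines a
# coarse secondary-structure class (H/E/C from the representative
# model's phi/psi) with a two-bin relative solvent accessibility
# (Shrake-Rupley ASA over the Gly-X-Gly maximum).

# Deterministic near-uniform unit sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible surface area from deterministic sphere sampling:
#' each atom is covered with `n_points` quasi-uniform points at radius
#' `vdw + probe`; points inside any neighbour's expanded sphere are
#' occluded. Hydrogens are excluded from both the surface and the
#' occluders (heavy-atom SASA).
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param elements element symbols per atom ("C", "N", "O", "S", "P",
#'   "H").
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 256).
#' @return numeric vector of per-atom ASA (Angstrom^2; hydrogens get 0).
#' @export
shrake_rupley_sasa <- function(coords, elements, probe = 1.4,
                               n_points = 256L) {
  coords <- as.matrix(coords)
  heavy <- elements != "H"
  radii <- vdw_radius(elements) + probe
  pts <- sphere_points(n_points)
  out <- numeric(nrow(coords))
  hidx <- which(heavy)
  for (i in hidx) {
    ri <- radii[i]
    surf <- sweep(pts * ri, 2L, coords[i, ], `+`)
    # neighbours that can occlude at all
    d2 <- rowSums(sweep(coords[hidx, , drop = FALSE], 2L, coords[i, ])^2)
    nb <- hidx[d2 < (ri + radii[hidx])^2 & hidx != i]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- rowSums(sweep(surf, 2L, coords[j, ])^2)
      acc <- acc & dj > radii[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  out
}

# H/E/C secondary-structure class from phi/psi (degrees, possibly NA).
ss_from_phipsi <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("C")
  if (phi > -100 && phi < -30 && psi > -80 && psi < -5) return("H")
  if (phi > -180 && phi < -45 &&
      ((psi > 90 && psi <= 180) || (psi > -180 && psi < -150))) return("E")
  "C"
}

#' Residue environment for shift-reference lookup
#'
#' Secondary structure comes from the representative model's phi/psi
#' (helix window phi in (-100,-30), psi in (-80,-5); strand window phi
#' in (-180,-45), psi in (90,180] or (-180,-150); everything else,
#' including chain termini, is coil). Relative accessibility is the
#' residue's heavy-atom Shrake-Rupley ASA in the representative model
#' divided by the Gly-X-Gly maximum for its type, binned buried/exposed
#' at `config$acc_buried_threshold`.
#'
#' @param ensemble an `nmr_ensemble` (protein chains).
#' @param model representative model index.
#' @param config validation configuration.
#' @param dihedrals optional precomputed `nmr_dihedrals`.
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, `ss`, `rel_acc`, `acc_bin`.
#' @export
residue_environments <- function(ensemble, model = 1L,
                                 config = nmr_config(),
                                 dihedrals = NULL) {
  if (is.null(dihedrals))
    dihedrals <- suppressWarnings(compute_backbone_dihedrals(ensemble))
  env <- ensemble$sequence
  # secondary structure
  env$ss <- vapply(seq_len(nrow(env)), function(i) {
    get_ang <- function(a) {
      r <- which(dihedrals$index$chain == env$chain[i] &
                 dihedrals$index$resno == env$resno[i] &
                 dihedrals$index$angle == a)
      if (length(r) == 1L) dihedrals$values[r, model] else NA_real_
    }
    ss_from_phipsi(get_ang("phi"), get_ang("psi"))
  }, "")
  # relative accessibility
  asa <- shrake_rupley_sasa(ensemble$coords[, , model],
                            ensemble$atoms$element,
                            probe = config$sasa_probe_A,
                            n_points = config$sasa_n_points)
  res_tag <- paste(ensemble$atoms$chain, ensemble$atoms$resno)
  asa_res <- tapply(asa, res_tag, sum)
  env$rel_acc <- vapply(seq_len(nrow(env)), function(i) {
    total <- asa_res[[paste(env$chain[i], env$resno[i])]]
    mx <- max_asa_table[env$resname[i]]
    if (is.na(mx)) mx <- mean(max_asa_table)
    min(unname(total / mx), 1)
  }, 0)
  env$acc_bin <- ifelse(env$rel_acc < config$acc_buried_threshold,
                        "buried", "exposed")
  env
}

# Join observed shifts to reference entries via their environment.
match_reference <- function(shifts, reference, environments) {
  ei <- match(paste(shifts$chain, shifts$resno),
              paste(environments$chain, environments$resno))
  key <- paste(shifts$resname, shifts$atom,
               environments$ss[ei], environments$acc_bin[ei], sep = "|")
  ri <- match(key, reference$key)
  data.frame(shifts,
             ss = environments$ss[ei], acc_bin = environments$acc_bin[ei],
             ref_mean = reference$mean_ppm[ri],
             ref_sd = reference$sd_ppm[ri],
             ref_n = reference$n[ri],
             stringsAsFactors = FALSE)
}

#' Per-nucleus-class chemical-shift referencing offsets
#'
#' For each class (1H, 15N, 13C_aliphatic, 13C_aromatic, 13C') with at
#' least `config$min_atoms_for_offset` shifts that have a matching
#' reference entry, the offset is the median of (observed - reference
#' mean). Classes below the minimum get offset 0 with a warning.
#'
#' @param shifts shift data.frame from [read_constraint_table()].
#' @param reference a `shift_reference` table.
#' @param environments from [residue_environments()].
#' @param config validation configuration.
#' @return named numeric vector of offsets (ppm) over the five classes,
#'   with attribute `n_matched` (atoms used per class).
#' @export
referencing_offset <- function(shifts, reference, environments,
                               config = nmr_config()) {
  classes <- c("1H", "15N", "13C_aliphatic", "13C_aromatic", "13C'")
  joined <- match_reference(shifts, reference, environments)
  offsets <- setNames(numeric(length(classes)), classes)
  n_matched <- setNames(integer(length(classes)), classes)
  for (cl in classes) {
    sel <- joined$nucleus_class == cl & !is.na(joined$ref_mean)
    n_matched[cl] <- sum(sel)
    if (n_matched[cl] >= config$min_atoms_for_offset) {
      offsets[cl] <- median(joined$value[sel] - joined$ref_mean[sel])
    } else if (n_matched[cl] > 0L) {
      warning("only ", n_matched[cl], " matched atoms for class ", cl,
              " (< ", config$min_atoms_for_offset,
              "): referencing offset set to 0")
    }
  }
  attr(offsets, "n_matched") <- n_matched
  offsets
}

#' Z-scores and outlier flags for chemical shifts
#'
#' After subtracting the per-class referencing offset, each shift with a
#' reference entry backed by at least `config$min_reference_count`
#' observations gets `z = (observed - offset - mean) / sd`; it is an
#' outlier when |z| strictly exceeds `config$zscore_outlier` (default
#' 3). Shifts without an adequate reference keep `z = NA`.
#'
#' @inheritParams referencing_offset
#' @param offsets from [referencing_offset()].
#' @return data.frame: the shift columns plus `ss`, `acc_bin`,
#'   `applied_offset`, `ref_mean`, `ref_sd`, `z`, `outlier`, `color`
#'   (hex "#RRGGBB" or NA).
#' @export
shift_zscores <- function(shifts, reference, environments, offsets,
                          config = nmr_config()) {
  joined <- match_reference(shifts, reference, environments)
  joined$applied_offset <- unname(offsets[joined$nucleus_class])
  usable <- !is.na(joined$ref_mean) & joined$ref_n >= config$min_reference_count
  bad_sd <- usable & joined$ref_sd <= 0
  if (any(bad_sd)) {
    warning("reference entries with sd <= 0 skipped for ",
            sum(bad_sd), " shift(s)")
    usable <- usable & !bad_sd
  }
  joined$z <- ifelse(usable,
                     (joined$value - joined$applied_offset - joined$ref_mean) /
                       joined$ref_sd,
                     NA_real_)
  joined$outlier <- !is.na(joined$z) & abs(joined$z) > config$zscore_outlier
  joined$color <- vapply(joined$z, function(z) {
    if (is.na(z)) NA_character_ else {
      rgb <- zscore_color(z)
      sprintf("#%02X%02X%02X", rgb[1L], rgb[2L], rgb[3L])
    }
  }, "")
  joined
}

#' Color ramp for shift Z-scores
#'
#' Green for |z| <= 2, ramping linearly to yellow at |z| = 3.5 and on to
#' red at |z| >= 5 (the display convention for shift outliers).
#'
#' @param z Z-score (sign ignored).
#' @return integer RGB triple in 0..255.
#' @export
#' @examples
#' zscore_color(1)    # green  (0, 255, 0)
#' zscore_color(3.5)  # yellow (255, 255, 0)
#' zscore_color(-6)   # red    (255, 0, 0)
zscore_color <- function(z) {
  if (is.na(z)) return(c(NA_integer_, NA_integer_, NA_integer_))
  a <- abs(z)
  rgb <- if (a <= 2) c(0, 255, 0)
  else if (a <= 3.5) {
    t <- (a - 2) / 1.5
    c(255 * t, 255, 0)
  } else if (a < 5) {
    t <- (a - 3.5) / 1.5
    c(255, 255 * (1 - t), 0)
  } else c(255, 0, 0)
  as.integer(round(rgb))
}

#' Residues near an aromatic ring
#'
#' Ring currents of PHE/TYR/TRP/HIS shift nearby nuclei but are not
#' modelled by the reference-table Z-score; residues with any atom
#' within `config$aromatic_cutoff_A` of another residue's aromatic ring
#' centroid are therefore marked so that their outliers can be
#' discounted.
#'
#' @param ensemble an `nmr_ensemble`.
#' @param model model index used for geometry.
#' @param config validation configuration.
#' @return data.frame `chain`, `resno`, `near_aromatic` (logical).
#' @export
aromatic_proximity <- function(ensemble, model = 1L,
                               config = nmr_config()) {
  seq_df <- ensemble$sequence
  out <- seq_df[, c("chain", "resno")]
  out$near_aromatic <- FALSE
  arom <- seq_df[seq_df$resname %in% names(aromatic_ring_atoms), ,
                 drop = FALSE]
  if (nrow(arom) == 0L) return(out)
  centroids <- lapply(seq_len(nrow(arom)), function(i) {
    ring <- aromatic_ring_atoms[[arom$resname[i]]]
    keys <- atom_key(arom$chain[i], arom$resno[i], ring)
    idx <- match(keys, ensemble$atoms$key)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 3L) return(NULL)
    colMeans(matrix(ensemble$coords[idx, , model], length(idx), 3L))
  })
  atom_tag <- paste(ensemble$atoms$chain, ensemble$atoms$resno)
  for (i in seq_len(nrow(out))) {
    idx <- which(atom_tag == paste(out$chain[i], out$resno[i]))
    xyz <- matrix(ensemble$coords[idx, , model], length(idx), 3L)
    for (j in seq_along(centroids)) {
      cen <- centroids[[j]]
      if (is.null(cen)) next
      same <- arom$chain[j] == out$chain[i] && arom$resno[j] == out$resno[i]
      if (!same &&
          min(sqrt(rowSums(sweep(xyz, 2L, cen)^2))) <=
            config$aromatic_cutoff_A) {
        out$near_aromatic[i] <- TRUE
        break
      }
    }
  }
  out
}
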