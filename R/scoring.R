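# Per-residue red/orange/green roll-up and report assembly. The rule
# set is deliberately simple and self-describing: the thresholds used
# are embedded in the report. A residue is scored on the worst evidence
# attached to it; missing evidence types simply cannot fire.

#' Red/orange/green score for one residue
#'
#' Triggers (defaults from [nmr_config()]):
#' * red: a distance restraint violated by more than `red_dist_A`
#'   (0.5 Angstrom) in at least `model_fraction` (50%) of models; a
#'   dihedral restraint violated by more than `red_dih_deg` (20 deg) in
#'   at least that fraction; or any shift with |Z| > `red_z` (5).
#' * orange: the same with the orange thresholds (0.3 Angstrom / 10 deg),
#'   or any shift with `zscore_outlier` < |Z| <= `red_z`.
#' * green otherwise.
#'
#' @param evidence list with optional elements `dist` and `dih` (each a
#'   list of per-model violation-magnitude vectors, one per restraint
#'   touching the residue) and `z` (Z-scores of the residue's shifts).
#' @param thresholds the `rog` element of [nmr_config()].
#' @param zscore_outlier |Z| outlier threshold (orange floor).
#' @return list `rog` ("red"/"orange"/"green") and `rationale`
#'   (character vector of every fired trigger).
#' @export
residue_rog <- function(evidence, thresholds = nmr_config()$rog,
                        zscore_outlier = 3) {
  rationale <- character(0)
  frac_over <- function(mags, thr)
    vapply(mags, function(v) mean(v > thr), 0)
  red <- orange <- FALSE
  if (length(evidence$dist)) {
    if (any(frac_over(evidence$dist, thresholds$red_dist_A) >=
            thresholds$model_fraction)) {
      red <- TRUE; rationale <- c(rationale, "distance_violation_severe")
    } else if (any(frac_over(evidence$dist, thresholds$orange_dist_A) >=
                   thresholds$model_fraction)) {
      orange <- TRUE; rationale <- c(rationale, "distance_violation")
    }
  }
  if (length(evidence$dih)) {
    if (any(frac_over(evidence$dih, thresholds$red_dih_deg) >=
            thresholds$model_fraction)) {
      red <- TRUE; rationale <- c(rationale, "dihedral_violation_severe")
    } else if (any(frac_over(evidence$dih, thresholds$orange_dih_deg) >=
                   thresholds$model_fraction)) {
      orange <- TRUE; rationale <- c(rationale, "dihedral_violation")
    }
  }
  z <- evidence$z[!is.na(evidence$z)]
  if (length(z)) {
    if (any(abs(z) > thresholds$red_z)) {
      red <- TRUE; rationale <- c(rationale, "shift_outlier_severe")
    } else if (any(abs(z) > zscore_outlier)) {
      orange <- TRUE; rationale <- c(rationale, "shift_outlier")
    }
  }
  list(rog = if (red) "red" else if (orange) "orange" else "green",
       rationale = rationale)
}

# Residues touched by a distance restraint (both endpoints of every
# member pair, each residue once).
constraint_residues <- function(constraint) {
  members <- constraint$members[[1L]]
  res <- rbind(parse_atom_key(members[, 1L])[, c("chain", "resno")],
               parse_atom_key(members[, 2L])[, c("chain", "resno")])
  unique(res)
}

#' Run the full validation pipeline
#'
#' Loads (or accepts) an ensemble, computes dihedrals, order parameters
#' and model clustering, evaluates whatever restraint/shift data is
#' supplied, scores every residue red/orange/green and assembles the
#' JSON-ready report. Absent data types produce empty report sections.
#'
#' @param coordinates path to a PDB/mmCIF file, or an `nmr_ensemble`.
#' @param distance,dihedral,rdc,shifts,shift_reference paths to the
#'   corresponding TSV tables (or pre-parsed data.frames), or NULL.
#' @param config validation configuration ([nmr_config()]).
#' @param per_model include per-model violation detail in the report
#'   (off by default to bound file size).
#' @param entry_name label stored in the report's entry block.
#' @return object of class `nmr_validation`: list with `report` (the
#'   JSON-ready structure), plus the intermediate `ensemble`,
#'   `dihedrals`, `clusters` and per-module results.
#' @export
validate_ensemble <- function(coordinates, distance = NULL,
                              dihedral = NULL, rdc = NULL, shifts = NULL,
                              shift_reference = NULL,
                              config = nmr_config(), per_model = FALSE,
                              entry_name = NULL) {
  ensemble <- if (inherits(coordinates, "nmr_ensemble")) coordinates
    else read_ensemble(coordinates)
  if (is.null(entry_name))
    entry_name <- if (is.character(coordinates))
      sub("\\.[^.]+$", "", basename(coordinates)) else "ensemble"
  load_tab <- function(x, kind)
    if (is.null(x) || is.data.frame(x)) x else read_constraint_table(x, kind)
  distance <- load_tab(distance, "distance")
  dihedral <- load_tab(dihedral, "dihedral")
  rdc <- load_tab(rdc, "rdc")
  shifts <- load_tab(shifts, "shift")
  if (!is.null(shift_reference) && !is.data.frame(shift_reference))
    shift_reference <- read_shift_reference(shift_reference)

  dih_set <- suppressWarnings(compute_backbone_dihedrals(ensemble))
  s2 <- order_parameters(dih_set)
  clusters <- cluster_and_represent(ensemble,
                                    rmsd_cutoff_A = config$cluster_cutoff_A)
  rep_model <- clusters$overall_representative
  n_mod <- length(ensemble$model_ids)

  residues <- ensemble$sequence
  residues$s2 <- s2$s2[match(paste(residues$chain, residues$resno),
                             paste(s2$chain, s2$resno))]
  res_tag <- paste(residues$chain, residues$resno)
  dist_ev <- rep(list(list()), nrow(residues))
  dih_ev <- rep(list(list()), nrow(residues))
  z_ev <- rep(list(numeric(0)), nrow(residues))

  dist_res <- NULL
  lr_counts <- NULL
  if (!is.null(distance) && nrow(distance)) {
    dist_res <- evaluate_distance_constraints(distance, ensemble)
    lr_counts <- long_range_counts(distance, ensemble)
    for (i in seq_len(nrow(distance))) {
      v <- dist_res$violations[dist_res$violations$id == distance$id[i], ]
      mags <- v$magnitude[order(v$model)]
      for (tag in paste(constraint_residues(distance[i, ])$chain,
                        constraint_residues(distance[i, ])$resno)) {
        k <- match(tag, res_tag)
        if (!is.na(k)) dist_ev[[k]] <- c(dist_ev[[k]], list(mags))
      }
    }
  }
  dih_res <- NULL
  if (!is.null(dihedral) && nrow(dihedral)) {
    dih_res <- evaluate_dihedral_constraints(dihedral, dih_set)
    for (i in seq_len(nrow(dihedral))) {
      v <- dih_res$violations[dih_res$violations$id == dihedral$id[i], ]
      k <- match(paste(dihedral$chain[i], dihedral$resno[i]), res_tag)
      if (!is.na(k)) dih_ev[[k]] <- c(dih_ev[[k]], list(v$magnitude))
    }
  }

  rdc_section <- list()
  if (!is.null(rdc) && nrow(rdc)) {
    for (med in unique(rdc$medium)) {
      sub <- rdc[rdc$medium == med, , drop = FALSE]
      conv <- detect_rdc_unit_convention(sub, ensemble, rep_model, config)
      normalize <- conv$convention == "raw"
      fits <- lapply(seq_len(n_mod), function(m)
        suppressWarnings(fit_alignment_tensor(sub, ensemble, m,
                                              normalize = normalize,
                                              config = config)))
      st <- ensemble_rdc_stats(fits)
      rdc_section[[length(rdc_section) + 1L]] <- list(
        medium = med,
        convention = conv$convention,
        q_raw = conv$q_raw, q_prescaled = conv$q_prescaled,
        n_constraints = nrow(sub),
        models = lapply(fits, function(f) list(
          model = f$model,
          tensor = list(matrix = f$matrix,
                        eigenvalues = f$eigenvalues,
                        axes = f$axes, Da = f$Da, R = f$R),
          rmsd_hz = f$rmsd_hz, pearson_r = f$pearson_r,
          q_value = f$q_value,
          condition_number = f$condition_number,
          degenerate = f$degenerate)),
        per_constraint = st$per_constraint,
        mean_metrics = st$metrics)
    }
  }

  shift_section <- NULL
  environments <- NULL
  if (!is.null(shifts) && nrow(shifts) && !is.null(shift_reference)) {
    environments <- residue_environments(ensemble, rep_model, config,
                                         dihedrals = dih_set)
    offsets <- suppressWarnings(
      referencing_offset(shifts, shift_reference, environments, config))
    zrec <- shift_zscores(shifts, shift_reference, environments, offsets,
                          config)
    arom <- aromatic_proximity(ensemble, rep_model, config)
    zrec$near_aromatic <- arom$near_aromatic[
      match(paste(zrec$chain, zrec$resno), paste(arom$chain, arom$resno))]
    for (i in seq_len(nrow(zrec))) {
      k <- match(paste(zrec$chain[i], zrec$resno[i]), res_tag)
      if (!is.na(k)) z_ev[[k]] <- c(z_ev[[k]], zrec$z[i])
    }
    shift_section <- list(offsets = as.list(offsets),
                          n_matched = as.list(attr(offsets, "n_matched")),
                          records = zrec)
  }

  # per-residue roll-up
  rog <- lapply(seq_len(nrow(residues)), function(k)
    residue_rog(list(dist = dist_ev[[k]], dih = dih_ev[[k]],
                     z = z_ev[[k]]),
                thresholds = config$rog,
                zscore_outlier = config$zscore_outlier))
  residues$rog <- vapply(rog, `[[`, "", "rog")
  residues$n_long_range <- if (is.null(lr_counts)) 0L else
    lr_counts$n_long_range[match(res_tag,
                                 paste(lr_counts$chain, lr_counts$resno))]
  worst <- function(ev) if (length(ev)) max(vapply(ev, max, 0)) else 0
  residues$worst_distance_violation <- vapply(dist_ev, worst, 0)
  residues$worst_dihedral_violation <- vapply(dih_ev, worst, 0)
  residues$worst_abs_z <- vapply(z_ev, function(z) {
    z <- z[!is.na(z)]; if (length(z)) max(abs(z)) else NA_real_
  }, 0)

  report <- assemble_report(
    entry_name = entry_name, ensemble = ensemble, clusters = clusters,
    residues = residues, rog = rog, dist_res = dist_res,
    dih_res = dih_res, rdc_section = rdc_section,
    shift_section = shift_section, config = config,
    per_model = per_model)

  structure(list(report = report, ensemble = ensemble,
                 dihedrals = dih_set, clusters = clusters,
                 residues = residues, distance = dist_res,
                 dihedral = dih_res, rdc = rdc_section,
                 shifts = shift_section, config = config),
            class = "nmr_validation")
}

#' Assemble the JSON-ready validation report
#'
#' Composes the fixed-order report structure from the module outputs.
#' Top-level keys are always present; absent data types give empty
#' arrays. Summary counts are recomputed here from the per-residue and
#' per-constraint lists.
#'
#' @param entry_name entry label.
#' @param ensemble,clusters,residues,rog,dist_res,dih_res,rdc_section,shift_section
#'   module outputs as produced inside [validate_ensemble()].
#' @param config configuration used (embedded for self-description).
#' @param per_model include per-model violation records.
#' @return nested list ready for [write_report()].
#' @export
assemble_report <- function(entry_name, ensemble, clusters, residues, rog,
                            dist_res = NULL, dih_res = NULL,
                            rdc_section = list(), shift_section = NULL,
                            config = nmr_config(), per_model = FALSE) {
  if (nrow(residues) != nrow(ensemble$sequence))
    stop("residue bookkeeping mismatch: ", nrow(residues), " scored vs ",
         nrow(ensemble$sequence), " in ensemble")
  num <- function(x) ifelse(is.nan(x), NA, x)
  res_list <- lapply(seq_len(nrow(residues)), function(i) list(
    chain = residues$chain[i], resno = residues$resno[i],
    resname = residues$resname[i],
    s2 = num(residues$s2[i]),
    n_long_range = residues$n_long_range[i],
    worst_distance_violation = num(residues$worst_distance_violation[i]),
    worst_dihedral_violation = num(residues$worst_dihedral_violation[i]),
    worst_abs_z = num(residues$worst_abs_z[i]),
    rog = residues$rog[i],
    rationale = rog[[i]]$rationale))
  stats_list <- function(df) {
    if (is.null(df)) return(list())
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  dist_stats <- if (is.null(dist_res)) list() else
    stats_list(dist_res$stats)
  if (per_model && !is.null(dist_res)) {
    for (i in seq_along(dist_stats))
      dist_stats[[i]]$models <- stats_list(
        dist_res$violations[dist_res$violations$id == dist_stats[[i]]$id, ])
  }
  dih_stats <- if (is.null(dih_res)) list() else stats_list(dih_res$stats)
  if (per_model && !is.null(dih_res)) {
    for (i in seq_along(dih_stats))
      dih_stats[[i]]$models <- stats_list(
        dih_res$violations[dih_res$violations$id == dih_stats[[i]]$id, ])
  }
  rdc_out <- lapply(rdc_section, function(sec) {
    sec$per_constraint <- stats_list(sec$per_constraint)
    sec
  })
  shift_out <- if (is.null(shift_section)) {
    list(offsets = list(), n_matched = list(), records = list())
  } else {
    shift_section$records <- stats_list(
      transform(shift_section$records, z = num(z)))
    shift_section
  }
  n_class <- function(df, cls) if (is.null(df)) 0L else
    sum(df$stats$range_class == cls & df$stats$n_violated > 0L)
  list(
    entry = list(name = entry_name, tool = "nmrvalid",
                 config = config[c("cluster_cutoff_A",
                                   "acc_buried_threshold",
                                   "min_atoms_for_offset",
                                   "min_reference_count",
                                   "zscore_outlier", "rog",
                                   "rdc_q_norm")]),
    ensemble = list(
      n_models = length(ensemble$model_ids),
      n_residues = nrow(ensemble$sequence),
      representative_model = clusters$overall_representative,
      clusters = lapply(seq_along(clusters$clusters), function(i) list(
        models = clusters$clusters[[i]],
        representative = clusters$representatives[i]))),
    residues = res_list,
    distance_constraints = dist_stats,
    dihedral_constraints = dih_stats,
    rdc = rdc_out,
    shifts = shift_out,
    rog = list(
      summary = list(
        n_red = sum(residues$rog == "red"),
        n_orange = sum(residues$rog == "orange"),
        n_green = sum(residues$rog == "green"),
        n_violated_distance = list(
          intra = n_class(dist_res, "intra"),
          short = n_class(dist_res, "short"),
          medium = n_class(dist_res, "medium"),
          long = n_class(dist_res, "long"))),
      residues = lapply(seq_len(nrow(residues)), function(i) list(
        chain = residues$chain[i], resno = residues$resno[i],
        rog = residues$rog[i])))
  )
}

#' Write a validation report as JSON
#'
#' UTF-8, deterministic key order (the assembly order), full numeric
#' precision, `null` for undefined values; NaN is never emitted, so the
#' output parses under strict JSON.
#'
#' @param report an `nmr_validation` object or the report list itself.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "nmr_validation")) report <- report$report
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Read a validation report back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return the report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' @export
print.nmr_validation <- function(x, ...) {
  r <- x$report
  cat("NMR ensemble validation:", r$entry$name, "\n")
  cat("  models:", r$ensemble$n_models,
      " residues:", r$ensemble$n_residues,
      " clusters:", length(r$ensemble$clusters),
      " representative: model", r$ensemble$representative_model, "\n")
  cat("  ROG: ", r$rog$summary$n_red, " red / ",
      r$rog$summary$n_orange, " orange / ",
      r$rog$summary$n_green, " green\n", sep = "")
  invisible(x)
}

#' @export
summary.nmr_validation <- function(object, ...) {
  r <- object$report
  s2 <- object$residues$s2
  cat("Entry:", r$entry$name, "\n")
  cat("Models:", r$ensemble$n_models, "; residues:",
      r$ensemble$n_residues, "\n")
  cat(sprintf("S^2: median %.3f (min %.3f at %s)\n",
              median(s2, na.rm = TRUE), min(s2, na.rm = TRUE),
              paste(object$residues$chain[which.min(s2)],
                    object$residues$resno[which.min(s2)])))
  if (length(r$distance_constraints)) {
    nv <- sum(vapply(r$distance_constraints,
                     function(d) d$n_violated > 0, TRUE))
    cat("Distance restraints:", length(r$distance_constraints),
        "(", nv, "violated in >=1 model )\n")
  }
  if (length(r$dihedral_constraints)) {
    nv <- sum(vapply(r$dihedral_constraints,
                     function(d) d$n_violated > 0, TRUE))
    cat("Dihedral restraints:", length(r$dihedral_constraints),
        "(", nv, "violated in >=1 model )\n")
  }
  for (sec in r$rdc)
    cat(sprintf("RDC medium %s: n=%d, mean Q = %.3f (%s)\n", sec$medium,
                sec$n_constraints, sec$mean_metrics$q_value,
                sec$convention))
  if (length(r$shifts$records))
    cat("Shifts:", length(r$shifts$records), "records,",
        sum(vapply(r$shifts$records,
                   function(s) isTRUE(s$outlier), TRUE)), "outliers\n")
  cat("ROG:", r$rog$summary$n_red, "red,", r$rog$summary$n_orange,
      "orange,", r$rog$summary$n_green, "green\n")
  invisible(object)
}
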