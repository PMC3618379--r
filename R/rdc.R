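# Residual dipolar coupling analysis. One traceless symmetric Saupe
# alignment tensor is fitted per model and alignment medium by linear
# least squares (SVD pseudo-inverse) over the five independent tensor
# elements; reported are the tensor magnitude Da, rhombicity R,
# principal axes and the goodness-of-fit metrics RMSD (Hz), Pearson R
# and the Cornilescu Q factor.

#' Normalise an observed RDC to the N-HN scale
#'
#' Couplings of type A-B scale as `gamma_A * gamma_B / r_AB^3`; the
#' normalisation factor is `(gamma_N gamma_H / r_NH^3) / (gamma_A
#' gamma_B / r_AB^3)`, so an N-HN coupling is returned unchanged.
#'
#' @param observed_hz observed coupling(s) in Hz.
#' @param type RDC type label(s) present in the bond table.
#' @param bond_table as from [default_bond_table()].
#' @return normalised coupling(s) in Hz.
#' @export
normalize_rdc <- function(observed_hz, type,
                          bond_table = default_bond_table()) {
  idx <- match(type, bond_table$type)
  if (anyNA(idx))
    stop("unknown RDC type(s): ",
         paste(unique(type[is.na(idx)]), collapse = ", "),
         "; known: ", paste(bond_table$type, collapse = ", "))
  observed_hz * bond_table$scale[idx]
}

# Saupe tensor from the 5-vector (Sxx, Syy, Sxy, Sxz, Syz).
saupe_from_elements <- function(s) {
  matrix(c(s[1L], s[3L], s[4L],
           s[3L], s[2L], s[5L],
           s[4L], s[5L], -s[1L] - s[2L]), 3L, 3L)
}

# Eigen-analysis with |l1| <= |l2| <= |l3|; Da = l3/2, R = 2(l1-l2)/(3 l3).
saupe_summary <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))
  lambda <- e$values[ord]
  axes <- e$vectors[, ord, drop = FALSE]
  # sign convention: make the largest component of each axis positive
  for (k in 1:3) if (axes[which.max(abs(axes[, k])), k] < 0)
    axes[, k] <- -axes[, k]
  Da <- lambda[3L] / 2
  R <- if (abs(lambda[3L]) > 0) 2 * (lambda[1L] - lambda[2L]) / (3 * lambda[3L]) else NA_real_
  list(matrix = S, eigenvalues = lambda, axes = axes, Da = Da, R = R)
}

#' Goodness of fit between observed and calculated RDCs
#'
#' @param observed,calculated equal-length numeric vectors (Hz), n >= 2.
#' @return list `rmsd_hz` (root-mean-square deviation), `pearson_r`
#'   (NA when the observed values have zero variance) and `q_value`
#'   (Cornilescu Q = rmsd / rms(observed); NA when all observed are 0).
#' @export
goodness_of_fit <- function(observed, calculated) {
  stopifnot(length(observed) == length(calculated), length(observed) >= 2L)
  rmsd <- sqrt(mean((observed - calculated)^2))
  pearson <- if (stats::sd(observed) > 0 && stats::sd(calculated) > 0)
    stats::cor(observed, calculated) else NA_real_
  rms_obs <- sqrt(mean(observed^2))
  q <- if (rms_obs > 0) rmsd / rms_obs else NA_real_
  list(rmsd_hz = rmsd, pearson_r = pearson, q_value = q)
}

# Design matrix rows (x2-z2, y2-z2, 2xy, 2xz, 2yz) from unit bond vectors.
rdc_design <- function(unit_vectors) {
  x <- unit_vectors[, 1L]; y <- unit_vectors[, 2L]; z <- unit_vectors[, 3L]
  cbind(x^2 - z^2, y^2 - z^2, 2 * x * y, 2 * x * z, 2 * y * z)
}

# Unit internuclear vectors for a set of RDC rows in one model.
rdc_unit_vectors <- function(rdcs, ensemble, model) {
  i1 <- resolve_atoms(ensemble, rdcs$atom1)
  i2 <- resolve_atoms(ensemble, rdcs$atom2)
  v <- ensemble$coords[i2, , model, drop = FALSE][, , 1L] -
       ensemble$coords[i1, , model, drop = FALSE][, , 1L]
  v <- matrix(v, nrow(rdcs), 3L)
  v / sqrt(rowSums(v^2))
}

#' Fit a Saupe alignment tensor to RDCs in one model
#'
#' Solves the linear system `D = A s` for the five independent tensor
#' elements by SVD pseudo-inverse, where each row of `A` is
#' `(x^2-z^2, y^2-z^2, 2xy, 2xz, 2yz)` from the unit internuclear vector
#' and `s = (Sxx, Syy, Sxy, Sxz, Syz)` with `Szz = -Sxx - Syy`.
#'
#' @param rdcs RDC data.frame (one medium) as from
#'   [read_constraint_table()].
#' @param ensemble an `nmr_ensemble`.
#' @param model model index.
#' @param normalize normalise observed values to the N-HN scale first
#'   (set `FALSE` for data already deposited prescaled).
#' @param config validation configuration ([nmr_config()]).
#' @return object of class `rdc_fit`: tensor summary (`matrix`,
#'   `eigenvalues`, `axes`, `Da`, `R`), per-constraint `observed` and
#'   `calculated` values (Hz, normalised scale), metrics `rmsd_hz`,
#'   `pearson_r`, `q_value`, the design-matrix `condition_number`, a
#'   `degenerate` flag, `n` constraints used, `model` and `medium`.
#' @export
fit_alignment_tensor <- function(rdcs, ensemble, model,
                                 normalize = TRUE,
                                 config = nmr_config()) {
  if (nrow(rdcs) < 5L)
    stop("at least 5 RDCs are required to fit an alignment tensor (got ",
         nrow(rdcs), ")")
  obs <- if (normalize)
    normalize_rdc(rdcs$observed_hz, rdcs$type, config$bond_table)
  else rdcs$observed_hz
  u <- rdc_unit_vectors(rdcs, ensemble, model)
  A <- rdc_design(u)
  sv <- svd(A)
  cond <- sv$d[1L] / max(sv$d[5L], .Machine$double.xmin)
  degenerate <- cond > config$rdc_condition_max
  if (degenerate)
    warning("degenerate RDC design matrix (condition number ",
            format(cond, digits = 3), "); tensor is ill-determined")
  dinv <- ifelse(sv$d > sv$d[1L] * 1e-12, 1 / sv$d, 0)
  s <- sv$v %*% (dinv * (t(sv$u) %*% obs))
  S <- saupe_from_elements(as.numeric(s))
  calc <- as.numeric(A %*% s)
  gof <- goodness_of_fit(obs, calc)
  q <- gof$q_value
  if (identical(config$rdc_q_norm, "da")) {
    ts <- saupe_summary(S)
    denom <- sqrt(2 * ts$Da^2 * (4 + 3 * ts$R^2) / 5)
    q <- if (is.finite(denom) && denom > 0) gof$rmsd_hz / denom else NA_real_
  }
  structure(c(saupe_summary(S),
              list(observed = obs, calculated = calc, ids = rdcs$id,
                   rmsd_hz = gof$rmsd_hz, pearson_r = gof$pearson_r,
                   q_value = q, condition_number = cond,
                   degenerate = degenerate, n = nrow(rdcs),
                   model = model,
                   medium = if (nrow(rdcs)) rdcs$medium[1L] else NA_character_,
                   normalized = normalize)),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf(
    "Saupe tensor fit (model %s, medium %s, n = %d)\n", x$model, x$medium,
    x$n))
  cat(sprintf("  Da = %.3f Hz, rhombicity R = %.3f\n", x$Da, x$R))
  cat(sprintf("  rmsd = %.3f Hz, Pearson R = %.3f, Q = %.3f\n",
              x$rmsd_hz, x$pearson_r, x$q_value))
  if (isTRUE(x$degenerate))
    cat("  WARNING: degenerate design matrix\n")
  invisible(x)
}

#' @export
coef.rdc_fit <- function(object, ...) {
  S <- object$matrix
  c(Sxx = S[1L, 1L], Syy = S[2L, 2L], Sxy = S[1L, 2L],
    Sxz = S[1L, 3L], Syz = S[2L, 3L])
}

#' Ensemble statistics of fitted RDCs
#'
#' @param fits list of `rdc_fit` objects for the same medium across
#'   models (same constraints in the same order).
#' @return list with `per_constraint` (data.frame id/observed/mean/sd/
#'   min/max of calculated values across models; sd is 0 for a single
#'   model) and `metrics` (mean rmsd_hz/pearson_r/q_value over models).
#' @export
ensemble_rdc_stats <- function(fits) {
  stopifnot(length(fits) >= 1L)
  calc <- do.call(cbind, lapply(fits, `[[`, "calculated"))
  per <- data.frame(
    id = fits[[1L]]$ids,
    observed = fits[[1L]]$observed,
    mean = rowMeans(calc),
    sd = if (ncol(calc) > 1L) apply(calc, 1L, stats::sd) else
      rep(0, nrow(calc)),
    min = apply(calc, 1L, min),
    max = apply(calc, 1L, max),
    stringsAsFactors = FALSE
  )
  list(per_constraint = per,
       metrics = list(
         rmsd_hz = mean(vapply(fits, `[[`, 0, "rmsd_hz")),
         pearson_r = mean(vapply(fits, `[[`, 0, "pearson_r")),
         q_value = mean(vapply(fits, `[[`, 0, "q_value"))))
}

#' Detect whether deposited RDCs are raw or prescaled
#'
#' When a medium carries more than one RDC type, the values may have
#' been deposited either as raw couplings or already scaled to the N-HN
#' frame. Both hypotheses are fitted; the one with the lower Q wins.
#' Single-type media return "raw" trivially (the two hypotheses differ
#' only by an overall factor there).
#'
#' @inheritParams fit_alignment_tensor
#' @return list `convention` ("raw" or "prescaled"), `q_raw`,
#'   `q_prescaled` (NA when not evaluated).
#' @export
detect_rdc_unit_convention <- function(rdcs, ensemble, model,
                                       config = nmr_config()) {
  if (length(unique(rdcs$type)) < 2L)
    return(list(convention = "raw", q_raw = NA_real_,
                q_prescaled = NA_real_))
  fit_raw <- fit_alignment_tensor(rdcs, ensemble, model, normalize = TRUE,
                                  config = config)
  fit_pre <- fit_alignment_tensor(rdcs, ensemble, model, normalize = FALSE,
                                  config = config)
  list(convention = if (fit_raw$q_value <= fit_pre$q_value) "raw"
       else "prescaled",
       q_raw = fit_raw$q_value, q_prescaled = fit_pre$q_value)
}
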