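# NOE distance and dihedral restraint validation. Distances for
# ambiguous restraints (several candidate atom pairs, e.g. methyl
# protons) are combined by r^-6 sum averaging; violations are assessed
# per model against closed bounds [lower, upper] and aggregated over the
# ensemble.

#' Sequence-range class of a distance restraint
#'
#' Classifies by sequence separation: 0 residues apart is `intra`,
#' 1-2 `short`, 3-4 `medium`, 5 or more `long`. For ambiguous restraints
#' the separation is the maximum over member pairs; pairs on different
#' chains are `long`.
#'
#' @param constraint one row of a distance-restraint data.frame (see
#'   [read_constraint_table()]).
#' @param ensemble an `nmr_ensemble` (members must resolve; an unknown
#'   atom is an error naming it).
#' @return one of "intra", "short", "medium", "long".
#' @export
classify_distance_constraint <- function(constraint, ensemble) {
  members <- constraint$members[[1L]]
  resolve_atoms(ensemble, as.vector(members))
  a <- parse_atom_key(members[, 1L])
  b <- parse_atom_key(members[, 2L])
  sep <- ifelse(a$chain != b$chain, Inf, abs(a$resno - b$resno))
  sep <- max(sep)
  if (sep == 0) "intra"
  else if (sep <= 2) "short"
  else if (sep <= 4) "medium"
  else "long"
}

#' r^-6 sum-averaged effective distance
#'
#' `(sum_p d_p^-6)^(-1/6)` over the member-pair distances of an ambiguous
#' restraint. Always less than or equal to the smallest member distance.
#'
#' @param distances positive distances in Angstrom.
#' @return effective distance in Angstrom.
#' @export
#' @examples
#' effective_distance(5)           # 5
#' effective_distance(c(4, 4))     # 4 * 2^(-1/6)
effective_distance <- function(distances) {
  if (length(distances) == 0L) stop("empty distance list")
  if (any(distances <= 0)) stop("distances must be positive")
  sum(distances^-6)^(-1 / 6)
}

# Per-model member-pair distances for one constraint: members x models.
member_distances <- function(constraint, ensemble) {
  members <- constraint$members[[1L]]
  i1 <- resolve_atoms(ensemble, members[, 1L])
  i2 <- resolve_atoms(ensemble, members[, 2L])
  n_mod <- length(ensemble$model_ids)
  d <- matrix(0, nrow(members), n_mod)
  for (m in seq_len(n_mod)) {
    diff <- ensemble$coords[i1, , m, drop = FALSE] -
            ensemble$coords[i2, , m, drop = FALSE]
    d[, m] <- sqrt(rowSums(matrix(diff, nrow(members), 3L)^2))
  }
  d
}

violation_stats <- function(viol) {
  # viol: data.frame id/model/actual/bound/magnitude for one constraint
  v <- viol[viol$bound != "none", , drop = FALSE]
  list(n_violated = nrow(v),
       max_magnitude = if (nrow(v)) max(v$magnitude) else 0,
       mean_violating_magnitude = if (nrow(v)) mean(v$magnitude) else 0)
}

#' Evaluate distance restraints against an ensemble
#'
#' For every restraint and model, the effective (r^-6 sum-averaged)
#' distance is compared with the closed bounds: a violation is
#' `d_eff > upper` (magnitude `d_eff - upper`) or `d_eff < lower`
#' (magnitude `lower - d_eff`); `d_eff == upper` or `== lower` is
#' satisfied.
#'
#' @param constraints distance-restraint data.frame.
#' @param ensemble an `nmr_ensemble`.
#' @return list with `violations` (data.frame id/model/actual/bound/
#'   magnitude, one row per restraint per model) and `stats` (per
#'   restraint: `id`, `range_class`, `n_violated`, `max_magnitude`,
#'   `mean_violating_magnitude`).
#' @export
evaluate_distance_constraints <- function(constraints, ensemble) {
  n_mod <- length(ensemble$model_ids)
  viols <- list(); stats_rows <- list()
  for (i in seq_len(nrow(constraints))) {
    cst <- constraints[i, ]
    d <- member_distances(cst, ensemble)
    d_eff <- apply(d, 2L, effective_distance)
    bound <- rep("none", n_mod)
    mag <- rep(0, n_mod)
    over <- d_eff > cst$upper
    under <- d_eff < cst$lower
    bound[over] <- "upper"; mag[over] <- d_eff[over] - cst$upper
    bound[under] <- "lower"; mag[under] <- cst$lower - d_eff[under]
    v <- data.frame(id = cst$id, model = seq_len(n_mod), actual = d_eff,
                    bound = bound, magnitude = mag,
                    stringsAsFactors = FALSE)
    viols[[i]] <- v
    st <- violation_stats(v)
    stats_rows[[i]] <- data.frame(
      id = cst$id,
      range_class = classify_distance_constraint(cst, ensemble),
      n_violated = st$n_violated, max_magnitude = st$max_magnitude,
      mean_violating_magnitude = st$mean_violating_magnitude,
      stringsAsFactors = FALSE)
  }
  list(violations = if (length(viols)) do.call(rbind, viols) else
         data.frame(id = character(), model = integer(), actual = numeric(),
                    bound = character(), magnitude = numeric()),
       stats = if (length(stats_rows)) do.call(rbind, stats_rows) else
         data.frame(id = character(), range_class = character(),
                    n_violated = integer(), max_magnitude = numeric(),
                    mean_violating_magnitude = numeric()))
}

# Is angle theta inside the closed counter-clockwise arc lower -> upper?
# All in degrees; lower > upper encodes a wrap through +/-180.
angle_in_arc <- function(theta, lower, upper) {
  span <- (upper - lower) %% 360
  pos <- (theta - lower) %% 360
  pos <= span + 1e-12
}

# Shortest angular distance (degrees, <= 180) between two angles.
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Evaluate dihedral restraints against ensemble dihedrals
#'
#' An angle satisfies a restraint when it lies in the closed
#' counter-clockwise arc from `lower` to `upper` (wrapping through
#' +/-180 when `lower > upper`). The violation magnitude is the shortest
#' angular distance to the nearer arc endpoint. Models in which the
#' angle is undefined are skipped and counted in `n_undefined`.
#'
#' @param constraints dihedral-restraint data.frame.
#' @param dihedrals an `nmr_dihedrals`.
#' @return list with `violations` (id/model/actual/bound/magnitude) and
#'   `stats` (id/chain/resno/angle/n_violated/n_undefined/max_magnitude/
#'   mean_violating_magnitude).
#' @export
evaluate_dihedral_constraints <- function(constraints, dihedrals) {
  n_mod <- dihedrals$n_models
  viols <- list(); stats_rows <- list()
  for (i in seq_len(nrow(constraints))) {
    cst <- constraints[i, ]
    r <- which(dihedrals$index$chain == cst$chain &
               dihedrals$index$resno == cst$resno &
               dihedrals$index$angle == cst$angle)
    vals <- if (length(r) == 1L) dihedrals$values[r, ] else
      rep(NA_real_, n_mod)
    defined <- which(!is.na(vals))
    bound <- character(0); mag <- numeric(0)
    for (m in defined) {
      th <- vals[m]
      if (angle_in_arc(th, cst$lower, cst$upper)) {
        bound <- c(bound, "none"); mag <- c(mag, 0)
      } else {
        dl <- angular_distance(th, cst$lower)
        du <- angular_distance(th, cst$upper)
        bound <- c(bound, if (dl <= du) "lower" else "upper")
        mag <- c(mag, min(dl, du))
      }
    }
    v <- data.frame(id = cst$id, model = defined,
                    actual = vals[defined], bound = bound, magnitude = mag,
                    stringsAsFactors = FALSE)
    viols[[i]] <- v
    st <- violation_stats(v)
    stats_rows[[i]] <- data.frame(
      id = cst$id, chain = cst$chain, resno = cst$resno, angle = cst$angle,
      n_violated = st$n_violated,
      n_undefined = n_mod - length(defined),
      max_magnitude = st$max_magnitude,
      mean_violating_magnitude = st$mean_violating_magnitude,
      stringsAsFactors = FALSE)
  }
  list(violations = if (length(viols)) do.call(rbind, viols) else
         data.frame(id = character(), model = integer(), actual = numeric(),
                    bound = character(), magnitude = numeric()),
       stats = if (length(stats_rows)) do.call(rbind, stats_rows) else
         data.frame(id = character(), chain = character(), resno = integer(),
                    angle = character(), n_violated = integer(),
                    n_undefined = integer(), max_magnitude = numeric(),
                    mean_violating_magnitude = numeric()))
}

#' Long-range distance restraints per residue
#'
#' Counts, for every residue, the number of long-range restraints
#' (5 or more residues apart, or inter-chain) that touch it. Each
#' restraint increments both participating residues once, regardless of
#' how many member pairs involve them.
#'
#' @param constraints distance-restraint data.frame.
#' @param ensemble an `nmr_ensemble`.
#' @return data.frame `chain`, `resno`, `n_long_range` covering every
#'   polymer residue (zeros included).
#' @export
long_range_counts <- function(constraints, ensemble) {
  out <- ensemble$sequence[, c("chain", "resno")]
  out$n_long_range <- 0L
  for (i in seq_len(nrow(constraints))) {
    cst <- constraints[i, ]
    if (classify_distance_constraint(cst, ensemble) != "long") next
    members <- cst$members[[1L]]
    res <- unique(rbind(parse_atom_key(members[, 1L])[, c("chain", "resno")],
                        parse_atom_key(members[, 2L])[, c("chain", "resno")]))
    hit <- match(paste(res$chain, res$resno),
                 paste(out$chain, out$resno))
    hit <- hit[!is.na(hit)]
    out$n_long_range[hit] <- out$n_long_range[hit] + 1L
  }
  out
}
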