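# Ensemble precision analysis: backbone dihedral angles across models,
# the per-residue circular order parameter S^2, pairwise-RMSD model
# clustering and medoid representative selection.

# Backbone atom definitions per polymer type for dihedral construction.
# phi(i):  C(i-1), N(i), CA(i), C(i)
# psi(i):  N(i), CA(i), C(i), N(i+1)
# Nucleic-acid backbone torsions alpha..zeta follow the standard
# O3'(i-1)-P-O5'-C5'-C4'-C3'-O3'-P(i+1) chain.
DIHEDRAL_DEFS <- list(
  protein = list(
    phi = list(atoms = c("C", "N", "CA", "C"),  offs = c(-1L, 0L, 0L, 0L)),
    psi = list(atoms = c("N", "CA", "C", "N"),  offs = c(0L, 0L, 0L, 1L))
  ),
  nucleic = list(
    alpha   = list(atoms = c("O3'", "P", "O5'", "C5'"), offs = c(-1L, 0L, 0L, 0L)),
    beta    = list(atoms = c("P", "O5'", "C5'", "C4'"), offs = c(0L, 0L, 0L, 0L)),
    gamma   = list(atoms = c("O5'", "C5'", "C4'", "C3'"), offs = c(0L, 0L, 0L, 0L)),
    delta   = list(atoms = c("C5'", "C4'", "C3'", "O3'"), offs = c(0L, 0L, 0L, 0L)),
    epsilon = list(atoms = c("C4'", "C3'", "O3'", "P"),  offs = c(0L, 0L, 0L, 1L)),
    zeta    = list(atoms = c("C3'", "O3'", "P", "O5'"),  offs = c(0L, 0L, 1L, 1L))
  )
)

# Default atom selections for superposition/clustering.
BACKBONE_SELECTION <- list(
  protein = c("N", "CA", "C", "O"),
  nucleic = c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
)

#' Backbone dihedral angles across an ensemble
#'
#' Computes phi/psi for every protein residue (alpha..zeta for
#' nucleotides) in every model. Angles whose defining atoms fall outside
#' the chain (termini) are absent; a missing backbone atom mid-chain
#' leaves that angle undefined (`NA`) with a warning.
#'
#' @param ensemble an `nmr_ensemble`.
#' @return Object of class `nmr_dihedrals`: list with `index`
#'   (data.frame chain/resno/angle) and `values` (matrix, one row per
#'   index entry, one column per model; degrees in (-180, 180]).
#' @export
compute_backbone_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "nmr_ensemble"))
  n_mod <- length(ensemble$model_ids)
  idx_rows <- list(); val_rows <- list(); k <- 0L
  for (ch in names(ensemble$polymer_type)) {
    defs <- DIHEDRAL_DEFS[[ensemble$polymer_type[[ch]]]]
    res <- ensemble$sequence[ensemble$sequence$chain == ch, ]
    resnos <- res$resno
    for (ri in seq_along(resnos)) {
      for (ang in names(defs)) {
        def <- defs[[ang]]
        pos <- ri + def$offs
        if (any(pos < 1L | pos > length(resnos))) next  # terminal: absent
        keys <- atom_key(ch, resnos[pos], def$atoms)
        ai <- match(keys, ensemble$atoms$key)
        if (anyNA(ai)) {
          warning("missing backbone atom(s) for ", ch, "/", resnos[ri], " ",
                  ang, ": ", paste(keys[is.na(ai)], collapse = ", "),
                  "; angle undefined")
          vals <- rep(NA_real_, n_mod)
        } else {
          vals <- vapply(seq_len(n_mod), function(m) {
            dihedral_angle(ensemble$coords[ai[1L], , m],
                           ensemble$coords[ai[2L], , m],
                           ensemble$coords[ai[3L], , m],
                           ensemble$coords[ai[4L], , m])
          }, 0)
        }
        k <- k + 1L
        idx_rows[[k]] <- data.frame(chain = ch, resno = resnos[ri],
                                    angle = ang, stringsAsFactors = FALSE)
        val_rows[[k]] <- vals
      }
    }
  }
  index <- if (k) do.call(rbind, idx_rows) else
    data.frame(chain = character(), resno = integer(), angle = character())
  values <- if (k) do.call(rbind, val_rows) else
    matrix(numeric(), 0L, n_mod)
  structure(list(index = index, values = values, n_models = n_mod),
            class = "nmr_dihedrals")
}

#' Circular dihedral order parameter S^2 for one residue
#'
#' For each angle type i present with defined values in all N models,
#' `s_i = (mean_j cos g_ij)^2 + (mean_j sin g_ij)^2`; S^2 is the
#' arithmetic mean of `s_i` over the M available angle types. S^2 is 1
#' when the angles are identical in every model and approaches 0 for
#' angles spread uniformly around the circle.
#'
#' @param dihedrals an `nmr_dihedrals` from [compute_backbone_dihedrals()].
#' @param chain,resnum residue address.
#' @return numeric in \[0, 1\], or `NA` when no angle type is defined in
#'   all models. A single-model ensemble returns 1 with a warning.
#' @export
angular_order_parameter <- function(dihedrals, chain, resnum) {
  stopifnot(inherits(dihedrals, "nmr_dihedrals"))
  rows <- which(dihedrals$index$chain == chain &
                dihedrals$index$resno == resnum)
  if (length(rows) == 0L) return(NA_real_)
  if (dihedrals$n_models == 1L) {
    warning("single-conformer ensemble: S^2 is trivially 1")
    return(1)
  }
  s <- c()
  for (r in rows) {
    v <- dihedrals$values[r, ]
    if (anyNA(v)) next
    rad <- v * pi / 180
    s <- c(s, mean(cos(rad))^2 + mean(sin(rad))^2)
  }
  if (length(s) == 0L) return(NA_real_)
  mean(s)
}

#' Per-residue order parameters for a whole ensemble
#'
#' @param dihedrals an `nmr_dihedrals`.
#' @return data.frame with columns `chain`, `resno`, `s2`.
#' @export
order_parameters <- function(dihedrals) {
  res <- unique(dihedrals$index[, c("chain", "resno")])
  if (nrow(res) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      s2 = numeric()))
  res$s2 <- vapply(seq_len(nrow(res)), function(i)
    suppressWarnings(
      angular_order_parameter(dihedrals, res$chain[i], res$resno[i])), 0)
  rownames(res) <- NULL
  res
}

# Coordinates of a named-atom selection for one model, as an n x 3 matrix.
selection_coords <- function(ensemble, model, selection) {
  keep <- ensemble$atoms$atom %in% selection
  if (!any(keep)) stop("atom selection matches no atoms")
  ensemble$coords[keep, , model, drop = FALSE][, , 1L]
}

#' Pairwise superposition RMSD matrix of an ensemble
#'
#' @param ensemble an `nmr_ensemble`.
#' @param atom_selection atom-name filter; defaults to backbone heavy
#'   atoms for the chain polymer types present.
#' @return symmetric N x N matrix of post-superposition RMSD (Angstrom).
#' @export
rmsd_matrix <- function(ensemble, atom_selection = NULL) {
  if (is.null(atom_selection))
    atom_selection <- unique(unlist(
      BACKBONE_SELECTION[unique(ensemble$polymer_type)]))
  n <- length(ensemble$model_ids)
  sel <- lapply(seq_len(n), selection_coords, ensemble = ensemble,
                selection = atom_selection)
  m <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- fit_rmsd(sel[[i]], sel[[j]])
  m
}

#' Cluster ensemble models and pick representatives
#'
#' Average-linkage agglomerative clustering of the pairwise
#' post-superposition RMSD matrix, cut at `rmsd_cutoff_A`. The
#' representative of each cluster is its medoid (minimum summed RMSD to
#' the other members); the overall representative is the medoid of the
#' largest cluster. All ties break toward the lower model id.
#'
#' @param ensemble an `nmr_ensemble`.
#' @param atom_selection atom-name filter (default backbone heavy atoms).
#' @param rmsd_cutoff_A cluster cut height in Angstrom (default 2.0).
#' @return list of class `nmr_clusters`: `clusters` (list of model-id
#'   vectors, largest first), `representatives` (one per cluster),
#'   `overall_representative`, `rmsd` (the matrix).
#' @export
cluster_and_represent <- function(ensemble, atom_selection = NULL,
                                  rmsd_cutoff_A = 2.0) {
  m <- rmsd_matrix(ensemble, atom_selection)
  n <- nrow(m)
  membership <- if (n == 1L || max(m) <= rmsd_cutoff_A) rep(1L, n) else
    stats::cutree(stats::hclust(stats::as.dist(m), method = "average"),
                  h = rmsd_cutoff_A)
  ids <- split(seq_len(n), membership)
  sizes <- vapply(ids, length, 1L)
  # largest first; among equal sizes, the cluster containing the lower id
  ord <- order(-sizes, vapply(ids, min, 1L))
  ids <- ids[ord]
  medoid <- function(members) {
    if (length(members) == 1L) return(members)
    ssum <- rowSums(m[members, members, drop = FALSE])
    members[which.min(ssum)]  # which.min takes the first (lowest id) on ties
  }
  reps <- vapply(ids, medoid, 1L)
  structure(list(clusters = unname(ids),
                 representatives = unname(reps),
                 overall_representative = unname(reps[1L]),
                 rmsd = m),
            class = "nmr_clusters")
}

#' @export
print.nmr_clusters <- function(x, ...) {
  cat("Model clustering:", length(x$clusters), "cluster(s);",
      "overall representative: model", x$overall_representative, "\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d model(s), representative %d\n",
                i, length(x$clusters[[i]]), x$representatives[i]))
  invisible(x)
}
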