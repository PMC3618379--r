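# Configuration: every tunable threshold and physical-constant table lives
# here so that reports are self-describing (the config used is embedded in
# the report) and so tests can tighten or relax rules explicitly.

#' Default validation configuration
#'
#' Returns the full set of tunable parameters used by the validation
#' pipeline. Any element may be overridden by passing a named list to the
#' `config` argument of the relevant function; unnamed elements keep their
#' defaults.
#'
#' @param ... named overrides, e.g. `nmr_config(cluster_cutoff_A = 1.5)`.
#'
#' @return A named list with components:
#' \describe{
#'   \item{cluster_cutoff_A}{average-linkage RMSD cut for model clustering
#'     (Angstrom, default 2.0).}
#'   \item{acc_buried_threshold}{relative solvent accessibility below which
#'     a residue is binned as buried (default 0.20).}
#'   \item{sasa_probe_A}{solvent probe radius (Angstrom, default 1.4).}
#'   \item{sasa_n_points}{sphere points per atom for Shrake-Rupley
#'     (default 256).}
#'   \item{min_atoms_for_offset}{minimum matched shifts per nucleus class
#'     before a referencing offset is estimated (default 10).}
#'   \item{min_reference_count}{minimum reference-table count for a Z-score
#'     to be computed (default 10).}
#'   \item{zscore_outlier}{|Z| above which a shift is an outlier
#'     (default 3, strict inequality).}
#'   \item{rog}{red/orange/green trigger thresholds (see
#'     [residue_rog()]).}
#'   \item{rdc_q_norm}{"obs" (Q = rmsd / rms(observed)) or "da" (normalise
#'     by Da*sqrt(4 + 3 R^2)).}
#'   \item{rdc_condition_max}{design-matrix condition number above which a
#'     tensor fit is flagged degenerate (default 1e6).}
#'   \item{bond_table}{per-RDC-type gyromagnetic ratios and effective bond
#'     lengths used for normalisation to the N-HN scale.}
#'   \item{aromatic_cutoff_A}{distance from an aromatic ring centroid below
#'     which a residue is marked ring-current-suspect (default 5.0).}
#' }
#' @export
#' @examples
#' cfg <- nmr_config(cluster_cutoff_A = 1.0)
#' cfg$cluster_cutoff_A
nmr_config <- function(...) {
  cfg <- list(
    cluster_cutoff_A     = 2.0,
    acc_buried_threshold = 0.20,
    sasa_probe_A         = 1.4,
    sasa_n_points        = 256L,
    min_atoms_for_offset = 10L,
    min_reference_count  = 10L,
    zscore_outlier       = 3,
    rog = list(
      red_dist_A    = 0.5,
      red_dih_deg   = 20,
      red_z         = 5,
      orange_dist_A = 0.3,
      orange_dih_deg = 10,
      model_fraction = 0.5
    ),
    rdc_q_norm        = "obs",
    rdc_condition_max = 1e6,
    bond_table        = default_bond_table(),
    aromatic_cutoff_A = 5.0
  )
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]]))
    dots <- dots[[1L]]
  for (nm in names(dots)) {
    if (nm == "rog" && is.list(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg$rog[[k]] <- dots[[nm]][[k]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Dipolar bond table for RDC normalisation
#'
#' Gyromagnetic ratios (1e7 rad s^-1 T^-1) and effective internuclear
#' distances (Angstrom) per RDC type. These are conventions of the field,
#' not fitted values; edit or extend via `nmr_config(bond_table = ...)`.
#' Scaling to the N-HN frame uses
#' `scale = (gN * gH / r_NH^3) / (gA * gB / r_AB^3)`, so N-HN has scale 1
#' exactly. Gyromagnetic ratios keep their physical signs (15N is
#' negative), so scale factors can be negative.
#'
#' @return data.frame with columns `type`, `gamma_a`, `gamma_b`, `r_A` and
#'   the derived `scale` (multiply an observed coupling of that type by
#'   `scale` to express it in N-HN-normalised Hz).
#' @export
default_bond_table <- function() {
  g <- c(H1 = 26.7522128, C13 = 6.728284, N15 = -2.7126)
  tab <- data.frame(
    type    = c("N-HN", "CA-HA", "N-C", "CA-C"),
    gamma_a = c(g[["N15"]], g[["C13"]], g[["N15"]], g[["C13"]]),
    gamma_b = c(g[["H1"]],  g[["H1"]],  g[["C13"]], g[["C13"]]),
    r_A     = c(1.02, 1.09, 1.329, 1.525),
    stringsAsFactors = FALSE
  )
  ref <- g[["N15"]] * g[["H1"]] / 1.02^3
  tab$scale <- ref / (tab$gamma_a * tab$gamma_b / tab$r_A^3)
  tab
}

# Nucleus class for a (residue name, atom name) pair.
# 1H for hydrogens, 15N for nitrogens, 13C' for backbone carbonyl C,
# 13C_aromatic for ring carbons of PHE/TYR/TRP/HIS, 13C_aliphatic otherwise.
aromatic_ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Map an atom to its nucleus class
#'
#' Classes follow the five groups used for chemical-shift re-referencing:
#' `1H`, `15N`, `13C_aliphatic`, `13C_aromatic` and `13C'` (backbone
#' carbonyl). Ring carbons of PHE, TYR, TRP and HIS are aromatic.
#'
#' @param resname three-letter residue name.
#' @param atom atom name (PDB convention, e.g. "CA", "HB2").
#' @return character scalar, one of the five classes, or `NA` for
#'   non-H/C/N elements.
#' @export
nucleus_class <- function(resname, atom) {
  stopifnot(length(resname) == length(atom))
  el <- substr(gsub("^[0-9]+", "", atom), 1L, 1L)
  out <- rep(NA_character_, length(atom))
  out[el == "H"] <- "1H"
  out[el == "N"] <- "15N"
  isC <- el == "C"
  out[isC] <- "13C_aliphatic"
  out[isC & atom == "C"] <- "13C'"
  ring <- mapply(function(rn, at) {
    !is.null(aromatic_ring_atoms[[rn]]) && at %in% aromatic_ring_atoms[[rn]]
  }, resname, atom, USE.NAMES = FALSE)
  out[isC & ring] <- "13C_aromatic"
  # aromatic ring nitrogens (TRP NE1, HIS ND1/NE2) stay 15N by convention
  out
}

# Van der Waals radii (Angstrom) for SASA; Bondi-style values.
vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

# Theoretical Gly-X-Gly maximum accessible surface areas (Angstrom^2),
# used to convert absolute residue ASA to relative accessibility.
max_asa_table <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)
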