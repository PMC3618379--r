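# Reading coordinate ensembles and the tab-separated restraint/shift
# tables. Atom addressing throughout the package is the triple
# (chain id, author residue number, atom name), rendered as the key string
# "chain/resno/atom" (e.g. "A/5/HB2"). Insertion codes are rejected so
# keys stay total-ordered.

NUCLEIC_RESNAMES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "I", "DI")

atom_key <- function(chain, resno, atom) paste(chain, resno, atom, sep = "/")

#' Parse an "chain/resno/atom" key
#' @param key character vector of atom keys such as "A/5/HB2".
#' @return data.frame with columns `chain`, `resno` (integer), `atom`.
#' @export
parse_atom_key <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed atom key(s): ", paste(key[bad], collapse = ", "))
  data.frame(
    chain = vapply(parts, `[[`, "", 1L),
    resno = as.integer(vapply(parts, `[[`, "", 2L)),
    atom  = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# Build the nmr_ensemble object from a list of per-model atom tables
# (columns chain, resno, atom, resname, element, x, y, z).
build_ensemble <- function(models, source = "") {
  if (length(models) == 0L) stop("ensemble contains zero models")
  keyed <- lapply(models, function(m) {
    k <- atom_key(m$chain, m$resno, m$atom)
    if (anyDuplicated(k))
      stop("duplicate atom key(s) within one model: ",
           paste(unique(k[duplicated(k)]), collapse = ", "))
    m$key <- k
    m
  })
  ref_keys <- keyed[[1L]]$key
  for (i in seq_along(keyed)) {
    diff <- c(setdiff(ref_keys, keyed[[i]]$key),
              setdiff(keyed[[i]]$key, ref_keys))
    if (length(diff))
      stop("mismatched atom sets across models (model ", i,
           " vs model 1): ", paste(sort(diff), collapse = ", "))
  }
  atoms <- keyed[[1L]][, c("chain", "resno", "atom", "resname", "element", "key")]
  n <- nrow(atoms)
  coords <- array(NA_real_, dim = c(n, 3L, length(keyed)),
                  dimnames = list(atoms$key, c("x", "y", "z"), NULL))
  for (i in seq_along(keyed)) {
    m <- keyed[[i]]
    idx <- match(atoms$key, m$key)
    coords[, , i] <- as.matrix(m[idx, c("x", "y", "z")])
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  seq_df <- unique(atoms[, c("chain", "resno")])
  seq_df$resname <- atoms$resname[match(atom_key(seq_df$chain, seq_df$resno, ""),
                                        atom_key(atoms$chain, atoms$resno, ""))]
  seq_df <- seq_df[order(seq_df$chain, seq_df$resno), ]
  rownames(seq_df) <- NULL
  ptype <- vapply(split(seq_df$resname, seq_df$chain), function(rn) {
    if (mean(rn %in% NUCLEIC_RESNAMES) > 0.5) "nucleic" else "protein"
  }, "")
  structure(
    list(atoms = atoms, coords = coords,
         model_ids = seq_along(keyed),
         sequence = seq_df, polymer_type = ptype, source = source),
    class = "nmr_ensemble"
  )
}

#' Read a multi-model coordinate ensemble
#'
#' Reads a PDB (MODEL/ENDMDL) or mmCIF file into an `nmr_ensemble`.
#' Alternate locations other than blank/'A' are dropped; hydrogens are
#' retained; insertion codes are rejected. Every model must contain
#' exactly the same set of (chain, residue number, atom name) keys;
#' a mismatch is a hard error naming the offending atoms.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @return An object of class `nmr_ensemble`: list with `atoms`
#'   (data.frame of chain/resno/atom/resname/element/key), `coords`
#'   (atoms x 3 x models array, Angstrom), `model_ids`, `sequence`
#'   (per-chain residue table) and `polymer_type` (named per chain,
#'   "protein" or "nucleic").
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  models <- if (format == "pdb") read_pdb_models(path) else read_cif_models(path)
  build_ensemble(models, source = path)
}

# One bio3d atom table -> the column set build_ensemble expects.
tidy_atom_table <- function(at) {
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported (residue ",
         paste(unique(at$resno[!is.na(at$insert) & nzchar(at$insert)]),
               collapse = ","), ")")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)))
    el <- substr(gsub("^[0-9]+", "", at$elety), 1L, 1L)
  el <- toupper(ifelse(is.na(el) | !nzchar(el),
                       substr(gsub("^[0-9]+", "", at$elety), 1L, 1L), el))
  data.frame(chain = chain, resno = at$resno, atom = at$elety,
             resname = at$resid, element = el,
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
  }
  lapply(blocks, function(b) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(c(b, "END"), tf)
    pdb <- bio3d::read.pdb(tf, verbose = FALSE)
    tidy_atom_table(pdb$atom)
  })
}

read_cif_models <- function(path) {
  pdb <- suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE))
  at <- tidy_atom_table(pdb$atom)
  xyz <- pdb$xyz
  nmod <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (is.matrix(xyz) && ncol(xyz) != 3L * nrow(pdb$atom))
    stop("mismatched atom sets across models in ", path)
  lapply(seq_len(nmod), function(i) {
    row <- if (is.matrix(xyz)) xyz[i, ] else as.numeric(xyz)
    m <- matrix(row, ncol = 3L, byrow = TRUE)
    keep <- is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A")
    out <- at
    out$x <- m[keep, 1L]; out$y <- m[keep, 2L]; out$z <- m[keep, 3L]
    out
  })
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ensemble an `nmr_ensemble`.
#' @param path output path.
#' @param header optional character vector written as REMARK lines before
#'   the first MODEL (used by the fixture generator to record seeds).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, header = NULL) {
  stopifnot(inherits(ensemble, "nmr_ensemble"))
  n_mod <- length(ensemble$model_ids)
  xyz <- t(apply(ensemble$coords, 3L, function(m) as.numeric(t(m))))
  if (n_mod == 1L) xyz <- matrix(xyz, nrow = 1L)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resname,
                   chain = ensemble$atoms$chain,
                   elety = ensemble$atoms$atom,
                   elesy = ensemble$atoms$element)
  if (!is.null(header)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   6 %s", header), body), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSV dialects. Tab-separated, '#' comment lines and blank lines skipped,
# header row required and checked verbatim.

TSV_HEADERS <- list(
  distance  = c("id", "members", "lower_A", "upper_A"),
  dihedral  = c("id", "chain", "resnum", "angle", "lower_deg", "upper_deg"),
  rdc       = c("id", "atom1", "atom2", "type", "medium", "observed_hz"),
  shift     = c("chain", "resnum", "resname", "atom", "nucleus_class",
                "shift_ppm")
)

ANGLE_NAMES <- list(
  protein = c("phi", "psi"),
  nucleic = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
)

read_tsv_rows <- function(path, expected_header) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no header row in ", path)
  header <- strsplit(lines[keep[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, expected_header))
    stop("header mismatch in ", path, ": expected '",
         paste(expected_header, collapse = "\\t"), "', got '",
         paste(header, collapse = "\\t"), "'")
  rows <- lapply(keep[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(expected_header))
      stop("line ", i, " of ", path, ": expected ",
           length(expected_header), " columns, found ", length(f))
    f
  })
  list(rows = rows, lines = keep[-1L])
}

num_field <- function(x, what, line, path) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop("line ", line[is.na(v)][1L], " of ", path, ": non-numeric ", what,
         " '", x[is.na(v)][1L], "'")
  v
}

#' Read a restraint or chemical-shift table
#'
#' Parses one of the four tab-separated dialects. Blank lines and lines
#' starting with `#` are skipped; the header row must match the dialect.
#' Ambiguous distance members are '|'-separated
#' `chain/resnum/atom-chain/resnum/atom` pairs.
#'
#' @param path file path.
#' @param kind one of "distance", "dihedral", "rdc", "shift".
#' @return A data.frame, one row per record:
#'   * distance: `id`, `members` (list column of 2-column key matrices),
#'     `lower`, `upper` (Angstrom);
#'   * dihedral: `id`, `chain`, `resno`, `angle`, `lower`, `upper`
#'     (degrees; `lower > upper` encodes an interval wrapping +/-180);
#'   * rdc: `id`, `atom1`, `atom2`, `type`, `medium`, `observed_hz`;
#'   * shift: `chain`, `resno`, `resname`, `atom`, `nucleus_class`,
#'     `value` (ppm).
#' @export
read_constraint_table <- function(path,
                                  kind = c("distance", "dihedral", "rdc",
                                           "shift")) {
  kind <- match.arg(kind)
  tsv <- read_tsv_rows(path, TSV_HEADERS[[kind]])
  rows <- tsv$rows; ln <- tsv$lines
  col <- function(i) vapply(rows, `[[`, "", i)
  if (length(rows) == 0L) {
    out <- switch(kind,
      distance = data.frame(id = character(), lower = numeric(),
                            upper = numeric()),
      dihedral = data.frame(id = character(), chain = character(),
                            resno = integer(), angle = character(),
                            lower = numeric(), upper = numeric()),
      rdc = data.frame(id = character(), atom1 = character(),
                       atom2 = character(), type = character(),
                       medium = character(), observed_hz = numeric()),
      shift = data.frame(chain = character(), resno = integer(),
                         resname = character(), atom = character(),
                         nucleus_class = character(), value = numeric()))
    if (kind == "distance") out$members <- list()
    return(out)
  }
  switch(kind,
    distance = {
      members <- lapply(seq_along(rows), function(i) {
        pairs <- strsplit(col(2L)[i], "|", fixed = TRUE)[[1L]]
        m <- t(vapply(strsplit(pairs, "-", fixed = TRUE), function(p) {
          if (length(p) != 2L)
            stop("line ", ln[i], " of ", path, ": malformed member pair '",
                 paste(p, collapse = "-"), "'")
          p
        }, character(2L)))
        if (nrow(m) == 0L)
          stop("line ", ln[i], " of ", path, ": empty member list")
        parse_atom_key(as.vector(m))  # validates key syntax
        m
      })
      lower <- num_field(col(3L), "lower_A", ln, path)
      upper <- num_field(col(4L), "upper_A", ln, path)
      if (any(lower < 0)) stop("negative lower bound in ", path)
      if (any(upper < lower)) stop("upper < lower in ", path)
      out <- data.frame(id = col(1L), lower = lower, upper = upper,
                        stringsAsFactors = FALSE)
      out$members <- members
      out
    },
    dihedral = {
      lower <- num_field(col(5L), "lower_deg", ln, path)
      upper <- num_field(col(6L), "upper_deg", ln, path)
      if (any(lower <= -180 | lower > 180 | upper <= -180 | upper > 180))
        stop("dihedral bounds must lie in (-180, 180] in ", path)
      ang <- col(4L)
      ok <- ang %in% unlist(ANGLE_NAMES)
      if (!all(ok))
        stop("unknown angle name(s) in ", path, ": ",
             paste(unique(ang[!ok]), collapse = ", "))
      data.frame(id = col(1L), chain = col(2L),
                 resno = as.integer(num_field(col(3L), "resnum", ln, path)),
                 angle = ang, lower = lower, upper = upper,
                 stringsAsFactors = FALSE)
    },
    rdc = {
      parse_atom_key(col(2L)); parse_atom_key(col(3L))
      if (any(col(2L) == col(3L)))
        stop("RDC with identical atoms in ", path)
      data.frame(id = col(1L), atom1 = col(2L), atom2 = col(3L),
                 type = col(4L), medium = col(5L),
                 observed_hz = num_field(col(6L), "observed_hz", ln, path),
                 stringsAsFactors = FALSE)
    },
    shift = {
      out <- data.frame(chain = col(1L),
                        resno = as.integer(num_field(col(2L), "resnum", ln, path)),
                        resname = col(3L), atom = col(4L),
                        nucleus_class = col(5L),
                        value = num_field(col(6L), "shift_ppm", ln, path),
                        stringsAsFactors = FALSE)
      expected <- nucleus_class(out$resname, out$atom)
      bad <- !is.na(expected) & expected != out$nucleus_class
      if (any(bad))
        stop("nucleus_class inconsistent with atom name at line(s) ",
             paste(ln[bad], collapse = ","), " of ", path,
             " (e.g. ", out$atom[bad][1L], " should be ",
             expected[bad][1L], ")")
      out
    })
}

#' Read a chemical-shift reference table
#'
#' Expected means and standard deviations of shifts keyed by
#' (residue name, atom name, secondary-structure class, accessibility
#' bin). Duplicate keys, non-positive standard deviations and counts
#' below 1 are errors.
#'
#' @param path TSV file with header
#'   `resname atom ss acc_bin mean_ppm sd_ppm n`.
#' @return data.frame of class `shift_reference` with those columns plus
#'   a `key` column used for lookup.
#' @export
read_shift_reference <- function(path) {
  tsv <- read_tsv_rows(path, c("resname", "atom", "ss", "acc_bin",
                               "mean_ppm", "sd_ppm", "n"))
  rows <- tsv$rows; ln <- tsv$lines
  col <- function(i) vapply(rows, `[[`, "", i)
  if (length(rows) == 0L) {
    out <- data.frame(resname = character(), atom = character(),
                      ss = character(), acc_bin = character(),
                      mean_ppm = numeric(), sd_ppm = numeric(),
                      n = integer(), key = character())
    class(out) <- c("shift_reference", "data.frame")
    return(out)
  }
  out <- data.frame(
    resname = col(1L), atom = col(2L), ss = col(3L), acc_bin = col(4L),
    mean_ppm = num_field(col(5L), "mean_ppm", ln, path),
    sd_ppm = num_field(col(6L), "sd_ppm", ln, path),
    n = as.integer(num_field(col(7L), "n", ln, path)),
    stringsAsFactors = FALSE
  )
  if (any(out$sd_ppm <= 0)) stop("sd_ppm must be > 0 in ", path)
  if (any(out$n < 1L)) stop("count n must be >= 1 in ", path)
  out$key <- paste(out$resname, out$atom, out$ss, out$acc_bin, sep = "|")
  if (anyDuplicated(out$key))
    stop("duplicate reference key(s) in ", path, ": ",
         paste(unique(out$key[duplicated(out$key)]), collapse = ", "))
  class(out) <- c("shift_reference", "data.frame")
  out
}

# Resolve atom keys to row indices in the ensemble atom table.
resolve_atoms <- function(ensemble, keys) {
  idx <- match(keys, ensemble$atoms$key)
  if (anyNA(idx))
    stop("atom(s) not present in ensemble: ",
         paste(unique(keys[is.na(idx)]), collapse = ", "))
  idx
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat("NMR ensemble:", length(x$model_ids), "model(s),",
      nrow(x$sequence), "residues,", nrow(x$atoms), "atoms/model\n")
  for (ch in names(x$polymer_type))
    cat("  chain ", ch, ": ", sum(x$sequence$chain == ch), " residues (",
        x$polymer_type[[ch]], ")\n", sep = "")
  invisible(x)
}
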