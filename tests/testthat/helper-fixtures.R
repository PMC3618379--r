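# Shared helpers: tiny hand-written coordinate files and constructed
# dihedral sets used across the unit tests. All fixtures are built in
# code at test time.

toy_pdb_lines <- function(models) {
  # models: list of data.frames chain/resno/atom/resname/element/x/y/z
  fmt <- function(m) sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(m)),
    ifelse(nchar(m$atom) < 4, paste0(" ", m$atom), m$atom),
    m$resname, m$chain, m$resno, m$x, m$y, m$z, m$element)
  out <- character(0)
  for (i in seq_along(models))
    out <- c(out, sprintf("MODEL     %4d", i), fmt(models[[i]]), "ENDMDL")
  c(out, "END")
}

toy_atoms <- function(dx = 0) {
  data.frame(
    chain = "A", resno = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    atom = rep(c("N", "CA", "C"), 3L),
    resname = "ALA", element = rep(c("N", "C", "C"), 3L),
    x = c(0, 1.458, 2.009, 3.3, 4.6, 5.2, 6.5, 7.8, 8.4) + dx,
    y = c(0, 0, 1.42, 1.6, 0.9, 2.2, 2.4, 1.8, 3.1),
    z = c(0, 0, 0, 0.3, 0.5, 0.8, 1.1, 1.4, 1.7),
    stringsAsFactors = FALSE)
}

write_toy_pdb <- function(path, n_models = 2L) {
  models <- lapply(seq_len(n_models) - 1L, function(i) toy_atoms(dx = 0.1 * i))
  writeLines(toy_pdb_lines(models), path)
  path
}

# A dihedral set built directly (bypassing coordinates) for S^2 tests:
# one residue, one angle type, given per-model values.
manual_dihedrals <- function(values, chain = "A", resno = 1L,
                             angle = "phi") {
  structure(list(
    index = data.frame(chain = chain, resno = resno, angle = angle,
                       stringsAsFactors = FALSE),
    values = matrix(values, nrow = 1L),
    n_models = length(values)), class = "nmr_dihedrals")
}

# Single-member distance restraint row in the parsed shape.
dist_row <- function(id, key1, key2, lower, upper) {
  out <- data.frame(id = id, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  out$members <- list(matrix(c(key1, key2), 1L, 2L))
  out
}
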