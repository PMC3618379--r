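# Structural validation of reports against the shipped schema. A small
# purpose-built checker (required keys, basic types, enums) rather than
# a full JSON-Schema engine: the schema file documents the contract,
# this function enforces the parts the pipeline relies on.

#' Path to the shipped report schema
#' @return file path of `report-schema.json`.
#' @export
report_schema_path <- function() {
  system.file("extdata", "report-schema.json", package = "nmrvalid",
              mustWork = TRUE)
}

check_required <- function(x, keys, where, problems) {
  miss <- setdiff(keys, names(x))
  if (length(miss))
    problems <- c(problems, paste0(where, ": missing key(s) ",
                                   paste(miss, collapse = ", ")))
  problems
}

#' Check a report against the shipped schema
#'
#' Verifies required top-level and per-section keys, the red/orange/
#' green and range-class enumerations and the S^2 range. Returns
#' `TRUE` invisibly on success; otherwise throws (default) or returns
#' the character vector of problems.
#'
#' @param report report list (as from [read_report()] or the `report`
#'   element of an `nmr_validation`).
#' @param error throw on failure (default) instead of returning
#'   problems.
#' @return `TRUE` invisibly, or a character vector of problems when
#'   `error = FALSE`.
#' @export
check_report_schema <- function(report, error = TRUE) {
  if (inherits(report, "nmr_validation")) report <- report$report
  p <- character(0)
  p <- check_required(report,
                      c("entry", "ensemble", "residues",
                        "distance_constraints", "dihedral_constraints",
                        "rdc", "shifts", "rog"), "report", p)
  if (!is.null(report$entry))
    p <- check_required(report$entry, c("name", "tool", "config"),
                        "entry", p)
  if (!is.null(report$ensemble))
    p <- check_required(report$ensemble,
                        c("n_models", "n_residues",
                          "representative_model", "clusters"),
                        "ensemble", p)
  for (i in seq_along(report$residues)) {
    r <- report$residues[[i]]
    p <- check_required(r, c("chain", "resno", "resname", "s2", "rog",
                             "rationale"), paste0("residues[", i, "]"), p)
    if (!is.null(r$rog) && !(r$rog %in% c("red", "orange", "green")))
      p <- c(p, paste0("residues[", i, "]: bad rog '", r$rog, "'"))
    if (!is.null(r$s2) && !is.na(r$s2) && (r$s2 < -1e-9 || r$s2 > 1 + 1e-9))
      p <- c(p, paste0("residues[", i, "]: s2 out of [0,1]"))
  }
  for (i in seq_along(report$distance_constraints)) {
    d <- report$distance_constraints[[i]]
    p <- check_required(d, c("id", "range_class", "n_violated",
                             "max_magnitude",
                             "mean_violating_magnitude"),
                        paste0("distance_constraints[", i, "]"), p)
    if (!is.null(d$range_class) &&
        !(d$range_class %in% c("intra", "short", "medium", "long")))
      p <- c(p, paste0("distance_constraints[", i, "]: bad class"))
  }
  for (i in seq_along(report$rdc)) {
    s <- report$rdc[[i]]
    p <- check_required(s, c("medium", "convention", "n_constraints",
                             "models", "per_constraint", "mean_metrics"),
                        paste0("rdc[", i, "]"), p)
  }
  if (!is.null(report$shifts))
    p <- check_required(report$shifts, c("offsets", "n_matched",
                                         "records"), "shifts", p)
  if (!is.null(report$rog))
    p <- check_required(report$rog, c("summary", "residues"), "rog", p)
  if (length(p)) {
    if (error) stop("report schema violations:\n  ",
                    paste(p, collapse = "\n  "))
    return(p)
  }
  invisible(TRUE)
}
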