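#' Reporting-engine threshold configuration
#'
#' Every numeric threshold of the reporting algorithm lives here, never
#' inline in the rules: serum-index behaviour is analyzer-specific, so each
#' laboratory must be able to substitute its own validated values.
#'
#' Strictness follows the algorithm's wording: "exceeds" thresholds
#' (`icterus_trigger`, `h_trigger`, `fhb_review`) are strict `>`,
#' `tbil_restrict` is `>=` ("equal to or greater"), and "below" bounds
#' (`tbil_review_ceiling`, `lipemic_report_max`) are strict `<`.
#'
#' @param icterus_trigger Icterus index above which total bilirubin must be
#'   measured before reporting (analyzer units; default 4).
#' @param tbil_restrict Total bilirubin at or above which fHb is reported
#'   only on prior clinician request (umol/L; default 75).
#' @param h_trigger Hemolysis index above which venipuncture must be
#'   verified (analyzer units; default 10, ~100 mg/L fHb).
#' @param fhb_review fHb above which sampling is reviewed when bilirubin is
#'   unremarkable (mg/L; default 200).
#' @param tbil_review_ceiling Total bilirubin below which the `fhb_review`
#'   rule applies (umol/L; default 100).
#' @param lipemic_report_max fHb below which a lipemic sample may still be
#'   reported with an annotation (mg/L; default 50).
#' @param h_to_fhb_factor mg/L free hemoglobin per hemolysis-index unit
#'   (default 10).
#' @param i_to_tbil_factor umol/L total bilirubin per icterus-index unit
#'   (default 69).
#' @param rel_delta_threshold Relative inter-method difference regarded as
#'   clinically significant icteric interference (fraction in (0, 1];
#'   default 0.5).
#' @return An object of class `threshold_config` (a validated named list).
#' @examples
#' threshold_config()
#' threshold_config(tbil_restrict = 90)
#' @export
threshold_config <- function(icterus_trigger = 4,
                             tbil_restrict = 75,
                             h_trigger = 10,
                             fhb_review = 200,
                             tbil_review_ceiling = 100,
                             lipemic_report_max = 50,
                             h_to_fhb_factor = 10,
                             i_to_tbil_factor = 69,
                             rel_delta_threshold = 0.5) {
  cfg <- list(
    icterus_trigger = icterus_trigger,
    tbil_restrict = tbil_restrict,
    h_trigger = h_trigger,
    fhb_review = fhb_review,
    tbil_review_ceiling = tbil_review_ceiling,
    lipemic_report_max = lipemic_report_max,
    h_to_fhb_factor = h_to_fhb_factor,
    i_to_tbil_factor = i_to_tbil_factor,
    rel_delta_threshold = rel_delta_threshold
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("threshold `", nm, "` must be a single positive number"),
            class = "freehb_input_error")
    }
    cfg[[nm]] <- as.numeric(v)
  }
  if (cfg$rel_delta_threshold > 1) {
    abort("`rel_delta_threshold` must lie in (0, 1]", class = "freehb_input_error")
  }
  structure(cfg, class = "threshold_config")
}

#' Read a threshold configuration from a YAML file
#'
#' Absent keys take the package defaults; unknown keys are rejected so a
#' typo cannot silently leave a threshold at its default.
#'
#' @param path Path to a YAML mapping of [threshold_config()] fields.
#' @return A `threshold_config`.
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "freehb_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(threshold_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown threshold key(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")),
          class = "freehb_input_error")
  }
  do.call(threshold_config, raw)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
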