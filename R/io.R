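#' Read a sample table from CSV with schema validation
#'
#' The CSV dialect is pinned: UTF-8, comma delimiter, dot decimal
#' separator, header required. Three schemas are supported:
#'
#' * `"absorbance"` — `sample_id`, `a380`, `a415`, `a450` (Harboe input).
#' * `"panel"` — the full reporting-engine schema (`sample_id`, indices,
#'   `fhb_mg_l`, `tbil_umol_l`, `dbil_umol_l`, context booleans; empty
#'   cells in the concentration columns mean "not measured").
#' * `"paired"` — `fhb`, `efhb` (mg/L) with optional `tbil`, `dbil` for
#'   the method-comparison and cut-off analyses.
#'
#' Every validation failure names the file, data row (1-based, header
#' excluded) and column.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"absorbance"`, `"panel"`, `"paired"`.
#' @return A typed tibble; for `"panel"` the columns are renamed to the
#'   [decide_reports()] field names (`fhb`, `tbil`, `dbil`).
#' @export
read_samples <- function(path, schema = c("panel", "absorbance", "paired")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "freehb_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0(path, ": no records"), class = "freehb_input_error")
  }
  sch <- schema_spec(schema)
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "freehb_input_error")
  }
  out <- tibble::as_tibble(raw)
  for (col in intersect(c(sch$numeric, sch$optional_numeric), names(out))) {
    optional <- col %in% sch$optional_numeric
    out[[col]] <- parse_numeric_col(out[[col]], path, col, optional)
  }
  for (col in intersect(sch$boolean, names(out))) {
    out[[col]] <- parse_boolean_col(out[[col]], path, col)
  }
  if (schema == "panel") {
    out <- dplyr::rename(out, fhb = "fhb_mg_l", tbil = "tbil_umol_l",
                         dbil = "dbil_umol_l")
    bad <- which(!is.na(out$tbil) & !is.na(out$dbil) & out$dbil > out$tbil)
    if (length(bad)) {
      abort(paste0(path, ": row ", bad[1],
                   ", column dbil_umol_l: dbil exceeds tbil"),
            class = "freehb_input_error")
    }
  }
  out
}

schema_spec <- function(schema) {
  switch(
    schema,
    absorbance = list(
      required = c("sample_id", "a380", "a415", "a450"),
      numeric = c("a380", "a415", "a450"),
      optional_numeric = character(), boolean = character()
    ),
    panel = list(
      required = c("sample_id", "h_index", "i_index", "l_index", "fhb_mg_l",
                   "tbil_umol_l", "dbil_umol_l", "lipemia_present",
                   "parenteral_nutrition", "nutrition_discontinuable",
                   "propofol_sedation", "sedation_adjustable",
                   "venipuncture_verified", "clinician_requested"),
      numeric = c("h_index", "i_index", "l_index"),
      optional_numeric = c("fhb_mg_l", "tbil_umol_l", "dbil_umol_l",
                           "efhb", "true_fhb", "true_interference"),
      boolean = c("lipemia_present", "parenteral_nutrition",
                  "nutrition_discontinuable", "propofol_sedation",
                  "sedation_adjustable", "venipuncture_verified",
                  "clinician_requested")
    ),
    paired = list(
      required = c("fhb", "efhb"),
      numeric = c("fhb", "efhb"),
      optional_numeric = c("tbil", "dbil", "bilirubin"),
      boolean = character()
    )
  )
}

parse_numeric_col <- function(v, path, col, optional) {
  blank <- is.na(v) | trimws(v) == ""
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!blank & is.na(num))
  if (length(bad)) {
    abort(paste0(path, ": row ", bad[1], ", column ", col,
                 ": not numeric (", v[bad[1]], ")"),
          class = "freehb_input_error")
  }
  if (!optional && any(blank)) {
    abort(paste0(path, ": row ", which(blank)[1], ", column ", col,
                 ": missing value"),
          class = "freehb_input_error")
  }
  num
}

parse_boolean_col <- function(v, path, col) {
  lv <- tolower(trimws(v))
  ok <- lv %in% c("true", "false")
  if (any(!ok)) {
    bad <- which(!ok)[1]
    abort(paste0(path, ": row ", bad, ", column ", col,
                 ": not a true/false value (", v[bad], ")"),
          class = "freehb_input_error")
  }
  lv == "true"
}

#' Write reporting decisions to CSV
#'
#' Columns, in fixed order: `sample_id`, `status`, `annotations`
#' (semicolon-joined codes) and `rule_trace` (JSON-encoded evaluation
#' trace).
#'
#' @param decisions A decision tibble from [decide_reports()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  out <- tibble::tibble(
    sample_id = decisions$sample_id,
    status = decisions$status,
    annotations = purrr::map_chr(decisions$annotations, paste, collapse = ";"),
    rule_trace = purrr::map_chr(decisions$rule_trace, function(tr) {
      jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA, na = "null")
    })
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read reporting decisions back from CSV
#'
#' Inverse of [write_decisions()]: annotations are split back into
#' character vectors and the rule trace is decoded from JSON.
#'
#' @param path A CSV written by [write_decisions()].
#' @return A tibble with `sample_id`, `status`, `annotations` (list-column)
#'   and `rule_trace` (list-column of data frames).
#' @export
read_decisions <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tibble::tibble(
    sample_id = raw$sample_id,
    status = raw$status,
    annotations = purrr::map(raw$annotations, function(a) {
      if (is.na(a) || a == "") character() else strsplit(a, ";", fixed = TRUE)[[1]]
    }),
    rule_trace = purrr::map(raw$rule_trace, function(j) {
      tibble::as_tibble(jsonlite::fromJSON(j, simplifyDataFrame = TRUE))
    })
  )
}

#' Serialize a method-comparison result to JSON
#'
#' Numbers are written at full precision so a read-back reproduces the
#' result to at least 12 significant digits.
#'
#' @param result An `fhb_comparison` from [compare_methods()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(result, path) {
  stopifnot(inherits(result, "fhb_comparison"))
  payload <- list(
    n = result$n, ci_level = result$ci_level,
    pb_slope = result$pb$slope, pb_slope_ci = result$pb$slope_ci,
    pb_intercept = result$pb$intercept,
    pb_intercept_ci = result$pb$intercept_ci,
    spearman_rho = result$sp$rho, spearman_rho_ci = result$sp$rho_ci,
    spearman_p = result$sp$p_value,
    ba_bias = result$ba$bias, ba_bias_ci = result$ba$bias_ci,
    ba_loa_low = result$ba$loa_low, ba_loa_high = result$ba$loa_high,
    difference_direction = result$ba$difference_direction
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a method-comparison JSON written by [write_comparison_json()]
#'
#' @param path JSON path.
#' @return A named list of the serialized fields.
#' @export
read_comparison_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write a cohort or measurement table to CSV
#'
#' Plain deterministic CSV in the pinned dialect; thin wrapper kept so
#' every file the package writes goes through one code path.
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}
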