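#' @name reporting
#' @title Interference-aware fHb reporting engine
#'
#' @description
#' The engine decides whether and how a plasma free hemoglobin result is
#' released, walking four steps in fixed order and stopping at the first
#' blocking outcome while non-blocking annotations accumulate:
#'
#' 1. **Icterus.** An icterus index above `icterus_trigger` demands a total
#'    bilirubin measurement (`NEEDS_TBIL` if absent). At or above
#'    `tbil_restrict` the spectrophotometric result is compromised by
#'    bilirubin, so it is released only on prior clinician request
#'    (`CLINICIAN_REQUEST_ONLY`); resampling is never recommended for
#'    icterus because the index will not change in a fresh draw.
#' 2. **Hemolysis.** An index above `h_trigger` with unverified venipuncture
#'    means possible preanalytical (in vitro) hemolysis:
#'    `VERIFY_PREANALYTICS`.
#' 3. **Lipemia.** If the source is modifiable (discontinuable parenteral
#'    nutrition, adjustable propofol sedation) a fresh sample is requested
#'    (`REQUEST_NEW_SAMPLE`); otherwise a low fHb (< `lipemic_report_max`)
#'    is released annotated `LIPEMIC_SAMPLE`, and a high one goes to the
#'    clinician (`CLINICIAN_REQUEST_ONLY`).
#' 4. **Severe hemolysis review.** fHb above `fhb_review` with total
#'    bilirubin below `tbil_review_ceiling` and unverified venipuncture
#'    triggers a sampling review (`VERIFY_PREANALYTICS`, `REVIEW_SAMPLING`).
#'
#' If no rule blocks, the status is `REPORT`, promoted to
#' `REPORT_WITH_ANNOTATION` when annotations accumulated.
NULL

# status vocabulary, in no particular order
fhb_statuses <- function() {
  c("REPORT", "REPORT_WITH_ANNOTATION", "CLINICIAN_REQUEST_ONLY",
    "REQUEST_NEW_SAMPLE", "VERIFY_PREANALYTICS", "NEEDS_TBIL")
}

#' Decide reporting of a single sample
#'
#' @param sample_id Sample label used in error messages.
#' @param h_index,i_index,l_index Analyzer serum indices (>= 0). `l_index`
#'   is carried for completeness; lipemia handling keys on
#'   `lipemia_present`, since index-to-turbidity mapping is qualitative.
#' @param fhb Harboe free hemoglobin, mg/L (`NA` until measured).
#' @param tbil,dbil Total / conjugated bilirubin, umol/L (`NA` if not
#'   measured; `dbil <= tbil` when both present).
#' @param lipemia_present Visible or index-flagged lipemia.
#' @param parenteral_nutrition,nutrition_discontinuable Parenteral nutrition
#'   status and whether it can be paused for a fresh draw.
#' @param propofol_sedation,sedation_adjustable Propofol sedation status and
#'   whether the protocol can be adjusted.
#' @param venipuncture_verified Phlebotomy already confirmed atraumatic.
#' @param clinician_requested Result release pre-agreed with the clinician.
#' @param config A [threshold_config()].
#' @return A list with `status` (one of `REPORT`, `REPORT_WITH_ANNOTATION`,
#'   `CLINICIAN_REQUEST_ONLY`, `REQUEST_NEW_SAMPLE`, `VERIFY_PREANALYTICS`,
#'   `NEEDS_TBIL`), `annotations` (character vector of codes) and
#'   `rule_trace` (tibble of every rule evaluated, in order, with whether it
#'   fired, the inputs it consulted, and the status it set, if any).
#' @examples
#' decide_sample(i_index = 5, tbil = 120, fhb = 150)$status
#' @export
decide_sample <- function(sample_id = NA_character_,
                          h_index = 0, i_index = 0, l_index = 0,
                          fhb = NA_real_, tbil = NA_real_, dbil = NA_real_,
                          lipemia_present = FALSE,
                          parenteral_nutrition = FALSE,
                          nutrition_discontinuable = FALSE,
                          propofol_sedation = FALSE,
                          sedation_adjustable = FALSE,
                          venipuncture_verified = FALSE,
                          clinician_requested = FALSE,
                          config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  validate_record(sample_id, h_index, i_index, l_index, fhb, tbil, dbil,
                  lipemia_present, parenteral_nutrition,
                  nutrition_discontinuable, propofol_sedation,
                  sedation_adjustable, venipuncture_verified,
                  clinician_requested)

  trace <- list()
  annotations <- character()
  status <- NULL
  log_rule <- function(rule, fired, inputs, outcome = NA_character_) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      rule = rule, fired = fired, inputs = list(inputs), outcome = outcome
    )
  }

  # Step 1 - icterus interference
  icteric <- i_index > config$icterus_trigger
  if (icteric && is.na(tbil)) {
    log_rule("icterus_needs_tbil", TRUE,
             list(i_index = i_index, icterus_trigger = config$icterus_trigger,
                  tbil = NA_real_),
             "NEEDS_TBIL")
    status <- "NEEDS_TBIL"
  } else {
    log_rule("icterus_needs_tbil", FALSE,
             list(i_index = i_index, icterus_trigger = config$icterus_trigger,
                  tbil = tbil))
    if (icteric && tbil >= config$tbil_restrict) {
      annotations <- c(annotations, "ICTERIC_INTERFERENCE")
      if (!clinician_requested) {
        log_rule("icterus_restrict", TRUE,
                 list(tbil = tbil, tbil_restrict = config$tbil_restrict,
                      clinician_requested = clinician_requested),
                 "CLINICIAN_REQUEST_ONLY")
        status <- "CLINICIAN_REQUEST_ONLY"
      } else {
        log_rule("icterus_restrict", TRUE,
                 list(tbil = tbil, tbil_restrict = config$tbil_restrict,
                      clinician_requested = clinician_requested))
      }
    } else {
      log_rule("icterus_restrict", FALSE,
               list(i_index = i_index, tbil = tbil,
                    tbil_restrict = config$tbil_restrict))
    }
  }

  # Step 2 - preanalytical hemolysis check
  if (is.null(status)) {
    fired <- h_index > config$h_trigger && !venipuncture_verified
    log_rule("hemolysis_verify", fired,
             list(h_index = h_index, h_trigger = config$h_trigger,
                  venipuncture_verified = venipuncture_verified),
             if (fired) "VERIFY_PREANALYTICS" else NA_character_)
    if (fired) status <- "VERIFY_PREANALYTICS"
  }

  # Step 3 - lipemia interference
  if (is.null(status)) {
    modifiable <- (parenteral_nutrition && nutrition_discontinuable) ||
      (propofol_sedation && sedation_adjustable)
    fired <- lipemia_present && modifiable
    log_rule("lipemia_resample", fired,
             list(lipemia_present = lipemia_present,
                  parenteral_nutrition = parenteral_nutrition,
                  nutrition_discontinuable = nutrition_discontinuable,
                  propofol_sedation = propofol_sedation,
                  sedation_adjustable = sedation_adjustable),
             if (fired) "REQUEST_NEW_SAMPLE" else NA_character_)
    if (fired) {
      status <- "REQUEST_NEW_SAMPLE"
    } else if (lipemia_present) {
      if (is.na(fhb)) {
        abort(sample_msg(sample_id,
                         "rule `lipemia_report` needs a measured fhb"),
              class = "freehb_input_error")
      }
      annotations <- c(annotations, "LIPEMIC_SAMPLE")
      if (fhb < config$lipemic_report_max) {
        log_rule("lipemia_report", TRUE,
                 list(fhb = fhb, lipemic_report_max = config$lipemic_report_max),
                 "REPORT_WITH_ANNOTATION")
        status <- "REPORT_WITH_ANNOTATION"
      } else {
        log_rule("lipemia_report", FALSE,
                 list(fhb = fhb, lipemic_report_max = config$lipemic_report_max))
        log_rule("lipemia_clinician", TRUE,
                 list(fhb = fhb, lipemic_report_max = config$lipemic_report_max),
                 "CLINICIAN_REQUEST_ONLY")
        status <- "CLINICIAN_REQUEST_ONLY"
      }
    } else {
      log_rule("lipemia_report", FALSE,
               list(lipemia_present = lipemia_present))
    }
  }

  # Step 4 - severe hemolysis sampling review; when tbil was never measured
  # (icterus index below trigger) the icterus-index estimate stands in
  if (is.null(status)) {
    if (is.na(fhb)) {
      abort(sample_msg(sample_id, "rule `fhb_review` needs a measured fhb"),
            class = "freehb_input_error")
    }
    tbil_eff <- if (is.na(tbil)) {
      etbil_from_i_index(i_index, factor = config$i_to_tbil_factor)
    } else {
      tbil
    }
    fired <- fhb > config$fhb_review && tbil_eff < config$tbil_review_ceiling &&
      !venipuncture_verified
    log_rule("fhb_review", fired,
             list(fhb = fhb, fhb_review = config$fhb_review,
                  tbil_eff = tbil_eff,
                  tbil_review_ceiling = config$tbil_review_ceiling,
                  venipuncture_verified = venipuncture_verified),
             if (fired) "VERIFY_PREANALYTICS" else NA_character_)
    if (fired) {
      annotations <- c(annotations, "REVIEW_SAMPLING")
      status <- "VERIFY_PREANALYTICS"
    }
  }

  if (is.null(status)) {
    status <- if (length(annotations)) "REPORT_WITH_ANNOTATION" else "REPORT"
  }
  list(status = status, annotations = annotations,
       rule_trace = dplyr::bind_rows(trace))
}

#' Decide reporting for a batch of samples
#'
#' Applies [decide_sample()] to every row of a per-sample panel, preserving
#' order; a summary of status counts is emitted as a message.
#'
#' @param data A data frame with (a subset of) the [decide_sample()] fields
#'   as columns; absent columns take the single-sample defaults. Must
#'   contain at least one row.
#' @param config A [threshold_config()].
#' @param quiet Suppress the status-count summary message.
#' @return A tibble with columns `sample_id`, `status`, `annotations`
#'   (list-column of character vectors) and `rule_trace` (list-column of
#'   per-sample trace tibbles), one row per input row.
#' @examples
#' fixture_batch() |> decide_reports(quiet = TRUE)
#' @export
decide_reports <- function(data, config = threshold_config(), quiet = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("empty batch: `data` must have at least one row",
          class = "freehb_input_error")
  }
  fields <- setdiff(names(formals(decide_sample)), "config")
  use <- intersect(fields, names(data))
  rows <- data[use]
  decisions <- purrr::pmap(rows, function(...) {
    rec <- list(...)
    tryCatch(
      do.call(decide_sample, c(rec, list(config = config))),
      freehb_input_error = function(e) {
        abort(sample_msg(rec$sample_id %||% NA_character_, conditionMessage(e)),
              class = "freehb_input_error")
      }
    )
  })
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% use) as.character(data$sample_id)
                else NA_character_,
    status = purrr::map_chr(decisions, "status"),
    annotations = purrr::map(decisions, "annotations"),
    rule_trace = purrr::map(decisions, "rule_trace")
  )
  if (!quiet) {
    counts <- table(out$status)
    message("decided ", nrow(out), " sample(s): ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  out
}

validate_record <- function(sample_id, h_index, i_index, l_index, fhb, tbil,
                            dbil, lipemia_present, parenteral_nutrition,
                            nutrition_discontinuable, propofol_sedation,
                            sedation_adjustable, venipuncture_verified,
                            clinician_requested) {
  num <- list(h_index = h_index, i_index = i_index, l_index = l_index)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || !is.finite(v) || v < 0) {
      abort(sample_msg(sample_id, paste0("`", nm, "` must be a single finite non-negative number")),
            class = "freehb_input_error")
    }
  }
  opt <- list(fhb = fhb, tbil = tbil, dbil = dbil)
  for (nm in names(opt)) {
    v <- opt[[nm]]
    if (!(length(v) == 1 && (is.na(v) || (is.numeric(v) && is.finite(v) && v >= 0)))) {
      abort(sample_msg(sample_id, paste0("`", nm, "` must be NA or a finite non-negative number")),
            class = "freehb_input_error")
    }
  }
  if (!is.na(tbil) && !is.na(dbil) && dbil > tbil) {
    abort(sample_msg(sample_id, "`dbil` exceeds `tbil`"),
          class = "freehb_input_error")
  }
  flags <- list(lipemia_present = lipemia_present,
                parenteral_nutrition = parenteral_nutrition,
                nutrition_discontinuable = nutrition_discontinuable,
                propofol_sedation = propofol_sedation,
                sedation_adjustable = sedation_adjustable,
                venipuncture_verified = venipuncture_verified,
                clinician_requested = clinician_requested)
  for (nm in names(flags)) {
    v <- flags[[nm]]
    if (!is.logical(v) || length(v) != 1 || is.na(v)) {
      abort(sample_msg(sample_id, paste0("`", nm, "` must be TRUE or FALSE")),
            class = "freehb_input_error")
    }
  }
  invisible(TRUE)
}

sample_msg <- function(sample_id, msg) {
  if (length(sample_id) == 1 && !is.na(sample_id) &&
      !grepl("^sample ", msg)) {
    paste0("sample ", sample_id, ": ", msg)
  } else {
    msg
  }
}
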