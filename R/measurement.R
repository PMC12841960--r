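#' Compute plasma free hemoglobin from a Harboe absorbance triplet
#'
#' The Harboe method quantifies free hemoglobin directly from plasma
#' absorbances read at 380, 415 and 450 nm. The 415 nm reading sits on the
#' oxyhemoglobin Soret peak; the flanking 380/450 nm readings correct for
#' background (e.g. bilirubin) via the Allen formula:
#'
#' \deqn{fHb\ (mg/L) = 836 \times (2 A_{415} - A_{380} - A_{450})}
#'
#' Near-blank samples can give a slightly negative bracket term; such
#' results are physically meaningless noise and are clamped to zero and
#' flagged rather than raising an error, so batch processing stays total.
#' Absorbances above `linear_max` (default 2.5 AU) are accepted but flagged
#' as beyond typical photometric linearity.
#'
#' @param a380,a415,a450 Numeric vectors of absorbances (AU) at 380, 415 and
#'   450 nm. Must be finite and non-negative; recycled to a common length.
#' @param linear_max Photometric linearity flag threshold in AU (default 2.5).
#' @return A tibble with columns `fhb_mg_l` (clamped concentration, mg/L),
#'   `clamped` (raw formula result was negative) and `out_of_range` (any
#'   absorbance exceeded `linear_max`).
#' @examples
#' compute_fhb(a380 = 0.5, a415 = 1.0, a450 = 0.5)
#' @export
compute_fhb <- function(a380, a415, a450, linear_max = 2.5) {
  n <- max(length(a380), length(a415), length(a450))
  a380 <- rep_len(a380, n)
  a415 <- rep_len(a415, n)
  a450 <- rep_len(a450, n)
  for (nm in c("a380", "a415", "a450")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(paste0("`", nm, "` must be finite numeric"), class = "freehb_input_error")
    }
    if (any(v < 0)) {
      abort(paste0("`", nm, "` contains negative absorbance"), class = "freehb_input_error")
    }
  }
  raw <- 836 * (2 * a415 - a380 - a450)
  tibble::tibble(
    fhb_mg_l = pmax(0, raw),
    clamped = raw < 0,
    out_of_range = a380 > linear_max | a415 > linear_max | a450 > linear_max
  )
}

#' Compute fHb for a table of absorbance triplets
#'
#' Data-frame front end to [compute_fhb()]: takes a table holding one
#' Harboe absorbance triplet per row and appends the result columns.
#'
#' @param data A data frame with numeric columns `a380`, `a415`, `a450`.
#' @param linear_max Photometric linearity flag threshold in AU.
#' @return The input as a tibble with `fhb_mg_l`, `clamped` and
#'   `out_of_range` columns appended.
#' @examples
#' tibble::tibble(a380 = 0.5, a415 = 1.0, a450 = 0.5) |> harboe_fhb()
#' @export
harboe_fhb <- function(data, linear_max = 2.5) {
  need <- c("a380", "a415", "a450")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "freehb_input_error")
  }
  res <- compute_fhb(data$a380, data$a415, data$a450, linear_max = linear_max)
  dplyr::bind_cols(tibble::as_tibble(data), res)
}

#' Estimate free hemoglobin from an analyzer hemolysis index
#'
#' Serum-index channels report semiquantitative interference estimates; one
#' hemolysis-index unit corresponds to roughly 10 mg/L of free hemoglobin
#' on the platform the defaults were established on. Conversion factors are
#' analyzer-specific, so the factor is a parameter.
#'
#' @param h Numeric vector of hemolysis-index values (analyzer units, >= 0).
#' @param factor mg/L of free hemoglobin per index unit (default 10).
#' @return Estimated free hemoglobin, mg/L.
#' @examples
#' efhb_from_h_index(10)  # 100 mg/L
#' @export
efhb_from_h_index <- function(h, factor = 10) {
  check_nonneg(h, "h")
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number", class = "freehb_input_error")
  }
  h * factor
}

#' Estimate total bilirubin from an analyzer icterus index
#'
#' One icterus-index unit corresponds to roughly 69 umol/L of total
#' bilirubin on the platform the defaults were established on; the factor
#' is analyzer-specific and therefore a parameter.
#'
#' @param i Numeric vector of icterus-index values (analyzer units, >= 0).
#' @param factor umol/L of total bilirubin per index unit (default 69).
#' @return Estimated total bilirubin, umol/L.
#' @examples
#' etbil_from_i_index(1)  # 69 umol/L
#' @export
etbil_from_i_index <- function(i, factor = 69) {
  check_nonneg(i, "i")
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number", class = "freehb_input_error")
  }
  i * factor
}

#' Convert free hemoglobin from mg/L to mg/dL
#'
#' Clinical thresholds for hemolysis on extracorporeal support are often
#' quoted in mg/dL (e.g. the 50 mg/dL action level), while laboratory
#' reports here use mg/L; conversion is explicit, never inferred.
#'
#' @param value Free hemoglobin in mg/L (non-negative numeric vector).
#' @return The same concentrations in mg/dL.
#' @examples
#' convert_fhb_units(500)  # 50 mg/dL
#' @export
convert_fhb_units <- function(value) {
  check_nonneg(value, "value")
  value / 10
}

#' Append index-derived analyte estimates to a sample table
#'
#' Converts the hemolysis and icterus index columns of a per-sample panel
#' to estimated free hemoglobin (`efhb_mg_l`) and estimated total bilirubin
#' (`etbil_umol_l`) using configurable analyzer factors.
#'
#' @param data A data frame with numeric columns `h_index` and `i_index`.
#' @param h_factor mg/L per hemolysis-index unit (default 10).
#' @param i_factor umol/L per icterus-index unit (default 69).
#' @return The input as a tibble with `efhb_mg_l` and `etbil_umol_l` added.
#' @export
estimate_from_indices <- function(data, h_factor = 10, i_factor = 69) {
  missing_cols <- setdiff(c("h_index", "i_index"), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "freehb_input_error")
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      efhb_mg_l = efhb_from_h_index(.data$h_index, factor = h_factor),
      etbil_umol_l = etbil_from_i_index(.data$i_index, factor = i_factor)
    )
}

# shared validator: finite, non-negative numeric
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0("`", name, "` must be finite numeric"), class = "freehb_input_error")
  }
  if (any(x < 0)) {
    abort(paste0("`", name, "` must be non-negative"), class = "freehb_input_error")
  }
  invisible(x)
}
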