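#' Parameters of the synthetic ECMO cohort generator
#'
#' The generator emulates the statistical structure of paired plasma free
#' hemoglobin measurements in an ECMO population: strongly right-skewed
#' fHb and bilirubin marginals (log-normal, medians 261 mg/L and
#' 82 umol/L), a constant negative offset of the index-estimated efHb
#' relative to the Harboe fHb, and a bilirubin-dependent inflation of the
#' Harboe channel that switches on above an interference onset. fHb and
#' total bilirubin are drawn from a Gaussian copula on the log scale
#' (correlation `log_correlation`), reflecting that intravascular
#' hemolysis itself raises bilirubin.
#'
#' @param n Cohort size (default 61).
#' @param fhb_log_median Median of true fHb, mg/L (default 261).
#' @param fhb_log_sd Log-scale SD of fHb (default 1.0).
#' @param tbil_log_median Median of total bilirubin, umol/L (default 82).
#' @param tbil_log_sd Log-scale SD of total bilirubin (default 0.8).
#' @param log_correlation Correlation of log fHb and log tBil (default 0.6).
#' @param dbil_fraction_shape1,dbil_fraction_shape2 Beta shapes for the
#'   conjugated fraction dBil/tBil (defaults 6 and 4; mean 0.6).
#' @param method_offset Constant offset of efHb relative to true fHb at low
#'   bilirubin, mg/L (default -91).
#' @param method_slope Proportional term of efHb vs true fHb (default 1).
#' @param interference_onset Total bilirubin above which icteric
#'   interference inflates the Harboe channel, umol/L (default 75).
#' @param interference_gain mg/L of spurious Harboe signal per umol/L of
#'   bilirubin above the onset (default 20; 0 disables interference).
#' @param interference_smoothness Softplus width in umol/L for a smooth
#'   interference ramp; 0 (default) gives a hard onset.
#' @param noise_sd Additive measurement noise SD on both channels, mg/L
#'   (default 15).
#' @param lipemia_rate Probability a sample is lipemic (default 0.15).
#' @param h_to_fhb_factor,i_to_tbil_factor Analyzer conversion factors used
#'   to derive the serum indices from the generated concentrations
#'   (defaults 10 and 69), keeping generator and measurement module
#'   consistent by construction.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n = 61,
                          fhb_log_median = 261, fhb_log_sd = 1.0,
                          tbil_log_median = 82, tbil_log_sd = 0.8,
                          log_correlation = 0.6,
                          dbil_fraction_shape1 = 6, dbil_fraction_shape2 = 4,
                          method_offset = -91, method_slope = 1.0,
                          interference_onset = 75, interference_gain = 20,
                          interference_smoothness = 0,
                          noise_sd = 15, lipemia_rate = 0.15,
                          h_to_fhb_factor = 10, i_to_tbil_factor = 69) {
  p <- as.list(environment())
  if (!is.numeric(p$n) || length(p$n) != 1 || p$n < 2 || p$n != floor(p$n)) {
    abort("`n` must be an integer >= 2", class = "freehb_input_error")
  }
  pos <- c("fhb_log_median", "fhb_log_sd", "tbil_log_median", "tbil_log_sd",
           "dbil_fraction_shape1", "dbil_fraction_shape2", "method_slope",
           "interference_onset", "h_to_fhb_factor", "i_to_tbil_factor")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"),
            class = "freehb_input_error")
    }
  }
  nonneg <- c("interference_gain", "interference_smoothness", "noise_sd")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(paste0("`", nm, "` must be a single non-negative number"),
            class = "freehb_input_error")
    }
  }
  if (abs(p$log_correlation) >= 1) {
    abort("`log_correlation` must lie in (-1, 1)", class = "freehb_input_error")
  }
  if (p$lipemia_rate < 0 || p$lipemia_rate > 1) {
    abort("`lipemia_rate` must lie in [0, 1]", class = "freehb_input_error")
  }
  structure(p, class = "cohort_params")
}

#' Simulate a synthetic ECMO cohort of paired fHb measurements
#'
#' Per sample: true fHb and total bilirubin are drawn log-normal (Gaussian
#' copula on the log scale), conjugated bilirubin is a Beta-distributed
#' fraction of total, the comparator channel is
#' `efhb = max(0, method_slope * fhb_true + method_offset + noise)`, and
#' the observed Harboe channel is
#' `fhb = max(0, fhb_true + interference + noise)` where the interference
#' term `interference_gain * max(0, tbil - interference_onset)` inflates
#' the spectrophotometric reading above the bilirubin onset. Serum indices
#' are back-derived from the generated concentrations through the same
#' conversion factors the measurement functions use. Output is
#' deterministic given `seed` and leaves the caller's RNG state untouched.
#'
#' @param n Cohort size; overrides `params$n` when supplied.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param params A [cohort_params()].
#' @return A tibble with one row per sample: reporting-engine columns
#'   (`sample_id`, indices, `fhb`, `efhb`, `tbil`, `dbil`, context flags)
#'   plus latent truths `true_fhb` and `true_interference`.
#' @examples
#' simulate_cohort(n = 61, seed = 42)
#' @export
simulate_cohort <- function(n = NULL, seed = NULL, params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(n)) {
    params$n <- n
    params <- do.call(cohort_params, unclass(params))
  }
  n <- params$n
  with_local_seed(seed, {
    z1 <- rnorm(n)
    z2 <- params$log_correlation * z1 +
      sqrt(1 - params$log_correlation^2) * rnorm(n)
    fhb_true <- exp(log(params$fhb_log_median) + params$fhb_log_sd * z1)
    tbil <- exp(log(params$tbil_log_median) + params$tbil_log_sd * z2)
    dbil <- tbil * stats::rbeta(n, params$dbil_fraction_shape1,
                                params$dbil_fraction_shape2)
    interference <- interference_term(tbil, params)
    efhb <- pmax(0, params$method_slope * fhb_true + params$method_offset +
                   rnorm(n, sd = params$noise_sd))
    fhb_obs <- pmax(0, fhb_true + interference + rnorm(n, sd = params$noise_sd))
    lipemia <- rbinom(n, 1, params$lipemia_rate) == 1
    pn <- lipemia & rbinom(n, 1, 0.7) == 1
    pn_disc <- pn & rbinom(n, 1, 0.5) == 1
    prop <- rbinom(n, 1, 0.3) == 1
    prop_adj <- prop & rbinom(n, 1, 0.5) == 1
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      h_index = efhb / params$h_to_fhb_factor,
      i_index = tbil / params$i_to_tbil_factor,
      l_index = ifelse(lipemia, 3, 0),
      fhb = fhb_obs,
      efhb = efhb,
      tbil = tbil,
      dbil = dbil,
      lipemia_present = lipemia,
      parenteral_nutrition = pn,
      nutrition_discontinuable = pn_disc,
      propofol_sedation = prop,
      sedation_adjustable = prop_adj,
      venipuncture_verified = rbinom(n, 1, 0.5) == 1,
      clinician_requested = rbinom(n, 1, 0.2) == 1,
      true_fhb = fhb_true,
      true_interference = interference
    )
  })
}

# additive icteric interference on the Harboe channel; softplus ramp when
# smoothness > 0, hard hinge otherwise
interference_term <- function(tbil, params) {
  if (params$interference_gain == 0) return(rep(0, length(tbil)))
  s <- params$interference_smoothness
  excess <- tbil - params$interference_onset
  if (s > 0) {
    params$interference_gain * s * log1p(exp(excess / s))
  } else {
    params$interference_gain * pmax(0, excess)
  }
}

#' Hand-authored 12-sample fixture exercising every reporting branch
#'
#' A fixed batch covering each reporting-engine outcome at least once:
#' plain reporting, the reflex bilirubin request (exactly one sample),
#' icteric restriction with and without a prior clinician request,
#' preanalytical verification on a high hemolysis index, both
#' new-sample lipemia branches (parenteral nutrition, propofol), lipemic
#' reporting below and referral above the reportability bound, the severe
#' hemolysis sampling review, and a combined icterus-plus-lipemia case.
#'
#' @return A tibble of 12 sample records in the [decide_reports()] schema.
#' @examples
#' fixture_batch() |> decide_reports(quiet = TRUE)
#' @export
fixture_batch <- function() {
  tibble::tribble(
    ~sample_id, ~h_index, ~i_index, ~l_index, ~fhb, ~tbil, ~dbil,
    ~lipemia_present, ~parenteral_nutrition, ~nutrition_discontinuable,
    ~propofol_sedation, ~sedation_adjustable, ~venipuncture_verified,
    ~clinician_requested,
    # plain report, everything benign
    "F01", 2, 1, 0, 40, 10, 5, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # icterus trigger with no bilirubin measured yet -> reflex request
    "F02", 2, 6, 0, NA, NA, NA, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # restricted icteric sample, no prior clinician contact
    "F03", 2, 5, 0, 300, 120, 60, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # same, but the clinician asked for it -> annotated release
    "F04", 2, 5, 0, 150, 120, 60, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
    # high hemolysis index, venipuncture unverified
    "F05", 15, 1, 0, 160, 20, 10, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # high hemolysis index but venipuncture already verified
    "F06", 15, 1, 0, 120, 20, 10, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
    # lipemia from discontinuable parenteral nutrition
    "F07", 2, 1, 3, 60, 15, 8, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
    # lipemia from adjustable propofol sedation
    "F08", 2, 1, 3, 60, 15, 8, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
    # unavoidable lipemia, low fHb -> annotated release
    "F09", 2, 1, 3, 30, 15, 8, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # unavoidable lipemia, fHb at/above the reportability bound
    "F10", 2, 1, 3, 80, 15, 8, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # severe hemolysis with unremarkable bilirubin -> sampling review
    "F11", 8, 1, 0, 250, 50, 20, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    # combined icterus (clinician aware) + unavoidable lipemia, low fHb
    "F12", 2, 5, 3, 30, 120, 60, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE
  )
}

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
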