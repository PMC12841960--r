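# Independent brute-force Passing-Bablok oracle: explicit double loop over
# all i < j pairs, exclusions and K-offset applied by direct enumeration.
# Deliberately naive; shares no code with the package implementation.
pb_oracle <- function(x, y) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) ifelse(dy > 0, Inf, -Inf) else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  n_s <- length(slopes)
  k <- sum(slopes < -1)
  b <- if (n_s %% 2 == 1) {
    slopes[k + (n_s + 1) / 2]
  } else {
    (slopes[k + n_s / 2] + slopes[k + n_s / 2 + 1]) / 2
  }
  list(slope = b, intercept = median(y - b * x))
}

# a fully benign reporting record; override fields of interest
benign_record <- function(...) {
  utils::modifyList(
    list(sample_id = "T", h_index = 0, i_index = 0, l_index = 0,
         fhb = 40, tbil = 10, dbil = 5,
         lipemia_present = FALSE, parenteral_nutrition = FALSE,
         nutrition_discontinuable = FALSE, propofol_sedation = FALSE,
         sedation_adjustable = FALSE, venipuncture_verified = FALSE,
         clinician_requested = FALSE),
    list(...)
  )
}

decide_with <- function(...) do.call(decide_sample, benign_record(...))

# random reporting record generator for property tests
random_record <- function() {
  tbil <- if (runif(1) < 0.2) NA_real_ else runif(1, 0, 300)
  dbil <- if (is.na(tbil)) NA_real_ else tbil * runif(1)
  benign_record(
    h_index = runif(1, 0, 30), i_index = runif(1, 0, 8),
    l_index = runif(1, 0, 5), fhb = runif(1, 0, 1000),
    tbil = tbil, dbil = dbil,
    lipemia_present = runif(1) < 0.3,
    parenteral_nutrition = runif(1) < 0.3,
    nutrition_discontinuable = runif(1) < 0.5,
    propofol_sedation = runif(1) < 0.3,
    sedation_adjustable = runif(1) < 0.5,
    venipuncture_verified = runif(1) < 0.5,
    clinician_requested = runif(1) < 0.3
  )
}
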