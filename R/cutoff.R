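#' Per-sample deltas between the two fHb measurement routes
#'
#' For every sample the absolute inter-method difference
#' `delta = fhb - efhb` (mg/L) and the relative difference
#' `rel_delta = |delta| / fhb` are computed, with the Harboe value as
#' denominator since it is the reference method. Samples with `fhb = 0`
#' carry an undefined (`NA`) `rel_delta` and are excluded downstream.
#'
#' @param data A data frame with numeric columns `bilirubin` (umol/L;
#'   either total or conjugated, whichever axis is under study), `fhb` and
#'   `efhb` (mg/L). Must be non-empty.
#' @return A tibble with `bilirubin`, `fhb`, `efhb`, `delta`, `rel_delta`.
#' @examples
#' tibble::tibble(bilirubin = 50, fhb = 100, efhb = 95) |> compute_deltas()
#' @export
compute_deltas <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("empty input: `data` must have at least one row",
          class = "freehb_input_error")
  }
  need <- c("bilirubin", "fhb", "efhb")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "freehb_input_error")
  }
  for (nm in need) check_nonneg(data[[nm]], nm)
  data |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::mutate(
      delta = .data$fhb - .data$efhb,
      rel_delta = dplyr::if_else(.data$fhb > 0,
                                 abs(.data$delta) / .data$fhb, NA_real_)
    )
}

#' Locate the bilirubin concentration where interference becomes significant
#'
#' Sorts the delta points by bilirubin, smooths the relative inter-method
#' difference with a centered rolling median (edge windows truncated), and
#' reports the smallest bilirubin value from which the smoothed relative
#' difference exceeds `rel_threshold` and stays above it for every larger
#' bilirubin value. The persistence requirement implements the idea of an
#' inflection point beyond which interference compromises the reference
#' method: a single outlying sample cannot set the cut-off.
#'
#' @param points A delta table from [compute_deltas()] (rows with `NA`
#'   `rel_delta` are dropped first).
#' @param rel_threshold Relative-difference threshold regarded as
#'   clinically significant (fraction; default 0.5).
#' @param window Rolling-median window in samples (default 7).
#' @return An object of class `fhb_cutoff` with elements `cutoff` (umol/L,
#'   an observed bilirubin value, or `NA` if never exceeded), `analyte`,
#'   `window`, `rel_threshold`, `n`, and `trace` (tibble of bilirubin vs
#'   rolling-median rel_delta). See [tidy.fhb_cutoff()],
#'   [glance.fhb_cutoff()], [autoplot.fhb_cutoff()].
#' @param analyte Label for the bilirubin axis, `"tBil"` or `"dBil"`.
#' @examples
#' cohort <- simulate_cohort(n = 200, seed = 7)
#' cohort |>
#'   dplyr::transmute(bilirubin = tbil, fhb, efhb) |>
#'   compute_deltas() |>
#'   derive_cutoff()
#' @export
derive_cutoff <- function(points, rel_threshold = 0.5, window = 7,
                          analyte = c("tBil", "dBil")) {
  analyte <- match.arg(analyte)
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1 ||
      !is.finite(rel_threshold) || rel_threshold <= 0 || rel_threshold > 1) {
    abort("`rel_threshold` must lie in (0, 1]", class = "freehb_input_error")
  }
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != floor(window)) {
    abort("`window` must be a positive integer", class = "freehb_input_error")
  }
  pts <- points |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$rel_delta)) |>
    dplyr::arrange(.data$bilirubin)
  n <- nrow(pts)
  if (n < window) {
    abort(paste0("need at least `window` (", window,
                 ") points with defined rel_delta, got ", n),
          class = "freehb_estimation_error")
  }
  half <- (window - 1) %/% 2
  roll <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    median(pts$rel_delta[lo:hi])
  }, numeric(1))
  above <- roll > rel_threshold
  # smallest index from which exceedance persists to the end
  persists <- rev(cumprod(rev(above))) > 0
  cutoff <- if (any(persists)) pts$bilirubin[which(persists)[1]] else NA_real_
  structure(
    list(cutoff = cutoff, analyte = analyte, window = as.integer(window),
         rel_threshold = rel_threshold, n = n,
         trace = tibble::tibble(bilirubin = pts$bilirubin,
                                rel_delta = pts$rel_delta,
                                rolling_median = roll)),
    class = "fhb_cutoff"
  )
}

#' @export
print.fhb_cutoff <- function(x, ...) {
  cat("<fhb_cutoff>", x$analyte, " n =", x$n,
      " window =", x$window, " threshold =", x$rel_threshold, "\n")
  if (is.na(x$cutoff)) {
    cat("  no cut-off detected: rolling-median relative difference never",
        "persistently exceeds the threshold\n")
  } else {
    cat(sprintf("  cut-off: %.1f umol/L\n", x$cutoff))
  }
  invisible(x)
}

#' Tidy the smoothing trace of a cut-off derivation
#'
#' @param x An `fhb_cutoff`.
#' @param ... Unused.
#' @return The trace tibble: `bilirubin`, raw `rel_delta`, and
#'   `rolling_median`.
#' @export
tidy.fhb_cutoff <- function(x, ...) x$trace

#' One-row summary of a cut-off derivation
#'
#' @param x An `fhb_cutoff`.
#' @param ... Unused.
#' @return A one-row tibble with `analyte`, `cutoff`, `rel_threshold`,
#'   `window`, `n`, and `detected`.
#' @export
glance.fhb_cutoff <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, cutoff = x$cutoff,
    rel_threshold = x$rel_threshold, window = x$window, n = x$n,
    detected = !is.na(x$cutoff)
  )
}

#' Plot the relative difference against bilirubin with the detected cut-off
#'
#' @param object An `fhb_cutoff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fhb_cutoff
#' @export
autoplot.fhb_cutoff <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$bilirubin, y = .data$rel_delta)) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rolling_median),
                       colour = "#2166AC") +
    ggplot2::geom_hline(yintercept = object$rel_threshold,
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(x = paste0(object$analyte, " (umol/L)"),
                  y = "Relative difference |fHb - efHb| / fHb",
                  title = "Inter-method divergence vs bilirubin") +
    ggplot2::theme_minimal()
  if (!is.na(object$cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cutoff,
                                 colour = "#B2182B")
  }
  p
}
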