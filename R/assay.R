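#' Bead-event intensity table
#'
#' Per-event fluorescence intensities for one sample/channel, as exported
#' from flow-cytometry analysis software.
#'
#' @param intensity numeric vector of per-event intensities (>= 0, finite).
#' @param sample_id sample identifier.
#' @param marker marker/channel label.
#' @return Object of class `bead_event_table`.
#' @export
bead_event_table <- function(intensity, sample_id = "sample", marker = "marker") {
  if (length(intensity) < 1) stop("empty event table", call. = FALSE)
  .check_num(intensity, "intensity", nonneg = TRUE)
  structure(list(intensity = as.numeric(intensity),
                 sample_id = as.character(sample_id)[1],
                 marker = as.character(marker)[1],
                 n_events = length(intensity)),
            class = "bead_event_table")
}

#' @export
print.bead_event_table <- function(x, ...) {
  cat(sprintf("Bead events: %s / %s, %d events, median intensity %.4g\n",
              x$sample_id, x$marker, x$n_events, median(x$intensity)))
  invisible(x)
}

#' Summarize bead events to a median intensity
#'
#' The per-sample intensity `I` is the median fluorescence intensity (MFI)
#' of the recorded events; for an even event count the mean of the two
#' central order statistics is used.
#'
#' @param events a [bead_event_table()] or numeric vector of intensities.
#' @return Median intensity (scalar).
#' @export
summarize_events <- function(events) {
  x <- if (inherits(events, "bead_event_table")) events$intensity else events
  if (length(x) < 1) stop("empty event table", call. = FALSE)
  .check_num(x, "intensity")
  median(x)
}

#' Background-corrected and EV-normalized marker intensities
#'
#' `dI_M = I_M - I_IgG` subtracts the isotype-control background;
#' `xi_M = dI_M / dI_CD63` normalizes the marker signal to EV abundance via
#' the reference EV marker CD63. `xi` is undefined (returned as `NA` with
#' `xi_defined = FALSE`) when `dI_CD63 <= 0`.
#'
#' @param I_M marker intensity (median MFI).
#' @param I_IgG isotype-IgG control intensity.
#' @param dI_CD63 background-corrected CD63 intensity of the same sample.
#' @return A list with `dI`, `xi`, and `xi_defined`.
#' @export
normalize_marker <- function(I_M, I_IgG, dI_CD63 = NULL) {
  .check_num(I_M, "I_M")
  .check_num(I_IgG, "I_IgG")
  dI <- I_M - I_IgG
  if (is.null(dI_CD63))
    return(list(dI = dI, xi = NULL, xi_defined = NA))
  .check_num(dI_CD63, "dI_CD63")
  defined <- dI_CD63 > 0
  xi <- ifelse(defined, dI / dI_CD63, NA_real_)
  list(dI = dI, xi = xi, xi_defined = defined)
}

#' Target-to-background ratio
#'
#' `(I_target - I_background) / I_background`, the signal contrast of a
#' labeled sample over its isotype control.
#'
#' @param I_target target-channel intensity.
#' @param I_background background (isotype IgG) intensity; must be > 0.
#' @return The ratio.
#' @export
target_to_background <- function(I_target, I_background) {
  .check_num(I_target, "I_target")
  .check_num(I_background, "I_background")
  if (any(I_background <= 0))
    stop("I_background must be > 0", call. = FALSE)
  (I_target - I_background) / I_background
}

#' Titration series container
#'
#' @param concentrations particle concentrations (EVs/mL), ascending.
#' @param intensities matrix of replicate summarized intensities, one row per
#'   concentration.
#' @param blanks replicate blank intensities (>= 2).
#' @param planted_lod optional ground-truth crossing concentration carried by
#'   synthetic series.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(concentrations, intensities, blanks,
                             planted_lod = NULL) {
  .check_num(concentrations, "concentrations", positive = TRUE)
  if (length(concentrations) < 4)
    stop("need at least 4 concentrations", call. = FALSE)
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending", call. = FALSE)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(concentrations))
    stop("one row of intensities per concentration required", call. = FALSE)
  .check_num(as.numeric(intensities), "intensities")
  .check_num(blanks, "blanks")
  if (length(blanks) < 2) stop("need at least 2 blank replicates", call. = FALSE)
  structure(list(concentrations = concentrations, intensities = intensities,
                 blanks = blanks, planted_lod = planted_lod),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration: %d concentrations (%.3g - %.3g EVs/mL), %d replicates, %d blanks\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), ncol(x$intensities), length(x$blanks)))
  invisible(x)
}

#' Detection limit from a titration series
#'
#' The limit of detection (LOD) is the concentration at which the mean
#' response first crosses `mean(blank) + 3 * sd(blank)`, located by linear
#' interpolation in log10-concentration between the bracketing tested
#' concentrations. If the lowest tested concentration already exceeds the
#' threshold the series floor is returned with status `"at_range_floor"`;
#' if no tested concentration crosses it the status is `"above_range"`.
#'
#' @param titration a [titration_series()].
#' @param k_sd threshold multiple of the blank standard deviation (default 3).
#' @return Object of class `lod_estimate`: `lod` (EVs/mL or `NA`),
#'   `threshold`, `status`.
#' @export
estimate_lod <- function(titration, k_sd = 3) {
  stopifnot(inherits(titration, "titration_series"))
  thr <- mean(titration$blanks) + k_sd * sd(titration$blanks)
  m <- rowMeans(titration$intensities)
  conc <- titration$concentrations
  above <- which(m > thr)
  if (!length(above)) {
    out <- list(lod = NA_real_, threshold = thr, status = "above_range")
  } else if (sd(titration$blanks) == 0) {
    # degenerate threshold (zero blank spread): the crossing point is not
    # localizable by interpolation; report the lowest concentration whose
    # response exceeds the blank mean
    out <- list(lod = conc[above[1]], threshold = thr, status = "ok")
  } else if (above[1] == 1L) {
    out <- list(lod = conc[1], threshold = thr, status = "at_range_floor")
  } else {
    i <- above[1]
    lc <- log10(conc[i - 1]) + (thr - m[i - 1]) / (m[i] - m[i - 1]) *
      (log10(conc[i]) - log10(conc[i - 1]))
    out <- list(lod = 10^lc, threshold = thr, status = "ok")
  }
  structure(out, class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  if (x$status == "above_range")
    cat(sprintf("LOD above tested range (threshold %.4g)\n", x$threshold))
  else
    cat(sprintf("LOD = %.4g EVs/mL (threshold %.4g, %s)\n",
                x$lod, x$threshold, x$status))
  invisible(x)
}

#' Convert an EV particle concentration to a molar protein concentration
#'
#' `M = c * 1000 * molecules_per_ev / N_A` for `c` in EVs/mL, with Avogadro's
#' number `N_A = 6.02214e23`. A detection limit of 4.6e5 EVs/mL at ~12 CD63
#' molecules per EV corresponds to about 10 fM of protein.
#'
#' @param c_ev_ml particle concentration (EVs/mL).
#' @param molecules_per_ev average target protein copies per EV (default 12
#'   for CD63).
#' @return Molar concentration (mol/L).
#' @export
ev_concentration_to_molar <- function(c_ev_ml, molecules_per_ev = 12) {
  .check_num(c_ev_ml, "c_ev_ml", nonneg = TRUE)
  .check_num(molecules_per_ev, "molecules_per_ev", nonneg = TRUE)
  c_ev_ml * 1000 * molecules_per_ev / 6.02214e23
}

#' Column-wise z-score standardization
#'
#' Centers each marker column to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator), storing the parameters for later reuse on
#' new samples.
#'
#' @param X numeric matrix (samples x markers).
#' @return A list with the standardized matrix `X`, `center` and `scale`
#'   vectors; class `zscore_transform`.
#' @export
zscore_standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero))
    stop("zero-variance marker column(s): ",
         paste(colnames(X)[zero] %||% zero, collapse = ", "), call. = FALSE)
  structure(list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"),
                 center = ctr, scale = scl),
            class = "zscore_transform")
}

#' @rdname zscore_standardize
#' @param transform a `zscore_transform`.
#' @param newX new data to standardize with the stored parameters.
#' @export
apply_zscore <- function(transform, newX) {
  stopifnot(inherits(transform, "zscore_transform"))
  sweep(sweep(as.matrix(newX), 2, transform$center), 2, transform$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
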