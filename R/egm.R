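# Electrogram construction, clinical-standard filtering, and feature
# extraction (peak amplitudes, peak-to-peak voltage, local activation
# time).

new_egm_trace <- function(t, samples, kind, electrodes, filtered = FALSE) {
  stopifnot(length(t) == length(samples), kind %in% c("unipolar", "bipolar"))
  structure(list(t = t, samples = samples, kind = kind,
                 electrodes = electrodes, filtered = filtered,
                 fs_khz = 1 / (t[2] - t[1])),
            class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat("<egm_trace> ", x$kind, " ", paste(x$electrodes, collapse = "-"),
      ", ", length(x$samples), " samples at ", round(x$fs_khz, 3),
      " kHz", if (x$filtered) ", filtered", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.egm_trace <- function(x, ...) {
  data.frame(t = x$t, phi = x$samples, kind = x$kind,
             electrode = paste(x$electrodes, collapse = "-"),
             filtered = x$filtered)
}

#' Unipolar electrogram from extracellular field snapshots
#'
#' Builds the referenced unipolar electrogram from a series of
#' extracellular fields: mean potential over the electrode voxels minus
#' the mean over the top 1 mm blood layer (the reference; catheter-
#' occupied voxels are not blood-labeled and hence excluded).
#' The scenario pipeline computes the same quantity via lead fields
#' ([lead_vector()]); this explicit route is exact and used for
#' verification and one-off analyses.
#'
#' @param fields List of `extracellular_field` objects.
#' @param grid The `labeled_grid`.
#' @param electrode_label Electrode label name.
#' @param t Sample times, ms.
#' @return An unfiltered `egm_trace`.
#' @export
unipolar_trace <- function(fields, grid, electrode_label, t) {
  wE <- label_weights(grid, electrode_label)
  wR <- reference_weights(grid)
  v <- vapply(fields, function(f) {
    ph <- as.vector(f$phi)
    sum(ph * wE) - sum(ph * wR)
  }, numeric(1))
  new_egm_trace(t, v, "unipolar", electrode_label)
}

#' Bipolar electrogram from two unipolar traces
#'
#' Samplewise difference `u1 - u2` of two unfiltered unipolar traces.
#'
#' @param u1,u2 Unfiltered `egm_trace` objects on the same time base.
#' @return An unfiltered bipolar `egm_trace`.
#' @export
bipolar_trace <- function(u1, u2) {
  stopifnot(inherits(u1, "egm_trace"), inherits(u2, "egm_trace"))
  if (length(u1$samples) != length(u2$samples))
    stop("traces differ in length")
  if (u1$filtered || u2$filtered)
    stop("bipolar traces are built from unfiltered unipolar traces")
  new_egm_trace(u1$t, u1$samples - u2$samples, "bipolar",
                c(u1$electrodes, u2$electrodes))
}

#' Clinical-standard electrogram filtering
#'
#' Causal first-order Butterworth band limiting, applied as a high-pass
#' then a low-pass section: 0.5-250 Hz for unipolar and 30-350 Hz for
#' bipolar electrograms.
#'
#' @param trace An unfiltered `egm_trace`.
#' @param hp_hz,lp_hz Cutoffs; defaults depend on the trace kind.
#' @return The filtered `egm_trace` (marked `filtered = TRUE`).
#' @export
filter_trace <- function(trace, hp_hz = NULL, lp_hz = NULL) {
  stopifnot(inherits(trace, "egm_trace"))
  if (trace$filtered) stop("trace is already filtered")
  if (is.null(hp_hz)) hp_hz <- if (trace$kind == "unipolar") 0.5 else 30
  if (is.null(lp_hz)) lp_hz <- if (trace$kind == "unipolar") 250 else 350
  fs <- trace$fs_khz * 1000
  hp <- signal::butter(1, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(1, lp_hz / (fs / 2), type = "low")
  v <- signal::filter(lp, signal::filter(hp, trace$samples))
  out <- trace
  out$samples <- as.numeric(v)
  out$filtered <- TRUE
  out
}

#' Electrogram features
#'
#' Positive and negative peak amplitudes, peak-to-peak voltage and local
#' activation time (LAT): the instant of steepest downstroke between the
#' maximum and minimum peaks. For traces without RS morphology (maximum
#' after minimum) the LAT is undefined and returned as `NA`.
#'
#' @param trace An `egm_trace` (normally filtered, containing one
#'   activation complex).
#' @return A one-row tibble: `pos_peak_mV`, `neg_peak_mV`, `v_pp_mV`,
#'   `lat_ms`, `lat_defined`.
#' @export
egm_features <- function(trace) {
  stopifnot(inherits(trace, "egm_trace"))
  v <- trace$samples; t <- trace$t
  i_max <- which.max(v); i_min <- which.min(v)
  pos <- v[i_max]; neg <- v[i_min]
  if (i_max < i_min) {
    seg <- i_max:(i_min - 1)
    dv <- diff(v)[seg]
    i_lat <- seg[which.min(dv)]
    lat <- (t[i_lat] + t[i_lat + 1]) / 2
    lat_def <- TRUE
  } else {
    lat <- NA_real_
    lat_def <- FALSE
  }
  tibble::tibble(pos_peak_mV = pos, neg_peak_mV = neg,
                 v_pp_mV = pos - neg, lat_ms = lat, lat_defined = lat_def)
}

#' Reference-normalized peak-to-peak voltages
#'
#' Expresses a sweep of Vpp values as percentages of a reference element,
#' `100 * v_pp / v_pp[reference]`.
#'
#' @param v_pp Numeric vector of peak-to-peak voltages.
#' @param reference_index Index of the reference element, or `"min"` for
#'   each sweep's minimum (the rotation-scenario convention).
#' @return Percentages (the reference maps to 100).
#' @export
relative_vpp <- function(v_pp, reference_index = 1) {
  ref <- if (identical(reference_index, "min")) min(v_pp)
         else v_pp[reference_index]
  if (!isTRUE(ref > 0)) stop("reference Vpp must be positive")
  100 * v_pp / ref
}
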