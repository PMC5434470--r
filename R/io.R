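# CSV and VTK export.

#' Write scenario features to CSV
#'
#' One row per (sweep value, electrode, trace kind) with the feature
#' columns `v_pp_mV`, `pos_peak_mV`, `neg_peak_mV`, `lat_ms`,
#' `rel_vpp_pct`.
#'
#' @param result A `sweep_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(result, path) {
  df <- tibble::as_tibble(result)
  cols <- intersect(c("scenario", "orientation", "parameter", "phase",
                      "electrode", "kind", "v_pp_mV", "pos_peak_mV",
                      "neg_peak_mV", "lat_ms", "rel_vpp_pct"),
                    names(df))
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write electrogram traces to CSV
#'
#' One column per electrode trace (header row gives the electrode ids),
#' sampled at 10 kHz; the first column is time in ms.
#'
#' @param result A `sweep_result` produced with `keep_traces = TRUE`.
#' @param path Output file.
#' @param parameter Which sweep value to export (default: first).
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path, parameter = NULL) {
  tr <- attr(result, "traces")
  if (is.null(tr)) stop("result was produced without keep_traces")
  nm <- if (is.null(parameter)) names(tr)[1] else as.character(parameter)
  set <- tr[[nm]]
  if (is.null(set)) stop("no traces for parameter ", nm)
  df <- data.frame(t_ms = set[[1]]$t)
  for (e in names(set)) df[[e]] <- set[[e]]$samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a voxel field as legacy VTK image data
#'
#' Writes an ASCII VTK `STRUCTURED_POINTS` file for visual inspection of
#' label or conductivity fields (e.g. in ParaView).
#'
#' @param grid A `labeled_grid`.
#' @param path Output file (.vtk).
#' @param fields Character vector of fields to export; any of `"label"`,
#'   `"sigma_i"`, `"sigma_e"`, `"temperature"`.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(grid, path,
                            fields = c("label", "sigma_i", "sigma_e")) {
  stopifnot(inherits(grid, "labeled_grid"))
  dims <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "egmsim voxel fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", grid$h / 2, grid$h / 2,
                       grid$h / 2),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (f in fields) {
    v <- grid[[f]]
    if (is.null(v)) stop("unknown field: ", f)
    writeLines(c(sprintf("SCALARS %s double 1", f),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(as.vector(v), format = "g", digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export an extracellular field as legacy VTK image data
#'
#' @param field An `extracellular_field`.
#' @param path Output file (.vtk).
#' @return `path`, invisibly.
#' @export
write_vtk_phie <- function(field, path) {
  stopifnot(inherits(field, "extracellular_field"))
  dims <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "egmsim extracellular potential", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", field$h / 2, field$h / 2,
                       field$h / 2),
               sprintf("SPACING %g %g %g", field$h, field$h, field$h),
               sprintf("POINT_DATA %d", prod(dims)),
               "SCALARS phi_e double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(formatC(as.vector(field$phi), format = "g",
                           digits = 7), collapse = " "), con)
  invisible(path)
}
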