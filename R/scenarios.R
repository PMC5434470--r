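# End-to-end mapping scenarios: geometry -> propagation -> extracellular
# lead fields -> electrogram features.

#' Simulation configuration
#'
#' Bundles grid, catheter, solver and sweep settings. Two scales are
#' provided: `"scaled"` (default) is a reduced slab that reproduces the
#' study's relative electrogram effects at desk runtimes, `"paper"` is the
#' full-size setup (80 x 24 x 4.8 mm slab, 24.6/6.6 mm blood, h = 0.3 mm).
#' Any element can be overridden.
#'
#' @param scale `"scaled"` or `"paper"`.
#' @param ... Named overrides for elements of the returned list (`grid`,
#'   `catheter`, `params`, `stim`, `t_end`, `sweeps`, ...).
#' @return An `egmsim_config` list.
#' @export
egmsim_config <- function(scale = c("scaled", "paper"), ...) {
  scale <- match.arg(scale)
  cfg <- if (scale == "scaled") {
    list(
      scale = scale,
      grid = grid_spec(tissue_dims = c(40, 16, 4.8), blood_above = 13,
                       blood_below = 3.2, h = 0.4),
      catheter = catheter_spec(shaft_length = 4),
      params = tissue_params(),
      stim = stimulus_spec(),
      t_end = 55)
  } else {
    list(
      scale = scale,
      grid = grid_spec(tissue_dims = c(80, 24, 4.8), blood_above = 24.6,
                       blood_below = 6.6, h = 0.3),
      catheter = catheter_spec(shaft_length = 10),
      params = tissue_params(),
      stim = stimulus_spec(),
      t_end = 115)
  }
  cfg$sweeps <- list(
    tilt = seq(90, 0, by = -15),
    rotation = seq(0, 345, by = 15),
    penetration_O = seq(1.2, 0, by = -0.2),
    penetration_P = seq(0.6, -0.6, by = -0.2),
    lesion_move = seq(-7, 7, by = 1),
    linear_gap = seq(-4, 4, by = 1))
  cfg$lead_tol <- 1e-9
  cfg$keep_traces <- TRUE
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  class(cfg) <- "egmsim_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML run configuration mirroring the [egmsim_config()] fields
#' (`scale`, `grid`, `catheter`, `t_end`, `sweeps`, ...).
#'
#' @param path Path to a YAML file.
#' @return An `egmsim_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  num <- function(x) lapply(x, function(v) unlist(v))
  scale <- y$scale %||% "scaled"
  cfg <- egmsim_config(scale)
  if (!is.null(y$grid)) cfg$grid <- do.call(grid_spec, num(y$grid))
  if (!is.null(y$catheter))
    cfg$catheter <- do.call(catheter_spec, num(y$catheter))
  if (!is.null(y$params)) cfg$params <- do.call(tissue_params, num(y$params))
  if (!is.null(y$stim)) cfg$stim <- do.call(stimulus_spec, num(y$stim))
  if (!is.null(y$t_end)) cfg$t_end <- y$t_end
  if (!is.null(y$sweeps))
    cfg$sweeps <- utils::modifyList(cfg$sweeps, num(y$sweeps))
  cfg
}

unipolar_electrodes <- function() {
  c(D = "electrode_distal", ME1 = "electrode_me1", ME2 = "electrode_me2",
    ME3 = "electrode_me3")
}

bipolar_pairs <- function() {
  list(`ME1-ME2` = c("ME1", "ME2"), `ME2-ME3` = c("ME2", "ME3"),
       `ME3-ME1` = c("ME3", "ME1"), `D-ME1` = c("D", "ME1"),
       `D-ME2` = c("D", "ME2"), `D-ME3` = c("D", "ME3"))
}

# slab-content signature used to share one propagation run among poses
# whose excitable tissue is identical
tissue_signature <- function(dom) {
  kt <- dom$k_tissue
  list(ex = dom$excitable[, , kt], si = dom$sigma_i[, , kt])
}

# Run a list of poses over a common lesion/grid. One monodomain run per
# distinct excitable-tissue configuration; per pose, one elliptic operator
# and four lead-field solves.
simulate_poses <- function(config, poses, lesion = lesion_spec("none"),
                           verbose = FALSE) {
  el <- unipolar_electrodes()
  groups <- list()   # each: list(sig, dom, pose_ids)
  leads <- vector("list", length(poses))
  warm <- list()     # adjoint solutions reused as warm starts across poses
  for (pi in seq_along(poses)) {
    dom <- build_domain(config$grid, config$catheter, poses[[pi]], lesion)
    sig <- tissue_signature(dom)
    gi <- NULL
    for (q in seq_along(groups))
      if (identical(groups[[q]]$sig, sig)) { gi <- q; break }
    if (is.null(gi)) {
      groups[[length(groups) + 1]] <- list(sig = sig, dom = dom,
                                           pose_ids = integer(0))
      gi <- length(groups)
    }
    groups[[gi]]$pose_ids <- c(groups[[gi]]$pose_ids, pi)
    op <- assemble_operator(dom)
    leads[[pi]] <- lapply(el, function(lb) {
      lv <- lead_vector(op, dom, lb, tol = config$lead_tol,
                        warm_start = warm[[lb]])
      warm[[lb]] <<- lv$z
      lv$w
    })
    if (verbose)
      message(sprintf("pose %d/%d: leads solved (group %d)",
                      pi, length(poses), gi))
  }

  traces <- vector("list", length(poses))
  t_axis <- NULL
  for (q in seq_along(groups)) {
    gr <- groups[[q]]
    W <- do.call(cbind, unlist(lapply(gr$pose_ids,
                                      function(pi) leads[[pi]]),
                               recursive = FALSE))
    f <- run_propagation(gr$dom, config$params, config$stim,
                         t_end = config$t_end, leads = W)
    t_axis <- f$t
    for (w in seq_along(gr$pose_ids)) {
      pi <- gr$pose_ids[w]
      cols <- (w - 1) * length(el) + seq_along(el)
      traces[[pi]] <- stats::setNames(
        lapply(seq_along(el), function(e)
          new_egm_trace(f$t, f$lead_traces[, cols[e]], "unipolar",
                        names(el)[e])),
        names(el))
    }
    if (verbose)
      message(sprintf("group %d/%d: propagation done (%d poses)",
                      q, length(groups), length(gr$pose_ids)))
  }
  list(traces = traces, t = t_axis)
}

# features of all unipolar and bipolar traces of one pose
pose_features <- function(utraces) {
  uni <- dplyr::bind_rows(lapply(names(utraces), function(e) {
    ft <- egm_features(filter_trace(utraces[[e]]))
    dplyr::mutate(ft, electrode = e, kind = "unipolar", .before = 1)
  }))
  bip <- dplyr::bind_rows(lapply(names(bipolar_pairs()), function(nm) {
    pr <- bipolar_pairs()[[nm]]
    bt <- bipolar_trace(utraces[[pr[1]]], utraces[[pr[2]]])
    ft <- egm_features(filter_trace(bt))
    dplyr::mutate(ft, electrode = nm, kind = "bipolar", .before = 1)
  }))
  dplyr::bind_rows(uni, bip)
}

filtered_traces <- function(utraces) {
  out <- lapply(utraces, filter_trace)
  for (nm in names(bipolar_pairs())) {
    pr <- bipolar_pairs()[[nm]]
    out[[nm]] <- filter_trace(bipolar_trace(utraces[[pr[1]]],
                                            utraces[[pr[2]]]))
  }
  out
}

new_sweep_result <- function(df, scenario, orientation, config,
                             traces = NULL) {
  structure(df, class = c("sweep_result", class(df)),
            scenario = scenario, orientation = orientation,
            config_scale = config$scale, traces = traces)
}

sweep_table <- function(config, poses, values, lesion, scenario,
                        orientation, reference, verbose = FALSE) {
  sim <- simulate_poses(config, poses, lesion, verbose = verbose)
  tabs <- lapply(seq_along(poses), function(pi)
    dplyr::mutate(pose_features(sim$traces[[pi]]),
                  parameter = values[pi], .before = 1))
  df <- dplyr::bind_rows(tabs)
  df <- dplyr::mutate(df, scenario = scenario, orientation = orientation,
                      .before = 1)
  df <- dplyr::group_by(df, .data$electrode, .data$kind)
  df <- dplyr::mutate(df, rel_vpp_pct = {
    ref <- if (identical(reference, "min")) min(.data$v_pp_mV)
           else .data$v_pp_mV[match(reference, .data$parameter)]
    100 * .data$v_pp_mV / ref
  })
  df <- dplyr::ungroup(df)
  traces <- if (isTRUE(config$keep_traces))
    stats::setNames(lapply(sim$traces, filtered_traces),
                    as.character(values))
  new_sweep_result(df, scenario, orientation, config, traces)
}

healthy_pose <- function(orientation, penetration = NULL,
                         translation = c(0, 0)) {
  if (orientation == "O")
    pose(tilt_deg = 90, rotation_deg = 0,
         penetration_mm = penetration %||% 1.2, translation_mm = translation)
  else
    pose(tilt_deg = 0, rotation_deg = 30,
         penetration_mm = penetration %||% 0, translation_mm = translation)
}

#' Healthy-myocardium scenario
#'
#' Catheter on healthy tissue: orthogonal (tilt 90, penetration 1.2 mm,
#' all MEs in blood) or parallel (tilt 0, gentle contact, rotation 30 so
#' that ME2 touches the tissue). Produces unipolar electrograms for the
#' distal electrode and the three MEs plus the standard bipolar pairs.
#'
#' @param orientation `"O"` (orthogonal) or `"P"` (parallel).
#' @param config An [egmsim_config()].
#' @param verbose Print progress.
#' @return A `sweep_result` tibble (single pose; `rel_vpp_pct` = 100).
#' @export
run_healthy <- function(orientation = c("O", "P"),
                        config = egmsim_config(), verbose = FALSE) {
  orientation <- match.arg(orientation)
  sweep_table(config, list(healthy_pose(orientation)), 0,
              lesion_spec("none"), "healthy", orientation, 0,
              verbose = verbose)
}

#' Tilting-angle sweep
#'
#' Tilts the catheter from orthogonal (90 deg) to parallel (0 deg). The
#' tip-to-surface distance is 0.6 mm at 90 deg and shrinks linearly to
#' gentle contact at 0 deg; rotation is 30 deg so that ME2 faces the
#' tissue when parallel. Vpp is referenced to the 90 deg pose.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with one row per tilt angle and electrode.
#' @export
run_tilt_sweep <- function(config = egmsim_config(), verbose = FALSE) {
  tilts <- config$sweeps$tilt
  poses <- lapply(tilts, function(tt)
    pose(tilt_deg = tt, rotation_deg = 30,
         penetration_mm = -0.6 * tt / 90))
  sweep_table(config, poses, tilts, lesion_spec("none"), "tilt", "OP", 90,
              verbose = verbose)
}

#' Rotation sweep
#'
#' Rotates the catheter about its long axis above healthy myocardium.
#' Each electrode's Vpp is referenced to its own minimum over the sweep.
#' In parallel orientation ME2 faces the tissue at 30 deg.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with one row per rotation angle and electrode.
#' @export
run_rotation_sweep <- function(orientation = c("O", "P"),
                               config = egmsim_config(), verbose = FALSE) {
  orientation <- match.arg(orientation)
  rots <- config$sweeps$rotation
  poses <- lapply(rots, function(rr)
    if (orientation == "O") pose(90, rr, 1.2) else pose(0, rr, 0))
  sweep_table(config, poses, rots, lesion_spec("none"), "rotation",
              orientation, "min", verbose = verbose)
}

#' Penetration-depth sweep
#'
#' Steps the penetration depth down by 0.2 mm from 1.2 mm (orthogonal) or
#' 0.6 mm (parallel); negative depths leave a blood layer between catheter
#' and tissue. Vpp is referenced to the initial pose.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with one row per depth and electrode.
#' @export
run_penetration_sweep <- function(orientation = c("O", "P"),
                                  config = egmsim_config(),
                                  verbose = FALSE) {
  orientation <- match.arg(orientation)
  depths <- if (orientation == "O") config$sweeps$penetration_O
            else config$sweeps$penetration_P
  poses <- lapply(depths, function(d) healthy_pose(orientation, d))
  sweep_table(config, poses, depths, lesion_spec("none"), "penetration",
              orientation, depths[1], verbose = verbose)
}

#' Acute-lesion (border zone) scenario
#'
#' Paired runs with the catheter centrally above a transmural point
#' lesion: before ablation (healthy tissue) and after (necrotic core with
#' a 3 mm exponential-temperature border zone; width/depth ratio 1.25 in
#' O, 1.6 in P). `rel_vpp_pct` references the pre-ablation Vpp; use
#' [lesion_attenuation()] for peak attenuations.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with `parameter` 0 (pre) and 1 (post) and a
#'   `phase` column.
#' @export
run_lesion_border <- function(orientation = c("O", "P"),
                              config = egmsim_config(), verbose = FALSE) {
  orientation <- match.arg(orientation)
  ratio <- if (orientation == "O") 1.25 else 1.6
  lesion <- lesion_spec("point_with_border", width_depth_ratio = ratio)
  pose1 <- healthy_pose(orientation)
  pre <- sweep_table(config, list(pose1), 0, lesion_spec("none"),
                     "lesion_border", orientation, 0, verbose = verbose)
  post <- sweep_table(config, list(pose1), 1, lesion,
                      "lesion_border", orientation, 1, verbose = verbose)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(pre), phase = "pre"),
    dplyr::mutate(tibble::as_tibble(post), phase = "post"))
  df <- dplyr::group_by(df, .data$electrode, .data$kind)
  df <- dplyr::mutate(df, rel_vpp_pct =
    100 * .data$v_pp_mV / .data$v_pp_mV[.data$phase == "pre"])
  df <- dplyr::ungroup(df)
  traces <- c(pre = list(attr(pre, "traces")[[1]]),
              post = list(attr(post, "traces")[[1]]))
  new_sweep_result(df, "lesion_border", orientation, config, traces)
}

#' Peak attenuation by an ablation lesion
#'
#' Percentage attenuation of positive peak, negative peak and Vpp caused
#' by the lesion in a [run_lesion_border()] result:
#' `100 * (1 - |post| / |pre|)`.
#'
#' @param result A `sweep_result` from [run_lesion_border()].
#' @return A tibble with one row per electrode and trace kind.
#' @export
lesion_attenuation <- function(result) {
  stopifnot(attr(result, "scenario") == "lesion_border")
  df <- tibble::as_tibble(result)
  wide <- tidyr::pivot_wider(
    dplyr::select(df, "electrode", "kind", "phase", "pos_peak_mV",
                  "neg_peak_mV", "v_pp_mV"),
    names_from = "phase",
    values_from = c("pos_peak_mV", "neg_peak_mV", "v_pp_mV"))
  dplyr::transmute(
    wide, .data$electrode, .data$kind,
    pos_peak_att_pct = 100 * (1 - abs(.data$pos_peak_mV_post) /
                                abs(.data$pos_peak_mV_pre)),
    neg_peak_att_pct = 100 * (1 - abs(.data$neg_peak_mV_post) /
                                abs(.data$neg_peak_mV_pre)),
    v_pp_att_pct = 100 * (1 - .data$v_pp_mV_post / .data$v_pp_mV_pre))
}

#' Catheter movement over a matured (necrotic-only) lesion
#'
#' Translates the catheter stepwise along the propagation direction over
#' a 13 mm wide transmural necrotic core without border zone. Negative
#' shifts move towards the arriving wavefront. Vpp is referenced to the
#' central position.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with one row per shift and electrode.
#' @export
run_lesion_move <- function(orientation = c("O", "P"),
                            config = egmsim_config(), verbose = FALSE) {
  orientation <- match.arg(orientation)
  lesion <- lesion_spec("point_necrotic_only", necrotic_width = 13)
  shifts <- config$sweeps$lesion_move
  poses <- lapply(shifts, function(s)
    healthy_pose(orientation, translation = c(s, 0)))
  sweep_table(config, poses, shifts, lesion, "lesion_move", orientation, 0,
              verbose = verbose)
}

#' Catheter movement along a linear lesion with a conduction gap
#'
#' A linear transmural lesion (the point-lesion profile swept across the
#' slab) blocks the wavefront except for an excitable conduction gap
#' (width 1.5 mm). The catheter is shifted stepwise along the lesion
#' line; Vpp is referenced to the position above the gap. In parallel
#' orientation the mini electrodes lie above the lesion line.
#'
#' @inheritParams run_healthy
#' @return A `sweep_result` with one row per shift and electrode.
#' @export
run_linear_gap <- function(orientation = c("O", "P"),
                           config = egmsim_config(), verbose = FALSE) {
  orientation <- match.arg(orientation)
  lesion <- lesion_spec("linear_with_gap", necrotic_width = 13)
  shifts <- config$sweeps$linear_gap
  xoff <- if (orientation == "P") -config$catheter$me_offset_from_tip else 0
  poses <- lapply(shifts, function(s)
    healthy_pose(orientation, translation = c(xoff, s)))
  sweep_table(config, poses, shifts, lesion, "linear_gap", orientation, 0,
              verbose = verbose)
}

#' Run a scenario by name
#'
#' Dispatches to the individual scenario functions.
#'
#' @param scenario One of `"healthy"`, `"tilt"`, `"rotation"`,
#'   `"penetration"`, `"lesion_border"`, `"lesion_move"`, `"linear_gap"`.
#' @inheritParams run_healthy
#' @return A `sweep_result`.
#' @export
run_scenario <- function(scenario = c("healthy", "tilt", "rotation",
                                      "penetration", "lesion_border",
                                      "lesion_move", "linear_gap"),
                         orientation = c("O", "P"),
                         config = egmsim_config(), verbose = FALSE) {
  scenario <- match.arg(scenario)
  orientation <- match.arg(orientation)
  switch(scenario,
         healthy = run_healthy(orientation, config, verbose),
         tilt = run_tilt_sweep(config, verbose),
         rotation = run_rotation_sweep(orientation, config, verbose),
         penetration = run_penetration_sweep(orientation, config, verbose),
         lesion_border = run_lesion_border(orientation, config, verbose),
         lesion_move = run_lesion_move(orientation, config, verbose),
         linear_gap = run_linear_gap(orientation, config, verbose))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> scenario:", attr(x, "scenario"),
      " orientation:", attr(x, "orientation"), "\n")
  NextMethod()
}
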