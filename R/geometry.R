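# Voxelized simulation domain: myocardial slab, blood pool, ablation
# catheter with mini electrodes, and radiofrequency lesions.

#' Label codes used in a labeled grid
#'
#' Integer codes identifying the material occupying each voxel. Every voxel
#' carries exactly one label.
#'
#' @return Named integer vector of label codes.
#' @export
egm_labels <- function() {
  c(tissue = 1L, lesion_necrotic = 2L, lesion_border = 3L, blood = 4L,
    electrode_distal = 5L, electrode_me1 = 6L, electrode_me2 = 7L,
    electrode_me3 = 8L, isolation = 9L, shaft = 10L)
}

#' Specify the voxel grid of the simulation domain
#'
#' The domain is a rectangular box: a myocardial slab of size `tissue_dims`
#' with blood layers of thickness `blood_above` and `blood_below` on top and
#' underneath, discretized into cubic voxels of edge length `h`. Axis
#' convention: the planar excitation wavefront propagates along +x, y runs
#' across the slab, z points from the lower blood layer up through the
#' tissue into the upper blood pool.
#'
#' @param tissue_dims Length-3 numeric, slab extent in mm (x, y, z).
#' @param blood_above,blood_below Blood layer thickness above/below the
#'   slab, mm. May be zero for bath-free propagation-only domains.
#' @param h Voxel edge length, mm.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(tissue_dims = c(80, 24, 4.8), blood_above = 24.6,
                      blood_below = 6.6, h = 0.3) {
  stopifnot(length(tissue_dims) == 3, all(tissue_dims > 0), h > 0,
            blood_above >= 0, blood_below >= 0)
  n_tissue <- pmax(round(tissue_dims / h), c(2L, 1L, 2L))
  nz_below <- round(blood_below / h)
  nz_above <- round(blood_above / h)
  if (n_tissue[1] < 2 || n_tissue[3] < 2)
    stop("grid too coarse: fewer than 2 voxels across the slab")
  structure(
    list(tissue_dims = tissue_dims, blood_above = blood_above,
         blood_below = blood_below, h = h,
         n_tissue = as.integer(n_tissue),
         nz_below = as.integer(nz_below), nz_above = as.integer(nz_above),
         dims = as.integer(c(n_tissue[1], n_tissue[2],
                             nz_below + n_tissue[3] + nz_above))),
    class = "grid_spec")
}

#' Specify the ablation catheter
#'
#' An 8 mm nonirrigated tip ablation catheter with three 1 mm mini
#' electrodes (MEs) embedded in the distal electrode near the tip,
#' separated from it by a thin insulating layer, plus an insulated shaft.
#'
#' @param distal_length Distal (tip) electrode length, mm.
#' @param distal_diameter Distal electrode diameter, mm (8F is about 2.7).
#' @param me_diameter Mini-electrode diameter, mm.
#' @param me_offset_from_tip Axial distance from the catheter tip to the ME
#'   centers, mm.
#' @param isolation_thickness Insulation layer thickness around each ME, mm.
#'   At voxel sizes coarser than this value, a one-voxel insulating shell is
#'   still guaranteed around every ME.
#' @param shaft_length Length of the insulated shaft proximal to the distal
#'   electrode, mm.
#' @return A `catheter_spec` object.
#' @export
catheter_spec <- function(distal_length = 8, distal_diameter = 2.7,
                          me_diameter = 1, me_offset_from_tip = 2,
                          isolation_thickness = 0.2, shaft_length = 10) {
  stopifnot(me_diameter < distal_diameter,
            me_offset_from_tip < distal_length,
            distal_length > 0, distal_diameter > 0, shaft_length >= 0,
            isolation_thickness >= 0)
  structure(
    list(distal_length = distal_length, distal_diameter = distal_diameter,
         me_diameter = me_diameter, me_offset_from_tip = me_offset_from_tip,
         isolation_thickness = isolation_thickness,
         shaft_length = shaft_length,
         me_azimuth_deg = c(90, 330, 210)),
    class = "catheter_spec")
}

#' Specify the catheter pose
#'
#' @param tilt_deg Angle between the catheter long axis and the tissue
#'   surface: 90 = orthogonal (O), 0 = parallel (P). The axis tilts in the
#'   x-z plane with the tip pointing towards the arriving wavefront.
#' @param rotation_deg Rotation about the catheter long axis. At
#'   `rotation_deg = 0`, ME1 sits at 90 degrees azimuth to the propagation
#'   direction; in parallel pose ME2 faces the tissue at 30 degrees.
#' @param penetration_mm Signed depth of the deepest catheter surface point
#'   below the tissue surface; negative values leave a blood gap.
#' @param translation_mm Length-2 (x, y) offset of the contact point from
#'   the slab center, mm.
#' @return A `pose` object.
#' @export
pose <- function(tilt_deg = 90, rotation_deg = 0, penetration_mm = 0,
                 translation_mm = c(0, 0)) {
  stopifnot(tilt_deg >= 0, tilt_deg <= 90,
            length(translation_mm) == 2)
  rotation_deg <- rotation_deg %% 360
  structure(
    list(tilt_deg = tilt_deg, rotation_deg = rotation_deg,
         penetration_mm = penetration_mm,
         translation_mm = as.numeric(translation_mm)),
    class = "pose")
}

#' Specify a radiofrequency ablation lesion
#'
#' Point lesions are truncated-cone ("cone-like") bodies with their axis
#' normal to the tissue surface; the necrotic-core surface width is
#' `necrotic_width` if given, otherwise `width_depth_ratio * depth`. An
#' acute lesion (`point_with_border`) carries a 3 mm thermal border zone
#' with temperature-dependent intracellular conductivity; a matured lesion
#' (`point_necrotic_only`) has cooled down and consists of the necrotic
#' core only. A linear lesion sweeps the point profile along y and leaves
#' an excitable conduction gap of width `gap_width`.
#'
#' @param kind One of `"none"`, `"point_with_border"`,
#'   `"point_necrotic_only"`, `"linear_with_gap"`.
#' @param depth Lesion depth, mm; defaults to the slab thickness
#'   (transmural) when the lesion is applied.
#' @param width_depth_ratio Surface width of the necrotic core divided by
#'   its depth.
#' @param necrotic_width Necrotic-core surface width, mm (overrides the
#'   ratio).
#' @param border_width Border-zone width, mm.
#' @param gap_width Conduction-gap width for linear lesions, mm (0 gives
#'   a continuous blocking line).
#' @param center (x, y) offset of the lesion center/line from the slab
#'   center, mm.
#' @param taper Bottom-to-top radius ratio of the truncated cone.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(kind = c("none", "point_with_border",
                                 "point_necrotic_only", "linear_with_gap"),
                        depth = NULL, width_depth_ratio = 1.25,
                        necrotic_width = NULL, border_width = 3,
                        gap_width = 1.5, center = c(0, 0), taper = 0.5) {
  kind <- match.arg(kind)
  if (kind == "point_with_border" && border_width != 3)
    stop("acute point lesions carry a 3 mm border zone")
  if (kind == "linear_with_gap" && gap_width < 0)
    stop("gap_width must be nonnegative for a linear lesion")
  structure(
    list(kind = kind, depth = depth, width_depth_ratio = width_depth_ratio,
         necrotic_width = necrotic_width, border_width = border_width,
         gap_width = gap_width, center = as.numeric(center), taper = taper),
    class = "lesion_spec")
}

# voxel center coordinates along one axis
axis_centers <- function(n, h) (seq_len(n) - 0.5) * h

# catheter frame: axis direction (tip -> shaft) and cross-sectional basis.
# e1 points along +x in orthogonal pose and straight down (-z) in parallel
# pose; e2 is +y. ME azimuths are measured from e1 towards e2.
catheter_frame <- function(tilt_deg) {
  t <- tilt_deg * pi / 180
  list(d = c(cos(t), 0, sin(t)),
       e1 = c(sin(t), 0, -cos(t)),
       e2 = c(0, 1, 0))
}

# hemisphere center of the tip in domain coordinates
catheter_c0 <- function(grid, cath, pose) {
  r <- cath$distal_diameter / 2
  z_surf <- (grid$nz_below + grid$n_tissue[3]) * grid$h
  cx <- grid$n_tissue[1] * grid$h / 2 + pose$translation_mm[1]
  cy <- grid$n_tissue[2] * grid$h / 2 + pose$translation_mm[2]
  c(cx, cy, z_surf - pose$penetration_mm + r)
}

#' Mini-electrode center positions
#'
#' Returns the center of mini electrode `k` on the distal-electrode surface
#' for a catheter pose, in domain coordinates (mm). The three MEs sit 120
#' degrees apart in the cross-sectional plane at the configured axial
#' offset from the tip.
#'
#' @param cath A [catheter_spec()].
#' @param pose A [pose()].
#' @param k Mini-electrode index, 1, 2 or 3.
#' @param grid A [grid_spec()] fixing the domain coordinates (defaults to
#'   the paper-scale grid).
#' @return Numeric length-3 point (x, y, z) in mm.
#' @export
me_center <- function(cath, pose, k, grid = grid_spec()) {
  stopifnot(k %in% 1:3)
  fr <- catheter_frame(pose$tilt_deg)
  r <- cath$distal_diameter / 2
  c0 <- catheter_c0(grid, cath, pose)
  s_me <- cath$me_offset_from_tip - r
  phi <- (cath$me_azimuth_deg[k] + pose$rotation_deg) * pi / 180
  u <- cos(phi) * fr$e1 + sin(phi) * fr$e2
  c0 + s_me * fr$d + r * u
}

#' Build the labeled simulation domain
#'
#' Voxelizes tissue slab, blood bath, lesion and catheter into a labeled
#' grid with per-voxel intracellular and extracellular conductivities,
#' temperature and excitability. The catheter displaces blood, and - where
#' it penetrates - tissue ("carving"; no elastic deformation is modeled).
#'
#' @param grid A [grid_spec()].
#' @param cath A [catheter_spec()] or `NULL` for no catheter.
#' @param pose A [pose()] (required when `cath` is given).
#' @param lesion A [lesion_spec()].
#' @return A `labeled_grid` object: 3-d arrays `label`, `sigma_i`,
#'   `sigma_e`, `temperature`, logical array `excitable`, plus grid
#'   metadata.
#' @export
build_domain <- function(grid, cath = NULL, pose = NULL,
                         lesion = lesion_spec("none")) {
  stopifnot(inherits(grid, "grid_spec"))
  h <- grid$h
  dims <- grid$dims
  labs <- egm_labels()
  lab <- array(labs[["blood"]], dims)
  kt <- grid$nz_below + seq_len(grid$n_tissue[3])
  lab[, , kt] <- labs[["tissue"]]

  g <- structure(
    list(dims = dims, h = h, grid = grid, catheter = cath, pose = pose,
         lesion = lesion, label = lab,
         z_surface = (grid$nz_below + grid$n_tissue[3]) * h,
         k_tissue = kt),
    class = "labeled_grid")

  if (lesion$kind != "none") g <- apply_lesion_labels(g, lesion)

  if (!is.null(cath)) {
    if (is.null(pose)) stop("a pose is required when a catheter is given")
    if (cath$me_diameter / h < 2)
      stop("voxel size too coarse to resolve a mini electrode ",
           "(fewer than 2 voxels across); reduce h")
    g <- carve_catheter(g, cath, pose)
  }
  finalize_materials(g)
}

# signed planar profile distance for the truncated-cone lesion:
# coordinates (u = lateral distance from axis/line, zd = depth below the
# tissue surface). Negative inside the necrotic profile.
cone_profile_dist <- function(u, zd, r_top, r_bot, depth) {
  # lateral boundary segment from (r_top, 0) to (r_bot, depth)
  px <- r_top; py <- 0
  qx <- r_bot; qy <- depth
  vx <- qx - px; vy <- qy - py
  tt <- pmin(1, pmax(0, ((u - px) * vx + (zd - py) * vy) / (vx^2 + vy^2)))
  dx <- u - (px + tt * vx); dy <- zd - (py + tt * vy)
  dseg <- sqrt(dx^2 + dy^2)
  rline <- r_top + (r_bot - r_top) * pmin(1, pmax(0, zd / depth))
  inside <- (u <= rline) & (zd <= depth) & (zd >= 0)
  ifelse(inside, -dseg, dseg)
}

# distance from every tissue voxel to the necrotic core, and membership
lesion_geometry <- function(g, lesion) {
  grid <- g$grid; h <- g$h
  depth <- lesion$depth %||% (grid$n_tissue[3] * h)
  r_top <- (lesion$necrotic_width %||%
              (lesion$width_depth_ratio * depth)) / 2
  r_bot <- lesion$taper * r_top
  if (2 * r_top > min(grid$n_tissue[1] * h, grid$n_tissue[2] * h) &&
      lesion$kind != "linear_with_gap")
    stop("lesion wider than the tissue slab")
  x0 <- grid$n_tissue[1] * h / 2 + lesion$center[1]
  y0 <- grid$n_tissue[2] * h / 2 + lesion$center[2]
  xs <- axis_centers(g$dims[1], h)
  ys <- axis_centers(g$dims[2], h)
  zs <- axis_centers(g$dims[3], h)[g$k_tissue]
  zd <- g$z_surface - zs  # depth below surface, per tissue layer

  X <- array(rep(xs, times = g$dims[2] * length(zd)),
             c(g$dims[1], g$dims[2], length(zd)))
  Y <- array(rep(rep(ys, each = g$dims[1]), times = length(zd)),
             c(g$dims[1], g$dims[2], length(zd)))
  ZD <- array(rep(zd, each = g$dims[1] * g$dims[2]),
              c(g$dims[1], g$dims[2], length(zd)))

  if (lesion$kind %in% c("point_with_border", "point_necrotic_only")) {
    u <- sqrt((X - x0)^2 + (Y - y0)^2)
    d <- cone_profile_dist(u, ZD, r_top, r_bot, depth)
    necrotic <- d <= 0
    dist <- pmax(d, 0)
  } else {  # linear lesion along y with a conduction gap
    u <- abs(X - x0)
    dxz <- cone_profile_dist(u, ZD, r_top, r_bot, depth)
    half_gap <- lesion$gap_width / 2
    in_gap_band <- abs(Y - y0) < half_gap
    necrotic <- (dxz <= 0) & !in_gap_band
    # distance to the necrotic set combines the profile distance with the
    # in-plane distance to the gap edge
    dy_gap <- pmax(half_gap - abs(Y - y0), 0)
    dist <- sqrt(pmax(dxz, 0)^2 + dy_gap^2)
  }
  list(necrotic = necrotic, dist = dist)
}

apply_lesion_labels <- function(g, lesion) {
  labs <- egm_labels()
  geo <- lesion_geometry(g, lesion)
  sl <- g$label[, , g$k_tissue]
  is_tissue <- sl == labs[["tissue"]]
  sl[geo$necrotic & is_tissue] <- labs[["lesion_necrotic"]]
  if (lesion$kind == "point_with_border") {
    border <- !geo$necrotic & geo$dist <= lesion$border_width & is_tissue
    sl[border] <- labs[["lesion_border"]]
    bdist <- geo$dist[border]
    g$border_dist <- bdist          # distances reused for conductivities
    g$border_index <- which(border) # within the slab sub-array
  }
  g$label[, , g$k_tissue] <- sl
  g
}

#' Apply a lesion to an existing domain
#'
#' Relabels tissue voxels as necrotic core and (for acute lesions) border
#' zone and updates conductivities, temperature and excitability.
#'
#' @param grid A `labeled_grid` built by [build_domain()].
#' @param lesion A [lesion_spec()] with `kind != "none"`.
#' @return The modified `labeled_grid`.
#' @export
apply_lesion <- function(grid, lesion) {
  stopifnot(inherits(grid, "labeled_grid"), lesion$kind != "none")
  grid$lesion <- lesion
  g <- apply_lesion_labels(grid, lesion)
  finalize_materials(g)
}

carve_catheter <- function(g, cath, pose) {
  labs <- egm_labels()
  h <- g$h
  r <- cath$distal_diameter / 2
  fr <- catheter_frame(pose$tilt_deg)
  c0 <- catheter_c0(g$grid, cath, pose)
  L <- cath$distal_length
  s_max <- L - r + cath$shaft_length

  # geometric bounds check: the catheter body (tip sphere + cylinder with a
  # flat proximal end disk) must stay inside the domain box
  E <- c0 + s_max * fr$d
  disk <- r * sqrt(pmax(1 - fr$d^2, 0))   # per-axis half-width of end disk
  lo <- pmin(c0 - r, E - disk)
  hi <- pmax(c0 + r, E + disk)
  size <- g$dims * h
  if (any(lo < -1e-9) || any(hi > size + 1e-9))
    stop("catheter extends outside the simulation domain")

  # candidate voxel bounding box
  lo <- pmin(c0 - r * fr$d, c0 + s_max * fr$d) - r - h
  hi <- pmax(c0 - r * fr$d, c0 + s_max * fr$d) + r + h
  ir <- pmax(1, floor(lo / h - 0.5) + 1)
  ix <- max(1, ir[1]):min(g$dims[1], ceiling(hi[1] / h + 0.5))
  iy <- max(1, ir[2]):min(g$dims[2], ceiling(hi[2] / h + 0.5))
  iz <- max(1, ir[3]):min(g$dims[3], ceiling(hi[3] / h + 0.5))
  xs <- axis_centers(g$dims[1], h)[ix]
  ys <- axis_centers(g$dims[2], h)[iy]
  zs <- axis_centers(g$dims[3], h)[iz]
  nb <- c(length(ix), length(iy), length(iz))
  PX <- array(rep(xs, times = nb[2] * nb[3]), nb) - c0[1]
  PY <- array(rep(rep(ys, each = nb[1]), times = nb[3]), nb) - c0[2]
  PZ <- array(rep(zs, each = nb[1] * nb[2]), nb) - c0[3]

  S <- PX * fr$d[1] + PY * fr$d[2] + PZ * fr$d[3]
  R2 <- PX^2 + PY^2 + PZ^2 - S^2
  in_cyl <- S >= 0 & S <= (L - r) & R2 <= r^2
  in_tip <- S < 0 & (R2 + S^2) <= r^2
  in_shaft <- S > (L - r) & S <= s_max & R2 <= r^2

  sub <- array(0L, nb)
  sub[in_shaft] <- labs[["shaft"]]
  sub[in_cyl | in_tip] <- labs[["electrode_distal"]]

  body <- in_cyl | in_tip
  me_lab <- c(labs[["electrode_me1"]], labs[["electrode_me2"]],
              labs[["electrode_me3"]])
  r_me <- cath$me_diameter / 2
  r_iso <- r_me + cath$isolation_thickness
  for (k in 1:3) {
    cm <- me_center(cath, pose, k, g$grid)
    D2 <- (PX - (cm[1] - c0[1]))^2 + (PY - (cm[2] - c0[2]))^2 +
      (PZ - (cm[3] - c0[3]))^2
    sub[body & D2 <= r_iso^2] <- labs[["isolation"]]
    sub[body & D2 <= r_me^2] <- me_lab[k]
  }

  # guarantee at least a one-voxel insulating shell around each ME
  is_me <- array(sub %in% me_lab, nb)
  nb_me <- array(FALSE, nb)
  nb_me[-1, , ] <- nb_me[-1, , ] | is_me[-nb[1], , ]
  nb_me[-nb[1], , ] <- nb_me[-nb[1], , ] | is_me[-1, , ]
  nb_me[, -1, ] <- nb_me[, -1, ] | is_me[, -nb[2], ]
  nb_me[, -nb[2], ] <- nb_me[, -nb[2], ] | is_me[, -1, ]
  nb_me[, , -1] <- nb_me[, , -1] | is_me[, , -nb[3]]
  nb_me[, , -nb[3]] <- nb_me[, , -nb[3]] | is_me[, , -1]
  sub[nb_me & sub == labs[["electrode_distal"]]] <- labs[["isolation"]]

  occupied <- sub != 0L
  block <- g$label[ix, iy, iz]
  block[occupied] <- sub[occupied]
  g$label[ix, iy, iz] <- block
  g
}

# fill per-voxel conductivities, temperature and excitability from labels
finalize_materials <- function(g) {
  labs <- egm_labels()
  lab <- g$label
  sigma_i <- array(0, g$dims)
  sigma_e <- array(NA_real_, g$dims)
  temperature <- array(37, g$dims)

  tab <- material_sigma()
  for (nm in names(labs)) {
    m <- lab == labs[[nm]]
    sigma_e[m] <- tab[[nm]]["sigma_e"]
    sigma_i[m] <- tab[[nm]]["sigma_i"]
  }

  excitable <- lab == labs[["tissue"]] | lab == labs[["lesion_border"]]

  # acute border zone: exponential temperature profile drives sigma_i
  if (!is.null(g$border_dist) && length(g$border_index)) {
    sl_t <- temperature[, , g$k_tissue]
    sl_i <- sigma_i[, , g$k_tissue]
    sl_l <- lab[, , g$k_tissue]
    Tb <- lesion_temperature(g$lesion, g$border_dist)
    keep <- sl_l[g$border_index] == labs[["lesion_border"]]
    sl_t[g$border_index[keep]] <- Tb[keep]
    sl_i[g$border_index[keep]] <- sigma_i_of_temperature(Tb[keep])
    temperature[, , g$k_tissue] <- sl_t
    sigma_i[, , g$k_tissue] <- sl_i
  }
  m <- lab == labs[["lesion_necrotic"]]
  temperature[m] <- 50

  sigma_i[!excitable] <- 0
  g$sigma_i <- sigma_i
  g$sigma_e <- sigma_e
  g$temperature <- temperature
  g$excitable <- excitable
  g
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat("<labeled_grid> ", paste(x$dims, collapse = " x "),
      " voxels, h = ", x$h, " mm\n", sep = "")
  tb <- table(factor(x$label, levels = egm_labels(),
                     labels = names(egm_labels())))
  tb <- tb[tb > 0]
  cat(paste0("  ", format(names(tb)), " ", tb, collapse = "\n"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
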