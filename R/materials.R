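# Material conductivities and the acute-lesion thermal model.

# per-label intracellular/extracellular conductivities in S/m
material_sigma <- function() {
  list(
    tissue           = c(sigma_i = 0.40, sigma_e = 0.264),
    lesion_necrotic  = c(sigma_i = 0,    sigma_e = 0.10),
    lesion_border    = c(sigma_i = 0.40, sigma_e = 0.264),  # sigma_i re-set from T
    blood            = c(sigma_i = 0,    sigma_e = 0.70),
    electrode_distal = c(sigma_i = 0,    sigma_e = 7000),
    electrode_me1    = c(sigma_i = 0,    sigma_e = 7000),
    electrode_me2    = c(sigma_i = 0,    sigma_e = 7000),
    electrode_me3    = c(sigma_i = 0,    sigma_e = 7000),
    isolation        = c(sigma_i = 0,    sigma_e = 1e-10),
    shaft            = c(sigma_i = 0,    sigma_e = 1e-10)
  )
}

#' Material conductivity table
#'
#' Intracellular and extracellular conductivities assigned to each voxel
#' label: healthy myocardium 0.40 / 0.264 S/m, blood 0.7 S/m, necrotic
#' lesion core 0.10 S/m (extracellular only), recording electrodes
#' 7000 S/m, insulation 1e-10 S/m. Border-zone intracellular conductivity
#' is temperature dependent, see [sigma_i_of_temperature()].
#'
#' @return A tibble with columns `material`, `sigma_i`, `sigma_e` (S/m).
#' @export
material_table <- function() {
  tab <- material_sigma()
  tibble::tibble(
    material = names(tab),
    sigma_i = vapply(tab, `[[`, numeric(1), "sigma_i"),
    sigma_e = vapply(tab, `[[`, numeric(1), "sigma_e"))
}

# decay length of the border-zone temperature profile (mm):
# T(d) = 37 + 13 exp(-d/lambda) with T(0) = 50 and T(3) = 40
lesion_lambda <- function() 3 / log(13 / 3)

#' Border-zone temperature profile
#'
#' Temperature as a function of distance from the necrotic-core boundary
#' for an acute lesion: 50 C at the boundary, decaying exponentially to
#' 40 C at the 3 mm border-zone edge and towards body temperature (37 C)
#' beyond. Lesions without a border zone are at body temperature.
#'
#' @param lesion A [lesion_spec()].
#' @param distance_mm Distance(s) from the necrotic boundary, mm.
#' @return Temperature(s) in degrees C.
#' @export
lesion_temperature <- function(lesion, distance_mm) {
  stopifnot(all(distance_mm >= 0))
  if (lesion$kind != "point_with_border")
    return(rep(37, length(distance_mm)))
  pmax(37 + 13 * exp(-distance_mm / lesion_lambda()), 37)
}

# temperature knots of the border-zone intracellular conductivity
# (hyperthermia first increases, then abolishes, cell coupling)
sigma_i_knots <- function() {
  list(T = c(37, 40, 43, 46, 50), sigma = c(0.40, 0.47, 0.53, 0.36, 0.01))
}

#' Intracellular conductivity of heated border-zone myocardium
#'
#' Piecewise-exponential (log-linear) interpolation through the
#' border-zone conductivity ranges: 0.47-0.53 S/m over 40-43 C,
#' 0.53-0.36 S/m over 43-46 C and 0.36-0.01 S/m over 46-50 C, anchored at
#' the healthy value 0.40 S/m at body temperature. Clamped outside
#' 37-50 C.
#'
#' @param temp_c Temperature(s) in degrees C.
#' @return Intracellular conductivity in S/m.
#' @export
sigma_i_of_temperature <- function(temp_c) {
  kn <- sigma_i_knots()
  tc <- pmin(pmax(temp_c, kn$T[1]), kn$T[length(kn$T)])
  exp(stats::approx(kn$T, log(kn$sigma), xout = tc)$y)
}

#' Monodomain effective conductivity
#'
#' Harmonic combination of the intracellular and extracellular
#' conductivities, exact for the equal-anisotropy (here: isotropic)
#' reduction of the bidomain equations.
#'
#' @param sigma_i,sigma_e Conductivities in S/m.
#' @return Effective conductivity in S/m (0 where `sigma_i` is 0).
#' @export
effective_conductivity <- function(sigma_i, sigma_e) {
  stopifnot(all(sigma_i >= 0), all(sigma_e > 0))
  ifelse(sigma_i > 0, sigma_i * sigma_e / (sigma_i + sigma_e), 0)
}
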