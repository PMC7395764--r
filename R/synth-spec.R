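#' Cultivar morphology specification
#'
#' Describes one lettuce cultivar for the synthetic scene generator: leaf
#' habit (flat vs curled), how leaf count scales across the seven weekly
#' growth stages, the green hue band, the curl amplitude driving
#' self-occlusion, and the allometric link between leaf area and biomass
#' (LFW = alpha * LA^beta, LDW = dry-matter fraction * LFW).
#'
#' @param name Cultivar label.
#' @param leaf_habit `"flat"` or `"curled"`.
#' @param leaf_count_range Length-2 integer vector: expected leaf count at
#'   stage 1 and stage 7 (linear in between).
#' @param hue_range Length-2 numeric, HSV hue band in degrees (greens).
#' @param curl_amplitude Dimensionless >= 0; must be 0 exactly when
#'   `leaf_habit == "flat"` and positive when curled.
#' @param dry_matter_fraction LDW/LFW ratio, in (0.02, 0.15).
#' @param allometry_alpha,allometry_beta Power-law coefficients of
#'   LFW (g) = alpha * LA (cm^2) ^ beta.
#' @return A list of class `cultivar_spec`.
#' @export
cultivar_spec <- function(name, leaf_habit = c("flat", "curled"),
                          leaf_count_range = c(5L, 22L),
                          hue_range = c(95, 125),
                          curl_amplitude = 0,
                          dry_matter_fraction = 0.05,
                          allometry_alpha = 0.035,
                          allometry_beta = 1.1) {
  leaf_habit <- match.arg(leaf_habit)
  if ((curl_amplitude == 0) != (leaf_habit == "flat")) {
    abort("`curl_amplitude` must be 0 exactly for flat habit and > 0 for curled.")
  }
  if (dry_matter_fraction <= 0.02 || dry_matter_fraction >= 0.15) {
    abort("`dry_matter_fraction` must lie in (0.02, 0.15).")
  }
  if (length(leaf_count_range) != 2L || any(leaf_count_range < 1)) {
    abort("`leaf_count_range` must be two positive integers (stage 1, stage 7).")
  }
  structure(list(
    name = name, leaf_habit = leaf_habit,
    leaf_count_range = as.integer(leaf_count_range),
    hue_range = hue_range, curl_amplitude = curl_amplitude,
    dry_matter_fraction = dry_matter_fraction,
    allometry_alpha = allometry_alpha, allometry_beta = allometry_beta
  ), class = "cultivar_spec")
}

#' Default cultivar set
#'
#' Three cultivars spanning the two morphology classes: Flandria and
#' Tiberius (flat, stretched leaves) and Locarno (curled, frilly leaves
#' with stronger self-occlusion in top view).
#'
#' @return Named list of three [cultivar_spec()] objects.
#' @export
default_cultivars <- function() {
  list(
    Flandria = cultivar_spec("Flandria", "flat", c(5L, 24L), c(95, 125),
                             0, 0.050),
    Tiberius = cultivar_spec("Tiberius", "flat", c(5L, 22L), c(100, 130),
                             0, 0.055),
    Locarno  = cultivar_spec("Locarno", "curled", c(6L, 26L), c(85, 115),
                             0.35, 0.045)
  )
}

#' Scene specification for the synthetic renderer
#'
#' @param image_size Side of the square output images, pixels.
#' @param sensor_height Nadir sensor height above the ground plane, cm.
#' @param px_per_cm Pixel scale at the canopy plane.
#' @param background_style One of `"dark"`, `"tray"`, `"foam"` (all dark,
#'   mildly textured; style shifts hue/brightness of the background).
#' @param illumination_scale Multiplicative brightness factor (> 0).
#' @param rng_seed Integer seed controlling every random draw of the scene.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 480L, sensor_height = 78,
                       px_per_cm = 13, background_style = c("dark", "tray", "foam"),
                       illumination_scale = 1, rng_seed = 1L) {
  background_style <- match.arg(background_style)
  if (image_size <= 0 || sensor_height <= 0 || px_per_cm <= 0 ||
      illumination_scale <= 0) {
    abort("Scene dimensions, sensor height, pixel scale and illumination must be positive.")
  }
  structure(list(
    image_size = as.integer(image_size), sensor_height = sensor_height,
    px_per_cm = px_per_cm, background_style = background_style,
    illumination_scale = illumination_scale, rng_seed = as.integer(rng_seed)
  ), class = "scene_spec")
}
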