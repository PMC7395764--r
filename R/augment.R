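#' Augmentation configuration
#'
#' The default scheme mirrors a 26-fold enlargement: the six geometric
#' variants (identity, rotations by 90/180/270 degrees, horizontal and
#' vertical flips) plus the four brightness factors applied to each of the
#' five non-identity geometric variants (6 + 4 x 5 = 26). The factor is
#' always derived from the composition rule, never hard-coded.
#'
#' @param rotations Rotation angles in degrees, multiples of 90.
#' @param flips Subset of `c("horizontal", "vertical")`.
#' @param brightness_factors Positive multipliers applied to the HSV value
#'   channel.
#' @param composition_rule `"default26"` (brightness on non-identity
#'   geometric variants only) or `"cross"` (brightness on every geometric
#'   variant including identity).
#' @return List of class `augment_config`.
#' @export
augment_config <- function(rotations = c(90, 180, 270),
                           flips = c("horizontal", "vertical"),
                           brightness_factors = c(0.8, 0.9, 1.1, 1.2),
                           composition_rule = c("default26", "cross")) {
  composition_rule <- match.arg(composition_rule)
  if (length(rotations) && any(rotations %% 90 != 0)) {
    abort("`rotations` must be multiples of 90 degrees.")
  }
  if (length(brightness_factors) && any(brightness_factors <= 0)) {
    abort("`brightness_factors` must be positive.")
  }
  stopifnot(all(flips %in% c("horizontal", "vertical")))
  structure(list(rotations = rotations, flips = flips,
                 brightness_factors = brightness_factors,
                 composition_rule = composition_rule),
            class = "augment_config")
}

#' @rdname augment_config
#' @param config An `augment_config`.
#' @return `augmentation_factor()`: the number of output images per source
#'   image under the configured composition rule.
#' @export
augmentation_factor <- function(config) {
  nrow(augmentation_plan(config))
}

# enumerate the transform chains of the composition rule
augmentation_plan <- function(config) {
  geo <- c("identity",
           if (length(config$rotations)) paste0("rot", config$rotations),
           if ("horizontal" %in% config$flips) "fliph",
           if ("vertical" %in% config$flips) "flipv")
  nb <- length(config$brightness_factors)
  plan <- tibble(geometric = geo, brightness = NA_real_)
  if (nb > 0) {
    with_b <- if (config$composition_rule == "default26") setdiff(geo, "identity") else geo
    if (length(with_b)) {
      plan <- bind_rows(plan, tidyr::expand_grid(
        geometric = with_b, brightness = config$brightness_factors))
    }
  }
  plan %>% mutate(chain = ifelse(is.na(.data$brightness), .data$geometric,
                                 sprintf("%s+b%g", .data$geometric, .data$brightness)))
}

# exact 90-degree-family geometric ops on H x W x C arrays (lossless)
apply_geometric <- function(image, op) {
  switch(op,
    identity = image,
    rot90  = aperm(image, c(2, 1, 3))[dim(image)[2]:1, , , drop = FALSE],
    rot180 = image[dim(image)[1]:1, dim(image)[2]:1, , drop = FALSE],
    rot270 = aperm(image, c(2, 1, 3))[, dim(image)[1]:1, , drop = FALSE],
    fliph  = image[, dim(image)[2]:1, , drop = FALSE],
    flipv  = image[dim(image)[1]:1, , , drop = FALSE],
    abort(sprintf("Unknown geometric op '%s'.", op))
  )
}

#' Adjust image brightness in HSV space
#'
#' Converts to HSV, multiplies the value channel by `factor` (clipped to
#' \[0, 1\]), and converts back; hue and saturation are untouched up to the
#' 8-bit round trip.
#'
#' @param image RGB array in \[0, 1\].
#' @param factor Positive brightness multiplier.
#' @return RGB array of the same shape.
#' @export
brightness_adjust <- function(image, factor) {
  assert_rgb(image)
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  d <- dim(image)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- rgb_to_hsv(px)
  v <- pmin(hsv[, 3] * factor, 1)
  out <- hsv_to_rgb(hsv[, 1], hsv[, 2], v)
  out <- round(out * 255) / 255
  array(out, d)
}

#' Expand a training set by deterministic augmentation
#'
#' Applies the configured transform chains to every training image and
#' writes the variants as PNG. Augmentation is a training-set operation:
#' callers must pass training ids only (the pipeline enforces this).
#'
#' @param manifest Dataset manifest ([generate_dataset()]) restricted to, or
#'   filtered by, `train_ids`.
#' @param train_ids Character ids to augment.
#' @param config An [augment_config()].
#' @param out_dir Output directory for augmented PNGs.
#' @return Augmented manifest tibble `(aug_id, source_id, transform_chain,
#'   path)` carrying provenance for every output image.
#' @export
expand_training_set <- function(manifest, train_ids, config = augment_config(),
                                out_dir) {
  src <- manifest %>% filter(.data$id %in% train_ids)
  if (!nrow(src)) abort("No training images to augment.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- augmentation_plan(config)
  rows <- vector("list", nrow(src) * nrow(plan))
  k <- 0L
  for (i in seq_len(nrow(src))) {
    img <- read_rgb(src$rgb_path[i])
    geo_cache <- list()
    for (j in seq_len(nrow(plan))) {
      g <- plan$geometric[j]
      if (is.null(geo_cache[[g]])) geo_cache[[g]] <- apply_geometric(img, g)
      out <- geo_cache[[g]]
      if (!is.na(plan$brightness[j])) {
        out <- brightness_adjust(out, plan$brightness[j])
      }
      aug_id <- sprintf("%s__%s", src$id[i], gsub("[+.]", "_", plan$chain[j]))
      path <- file.path(out_dir, paste0(aug_id, ".png"))
      if (file.exists(path)) abort(sprintf("Augmented name collision: %s", path))
      write_rgb(out, path)
      k <- k + 1L
      rows[[k]] <- tibble(aug_id = aug_id, source_id = src$id[i],
                          transform_chain = plan$chain[j], path = path)
    }
  }
  out_tbl <- bind_rows(rows)
  readr::write_csv(out_tbl, file.path(out_dir, "augmented_manifest.csv"))
  out_tbl
}

#' In-memory augmentation of a list of images
#'
#' Same transform chains as [expand_training_set()] but operating on and
#' returning in-memory arrays (used by the training pipeline to avoid disk
#' round-trips).
#'
#' @param images Named list of RGB arrays.
#' @param config An [augment_config()].
#' @return Named list of augmented arrays; names are `sourceid__chain`.
#' @export
augment_images <- function(images, config = augment_config()) {
  plan <- augmentation_plan(config)
  out <- list()
  for (nm in names(images)) {
    img <- images[[nm]]
    for (j in seq_len(nrow(plan))) {
      v <- apply_geometric(img, plan$geometric[j])
      if (!is.na(plan$brightness[j])) v <- brightness_adjust(v, plan$brightness[j])
      out[[sprintf("%s__%s", nm, gsub("[+.]", "_", plan$chain[j]))]] <- v
    }
  }
  out
}
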