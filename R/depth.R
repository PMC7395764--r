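# Depth-image pipeline: superpixel segmentation of the plant, structural
# traits (canopy height H, projected area PA, digital volume V = PA * H),
# and the univariate linear models LR-H / LR-PA / LR-V.

#' Segment the plant in a depth image via superpixels
#'
#' Partitions the depth map into superpixels (grid-seeded local k-means on
#' position + depth), selects the superpixel whose centroid is nearest the
#' image centre (Euclidean distance), then grows the plant region by
#' breadth-first merging of adjacent superpixels whose mean depth lies
#' within `tolerance_mm` of the seed's mean depth. A depth-plausibility
#' check flags selections that are not nearer to the sensor than their
#' surroundings (e.g. a plant shifted far off-centre).
#'
#' @param depth Matrix of depth values in millimetres.
#' @param n_superpixels Target number of superpixels (>= 2).
#' @param tolerance_mm Region-growing tolerance in mm. Under the default
#'   `"floor"` rule a candidate superpixel is mergeable when its mean depth
#'   is at least `tolerance_mm / 3` nearer than the estimated ground plane;
#'   under `"seed"` when its mean depth lies within `tolerance_mm` of the
#'   seed's mean depth. 0 keeps only the centre superpixel.
#' @param merge_rule `"floor"` (default; robust to canopies whose depth
#'   spans more than the tolerance) or `"seed"` (strict seed-relative
#'   growing).
#' @param depth_scale,compactness,iters Superpixel backend tuning.
#' @return List of class `segmentation_mask` with `mask`,
#'   `plant_pixel_count`, `labels` (superpixel label matrix), `selected`
#'   (merged label ids) and `flagged` (TRUE when the plausibility check
#'   failed).
#' @export
segment_depth <- function(depth, n_superpixels = 400L, tolerance_mm = 25,
                          merge_rule = c("floor", "seed"),
                          depth_scale = 30, compactness = 0.5, iters = 5L) {
  merge_rule <- match.arg(merge_rule)
  if (!is.matrix(depth)) abort("`depth` must be a single-channel matrix (mm).")
  if (n_superpixels < 2) abort("`n_superpixels` must be >= 2.")
  labels <- cpp_slic_depth(depth, as.integer(n_superpixels), depth_scale,
                           compactness, as.integer(iters))
  st <- cpp_label_stats(labels, depth)
  nl <- length(st$mean_depth)
  ctr <- (dim(depth) + 1) / 2
  seed <- which.min((st$row - ctr[1])^2 + (st$col - ctr[2])^2)

  if (diff(range(depth)) < 1e-9) {
    warn("Depth map is constant; returning the centre superpixel only.")
    mask <- labels == seed
    return(structure(list(mask = mask, plant_pixel_count = sum(mask),
                          labels = labels, selected = seed, flagged = TRUE),
                     class = "segmentation_mask"))
  }

  adj <- vector("list", nl)
  for (i in seq_len(nrow(st$pairs))) {
    a <- st$pairs[i, 1]; b <- st$pairs[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  # ground plane estimate: area-weighted deep tail of the superpixel means
  floor_mm <- quantile(rep(st$mean_depth, st$count), 0.95, names = FALSE)
  mergeable <- if (merge_rule == "floor") {
    st$mean_depth <= floor_mm - tolerance_mm / 3
  } else {
    abs(st$mean_depth - st$mean_depth[seed]) <= tolerance_mm
  }
  selected <- rep(FALSE, nl)
  selected[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nxt <- integer()
    for (f in frontier) {
      for (nb in unique(adj[[f]])) {
        if (!selected[nb] && mergeable[nb]) {
          selected[nb] <- TRUE
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  mask <- matrix(selected[labels], nrow(labels), ncol(labels))

  flagged <- FALSE
  if (all(mask) || mean(depth[mask]) >= mean(depth[!mask]) - 10) {
    flagged <- TRUE
    warn("Selected depth region is not clearly nearer than its surroundings; selection may be background.")
  }
  structure(list(mask = mask, plant_pixel_count = sum(mask), labels = labels,
                 selected = which(selected), flagged = flagged),
            class = "segmentation_mask")
}

#' Structural traits from a depth image
#'
#' `PA` is the plant pixel count; `H` is the sensor height minus the mean
#' plant-pixel depth (converted mm to cm); `V = PA * H` exactly.
#'
#' @param depth Depth matrix in millimetres.
#' @param mask A segmentation mask (logical matrix or `segmentation_mask`).
#' @param sensor_height Sensor height above the ground plane, cm.
#' @param px_per_cm Optional pixel scale; when given, `PA_cm2` is added.
#' @return One-row tibble `(H_cm, PA_px, V)` (+ `PA_cm2` when calibrated).
#' @export
structural_features <- function(depth, mask, sensor_height = 78,
                                px_per_cm = NULL) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  if (!any(mask)) abort("`mask` is empty; structural traits are undefined.")
  h <- sensor_height - mean(depth[mask]) / 10
  if (h < 0) {
    warn(sprintf("Negative canopy height (%.2f cm) clamped to 0.", h))
    h <- 0
  }
  pa <- sum(mask)
  out <- tibble(H_cm = h, PA_px = pa, V = pa * h)
  if (!is.null(px_per_cm)) out$PA_cm2 <- pa / px_per_cm^2
  out
}

#' Univariate linear trait model (LR-H, LR-PA, LR-V)
#'
#' Ordinary least squares of one trait on one structural feature.
#'
#' @param data Tibble holding the feature and target columns.
#' @param feature,target Column names (strings).
#' @return Object of class `lr_fit` with `slope`, `intercept`, the
#'   underlying `lm` fit, and in-sample predictions.
#' @export
fit_lr <- function(data, feature, target) {
  if (nrow(data) < 3) abort("Need at least 3 samples for a linear fit.")
  x <- data[[feature]]; y <- data[[target]]
  if (is.null(x) || is.null(y)) abort("`feature`/`target` columns not found.")
  if (stats::sd(x) == 0) abort(sprintf("Feature '%s' is constant.", feature))
  fit <- lm(y ~ x, data = tibble(x = x, y = y))
  structure(list(feature = feature, target = target,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 model = fit, fitted = unname(stats::fitted(fit)),
                 r2_train = summary(fit)$r.squared),
            class = "lr_fit")
}

#' @export
predict.lr_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[object$feature]] else newdata
  if (is.null(x)) abort(sprintf("Column '%s' not found in newdata.", object$feature))
  unname(object$intercept + object$slope * x)
}

#' @export
print.lr_fit <- function(x, ...) {
  cat(sprintf("<lr_fit> %s ~ %s: slope %.4g, intercept %.4g (train R2 %.3f)\n",
              x$target, x$feature, x$slope, x$intercept, x$r2_train))
  invisible(x)
}
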