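# Handcrafted-feature pipeline: greenness segmentation, 30 colour + 60 GLCM
# texture + 2 shape descriptors, and Pearson screening against the traits.

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

#' Segment the plant by adaptive colour thresholding
#'
#' Computes a greenness map (the a* channel of CIE L*a*b*; vegetation is
#' strongly negative), splits it with a within-image Otsu threshold, keeps
#' pixels below the threshold, fills holes and retains the largest connected
#' component. A plausibility check requires the foreground to be clearly
#' greener than the background (mean a* gap of at least `min_gap`),
#' otherwise an empty-mask error naming the image is raised.
#'
#' @param image RGB array in \[0, 1\].
#' @param min_gap Minimum a* separation between background and foreground
#'   means for a segmentation to count as "plant found".
#' @param .name Image label used in error messages.
#' @return List of class `segmentation_mask`: `mask` (logical matrix),
#'   `plant_pixel_count`, `threshold`.
#' @export
segment_plant <- function(image, min_gap = 8, .name = "image") {
  assert_rgb(image)
  d <- dim(image)[1:2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  astar <- rgb_to_lab(px)[, 2]
  thr <- otsu_threshold(astar)
  fg <- astar < thr
  gap <- mean(astar[!fg]) - mean(astar[fg])
  if (!any(fg) || all(fg) || !is.finite(gap) || gap < min_gap) {
    abort(sprintf("No plant foreground found in '%s' (a* separation %.2f below %.2f).",
                  .name, ifelse(is.finite(gap), gap, 0), min_gap))
  }
  m <- EBImage::Image(matrix(as.numeric(fg), d[1], d[2]))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(counts)
  mask <- matrix(as.integer(EBImage::imageData(lab)) == keep, d[1], d[2])
  structure(list(mask = mask, plant_pixel_count = sum(mask), threshold = thr),
            class = "segmentation_mask")
}

# gray-level co-occurrence statistics for one channel over a mask.
# Quantization: `levels` equal-width bins over the masked min..max range;
# displacement 1 px; ordered pairs along each of the four standard
# directions; statistics averaged over directions.
glcm_stats <- function(channel, mask, levels = 16L, directions = 1:4,
                       gray_limits = NULL) {
  vals <- channel[mask]
  rng <- gray_limits %||% range(vals)  # adaptive limits by default
  q <- matrix(0L, nrow(channel), ncol(channel))
  if (diff(rng) > 0) {
    q[mask] <- pmin(pmax(floor((vals - rng[1]) / diff(rng) * levels), 0L),
                    levels - 1L)
  }
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))[directions]
  acc <- c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0)
  nd <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (d in dirs) {
    r0 <- max(1L, 1L - d[1]):min(nr, nr - d[1])
    c0 <- max(1L, 1L - d[2]):min(nc, nc - d[2])
    ok <- mask[r0, c0, drop = FALSE] & mask[r0 + d[1], c0 + d[2], drop = FALSE]
    if (!any(ok)) next
    i <- q[r0, c0, drop = FALSE][ok]
    j <- q[r0 + d[1], c0 + d[2], drop = FALSE][ok]
    P <- matrix(tabulate(i * levels + j + 1L, levels * levels),
                levels, levels, byrow = TRUE)
    P <- P / sum(P)
    lev <- 0:(levels - 1L)
    pi_ <- rowSums(P); pj <- colSums(P)
    mui <- sum(lev * pi_); muj <- sum(lev * pj)
    sdi <- sqrt(sum((lev - mui)^2 * pi_)); sdj <- sqrt(sum((lev - muj)^2 * pj))
    II <- matrix(lev, levels, levels); JJ <- t(II)
    corr <- if (sdi > 1e-12 && sdj > 1e-12) {
      sum((II - mui) * (JJ - muj) * P) / (sdi * sdj)
    } else 0
    acc <- acc + c(contrast = sum(P * (II - JJ)^2),
                   correlation = corr,
                   energy = sum(P^2),
                   homogeneity = sum(P / (1 + abs(II - JJ))))
    nd <- nd + 1L
  }
  if (nd == 0L) abort("Mask has no co-occurring pixel pairs.")
  acc / nd
}

# chain-code perimeter of the mask's outer contour with the standard
# straight/diagonal step weights (Vossepoel-Smeulders)
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(matrix(as.numeric(mask), nrow(mask))))
  if (!length(oc)) return(0)
  per_contour <- vapply(oc, function(ct) {
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    step <- sqrt(rowSums((nxt - ct)^2))
    sum(ifelse(step > 1.2, 1.340, 0.948) * (step > 0))
  }, numeric(1))
  max(per_contour)
}

#' Extract the 92 handcrafted descriptors of a segmented plant
#'
#' Colour features: mean and standard deviation of 15 colour components
#' (RGB, HSV, CIE L*a*b*, YCrCb, HSI channels) over the masked pixels.
#' Texture features: GLCM contrast, correlation, energy and homogeneity per
#' component (16 quantization levels, displacement 1, averaged over the four
#' standard directions, masked region only). Shape features: plant area in
#' pixels and boundary perimeter in pixels.
#'
#' @param image RGB array in \[0, 1\].
#' @param mask A [segment_plant()] result or a logical matrix.
#' @param glcm_levels Number of gray levels for the co-occurrence matrix.
#' @return One-row tibble with 92 named columns
#'   (`<space>_<channel>_<stat>`, `Area`, `Perimeter`).
#' @export
extract_features <- function(image, mask, glcm_levels = 16L) {
  assert_rgb(image)
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  if (!is.matrix(mask) || !any(mask)) abort("`mask` must be a nonempty logical matrix.")
  chans <- color_channel_stack(image)
  out <- list()
  for (nm in names(chans)) {
    v <- chans[[nm]][mask]
    out[[paste0(nm, "_Average")]] <- mean(v)
    out[[paste0(nm, "_Std")]] <- stats::sd(v)
  }
  for (nm in names(chans)) {
    g <- glcm_stats(chans[[nm]], mask, glcm_levels)
    out[[paste0(nm, "_Contrast")]] <- g[["contrast"]]
    out[[paste0(nm, "_Correlation")]] <- g[["correlation"]]
    out[[paste0(nm, "_Energy")]] <- g[["energy"]]
    out[[paste0(nm, "_Homogeneity")]] <- g[["homogeneity"]]
  }
  out$Area <- sum(mask)
  out$Perimeter <- mask_perimeter(mask)
  tibble::as_tibble(out)
}

#' Screen features by Pearson correlation with a trait
#'
#' @param features Tibble of numeric feature columns (an `id` column, if
#'   present, is ignored).
#' @param target Numeric trait vector, one value per row of `features`.
#' @param threshold Minimum `|r|` for selection (default 0.65).
#' @return Tibble `(feature, r, p)` of features with `|r| >= threshold`,
#'   sorted by `|r|` descending. Constant features are skipped with a
#'   warning.
#' @export
pearson_screen <- function(features, target, threshold = 0.65) {
  X <- features %>% select(-dplyr::any_of("id"))
  if (nrow(X) < 3) abort("Need at least 3 samples for correlation screening.")
  if (length(target) != nrow(X)) abort("`target` length must match rows of `features`.")
  if (stats::sd(target) == 0) abort("`target` is constant; correlations are undefined.")
  res <- purrr::map_dfr(names(X), function(nm) {
    x <- X[[nm]]
    if (!is.numeric(x)) return(NULL)
    if (stats::sd(x) == 0) {
      warn(sprintf("Feature '%s' is constant; skipped.", nm))
      return(NULL)
    }
    ct <- stats::cor.test(x, target)
    tibble(feature = nm, r = unname(ct$estimate), p = ct$p.value)
  })
  res %>% filter(abs(.data$r) >= threshold) %>% arrange(desc(abs(.data$r)))
}
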