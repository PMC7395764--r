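# Colour-space conversions used by rendering, augmentation and feature
# extraction. All take/return per-pixel matrices or arrays with channels last.

# h, s, v in [0, 1] -> n x 3 matrix of R, G, B in [0, 1]
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  f <- function(n) {
    k <- (n + h6) %% 6
    v - v * s * pmax(0, pmin(k, 4 - k, 1))
  }
  cbind(f(5), f(3), f(1), deparse.level = 0)
}

# n x 3 RGB in [0, 1] -> n x 3 H, S, V in [0, 1]
rgb_to_hsv <- function(rgb) {
  t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
}

# n x 3 RGB in [0, 1] -> n x 3 CIE L*, a*, b* (D65, sRGB gamma)
rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

# n x 3 RGB in [0, 1] -> n x 3 digital Y, Cr, Cb (BT.601, 0..255 scale)
rgb_to_ycrcb <- function(rgb) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  y  <-  16 +  65.481 * r + 128.553 * g +  24.966 * b
  cr <- 128 + 112.000 * r -  93.786 * g -  18.214 * b
  cb <- 128 -  37.797 * r -  74.203 * g + 112.000 * b
  cbind(y, cr, cb, deparse.level = 0)
}

# n x 3 RGB in [0, 1] -> n x 3 H (degrees), S, I. The intensity/saturation
# form: I = (R+G+B)/3, S = 1 - min/I, H the hue angle (distinct from HSV).
rgb_to_hsi <- function(rgb) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 0), -1), 1)) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  h[den == 0] <- 0
  cbind(h, s, i, deparse.level = 0)
}

# RGB array (H x W x 3) -> list of 15 named channel matrices across the five
# colour spaces, in the fixed order used by the feature extractor.
color_channel_stack <- function(image) {
  assert_rgb(image)
  d <- dim(image)[1:2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- rgb_to_hsv(px)
  lab <- rgb_to_lab(px)
  ycc <- rgb_to_ycrcb(px)
  hsi <- rgb_to_hsi(px)
  chans <- list(
    RGB_R = px[, 1] * 255, RGB_G = px[, 2] * 255, RGB_B = px[, 3] * 255,
    HSV_H = hsv[, 1], HSV_S = hsv[, 2], HSV_V = hsv[, 3],
    LAB_L = lab[, 1], LAB_A = lab[, 2], LAB_B = lab[, 3],
    YCrCb_Y = ycc[, 1], YCrCb_Cr = ycc[, 2], YCrCb_Cb = ycc[, 3],
    HSI_H = hsi[, 1], HSI_S = hsi[, 2], HSI_I = hsi[, 3]
  )
  lapply(chans, function(v) matrix(v, d[1], d[2]))
}
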