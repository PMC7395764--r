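# Top-view rosette renderer. Leaves are lobed ellipses placed on a golden-
# angle spiral; each leaf's area is computed analytically (polar quadrature)
# before rasterization, so ground-truth LA is independent of the pixel grid.

LEAF_ANGLES <- 1024L

# polar radius of a lobed ellipse, major axis along t = 0
leaf_radius <- function(t, a, b, lobe_amp, lobe_n) {
  base <- a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
  base * (1 + lobe_amp * cos(lobe_n * t))
}

# intrinsic (flat) area of one leaf, cm^2, by periodic trapezoid quadrature
leaf_area_cm2 <- function(a, b, lobe_amp, lobe_n) {
  t <- seq(0, 2 * pi, length.out = LEAF_ANGLES + 1L)[-(LEAF_ANGLES + 1L)]
  r <- leaf_radius(t, a, b, lobe_amp, lobe_n)
  0.5 * mean(r^2) * 2 * pi
}

# circumferential arc-length factor of a curled leaf: footprint radii are
# divided by lambda >= 1, while intrinsic area is unchanged by bending
curl_lambda <- function(curl, b, lobe_n, a, lobe_amp) {
  if (curl <= 0) return(1)
  t <- seq(0, 2 * pi, length.out = 256L)
  rbar <- mean(leaf_radius(t, a, b, lobe_amp, lobe_n))
  amp <- 0.4 * curl * b
  mean(sqrt(1 + (amp * lobe_n * cos(lobe_n * t) / rbar)^2))
}

sample_leaves <- function(cultivar, stage) {
  rng <- cultivar$leaf_count_range
  mu_n <- rng[1] + (rng[2] - rng[1]) * (stage - 1) / 6
  n <- max(3L, as.integer(round(mu_n + runif(1, -1.5, 1.5))))
  mu_a <- 2.2 + (8 - 2.2) * (stage - 1) / 6
  h_canopy <- 2.5 + 2.0 * stage
  i <- seq_len(n)
  size_f <- 1 - 0.45 * (i - 1) / max(n - 1, 1)  # outer (older) leaves larger
  a <- mu_a * size_f * exp(rnorm(n, 0, 0.12))
  b <- a * runif(n, 0.50, 0.65)
  curled <- cultivar$leaf_habit == "curled"
  tibble(
    a_cm = a, b_cm = b,
    angle_deg = (i * 137.508 + runif(n, -8, 8)) %% 360,
    dist_cm = 0.55 * a,
    lobe_amp = if (curled) 0.05 + 0.10 * cultivar$curl_amplitude + runif(n, 0, 0.03)
               else runif(n, 0.03, 0.07),
    lobe_n = if (curled) sample(9:13, n, replace = TRUE)
             else sample(6:9, n, replace = TRUE),
    z_cm = h_canopy * (0.25 + 0.70 * (i - 1) / max(n - 1, 1))  # inner on top
  )
}

#' Render one synthetic lettuce plant
#'
#' Draws a top-view rosette (RGB), the matching nadir depth map (integer
#' millimetres; plant pixels strictly nearer than the ground plane), the
#' renderer's own plant mask and per-pixel canopy height, and the ground
#' truth: total leaf area summed analytically over every modelled leaf
#' (including occluded parts), LFW from the cultivar's allometry
#' `alpha * LA^beta * exp(eps)` with log-normal noise, and LDW as the
#' dry-matter fraction of LFW with its own log-normal noise.
#'
#' @param cultivar A [cultivar_spec()].
#' @param stage Growth stage (weekly session), integer 1..7.
#' @param scene A [scene_spec()]; `scene$rng_seed` fixes every random draw.
#' @param leaves Optional tibble overriding the sampled leaf geometry, with
#'   columns `a_cm`, `b_cm`, `angle_deg`, `dist_cm`, `lobe_amp`, `lobe_n`,
#'   `z_cm` (one row per leaf). Used for controlled experiments, e.g. a
#'   single pure ellipse.
#' @param sigma_fw,sigma_dw Log-scale standard deviations of the trait noise.
#' @return A list of class `plant_sample`: `rgb` (S x S x 3 in \[0,1\]),
#'   `depth` (S x S integer mm), `mask` (logical), `height_cm` (numeric
#'   matrix), `cultivar`, `stage`, `ground_truth` (list with `traits`
#'   = c(lfw_g, ldw_g, la_cm2), `total_leaf_area_cm2`,
#'   `visible_projected_area_px`) and `scene`.
#' @export
render_plant <- function(cultivar, stage, scene = scene_spec(),
                         leaves = NULL, sigma_fw = 0.08, sigma_dw = 0.08) {
  if (!inherits(cultivar, "cultivar_spec")) abort("`cultivar` must be a cultivar_spec.")
  if (!inherits(scene, "scene_spec")) abort("`scene` must be a scene_spec.")
  if (length(stage) != 1L || is.na(stage) || stage < 1 || stage > 7 ||
      stage != round(stage)) {
    abort("`stage` must be an integer in 1..7.")
  }
  stage <- as.integer(stage)
  seed <- (scene$rng_seed + 131L * stage) %% .Machine$integer.max
  withr::with_seed(seed, render_plant_impl(cultivar, stage, scene, leaves,
                                           sigma_fw, sigma_dw))
}

render_plant_impl <- function(cultivar, stage, scene, leaves,
                              sigma_fw, sigma_dw) {
  S <- scene$image_size
  ppc <- scene$px_per_cm
  if (is.null(leaves)) leaves <- sample_leaves(cultivar, stage)
  n <- nrow(leaves)
  curl <- cultivar$curl_amplitude

  cx0 <- S / 2 + runif(1, -0.5, 0.5) * ppc
  cy0 <- S / 2 + runif(1, -0.5, 0.5) * ppc

  Z <- matrix(0, S, S)        # canopy height, cm (0 = ground)
  TOP <- matrix(0L, S, S)     # winning leaf per pixel
  Tm <- matrix(0, S, S)       # leaf-frame angle of winning leaf
  Rm <- matrix(0, S, S)       # relative radius of winning leaf

  areas <- numeric(n)
  for (i in seq_len(n)) {
    lf <- leaves[i, ]
    areas[i] <- leaf_area_cm2(lf$a_cm, lf$b_cm, lf$lobe_amp, lf$lobe_n)
    lam <- curl_lambda(curl, lf$b_cm, lf$lobe_n, lf$a_cm, lf$lobe_amp)
    psi <- lf$angle_deg * pi / 180
    lcx <- cx0 + lf$dist_cm * cos(psi) * ppc
    lcy <- cy0 + lf$dist_cm * sin(psi) * ppc
    rmax_px <- lf$a_cm * (1 + lf$lobe_amp) / lam * ppc + 2
    xs <- max(1L, floor(lcx - rmax_px)):min(S, ceiling(lcx + rmax_px))
    ys <- max(1L, floor(lcy - rmax_px)):min(S, ceiling(lcy + rmax_px))
    if (!length(xs) || !length(ys)) next
    DX <- outer(rep(1, length(ys)), (xs - lcx) / ppc)
    DY <- outer((ys - lcy) / ppc, rep(1, length(xs)))
    tt <- atan2(DY, DX) - psi
    rho <- sqrt(DX^2 + DY^2)
    rt <- leaf_radius(tt, lf$a_cm, lf$b_cm, lf$lobe_amp, lf$lobe_n)
    rrel <- rho * lam / rt
    amp <- 0.4 * curl * lf$b_cm
    zsurf <- pmax(lf$z_cm * (0.45 + 0.55 * (1 - rrel)) +
                    amp * sin(lf$lobe_n * tt) * rrel, 0.5)
    win <- rrel <= 1 & zsurf > Z[ys, xs]
    if (any(win)) {
      sub <- Z[ys, xs]; sub[win] <- zsurf[win]; Z[ys, xs] <- sub
      sub <- TOP[ys, xs]; sub[win] <- i; TOP[ys, xs] <- sub
      sub <- Tm[ys, xs]; sub[win] <- tt[win]; Tm[ys, xs] <- sub
      sub <- Rm[ys, xs]; sub[win] <- rrel[win]; Rm[ys, xs] <- sub
    }
  }

  mask <- TOP > 0L

  # --- colour ---
  style <- switch(scene$background_style,
    dark = list(v = 0.10, h = 30 / 360, s = 0.35),
    tray = list(v = 0.13, h = 20 / 360, s = 0.40),
    foam = list(v = 0.20, h = 45 / 360, s = 0.15)
  )
  coarse <- as.matrix(EBImage::resize(EBImage::Image(matrix(runif(24 * 24), 24)),
                                      w = S, h = S))
  H <- matrix(style$h, S, S)
  Sat <- matrix(style$s, S, S)
  V <- style$v * (0.85 + 0.30 * coarse)

  hue <- runif(n, cultivar$hue_range[1], cultivar$hue_range[2]) / 360
  for (i in seq_len(n)) {
    w <- which(TOP == i)
    if (!length(w)) next
    lf <- leaves[i, ]
    H[w] <- hue[i] + 0.01 * sin(3 * Tm[w])
    Sat[w] <- 0.60 + 0.12 * (1 - Rm[w])
    V[w] <- 0.38 + 0.22 * (1 - Rm[w]) +
      0.05 * sin(2 * lf$lobe_n * Tm[w])^2 +
      0.12 * curl * sin(lf$lobe_n * Tm[w] + pi / 4) * Rm[w]
  }
  grad <- outer(rep(1, S), seq(0.90, 1.10, length.out = S))
  V <- V * scene$illumination_scale * grad
  V <- pmin(pmax(V + matrix(rnorm(S * S, 0, 0.01), S, S), 0), 1)
  rgb <- hsv_to_rgb(as.vector(H), as.vector(pmin(pmax(Sat, 0), 1)), as.vector(V))
  rgb <- round(rgb * 255) / 255
  rgb <- array(rgb, c(S, S, 3L))

  # --- depth (mm): ground plane at sensor height, plants strictly nearer ---
  ground_mm <- round(scene$sensor_height * 10)
  depth <- matrix(ground_mm, S, S) +
    matrix(sample(-2:2, S * S, replace = TRUE), S, S)
  depth[mask] <- ground_mm - round(Z[mask] * 10)

  # --- ground truth ---
  la <- sum(areas)
  lfw <- cultivar$allometry_alpha * la^cultivar$allometry_beta *
    exp(rnorm(1, 0, sigma_fw))
  ldw <- min(cultivar$dry_matter_fraction * lfw * exp(rnorm(1, 0, sigma_dw)),
             0.95 * lfw)
  gt <- list(
    traits = c(lfw_g = lfw, ldw_g = ldw, la_cm2 = la),
    total_leaf_area_cm2 = la,
    visible_projected_area_px = sum(mask)
  )
  structure(list(rgb = rgb, depth = depth, mask = mask,
                 height_cm = Z * ifelse(mask, 1, 0), cultivar = cultivar$name,
                 stage = stage, ground_truth = gt, scene = scene),
            class = "plant_sample")
}

#' @export
print.plant_sample <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<plant_sample> %s, stage %d, %dx%d px\n", x$cultivar, x$stage,
              nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  LFW %.2f g, LDW %.2f g, LA %.1f cm2, visible %d px\n",
              gt$traits[["lfw_g"]], gt$traits[["ldw_g"]],
              gt$traits[["la_cm2"]], gt$visible_projected_area_px))
  invisible(x)
}
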