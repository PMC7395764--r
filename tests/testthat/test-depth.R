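test_that("a centred near disk is selected against a far background", {
  d <- matrix(780, 120, 120)
  d2 <- outer((1:120 - 60.5)^2, (1:120 - 60.5)^2, "+")
  disk <- d2 <= 35^2
  d[disk] <- 700
  seg <- segment_depth(d, 100)
  iou <- sum(seg$mask & disk) / sum(seg$mask | disk)
  expect_gte(iou, 0.9)
  expect_false(seg$flagged)
})

test_that("synthetic plant depth maps segment close to the renderer mask", {
  for (stage in c(4L, 6L)) {
    ps <- fx_sample("Flandria", stage, seed = 23L)
    seg <- segment_depth(ps$depth, 300)
    iou <- sum(seg$mask & ps$mask) / sum(seg$mask | ps$mask)
    expect_gte(iou, 0.85)
  }
})

test_that("a constant depth map degrades to the centre superpixel with a warning", {
  d <- matrix(780, 60, 60)
  expect_warning(seg <- segment_depth(d, 36), "constant")
  expect_true(seg$flagged)
  expect_lt(sum(seg$mask), length(d))
  ctr <- seg$labels[30, 30]
  expect_true(all(seg$labels[seg$mask] == ctr))
})

test_that("an off-centre plant triggers the depth-plausibility flag", {
  d <- matrix(780, 120, 120)
  d2 <- outer((1:120 - 18)^2, (1:120 - 18)^2, "+")  # far corner
  d[d2 <= 14^2] <- 700
  expect_warning(seg <- segment_depth(d, 100), "background")
  expect_true(seg$flagged)
})

test_that("structural features follow their closed forms", {
  d <- matrix(780, 60, 60)
  mask <- matrix(FALSE, 60, 60)
  mask[cbind(sample(1:60, 50, TRUE), sample(1:60, 50, TRUE))] <- TRUE
  mask[1:40, 1:25] <- TRUE
  d[mask] <- 700
  n <- sum(mask)
  sf <- structural_features(d, mask, sensor_height = 78)
  expect_equal(sf$H_cm, 8)
  expect_equal(sf$PA_px, n)
  expect_equal(sf$V, n * 8)

  # mask covering the background plane exactly
  bg_mask <- matrix(FALSE, 60, 60); bg_mask[50:60, 50:60] <- TRUE
  d2 <- matrix(780, 60, 60)
  sf2 <- structural_features(d2, bg_mask, sensor_height = 78)
  expect_equal(sf2$H_cm, 0)
  expect_equal(sf2$V, 0)

  expect_warning(structural_features(matrix(800, 4, 4), matrix(TRUE, 4, 4), 78),
                 "clamped")
  expect_error(structural_features(d, matrix(FALSE, 60, 60), 78), "empty")
})

test_that("H matches the renderer's area-weighted mean height", {
  ps <- fx_sample("Tiberius", 5L, seed = 19L)
  sf <- structural_features(ps$depth, ps$mask, ps$scene$sensor_height)
  gt_h <- mean(ps$height_cm[ps$mask])
  expect_equal(sf$H_cm, gt_h, tolerance = 0.02)
})

test_that("PA depends only on the mask and H only on the depth multiset", {
  ps <- fx_sample("Flandria", 4L)
  d <- ps$depth
  noisy <- d + matrix(sample(-3:3, length(d), TRUE), nrow(d))
  expect_equal(structural_features(noisy, ps$mask, 78)$PA_px,
               structural_features(d, ps$mask, 78)$PA_px)
  shuf <- d
  withr::with_seed(1, shuf[ps$mask] <- sample(d[ps$mask]))
  expect_equal(structural_features(shuf, ps$mask, 78)$H_cm,
               structural_features(d, ps$mask, 78)$H_cm)
})

test_that("V equals PA times H on rendered samples", {
  for (stage in c(2L, 5L)) {
    ps <- fx_sample("Locarno", stage)
    sf <- structural_features(ps$depth, ps$mask, 78)
    expect_identical(sf$V, sf$PA_px * sf$H_cm)
  }
})

test_that("univariate linear fits recover exact and null relations", {
  withr::with_seed(8, {
    d <- tibble::tibble(x = runif(200, 0, 50))
    d$y <- 2 * d$x + 5
    fit <- suppressWarnings(fit_lr(d, "x", "y"))  # lm warns on exact fits
    expect_equal(fit$slope, 2)
    expect_equal(fit$intercept, 5)
    expect_equal(suppressWarnings(glance(fit))$r.squared, 1)
    expect_equal(predict(fit, tibble::tibble(x = c(0, 10))), c(5, 25))

    d$y_perm <- sample(d$y)
    null_fit <- fit_lr(d, "x", "y_perm")
    expect_lt(r_squared(d$y_perm, null_fit$fitted), 0.1)
  })
  expect_error(fit_lr(tibble::tibble(x = rep(1, 10), y = 1:10), "x", "y"),
               "constant")
  expect_error(fit_lr(tibble::tibble(x = 1:2, y = 1:2), "x", "y"), "3 samples")
})
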