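test_that("greenness segmentation recovers the rendered plant", {
  ps <- fx_sample("Tiberius", 4L)
  seg <- segment_plant(ps$rgb)
  iou <- sum(seg$mask & ps$mask) / sum(seg$mask | ps$mask)
  expect_gte(iou, 0.9)
  expect_equal(seg$plant_pixel_count, sum(seg$mask))
})

test_that("an all-background image raises an empty-mask error naming the image", {
  bg <- array(0.1, c(64, 64, 3))
  bg[, , 1] <- 0.1 + runif(64 * 64, 0, 0.02)
  expect_error(segment_plant(bg, .name = "tray_only.png"), "tray_only.png")
})

test_that("segmented area is invariant to image rotation", {
  ps <- fx_sample("Flandria", 3L)
  rot <- lactuca:::apply_geometric(ps$rgb, "rot90")
  expect_identical(segment_plant(ps$rgb)$plant_pixel_count,
                   segment_plant(rot)$plant_pixel_count)
})

test_that("the descriptor set has exactly 92 stable, finite entries", {
  ps <- fx_sample("Locarno", 3L)
  fv <- extract_features(ps$rgb, ps$mask)
  expect_equal(ncol(fv), 92L)
  expect_true(all(is.finite(as.numeric(fv[1, ]))))
  expect_equal(sum(grepl("_Average$", names(fv))), 15L)
  expect_equal(sum(grepl("_Std$", names(fv))), 15L)
  expect_equal(sum(grepl("_(Contrast|Correlation|Energy|Homogeneity)$", names(fv))), 60L)
  expect_true(all(c("Area", "Perimeter", "RGB_G_Energy", "HSI_S_Std",
                    "YCrCb_Cb_Average", "LAB_A_Average") %in% names(fv)))
  en <- as.numeric(fv[grepl("_Energy$", names(fv))])
  ho <- as.numeric(fv[grepl("_Homogeneity$", names(fv))])
  expect_true(all(en > 0 & en <= 1))
  expect_true(all(ho > 0 & ho <= 1))
  # repeat run: identical names and values
  expect_identical(extract_features(ps$rgb, ps$mask), fv)
})

test_that("a constant-colour region has degenerate texture and zero spread", {
  img <- array(0.4, c(16, 16, 3))
  mask <- matrix(TRUE, 16, 16)
  fv <- extract_features(img, mask)
  expect_equal(as.numeric(fv[grepl("_Energy$", names(fv))]), rep(1, 15))
  expect_equal(as.numeric(fv[grepl("_Contrast$", names(fv))]), rep(0, 15))
  expect_equal(as.numeric(fv[grepl("_Std$", names(fv))]), rep(0, 15))
})

test_that("a two-level checkerboard matches the hand-enumerated co-occurrence", {
  # two adjacent quantization levels under fixed [0, 1] gray limits:
  # P = [[0, .5], [.5, 0]] -> contrast 1, energy 0.5
  ch <- matrix(c(0, 1, 1, 0) / 16, 2, 2)
  mask <- matrix(TRUE, 2, 2)
  g <- lactuca:::glcm_stats(ch, mask, levels = 16L, directions = 1L,
                            gray_limits = c(0, 1))
  expect_equal(g[["contrast"]], 1)
  expect_equal(g[["energy"]], 0.5)
  expect_equal(g[["correlation"]], -1)
})

test_that("texture statistics equal the brute-force pair enumeration", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(2:8, 1); m <- sample(2:8, 1)
      ch <- matrix(sample(0:5, n * m, replace = TRUE) / 5, n, m)
      mask <- matrix(runif(n * m) < 0.8, n, m)
      if (sum(mask) < 2) next
      got <- tryCatch(lactuca:::glcm_stats(ch, mask, 16L),
                      error = function(e) NULL)
      want <- glcm_oracle(ch, mask, 16L, glcm_offsets)
      if (is.null(got)) {
        expect_true(all(is.nan(want)) || sum(mask) < 2)
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("disk shape features match their closed forms", {
  r <- 50
  d2 <- outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, "+")
  mask <- d2 <= r^2
  img <- array(0.3, c(128, 128, 3)); img[, , 2] <- 0.6
  fv <- extract_features(img, mask)
  expect_equal(fv$Area, pi * r^2, tolerance = 0.01)
  expect_equal(fv$Perimeter, 2 * pi * r, tolerance = 0.05)
})

test_that("Pearson screening selects by absolute correlation", {
  withr::with_seed(5, {
    n <- 40
    y <- runif(n, 10, 100)
    feats <- tibble::tibble(same = y, neg = -y, noise = rnorm(n),
                            const = rep(1, n))
  })
  expect_warning(sel <- pearson_screen(feats, y, threshold = 0.65), "constant")
  expect_setequal(sel$feature, c("same", "neg"))
  expect_equal(sel$r[sel$feature == "same"], 1)
  expect_equal(sel$r[sel$feature == "neg"], -1)
  expect_true(all(sel$p < 0.01))
  expect_error(pearson_screen(feats, rep(2, n)), "constant")
  expect_error(pearson_screen(feats[1:2, ], y[1:2]), "3 samples")
})
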