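test_that("rendering is byte-deterministic under a fixed scene seed", {
  sc <- fx_scene(seed = 31L)
  a <- render_plant(default_cultivars()$Tiberius, 3L, sc)
  b <- render_plant(default_cultivars()$Tiberius, 3L, sc)
  expect_identical(a, b)
})

test_that("stage and scene inputs are validated", {
  cv <- default_cultivars()$Flandria
  expect_error(render_plant(cv, 0L, fx_scene()), "1\\.\\.7")
  expect_error(render_plant(cv, 8L, fx_scene()), "1\\.\\.7")
  expect_error(scene_spec(image_size = -5), "positive")
  expect_error(cultivar_spec("x", "flat", curl_amplitude = 0.2), "curl")
  expect_error(cultivar_spec("x", "flat", dry_matter_fraction = 0.2), "dry_matter")
})

test_that("a single flat ellipse recovers the closed-form area", {
  cv <- default_cultivars()$Flandria
  sc <- scene_spec(image_size = 240L, px_per_cm = 12, rng_seed = 4L)
  one_leaf <- tibble::tibble(a_cm = 5, b_cm = 3, angle_deg = 30, dist_cm = 0,
                             lobe_amp = 0, lobe_n = 8L, z_cm = 5)
  ps <- render_plant(cv, 3L, sc, leaves = one_leaf)
  expect_equal(ps$ground_truth$total_leaf_area_cm2, pi * 5 * 3, tolerance = 1e-6)
  raster_cm2 <- ps$ground_truth$visible_projected_area_px / sc$px_per_cm^2
  expect_equal(raster_cm2, pi * 5 * 3, tolerance = 0.02)
})

test_that("curling reduces the visible fraction of the true leaf area", {
  occl <- function(ps) {
    ps$ground_truth$visible_projected_area_px /
      (ps$ground_truth$total_leaf_area_cm2 * ps$scene$px_per_cm^2)
  }
  for (seed in c(5L, 17L, 29L)) {
    flat <- render_plant(default_cultivars()$Flandria, 4L, fx_scene(seed))
    curled <- render_plant(default_cultivars()$Locarno, 4L, fx_scene(seed))
    expect_lt(occl(curled), occl(flat))
  }
})

test_that("ground truth satisfies its structural invariants", {
  for (stage in c(2L, 5L)) {
    ps <- fx_sample("Locarno", stage, seed = 13L)
    gt <- ps$ground_truth
    expect_equal(gt$traits[["la_cm2"]], gt$total_leaf_area_cm2)
    expect_lt(gt$traits[["ldw_g"]], gt$traits[["lfw_g"]])
    expect_gte(gt$total_leaf_area_cm2,
               gt$visible_projected_area_px / ps$scene$px_per_cm^2)
    # depth: every plant pixel strictly above the ground plane
    expect_true(all(ps$scene$sensor_height * 10 - ps$depth[ps$mask] > 0))
  }
})

test_that("log-log regression of LFW on LA recovers the allometric exponent", {
  cv <- default_cultivars()$Tiberius
  sc <- scene_spec(image_size = 160L, px_per_cm = 4, rng_seed = 1L)
  gt <- purrr::map_dfr(1:200, function(i) {
    s <- sc; s$rng_seed <- 1000L + i
    tr <- render_plant(cv, ((i - 1) %% 7) + 1L, s)$ground_truth$traits
    tibble::tibble(lfw = tr[["lfw_g"]], la = tr[["la_cm2"]])
  })
  fit <- lm(log(lfw) ~ log(la), data = gt)
  beta_hat <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(beta_hat - cv$allometry_beta), 3 * se)
})

test_that("mean ground-truth leaf area increases strictly with session", {
  cv <- default_cultivars()$Flandria
  sc <- scene_spec(image_size = 160L, px_per_cm = 4, rng_seed = 2L)
  means <- vapply(1:7, function(stage) {
    mean(vapply(1:50, function(i) {
      s <- sc; s$rng_seed <- 5000L + 77L * i
      render_plant(cv, stage, s)$ground_truth$traits[["la_cm2"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generate_dataset balances sessions and writes a reproducible CSV", {
  man <- fx_manifest(7L)
  expect_equal(nrow(man), 21L)
  one <- generate_dataset(7L, default_cultivars()["Flandria"],
                          fx_scene(3L), write_images = FALSE)
  expect_equal(sort(one$session), 1:7)

  expect_error(generate_dataset(5L, write_images = FALSE), ">= 7")

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  sc <- scene_spec(image_size = 120L, px_per_cm = 3, rng_seed = 9L)
  m1 <- generate_dataset(7L, default_cultivars()["Tiberius"], sc, out_dir = out1)
  m2 <- generate_dataset(7L, default_cultivars()["Tiberius"], sc, out_dir = out2)
  expect_identical(readLines(file.path(out1, "manifest.csv")),
                   readLines(file.path(out2, "manifest.csv")))
  expect_true(all(file.exists(m1$rgb_path)))
  expect_true(all(file.exists(m1$depth_path)))
  # depth round-trips exactly through the 16-bit raster
  ps <- attr(generate_dataset(7L, default_cultivars()["Tiberius"], sc,
                              write_images = FALSE), "samples")[[m1$id[1]]]
  expect_identical(read_depth(m1$depth_path[1]), ps$depth)
})
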