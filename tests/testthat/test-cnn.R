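# A reduced-width architecture (same layer pattern, tiny channel counts) is
# used for the fast functional checks; the full-width network is exercised
# by the trait-recovery and memorization tests in the acceptance suite.
tiny_cfg <- function() cnn_config(conv_channels = c(2L, 3L, 4L, 5L, 6L))
tiny_sched <- function(epochs = 2L) {
  train_config(max_epochs = epochs, batch_size = 4L, rng_seed = 9L)
}

rand_images <- function(n, side = 128L, seed = 1L) {
  withr::with_seed(seed, {
    setNames(lapply(seq_len(n), function(i) array(runif(side * side * 3), c(side, side, 3L))),
             sprintf("im%02d", seq_len(n)))
  })
}

rand_traits <- function(n, seed = 2L) {
  withr::with_seed(seed, tibble::tibble(lfw_g = runif(n, 5, 50),
                                        ldw_g = runif(n, 0.5, 5),
                                        la_cm2 = runif(n, 50, 500)))
}

test_that("the default shape plan matches the architecture's arithmetic", {
  plan <- layer_shape_plan(cnn_config())
  got <- setNames(plan$side, plan$layer)
  expect_equal(unname(got[c("conv1", "pool1", "conv2 (pad 1)", "pool2",
                            "conv3 (pad 1)", "pool3", "conv4", "pool4",
                            "conv5")]),
               c(124L, 62L, 60L, 30L, 28L, 14L, 10L, 5L, 1L))
  expect_equal(plan$channels[plan$layer == "conv5"], 512L)
  expect_equal(sum(plan$type == "pool"), 4L)
  expect_equal(plan$side[plan$type == "fc"], 1L)
})

test_that("invalid feature-map geometries are rejected with the offending layer", {
  expect_error(layer_shape_plan(cnn_config(padded_layers = integer())), "odd")
  expect_error(layer_shape_plan(cnn_config(input_side = 64L)), "conv5")
})

test_that("the learning-rate schedule steps by the drop factor every 20 epochs", {
  sched <- train_config()
  expect_equal(lr_schedule(45, sched), 0.001 * 0.1^2)
  epochs <- 0:300
  expect_equal(lr_schedule(epochs, sched), 0.001 * 0.1^floor(epochs / 20))
})

test_that("training is deterministic per seed and logs the lr sequence", {
  imgs <- rand_images(8)
  tr <- rand_traits(8)
  f1 <- train_cnn(imgs, tr, config = tiny_cfg(), schedule = tiny_sched())
  f2 <- train_cnn(imgs, tr, config = tiny_cfg(), schedule = tiny_sched())
  expect_identical(f1$weights, f2$weights)
  expect_equal(f1$log$lr, lr_schedule(0:1, tiny_sched()))
})

test_that("prediction is stateless, order-equivariant and batch-agnostic", {
  imgs <- rand_images(6)
  fit <- train_cnn(imgs, rand_traits(6), config = tiny_cfg(),
                   schedule = tiny_sched())
  p_all <- predict(fit, imgs)
  p_perm <- predict(fit, imgs[c(4, 1, 6, 2, 3, 5)])
  expect_equal(p_perm, p_all[c(4, 1, 6, 2, 3, 5), ], tolerance = 1e-7,
               ignore_attr = TRUE)
  p_single <- do.call(rbind, lapply(names(imgs), function(nm) predict(fit, imgs[nm])))
  expect_equal(unname(p_single), unname(p_all), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(predict(fit, rand_images(2, side = 64L)), "128")
})

test_that("the conv/pool stack output is invariant to rotating a constant input", {
  imgs <- rand_images(4)
  fit <- train_cnn(imgs, rand_traits(4), config = tiny_cfg(),
                   schedule = tiny_sched())
  const <- array(0.5, c(128, 128, 3))
  rot <- aperm(const, c(2, 1, 3))[128:1, , , drop = FALSE]
  expect_equal(predict(fit, list(a = const)), predict(fit, list(a = rot)),
               tolerance = 1e-7)
})

test_that("oversized batches are clipped with a warning and NaN-free training", {
  imgs <- rand_images(4)
  expect_warning(
    train_cnn(imgs, rand_traits(4), config = tiny_cfg(),
              schedule = train_config(max_epochs = 1L, batch_size = 64L,
                                      rng_seed = 1L)),
    "clipped")
})

test_that("targets are de-standardized to physical units and clamped at zero", {
  imgs <- rand_images(10)
  tr <- rand_traits(10)
  fit <- train_cnn(imgs, tr, config = tiny_cfg(), schedule = tiny_sched(1L))
  p <- predict(fit, imgs)
  expect_true(all(p >= 0))
  expect_equal(colnames(p), c("lfw_g", "ldw_g", "la_cm2"))
  # standardization constants come from the training targets
  expect_equal(fit$scaling$mean, colMeans(as.matrix(tr)), ignore_attr = TRUE)
})

test_that("checkpoints round-trip through save/load", {
  imgs <- rand_images(4)
  fit <- train_cnn(imgs, rand_traits(4), config = tiny_cfg(),
                   schedule = tiny_sched(1L))
  f <- withr::local_tempfile(fileext = ".rds")
  save_cnn(fit, f)
  fit2 <- load_cnn(f)
  expect_equal(predict(fit2, imgs), predict(fit, imgs))
})
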