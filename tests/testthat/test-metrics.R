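test_that("R-squared against the 1:1 line matches hand arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("NRMSE normalizes by the mean and is scale invariant", {
  expect_equal(nrmse(c(10, 10), c(9, 11)), 10)
  expect_equal(nrmse(c(5, 7, 9), c(5, 7, 9)), 0)
  a <- c(10, 20, 30); p <- c(12, 18, 33)
  expect_equal(nrmse(3 * a, 3 * p), nrmse(a, p))
  expect_error(nrmse(c(-5, 5), c(1, 2)), "positive")
  expect_equal(nrmse(c(10, 10, 40), c(9, 11, 40), mode = "range"),
               100 * sqrt(2 / 3) / 30)
})

fake_predictions <- function() {
  withr::with_seed(12, {
    ids <- sprintf("s%02d", 1:12)
    cultivar <- rep(c("A", "B", "C"), each = 4)
    purrr::map_dfr(c("m1", "m2"), function(m) {
      purrr::map_dfr(c("lfw_g", "ldw_g"), function(tr) {
        actual <- runif(12, 10, 100)
        tibble::tibble(model = m, trait = tr, id = ids, cultivar = cultivar,
                       actual = actual,
                       predicted = actual + rnorm(12, 0, 5))
      })
    })
  })
}

test_that("the report grid has one row per model, trait and stratum", {
  pred <- fake_predictions()
  rep <- build_report(pred, strata = c("all", "cultivar"))
  expect_equal(nrow(rep), 2 * 2 * (1 + 3))
  expect_true(all(is.finite(rep$r2)) && all(rep$r2 <= 1))
  expect_true(all(rep$nrmse >= 0))
  perfect <- pred %>% dplyr::mutate(predicted = actual)
  rp <- build_report(perfect)
  expect_true(all(rp$r2 == 1) && all(rp$nrmse == 0))
})

test_that("report rows satisfy the R2/NRMSE variance identity", {
  rep <- build_report(fake_predictions(), strata = c("all", "cultivar"))
  pred <- report_predictions(rep)
  for (i in seq_len(nrow(rep))) {
    rows <- pred %>% dplyr::filter(.data$model == rep$model[i],
                                   .data$trait == rep$trait[i])
    if (rep$stratum[i] != "all") rows <- rows %>% dplyr::filter(.data$cultivar == rep$stratum[i])
    var_pop <- mean((rows$actual - mean(rows$actual))^2)
    expect_equal(rep$r2[i],
                 1 - (rep$nrmse[i] / 100)^2 * mean(rows$actual)^2 / var_pop)
  }
})

test_that("pooled squared error equals the sum of per-cultivar errors", {
  rep <- build_report(fake_predictions(), strata = c("all", "cultivar"))
  sse <- function(row) {
    (row$nrmse / 100)^2 * row$mean_a^2 * row$n
  }
  pred <- report_predictions(rep)
  means <- pred %>% dplyr::group_by(.data$model, .data$trait) %>%
    dplyr::summarise(mean_a = mean(.data$actual), .groups = "drop")
  aug <- rep %>% dplyr::left_join(means, by = c("model", "trait"))
  # recompute per-row mean over the row's own stratum
  for (m in unique(rep$model)) for (tr in unique(rep$trait)) {
    rows <- pred %>% dplyr::filter(.data$model == m, .data$trait == tr)
    pooled <- sum((rows$actual - rows$predicted)^2)
    per_cv <- sum(vapply(split(rows, rows$cultivar), function(g) {
      sum((g$actual - g$predicted)^2)
    }, numeric(1)))
    expect_equal(pooled, per_cv)
  }
  expect_true(all(c("n", "r2", "nrmse") %in% names(aug)))
})

test_that("incomplete prediction sets are rejected", {
  pred <- fake_predictions()
  expect_error(build_report(pred[-1, ]), "differing test id")
  pred2 <- fake_predictions()
  pred2$predicted[3] <- NA
  expect_error(build_report(pred2), "[Mm]issing")
})

test_that("cross-season evaluation never refits and demands disjoint ids", {
  skip_if_not_installed("lactuca")
  imgs <- withr::with_seed(3, setNames(
    lapply(1:6, function(i) array(runif(128 * 128 * 3), c(128, 128, 3))),
    sprintf("n%02d", 1:6)))
  traits <- tibble::tibble(id = names(imgs), lfw_g = runif(6, 10, 60),
                           ldw_g = runif(6, 1, 6), la_cm2 = runif(6, 100, 600))
  fit <- train_cnn(imgs[1:4], traits[1:4, c("lfw_g", "ldw_g", "la_cm2")],
                   config = cnn_config(conv_channels = c(2L, 3L, 4L, 5L, 6L)),
                   schedule = train_config(max_epochs = 1L, batch_size = 2L,
                                           rng_seed = 2L))
  h0 <- rlang::hash(fit$weights)
  rep <- generalization_eval(fit, imgs[5:6], traits, train_ids = names(imgs)[1:4])
  expect_identical(rlang::hash(fit$weights), h0)
  expect_true(all(rep$stratum == "cross-season"))
  expect_true(all(is.finite(rep$r2)))
  expect_error(generalization_eval(fit, imgs[4:6], traits, names(imgs)[1:4]),
               "overlap")
  expect_error(generalization_eval(fit, list(), traits, character()), "empty")
})
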