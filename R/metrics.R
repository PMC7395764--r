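# Evaluation layer: R^2 against the 1:1 line, NRMSE (percent of the mean of
# the observed values by default), the model x trait comparison grid and the
# cross-season generalization protocol.

#' Coefficient of determination against the 1:1 line
#'
#' `1 - sum((a - p)^2) / sum((a - mean(a))^2)`. This is agreement with the
#' identity line, not squared correlation, so it can be negative.
#'
#' @param actual,predicted Equal-length numeric vectors (>= 2 values).
#' @return A single number <= 1.
#' @export
r_squared <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (stats::sd(actual) == 0) abort("`actual` is constant; R^2 is undefined.")
  1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)
}

#' Normalized root mean square error, percent
#'
#' `100 * sqrt(mean((a - p)^2)) / norm` where the normalizer is the mean of
#' the observed values by default (`mode = "mean"`), or their range or
#' standard deviation.
#'
#' @param actual,predicted Equal-length numeric vectors (>= 2 values).
#' @param mode Normalization mode: `"mean"`, `"range"` or `"sd"`.
#' @return NRMSE in percent (>= 0).
#' @export
nrmse <- function(actual, predicted, mode = c("mean", "range", "sd")) {
  mode <- match.arg(mode)
  check_pair(actual, predicted)
  norm <- switch(mode, mean = mean(actual), range = diff(range(actual)),
                 sd = stats::sd(actual))
  if (!is.finite(norm) || norm <= 0) {
    abort(sprintf("NRMSE normalizer (%s of actual) must be positive.", mode))
  }
  100 * sqrt(mean((actual - predicted)^2)) / norm
}

check_pair <- function(actual, predicted) {
  if (length(actual) != length(predicted)) abort("`actual` and `predicted` lengths differ.")
  if (length(actual) < 2) abort("Need at least 2 observations.")
  if (anyNA(actual) || anyNA(predicted)) abort("Missing values in actual/predicted.")
  invisible(TRUE)
}

#' Build the model-comparison evaluation report
#'
#' Takes a long table of test-set predictions and computes R^2 and NRMSE
#' per (model, trait), optionally also per cultivar. Every model must
#' predict on the identical set of test ids for every trait.
#'
#' @param predictions Tibble with columns `model`, `trait`, `id`, `actual`,
#'   `predicted` and (for cultivar strata) `cultivar`.
#' @param strata `"all"` or `"cultivar"` (both may be given; rows are
#'   labelled by a `stratum` column).
#' @param nrmse_mode Normalization mode passed to [nrmse()].
#' @return A tibble of class `eval_report`: `(model, trait, stratum, n, r2,
#'   nrmse)`, with the prediction pairs retained as attribute `predictions`.
#' @export
build_report <- function(predictions, strata = "all", nrmse_mode = "mean") {
  needed <- c("model", "trait", "id", "actual", "predicted")
  if (!all(needed %in% names(predictions))) {
    abort(sprintf("`predictions` must contain columns: %s.", paste(needed, collapse = ", ")))
  }
  if ("cultivar" %in% strata && !"cultivar" %in% names(predictions)) {
    abort("Cultivar strata requested but no `cultivar` column present.")
  }
  # every model must cover the same ids per trait
  cover <- predictions %>% group_by(.data$model, .data$trait) %>%
    summarise(ids = list(sort(unique(.data$id))), .groups = "drop")
  ref <- cover$ids[[1]]
  if (!all(vapply(cover$ids, identical, logical(1), ref))) {
    abort("Models predict on differing test id sets; report would not be comparable.")
  }
  if (anyNA(predictions$predicted)) abort("Missing predictions for some test ids.")

  summarize_cell <- function(df) {
    tibble(n = nrow(df), r2 = r_squared(df$actual, df$predicted),
           nrmse = nrmse(df$actual, df$predicted, nrmse_mode))
  }
  out <- list()
  if ("all" %in% strata) {
    out$all <- predictions %>% group_by(.data$model, .data$trait) %>%
      dplyr::group_modify(~ summarize_cell(.x)) %>% ungroup() %>%
      mutate(stratum = "all")
  }
  if ("cultivar" %in% strata) {
    out$cultivar <- predictions %>%
      group_by(.data$model, .data$trait, .data$cultivar) %>%
      dplyr::group_modify(~ summarize_cell(.x)) %>% ungroup() %>%
      mutate(stratum = .data$cultivar) %>% select(-"cultivar")
  }
  rep <- bind_rows(out) %>% select("model", "trait", "stratum", "n", "r2", "nrmse")
  attr(rep, "predictions") <- predictions
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Cross-season generalization evaluation
#'
#' Applies an already-fitted model to a new-season sample set with zero
#' refitting and reports R^2/NRMSE labelled as cross-season. Ids must be
#' disjoint from the training ids.
#'
#' @param fit A fitted model with a `predict` method returning a 3-column
#'   trait matrix (e.g. [train_cnn()]'s `cnn_fit`).
#' @param new_images Named list of images (names are sample ids).
#' @param new_traits Tibble with `id`, `lfw_g`, `ldw_g`, `la_cm2` (and
#'   optionally `cultivar`).
#' @param train_ids Ids used for training, for the disjointness check.
#' @param model_label Label used in the report's `model` column.
#' @return An `eval_report` with `stratum = "cross-season"`.
#' @export
generalization_eval <- function(fit, new_images, new_traits, train_ids,
                                model_label = "CNN") {
  if (!length(new_images)) abort("New-season sample set is empty.")
  overlap <- intersect(names(new_images), train_ids)
  if (length(overlap)) {
    abort(sprintf("New-season ids overlap the training set (%d ids).", length(overlap)))
  }
  pred <- predict(fit, new_images)
  traits <- c("lfw_g", "ldw_g", "la_cm2")
  long <- purrr::map_dfr(seq_along(traits), function(k) {
    tibble(model = model_label, trait = traits[k], id = names(new_images),
           actual = new_traits[[traits[k]]][match(names(new_images), new_traits$id)],
           predicted = pred[, k])
  })
  rep <- build_report(long, strata = "all")
  rep$stratum <- "cross-season"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  NextMethod()
  invisible(x)
}

#' Scatter data for predicted-vs-actual plots
#'
#' @param report An `eval_report`.
#' @return The long predictions tibble stored in the report.
#' @export
report_predictions <- function(report) {
  attr(report, "predictions")
}
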