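#' Shallow baseline model specification
#'
#' @param kind `"svr"` (epsilon support-vector regression, radial kernel) or
#'   `"rf"` (random forest).
#' @param hyperparameters Named list. SVR: `kernel`, `C`, `epsilon`,
#'   `gamma` (optional). RF: `n_trees`, `max_depth` (NULL = unlimited),
#'   `min_leaf`.
#' @param rng_seed Integer seed for the stochastic fit (RF bootstrap).
#' @return List of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("svr", "rf"), hyperparameters = list(),
                          rng_seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svr = list(kernel = "radial", C = 10, epsilon = 0.1),
    rf = list(n_trees = 500L, max_depth = NULL, min_leaf = 5L)
  )
  hp <- modifyList(defaults, hyperparameters)
  if (kind == "svr" && (hp$C <= 0 || hp$epsilon <= 0)) {
    abort("SVR `C` and `epsilon` must be positive.")
  }
  if (kind == "rf" && hp$n_trees <= 0) abort("RF `n_trees` must be positive.")
  structure(list(kind = kind, hyperparameters = hp,
                 rng_seed = as.integer(rng_seed)),
            class = "baseline_spec")
}

#' Fit a shallow baseline regressor on selected features
#'
#' One single-output model per trait (the multi-output head is specific to
#' the convolutional regressor). Features are standardized inside the fit
#' using training statistics only; the scaling constants are stored in the
#' fitted object and reused at prediction.
#'
#' @param spec A [baseline_spec()].
#' @param features Training feature tibble/data frame (numeric columns; an
#'   `id` column is ignored).
#' @param target Numeric trait vector (one per row).
#' @return Object of class `baseline_fit`.
#' @export
fit_baseline <- function(spec, features, target) {
  X <- as.data.frame(features)[setdiff(names(features), "id")]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (nrow(X) < 10) abort("Need at least 10 training samples for a baseline fit.")
  if (length(target) != nrow(X)) abort("`target` length must match `features` rows.")
  if (anyNA(X) || anyNA(target)) abort("Baselines do not accept missing values.")
  mu <- vapply(X, mean, numeric(1))
  sdev <- vapply(X, stats::sd, numeric(1))
  sdev[sdev == 0] <- 1
  Xs <- as.data.frame(scale(X, center = mu, scale = sdev))
  hp <- spec$hyperparameters
  if (stats::sd(target) == 0) {
    # degenerate regression target: both kinds reduce to the constant
    return(structure(list(spec = spec, model = list(constant = target[1]),
                          feature_names = names(Xs), center = mu, scale = sdev),
                     class = "baseline_fit"))
  }
  model <- withr::with_seed(spec$rng_seed, switch(spec$kind,
    svr = e1071::svm(x = as.matrix(Xs), y = target, type = "eps-regression",
                     kernel = hp$kernel, cost = hp$C, epsilon = hp$epsilon,
                     gamma = hp$gamma %||% (1 / ncol(Xs)), scale = FALSE),
    rf = randomForest::randomForest(
      x = Xs, y = target, ntree = hp$n_trees,
      nodesize = hp$min_leaf %||% 5L,
      maxnodes = if (!is.null(hp$max_depth)) 2L^hp$max_depth else NULL)
  ))
  structure(list(spec = spec, model = model, feature_names = names(Xs),
                 center = mu, scale = sdev),
            class = "baseline_fit")
}

#' Predict traits with a fitted baseline
#'
#' @param object A `baseline_fit`.
#' @param newdata Feature tibble with the same columns as at fit time.
#' @param ... Unused.
#' @return Numeric predictions, negative values clamped to 0 (the clamp
#'   count is attached as attribute `n_clamped`).
#' @export
predict.baseline_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    abort(sprintf("Missing feature columns: %s", paste(missing, collapse = ", ")))
  }
  X <- as.data.frame(newdata)[object$feature_names]
  Xs <- as.data.frame(scale(X, center = object$center, scale = object$scale))
  if (is.list(object$model) && !is.null(object$model$constant)) {
    return(structure(rep(max(object$model$constant, 0), nrow(Xs)), n_clamped = 0L))
  }
  p <- as.numeric(switch(object$spec$kind,
    svr = predict(object$model, as.matrix(Xs)),
    rf = predict(object$model, Xs)
  ))
  n_clamped <- sum(p < 0)
  if (n_clamped > 0) {
    inform(sprintf("Clamped %d negative baseline prediction(s) to 0.", n_clamped))
  }
  structure(pmax(p, 0), n_clamped = n_clamped)
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s on %d features\n", toupper(x$spec$kind),
              length(x$feature_names)))
  invisible(x)
}
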