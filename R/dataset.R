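#' Crop and resize an image to a square
#'
#' Crops either an explicit pixel rectangle or, in auto mode, the largest
#' centered square containing the plant bounding box plus a 5% margin, then
#' resizes to `target_side` x `target_side` (bilinear by default).
#'
#' @param image RGB array (height x width x 3).
#' @param crop_box `"auto"`, `NULL` (no crop, but the image must be made
#'   square by centered cropping of the long side), or an integer vector
#'   `c(y0, y1, x0, x1)` of inclusive pixel bounds.
#' @param target_side Output side in pixels (> 0).
#' @param mask Optional logical plant mask for auto mode; when absent the
#'   plant bounding box is found by greenness segmentation
#'   ([segment_plant()]).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return RGB array `target_side` x `target_side` x 3.
#' @export
center_crop_resize <- function(image, crop_box = "auto", target_side = 900L,
                               mask = NULL,
                               interpolation = c("bilinear", "nearest")) {
  assert_rgb(image)
  interpolation <- match.arg(interpolation)
  if (target_side <= 0) abort("`target_side` must be positive.")
  h <- dim(image)[1]; w <- dim(image)[2]

  if (is.character(crop_box) && identical(crop_box, "auto")) {
    if (is.null(mask)) mask <- segment_plant(image)$mask
    ys <- range(which(rowSums(mask) > 0))
    xs <- range(which(colSums(mask) > 0))
    side <- max(ys[2] - ys[1], xs[2] - xs[1]) + 1
    side <- min(ceiling(side * 1.05), h, w)
    cy <- mean(ys); cx <- mean(xs)
    y0 <- round(cy - side / 2); x0 <- round(cx - side / 2)
    y0 <- min(max(y0, 1), h - side + 1)
    x0 <- min(max(x0, 1), w - side + 1)
    crop_box <- c(y0, y0 + side - 1, x0, x0 + side - 1)
  } else if (is.null(crop_box)) {
    side <- min(h, w)
    y0 <- floor((h - side) / 2) + 1
    x0 <- floor((w - side) / 2) + 1
    crop_box <- c(y0, y0 + side - 1, x0, x0 + side - 1)
  }
  cb <- as.integer(round(crop_box))
  if (length(cb) != 4L || cb[1] < 1 || cb[3] < 1 || cb[2] > h || cb[4] > w ||
      cb[1] > cb[2] || cb[3] > cb[4]) {
    abort("`crop_box` must be c(y0, y1, x0, x1) within the image bounds.")
  }
  out <- image[cb[1]:cb[2], cb[3]:cb[4], , drop = FALSE]
  if (dim(out)[1] == target_side && dim(out)[2] == target_side) return(out)
  resized <- EBImage::resize(EBImage::Image(out, colormode = "Color"),
                             w = target_side, h = target_side,
                             filter = if (interpolation == "bilinear") "bilinear" else "none")
  array(as.numeric(EBImage::imageData(resized)),
        c(target_side, target_side, 3L))
}

#' Split specification
#'
#' @param train_fraction Fraction of samples assigned to training (0..1,
#'   default 0.8 for the 8:2 protocol).
#' @param val_fraction_of_train Fraction of the training set carved out as
#'   validation (default 0.2).
#' @param stratify_by Stratification columns, subset of
#'   `c("cultivar", "session")`.
#' @param rng_seed Integer seed.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, val_fraction_of_train = 0.2,
                       stratify_by = c("cultivar", "session"), rng_seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  if (val_fraction_of_train < 0 || val_fraction_of_train >= 1) {
    abort("`val_fraction_of_train` must lie in [0, 1).")
  }
  stopifnot(all(stratify_by %in% c("cultivar", "session")))
  structure(list(train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 stratify_by = stratify_by, rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' Assigns each sample to train, validation or test. Training counts are
#' computed per stratum by round-half-up, then reconciled to the global
#' target `round(train_fraction * N)` by moving at most one sample per
#' stratum (those with the largest rounding surplus/deficit first), so every
#' stratum with at least two samples keeps presence in both train and test.
#' The validation set is `round(val_fraction_of_train * |train|)` samples
#' drawn at random from the training set.
#'
#' @param manifest Tibble with at least `id` plus the stratification columns.
#' @param spec A [split_spec()].
#' @return Tibble `(id, split)` with `split` in
#'   `c("train", "val", "test")`; also carries the spec as an attribute.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  if (!nrow(manifest)) abort("`manifest` is empty.")
  if (!all(c("id", spec$stratify_by) %in% names(manifest))) {
    abort("`manifest` must contain `id` and the stratification columns.")
  }
  N <- nrow(manifest)
  target_train <- round_half_up(spec$train_fraction * N)

  withr::with_seed(spec$rng_seed, {
    strata <- manifest
    strata$.stratum <- if (length(spec$stratify_by)) {
      do.call(paste, c(unclass(manifest[spec$stratify_by]), sep = "/"))
    } else ".all"
    # per-stratum tallies
    tab <- strata %>% group_by(.data$.stratum) %>%
      summarise(n = n(), .groups = "drop") %>%
      mutate(exact = spec$train_fraction * .data$n,
             n_train = round_half_up(.data$exact))
    # keep both sides covered where possible
    tab <- tab %>% mutate(
      n_train = pmin(pmax(.data$n_train, ifelse(.data$n >= 2, 1L, .data$n_train)),
                     ifelse(.data$n >= 2, .data$n - 1L, .data$n))
    )
    # reconcile to the global target, one move per stratum
    excess <- sum(tab$n_train) - target_train
    if (excess > 0) {
      ord <- order(tab$n_train - tab$exact, decreasing = TRUE)
      for (i in ord) {
        if (excess == 0) break
        if (tab$n_train[i] > ifelse(tab$n[i] >= 2, 1L, 0L)) {
          tab$n_train[i] <- tab$n_train[i] - 1L; excess <- excess - 1L
        }
      }
    } else if (excess < 0) {
      ord <- order(tab$exact - tab$n_train, decreasing = TRUE)
      for (i in ord) {
        if (excess == 0) break
        cap <- ifelse(tab$n[i] >= 2, tab$n[i] - 1L, tab$n[i])
        if (tab$n_train[i] < cap) {
          tab$n_train[i] <- tab$n_train[i] + 1L; excess <- excess + 1L
        }
      }
    }
    if (sum(tab$n_train) != target_train) {
      warn("Stratified rounding could not match the global train target exactly.")
    }

    assign <- strata %>% left_join(tab, by = ".stratum") %>%
      group_by(.data$.stratum) %>%
      mutate(.r = sample.int(n()),
             split = ifelse(.data$.r <= .data$n_train[1], "train", "test")) %>%
      ungroup()
    train_ids <- assign$id[assign$split == "train"]
    n_val <- round_half_up(spec$val_fraction_of_train * length(train_ids))
    val_ids <- if (n_val > 0) sample(train_ids, n_val) else character()
    out <- tibble(id = manifest$id,
                  split = assign$split[match(manifest$id, assign$id)])
    out$split[out$id %in% val_ids] <- "val"
  })
  attr(out, "split_spec") <- spec
  out
}

#' Partition id sets
#'
#' Convenience accessors over the `(id, split)` table from
#' [split_dataset()]. `train` excludes the validation ids (which were carved
#' out of the training set); `split_sizes()` reports the training total both
#' ways.
#'
#' @param partition Tibble from [split_dataset()].
#' @return `partition_ids()`: named list of character vectors `train`,
#'   `val`, `test`. `split_sizes()`: one-row tibble with `n_train_total`
#'   (train + val, the 8:2 training side), `n_train`, `n_val`, `n_test`.
#' @export
partition_ids <- function(partition) {
  list(train = partition$id[partition$split == "train"],
       val = partition$id[partition$split == "val"],
       test = partition$id[partition$split == "test"])
}

#' @rdname partition_ids
#' @export
split_sizes <- function(partition) {
  n <- table(factor(partition$split, levels = c("train", "val", "test")))
  tibble(n_train_total = unname(n["train"] + n["val"]),
         n_train = unname(n["train"]), n_val = unname(n["val"]),
         n_test = unname(n["test"]))
}
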