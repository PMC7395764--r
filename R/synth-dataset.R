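#' Generate a synthetic lettuce image dataset
#'
#' Renders `n_per_cultivar` plants for each cultivar, balanced across the
#' seven weekly growth sessions, writes the RGB images (PNG), depth maps
#' (16-bit TIFF, millimetres) and a trait table (CSV), and returns the
#' manifest.
#'
#' @param n_per_cultivar Plants per cultivar (>= 7, at least one per session).
#'   May also be a vector with one count per cultivar.
#' @param cultivars List of [cultivar_spec()]; defaults to the three-cultivar
#'   set of [default_cultivars()].
#' @param scene A [scene_spec()]; `scene$rng_seed` seeds the whole dataset.
#' @param out_dir Output directory (created if needed).
#' @param write_images If `FALSE`, renders nothing to disk and returns the
#'   manifest with in-memory samples attached as an attribute `samples`
#'   (used for fast in-memory pipelines).
#' @return A tibble manifest with columns `id`, `cultivar`, `session`,
#'   `rgb_path`, `depth_path`, `lfw_g`, `ldw_g`, `la_cm2`.
#' @export
generate_dataset <- function(n_per_cultivar, cultivars = default_cultivars(),
                             scene = scene_spec(), out_dir = NULL,
                             write_images = !is.null(out_dir)) {
  if (any(n_per_cultivar < 7)) {
    abort("`n_per_cultivar` must be >= 7 (at least one plant per session).")
  }
  counts <- rep_len(as.integer(n_per_cultivar), length(cultivars))
  if (write_images) {
    if (is.null(out_dir)) abort("`out_dir` is required when writing images.")
    dir.create(file.path(out_dir, "rgb"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "depth"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) abort(sprintf("Cannot create output directory: %s", out_dir))
  }

  rows <- list()
  samples <- list()
  k <- 0L
  for (ci in seq_along(cultivars)) {
    cv <- cultivars[[ci]]
    sessions <- sort(rep_len(1:7, counts[ci]))
    for (j in seq_len(counts[ci])) {
      k <- k + 1L
      sample_scene <- scene
      sample_scene$rng_seed <-
        as.integer((scene$rng_seed + 7919 * k + 104729 * ci) %% 2147483647)
      ps <- render_plant(cv, sessions[j], sample_scene)
      id <- sprintf("%s_s%d_%03d", cv$name, sessions[j], j)
      rgb_path <- if (write_images) file.path(out_dir, "rgb", paste0(id, ".png")) else NA_character_
      depth_path <- if (write_images) file.path(out_dir, "depth", paste0(id, ".tif")) else NA_character_
      if (write_images) {
        write_rgb(ps$rgb, rgb_path)
        write_depth(ps$depth, depth_path)
      } else {
        samples[[id]] <- ps
      }
      gt <- ps$ground_truth$traits
      rows[[k]] <- tibble(
        id = id, cultivar = cv$name, session = sessions[j],
        rgb_path = rgb_path, depth_path = depth_path,
        lfw_g = gt[["lfw_g"]], ldw_g = gt[["ldw_g"]], la_cm2 = gt[["la_cm2"]]
      )
    }
  }
  manifest <- bind_rows(rows)
  if (write_images) {
    # the CSV stores paths relative to the dataset directory so that a
    # regenerated dataset is byte-identical wherever it lives
    rel <- manifest %>% mutate(
      rgb_path = file.path("rgb", basename(.data$rgb_path)),
      depth_path = file.path("depth", basename(.data$depth_path)))
    readr::write_csv(rel, file.path(out_dir, "manifest.csv"))
    yaml::write_yaml(list(
      scene = unclass(scene),
      cultivars = lapply(cultivars, unclass),
      n_per_cultivar = counts
    ), file.path(out_dir, "generation_params.yaml"))
  } else {
    attr(manifest, "samples") <- samples
  }
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path Either a manifest CSV file or the dataset directory.
#' @return The manifest tibble.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  man <- readr::read_csv(path, show_col_types = FALSE)
  base <- dirname(path)
  man %>% mutate(rgb_path = file.path(base, .data$rgb_path),
                 depth_path = file.path(base, .data$depth_path))
}
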