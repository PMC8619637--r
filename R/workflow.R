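# Configuration handling and pipeline orchestration: train the matcher from
# the leading frames of a sequence, reconstruct a textured mesh for one
# frame, and track selected categories over a frame range. File outputs are
# written atomically (temp file + rename) so failed stages leave nothing
# partial behind.

config_defaults <- list(
  camera = list(focal_length_mm = 1.0, baseline_mm = 0.99,
                principal_point_px = c(159.5, 159.5),
                pixel_size_mm = 0.0015, vertical_tolerance_mm = NULL),
  matcher = list(lambda = 0.3, link_radius = 5, threshold = 0.08,
                 nonmax_radius = 8, n_train_frames = 20, epochs = 30,
                 learning_rate = 1e-3, batch_size = 64, dropout = 0.5,
                 conv1 = 64, conv2 = 128, fc = 1024, seed = 1),
  triangulation = list(margin_factor = 10),
  tracking = list(frames = NULL, fps = 25, fill_gaps = TRUE,
                  categories = "auto3"),
  paths = list(left_dir = NULL, right_dir = NULL, model = NULL,
               out_dir = NULL, mesh_format = "obj"),
  log_level = "info"
)

#' Build and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) with blocks `camera`, `matcher`,
#' `triangulation`, `tracking`, `paths` and `log_level`; every block is
#' validated before any stage runs and unknown keys are rejected. Missing
#' keys take the package defaults (the example camera block matches the
#' reference rig: f = 1 mm, b = 0.99 mm).
#'
#' @param source path of a YAML config file, or a list with the same
#'   structure.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = list()) {
  user <- if (is.character(source)) yaml::read_yaml(source) else source
  stopifnot(is.list(user))
  bad <- setdiff(names(user), names(config_defaults))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  cfg <- config_defaults
  for (blk in names(user)) {
    if (blk == "log_level") { cfg$log_level <- user$log_level; next }
    bad <- setdiff(names(user[[blk]]), names(config_defaults[[blk]]))
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  cam <- cfg$camera
  cfg$cam <- stereo_camera(
    focal_length = cam$focal_length_mm, baseline = cam$baseline_mm,
    principal_point = unlist(cam$principal_point_px),
    pixel_size = cam$pixel_size_mm,
    vertical_tolerance = cam$vertical_tolerance_mm %||% (2 * cam$pixel_size_mm))
  with(cfg$matcher, stopifnot(lambda > 0, lambda <= 1, link_radius > 0,
                              threshold > 0, n_train_frames >= 1))
  if (!cfg$log_level %in% c("debug", "info", "quiet"))
    stop("log_level must be debug, info or quiet")
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(cfg, level, ...) {
  lv <- c(debug = 1, info = 2, quiet = 3)
  if (lv[[level]] >= lv[[cfg$log_level %||% "info"]]) message(...)
}

#' Fit the feature matcher from training frames
#'
#' Detects features in the supplied left frames, links them into persistent
#' categories ([select_categories()]), cuts labelled 16x16 patches at every
#' chain observation and trains the patch classifier.
#'
#' @param left_frames list of grayscale left-frame matrices (the training
#'   span, e.g. the first 20 or 200 frames of a sequence).
#' @param lambda,link_radius category-selection settings, see
#'   [select_categories()].
#' @param threshold,nonmax_radius detector settings.
#' @param epochs,learning_rate,batch_size,dropout,seed training settings.
#' @param conv1,conv2,fc network widths, see [classifier_spec()].
#' @param verbose print training progress.
#' @return List with `model` (a `patch_classifier`), `categories` (the
#'   [select_categories()] data frame) and `n_patches`.
#' @export
fit_matcher <- function(left_frames, lambda = 0.3, link_radius = 5,
                        threshold = 0.08, nonmax_radius = 8, epochs = 30,
                        learning_rate = 1e-3, batch_size = 64, dropout = 0.5,
                        seed = 1, conv1 = 64, conv2 = 128, fc = 1024,
                        verbose = FALSE) {
  detections <- lapply(left_frames, detect_features, threshold = threshold,
                       nonmax_radius = nonmax_radius)
  categories <- select_categories(detections, lambda = lambda,
                                  link_radius = link_radius)
  obs <- attr(categories, "observations")
  n <- nrow(categories)
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, nrow(obs)))
  for (i in seq_len(nrow(obs)))
    patches[, , i] <- extract_patch(left_frames[[obs$frame[i]]],
                                    c(obs$u[i], obs$v[i]))
  spec <- classifier_spec(n, conv1 = conv1, conv2 = conv2, fc = fc,
                          dropout = dropout)
  model <- train_classifier(spec, patches, obs$category,
                            train_config(epochs = epochs,
                                         learning_rate = learning_rate,
                                         batch_size = batch_size,
                                         seed = seed, verbose = verbose))
  list(model = model, categories = categories, n_patches = nrow(obs))
}

read_frame_range <- function(cfg, idx) {
  pairs <- list_frame_pairs(cfg$paths$left_dir, cfg$paths$right_dir)
  if (any(idx < 1 | idx > nrow(pairs)))
    stop("frame range outside the available ", nrow(pairs), " frames")
  list(left = lapply(pairs$left[idx], read_frame),
       right = lapply(pairs$right[idx], read_frame),
       pairs = pairs[idx, , drop = FALSE])
}

#' Train the matcher from the leading frames of a sequence on disk
#'
#' Reads the first `matcher$n_train_frames` left frames, fits the matcher
#' ([fit_matcher()]) and writes the model checkpoint plus a JSON manifest
#' (category count, lambda, link radius, reference positions) to
#' `paths$model`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the [fit_matcher()] result.
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  k <- config$matcher$n_train_frames
  fr <- read_frame_range(config, seq_len(k))
  log_msg(config, "info", "training on ", k, " frames")
  fit <- fit_matcher(fr$left,
                     lambda = config$matcher$lambda,
                     link_radius = config$matcher$link_radius,
                     threshold = config$matcher$threshold,
                     nonmax_radius = config$matcher$nonmax_radius,
                     epochs = config$matcher$epochs,
                     learning_rate = config$matcher$learning_rate,
                     batch_size = config$matcher$batch_size,
                     dropout = config$matcher$dropout,
                     seed = config$matcher$seed,
                     conv1 = config$matcher$conv1,
                     conv2 = config$matcher$conv2, fc = config$matcher$fc)
  manifest <- list(n_categories = nrow(fit$categories),
                   lambda = config$matcher$lambda,
                   link_radius = config$matcher$link_radius,
                   categories = fit$categories[, c("category", "u", "v", "n_seen")])
  save_classifier(fit$model, config$paths$model, manifest = manifest)
  log_msg(config, "info", nrow(fit$categories), " categories, train accuracy ",
          sprintf("%.3f", fit$model$train_accuracy))
  invisible(fit)
}

#' Reconstruct a textured surface mesh for one frame pair
#'
#' Executes detect, classify, match, gate, recover, triangulate, mesh and
#' export for the given frame, writing the mesh (OBJ or PLY per
#' `paths$mesh_format`) and a JSON report of per-stage counts to
#' `paths$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param frame_index 1-based frame number in the paired sequence.
#' @return Invisibly, a list with `mesh`, `report` and the output paths.
#' @export
run_reconstruct <- function(config, frame_index) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- load_classifier(config$paths$model)
  fr <- read_frame_range(config, frame_index)
  m <- frame_matches(fr$left[[1]], fr$right[[1]], model,
                     threshold = config$matcher$threshold,
                     nonmax_radius = config$matcher$nonmax_radius)
  counts <- attr(m, "counts")
  rec <- reconstruct_surface(m, config$cam,
                             image_size = rev(dim(fr$left[[1]])),
                             left_image = fr$left[[1]])
  fmt <- config$paths$mesh_format
  mesh_path <- file.path(config$paths$out_dir,
                         sprintf("frame_%04d.%s", frame_index, fmt))
  export_mesh(rec$mesh, mesh_path, format = fmt)
  report <- c(list(frame = frame_index), as.list(counts), rec$report)
  report_path <- file.path(config$paths$out_dir,
                           sprintf("frame_%04d_report.json", frame_index))
  atomic_write(report_path, function(tmp)
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA))
  log_msg(config, "info", "frame ", frame_index, ": ",
          report$vertices, " vertices, ", report$faces, " faces")
  invisible(list(mesh = rec$mesh, report = report,
                 mesh_path = mesh_path, report_path = report_path))
}

#' Track feature categories over a frame range
#'
#' Tracks the configured categories (or, with `tracking$categories =
#' "auto3"`, the three categories nearest the category centroid) over
#' `tracking$frames`, optionally fills gaps, and writes the tracks CSV plus
#' a per-track motion-summary JSON to `paths$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `tracks`, `summaries` and output paths.
#' @export
run_track <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- load_classifier(config$paths$model)
  manifest <- attr(model, "manifest")
  rng <- config$tracking$frames
  pairs <- list_frame_pairs(config$paths$left_dir, config$paths$right_dir)
  idx <- if (is.null(rng)) seq_len(nrow(pairs)) else seq.int(rng[1], rng[2])
  fr <- read_frame_range(config, idx)
  cats <- config$tracking$categories
  if (identical(cats, "auto3")) {
    if (is.null(manifest$categories))
      stop("auto3 needs category reference positions in the model manifest")
    cats <- select_tracking_points(as.data.frame(manifest$categories),
                                   k = 3)$category
  }
  tracks <- track_categories(fr$left, fr$right, cats, model, config$cam,
                             threshold = config$matcher$threshold,
                             nonmax_radius = config$matcher$nonmax_radius,
                             frame_ids = idx)
  if (isTRUE(config$tracking$fill_gaps)) tracks <- lapply(tracks, fill_gaps)
  csv_path <- file.path(config$paths$out_dir, "tracks.csv")
  export_tracks(tracks, csv_path)
  summaries <- lapply(tracks, function(tr) {
    ms <- motion_summary(tr, fps = config$tracking$fps)
    list(category = tr$category, range = as.list(ms$range),
         period_frames = ms$period_frames, rate_per_min = ms$rate_per_min,
         blank_fraction = ms$blank_fraction)
  })
  sum_path <- file.path(config$paths$out_dir, "track_summaries.json")
  atomic_write(sum_path, function(tmp)
    jsonlite::write_json(summaries, tmp, auto_unbox = TRUE, digits = NA,
                         na = "null"))
  log_msg(config, "info", length(tracks), " tracks over ", length(idx),
          " frames")
  invisible(list(tracks = tracks, summaries = summaries,
                 csv_path = csv_path, summary_path = sum_path))
}
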