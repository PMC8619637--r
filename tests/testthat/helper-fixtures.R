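# Shared fixtures, built once per test run and cached: a reduced synthetic
# study (20 markers, 16 frames, narrow network) used by the matcher,
# tracking and workflow tests, and the full-size study used by the
# acceptance tests. Everything is generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

# Small study: 20 markers, 16 frames; matcher trained on the first 8 frames
# with a narrow network so the whole fixture builds in well under a minute.
small_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    scene <- generate_scene(scene_config(n_markers = 20, n_frames = 16,
                                         seed = 11))
    fit <- fit_matcher(scene$left[1:8], epochs = 30, learning_rate = 2e-3,
                       seed = 3, conv1 = 24, conv2 = 48, fc = 256)
    .fixture_env$small <- list(scene = scene, fit = fit)
  }
  .fixture_env$small
}

# Full-size synthetic study mirroring the reference protocol at desk scale:
# default scene (52 markers, 25 fps, 18.75-frame period, f = 1 / b = 0.99),
# 60 frames, matcher trained on the first 20 frames, matching and tracking
# evaluated on the held-out frames 21-60. Used by the acceptance tests; the
# first run is cached, the determinism check performs a second full run.
run_full_study <- function(seed = 1, out_dir = tempfile("study")) {
  scene <- generate_scene(scene_config(seed = seed))
  fit <- fit_matcher(scene$left[1:20], seed = seed)
  cam <- scene$config$cam
  held <- 21:60
  matches <- lapply(held, function(f)
    frame_matches(scene$left[[f]], scene$right[[f]], fit$model))
  cmap <- category_marker_map(scene, fit$categories)
  sel <- select_tracking_points(fit$categories, 3)
  irr_marker <- scene$truth$markers$marker[scene$truth$markers$irregular]
  irr_cat <- as.integer(names(cmap)[which(cmap == irr_marker)])
  cats <- unique(c(sel$category, irr_cat))
  tracks <- track_categories(scene$left[held], scene$right[held], cats,
                             fit$model, cam, frame_ids = held)
  ev <- evaluate_pipeline(scene, matches, held, tracks = tracks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tracks_csv <- file.path(out_dir, "tracks.csv")
  export_tracks(lapply(tracks, fill_gaps), tracks_csv)
  mesh_ply <- file.path(out_dir, "frame21.ply")
  rec <- reconstruct_surface(matches[[1]], cam,
                             image_size = scene$config$image_size)
  export_mesh(rec$mesh, mesh_ply, format = "ply")
  list(scene = scene, fit = fit, matches = matches, held = held,
       cmap = cmap, sel = sel, irr_cat = irr_cat, tracks = tracks,
       ev = ev, tracks_csv = tracks_csv, mesh_ply = mesh_ply,
       reconstruction = rec)
}

full_study_cached <- function() {
  if (is.null(.fixture_env$full)) .fixture_env$full <- run_full_study(seed = 1)
  .fixture_env$full
}
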