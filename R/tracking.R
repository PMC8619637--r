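# Class-based 3D feature tracking: the tracked category is re-detected and
# re-classified in every frame (no fixed sample frame, no adjacent-frame
# chaining), so a failure in one frame never propagates to later frames.
# Frames where the category is missing from either view, or where the pair
# fails the epipolar/disparity gates, are marked blank and can later be
# filled with the mean of the nearest observed neighbours.

new_feature_track <- function(category, frames, xyz, status) {
  structure(list(category = category, frames = frames, xyz = xyz,
                 status = status),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> category %d, %d frames (%d observed, %d blank, %d filled)\n",
              x$category, length(x$frames), sum(x$status == "observed"),
              sum(x$status == "blank"), sum(x$status == "filled")))
  invisible(x)
}

#' Track feature categories across a stereo sequence
#'
#' For every frame pair the full matching stage is recomputed (detection,
#' classification, match matrices); a tracked category contributes a 3D
#' position when it is retained on both sides and the pair passes the
#' epipolar and positive-disparity gates, otherwise the frame is recorded
#' as blank and tracking simply continues with the next frame.
#'
#' `track_categories()` shares the per-frame matching work across all
#' requested categories; `track_category()` is the single-category form.
#'
#' @param left_frames,right_frames lists of grayscale frame matrices (same
#'   length, in frame order).
#' @param categories integer vector of category labels to track.
#' @param model a trained [train_classifier()] model.
#' @param cam a [stereo_camera()].
#' @param threshold,nonmax_radius detector settings, see [detect_features()].
#' @param frame_ids optional frame numbers stored in the tracks (defaults to
#'   `seq_along(left_frames)`).
#' @return `track_categories()` returns a named list of `feature_track`
#'   objects (elements `category`, `frames`, `xyz` — an `n x 3` matrix with
#'   `NA` rows for blanks — and per-frame `status` in
#'   `{"observed", "blank"}`).
#' @export
track_categories <- function(left_frames, right_frames, categories, model,
                             cam, threshold = 0.08, nonmax_radius = 8,
                             frame_ids = NULL) {
  stopifnot(length(left_frames) == length(right_frames),
            length(left_frames) >= 1)
  categories <- as.integer(categories)
  if (any(categories < 1L | categories > model$spec$n_categories))
    stop("unknown category: labels must lie in 1..n_categories")
  nfr <- length(left_frames)
  frame_ids <- frame_ids %||% seq_len(nfr)
  tracks <- lapply(categories, function(cc)
    new_feature_track(cc, frame_ids, matrix(NA_real_, nfr, 3,
                                            dimnames = list(NULL, c("X", "Y", "Z"))),
                      rep("blank", nfr)))
  names(tracks) <- as.character(categories)
  for (f in seq_len(nfr)) {
    m <- frame_matches(left_frames[[f]], right_frames[[f]], model,
                       threshold = threshold, nonmax_radius = nonmax_radius)
    for (k in seq_along(categories)) {
      row <- which(m$category == categories[k])
      if (length(row) != 1) next
      pair <- image_point_pair(
        pixel_to_camera(c(m$lu[row], m$lv[row]), cam),
        pixel_to_camera(c(m$ru[row], m$rv[row]), cam))
      if (!epipolar_gate(pair, cam) || disparity(pair) <= 0) next
      tracks[[k]]$xyz[f, ] <- recover_point3d(pair, cam)
      tracks[[k]]$status[f] <- "observed"
    }
  }
  tracks
}

#' @rdname track_categories
#' @param category a single category label.
#' @export
track_category <- function(left_frames, right_frames, category, model, cam,
                           ...) {
  track_categories(left_frames, right_frames, category, model, cam, ...)[[1]]
}

#' Select tracking points nearest the feature centroid
#'
#' Computes the centroid of all category positions on the initial frame and
#' returns the `k` categories closest to it (Euclidean distance in the left
#' image), ties broken by category index.
#'
#' @param categories data frame with columns `category`, `u`, `v` (initial
#'   left-image positions, e.g. from [select_categories()]).
#' @param k number of categories to select (the reference protocol uses 3).
#' @return The selected rows of `categories`, in increasing distance order,
#'   with a `label` column `a`, `b`, `c`, ... added.
#' @export
select_tracking_points <- function(categories, k = 3) {
  stopifnot(is.data.frame(categories), k >= 1)
  if (nrow(categories) < k)
    stop("fewer than k categories available")
  cen <- c(mean(categories$u), mean(categories$v))
  d2 <- (categories$u - cen[1])^2 + (categories$v - cen[2])^2
  ord <- order(d2, categories$category)[seq_len(k)]
  out <- categories[ord, , drop = FALSE]
  out$label <- letters[seq_len(k)]
  rownames(out) <- NULL
  out
}

#' Fill blank track entries from adjacent observations
#'
#' Every blank frame with a non-blank predecessor and successor becomes the
#' arithmetic mean of the nearest non-blank neighbours on each side
#' (scanning left to right, so a run of blanks between two observations is
#' filled progressively from the observed values). Leading and trailing
#' blanks stay blank. Observed entries are never altered and the operation
#' is idempotent.
#'
#' @param track a `feature_track`.
#' @return The track with fillable blanks replaced (status `"filled"`).
#' @export
fill_gaps <- function(track) {
  stopifnot(inherits(track, "feature_track"))
  n <- length(track$frames)
  for (i in seq_len(n)) {
    if (track$status[i] != "blank") next
    prev <- if (i > 1) max(which(track$status[seq_len(i - 1)] != "blank"), -Inf) else -Inf
    nxt_candidates <- which(track$status[seq.int(i, n)] != "blank")
    nxt <- if (length(nxt_candidates)) i - 1 + min(nxt_candidates) else Inf
    if (!is.finite(prev) || !is.finite(nxt)) next
    track$xyz[i, ] <- (track$xyz[prev, ] + track$xyz[nxt, ]) / 2
    track$status[i] <- "filled"
  }
  track
}

# Mean-removed autocorrelation normalized by (n - k) overlapping terms, so a
# pure sinusoid gives r(k) ~ cos(2 pi k / T) without the triangular damping
# of the biased estimator.
autocorr_unbiased <- function(x, max_lag) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) return(rep(NA_real_, max_lag))
  n <- length(x)
  vapply(seq_len(max_lag), function(k)
    mean(x[seq_len(n - k)] * x[seq.int(k + 1, n)]) / v, numeric(1))
}

#' Summarize the motion of a feature track
#'
#' Reports the per-axis range (max - min over non-blank entries, after
#' internal gap filling), the dominant oscillation period and the implied
#' rate per minute. The period is the first significant local maximum of
#' the mean-removed autocorrelation of the axis with the largest range,
#' refined to sub-frame precision by parabolic interpolation; when no
#' autocorrelation peak reaches `significance`, the period is reported as
#' undefined (`NA`).
#'
#' @param track a `feature_track`.
#' @param fps frame rate of the sequence (frames per second).
#' @param significance minimum autocorrelation value accepted as a periodic
#'   peak (default 0.5).
#' @return An object of class `motion_summary`: list with `range` (named
#'   X/Y/Z, length units), `period_frames`, `rate_per_min`
#'   (`60 * fps / period`), `blank_fraction` and `n_observed`.
#' @export
motion_summary <- function(track, fps, significance = 0.5) {
  stopifnot(inherits(track, "feature_track"), fps > 0)
  filled <- fill_gaps(track)
  ok <- filled$status != "blank"
  xyz <- filled$xyz[ok, , drop = FALSE]
  rng <- if (nrow(xyz)) apply(xyz, 2, function(v) diff(range(v))) else
    c(X = 0, Y = 0, Z = 0)
  out <- list(range = rng,
              period_frames = NA_real_, rate_per_min = NA_real_,
              blank_fraction = mean(track$status == "blank"),
              n_observed = sum(track$status == "observed"))
  # period estimation on the contiguous non-blank core
  idx <- which(ok)
  if (length(idx) >= 8 && all(diff(idx) == 1) && max(rng) > 0) {
    axis <- which.max(rng)
    x <- filled$xyz[idx, axis]
    max_lag <- floor(length(x) * 2 / 3)
    if (max_lag >= 3) {
      r <- autocorr_unbiased(x, max_lag)
      peaks <- which(diff(sign(diff(c(-Inf, r, -Inf)))) < 0)  # local maxima
      peaks <- peaks[peaks >= 2 & peaks < max_lag & r[peaks] >= significance]
      if (length(peaks)) {
        k <- peaks[1]
        # parabolic sub-sample refinement through (k-1, k, k+1)
        y1 <- r[k - 1]; y2 <- r[k]; y3 <- r[k + 1]
        denom <- y1 - 2 * y2 + y3
        delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
        period <- k + max(-0.5, min(0.5, delta))
        out$period_frames <- period
        out$rate_per_min <- 60 * fps / period
      }
    }
  }
  structure(out, class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> range X %.4g Y %.4g Z %.4g; period %s frames; rate %s /min; blanks %.1f%%\n",
              x$range[1], x$range[2], x$range[3],
              ifelse(is.na(x$period_frames), "undefined",
                     sprintf("%.2f", x$period_frames)),
              ifelse(is.na(x$rate_per_min), "undefined",
                     sprintf("%.1f", x$rate_per_min)),
              100 * x$blank_fraction))
  invisible(x)
}

#' Write / read feature tracks as CSV
#'
#' Columns `frame, category, X, Y, Z, status` with one row per tracked
#' frame; blank frames carry empty coordinate fields. `read_tracks()`
#' reverses the writer exactly.
#'
#' @param tracks a list of `feature_track` objects.
#' @param path output CSV path.
#' @return `export_tracks()` returns `path` invisibly; `read_tracks()` the
#'   reconstructed list of tracks.
#' @export
export_tracks <- function(tracks, path) {
  if (inherits(tracks, "feature_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(frame = tr$frames, category = tr$category,
               X = tr$xyz[, 1], Y = tr$xyz[, 2], Z = tr$xyz[, 3],
               status = tr$status)))
  rows <- rows[order(rows$category, rows$frame), ]
  numfmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c("frame,category,X,Y,Z,status",
             paste(rows$frame, rows$category, numfmt(rows$X), numfmt(rows$Y),
                   numfmt(rows$Z), rows$status, sep = ","))
  atomic_write(path, function(tmp) writeLines(lines, tmp))
  invisible(path)
}

#' @rdname export_tracks
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$category), function(d) {
    d <- d[order(d$frame), ]
    new_feature_track(d$category[1], d$frame,
                      matrix(c(d$X, d$Y, d$Z), ncol = 3,
                             dimnames = list(NULL, c("X", "Y", "Z"))),
                      d$status)
  })
}
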